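>IscU_ref
LMWPCKLDFEAQNKNTPGVTNAGLQFSVLTPPYYHHCPMPQVYHSTQIEWFRFVTPGHQM
IRCLNPRQQHWHQIVQLCFETGMECNRNKNVRETNIQHLPPVKVWCAIQVAEDCFWLMCM
IPTNWCWL
>IscU_seed01
LMWNITLCLRKQNKPQPGVTNDMLFFPKLPQPGMVHCPMKGVYHHFQIFGSRFVKPGHQM
SLCGNARQQHPHQAVQFCREGGMSCNLNHNTFCTNIQNLPPVKVHCWIQVASDCFWLMAL
IPPNWCWL
>IscU_seed02
YMWNCKLSVRAQNKQQLGVTDAMLLSLVHTPPYYHHCPMPQVYNCAQAFWERFITPGLSN
ILCLSPNQQHTHQITQFNSAGGLEQARLHIVECTNIQHLPPVKPWCWLVSASDWFWCMAM
TPTNNHMH
>IscU_seed03
YYWNIKLDFEFRNKNTLDQFDDSLLFSVLIQPYQHHCWMKNVYCHTQIFWESFITMVLQM
ILCGNPNRQHTCQCYQLVSEGGEDCATNKNVRETNIQHLPPVKVACWVQSASIMGPCMCM
NPPWPCWL
>IscU_seed04
LYTPGDDCFRAQHKPQLHVFNDGGLFSVLIQWYYHHCCMKGVYHSTQAFGELEVKMIDQM
ARCGNPRQCHWCQAVQNCFEGCEDCNTLKNVRETNIQHLPPVKVHCAIQDAEICFCLMCL
NWNWNCWL
>IscU_seed05
LMTPGDLDFRAQAKNTPHWPCAMGQFPVKIPPGYHHCCYPQVACSFQDEWESFVTPVHQM
SRCLMPRRQHWAGIYQLNFATCMEQVRVHSVRIFNIQHLPPVKFWCAIQVAGAMVCLPCV
NPNNWCWL
>IscU_seed06
TMWNGKRDLKFRNLNTPGVTNASLQTLKLTLLYQHICWMEQPYCSAQIEWFSFVTMIHAM
IRCGSPNQQDWHQATQLCFLTGLSCARNKIHFEFNIQHLPPVKVWCALPDAGDCVWWMAL
IEPNWHWH
>IscU_seed07
YMWNGKLSLRFRATNTPGWTNASGFFPVLTPLPQHACPMPQVYHSTQDFYFRFVIPIDSN
SLCLNPRQCYTATIYQLCRLTGMDCNTNHNTREDNIQNLPPVKVWCAVQDAGDCFWCPCM
NPNNWPWL
>IscU_seed08
LYWNIKDDFEARALNTPDVFDAGLQTSVLIPLYYVHCCMPGPAHSAQAEWSSFIIMGHQM
ALCGNPRQQHTAGIVQNNREGGMESARLKNVREDSRRFLPPVKVWCYIPVEEDWGWLPAL
IWTNWCWH
>IscU_seed09
YGWPCDRDFEFRNLNYPGVPNWMLFTSKLPPWYYHHCPMPGPYHSADIFWFREQTYVLQM
IRCHNACQSDPCQCVNLCSETCLDCATLWNHRCTNIQHLPPVKPACAIQDEEAWVWLMCM
IPNNPCMQ
>IscU_seed10
TMWPCKDSFEAENTNTLDVTCDSGLSPVLIPWYMHHCWMENKAHSTQAIWFREVKMVDAM
SRCGNPRRCHWHGITQFCRLTHMSCNLLWNVRETSIFHLPPVKFACYMVDAEICFPWMCM
IPTNWCMH
>IscU_seed11
LMWNIKRDFEAQHTPQEGVTNAGLFFPVHTPPGYAHCWYPGKYHSFDIFWSRFVIPIHQM
ILCHSPRRSYTAGIVQLNRLTGEDCNTNHNTRIDSIQHLPPVKVWCAIPSAGACGWLWNL
IWNNPCEL
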