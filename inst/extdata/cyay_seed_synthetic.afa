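>CyaY_ref
CQCHEDVWFMNFLIANPPPCLTVRFWSVSGDMYVDTRWGYHATHEHADYMMVLIEPWMHA
NPVCTGRKCNWQDAGLEPIHNPNWVHCGNLTQNYITPGDM
>CyaY_seed01
KQIGEDVWFMNWLTANPPGDWLVSHWNVSVDLSVGDWCRRTATAGRDDYMCTCIQLEMHM
KPSCTGCKCNGQDAQHEPIETQDNLPQGIPGDNQIDPEKD
>CyaY_seed02
YHIHHDRDMMNFRIANPPGCLFVDRWNPCGCMSADTRWGCQATHAHLQYMCVLIEPWFHA
NAVCRGRKKMWQFAGLGNWHCATNVHQGNLTDSYIPPGDD
>CyaY_seed03
YQCHECVWFMNCDFAIPPNCRLVRFPSVSGCCSVDDWWRRHATHEHDDYMMTLIEPWIHM
NAVMTYAKCDVADSGGENTHNATNLHDEILDQAQIDWDDM
>CyaY_seed04
CPMHHWTDFMNFDIQNNWPCLTVSFWSVCRDMEVDTFWDYHATAGRADYCLVLIEAEMHA
NPGMTYCKDDWQDSQGEYIECPNWVWDSNLTYNYITWGDM
>CyaY_seed05
CQIGEDTWMTNCDIAIPPPCRLVRRWEVWGQCSVGGRLGRQATAGHDDYMMCWIHPWITM
KAVCTQRPKDWFDAGGGYIMNPTWDWCSICGQAYWPPGKM
>CyaY_seed06
KQCHEWVMFTCWRIANPWGCRTSSRWSVCVDCSADDRLRYQARAARDQYCMVWIEAEFHV
TPGCTYCKKNVQDLGGEYIHCATWVHCGCPTYNYIPWDVM
>CyaY_seed07
KQCHEDRDLMLWDTAIPPNCLFSRFWNVCGCLERVGRWGRTATEGRLDYMCCWIQLWITA
KPVCTGRKCMGQDAGLEPIHNPNNVWCGILTQNYHDMGDM
>CyaY_seed08
YPCGEWVWFKNCDFAQYPPCLFVRRPNYSVQMYVDTRCGCQATAGHDDYCLTWIHPWMHM
NAGCPYCKCNWQFSGLEYTHNADWVPDGCLGDSQHTPDKD
>CyaY_seed09
CQIGYDVMFTLCLIAIPWPCWTSRRWSYSGCCSVVTRCRRQARHEVADYMMVLIEAEITA
NPVCTYRKKMVFNAQLEYIHNQTGVWCECPTQSYIPMDDY
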