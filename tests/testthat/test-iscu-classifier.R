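test_that("detect_cys_columns finds invariant cysteines and applies the gate", {
  # three invariant Cys columns at reference 2, 5, 8
  rows <- setNames(as.list(rep("ACDKCLMCQ", 6)), paste0("s", 1:6))
  expect_equal(detect_cys_columns(tiny_seed(rows)), c(2, 5, 8))

  # a 4th column with Cys frequency 0.5 is excluded by the 0.95 gate
  rows2 <- list(a = "ACDKCLMCC", b = "ACDKCLMCC", c = "ACDKCLMCQ",
                d = "ACDKCLMCQ")
  expect_equal(detect_cys_columns(tiny_seed(rows2)), c(2, 5, 8))

  # fewer than three qualifying columns is an error naming the shortfall
  rows3 <- setNames(as.list(rep("ACDKCLMQQ", 4)), paste0("s", 1:4))
  expect_error(detect_cys_columns(tiny_seed(rows3)), "2 column")
})

test_that("the packaged scaffold seed carries Cys106 among its detected columns", {
  fx <- scaffold_fixture()
  expect_length(fx$cys, 3)
  expect_true(106 %in% fx$cys)
})

test_that("a canonical scaffold passes all four criteria", {
  fx <- scaffold_fixture()
  prot <- fx$profile$consensus
  g <- mini_genome("tA", c("hyp", "iscU", "hyp", "iscS", "hyp"),
                   c("MKL", prot, "MKL", "MKL", "MKL"))
  cal_hit <- local({
    a <- align_to_profile(prot, fx$profile)
    h <- fake_hit("tA", "tA_g02", a$aligned)
    h$flank_n <- a$flank_lengths[["n_term"]]
    h$flank_c <- a$flank_lengths[["c_term"]]
    h
  })
  cl <- check_criteria(cal_hit, g, fx$cys)
  expect_true(cl$c_cys)
  expect_true(cl$c_motif)
  expect_true(cl$c_nodomain)
  expect_true(cl$c_neighbor)  # iscS at neighbor distance 2
  expect_true(cl$accepted)
  expect_equal(cl$residue_108, "I")
})

test_that("acceptance is the conjunction of the four criteria", {
  fx <- scaffold_fixture()
  prot <- fx$profile$consensus
  a <- align_to_profile(prot, fx$profile)

  variants <- expand.grid(cys = c(TRUE, FALSE), motif = c(TRUE, FALSE),
                          nodom = c(TRUE, FALSE), neigh = c(TRUE, FALSE))
  for (v in seq_len(nrow(variants))) {
    w <- variants[v, ]
    aligned <- a$aligned
    if (!w$cys) aligned[as.character(fx$cys[1])] <- "A"
    if (!w$motif) aligned[c("99", "100")] <- c("A", "A")
    flank <- if (!w$nodom) 200 else 0
    labels <- if (w$neigh) c("iscS", "iscU") else c("hyp", "iscU")
    g <- mini_genome("tB", labels, c("MKL", prot))
    h <- fake_hit("tB", "tB_g02", aligned, flank_n = flank)
    cl <- check_criteria(h, g, fx$cys)
    expect_equal(cl$c_cys, w$cys)
    expect_equal(cl$c_motif, w$motif)
    expect_equal(cl$c_nodomain, w$nodom)
    expect_equal(cl$c_neighbor, w$neigh)
    expect_equal(cl$accepted, all(unlist(w)))
  }
})

test_that("the motif rule tolerates one non-Pro substitution but never a Pro change", {
  fx <- scaffold_fixture()
  base <- align_to_profile(fx$profile$consensus, fx$profile)$aligned
  g <- mini_genome("tC", c("iscS", "iscU"), c("MKL", "MKL"))

  one_sub <- base; one_sub["103"] <- "R" # LPPVR
  expect_true(check_criteria(fake_hit("tC", "tC_g02", one_sub), g,
                             fx$cys)$c_motif)
  two_sub <- base; two_sub[c("99", "103")] <- c("I", "R")
  expect_false(check_criteria(fake_hit("tC", "tC_g02", two_sub), g,
                              fx$cys)$c_motif)
  pro_sub <- base; pro_sub["100"] <- "A"
  expect_false(check_criteria(fake_hit("tC", "tC_g02", pro_sub), g,
                              fx$cys)$c_motif)
})

test_that("the neighborhood window is an inclusive +/-5 gene rule", {
  fx <- scaffold_fixture()
  aligned <- align_to_profile(fx$profile$consensus, fx$profile)$aligned
  # iscS exactly 5 genes upstream: passes
  labels5 <- c("iscS", rep("hyp", 4), "iscU")
  g5 <- mini_genome("tD", labels5, rep("MKL", 6))
  expect_true(check_criteria(fake_hit("tD", "tD_g06", aligned), g5,
                             fx$cys)$c_neighbor)
  # iscS at distance 6: fails
  labels6 <- c("iscS", rep("hyp", 5), "iscU")
  g6 <- mini_genome("tE", labels6, rep("MKL", 7))
  expect_false(check_criteria(fake_hit("tE", "tE_g07", aligned), g6,
                              fx$cys)$c_neighbor)
  # the hit gene itself does not count as its own neighbor
  g_self <- mini_genome("tF", c("iscU"), "MKL")
  expect_false(check_criteria(fake_hit("tF", "tF_g01", aligned), g_self,
                              fx$cys)$c_neighbor)
})

test_that("NifU-like and SufU-like decoys fail exactly their defining criterion", {
  fx <- scaffold_fixture()
  prot <- fx$profile$consensus
  set.seed(31)
  nifu <- paste0(prot, paste(sample(AA20, 200, replace = TRUE),
                             collapse = ""))
  sufu_chars <- strsplit(prot, "")[[1]]
  motif_cols <- ref_to_column(fx$profile, 99:103)
  sufu_chars[motif_cols] <- c("A", "G", "G", "A", "E")
  sufu <- paste(sufu_chars, collapse = "")

  g <- mini_genome("tG", c("iscS", "nifU-like", "sufU-like"),
                   c("MKL", nifu, sufu))
  cal <- calibrate_evalues(fx$profile,
                           replicate(30, random_query(150,
                                                      sample.int(1e6, 1))),
                           n_shuffles = 120, seed = 1)
  hits <- scan_proteome(g, fx$profile, cal, evalue_max = 0.1)
  expect_setequal(hits$locus_id, c("tG_g02", "tG_g03"))
  cl <- classify_hits(hits, structure(list(genomes = list(tG = g)),
                                      class = "corpus"), fx$cys)

  nifu_cl <- cl[cl$locus_id == "tG_g02", ]
  expect_false(nifu_cl$c_nodomain)
  expect_true(nifu_cl$c_cys && nifu_cl$c_motif && nifu_cl$c_neighbor)
  expect_false(nifu_cl$accepted)

  sufu_cl <- cl[cl$locus_id == "tG_g03", ]
  expect_false(sufu_cl$c_motif)
  expect_true(sufu_cl$c_cys && sufu_cl$c_nodomain && sufu_cl$c_neighbor)
  expect_false(sufu_cl$accepted)
})

test_that("residue_census counts accepted, deduplicated homologs", {
  mk <- function(taxon, res, accepted = TRUE, score = 100) {
    out <- data.frame(taxon_id = taxon, locus_id = paste0(taxon, "_l"),
                      c_cys = accepted, c_motif = accepted,
                      c_nodomain = accepted, c_neighbor = accepted,
                      accepted = accepted, residue_108 = res,
                      score_bits = score, stringsAsFactors = FALSE)
    out$aligned <- I(list(setNames(res, "108")))
    out
  }
  cl <- do.call(rbind, c(
    lapply(sprintf("t%02d", 1:5), mk, res = "I"),
    lapply(sprintf("t%02d", 6:8), mk, res = "L"),
    lapply(sprintf("t%02d", 9:10), mk, res = "M")))
  taxonomy <- data.frame(taxon_id = sprintf("t%02d", 1:10),
                         phylum = "P1", stringsAsFactors = FALSE)
  cen <- residue_census(cl, taxonomy, rank = "corpus")
  expect_equal(cen$counts$count[cen$counts$residue == "I"], 5)
  expect_equal(cen$counts$count[cen$counts$residue == "L"], 3)
  expect_equal(cen$counts$count[cen$counts$residue == "M"], 2)
  expect_equal(unname(cen$ilv_fraction), 0.8)
  expect_equal(sum(cen$counts$count), 10)

  # a second, lower-scoring accepted homolog in one taxon is deduplicated
  extra <- mk("t01", "V", score = 10)
  cen2 <- residue_census(rbind(cl, extra), taxonomy, rank = "corpus")
  expect_equal(sum(cen2$counts$count), 10)
  expect_false("V" %in% cen2$counts$residue)

  # rejected rows never enter the census; empty input -> empty census
  cen3 <- residue_census(mk("t99", "I", accepted = FALSE), taxonomy,
                         rank = "corpus")
  expect_equal(nrow(cen3$counts), 0)
})

test_that("logo information matches the closed forms", {
  mk_row <- function(taxon, residues) {
    out <- data.frame(taxon_id = taxon, locus_id = paste0(taxon, "_l"),
                      c_cys = TRUE, c_motif = TRUE, c_nodomain = TRUE,
                      c_neighbor = TRUE, accepted = TRUE,
                      residue_108 = residues[["108"]], score_bits = 100,
                      stringsAsFactors = FALSE)
    out$aligned <- I(list(residues))
    out
  }
  # all P at 99; 50/50 V/I at 100; uniform over all 20 residues at 101
  n <- 20
  rows <- lapply(seq_len(n), function(i) {
    mk_row(sprintf("t%02d", i),
           setNames(c("P", if (i <= 10) "V" else "I", AA20[i], "I"),
                    c("99", "100", "101", "108")))
  })
  cl <- do.call(rbind, rows)
  logo <- compute_logo(cl, region = c(99, 101))
  expect_equal(logo$information_bits[1], log2(20), tolerance = 1e-9)
  expect_equal(logo$information_bits[2], log2(20) - 1, tolerance = 1e-9)
  expect_equal(logo$information_bits[3], 0, tolerance = 1e-9)
  expect_equal(sum(logo[1, AA20]), 1)

  # information is invariant under row order
  logo_rev <- compute_logo(cl[rev(seq_len(nrow(cl))), ], region = c(99, 101))
  expect_equal(logo_rev$information_bits, logo$information_bits)
})
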