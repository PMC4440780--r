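# In-code fixtures shared by the tests.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# tiny ungapped seed alignment from explicit rows
tiny_seed <- function(rows, reference = names(rows)[1]) {
  seed_alignment(names(rows), unname(unlist(rows)), reference = reference)
}

# random profile for DP-oracle tests: L columns over a reduced or full
# alphabet, log-odds drawn directly
random_profile <- function(L, seed) {
  set.seed(seed)
  freq <- matrix(stats::rgamma(L * 20, shape = 0.5), L, 20)
  freq <- freq / rowSums(freq)
  colnames(freq) <- AA20
  background <- rep(1 / 20, 20)
  structure(list(
    freq = freq,
    log_odds = log2(freq / (1 / 20)),
    is_match = rep(TRUE, L),
    match_cols = seq_len(L),
    consensus = paste(AA20[apply(freq, 1, which.max)], collapse = ""),
    ref_number = seq_len(L),
    background = setNames(background, AA20),
    alpha = 0,
    name = "random",
    n_seqs = 0
  ), class = "profile_model")
}

random_query <- function(n, seed) {
  set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# a hand-built mini genome: gene labels and proteins supplied as vectors
mini_genome <- function(taxon_id, labels, proteins,
                        phylum = "Gammaproteobacteria") {
  genome(taxon_id,
         lineage = c(domain = "Bacteria", phylum = phylum),
         genes = data.frame(
           locus_id = sprintf("%s_g%02d", taxon_id, seq_along(labels)),
           order_index = seq_along(labels) - 1L,
           strand = "+",
           annotation_label = labels,
           protein = proteins,
           stringsAsFactors = FALSE))
}

# fabricate a one-row calibrated hit (for classifier unit tests)
fake_hit <- function(taxon_id, locus_id, aligned, flank_n = 0, flank_c = 0,
                     score = 100) {
  out <- data.frame(taxon_id = taxon_id, locus_id = locus_id,
                    family = "iscU", score_bits = score, evalue = 1e-20,
                    coverage = 1, flank_n = flank_n, flank_c = flank_c,
                    stringsAsFactors = FALSE)
  out$aligned <- I(list(aligned))
  out
}

# the scaffold profile/seed pair used across classifier tests
scaffold_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      seed <- iscutrace_seed("iscu")
      cache <<- list(seed = seed,
                     profile = build_profile(seed, name = "iscU"),
                     cys = detect_cys_columns(seed))
    }
    cache
  }
})
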