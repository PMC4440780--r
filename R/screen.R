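#' Scan a proteome with a calibrated profile
#'
#' Aligns every protein of a genome to the profile and returns the hits with
#' E-value at or below `evalue_max`, each carrying its alignment summary.
#' Deterministic given its inputs; an empty genome yields an empty hit table.
#'
#' @param genome a [genome()].
#' @param profile a `profile_model`.
#' @param calibration an `evalue_calibration` for this profile, built against
#'   a database size consistent with the corpus being scanned.
#' @param evalue_max E-value threshold (the domain-mode default of the CyaY /
#'   U-family retrieval policy is 0.1).
#' @param gap_open,gap_extend alignment gap costs.
#' @return data.frame of class `calibrated_hits` with columns `taxon_id`,
#'   `locus_id`, `family`, `score_bits`, `evalue`, `coverage`, `flank_n`,
#'   `flank_c` and a list-column `aligned` (named residue vector by reference
#'   position, as in [align_to_profile()]).
#' @export
scan_proteome <- function(genome, profile, calibration, evalue_max = 0.1,
                          gap_open = 4, gap_extend = 1) {
  stopifnot(inherits(genome, "genome"))
  fam <- if (is.null(profile$name)) "family" else profile$name
  genes <- genome$genes
  if (nrow(genes) == 0L) return(empty_hits())
  alns <- lapply(genes$protein, align_to_profile, profile = profile,
                 gap_open = gap_open, gap_extend = gap_extend)
  scores <- vapply(alns, `[[`, numeric(1), "score_bits")
  evals <- evalue(calibration, scores)
  keep <- which(evals <= evalue_max)
  if (!length(keep)) return(empty_hits())
  out <- data.frame(
    taxon_id = genome$taxon_id,
    locus_id = genes$locus_id[keep],
    family = fam,
    score_bits = scores[keep],
    evalue = evals[keep],
    coverage = vapply(alns[keep], `[[`, numeric(1), "coverage"),
    flank_n = vapply(alns[keep], function(a) a$flank_lengths[["n_term"]],
                     numeric(1)),
    flank_c = vapply(alns[keep], function(a) a$flank_lengths[["c_term"]],
                     numeric(1)),
    stringsAsFactors = FALSE
  )
  out$aligned <- I(lapply(alns[keep], `[[`, "aligned"))
  out <- out[order(-out$score_bits, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("calibrated_hits", class(out))
  out
}

empty_hits <- function() {
  out <- data.frame(taxon_id = character(0), locus_id = character(0),
                    family = character(0), score_bits = numeric(0),
                    evalue = numeric(0), coverage = numeric(0),
                    flank_n = integer(0), flank_c = integer(0),
                    stringsAsFactors = FALSE)
  out$aligned <- I(list())
  class(out) <- c("calibrated_hits", class(out))
  out
}

#' Scan every genome of a corpus
#'
#' @param corpus a `corpus`.
#' @inheritParams scan_proteome
#' @return A `calibrated_hits` data.frame over all genomes.
#' @export
scan_corpus <- function(corpus, profile, calibration, evalue_max = 0.1,
                        gap_open = 4, gap_extend = 1) {
  res <- lapply(corpus$genomes, scan_proteome, profile = profile,
                calibration = calibration, evalue_max = evalue_max,
                gap_open = gap_open, gap_extend = gap_extend)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Full-sequence retrieval policy
#'
#' Keeps hits whose alignment covers the profile over at least `min_coverage`
#' of its match columns and whose E-value is at or below `evalue_max`. This
#' operationalizes the requirement of homology with the entire CyaY sequence
#' (rather than a domain embedded in a larger fusion); the stringent
#' full-sequence E-value default is 1.7e-7.
#'
#' @param hits a `calibrated_hits` data.frame carrying alignments.
#' @param min_coverage minimum fraction of profile match columns aligned
#'   (default 0.9).
#' @param evalue_max E-value ceiling (default 1.7e-7).
#' @return The surviving subset of `hits`.
#' @export
apply_fullseq_policy <- function(hits, min_coverage = 0.9,
                                 evalue_max = 1.7e-7) {
  keep <- hits$coverage >= min_coverage & hits$evalue <= evalue_max
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a hits table to TSV
#'
#' @param hits a `calibrated_hits` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("taxon_id", "locus_id", "family", "score_bits", "evalue",
            "coverage", "flank_n", "flank_c")
  write.table(as.data.frame(hits)[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
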