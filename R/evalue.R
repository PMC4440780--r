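#' Calibrate empirical E-values for a profile against a target database
#'
#' Scores residue-shuffled decoys (drawn from randomly chosen target
#' sequences) against the profile and builds an empirical null: the survival
#' function is the empirical decoy distribution below its top decile and an
#' exponential tail fitted to the top decile above it. The E-value of a score
#' s is `E(s) = N * P(S >= s)` with N the database size; it is monotone
#' non-increasing in s and never exceeds N.
#'
#' @param profile a `profile_model`.
#' @param targets character vector of target protein sequences (the database).
#' @param n_shuffles number of shuffled decoys (>= 100; default 1000).
#' @param seed integer seed for decoy sampling and shuffling.
#' @param gap_open,gap_extend alignment gap costs, as in [align_to_profile()].
#' @param database_size N used in the E-value; defaults to `length(targets)`.
#' @return An object of class `evalue_calibration`: `n_decoys`,
#'   `decoy_scores` (sorted ascending), `tail_fit` (`location`, `scale` of the
#'   exponential tail), `tail_prob`, `database_size`, `seed`.
#' @export
calibrate_evalues <- function(profile, targets, n_shuffles = 1000, seed = 1,
                              gap_open = 4, gap_extend = 1,
                              database_size = length(targets)) {
  stopifnot(inherits(profile, "profile_model"))
  if (n_shuffles < 100) stop("n_shuffles must be >= 100")
  if (length(targets) < 1) stop("empty target database")

  set.seed(seed)
  idx <- sample.int(length(targets), n_shuffles, replace = TRUE)
  scores <- vapply(idx, function(i) {
    chars <- strsplit(targets[[i]], "")[[1]]
    decoy <- paste(chars[sample.int(length(chars))], collapse = "")
    align_to_profile(decoy, profile, gap_open, gap_extend)$score_bits
  }, numeric(1))

  scores <- sort(scores)
  k <- floor(n_shuffles / 10) # top decile
  s0 <- scores[n_shuffles - k]
  # fit strictly above s0 so the empirical part always dominates the tail at
  # the junction (E stays monotone even with ties at s0)
  tail_scores <- scores[scores > s0]
  if (length(tail_scores) < 10) {
    stop("fewer than 10 decoy scores in the tail-fit region")
  }
  scale <- mean(tail_scores - s0)
  if (!is.finite(scale) || scale <= 0) {
    stop("degenerate decoy score tail (scale <= 0); increase n_shuffles ",
         "or check the profile")
  }
  structure(list(
    n_decoys = n_shuffles,
    decoy_scores = scores,
    tail_fit = c(location = s0, scale = scale),
    tail_prob = length(tail_scores) / n_shuffles,
    database_size = database_size,
    seed = seed
  ), class = "evalue_calibration")
}

#' E-value of alignment scores under a calibration
#'
#' @param calibration an `evalue_calibration`.
#' @param score numeric vector of alignment scores in bits.
#' @return numeric vector of E-values (expected number of equal-or-better
#'   matches in a database of the calibrated size).
#' @export
evalue <- function(calibration, score) {
  stopifnot(inherits(calibration, "evalue_calibration"))
  s0 <- calibration$tail_fit[["location"]]
  scale <- calibration$tail_fit[["scale"]]
  p0 <- calibration$tail_prob
  M <- calibration$n_decoys
  N <- calibration$database_size
  sorted <- calibration$decoy_scores
  vapply(score, function(s) {
    if (s <= s0) {
      # empirical survival: fraction of decoys scoring >= s
      p <- (M - findInterval(s, sorted, left.open = TRUE)) / M
    } else {
      p <- p0 * exp(-(s - s0) / scale)
    }
    N * min(1, p)
  }, numeric(1))
}

#' @export
print.evalue_calibration <- function(x, ...) {
  cat("E-value calibration: ", x$n_decoys, " decoys, database size ",
      x$database_size, ", tail location ",
      format(x$tail_fit[["location"]], digits = 4), " scale ",
      format(x$tail_fit[["scale"]], digits = 4), "\n", sep = "")
  invisible(x)
}
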