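#' Build a column-wise profile model from a seed alignment
#'
#' Per-column residue frequencies use a background-weighted pseudocount:
#' `f(a) = (count(a) + alpha * background(a)) / (n_ungapped + alpha)`, where
#' `count` excludes gaps and `X`. Log-odds are `log2(f / background)` bits.
#' Columns whose gap fraction is >= 50% are marked non-match and excluded from
#' scoring; the consensus and reference numbering are carried on match
#' columns. Reference numbering is the 1-based ungapped residue numbering of
#' the reference row.
#'
#' @param seed a [seed_alignment()].
#' @param alpha nonnegative pseudocount weight (default 1).
#' @param background vector of 20 background probabilities in alphabet order
#'   (default uniform).
#' @param name optional family label carried on hits (e.g. `"iscU"`).
#' @return An object of class `profile_model` with elements `freq` and
#'   `log_odds` (L x 20 matrices over match columns), `is_match`,
#'   `consensus`, `ref_number` (reference residue number per match column, NA
#'   where the reference row is gapped), `background`, `alpha`, `name`.
#' @export
build_profile <- function(seed, alpha = 1, background = rep(1 / 20, 20),
                          name = NULL) {
  stopifnot(inherits(seed, "seed_alignment"))
  if (alpha < 0) stop("alpha must be nonnegative")
  if (length(background) != 20 || any(background <= 0)) {
    stop("background must be 20 positive probabilities")
  }
  background <- background / sum(background)
  names(background) <- AA_ALPHABET

  m <- seed_matrix(seed)
  ncol_aln <- ncol(m)
  is_gap <- m %in% GAP_CHARS
  dim(is_gap) <- dim(m)
  gap_frac <- colMeans(is_gap)
  is_match_all <- gap_frac < 0.5

  # reference numbering over all alignment columns
  ref_row <- m[seed$reference, ]
  ref_num_all <- rep(NA_integer_, ncol_aln)
  ref_num_all[!(ref_row %in% GAP_CHARS)] <-
    seq_len(sum(!(ref_row %in% GAP_CHARS)))

  match_cols <- which(is_match_all)
  L <- length(match_cols)
  if (L == 0L) stop("no match columns in seed alignment")

  freq <- matrix(NA_real_, L, 20, dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_len(L)) {
    col <- m[, match_cols[k]]
    col <- col[!(col %in% c(GAP_CHARS, "X"))]
    counts <- table(factor(col, levels = AA_ALPHABET))
    n_ungapped <- length(col)
    denom <- n_ungapped + alpha
    if (denom == 0) {
      freq[k, ] <- background
    } else {
      freq[k, ] <- (as.numeric(counts) + alpha * background) / denom
    }
  }
  log_odds <- log2(sweep(freq, 2, background, "/"))

  consensus <- apply(freq, 1, function(f) AA_ALPHABET[which.max(f)])

  structure(list(
    freq = freq,
    log_odds = log_odds,
    is_match = is_match_all,
    match_cols = match_cols,
    consensus = paste(consensus, collapse = ""),
    ref_number = ref_num_all[match_cols],
    background = background,
    alpha = alpha,
    name = name,
    n_seqs = length(seed$ids)
  ), class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat("Profile model", if (!is.null(x$name)) paste0(" '", x$name, "'"), ": ",
      nrow(x$freq), " match columns (", x$n_seqs, " seed rows, alpha=",
      x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Number of match columns of a profile
#' @param profile a `profile_model`.
#' @return integer count of match columns.
#' @export
profile_length <- function(profile) nrow(profile$freq)

#' Map reference residue numbers to match-column indices
#' @param profile a `profile_model`.
#' @param ref_positions integer vector of reference residue numbers.
#' @return integer vector of match-column indices (NA if unmapped).
#' @export
ref_to_column <- function(profile, ref_positions) {
  match(ref_positions, profile$ref_number)
}

#' Serialize a profile model to versioned JSON
#' @param profile a `profile_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(profile, path) {
  doc <- list(
    format = "iscutrace-profile",
    version = 1L,
    name = profile$name,
    alpha = profile$alpha,
    background = as.numeric(profile$background),
    alphabet = paste(AA_ALPHABET, collapse = ""),
    consensus = profile$consensus,
    ref_number = profile$ref_number,
    is_match = profile$is_match,
    match_cols = profile$match_cols,
    n_seqs = profile$n_seqs,
    freq = unname(apply(profile$freq, 1, as.numeric, simplify = FALSE))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a profile model from JSON
#' @param path path written by [write_profile_json()].
#' @return A `profile_model`.
#' @export
read_profile_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "iscutrace-profile")) {
    stop("not an iscutrace profile JSON: ", path)
  }
  freq <- if (is.matrix(doc$freq)) doc$freq else do.call(rbind, doc$freq)
  colnames(freq) <- AA_ALPHABET
  background <- setNames(doc$background, AA_ALPHABET)
  structure(list(
    freq = freq,
    log_odds = log2(sweep(freq, 2, background, "/")),
    is_match = doc$is_match,
    match_cols = doc$match_cols,
    consensus = doc$consensus,
    ref_number = as.integer(doc$ref_number),
    background = background,
    alpha = doc$alpha,
    name = doc$name,
    n_seqs = doc$n_seqs
  ), class = "profile_model")
}
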