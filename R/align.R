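#' Align a query sequence to a profile (glocal)
#'
#' Dynamic-programming alignment that is global in the profile (every match
#' column is consumed, matched or deleted) and local in the query (flanking
#' residues overhang unpenalized). A gap run of length k costs
#' `gap_open + k * gap_extend` bits. `X` residues score 0 bits in every
#' column. Traceback ties resolve match > deletion > insertion, so the path
#' is bit-reproducible.
#'
#' @param query amino-acid string (length >= 1). Characters outside the
#'   20-letter alphabet other than `X` are an error.
#' @param profile a `profile_model`.
#' @param gap_open gap-opening cost in bits (default 4).
#' @param gap_extend per-position gap-extension cost in bits (default 1).
#' @param query_id optional identifier carried on the result.
#' @return An object of class `profile_alignment`: `query_id`, `score_bits`,
#'   `path` (data.frame with `qpos`, `col` over matched positions; `col`
#'   indexes match columns 1..L), `coverage` (fraction of match columns
#'   aligned), `flank_lengths` (unaligned N-/C-terminal query residues), and
#'   `aligned` (named character vector: reference position -> query residue,
#'   for match columns with a reference number).
#' @export
align_to_profile <- function(query, profile, gap_open = 4, gap_extend = 1,
                             query_id = NULL) {
  stopifnot(inherits(profile, "profile_model"))
  query <- toupper(query)
  if (nchar(query) < 1L) stop("query must have length >= 1")
  qchars <- strsplit(query, "")[[1]]
  qidx <- match(qchars, AA_ALPHABET)
  bad <- qchars[is.na(qidx) & qchars != "X"]
  if (length(bad)) {
    stop("query contains characters outside the alphabet: ",
         paste(unique(bad), collapse = " "))
  }
  qidx[is.na(qidx)] <- 0L # 'X'
  res <- glocal_align_cpp(profile$log_odds, qidx - 1L, gap_open, gap_extend)

  path <- data.frame(qpos = res$path[, 1], col = res$path[, 2])
  L <- profile_length(profile)
  aligned <- character(0)
  if (nrow(path)) {
    refnum <- profile$ref_number[path$col]
    keep <- !is.na(refnum)
    aligned <- setNames(qchars[path$qpos[keep]], refnum[keep])
  }
  structure(list(
    query_id = query_id,
    score_bits = res$score,
    path = path,
    coverage = nrow(path) / L,
    flank_lengths = c(n_term = res$lead, c_term = res$trail),
    aligned = aligned
  ), class = "profile_alignment")
}

#' @export
print.profile_alignment <- function(x, ...) {
  cat("Profile alignment", if (!is.null(x$query_id)) paste0(" of ", x$query_id),
      ": ", format(x$score_bits, digits = 4), " bits, coverage ",
      format(x$coverage, digits = 3), ", flanks ", x$flank_lengths[1], "/",
      x$flank_lengths[2], "\n", sep = "")
  invisible(x)
}
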