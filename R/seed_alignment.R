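#' Seed alignment
#'
#' A small multiple alignment used to build a profile model. One row is the
#' reference row: its ungapped 1-based residue numbering anchors all
#' downstream reference positions (e.g. the scaffold motif at 99-103 and
#' position 108).
#'
#' @param ids character vector of sequence identifiers.
#' @param seqs character vector of gapped amino-acid strings, equal lengths.
#'   Alphabet: the 20 amino acids, gap characters `-`/`.`, and `X`.
#' @param reference id of the reference row.
#' @return An object of class `seed_alignment`.
#' @export
seed_alignment <- function(ids, seqs, reference = ids[[1]]) {
  if (length(ids) == 0L || length(seqs) == 0L) {
    stop("seed alignment is empty")
  }
  if (length(ids) != length(seqs)) {
    stop("ids and seqs differ in length")
  }
  seqs <- toupper(as.character(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("seed alignment rows have unequal lengths")
  }
  if (!reference %in% ids) {
    stop("reference row '", reference, "' not present in seed alignment")
  }
  ok <- c(AA_ALPHABET, GAP_CHARS, "X")
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(chars, ok)
  if (length(bad)) {
    stop("invalid characters in seed alignment: ", paste(bad, collapse = " "))
  }
  structure(list(ids = as.character(ids), seqs = seqs, reference = reference),
            class = "seed_alignment")
}

#' Read a seed alignment from aligned FASTA
#'
#' @param path path to an aligned FASTA file.
#' @param reference reference row id; defaults to the first record.
#' @return A [seed_alignment()].
#' @export
read_seed_alignment <- function(path, reference = NULL) {
  aln <- Biostrings::readAAStringSet(path)
  ids <- names(aln)
  if (is.null(reference)) reference <- ids[[1]]
  seed_alignment(ids, as.character(aln), reference = reference)
}

#' Write a seed alignment to aligned FASTA
#'
#' @param seed a [seed_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seed_alignment <- function(seed, path) {
  x <- Biostrings::AAStringSet(setNames(seed$seqs, seed$ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @export
print.seed_alignment <- function(x, ...) {
  cat("Seed alignment: ", length(x$ids), " rows x ", nchar(x$seqs[[1]]),
      " columns (reference: ", x$reference, ")\n", sep = "")
  invisible(x)
}

# character matrix view (rows x columns) of a seed alignment
seed_matrix <- function(seed) {
  m <- do.call(rbind, strsplit(seed$seqs, ""))
  rownames(m) <- seed$ids
  m
}
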