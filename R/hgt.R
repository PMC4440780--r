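#' Pairwise profile-anchored distances between family members
#'
#' Aligns each sequence to the family profile and computes, for every pair,
#' 1 - identity over the match columns where both sequences have an aligned
#' residue. Pairs with no jointly aligned column get distance 1.
#'
#' @param seqs named character vector of protein sequences.
#' @param profile the family `profile_model`.
#' @param gap_open,gap_extend alignment gap costs.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
seq_distances <- function(seqs, profile, gap_open = 4, gap_extend = 1) {
  n <- length(seqs)
  L <- profile_length(profile)
  res <- matrix(NA_character_, n, L)
  for (i in seq_len(n)) {
    a <- align_to_profile(seqs[[i]], profile, gap_open, gap_extend)
    qchars <- strsplit(toupper(seqs[[i]]), "")[[1]]
    res[i, a$path$col] <- qchars[a$path$qpos]
  }
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      both <- !is.na(res[i, ]) & !is.na(res[j, ])
      d[i, j] <- d[j, i] <- if (!any(both)) 1 else {
        1 - mean(res[i, both] == res[j, both])
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via \pkg{ape}) wrapped with a
#' deterministic cleanup: negative branch lengths are clamped to zero and the
#' deficit is moved to the sister branch, preserving path lengths between the
#' joined subtrees as far as possible.
#'
#' @param distances symmetric numeric matrix with zero diagonal (labelled).
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(distances) {
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(distances)) > 1e-12)) {
    stop("distance matrix must have a zero diagonal")
  }
  tree <- ape::nj(distances)
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sib <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sib)) {
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + deficit
    }
  }
  tree
}

#' Flag horizontal-transfer candidates by taxonomic incongruence
#'
#' For each leaf of a gene tree, the evidence score is the fraction of its k
#' nearest leaves (patristic distance) that belong to a different phylum. A
#' leaf is flagged iff evidence >= `threshold` and fewer than 2 of the k
#' neighbors share its phylum.
#'
#' @param gene_tree `phylo` tree over family members; tip labels are taxon
#'   ids.
#' @param taxonomy named character vector mapping taxon id to phylum.
#' @param k number of nearest neighbors (default 3).
#' @param threshold evidence threshold (default 1, i.e. all k neighbors
#'   foreign).
#' @return data.frame of class `hgt_flags`: `taxon_id`, `phylum`, `evidence`,
#'   `flagged`.
#' @export
flag_hgt <- function(gene_tree, taxonomy, k = 3, threshold = 1.0) {
  stopifnot(inherits(gene_tree, "phylo"), k >= 1)
  tips <- gene_tree$tip.label
  missing <- setdiff(tips, names(taxonomy))
  if (length(missing)) {
    stop("leaves absent from taxonomy: ", paste(missing, collapse = ", "))
  }
  if (length(tips) <= k) {
    stop("gene tree must have more than k leaves")
  }
  D <- ape::cophenetic.phylo(gene_tree)
  phyla <- taxonomy[tips]
  rows <- lapply(tips, function(t) {
    d <- D[t, setdiff(tips, t)]
    nn <- names(d)[order(d, names(d))][seq_len(k)]
    foreign <- phyla[nn] != phyla[t]
    evidence <- mean(foreign)
    data.frame(taxon_id = t, phylum = unname(phyla[t]), evidence = evidence,
               flagged = evidence >= threshold && sum(!foreign) < 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hgt_flags", class(out))
  out
}
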