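#' Default isc-operon gene vocabulary
#'
#' Labels counted as isc-related when checking the gene-neighborhood
#' criterion; drawn from the isc operon genes (iscRSUA-hscBA-fdx-iscX).
#' @return character vector of labels.
#' @export
default_isc_genes <- function() {
  c("iscR", "iscS", "iscU", "iscA", "hscB", "hscA", "fdx", "iscX")
}

#' Detect the conserved cysteine columns of a scaffold seed alignment
#'
#' Returns the reference positions of the three columns with the highest Cys
#' frequency (among ungapped residues), all of which must reach
#' `min_conservation`. For the canonical scaffold reference these are the
#' three cluster-ligand cysteines (including Cys106).
#'
#' @param seed the scaffold [seed_alignment()].
#' @param min_conservation minimum Cys frequency (default 0.95).
#' @return sorted integer vector of 3 reference positions.
#' @export
detect_cys_columns <- function(seed, min_conservation = 0.95) {
  m <- seed_matrix(seed)
  ref_row <- m[seed$reference, ]
  ref_num <- rep(NA_integer_, ncol(m))
  ref_num[!(ref_row %in% GAP_CHARS)] <- seq_len(sum(!(ref_row %in% GAP_CHARS)))

  cys_freq <- apply(m, 2, function(col) {
    col <- col[!(col %in% c(GAP_CHARS, "X"))]
    if (!length(col)) return(0)
    mean(col == "C")
  })
  qualifying <- which(cys_freq >= min_conservation & !is.na(ref_num))
  if (length(qualifying) < 3) {
    stop("only ", length(qualifying), " column(s) reach Cys conservation ",
         min_conservation, "; 3 required")
  }
  top <- qualifying[order(-cys_freq[qualifying], qualifying)][1:3]
  sort(ref_num[top])
}

#' Apply the four-criterion IscU acceptance rule to a hit
#'
#' A U-family hit is accepted as an IscU homolog only if (i) it carries Cys
#' at all three conserved cysteine reference positions, (ii) the residues
#' aligned at the chaperone-recognition motif positions (99-103) match the
#' motif pattern within the mismatch budget, (iii) it has no additional
#' domain, operationalized as both unaligned flanks being at most
#' `flank_max` residues, and (iv) at least one other isc-related gene lies
#' within `window` positions up- or downstream in the gene order.
#'
#' @param hit one row of a `calibrated_hits` data.frame (U-family).
#' @param genome the [genome()] the hit belongs to.
#' @param cys_columns integer vector of 3 reference positions, from
#'   [detect_cys_columns()].
#' @param motif_pattern motif string anchored at `motif_start` (default
#'   `"LPPVK"`).
#' @param motif_start reference position of the first motif residue (99).
#' @param motif_max_mismatch substitutions tolerated at non-Pro motif
#'   positions (default 1; mismatches at Pro positions always fail).
#' @param isc_gene_set labels counted as isc-related neighbors.
#' @param window neighborhood radius in gene-order positions (default 5).
#' @param flank_max maximum unaligned flank length in residues (default 50).
#' @param ref_position reference position whose residue is reported
#'   (default 108).
#' @return one-row data.frame: `taxon_id`, `locus_id`, `c_cys`, `c_motif`,
#'   `c_nodomain`, `c_neighbor`, `accepted`, `residue_108`, `score_bits`,
#'   plus the hit's `aligned` list-column.
#' @export
check_criteria <- function(hit, genome, cys_columns,
                           motif_pattern = "LPPVK", motif_start = 99,
                           motif_max_mismatch = 1,
                           isc_gene_set = default_isc_genes(),
                           window = 5, flank_max = 50, ref_position = 108) {
  aligned <- hit$aligned[[1]]
  if (is.null(aligned)) stop("hit carries no alignment")

  # (i) conserved cysteines
  got <- aligned[as.character(cys_columns)]
  c_cys <- length(cys_columns) == 3 && !any(is.na(got)) && all(got == "C")

  # (ii) chaperone-recognition motif at 99-103
  pat <- strsplit(motif_pattern, "")[[1]]
  pos <- motif_start + seq_along(pat) - 1L
  obs <- aligned[as.character(pos)]
  if (any(is.na(obs))) {
    c_motif <- FALSE
  } else {
    mismatch <- obs != pat
    fixed <- pat == "P" # prolines must match exactly
    c_motif <- !any(mismatch & fixed) &&
      sum(mismatch & !fixed) <= motif_max_mismatch
  }

  # (iii) no additional domain: bounded unaligned flanks
  c_nodomain <- hit$flank_n <= flank_max && hit$flank_c <= flank_max

  # (iv) >= 1 other isc-related gene within +/- window positions
  genes <- genome$genes
  self <- match(hit$locus_id, genes$locus_id)
  if (is.na(self)) stop("hit locus ", hit$locus_id, " not in genome ",
                        genome$taxon_id)
  dist <- abs(genes$order_index - genes$order_index[self])
  c_neighbor <- any(dist >= 1 & dist <= window &
                      genes$annotation_label %in% isc_gene_set)

  res108 <- aligned[as.character(ref_position)]
  out <- data.frame(
    taxon_id = hit$taxon_id, locus_id = hit$locus_id,
    c_cys = c_cys, c_motif = c_motif, c_nodomain = c_nodomain,
    c_neighbor = c_neighbor,
    accepted = c_cys && c_motif && c_nodomain && c_neighbor,
    residue_108 = if (is.na(res108)) NA_character_ else unname(res108),
    score_bits = hit$score_bits,
    stringsAsFactors = FALSE
  )
  out$aligned <- hit$aligned
  out
}

#' Classify all U-family hits of a corpus
#'
#' @param hits a `calibrated_hits` data.frame of U-family hits.
#' @param corpus the `corpus` the hits come from.
#' @param cys_columns from [detect_cys_columns()].
#' @param ... further arguments passed to [check_criteria()].
#' @return data.frame of per-hit classifications (one row per hit).
#' @export
classify_hits <- function(hits, corpus, cys_columns, ...) {
  if (nrow(hits) == 0L) return(empty_classifications())
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    g <- corpus$genomes[[hits$taxon_id[i]]]
    if (is.null(g)) stop("hit references unknown taxon ", hits$taxon_id[i])
    check_criteria(hits[i, , drop = FALSE], g, cys_columns, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_classifications <- function() {
  out <- data.frame(taxon_id = character(0), locus_id = character(0),
                    c_cys = logical(0), c_motif = logical(0),
                    c_nodomain = logical(0), c_neighbor = logical(0),
                    accepted = logical(0), residue_108 = character(0),
                    score_bits = numeric(0), stringsAsFactors = FALSE)
  out$aligned <- I(list())
  out
}

# one representative (highest score, ties by locus id) per taxon
dedupe_per_taxon <- function(classifications) {
  cl <- classifications
  ord <- order(cl$taxon_id, -cl$score_bits, cl$locus_id)
  cl <- cl[ord, , drop = FALSE]
  cl <- cl[!duplicated(cl$taxon_id), , drop = FALSE]
  rownames(cl) <- NULL
  cl
}

#' Census of the residue at reference position 108
#'
#' Counts the residue observed at the reference position across accepted
#' classifications, one representative per species (the highest-scoring
#' accepted homolog), grouped by a taxonomy rank. Also reports the fraction
#' of branched-chain residues Ile/Leu/Val per group.
#'
#' @param classifications output of [classify_hits()].
#' @param taxonomy data.frame with `taxon_id` and rank columns (e.g.
#'   `phylum`, `domain`).
#' @param rank grouping rank: a column of `taxonomy`, or `"corpus"` for a
#'   single group.
#' @return An object of class `residue_census`: `counts` (data.frame `group`,
#'   `residue`, `count`), `totals`, `ilv_fraction` per group, `rank`.
#' @export
residue_census <- function(classifications, taxonomy, rank = "phylum") {
  cl <- classifications[classifications$accepted &
                          !is.na(classifications$residue_108), , drop = FALSE]
  cl <- dedupe_per_taxon(cl)
  if (rank == "corpus") {
    group <- rep("corpus", nrow(cl))
  } else {
    if (!rank %in% names(taxonomy)) stop("unknown taxonomy rank: ", rank)
    group <- taxonomy[[rank]][match(cl$taxon_id, taxonomy$taxon_id)]
  }
  if (nrow(cl) == 0L) {
    return(structure(list(
      counts = data.frame(group = character(0), residue = character(0),
                          count = integer(0)),
      totals = integer(0), ilv_fraction = numeric(0), rank = rank),
      class = "residue_census"))
  }
  tab <- table(group = group, residue = cl$residue_108)
  counts <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(counts) <- c("group", "residue", "count")
  counts <- counts[counts$count > 0, , drop = FALSE]
  counts <- counts[order(counts$group, counts$residue), , drop = FALSE]
  rownames(counts) <- NULL
  totals <- tapply(counts$count, counts$group, sum)
  ilv <- tapply(counts$count * (counts$residue %in% c("I", "L", "V")),
                counts$group, sum)
  structure(list(counts = counts,
                 totals = as.integer(totals)[order(names(totals))] |>
                   setNames(sort(names(totals))),
                 ilv_fraction = (ilv / totals)[sort(names(totals))],
                 rank = rank),
            class = "residue_census")
}

#' @export
print.residue_census <- function(x, ...) {
  cat("Residue-108 census by ", x$rank, ": ", sum(x$counts$count),
      " accepted homologs\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Sequence logo over a reference region
#'
#' Per-column residue frequencies (gaps excluded from the denominator) and
#' information content `R = log2(20) - H` in bits, computed from the aligned
#' residues of accepted classifications. A column with zero aligned residues
#' has undefined information, reported as NA.
#'
#' @param classifications output of [classify_hits()]; only accepted rows are
#'   used.
#' @param region inclusive reference-position range (default `c(99, 108)`).
#' @return data.frame of class `sequence_logo` with `ref_position`, one
#'   frequency column per amino acid, and `information_bits`.
#' @export
compute_logo <- function(classifications, region = c(99, 108)) {
  cl <- classifications[classifications$accepted, , drop = FALSE]
  positions <- seq(region[1], region[2])
  rows <- lapply(positions, function(p) {
    res <- vapply(cl$aligned, function(a) {
      r <- a[as.character(p)]
      if (is.null(r) || is.na(r)) NA_character_ else unname(r)
    }, character(1))
    res <- res[!is.na(res) & res %in% AA_ALPHABET]
    n <- length(res)
    if (n == 0) {
      freq <- setNames(rep(NA_real_, 20), AA_ALPHABET)
      info <- NA_real_
    } else {
      freq <- as.numeric(table(factor(res, levels = AA_ALPHABET))) / n
      names(freq) <- AA_ALPHABET
      p_pos <- freq[freq > 0]
      info <- log2(20) + sum(p_pos * log2(p_pos))
    }
    c(list(ref_position = p), as.list(freq), list(information_bits = info))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  class(out) <- c("sequence_logo", class(out))
  out
}

#' Write classification, census, or logo tables to TSV
#'
#' @param classifications output of [classify_hits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classifications_tsv <- function(classifications, path) {
  cols <- c("taxon_id", "locus_id", "c_cys", "c_motif", "c_nodomain",
            "c_neighbor", "accepted", "residue_108")
  write.table(as.data.frame(classifications)[, cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
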