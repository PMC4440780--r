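#' Genome container
#'
#' One species' ordered gene list with protein sequences and taxonomy labels.
#'
#' @param taxon_id unique taxon identifier.
#' @param name display name.
#' @param lineage named character vector of rank labels (e.g.
#'   `c(domain = "Bacteria", phylum = "Gammaproteobacteria")`).
#' @param genes data.frame with columns `locus_id`, `order_index` (contiguous
#'   0-based position on the replicon), `strand` (`+`/`-`),
#'   `annotation_label`, `protein` (non-empty amino-acid string).
#' @return An object of class `genome`.
#' @export
genome <- function(taxon_id, name = taxon_id, lineage = character(0), genes) {
  req <- c("locus_id", "order_index", "strand", "annotation_label", "protein")
  if (!all(req %in% names(genes))) {
    stop("genes table lacks columns: ",
         paste(setdiff(req, names(genes)), collapse = ", "))
  }
  genes <- genes[order(genes$order_index), , drop = FALSE]
  if (!identical(as.integer(genes$order_index),
                 seq_len(nrow(genes)) - 1L)) {
    stop("gene order_index must be contiguous 0..n-1 in genome ", taxon_id)
  }
  if (anyDuplicated(genes$locus_id)) {
    stop("duplicated locus_id in genome ", taxon_id)
  }
  if (any(!nzchar(genes$protein))) {
    stop("empty protein sequence in genome ", taxon_id)
  }
  rownames(genes) <- NULL
  structure(list(taxon_id = taxon_id, name = name, lineage = lineage,
                 genes = genes), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("Genome ", x$taxon_id, " (", x$name, "): ", nrow(x$genes), " genes\n",
      sep = "")
  invisible(x)
}

#' Read a simulated or external corpus from disk
#'
#' Expects the layout written by [simulate_corpus()]: `genomes/<taxon>.faa`
#' (headers `taxon_id|locus_id`), `genes.tsv`, `taxonomy.tsv`, `tree.nwk`,
#' and optionally `truth.json`.
#'
#' @param dir corpus directory.
#' @return A `corpus` list: `genomes` (named list of [genome()]), `taxonomy`
#'   (data.frame), `tree` (ape `phylo` or NULL), `truth` (list or NULL).
#' @export
read_corpus <- function(dir) {
  genes <- read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  taxonomy <- read.delim(file.path(dir, "taxonomy.tsv"),
                         stringsAsFactors = FALSE)
  fa_dir <- file.path(dir, "genomes")
  genomes <- list()
  for (i in seq_len(nrow(taxonomy))) {
    tid <- taxonomy$taxon_id[i]
    aln <- Biostrings::readAAStringSet(file.path(fa_dir, paste0(tid, ".faa")))
    loci <- sub("^[^|]*\\|", "", names(aln))
    prot <- setNames(as.character(aln), loci)
    g <- genes[genes$taxon_id == tid, , drop = FALSE]
    if (!all(g$locus_id %in% loci)) {
      stop("gene table references loci without sequences in ", tid)
    }
    g$protein <- unname(prot[g$locus_id])
    lineage <- c(domain = taxonomy$domain[i], phylum = taxonomy$phylum[i])
    genomes[[tid]] <- genome(tid, name = taxonomy$name[i], lineage = lineage,
                             genes = g[, c("locus_id", "order_index", "strand",
                                           "annotation_label", "protein")])
  }
  tree_path <- file.path(dir, "tree.nwk")
  tree <- if (file.exists(tree_path)) ape::read.tree(tree_path) else NULL
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  structure(list(genomes = genomes, taxonomy = taxonomy, tree = tree,
                 truth = truth), class = "corpus")
}

#' Write a corpus to disk in the pipeline input layout
#'
#' @param corpus a `corpus` object (as from [simulate_corpus()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  gene_rows <- list()
  for (g in corpus$genomes) {
    seqs <- setNames(g$genes$protein,
                     paste0(g$taxon_id, "|", g$genes$locus_id))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(seqs),
      file.path(dir, "genomes", paste0(g$taxon_id, ".faa")))
    tab <- g$genes[, c("locus_id", "order_index", "strand",
                       "annotation_label")]
    tab <- cbind(taxon_id = g$taxon_id, tab)
    gene_rows[[g$taxon_id]] <- tab
  }
  write.table(do.call(rbind, gene_rows), file.path(dir, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(corpus$taxonomy, file.path(dir, "taxonomy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(corpus$tree)) {
    ape::write.tree(corpus$tree, file.path(dir, "tree.nwk"))
  }
  if (!is.null(corpus$truth)) {
    jsonlite::write_json(corpus$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

# all proteins of a corpus as a named character vector "taxon|locus" -> seq
corpus_proteins <- function(corpus) {
  out <- lapply(corpus$genomes, function(g) {
    setNames(g$genes$protein, paste0(g$taxon_id, "|", g$genes$locus_id))
  })
  unlist(unname(out))
}
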