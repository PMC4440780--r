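#' Default pipeline run configuration
#'
#' All thresholds of the analysis in one structure. The retrieval defaults
#' follow the published policy: domain-mode E-value 0.1, full-sequence CyaY
#' E-value 1.7e-7 with coverage 0.9, a +/-5 gene neighborhood window, and the
#' LPPVK motif with at most one substitution at non-Pro positions.
#'
#' @param corpus_dir corpus directory (NULL when `simulate = TRUE`).
#' @param out_dir output directory for run artifacts (NULL: no files
#'   written).
#' @param simulate simulate the corpus instead of reading `corpus_dir`.
#' @param sim_config [simulation_config()] used when simulating.
#' @param seed integer seed for calibration decoys (and simulation unless
#'   `sim_config` overrides it).
#' @param evalue_domain domain-mode screening threshold.
#' @param evalue_fullseq full-sequence CyaY threshold.
#' @param min_coverage full-sequence coverage floor.
#' @param motif_pattern,motif_max_mismatch motif criterion settings.
#' @param flank_max unaligned-flank ceiling for the no-extra-domain
#'   criterion.
#' @param window gene-neighborhood radius.
#' @param min_conservation Cys-column conservation gate.
#' @param census_rank taxonomy rank for the residue census.
#' @param parsimony_mode `"dollo"`, `"fitch"`, or `"both"`.
#' @param hgt_k,hgt_threshold k-NN incongruence settings.
#' @param n_shuffles decoys per calibration.
#' @param gap_open,gap_extend alignment gap costs (bits).
#' @return list of class `run_config`.
#' @export
run_config <- function(corpus_dir = NULL, out_dir = NULL, simulate = TRUE,
                       sim_config = simulation_config(seed = seed),
                       seed = 1,
                       evalue_domain = 0.1, evalue_fullseq = 1.7e-7,
                       min_coverage = 0.9,
                       motif_pattern = "LPPVK", motif_max_mismatch = 1,
                       flank_max = 50, window = 5, min_conservation = 0.95,
                       census_rank = "phylum",
                       parsimony_mode = "both",
                       hgt_k = 3, hgt_threshold = 1.0,
                       n_shuffles = 1000, gap_open = 4, gap_extend = 1) {
  stopifnot(evalue_domain > 0, evalue_fullseq > 0,
            min_coverage >= 0, min_coverage <= 1,
            flank_max >= 0, window >= 1, hgt_k >= 1,
            hgt_threshold >= 0, hgt_threshold <= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Read a YAML run configuration
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error.
#'
#' @param path YAML file.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Validate corpus input files
#'
#' Cross-checks FASTA, gene table, taxonomy and tree: every gene-table locus
#' must have a sequence, every taxon a FASTA file, and tree leaves must match
#' corpus taxa. Returns diagnostics rather than raising errors.
#'
#' @param dir corpus directory.
#' @return character vector of diagnostics; empty on success.
#' @export
validate_inputs <- function(dir) {
  diags <- character(0)
  need <- c("genes.tsv", "taxonomy.tsv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      diags <- c(diags, paste0("missing file: ", f))
    }
  }
  if (length(diags)) return(diags)
  genes <- read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  taxonomy <- read.delim(file.path(dir, "taxonomy.tsv"),
                         stringsAsFactors = FALSE)
  for (tid in taxonomy$taxon_id) {
    fa <- file.path(dir, "genomes", paste0(tid, ".faa"))
    if (!file.exists(fa)) {
      diags <- c(diags, paste0("missing proteome FASTA for taxon ", tid))
      next
    }
    aln <- Biostrings::readAAStringSet(fa)
    loci <- sub("^[^|]*\\|", "", names(aln))
    g <- genes$locus_id[genes$taxon_id == tid]
    orphan <- setdiff(g, loci)
    if (length(orphan)) {
      diags <- c(diags, paste0("gene table references missing locus ",
                               orphan, " in taxon ", tid))
    }
  }
  extra_tax <- setdiff(unique(genes$taxon_id), taxonomy$taxon_id)
  if (length(extra_tax)) {
    diags <- c(diags, paste0("gene table references unknown taxon ",
                             extra_tax))
  }
  tree_path <- file.path(dir, "tree.nwk")
  if (file.exists(tree_path)) {
    tree <- ape::read.tree(tree_path)
    orphan_leaf <- setdiff(tree$tip.label, taxonomy$taxon_id)
    if (length(orphan_leaf)) {
      diags <- c(diags, paste0("tree leaf not in corpus: ", orphan_leaf))
    }
    no_leaf <- setdiff(taxonomy$taxon_id, tree$tip.label)
    if (length(no_leaf)) {
      diags <- c(diags, paste0("corpus taxon not in tree: ", no_leaf))
    }
  }
  diags
}

#' Run the full evolutionary analysis pipeline
#'
#' simulate/load -> screen -> classify -> census/logo -> co-occurrence ->
#' parsimony reconstruction -> HGT flagging. Deterministic and idempotent
#' for a fixed config.
#'
#' @param config a [run_config()].
#' @param iscu_seed,cyay_seed seed alignments (default: packaged synthetic
#'   seeds).
#' @return list of class `run_report`: stage record counts, census,
#'   co-occurrence report, reconstructions per family and mode, HGT flags,
#'   and provenance (seed, thresholds, stage timings). When `out_dir` is set,
#'   all TSV/JSON artifacts and a manifest are written there.
#' @export
run_pipeline <- function(config = run_config(),
                         iscu_seed = iscutrace_seed("iscu"),
                         cyay_seed = iscutrace_seed("cyay")) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- numeric(0)
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  # stage: corpus
  if (config$simulate) {
    corpus <- simulate_corpus(config$sim_config, iscu_seed, cyay_seed)
  } else {
    if (is.null(config$corpus_dir)) stop("corpus_dir required")
    diags <- validate_inputs(config$corpus_dir)
    if (length(diags)) {
      stop("corpus validation failed:\n  ", paste(diags, collapse = "\n  "))
    }
    corpus <- read_corpus(config$corpus_dir)
  }
  taxa <- corpus$taxonomy$taxon_id
  tick("corpus")

  # stage: profiles + calibration
  iscu_profile <- build_profile(iscu_seed, name = "iscU")
  cyay_profile <- build_profile(cyay_seed, name = "cyaY")
  proteins <- corpus_proteins(corpus)
  iscu_cal <- calibrate_evalues(iscu_profile, proteins,
                                n_shuffles = config$n_shuffles,
                                seed = config$seed,
                                gap_open = config$gap_open,
                                gap_extend = config$gap_extend)
  cyay_cal <- calibrate_evalues(cyay_profile, proteins,
                                n_shuffles = config$n_shuffles,
                                seed = config$seed + 1L,
                                gap_open = config$gap_open,
                                gap_extend = config$gap_extend)
  tick("calibration")

  # stage: screening
  u_hits <- scan_corpus(corpus, iscu_profile, iscu_cal,
                        evalue_max = config$evalue_domain,
                        gap_open = config$gap_open,
                        gap_extend = config$gap_extend)
  cyay_domain_hits <- scan_corpus(corpus, cyay_profile, cyay_cal,
                                  evalue_max = config$evalue_domain,
                                  gap_open = config$gap_open,
                                  gap_extend = config$gap_extend)
  cyay_hits <- apply_fullseq_policy(cyay_domain_hits,
                                    min_coverage = config$min_coverage,
                                    evalue_max = config$evalue_fullseq)
  cyay_hits <- dedupe_hits_per_taxon(cyay_hits)
  tick("screen")

  # stage: classification + census + logo
  cys_columns <- detect_cys_columns(iscu_seed, config$min_conservation)
  classifications <- classify_hits(
    u_hits, corpus, cys_columns,
    motif_pattern = config$motif_pattern,
    motif_max_mismatch = config$motif_max_mismatch,
    window = config$window, flank_max = config$flank_max)
  census <- residue_census(classifications, corpus$taxonomy,
                           rank = config$census_rank)
  census_all <- residue_census(classifications, corpus$taxonomy,
                               rank = "corpus")
  logo <- compute_logo(classifications)
  tick("classify")

  # stage: phylogenetic profile
  pam <- build_matrix(classifications, cyay_hits, taxa)
  cooc <- cooccurrence_report(pam)
  recon <- list()
  if (!is.null(corpus$tree)) {
    modes <- if (config$parsimony_mode == "both") c("dollo", "fitch") else {
      config$parsimony_mode
    }
    for (fam in c("cyaY", "iscU")) {
      states <- setNames(pam[, fam], rownames(pam))
      for (m in modes) {
        recon[[paste0(fam, "_", m)]] <- reconstruct(corpus$tree, states, m)
      }
    }
  }
  tick("reconstruct")

  # stage: HGT flags from the cyaY gene tree
  hgt_flags <- NULL
  gene_tree <- NULL
  if (nrow(cyay_hits) > config$hgt_k + 1) {
    seqs <- setNames(
      vapply(seq_len(nrow(cyay_hits)), function(i) {
        g <- corpus$genomes[[cyay_hits$taxon_id[i]]]
        g$genes$protein[match(cyay_hits$locus_id[i], g$genes$locus_id)]
      }, character(1)),
      cyay_hits$taxon_id)
    d <- seq_distances(seqs, cyay_profile, config$gap_open,
                       config$gap_extend)
    gene_tree <- nj_tree(d)
    phyla <- setNames(corpus$taxonomy$phylum, corpus$taxonomy$taxon_id)
    hgt_flags <- flag_hgt(gene_tree, phyla, k = config$hgt_k,
                          threshold = config$hgt_threshold)
  }
  tick("hgt")

  report <- structure(list(
    n_taxa = length(taxa),
    n_proteins = length(proteins),
    n_u_hits = nrow(u_hits),
    n_accepted = sum(classifications$accepted),
    n_cyay = nrow(cyay_hits),
    census = census,
    census_corpus = census_all,
    logo = logo,
    matrix = pam,
    cooccurrence = cooc,
    reconstructions = recon,
    hgt_flags = hgt_flags,
    gene_tree = gene_tree,
    classifications = classifications,
    cyay_hits = cyay_hits,
    truth = corpus$truth,
    provenance = list(seed = config$seed,
                      config = config[!vapply(config, is.list,
                                              logical(1))],
                      timings = timings)
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_report(report, config)
  report
}

# per-taxon best-scoring hit (species-level deduplication)
dedupe_hits_per_taxon <- function(hits) {
  ord <- order(hits$taxon_id, -hits$score_bits, hits$locus_id)
  out <- hits[ord, , drop = FALSE]
  out <- out[!duplicated(out$taxon_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

write_report <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir
  write_classifications_tsv(report$classifications,
                            file.path(od, "classifications.tsv"))
  write_hits_tsv(report$cyay_hits, file.path(od, "cyay_hits.tsv"))
  write.table(report$census$counts, file.path(od, "census.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(report$logo), file.path(od, "logo.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(report$matrix, file.path(od, "matrix.tsv"))
  ev <- do.call(rbind, lapply(names(report$reconstructions), function(n) {
    r <- report$reconstructions[[n]]
    if (nrow(r$events) == 0) return(NULL)
    cbind(family_mode = n, r$events)
  }))
  if (!is.null(ev)) {
    write.table(ev, file.path(od, "events.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(report$hgt_flags)) {
    write.table(as.data.frame(report$hgt_flags),
                file.path(od, "hgt_flags.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    n_taxa = report$n_taxa, n_proteins = report$n_proteins,
    n_u_hits = report$n_u_hits, n_accepted = report$n_accepted,
    n_cyay = report$n_cyay,
    cooccurrence = as.list(report$cooccurrence$counts),
    violations = report$cooccurrence$violations,
    provenance = report$provenance
  )
  jsonlite::write_json(summary, file.path(od, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  # manifest: config echoed verbatim + hash
  cfg_path <- file.path(od, "config.json")
  cfg <- config
  cfg$sim_config <- unclass(cfg$sim_config)
  jsonlite::write_json(lapply(unclass(cfg), function(x) x),
                       cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest <- list(config_file = "config.json",
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("iscutrace")),
                   timings = as.list(report$provenance$timings))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(od)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run over ", x$n_taxa, " genomes (", x$n_proteins,
      " proteins)\n", sep = "")
  cat("  U-family hits: ", x$n_u_hits, "; accepted IscU: ", x$n_accepted,
      "; CyaY survivors: ", x$n_cyay, "\n", sep = "")
  cat("  co-occurrence: ", paste(names(x$cooccurrence$counts),
                                 x$cooccurrence$counts, sep = "=",
                                 collapse = ", "), "\n", sep = "")
  if (length(x$cooccurrence$violations)) {
    cat("  violations: ", paste(x$cooccurrence$violations, collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$hgt_flags)) {
    fl <- x$hgt_flags$taxon_id[x$hgt_flags$flagged]
    cat("  HGT flags: ", if (length(fl)) paste(fl, collapse = ", ") else
      "none", "\n", sep = "")
  }
  invisible(x)
}
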