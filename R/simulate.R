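#' Simulation configuration
#'
#' Defaults define the miniature study conditions the pipeline is validated
#' under: a 40-genome corpus, all genomes carrying an iscU-like scaffold, a
#' cyaY clade of about 25 genomes, a designated "rickettsia-like" clade of
#' about 12 genomes carrying Met at reference position 108 (Ile/Leu/Val
#' elsewhere), 30 decoy proteins, isc-operon gene neighborhoods, and two
#' planted horizontal transfers.
#'
#' @param n_taxa number of genomes (>= 3).
#' @param seed integer seed; recorded in all outputs.
#' @param birth_rate Yule birth rate for the species tree.
#' @param n_phyla number of phylum labels assigned to crown clades.
#' @param presence_mode `"planted"` (clade-based deterministic presence) or
#'   `"markov"` (two-state Markov evolution with the dependency rule: cyaY
#'   gain only where iscU is present, iscU loss forbidden while cyaY is
#'   present).
#' @param rates named list of per-unit-branch-length rates for markov mode:
#'   `iscu_gain`, `iscu_loss`, `cyay_gain`, `cyay_loss`.
#' @param cyay_target planted-mode target size of the cyaY clade.
#' @param met_target target size of the Met-at-108 clade.
#' @param ilv_weights sampling weights for Ile/Leu/Val outside the Met clade.
#' @param subst_rate per-column substitution probability per unit branch
#'   length.
#' @param hgt_divergence per-column divergence of a transferred gene copy.
#' @param n_genes_range genome size range (genes).
#' @param bg_len_range length range of background proteins.
#' @param p_ctx probability a planted iscU is placed within the neighborhood
#'   window of an isc-labeled gene (1 = always; lower values create true
#'   negatives for the neighborhood criterion).
#' @param window neighborhood radius used when placing genes.
#' @param decoys named counts: `nifu` (profile domain plus an extra
#'   segment), `sufu` (motif columns scrambled), `structural` (random
#'   length-matched), `random`.
#' @param nifu_extra_len length of the extra NifU-like segment (residues).
#' @param n_hgt number of planted cyaY transfers.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 40, seed = 1, birth_rate = 1,
                              n_phyla = 6,
                              presence_mode = c("planted", "markov"),
                              rates = list(iscu_gain = 0.3, iscu_loss = 0.15,
                                           cyay_gain = 0.2, cyay_loss = 0.3),
                              cyay_target = 25, met_target = 12,
                              ilv_weights = c(I = 0.5, L = 0.3, V = 0.2),
                              subst_rate = 0.1, hgt_divergence = 0.02,
                              n_genes_range = c(30, 100),
                              bg_len_range = c(100, 300),
                              p_ctx = 1.0, window = 5,
                              decoys = c(nifu = 8, sufu = 8, structural = 7,
                                         random = 7),
                              nifu_extra_len = 200, n_hgt = 2) {
  presence_mode <- match.arg(presence_mode)
  stopifnot(n_taxa >= 3, p_ctx >= 0, p_ctx <= 1, all(unlist(rates) >= 0),
            subst_rate >= 0, hgt_divergence >= 0, hgt_divergence <= 1,
            n_genes_range[1] >= 15)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a pure-birth species tree
#'
#' Yule tree with `n_taxa` leaves and exponential branch lengths; leaf labels
#' are zero-padded taxon ids (`t01`, `t02`, ...). Deterministic for a fixed
#' seed.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param birth_rate Yule birth rate.
#' @param seed integer seed.
#' @return rooted binary `phylo` tree.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = 1) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tree
}

# leaves (tip indices) below a node
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

#' Assign phylum labels to crown clades of a species tree
#'
#' Phyla are the lineages crossing a time slice of the (ultrametric) species
#' tree: starting from the root's children, the clade closest to the root is
#' split until `n_phyla` clades partition the leaves. Undersized clades
#' (fewer than `min_size` leaves) are then absorbed into the phylum of their
#' nearest relatives, so every phylum has enough members for
#' incongruence-based analyses to be meaningful. Clades are labelled in leaf
#' order with proteobacterial-style names.
#'
#' @param tree rooted `phylo` tree.
#' @param n_phyla number of phyla.
#' @param min_size minimum phylum size (default 3).
#' @return data.frame `taxon_id`, `name`, `domain`, `phylum`.
#' @export
assign_phyla <- function(tree, n_phyla = 6, min_size = 3) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  depth <- ape::node.depth.edgelength(tree)
  clades <- tree$edge[tree$edge[, 1] == root, 2]
  repeat {
    if (length(clades) >= n_phyla) break
    splittable <- clades[clades > ntip]
    if (!length(splittable)) break
    pick <- splittable[which.min(depth[splittable])]
    kids <- tree$edge[tree$edge[, 1] == pick, 2]
    clades <- c(setdiff(clades, pick), kids)
  }
  first_tip <- vapply(clades, function(v) min(clade_tips(tree, v)),
                      integer(1))
  clades <- clades[order(first_tip)]
  pool <- c("Alphaproteobacteria", "Betaproteobacteria",
            "Gammaproteobacteria", "DeltaEpsilonproteobacteria",
            "Firmicutes", "Euryarchaeota", "Chlorobi", "Acidobacteria")
  labels <- rep(pool, length.out = length(clades))
  phylum <- character(ntip)
  for (i in seq_along(clades)) {
    phylum[clade_tips(tree, clades[i])] <- labels[i]
  }
  # absorb undersized phyla into the phylum of their nearest relatives
  D <- ape::cophenetic.phylo(tree)
  repeat {
    sizes <- table(phylum)
    small <- names(sizes)[sizes < min_size]
    if (!length(small)) break
    ph <- small[order(sizes[small], small)][1]
    members <- which(phylum == ph)
    others <- which(phylum != ph)
    d <- D[tree$tip.label[members], tree$tip.label[others], drop = FALSE]
    nearest <- others[arrayInd(which.min(d), dim(d))[2]]
    phylum[members] <- phylum[nearest]
  }
  data.frame(taxon_id = tree$tip.label,
             name = paste0("Species ", tree$tip.label),
             domain = ifelse(phylum == "Euryarchaeota", "Archaea",
                             "Bacteria"),
             phylum = phylum, stringsAsFactors = FALSE)
}

# internal node whose clade size is closest to `target` (ties: smaller node)
closest_clade <- function(tree, target, within = NULL) {
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  if (!is.null(within)) nodes <- intersect(nodes, within)
  sizes <- vapply(nodes, function(v) length(clade_tips(tree, v)), integer(1))
  nodes[order(abs(sizes - target), nodes)][1]
}

#' Evolve gene-family presence along a species tree
#'
#' In planted mode, iscU is present in every genome and cyaY in the clade
#' whose size is closest to `cyay_target`. In markov mode, both families
#' evolve as two-state Markov chains under the dependency rule, which
#' guarantees that no genome is cyaY+/iscU-.
#'
#' @param tree rooted `phylo` species tree.
#' @param config a [simulation_config()]. The caller controls the RNG state.
#' @return list: `leaf_states` (data.frame `taxon_id`, `iscu`, `cyay`),
#'   `node_states` (logical matrix nodes x families, ape numbering),
#'   `cyay_clade` (planted-mode gain node or NA).
#' @export
evolve_presence <- function(tree, config) {
  ntip <- length(tree$tip.label)
  nmax <- ntip + tree$Nnode
  root <- ntip + 1L
  st <- matrix(FALSE, nmax, 2, dimnames = list(NULL, c("iscu", "cyay")))
  cyay_clade <- NA_integer_
  if (config$presence_mode == "planted") {
    st[, "iscu"] <- TRUE
    cyay_clade <- closest_clade(tree, config$cyay_target)
    members <- c(cyay_clade, clade_tips(tree, cyay_clade))
    # include internal nodes of the clade
    desc <- cyay_clade
    stack <- cyay_clade
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      kids <- tree$edge[tree$edge[, 1] == v, 2]
      desc <- c(desc, kids)
      stack <- c(stack, kids[kids > ntip])
    }
    st[desc, "cyay"] <- TRUE
  } else {
    r <- config$rates
    st[root, ] <- c(TRUE, FALSE)
    edge <- ape::reorder.phylo(tree, "cladewise")$edge
    len <- ape::reorder.phylo(tree, "cladewise")$edge.length
    p <- function(rate, l) 1 - exp(-rate * l)
    for (e in seq_len(nrow(edge))) {
      a <- edge[e, 1]; b <- edge[e, 2]; l <- len[e]
      iscu_p <- st[a, "iscu"]; cyay_p <- st[a, "cyay"]
      cyay_b <- if (cyay_p) {
        runif(1) >= p(r$cyay_loss, l)
      } else {
        iscu_p && runif(1) < p(r$cyay_gain, l)
      }
      iscu_b <- if (iscu_p) {
        cyay_b || runif(1) >= p(r$iscu_loss, l)
      } else {
        runif(1) < p(r$iscu_gain, l)
      }
      st[b, ] <- c(iscu_b, cyay_b)
    }
  }
  list(leaf_states = data.frame(taxon_id = tree$tip.label,
                                iscu = st[seq_len(ntip), "iscu"],
                                cyay = st[seq_len(ntip), "cyay"],
                                stringsAsFactors = FALSE),
       node_states = st, cyay_clade = cyay_clade)
}

#' Evolve protein sequences along a species tree from a profile
#'
#' The root sequence is the profile consensus over match columns. Along each
#' branch, every non-constrained column is resampled from its column
#' frequency distribution with probability `1 - exp(-subst_rate * length)`.
#' Constrained columns are invariant. The caller controls the RNG state.
#'
#' @param tree rooted `phylo` tree.
#' @param profile the family `profile_model`.
#' @param subst_rate substitution probability per column per unit branch
#'   length.
#' @param constrained_cols match-column indices kept invariant.
#' @return named character vector of leaf sequences.
#' @export
evolve_sequences <- function(tree, profile, subst_rate = 0.1,
                             constrained_cols = integer(0)) {
  ntip <- length(tree$tip.label)
  L <- profile_length(profile)
  free <- setdiff(seq_len(L), constrained_cols)
  root_seq <- strsplit(profile$consensus, "")[[1]]
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- root_seq
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    a <- ord$edge[e, 1]; b <- ord$edge[e, 2]; l <- ord$edge.length[e]
    s <- seqs[[a]]
    p <- 1 - exp(-subst_rate * l)
    hit <- free[runif(length(free)) < p]
    for (k in hit) {
      s[k] <- sample(AA_ALPHABET, 1, prob = profile$freq[k, ])
    }
    seqs[[b]] <- s
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  setNames(out, tree$tip.label)
}

# random protein from background frequencies
random_protein <- function(len, background) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = background),
        collapse = "")
}

# point-mutate a sequence: each position resampled from the column
# distribution with probability p
diverge_sequence <- function(seq, profile, p) {
  s <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(s)) < p)
  for (k in hit) {
    if (k <= nrow(profile$freq)) {
      s[k] <- sample(AA_ALPHABET, 1, prob = profile$freq[k, ])
    }
  }
  paste(s, collapse = "")
}

#' Simulate a miniature proteome corpus with planted ground truth
#'
#' Generates a species tree, phylum labels, presence/absence histories under
#' the dependency rule, profile-conditioned protein sequences with invariant
#' cysteine/motif columns and clade-structured residue-108 states, genomes
#' with isc-operon neighborhoods, decoy proteins (NifU-like fusions,
#' SufU-like motif-less homologs, structural-only analogs, random proteins),
#' and planted horizontal transfers. The truth record is sufficient to score
#' every downstream pipeline stage. Byte-identical output for a fixed config.
#'
#' @param config a [simulation_config()].
#' @param iscu_seed,cyay_seed seed alignments; default to the packaged
#'   synthetic seeds.
#' @param dir optional directory; if given the corpus is also written to disk
#'   in the pipeline input layout.
#' @return a `corpus` (see [read_corpus()]) whose `truth` element carries the
#'   planted labels, presence states, residue-108 map, HGT events, and count
#'   summaries.
#' @export
simulate_corpus <- function(config = simulation_config(),
                            iscu_seed = iscutrace_seed("iscu"),
                            cyay_seed = iscutrace_seed("cyay"),
                            dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- simulate_tree(config$n_taxa, config$birth_rate, config$seed)
  set.seed(config$seed + 1L)

  taxonomy <- assign_phyla(tree, config$n_phyla)
  # emission profiles use the raw seed-observed column distributions
  # (alpha = 0), so simulated residues are always ones the family has seen
  iscu_profile <- build_profile(iscu_seed, alpha = 0, name = "iscU")
  cyay_profile <- build_profile(cyay_seed, alpha = 0, name = "cyaY")

  presence <- evolve_presence(tree, config)
  leaf <- presence$leaf_states

  # residue-108 states: Met in the designated clade, Ile/Leu/Val elsewhere
  met_node <- closest_clade(tree, config$met_target)
  met_taxa <- tree$tip.label[clade_tips(tree, met_node)]
  res108 <- setNames(
    sample(names(config$ilv_weights), config$n_taxa, replace = TRUE,
           prob = config$ilv_weights),
    tree$tip.label)
  res108[met_taxa] <- "M"

  # constrained columns of the scaffold profile
  cys_ref <- detect_cys_columns(iscu_seed)
  motif_ref <- 99:103
  constrained <- ref_to_column(iscu_profile, c(cys_ref, motif_ref, 108))
  if (anyNA(constrained)) {
    stop("scaffold profile does not map the cysteine/motif/108 positions")
  }
  col108 <- ref_to_column(iscu_profile, 108)

  iscu_seqs <- evolve_sequences(tree, iscu_profile, config$subst_rate,
                                constrained)
  for (t in names(iscu_seqs)) {
    s <- strsplit(iscu_seqs[[t]], "")[[1]]
    s[col108] <- res108[[t]]
    iscu_seqs[[t]] <- paste(s, collapse = "")
  }
  cyay_seqs <- evolve_sequences(tree, cyay_profile, config$subst_rate)

  # planted horizontal transfers of cyaY
  hgt <- data.frame(donor = character(0), recipient = character(0),
                    family = character(0), stringsAsFactors = FALSE)
  if (config$n_hgt > 0) {
    donors_pool <- leaf$taxon_id[leaf$cyay]
    if (length(donors_pool) < config$n_hgt) {
      stop("not enough cyaY+ donors available for ", config$n_hgt,
           " transfers")
    }
    # each transfer gets a distinct donor and a recipient from a distinct
    # phylum (preferring phyla free of cyaY, and never the donor's own
    # phylum), so each planted event has clean taxonomic-incongruence ground
    # truth
    phy <- setNames(taxonomy$phylum, taxonomy$taxon_id)
    cyay_phyla <- unique(phy[leaf$taxon_id[leaf$cyay]])
    cand <- leaf$taxon_id[!leaf$cyay & leaf$iscu]
    if (length(cand) < config$n_hgt) {
      stop("not enough cyaY-/iscU+ recipients for ", config$n_hgt,
           " transfers")
    }
    pref <- cand[!(phy[cand] %in% cyay_phyla)]
    ordered <- c(sample(pref), sample(setdiff(cand, pref)))
    recipients <- character(0)
    for (t in ordered) { # one per phylum while possible
      if (length(recipients) == config$n_hgt) break
      if (!(phy[t] %in% phy[recipients])) recipients <- c(recipients, t)
    }
    if (length(recipients) < config$n_hgt) {
      extra <- setdiff(ordered, recipients)
      recipients <- c(recipients,
                      extra[seq_len(config$n_hgt - length(recipients))])
    }
    donors <- character(config$n_hgt)
    pool <- donors_pool
    for (i in seq_len(config$n_hgt)) {
      ok <- pool[phy[pool] != phy[recipients[i]]]
      if (!length(ok)) ok <- pool
      donors[i] <- if (length(ok) == 1) ok else sample(ok, 1)
      pool <- setdiff(pool, donors[i])
    }
    for (i in seq_len(config$n_hgt)) {
      cyay_seqs[[recipients[i]]] <-
        diverge_sequence(cyay_seqs[[donors[i]]], cyay_profile,
                         config$hgt_divergence)
      leaf$cyay[leaf$taxon_id == recipients[i]] <- TRUE
    }
    hgt <- data.frame(donor = donors, recipient = recipients,
                      family = "cyaY", stringsAsFactors = FALSE)
  }

  # distribute decoys over genomes
  decoy_kinds <- rep(names(config$decoys), config$decoys)
  decoy_home <- if (length(decoy_kinds)) {
    sample(leaf$taxon_id, length(decoy_kinds), replace = TRUE)
  } else character(0)

  operon_pool <- setdiff(default_isc_genes(), "iscU")
  genomes <- list()
  planted <- list()
  for (i in seq_len(config$n_taxa)) {
    tid <- leaf$taxon_id[i]
    n_genes <- sample(seq(config$n_genes_range[1], config$n_genes_range[2]),
                      1)
    bg_len <- sample(seq(config$bg_len_range[1], config$bg_len_range[2]),
                     n_genes, replace = TRUE)
    bg <- vapply(bg_len, random_protein, character(1),
                 background = iscu_profile$background)

    # operon segment: 3 isc-labeled neighbors, planted/context genes around
    seg_label <- sample(operon_pool, 3)
    seg <- data.frame(annotation_label = seg_label,
                      protein = vapply(
                        sample(seq(config$bg_len_range[1],
                                   config$bg_len_range[2]), 3,
                               replace = TRUE),
                        random_protein, character(1),
                        background = iscu_profile$background),
                      class = "operon", stringsAsFactors = FALSE)
    far <- seg[0, ]

    if (leaf$iscu[i]) {
      in_ctx <- runif(1) < config$p_ctx
      row <- data.frame(annotation_label = "iscU",
                        protein = iscu_seqs[[tid]], class = "iscU",
                        stringsAsFactors = FALSE)
      if (in_ctx) seg <- rbind(seg, row) else far <- rbind(far, row)
    }
    if (leaf$cyay[i]) {
      far <- rbind(far, data.frame(annotation_label = "cyaY",
                                   protein = cyay_seqs[[tid]],
                                   class = "cyaY", stringsAsFactors = FALSE))
    }
    for (k in which(decoy_home == tid)) {
      kind <- decoy_kinds[k]
      if (kind == "nifu") {
        prot <- paste0(iscu_seqs[[tid]],
                       random_protein(config$nifu_extra_len,
                                      iscu_profile$background))
        seg <- rbind(seg, data.frame(annotation_label = "nifU-like",
                                     protein = prot, class = "nifu_decoy",
                                     stringsAsFactors = FALSE))
      } else if (kind == "sufu") {
        s <- strsplit(iscu_seqs[[tid]], "")[[1]]
        motif_cols <- ref_to_column(iscu_profile, motif_ref)
        pat <- strsplit("LPPVK", "")[[1]]
        for (m in seq_along(motif_cols)) {
          s[motif_cols[m]] <- sample(setdiff(AA_ALPHABET, pat[m]), 1)
        }
        seg <- rbind(seg, data.frame(annotation_label = "sufU-like",
                                     protein = paste(s, collapse = ""),
                                     class = "sufu_decoy",
                                     stringsAsFactors = FALSE))
      } else if (kind == "structural") {
        far <- rbind(far, data.frame(
          annotation_label = "frataxin-analog",
          protein = random_protein(nchar(cyay_profile$consensus),
                                   cyay_profile$background),
          class = "structural_decoy", stringsAsFactors = FALSE))
      } else {
        far <- rbind(far, data.frame(
          annotation_label = "decoy",
          protein = random_protein(sample(seq(config$bg_len_range[1],
                                              config$bg_len_range[2]), 1),
                                   iscu_profile$background),
          class = "random_decoy", stringsAsFactors = FALSE))
      }
    }

    # layout: far genes early, >= window+1 background buffer, then the operon
    # segment, then the rest of the background
    n_head <- max(2L, floor(n_genes / 3))
    head_bg <- data.frame(annotation_label = "hyp", protein = bg[1:n_head],
                          class = "background", stringsAsFactors = FALSE)
    buffer <- data.frame(annotation_label = "hyp",
                         protein = bg[(n_head + 1):(n_head + config$window +
                                                      1)],
                         class = "background", stringsAsFactors = FALSE)
    rest <- data.frame(annotation_label = "hyp",
                       protein = bg[(n_head + config$window + 2):n_genes],
                       class = "background", stringsAsFactors = FALSE)
    # interleave far genes into the head block
    if (nrow(far)) {
      n_slots <- n_head + nrow(far)
      far_slots <- sort(sample.int(n_slots, nrow(far)))
      take_far <- seq_len(n_slots) %in% far_slots
      idx_far <- cumsum(take_far)
      idx_bg <- cumsum(!take_far)
      rows <- lapply(seq_len(n_slots), function(s) {
        if (take_far[s]) far[idx_far[s], , drop = FALSE]
        else head_bg[idx_bg[s], , drop = FALSE]
      })
      head_block <- do.call(rbind, rows)
    } else {
      head_block <- head_bg
    }
    genes <- rbind(head_block, buffer, seg, rest)
    genes$locus_id <- sprintf("%s_g%03d", tid, seq_len(nrow(genes)))
    genes$order_index <- seq_len(nrow(genes)) - 1L
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)

    cls <- genes$class
    genes_df <- genes[, c("locus_id", "order_index", "strand",
                          "annotation_label", "protein")]
    genomes[[tid]] <- genome(
      tid, name = taxonomy$name[match(tid, taxonomy$taxon_id)],
      lineage = c(domain = taxonomy$domain[match(tid, taxonomy$taxon_id)],
                  phylum = taxonomy$phylum[match(tid, taxonomy$taxon_id)]),
      genes = genes_df)
    keep <- cls != "background"
    if (any(keep)) {
      planted[[tid]] <- data.frame(taxon_id = tid,
                                   locus_id = genes$locus_id[keep],
                                   class = cls[keep],
                                   stringsAsFactors = FALSE)
    }
  }

  planted <- do.call(rbind, c(planted, list(make.row.names = FALSE)))
  iscu_taxa <- leaf$taxon_id[leaf$iscu]
  truth <- list(
    seed = config$seed,
    presence = leaf,
    node_states = presence$node_states,
    cyay_clade = presence$cyay_clade,
    residue_108 = as.list(res108[iscu_taxa]),
    met_taxa = met_taxa,
    planted = planted[planted$class %in%
                        c("iscU", "cyaY", "nifu_decoy", "sufu_decoy",
                          "structural_decoy", "random_decoy", "operon"), ],
    hgt_events = hgt,
    counts = list(
      n_taxa = config$n_taxa,
      n_iscu = sum(leaf$iscu),
      n_cyay = sum(leaf$cyay),
      n_met = sum(res108[iscu_taxa] == "M"),
      n_ilv = sum(res108[iscu_taxa] %in% c("I", "L", "V"))
    )
  )

  corpus <- structure(list(genomes = genomes, taxonomy = taxonomy,
                           tree = tree, truth = truth), class = "corpus")
  if (!is.null(dir)) write_corpus(corpus, dir)
  corpus
}

#' Load one of the packaged synthetic seed alignments
#'
#' The seeds are synthetic constructions (see the file names), not Pfam
#' exports: the scaffold seed's reference row carries the canonical
#' constraints (the three conserved cysteines including position 106, the
#' LPPVK motif at 99-103, and Ile at 108 over a 128-residue reference), and
#' the frataxin-like seed is an unconstrained ~100-column domain.
#'
#' @param family `"iscu"` or `"cyay"`.
#' @return a [seed_alignment()].
#' @export
iscutrace_seed <- function(family = c("iscu", "cyay")) {
  family <- match.arg(family)
  path <- system.file("extdata",
                      paste0(family, "_seed_synthetic.afa"),
                      package = "iscutrace", mustWork = TRUE)
  read_seed_alignment(path)
}
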