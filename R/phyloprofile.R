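#' Build a presence/absence matrix over taxa and gene families
#'
#' A cell is TRUE iff the genome has at least one accepted homolog of that
#' family. Every corpus taxon appears exactly once.
#'
#' @param iscu_classifications output of [classify_hits()]; accepted rows
#'   define iscU presence.
#' @param cyay_hits `calibrated_hits` surviving [apply_fullseq_policy()];
#'   they define cyaY presence.
#' @param taxa character vector of all corpus taxon ids.
#' @return logical matrix, rownames taxa, columns `cyaY`, `iscU`.
#' @export
build_matrix <- function(iscu_classifications, cyay_hits, taxa) {
  iscu_taxa <- unique(iscu_classifications$taxon_id[
    iscu_classifications$accepted])
  cyay_taxa <- unique(cyay_hits$taxon_id)
  unknown <- setdiff(c(iscu_taxa, cyay_taxa), taxa)
  if (length(unknown)) {
    stop("hits reference unknown taxa: ", paste(unknown, collapse = ", "))
  }
  m <- cbind(cyaY = taxa %in% cyay_taxa, iscU = taxa %in% iscu_taxa)
  rownames(m) <- taxa
  m
}

#' Co-occurrence report for the cyaY/iscU presence matrix
#'
#' Counts the four (cyaY, iscU) presence combinations and lists violations of
#' the containment observed across prokaryotes: taxa carrying cyaY without an
#' iscU homolog.
#'
#' @param matrix logical presence matrix from [build_matrix()].
#' @return list with `counts` (named integer vector `both`, `iscu_only`,
#'   `cyay_only`, `neither`, summing to the number of taxa) and `violations`
#'   (taxon ids with cyaY but not iscU).
#' @export
cooccurrence_report <- function(matrix) {
  cy <- matrix[, "cyaY"]
  iu <- matrix[, "iscU"]
  counts <- c(both = sum(cy & iu), iscu_only = sum(!cy & iu),
              cyay_only = sum(cy & !iu), neither = sum(!cy & !iu))
  list(counts = counts, violations = rownames(matrix)[cy & !iu])
}

#' Ancestral gain/loss reconstruction by parsimony
#'
#' Reconstructs presence/absence of a gene family at the internal nodes of a
#' rooted species tree. `mode = "fitch"` minimizes the total number of state
#' changes (computed by a binary-state Sankoff pass, exact on polytomies),
#' with root ties resolved to absent. `mode = "dollo"` allows a single gain,
#' placed at the most recent common ancestor of the present leaves, and
#' minimizes losses below it. Cost is the number of events: changes under
#' Fitch, losses + 1 under Dollo.
#'
#' @param tree rooted `phylo` tree; tip labels are taxon ids.
#' @param states named logical vector of leaf states (TRUE = present); every
#'   leaf must have a state.
#' @param mode `"dollo"` (default) or `"fitch"`.
#' @return list of class `ancestral_reconstruction`: `node_states` (character
#'   `"present"`/`"absent"` for all nodes, tips first in ape numbering),
#'   `events` (data.frame `parent`, `child`, `branch`, `type`), `cost`,
#'   `mode`.
#' @export
reconstruct <- function(tree, states, mode = c("dollo", "fitch")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  if (!all(tree$tip.label %in% names(states))) {
    stop("leaves without a state: ",
         paste(setdiff(tree$tip.label, names(states)), collapse = ", "))
  }
  leaf <- as.logical(states[tree$tip.label])
  if (anyNA(leaf)) stop("NA leaf state")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nmax <- ntip + nnode
  root <- ntip + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])

  state <- integer(nmax) # 0 absent, 1 present
  if (mode == "fitch") {
    # binary Sankoff: cost[node, s] = min changes in subtree if node has s
    cost <- matrix(0, nmax, 2)
    ord <- reorder_postorder(tree) # children before parents
    for (v in seq_len(ntip)) {
      cost[v, ] <- if (leaf[v]) c(Inf, 0) else c(0, Inf)
    }
    for (v in ord) {
      for (s in 0:1) {
        tot <- 0
        for (w in children[[as.character(v)]]) {
          tot <- tot + min(cost[w, s + 1], cost[w, 2 - s] + 1)
        }
        cost[v, s + 1] <- tot
      }
    }
    # root: min cost, tie -> absent
    state[root] <- if (cost[root, 1] <= cost[root, 2]) 0L else 1L
    # preorder assignment; ties prefer the parent state (no change), then
    # absent
    for (v in rev(ord)) {
      for (w in children[[as.character(v)]]) {
        assign_child <- function(w, ps) {
          stay <- cost[w, ps + 1]
          flip <- cost[w, 2 - ps] + 1
          if (stay <= flip) ps else 1L - ps
        }
        if (w > ntip) state[w] <- assign_child(w, state[v])
      }
    }
    for (v in seq_len(ntip)) state[v] <- as.integer(leaf[v])
    total_cost <- min(cost[root, ])
  } else {
    present_tips <- which(leaf)
    if (length(present_tips) == 0L) {
      state[] <- 0L
      total_cost <- 0
    } else {
      mrca <- if (length(present_tips) == 1L) present_tips else {
        ape::getMRCA(tree, tree$tip.label[present_tips])
      }
      # present = nodes within the mrca subtree that have >= 1 present
      # descendant leaf (the spanning subtree of the present leaves)
      desc_present <- logical(nmax)
      desc_present[present_tips] <- TRUE
      for (v in reorder_postorder(tree)) {
        desc_present[v] <- any(desc_present[children[[as.character(v)]]])
      }
      in_subtree <- logical(nmax)
      in_subtree[mrca] <- TRUE
      for (v in rev(reorder_postorder(tree))) {
        if (in_subtree[v]) {
          for (w in children[[as.character(v)]]) in_subtree[w] <- TRUE
        }
      }
      if (mrca <= ntip) in_subtree[mrca] <- TRUE
      state <- as.integer(in_subtree & desc_present)
      losses <- 0
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]; w <- tree$edge[e, 2]
        if (state[p] == 1L && state[w] == 0L) losses <- losses + 1
      }
      total_cost <- losses + 1
    }
  }

  # event list from state changes along branches
  lab <- function(v) {
    if (v <= ntip) tree$tip.label[v] else paste0("node", v)
  }
  events <- list()
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; w <- tree$edge[e, 2]
    if (state[p] != state[w]) {
      events[[length(events) + 1]] <- data.frame(
        parent = lab(p), child = lab(w),
        branch = paste0(lab(p), "->", lab(w)),
        type = if (state[w] == 1L) "gain" else "loss",
        stringsAsFactors = FALSE)
    }
  }
  if (mode == "dollo" && any(leaf)) {
    # the single gain: on the branch into the mrca, or at the root itself
    mrca_node <- which(state == 1L)
    top <- mrca_node[!mrca_node %in% tree$edge[, 2][
      state[tree$edge[, 1]] == 1L]]
    gain_at <- min(top)
    parent_edge <- which(tree$edge[, 2] == gain_at)
    gain <- if (length(parent_edge)) {
      data.frame(parent = lab(tree$edge[parent_edge, 1]), child = lab(gain_at),
                 branch = paste0(lab(tree$edge[parent_edge, 1]), "->",
                                 lab(gain_at)),
                 type = "gain", stringsAsFactors = FALSE)
    } else {
      data.frame(parent = NA_character_, child = lab(gain_at),
                 branch = paste0("root->", lab(gain_at)), type = "gain",
                 stringsAsFactors = FALSE)
    }
    events <- c(list(gain), events)
  }
  events <- if (length(events)) {
    ev <- do.call(rbind, events)
    ev[!duplicated(ev$branch), , drop = FALSE]
  } else {
    data.frame(parent = character(0), child = character(0),
               branch = character(0), type = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(events) <- NULL
  structure(list(
    node_states = ifelse(state == 1L, "present", "absent"),
    events = events, cost = total_cost, mode = mode
  ), class = "ancestral_reconstruction")
}

# internal nodes in postorder (children before parents)
reorder_postorder <- function(tree) {
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  unique(edge[, 1])
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat("Parsimony reconstruction (", x$mode, "): cost ", x$cost, ", ",
      nrow(x$events), " events\n", sep = "")
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Write a presence/absence matrix to TSV
#' @param matrix logical matrix from [build_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(taxon_id = rownames(matrix),
                   cyaY = matrix[, "cyaY"], iscU = matrix[, "iscU"])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
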