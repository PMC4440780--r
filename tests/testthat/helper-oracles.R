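# Independent oracles used by the tests. These deliberately use naive
# algorithms (exhaustive enumeration) so they share no code path with the
# package implementation.

# Exhaustive enumeration of all glocal alignment paths: every profile column
# consumed (matched or deleted), free query overhangs, insertions strictly
# between column events, affine gap runs. Returns the maximum score.
oracle_glocal_score <- function(query, lo, gap_open = 4, gap_extend = 1) {
  qchars <- strsplit(query, "")[[1]]
  aa <- colnames(lo)
  qi <- match(qchars, aa) # NA for X
  n <- length(qi)
  L <- nrow(lo)
  gop <- gap_open + gap_extend
  best <- -Inf
  rec <- function(i, j, prev, score) {
    if (j > L) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    # match column j to query residue i+1
    if (i < n) {
      sub <- if (is.na(qi[i + 1])) 0 else lo[j, qi[i + 1]]
      rec(i + 1L, j + 1L, 1L, score + sub)
    }
    # delete column j
    dcost <- if (prev == 2L) gap_extend else gop
    rec(i, j + 1L, 2L, score - dcost)
    # insert query residue i+1 between columns (not before the first column)
    if (i < n && j > 1L) {
      icost <- if (prev == 3L) gap_extend else gop
      rec(i + 1L, j, 3L, score - icost)
    }
  }
  for (i0 in 0:n) rec(i0, 1L, 0L, 0)
  unname(best)
}

# Brute-force parsimony: minimum number of state changes over all internal
# labelings; optionally restricted to single-gain (Dollo) labelings, where
# the cost is gains + losses and a present root counts as the gain.
oracle_parsimony <- function(tree, states, dollo = FALSE) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  leaf <- as.integer(states[tree$tip.label])
  best <- Inf
  for (mask in 0:(2^nnode - 1)) {
    internal <- as.integer(intToBits(mask))[seq_len(nnode)]
    lab <- c(leaf, internal)
    gains <- 0L
    losses <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      p <- lab[tree$edge[e, 1]]
      w <- lab[tree$edge[e, 2]]
      if (p == 0 && w == 1) gains <- gains + 1L
      if (p == 1 && w == 0) losses <- losses + 1L
    }
    if (dollo) {
      root_state <- lab[ntip + 1L]
      total_gains <- gains + root_state
      if (total_gains != 1L) next
      cost <- total_gains + losses
    } else {
      cost <- gains + losses
    }
    if (cost < best) best <- cost
  }
  best
}

# Shannon information content of a residue column, closed form
oracle_column_information <- function(freq) {
  p <- freq[freq > 0]
  log2(20) + sum(p * log2(p))
}
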