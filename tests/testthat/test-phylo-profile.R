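mk_cl <- function(taxa) {
  if (!length(taxa)) {
    out <- data.frame(taxon_id = character(0), accepted = logical(0))
    return(out)
  }
  data.frame(taxon_id = taxa, accepted = TRUE, stringsAsFactors = FALSE)
}
mk_cy <- function(taxa) data.frame(taxon_id = taxa, stringsAsFactors = FALSE)

test_that("build_matrix reflects accepted hits and rejects unknown taxa", {
  taxa <- c("A", "B", "C")
  m <- build_matrix(mk_cl("A"), mk_cy("A"), taxa)
  expect_equal(m["A", ], c(cyaY = TRUE, iscU = TRUE))
  expect_equal(unname(rowSums(m[c("B", "C"), ])), c(0, 0))
  expect_equal(rownames(m), taxa)
  expect_error(build_matrix(mk_cl("Z"), mk_cy("A"), taxa), "unknown taxa")
})

test_that("cooccurrence_report counts the four combinations and lists violations", {
  taxa <- c("A", "B", "C", "D")
  m <- build_matrix(mk_cl(c("A", "B")), mk_cy(c("A")), taxa)
  rep0 <- cooccurrence_report(m)
  expect_equal(sum(rep0$counts), 4)
  expect_equal(length(rep0$violations), 0)
  # plant one violation: cyaY without iscU
  m["D", "cyaY"] <- TRUE
  rep1 <- cooccurrence_report(m)
  expect_equal(rep1$violations, "D")
  expect_equal(unname(rep1$counts["cyay_only"]), 1L)
  expect_equal(sum(rep1$counts), 4)
})

test_that("single-leaf presence gives one terminal gain under both modes", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  states <- c(A = TRUE, B = FALSE, C = FALSE, D = FALSE)
  for (mode in c("dollo", "fitch")) {
    r <- reconstruct(tree, states, mode)
    expect_equal(r$cost, 1)
    expect_equal(r$events$type, "gain")
    expect_equal(r$events$child, "A")
  }
})

test_that("all leaves present puts the gain at the root with zero losses", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  states <- c(A = TRUE, B = TRUE, C = TRUE, D = TRUE)
  r <- reconstruct(tree, states, "dollo")
  expect_equal(r$cost, 1)
  expect_equal(nrow(r$events), 1)
  expect_match(r$events$branch, "^root->")
  rf <- reconstruct(tree, states, "fitch")
  expect_equal(rf$cost, 0)
  expect_equal(nrow(rf$events), 0)
})

test_that("the proteobacterial scenario yields one stem gain plus one clade loss", {
  # alpha/beta sister to (delta-epsilon sister to gamma), outgroups outside;
  # presence in alpha/beta/gamma, absence in delta-epsilon and outgroups
  tree <- ape::read.tree(
    text = "(((A:1,B:1):1,((D:1,E:1):1,(G1:1,G2:1):1):1):1,(O1:1,O2:1):1);")
  states <- c(A = TRUE, B = TRUE, D = FALSE, E = FALSE,
              G1 = TRUE, G2 = TRUE, O1 = FALSE, O2 = FALSE)
  r <- reconstruct(tree, states, "dollo")
  expect_equal(r$cost, 2)
  expect_equal(sort(r$events$type), c("gain", "loss"))
  # the gain sits on the proteobacterial stem (MRCA of A,B,G1,G2), the loss
  # on the delta-epsilon stem
  proteo <- ape::getMRCA(tree, c("A", "B", "G1", "G2"))
  de <- ape::getMRCA(tree, c("D", "E"))
  expect_equal(r$events$child[r$events$type == "gain"],
               paste0("node", proteo))
  expect_equal(r$events$child[r$events$type == "loss"], paste0("node", de))
  # both modes agree with the brute-force minimum here
  expect_equal(reconstruct(tree, states, "fitch")$cost,
               oracle_parsimony(tree, states, dollo = FALSE))
  expect_equal(r$cost, oracle_parsimony(tree, states, dollo = TRUE))
})

test_that("parsimony costs equal brute-force minima on random trees", {
  skip_if_not_installed("phangorn")
  set.seed(99)
  for (case in 1:60) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n)
    states <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE),
                       tree$tip.label)
    if (!any(states)) states[sample(n, 1)] <- TRUE
    rf <- reconstruct(tree, states, "fitch")
    expect_equal(rf$cost, oracle_parsimony(tree, states, dollo = FALSE),
                 label = paste("fitch case", case))
    rd <- reconstruct(tree, states, "dollo")
    expect_equal(rd$cost, oracle_parsimony(tree, states, dollo = TRUE),
                 label = paste("dollo case", case))
    # node states imply exactly the listed events
    st <- rf$node_states
    ev <- 0
    for (e in seq_len(nrow(tree$edge))) {
      if (st[tree$edge[e, 1]] != st[tree$edge[e, 2]]) ev <- ev + 1
    }
    expect_equal(ev, nrow(rf$events))
  }
  # independent cross-check of the Fitch score against phangorn
  set.seed(100)
  for (case in 1:20) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n)
    states <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE),
                       tree$tip.label)
    dat <- phangorn::phyDat(matrix(as.integer(states[tree$tip.label]),
                                   ncol = 1,
                                   dimnames = list(tree$tip.label, NULL)),
                            type = "USER", levels = c(0, 1))
    expect_equal(reconstruct(tree, states, "fitch")$cost,
                 as.integer(phangorn::fitch(tree, dat)))
  }
})

test_that("reconstruction is invariant under child-order permutation", {
  tree <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
  rot <- ape::rotateConstr(tree, c("E", "D", "C", "B", "A"))
  states <- c(A = TRUE, B = TRUE, C = FALSE, D = TRUE, E = FALSE)
  for (mode in c("dollo", "fitch")) {
    r1 <- reconstruct(tree, states, mode)
    r2 <- reconstruct(rot, states, mode)
    expect_equal(r1$cost, r2$cost)
    expect_setequal(paste(r1$events$type, r1$events$child),
                    paste(r2$events$type, r2$events$child))
  }
})

test_that("missing leaf states are an error", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  expect_error(reconstruct(tree, c(A = TRUE, B = FALSE), "fitch"),
               "without a state")
})

test_that("neighbor joining recovers additive topologies", {
  # explicit 4-taxon additive matrix with ((A,B),(C,D)) structure
  tr <- ape::read.tree(text = "((A:2,B:3):1,(C:2,D:4):2);")
  d <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(d)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
  # three taxa: the unique star with three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  s <- nj_tree(d3)
  expect_equal(ape::Ntip(s), 3)
  la <- s$edge.length[s$edge[, 2] == which(s$tip.label == "A")]
  expect_equal(la, (3 + 4 - 5) / 2)
  # validation
  dd <- d3; dd[1, 2] <- 9
  expect_error(nj_tree(dd), "symmetric")
  d0 <- d3; diag(d0) <- 0.5
  expect_error(nj_tree(d0), "zero diagonal")
})

test_that("NJ round-trips noise-free simulated trees and clamps negatives", {
  set.seed(17)
  for (case in 1:30) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n)
    nj <- nj_tree(ape::cophenetic.phylo(tr))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0,
                 label = paste("case", case))
    expect_true(all(nj$edge.length >= 0))
    # clamping preserves total tree length
    raw <- ape::nj(ape::cophenetic.phylo(tr))
    expect_equal(sum(nj$edge.length), sum(raw$edge.length))
  }
})

test_that("flag_hgt flags taxa whose k nearest gene-tree leaves are foreign", {
  # X1 sits inside a clade of phylum Y; its own phylum X is monophyletic
  gt <- ape::read.tree(
    text = "(((Y1:1,X1:1):1,(Y2:1,Y3:1):1):2,((X2:1,X3:1):1,X4:2):2);")
  tax <- c(Y1 = "Y", Y2 = "Y", Y3 = "Y",
           X1 = "X", X2 = "X", X3 = "X", X4 = "X")
  fl <- flag_hgt(gt, tax, k = 3, threshold = 1.0)
  expect_true(fl$flagged[fl$taxon_id == "X1"])
  expect_equal(fl$evidence[fl$taxon_id == "X1"], 1.0)
  # members of the monophyletic block are not flagged; X2's three nearest
  # (X3, X4, then X1 on the deterministic tie-break) are all its own phylum
  expect_false(any(fl$flagged[fl$taxon_id %in% c("X2", "X3", "X4")]))
  expect_equal(fl$evidence[fl$taxon_id == "X2"], 0)
  expect_error(flag_hgt(gt, tax[-1], k = 3), "absent from taxonomy")
})
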