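test_that("pseudo-sequences map calls onto ref/alt bases with N for missing", {
  calls <- rbind(c1 = c(1L, 0L, NA), c2 = c(0L, 0L, 0L), c3 = c(1L, 1L, 1L))
  colnames(calls) <- paste0("s", 1:3)
  gm <- make_gm(calls, ref = c("T", "C", "G"), alt = c("A", "G", "T"))
  aln <- build_alignment(gm)
  expect_equal(paste(aln$seq["c1", ], collapse = ""), "ACN")
  expect_equal(paste(aln$seq["c2", ], collapse = ""), "TCG")  # all-reference
  expect_equal(paste(aln$seq["c3", ], collapse = ""), "AGT")

  # INDEL sites are excluded from the alignment
  gm2 <- make_gm(calls, ref = c("T", "CA", "G"), alt = c("A", "C", "T"),
                 class = c("SNV", "INDEL", "SNV"))
  aln2 <- build_alignment(gm2)
  expect_equal(aln2$sites, c("s1", "s3"))

  gm3 <- make_gm(matrix(0L, 3, 1, dimnames = list(paste0("c", 1:3), "i1")),
                 ref = "TA", alt = "T", class = "INDEL")
  expect_error(build_alignment(gm3), "no SNV sites")
})

test_that("cells beyond the missing-fraction threshold are excluded and logged", {
  calls <- rbind(c1 = c(1L, 0L, 1L, 0L), c2 = c(0L, 1L, 0L, 1L),
                 c3 = c(1L, 1L, 0L, 0L), c4 = c(NA, NA, NA, 0L))
  colnames(calls) <- paste0("s", 1:4)
  gm <- make_gm(calls)
  expect_message(aln <- build_alignment(gm, max_missing_fraction = 0.5), "excluded")
  expect_equal(aln$excluded_cells, "c4")
  expect_equal(rownames(aln$seq), c("c1", "c2", "c3"))
})

test_that("alignment column differences equal genotype differences at co-observed sites", {
  sim <- simulate_dataset(two_tissue_preset(seed = 73))
  gm <- sim$matrix
  aln <- build_alignment(gm, max_missing_fraction = 1)
  snv <- aln$sites
  cells <- rownames(aln$seq)[1:10]
  for (i in 1:9) {
    a <- cells[i]; b <- cells[i + 1]
    ok <- !is.na(gm$calls[a, snv]) & !is.na(gm$calls[b, snv])
    geno_diff <- sum(gm$calls[a, snv][ok] != gm$calls[b, snv][ok])
    seq_ok <- aln$seq[a, ] != "N" & aln$seq[b, ] != "N"
    seq_diff <- sum(aln$seq[a, seq_ok] != aln$seq[b, seq_ok])
    expect_equal(seq_diff, geno_diff)
  }
})

test_that("Fitch scoring matches textbook cases and ignores all-N columns", {
  # identical sequences score 0
  seqm <- matrix("A", 4, 5, dimnames = list(paste0("c", 1:4), NULL))
  aln <- structure(list(seq = seqm, sites = paste0("s", 1:5),
                        excluded_cells = character()), class = "CellAlignment")
  phy <- ape::read.tree(text = "((c1,c2),(c3,c4));")
  expect_equal(fitch_score(phy, aln), 0L)

  # 4 taxa, one column (A,A,T,T) on the split-matching topology: one change
  seqm2 <- matrix(c("A", "A", "T", "T"), 4, 1,
                  dimnames = list(paste0("c", 1:4), NULL))
  aln2 <- structure(list(seq = seqm2, sites = "s1",
                         excluded_cells = character()), class = "CellAlignment")
  expect_equal(fitch_score(phy, aln2), 1L)
  # the split-breaking topology needs two changes
  phy2 <- ape::read.tree(text = "((c1,c3),(c2,c4));")
  expect_equal(fitch_score(phy2, aln2), 2L)

  # adding an all-N column never changes the score
  seqm3 <- cbind(seqm2, "N")
  aln3 <- structure(list(seq = seqm3, sites = c("s1", "s2"),
                         excluded_cells = character()), class = "CellAlignment")
  expect_equal(fitch_score(phy, aln3), 1L)

  # leaf mismatch is an error
  bad <- ape::read.tree(text = "((c1,c2),(c3,c9));")
  expect_error(fitch_score(bad, aln2), "c9")
})

test_that("Fitch equals the unit-cost Sankoff oracle on random instances", {
  for (s in 1:10) {
    aln <- random_alignment(n = 6, m = 15, seed = s)
    topo <- enumerate_topologies_r(6)[[sample(1:105, 1)]]
    phy <- ape::read.tree(text = helper_edges_to_newick(topo, 6, rownames(aln$seq)))
    expect_equal(fitch_score(phy, aln),
                 sankoff_score(topo, aln$seq),
                 label = sprintf("instance %d", s))
  }
})

test_that("Fitch agrees with an established parsimony implementation", {
  skip_if_not_installed("phangorn")
  for (s in 1:15) {
    set.seed(s)
    n <- sample(4:12, 1); m <- sample(5:30, 1)
    aln <- random_alignment(n = n, m = m, seed = 100 + s, p_n = 0.05)
    phy <- ape::rtree(n, rooted = FALSE, tip.label = sample(rownames(aln$seq)))
    pd <- phangorn::phyDat(aln$seq[phy$tip.label, , drop = FALSE], type = "DNA")
    expect_equal(fitch_score(phy, aln), as.integer(phangorn::fitch(phy, pd)))
  }
})

test_that("Fitch score is invariant to column order", {
  aln <- random_alignment(n = 7, m = 20, seed = 77)
  phy <- ape::rtree(7, rooted = FALSE, tip.label = rownames(aln$seq))
  s1 <- fitch_score(phy, aln)
  perm <- sample(ncol(aln$seq))
  aln2 <- structure(list(seq = aln$seq[, perm], sites = aln$sites[perm],
                         excluded_cells = character()), class = "CellAlignment")
  expect_equal(fitch_score(phy, aln2), s1)
})

test_that("exhaustive search on 4 unique sequences equals the best of 3 topologies", {
  set.seed(79)
  seqm <- matrix(sample(c("A", "C", "G", "T"), 4 * 12, replace = TRUE), 4, 12,
                 dimnames = list(paste0("c", 1:4), NULL))
  aln <- structure(list(seq = seqm, sites = paste0("s", 1:12),
                        excluded_cells = character()), class = "CellAlignment")
  ct <- search_mp_tree(aln)
  expect_equal(ct$mode, "exhaustive")
  scores <- vapply(c("((c1,c2),(c3,c4));", "((c1,c3),(c2,c4));",
                     "((c1,c4),(c2,c3));"),
                   function(t) fitch_score(ape::read.tree(text = t), aln),
                   integer(1))
  expect_equal(ct$score, min(scores))
})

test_that("noiseless clones form monophyletic groups on the cell tree", {
  cfg <- simulation_config(n_clones = 4, tree_shape = "bifurcating",
                           cells_per_clone = 6, ado_rate = 0, fp_rate = 0,
                           missing_rate = 0, n_paratumor_cells = 0, seed = 83)
  sim <- simulate_dataset(cfg)
  aln <- build_alignment(sim$matrix)
  ct <- search_mp_tree(aln)
  phy <- ct$phylo
  for (clone in unique(sim$truth$cell_labels)) {
    cells <- names(sim$truth$cell_labels)[sim$truth$cell_labels == clone]
    expect_true(ape::is.monophyletic(phy, cells),
                label = paste("monophyly of", clone))
  }
})

test_that("identical sequences collapse and re-attach as zero-length children", {
  seqm <- rbind(a = c("A", "A", "T"), b = c("A", "A", "T"), c = c("T", "A", "T"),
                d = c("T", "T", "A"), e = c("A", "T", "T"), f = c("T", "T", "A"))
  aln <- structure(list(seq = seqm, sites = paste0("s", 1:3),
                        excluded_cells = character()), class = "CellAlignment")
  ct <- search_mp_tree(aln)
  expect_equal(ct$n_unique, 4L)
  expect_setequal(ct$phylo$tip.label, rownames(seqm))
  # duplicate tips sit on zero-length pendant edges
  for (dup in c("b", "f")) {
    tip_idx <- which(ct$phylo$tip.label == dup)
    e <- which(ct$phylo$edge[, 2] == tip_idx)
    expect_equal(ct$phylo$edge.length[e], 0)
  }
})

test_that("degenerate inputs return a star with a warning", {
  seqm <- matrix("A", 5, 4, dimnames = list(paste0("c", 1:5), NULL))
  aln <- structure(list(seq = seqm, sites = paste0("s", 1:4),
                        excluded_cells = character()), class = "CellAlignment")
  expect_warning(ct <- search_mp_tree(aln), "degenerate")
  expect_equal(ct$score, 0L)
  expect_setequal(ct$phylo$tip.label, rownames(seqm))
})

test_that("NNI hill climbing never beats the exhaustive optimum and usually matches it", {
  n_match <- 0L
  for (s in 1:20) {
    aln <- random_alignment(n = 7, m = 20, seed = 200 + s)
    ex <- search_mp_tree(aln, mode = "exhaustive")
    nni <- search_mp_tree(aln, mode = "nni", seed = s)
    expect_gte(nni$score, ex$score)
    if (nni$score == ex$score) n_match <- n_match + 1L
  }
  expect_gte(n_match, 18L)  # >= 90% equality

  for (s in 1:5) {
    aln <- random_alignment(n = 8, m = 20, seed = 300 + s)
    ex <- search_mp_tree(aln, mode = "exhaustive")
    nni <- search_mp_tree(aln, mode = "nni", seed = s)
    expect_gte(nni$score, ex$score)
  }
})

test_that("branch lengths are a most-parsimonious reconstruction", {
  # zero-score tree: all lengths zero
  seqm <- matrix(rep(c("A", "C", "G", "T"), each = 4), 4, 4, byrow = TRUE,
                 dimnames = list(paste0("c", 1:4), NULL))
  seqm[] <- "A"
  aln0 <- structure(list(seq = seqm, sites = paste0("s", 1:4),
                         excluded_cells = character()), class = "CellAlignment")
  suppressWarnings(ct0 <- search_mp_tree(aln0))
  expect_true(all(ct0$phylo$edge.length == 0))

  # conservation: sum(length x columns) = parsimony score, on random instances
  for (s in 1:10) {
    aln <- random_alignment(n = sample(5:9, 1), m = sample(8:20, 1), seed = 400 + s)
    ct <- search_mp_tree(aln, seed = s)
    expect_equal(sum(ct$edge_changes$changes), ct$score)
    expect_equal(sum(ct$edge_changes$length) * ct$n_columns, ct$score)
  }
})

test_that("a worked 4-taxon case reproduces the hand-computed traceback", {
  # topology ((a,b),(c,d)); columns: AAAA, AATT, AAAT, ATAT, TTTT
  # hand Fitch: AATT -> 1 change on the internal edge; AAAT -> 1 change on
  # d's pendant edge; ATAT -> 2 changes (a's pendant edge under the
  # first-state tie-break, plus c's pendant edge); constant columns -> 0.
  seqm <- rbind(a = c("A", "A", "A", "A", "T"),
                b = c("A", "A", "A", "T", "T"),
                c = c("A", "T", "A", "A", "T"),
                d = c("A", "T", "T", "T", "T"))
  aln <- structure(list(seq = seqm, sites = paste0("s", 1:5),
                        excluded_cells = character()), class = "CellAlignment")
  # tips a=1 b=2 c=3 d=4; internal 5 joins (a,b), 6 joins (c,d)
  edges <- rbind(c(1L, 5L), c(2L, 5L), c(5L, 6L), c(3L, 6L), c(4L, 6L))
  tree <- structure(list(edges = edges, tip_labels = c("a", "b", "c", "d"),
                         score = 4L, n_unique = 4L, mode = "exhaustive",
                         n_columns = 5L,
                         duplicates = stats::setNames(vector("list", 4),
                                                      c("a", "b", "c", "d"))),
                    class = "CellTree")
  bl <- branch_lengths(tree, aln)
  expect_equal(sum(bl$changes), 4L)
  key <- paste(pmin(bl$parent, bl$child), pmax(bl$parent, bl$child))
  changes <- stats::setNames(bl$changes, key)
  expect_equal(unname(changes[["5 6"]]), 1L)  # internal edge: AATT
  expect_equal(unname(changes[["4 6"]]), 1L)  # d pendant: AAAT
  expect_equal(unname(changes[["1 5"]]), 1L)  # a pendant: ATAT tie-break
  expect_equal(unname(changes[["3 6"]]), 1L)  # c pendant: ATAT
  expect_equal(unname(changes[["2 5"]]), 0L)
})
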