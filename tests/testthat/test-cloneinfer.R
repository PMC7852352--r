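test_that("pairwise distances use co-observed sites with pairwise deletion", {
  calls <- rbind(a = c(1L, 0L, NA), b = c(1L, 1L, 0L), c = c(1L, 0L, NA))
  colnames(calls) <- paste0("s", 1:3)
  d <- pairwise_distance(make_gm(calls), min_overlap = 1)
  expect_equal(d["a", "c"], 0)                 # identical rows
  expect_equal(d["a", "b"], 1 / 2)             # 2 co-observed, 1 discordant

  # random matrix against a brute-force double loop
  set.seed(53)
  m <- matrix(sample(c(0L, 1L, NA), 20 * 30, replace = TRUE, prob = c(.45, .45, .1)),
              20, 30, dimnames = list(paste0("c", 1:20), paste0("s", 1:30)))
  d2 <- pairwise_distance(make_gm(m), min_overlap = 1)
  for (i in 1:19) for (j in (i + 1):20) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    expected <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else NA_real_
    expect_equal(unname(d2[i, j]), expected)
  }
})

test_that("low-overlap pairs are flagged unreliable and treated as maximal", {
  calls <- rbind(a = c(1L, NA, NA, NA), b = c(1L, 0L, 1L, 0L),
                 c = c(NA, 0L, 1L, 0L))
  colnames(calls) <- paste0("s", 1:4)
  d <- pairwise_distance(make_gm(calls), min_overlap = 2)
  expect_true(attr(d, "unreliable")["a", "c"])
  expect_equal(d["a", "c"], 1)
  expect_false(attr(d, "unreliable")["b", "c"])
})

test_that("noiseless clones are recovered exactly; tau = 0 shatters noisy data", {
  cfg <- simulation_config(n_clones = 2, tree_shape = "linear", trunk_size = 8,
                           cells_per_clone = 20, ado_rate = 0, fp_rate = 0,
                           missing_rate = 0, seed = 59)
  sim <- simulate_dataset(cfg)
  cl <- call_clones(sim$matrix, tau = 0.05, min_cells = 5)
  expect_length(cl$clones, 2L)
  for (clone in cl$clones) {
    expect_length(unique(sim$truth$cell_labels[clone$cells]), 1L)
  }
  expect_equal(as.numeric(clone_ari(cl, sim$truth)), 1.0)
  expect_length(cl$unassigned, 0L)
  # consensus equals the true cumulative set
  for (clone in cl$clones) {
    true_clone <- sim$truth$cell_labels[[clone$cells[1]]]
    expect_setequal(names(clone$consensus)[clone$consensus == 1L],
                    sim$truth$true_tree$cumulative[[true_clone]])
  }

  noisy_cfg <- two_tissue_preset(seed = 61)
  noisy <- simulate_dataset(noisy_cfg)
  cl0 <- suppressWarnings(call_clones(noisy$matrix, tau = 0, min_cells = 10))
  expect_gt(length(cl0$unassigned), nrow(noisy$matrix$calls) / 2)
  # no cluster reaching min_cells: empty clone list with a warning, not an error
  expect_warning(cl_none <- call_clones(sim$matrix, tau = 0.05, min_cells = 25),
                 "unassigned")
  expect_length(cl_none$clones, 0L)
  expect_length(cl_none$unassigned, 40L)
  expect_error(call_clones(sim$matrix, min_cells = 1000), "fewer tumor cells")
})

test_that("character conflicts are detected exactly as the three-pattern scan", {
  # nested sets are conflict-free; {A},{B},{A,B} conflicts
  nested <- rbind(c(1L, 0L), c(1L, 1L))
  colnames(nested) <- c("A", "B")
  expect_equal(nrow(conflict_test(nested)), 0L)
  tri <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L))
  colnames(tri) <- c("A", "B")
  conf <- conflict_test(tri)
  expect_equal(nrow(conf), 1L)
  expect_equal(c(conf$site_a, conf$site_b), c("A", "B"))

  for (s in 1:20) {
    set.seed(s)
    cmat <- matrix(rbinom(6 * 12, 1, 0.4), 6, 12,
                   dimnames = list(paste0("k", 1:6), paste0("s", sprintf("%02d", 1:12))))
    got <- conflict_test(cmat)
    want <- brute_conflicts(cmat)
    expect_equal(got[order(got$site_a, got$site_b), , drop = FALSE],
                 want[order(want$site_a, want$site_b), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("greedy conflict resolution terminates conflict-free and logs removals", {
  nested <- rbind(c(1L, 0L), c(1L, 1L))
  colnames(nested) <- c("A", "B")
  res <- resolve_conflicts(nested)
  expect_identical(res$clones, nested)
  expect_equal(nrow(res$removed), 0L)

  tri <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L))
  colnames(tri) <- c("A", "B")
  res1 <- resolve_conflicts(tri)
  expect_equal(nrow(res1$removed), 1L)
  expect_equal(res1$removed$site_id, "A")   # tie broken lexicographically
  res2 <- resolve_conflicts(tri, fractions = c(A = 0.8, B = 0.1))
  expect_equal(res2$removed$site_id, "B")   # tie broken by lower fraction

  for (s in 1:20) {
    set.seed(100 + s)
    cmat <- matrix(rbinom(7 * 15, 1, 0.45), 7, 15,
                   dimnames = list(paste0("k", 1:7), paste0("s", sprintf("%02d", 1:15))))
    res <- resolve_conflicts(cmat)
    expect_equal(nrow(conflict_test(res$clones)), 0L)
  }
})

test_that("a shared trunk and two divergent children build the expected tree", {
  trunk <- paste0("t", sprintf("%02d", 1:10))
  sites <- c(trunk, "x", "y")
  cmat <- rbind(cloneA = as.integer(sites %in% trunk),
                cloneB = as.integer(sites %in% c(trunk, "x")),
                cloneC = as.integer(sites %in% c(trunk, "y")))
  colnames(cmat) <- sites
  tree <- build_clone_tree(cmat)
  expect_length(tree$acquired[["cloneA"]], 10L)
  expect_equal(tree$edges$parent[tree$edges$child == "cloneA"], "root")
  expect_setequal(tree$acquired[["cloneB"]], "x")
  expect_setequal(tree$acquired[["cloneC"]], "y")
  expect_equal(tree$edges$parent[tree$edges$child == "cloneB"], "cloneA")
  # no virtual node: the ancestor is observed
  expect_false(any(grepl("virtual", tree$nodes$id)))
})

test_that("an unobserved shared ancestor is inserted as a virtual node", {
  trunk <- paste0("t", 1:4)
  s3 <- c("a", "b", "c")       # shared by the two metastasis clones only
  sites <- c(trunk, s3, "p", "q")
  cmat <- rbind(clone1 = as.integer(sites %in% trunk),
                clone2 = as.integer(sites %in% c(trunk, s3, "p")),
                clone3 = as.integer(sites %in% c(trunk, s3, "q")))
  colnames(cmat) <- sites
  tree <- build_clone_tree(cmat)
  virt <- tree$nodes$id[!tree$nodes$observed & tree$nodes$id != "root"]
  expect_length(virt, 1L)
  expect_setequal(tree$acquired[[virt]], s3)           # the 3 shared mutations
  expect_setequal(tree$cumulative[[virt]], c(trunk, s3))
  expect_equal(sum(tree$edges$parent == virt), 2L)     # two children
})

test_that("a single clone hangs off the root with its full mutation set", {
  cmat <- matrix(c(1L, 1L), 1, 2, dimnames = list("clone1", c("A", "B")))
  tree <- build_clone_tree(cmat)
  expect_equal(nrow(tree$nodes), 2L)
  expect_setequal(tree$acquired[["clone1"]], c("A", "B"))
})

test_that("tree building rejects conflicted input and ignores clone order", {
  tri <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L))
  colnames(tri) <- c("A", "B")
  rownames(tri) <- paste0("k", 1:3)
  expect_error(build_clone_tree(tri), "resolve_conflicts")

  for (s in 1:25) {
    cc <- random_clone_config(s)
    t1 <- build_clone_tree(cc$cmat)
    perm <- sample(nrow(cc$cmat))
    t2 <- build_clone_tree(cc$cmat[perm, , drop = FALSE])
    sig <- function(tr) sort(vapply(seq_len(nrow(tr$edges)), function(i) {
      paste(paste(sort(tr$cumulative[[tr$edges$parent[i]]]), collapse = "+"),
            paste(sort(tr$cumulative[[tr$edges$child[i]]]), collapse = "+"),
            sep = "->")
    }, character(1)))
    expect_identical(sig(t1), sig(t2))
  }
})

test_that("reconstructed trees satisfy the perfect-phylogeny set identities", {
  for (s in 1:30) {
    cc <- random_clone_config(s + 500)
    tree <- build_clone_tree(cc$cmat)
    expect_true(validate_clone_tree(tree))
    # every observed clone node reproduces its consensus exactly
    for (cl in rownames(cc$cmat)) {
      expect_setequal(tree$cumulative[[cl]],
                      colnames(cc$cmat)[cc$cmat[cl, ] == 1L])
    }
    # the LCA of two observed clones carries exactly their shared mutations
    parent_of <- stats::setNames(tree$edges$parent, tree$edges$child)
    path_to_root <- function(v) {
      p <- v
      while (v != "root") { v <- parent_of[[v]]; p <- c(p, v) }
      p
    }
    cls <- rownames(cc$cmat)
    if (length(cls) >= 2) {
      for (i in 1:(length(cls) - 1)) for (j in (i + 1):length(cls)) {
        pi_ <- path_to_root(cls[i]); pj <- path_to_root(cls[j])
        lca <- pi_[pi_ %in% pj][1]
        expect_setequal(tree$cumulative[[lca]],
                        intersect(tree$cumulative[[cls[i]]],
                                  tree$cumulative[[cls[j]]]))
      }
    }
  }
})

test_that("mutations classify as trunk / tissue-private-clonal / subclonal correctly", {
  # two-tissue structure: 10 trunk genes, 3 metastasis-private clonal genes
  trunk <- paste0("t", sprintf("%02d", 1:10))
  s3 <- c("m1", "m2", "m3")
  sites <- c(trunk, s3, "p", "q", "r")
  cmat <- rbind(clone1 = as.integer(sites %in% trunk),
                clone2 = as.integer(sites %in% c(trunk, "r")),
                clone3 = as.integer(sites %in% c(trunk, s3, "p")),
                clone4 = as.integer(sites %in% c(trunk, s3, "q")))
  colnames(cmat) <- sites
  tree <- build_clone_tree(cmat)
  tree$tissue_counts <- list(clone1 = c(tumor = 30L), clone2 = c(tumor = 20L),
                             clone3 = c(metastasis = 25L),
                             clone4 = c(metastasis = 15L))
  cls <- classify_mutations(tree)
  expect_equal(sum(cls$category == "trunk"), 10L)
  expect_setequal(cls$site_id[cls$category == "tissue-private-clonal"], s3)
  expect_setequal(cls$site_id[cls$category == "subclonal"], c("p", "q", "r"))

  # a single clone in a single tissue: every carried mutation is trunk
  single <- build_clone_tree(matrix(c(1L, 1L, 1L), 1, 3,
                                    dimnames = list("clone1", c("a", "b", "c"))))
  single$tissue_counts <- list(clone1 = c(tumor = 10L))
  cls1 <- classify_mutations(single)
  expect_true(all(cls1$category == "trunk"))
})

test_that("classification matches the brute-force set definitions on random trees", {
  for (s in 1:30) {
    cc <- random_clone_config(s + 900)
    tree <- build_clone_tree(cc$cmat)
    tree$tissue_counts <- lapply(cc$tissue_of, function(t) stats::setNames(10L, t))
    all_sites <- colnames(cc$cmat)
    got <- classify_mutations(tree, sites = all_sites)
    for (i in seq_len(nrow(got))) {
      expect_equal(got$category[i],
                   brute_classify(got$site_id[i], cc$cum, cc$tissue_of),
                   label = sprintf("seed %d site %s", s, got$site_id[i]))
    }
  }
})
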