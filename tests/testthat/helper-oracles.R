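# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive results by brute force (enumeration, dynamic
# programming, set scans) without touching the package's own code paths.

## ---- parsimony oracles -----------------------------------------------------

# Unit-cost Sankoff dynamic program on an unrooted tree given as an edge
# matrix (tips 1..n_tips, internal nodes above). Vectorized over columns.
sankoff_score <- function(edges, tip_chars) {
  n_tips <- nrow(tip_chars)
  n_col <- ncol(tip_chars)
  n_nodes <- max(edges)
  INF <- 1e9
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
  }
  bases <- c("A", "C", "G", "T")
  cost <- function(v, from) {
    if (v <= n_tips) {
      cm <- matrix(INF, 4, n_col)
      for (c in seq_len(n_col)) {
        ch <- tip_chars[v, c]
        if (ch == "N") cm[, c] <- 0 else cm[bases == ch, c] <- 0
      }
      return(cm)
    }
    kids <- setdiff(adj[[v]], from)
    total <- matrix(0, 4, n_col)
    for (k in kids) {
      ck <- cost(k, v)
      colmin <- apply(ck, 2, min)
      contrib <- t(vapply(1:4, function(s) pmin(ck[s, ], colmin + 1), numeric(n_col)))
      total <- total + contrib
    }
    total
  }
  root <- adj[[1]][1]   # internal neighbour of tip 1; its children include tip 1
  sum(apply(cost(root, 0L), 2, min))
}

# all unrooted binary topologies over n_tips labelled tips, by stepwise
# addition (edge matrices; tips 1..n, internal n+1..2n-2)
enumerate_topologies_r <- function(n_tips) {
  res <- list()
  grow <- function(edges, next_tip, next_int) {
    if (next_tip > n_tips) {
      res[[length(res) + 1L]] <<- edges
      return(invisible())
    }
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]
      grow(rbind(edges[-e, , drop = FALSE],
                 c(u, next_int), c(next_int, v), c(next_int, next_tip)),
           next_tip + 1L, next_int + 1L)
    }
  }
  grow(matrix(c(n_tips + 1L, 1L, n_tips + 1L, 2L, n_tips + 1L, 3L),
              ncol = 2, byrow = TRUE), 4L, n_tips + 2L)
  res
}

# edge matrix -> newick (so enumerated topologies can be handed to the
# package as ordinary ape trees)
helper_edges_to_newick <- function(edges, n_tips, labels) {
  adj <- vector("list", max(edges))
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
  }
  build <- function(v, from) {
    if (v <= n_tips) return(labels[v])
    kids <- setdiff(adj[[v]], from)
    paste0("(", paste(vapply(kids, build, "", v), collapse = ","), ")")
  }
  root <- adj[[1]][1]
  paste0("(", paste(vapply(adj[[root]], build, "", root), collapse = ","), ");")
}

random_alignment <- function(n, m, seed, p_n = 0.05) {
  set.seed(seed)
  seqm <- matrix(sample(c("A", "C", "G", "T", "N"), n * m, replace = TRUE,
                        prob = c(rep((1 - p_n) / 4, 4), p_n)),
                 n, m, dimnames = list(paste0("c", seq_len(n)), NULL))
  structure(list(seq = seqm, sites = paste0("s", seq_len(m)),
                 excluded_cells = character()), class = "CellAlignment")
}

## ---- set-logic oracles -----------------------------------------------------

# conflict scan by the literal three-patterns definition
brute_conflicts <- function(cmat) {
  sites <- colnames(cmat)
  out <- data.frame(site_a = character(), site_b = character())
  for (a in seq_along(sites)) for (b in seq_along(sites)) {
    if (a >= b) next
    p10 <- p01 <- p11 <- FALSE
    for (k in seq_len(nrow(cmat))) {
      if (cmat[k, a] == 1 && cmat[k, b] == 0) p10 <- TRUE
      if (cmat[k, a] == 0 && cmat[k, b] == 1) p01 <- TRUE
      if (cmat[k, a] == 1 && cmat[k, b] == 1) p11 <- TRUE
    }
    if (p10 && p01 && p11) out <- rbind(out, data.frame(site_a = sites[a],
                                                        site_b = sites[b]))
  }
  out
}

# mutation categories evaluated directly from the set definitions
brute_classify <- function(site, clone_sets, tissue_of) {
  carrying <- names(clone_sets)[vapply(clone_sets, function(s) site %in% s, TRUE)]
  if (length(carrying) == 0L) return("unassigned")
  if (length(carrying) == length(clone_sets)) return("trunk")
  tis <- unique(tissue_of[carrying])
  if (length(tis) >= 2L) return("tissue-shared")
  all_of_tissue <- names(tissue_of)[tissue_of == tis]
  if (setequal(carrying, all_of_tissue)) return("tissue-private-clonal")
  "subclonal"
}

# random conflict-free clone configuration: a random mutation tree plus a
# random observed subset of its clones
random_clone_config <- function(seed, max_clones = 8, max_sites = 30) {
  set.seed(seed)
  n <- sample(2:max_clones, 1)
  parent <- c(0L, vapply(2:n, function(i) sample(0:(i - 1), 1), integer(1)))
  sites <- paste0("s", sprintf("%02d", seq_len(max_sites)))
  avail <- sample(sites)
  acquired <- vector("list", n)
  for (i in seq_len(n)) {
    k <- min(length(avail), sample(0:4, 1))
    acquired[[i]] <- sort(utils::head(avail, k))
    avail <- utils::tail(avail, length(avail) - k)
  }
  cum <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parent[i]
    cum[[i]] <- sort(union(if (p == 0) character() else cum[[p]], acquired[[i]]))
  }
  obs <- which(stats::runif(n) < 0.7)
  if (length(obs) == 0L) obs <- sample(n, 1)
  cmat <- do.call(rbind, lapply(obs, function(i) as.integer(sites %in% cum[[i]])))
  dimnames(cmat) <- list(paste0("clone", obs), sites)
  tissue_of <- stats::setNames(sample(c("tumor", "metastasis"), length(obs),
                                      replace = TRUE), rownames(cmat))
  list(cmat = cmat, cum = stats::setNames(cum[obs], rownames(cmat)),
       tissue_of = tissue_of, parent = parent, n = n, obs = obs)
}

## ---- small genotype fixtures ----------------------------------------------

make_site_meta <- function(site_ids, ref = NULL, alt = NULL, class = NULL) {
  n <- length(site_ids)
  data.frame(site_id = site_ids, chrom = rep("chr1", n), pos = seq_len(n) * 100L,
             ref = ref %||% rep("T", n), alt = alt %||% rep("A", n),
             gene = paste0("G", seq_len(n)),
             variant_class = class %||% rep("SNV", n),
             vaf = NA_real_, stringsAsFactors = FALSE)
}

make_gm <- function(calls, tissues = NULL, ref = NULL, alt = NULL, class = NULL) {
  tissues <- tissues %||% rep("tumor", nrow(calls))
  genotype_matrix(calls,
                  make_site_meta(colnames(calls), ref = ref, alt = alt, class = class),
                  data.frame(cell_id = rownames(calls), tissue = tissues,
                             stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
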