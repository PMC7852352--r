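#' Build nucleotide pseudo-sequences for single cells
#'
#' Turns the ternary genotype calls at the SNV target sites into one
#' pseudo-sequence per cell: a mutant call contributes the alt base, a
#' reference call the ref base, and a missing call the wildcard `N`. INDEL
#' sites are excluded (they have no single-base state). Cells with more than
#' `max_missing_fraction` wildcard positions are dropped and logged.
#'
#' @param gm A `GenotypeMatrix`.
#' @param cells Cell ids to include (default: tumor-compartment cells).
#' @param max_missing_fraction Cells with a larger fraction of `N` are
#'   excluded.
#' @return Object of class `CellAlignment`: list with `seq` (character
#'   matrix cells x sites over `{A,C,G,T,N}`), `sites` (site ids, order
#'   fixed) and `excluded_cells`.
#' @export
build_alignment <- function(gm, cells = NULL, max_missing_fraction = 0.8) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  cells <- cells %||% tumor_cell_ids(gm)
  snv <- gm$site_meta$site_id[gm$site_meta$variant_class == "SNV"]
  if (length(snv) == 0L) stop2("no SNV sites; cannot build a nucleotide alignment")
  if (length(cells) < 3L) stop2("need at least 3 cells")
  calls <- gm$calls[cells, snv, drop = FALSE]
  ref <- gm$site_meta$ref[match(snv, gm$site_meta$site_id)]
  alt <- gm$site_meta$alt[match(snv, gm$site_meta$site_id)]
  seqm <- matrix("N", nrow(calls), ncol(calls), dimnames = dimnames(calls))
  for (j in seq_along(snv)) {
    seqm[!is.na(calls[, j]) & calls[, j] == 0L, j] <- ref[j]
    seqm[!is.na(calls[, j]) & calls[, j] == 1L, j] <- alt[j]
  }
  n_frac <- rowMeans(seqm == "N")
  excluded <- rownames(seqm)[n_frac > max_missing_fraction]
  if (length(excluded) > 0L) {
    message(length(excluded), " cell(s) excluded from the alignment (> ",
            max_missing_fraction * 100, "% missing)")
    seqm <- seqm[!(rownames(seqm) %in% excluded), , drop = FALSE]
  }
  structure(list(seq = seqm, sites = snv, excluded_cells = excluded),
            class = "CellAlignment")
}

#' Write a cell alignment as FASTA
#'
#' @param alignment A `CellAlignment`.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "CellAlignment"))
  dna <- ape::as.DNAbin(alignment$seq)
  ape::write.FASTA(dna, path)
  invisible(path)
}

# bitmask encoding A=1, C=2, G=4, T=8; N = full state set (wildcard)
encode_states <- function(seqm) {
  codes <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L)
  out <- matrix(codes[seqm], nrow(seqm), ncol(seqm))
  if (anyNA(out)) stop2("alignment contains characters outside {A,C,G,T,N}")
  rownames(out) <- rownames(seqm)
  out
}

low_bit <- function(x) bitwAnd(x, -x)

# Accept a topology as an ape phylo (unrooted binary over the tip labels) or
# a CellTree, and return the internal edge-list representation.
as_edge_rep <- function(topology, tip_labels = NULL) {
  if (inherits(topology, "CellTree")) {
    return(list(edges = topology$edges, tips = topology$tip_labels))
  }
  phy <- topology
  stopifnot(inherits(phy, "phylo"))
  phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  if (n >= 4L && nrow(phy$edge) != 2L * n - 3L) {
    stop2("topology must be an unrooted binary tree")
  }
  list(edges = phy$edge, tips = phy$tip.label)
}

#' Fitch parsimony score of a topology on a cell alignment
#'
#' Sums over alignment columns the minimum number of state changes on the
#' given unrooted binary topology (Fitch small parsimony). `N` is treated as
#' the full state set and never forces a change.
#'
#' @param topology An `ape` `phylo` (unrooted binary, tip labels = cell ids)
#'   or a `CellTree`.
#' @param alignment A `CellAlignment` covering all tips.
#' @return Non-negative integer parsimony score.
#' @export
fitch_score <- function(topology, alignment) {
  stopifnot(inherits(alignment, "CellAlignment"))
  rep <- as_edge_rep(topology)
  idx <- match(rep$tips, rownames(alignment$seq))
  if (anyNA(idx)) {
    stop2("tip(s) not in the alignment: ",
          paste(rep$tips[is.na(idx)], collapse = ", "))
  }
  states <- encode_states(alignment$seq[idx, , drop = FALSE])
  n <- length(rep$tips)
  if (n == 2L) {
    return(sum(bitwAnd(states[1, ], states[2, ]) == 0L))
  }
  fitch_score_edges(rep$edges, states, n)
}

## ---- tree search -----------------------------------------------------------

p_distance <- function(seqm) {
  n <- nrow(seqm)
  d <- matrix(0, n, n, dimnames = list(rownames(seqm), rownames(seqm)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- seqm[i, ] != "N" & seqm[j, ] != "N"
    d[i, j] <- d[j, i] <- if (any(ok)) mean(seqm[i, ok] != seqm[j, ok]) else NA_real_
  }
  mx <- suppressWarnings(max(d, na.rm = TRUE))
  d[is.na(d)] <- if (is.finite(mx)) mx else 0
  d
}

internal_edges <- function(edges, n_tips) {
  which(edges[, 1] > n_tips & edges[, 2] > n_tips)
}

node_neighbors <- function(edges, v, exclude) {
  nb <- c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
  setdiff(nb, exclude)
}

replace_edge <- function(edges, a, b, a2, b2) {
  hit <- which((edges[, 1] == a & edges[, 2] == b) |
                 (edges[, 1] == b & edges[, 2] == a))[1]
  edges[hit, ] <- c(a2, b2)
  edges
}

# random unrooted binary topology by stepwise addition (consumes the RNG stream)
random_topology <- function(n) {
  edges <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), ncol = 2, byrow = TRUE)
  nxt <- n + 2L
  for (tip in seq.int(4L, n)) {
    e <- sample.int(nrow(edges), 1L)
    v <- edges[e, 2]
    edges[e, 2] <- nxt
    edges <- rbind(edges, c(nxt, v), c(nxt, tip))
    nxt <- nxt + 1L
  }
  edges
}

# first-improvement NNI descent with a seeded edge-traversal order
nni_hill_climb <- function(edges, states, n_tips) {
  score <- fitch_score_edges(edges, states, n_tips)
  repeat {
    improved <- FALSE
    for (k in sample(internal_edges(edges, n_tips))) {
      for (cand in nni_moves(edges, k)) {
        s <- fitch_score_edges(cand, states, n_tips)
        if (s < score) {
          edges <- cand; score <- s; improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  list(edges = edges, score = score)
}

# the two nearest-neighbor-interchange rearrangements around internal edge k
nni_moves <- function(edges, k) {
  u <- edges[k, 1]; v <- edges[k, 2]
  ab <- node_neighbors(edges, u, v)
  cd <- node_neighbors(edges, v, u)
  m1 <- replace_edge(replace_edge(edges, u, ab[2], u, cd[1]), v, cd[1], v, ab[2])
  m2 <- replace_edge(replace_edge(edges, u, ab[2], u, cd[2]), v, cd[2], v, ab[2])
  list(m1, m2)
}

#' Search for a maximum-parsimony tree of single cells
#'
#' Identical pseudo-sequences are collapsed before the search and re-attached
#' afterwards as zero-length children of their representative. With at most
#' 9 unique sequences (`mode = "auto"`) every unrooted binary topology is
#' enumerated, so the returned tree is a global optimum; for larger inputs a
#' nearest-neighbor-interchange hill climb from a neighbor-joining start tree
#' (p-distance, pairwise deletion of `N`) runs until no rearrangement
#' improves the Fitch score. All tie-breaks are first-found under a fixed,
#' seeded traversal order.
#'
#' @param alignment A `CellAlignment`.
#' @param mode `"auto"`, `"exhaustive"` or `"nni"`.
#' @param seed Seed controlling only the NNI traversal order and restart
#'   topologies.
#' @param restarts Number of hill-climb starts in `"nni"` mode (the first
#'   from neighbor joining, the rest from random topologies).
#' @return Object of class `CellTree`: list with `phylo` (ape tree over all
#'   cells, branch lengths in substitutions per site), `score` (Fitch
#'   parsimony score), `edges`/`tip_labels` (internal representation over
#'   unique sequences), `n_unique`, `mode`, `n_columns` and `duplicates`.
#' @export
search_mp_tree <- function(alignment, mode = c("auto", "exhaustive", "nni"),
                           seed = 1L, restarts = 10L) {
  mode <- match.arg(mode)
  stopifnot(inherits(alignment, "CellAlignment"))
  seqm <- alignment$seq
  keys <- apply(seqm, 1L, paste0, collapse = "")
  reps <- !duplicated(keys)
  rep_ids <- rownames(seqm)[reps]
  duplicates <- lapply(rep_ids, function(r) {
    setdiff(rownames(seqm)[keys == keys[[r]]], r)
  })
  names(duplicates) <- rep_ids
  useq <- seqm[rep_ids, , drop = FALSE]
  n_u <- nrow(useq)
  states <- encode_states(useq)

  if (n_u < 4L) {
    warning("fewer than 4 unique sequences; returning a degenerate star tree")
    score <- if (n_u == 1L) 0L else {
      if (n_u == 2L) sum(bitwAnd(states[1, ], states[2, ]) == 0L)
      else fitch_star3(states)
    }
    tree <- structure(list(phylo = NULL, score = as.integer(score),
                           edges = NULL, tip_labels = rep_ids, n_unique = n_u,
                           mode = "degenerate", n_columns = ncol(seqm),
                           duplicates = duplicates), class = "CellTree")
    tree$phylo <- degenerate_phylo(rep_ids, duplicates)
    return(tree)
  }

  if (mode == "auto") mode <- if (n_u <= 9L) "exhaustive" else "nni"
  if (mode == "exhaustive") {
    res <- exhaustive_mp(states, n_u)
    edges <- res$edges
    score <- res$score
  } else {
    # multi-start hill climb: a neighbor-joining start plus seeded random
    # restarts, keeping the best tree (ties: first found)
    nj_tree <- ape::unroot(ape::nj(p_distance(useq)))
    nj_edges <- nj_tree$edge
    tip_map <- match(nj_tree$tip.label, rep_ids)
    is_tip <- nj_edges <= n_u
    nj_edges[is_tip] <- tip_map[nj_edges[is_tip]]
    best <- NULL
    with_seed(seed, {
      for (r in seq_len(max(1L, restarts))) {
        start_edges <- if (r == 1L) nj_edges else random_topology(n_u)
        res <- nni_hill_climb(start_edges, states, n_u)
        if (is.null(best) || res$score < best$score) best <- res
      }
    })
    edges <- best$edges
    score <- best$score
  }

  tree <- structure(list(phylo = NULL, score = as.integer(score), edges = edges,
                         tip_labels = rep_ids, n_unique = n_u, mode = mode,
                         n_columns = ncol(seqm), duplicates = duplicates),
                    class = "CellTree")
  bl <- branch_lengths(tree, alignment)
  tree$edge_changes <- bl
  tree$phylo <- edges_to_phylo(edges, n_u, rep_ids, bl$length, duplicates)
  tree
}

# minimal changes for 3 sequences joined at one internal node
fitch_star3 <- function(states) {
  score <- 0L
  for (c in seq_len(ncol(states))) {
    s <- states[, c]
    inter12 <- bitwAnd(s[1], s[2])
    if (inter12 == 0L) {
      score <- score + 1L
      inter12 <- bitwOr(s[1], s[2])
    }
    if (bitwAnd(inter12, s[3]) == 0L) score <- score + 1L
  }
  score
}

degenerate_phylo <- function(rep_ids, duplicates) {
  tips <- lapply(rep_ids, function(r) {
    if (length(duplicates[[r]]) == 0L) paste0(r, ":0")
    else paste0("(", paste(c(r, duplicates[[r]]), collapse = ":0,"), ":0):0")
  })
  nwk <- if (length(rep_ids) == 1L && length(duplicates[[1]]) > 0L) {
    paste0(sub(":0$", "", tips[[1]]), ";")
  } else {
    paste0("(", paste(unlist(tips), collapse = ","), ");")
  }
  ape::read.tree(text = nwk)
}

#' @export
print.CellTree <- function(x, ...) {
  cat("CellTree:", length(x$tip_labels), "unique sequences (",
      sum(lengths(x$duplicates)), "duplicates re-attached ),",
      "parsimony score", x$score, "[", x$mode, "]\n")
  invisible(x)
}

#' Most-parsimonious branch lengths in substitutions per site
#'
#' Assigns changes to edges via one deterministic most-parsimonious
#' ancestral reconstruction (Fitch traceback with a first-state tie-break,
#' states ordered A < C < G < T) and divides by the number of alignment
#' columns. The change counts sum to the parsimony score.
#'
#' @param tree A `CellTree` from [search_mp_tree()].
#' @param alignment The `CellAlignment` it was built from.
#' @return `data.frame` with columns `parent`, `child` (internal node
#'   numbers; tips 1..n index `tree$tip_labels`), `changes` and `length`.
#' @export
branch_lengths <- function(tree, alignment) {
  stopifnot(inherits(tree, "CellTree"), inherits(alignment, "CellAlignment"))
  if (is.null(tree$edges)) {
    return(data.frame(parent = integer(), child = integer(),
                      changes = integer(), length = numeric()))
  }
  edges <- tree$edges
  n_tips <- length(tree$tip_labels)
  states <- encode_states(alignment$seq[tree$tip_labels, , drop = FALSE])
  n_col <- ncol(states)
  n_nodes <- max(edges)
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
  }
  top <- adj[[1]][1]
  parent <- integer(n_nodes); parent[top] <- 1L
  order <- integer(0); stack <- top
  while (length(stack) > 0L) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    for (w in adj[[v]]) if (w != parent[v]) { parent[w] <- v; stack <- c(stack, w) }
  }
  prelim <- matrix(0L, n_nodes, n_col)
  for (v in rev(order)) {
    if (v <= n_tips) { prelim[v, ] <- states[v, ]; next }
    kids <- adj[[v]][adj[[v]] != parent[v]]
    s <- prelim[kids[1], ]
    for (k in kids[-1]) {
      inter <- bitwAnd(s, prelim[k, ])
      s <- ifelse(inter == 0L, bitwOr(s, prelim[k, ]), inter)
    }
    prelim[v, ] <- s
  }
  prelim[1, ] <- states[1, ]
  # virtual root on the pendant edge of tip 1
  root_inter <- bitwAnd(prelim[top, ], prelim[1, ])
  root_set <- ifelse(root_inter == 0L, bitwOr(prelim[top, ], prelim[1, ]), root_inter)
  final <- matrix(0L, n_nodes, n_col)
  changes <- stats::setNames(integer(nrow(edges) + 1L), NULL)  # +1: pendant edge of tip 1
  root_state <- low_bit(root_set)
  pendant_changes <- 0L
  assign_final <- function(v, parent_state) {
    hit <- bitwAnd(parent_state, prelim[v, ]) != 0L
    ifelse(hit, parent_state, low_bit(prelim[v, ]))
  }
  final[top, ] <- assign_final(top, root_state)
  pendant_changes <- pendant_changes + sum(bitwAnd(root_state, prelim[top, ]) == 0L)
  final[1, ] <- assign_final(1L, root_state)
  pendant_changes <- pendant_changes + sum(bitwAnd(root_state, prelim[1, ]) == 0L)
  edge_changes <- integer(nrow(edges))
  for (v in order) {
    if (v == top) next
    f <- assign_final(v, final[parent[v], ])
    edge_changes_v <- sum(bitwAnd(final[parent[v], ], prelim[v, ]) == 0L)
    final[v, ] <- f
    e <- which((edges[, 1] == parent[v] & edges[, 2] == v) |
                 (edges[, 2] == parent[v] & edges[, 1] == v))
    edge_changes[e] <- edge_changes_v
  }
  # fold the two virtual-root half-edges onto the real pendant edge
  e1 <- which((edges[, 1] == 1L & edges[, 2] == top) |
                (edges[, 2] == 1L & edges[, 1] == top))
  edge_changes[e1] <- pendant_changes
  data.frame(parent = edges[, 1], child = edges[, 2],
             changes = edge_changes, length = edge_changes / n_col)
}

edges_to_phylo <- function(edges, n_tips, tip_labels, edge_lengths, duplicates) {
  len <- stats::setNames(edge_lengths, paste(pmin(edges[, 1], edges[, 2]),
                                             pmax(edges[, 1], edges[, 2])))
  adj <- vector("list", max(edges))
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
  }
  tip_str <- function(v) {
    lab <- tip_labels[v]
    dups <- duplicates[[lab]]
    if (is.null(dups) || length(dups) == 0L) lab
    else paste0("(", paste0(c(lab, dups), ":0", collapse = ","), ")")
  }
  build <- function(v, from) {
    key <- paste(min(v, from), max(v, from))
    l <- len[[key]]
    body <- if (v <= n_tips) tip_str(v) else {
      kids <- adj[[v]][adj[[v]] != from]
      paste0("(", paste(vapply(kids, build, "", v), collapse = ","), ")")
    }
    sprintf("%s:%.10g", body, l)
  }
  top <- adj[[1]][1]
  kids <- adj[[top]]
  nwk <- paste0("(", paste(vapply(kids, build, "", top), collapse = ","), ");")
  ape::read.tree(text = nwk)
}

#' Write a cell tree as Newick
#'
#' @param tree A `CellTree`.
#' @param path Output path.
#' @export
write_cell_tree <- function(tree, path) {
  stopifnot(inherits(tree, "CellTree"))
  ape::write.tree(tree$phylo, path)
  invisible(path)
}
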