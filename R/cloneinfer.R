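#' Dropout-tolerant pairwise distances between single cells
#'
#' Normalized Hamming distance on the ternary genotype calls with pairwise
#' deletion of missing entries: the fraction of discordant calls among sites
#' non-missing in both cells. Pairs sharing fewer than `min_overlap`
#' co-observed sites are unreliable; their distance is set to the maximum (1)
#' and flagged.
#'
#' @param gm A `GenotypeMatrix` (or plain 0/1/NA matrix).
#' @param cells Optional subset of cell ids (default: tumor-compartment
#'   cells when `gm` is a `GenotypeMatrix`, else all rows).
#' @param min_overlap Minimum co-observed sites for a reliable distance.
#' @return Symmetric distance matrix with attributes `n_overlap` (co-observed
#'   site counts) and `unreliable` (logical matrix).
#' @export
pairwise_distance <- function(gm, cells = NULL, min_overlap = 10L) {
  calls <- if (inherits(gm, "GenotypeMatrix")) {
    cells <- cells %||% tumor_cell_ids(gm)
    gm$calls[cells, , drop = FALSE]
  } else {
    if (!is.null(cells)) gm[cells, , drop = FALSE] else gm
  }
  if (nrow(calls) < 2L) stop2("need at least 2 cells")
  m1 <- (!is.na(calls) & calls == 1L) + 0
  m0 <- (!is.na(calls) & calls == 0L) + 0
  disagree <- tcrossprod(m1, m0) + tcrossprod(m0, m1)
  overlap <- tcrossprod(m1) + tcrossprod(m0) + disagree
  d <- disagree / overlap
  d[overlap == 0] <- NA_real_
  unreliable <- overlap < min_overlap
  diag(unreliable) <- FALSE
  d[unreliable] <- 1
  diag(d) <- 0
  structure(d, n_overlap = overlap, unreliable = unreliable)
}

#' Group single cells into clones by their mutation combinations
#'
#' Average-linkage hierarchical clustering on the dropout-tolerant pairwise
#' distance, cut at height `tau`. Clusters with at least `min_cells` cells
#' become clones (numbered by decreasing size); cells in smaller clusters are
#' left unassigned. Each clone's consensus genotype takes, per site, the
#' majority among non-missing member calls, requires a fraction
#' `min_site_coverage` of members to be non-missing, and breaks ties toward
#' reference (0) so false positives do not inflate clone mutation sets.
#'
#' The defaults are calibrated to a ~60-site panel with tens of cells per
#' clone under moderate allele dropout: `tau` sits between the expected
#' within-clone distance (dropout noise, ~0.05-0.07 at d = 0.1) and the
#' distance of clones separated by 3+ mutations (>= 0.08), and `min_cells`
#' exceeds the expected size `n * d / (1 + d)` of spurious clusters of cells
#' sharing a dropout at the same site (~4-5 cells at 50 cells/clone), which
#' would otherwise masquerade as clones.
#'
#' @param gm A `GenotypeMatrix`.
#' @param tau Tree-cut height on the normalized Hamming scale.
#' @param min_cells Minimum cluster size for a clone.
#' @param min_overlap Passed to [pairwise_distance()].
#' @param min_site_coverage Minimum fraction of non-missing member calls for
#'   a consensus call; below it the consensus is 0.
#' @param cells Optional subset of cell ids (default tumor compartment).
#' @return Object of class `CloneSet`: list with `clones` (list of clones,
#'   each with `clone_id`, `cells`, `consensus` named 0/1 vector over sites,
#'   `tissue_counts`), `assignments` (named vector cell -> clone id, `NA`
#'   for unassigned) and `unassigned` (cell ids).
#' @export
call_clones <- function(gm, tau = 0.07, min_cells = 10L, min_overlap = 10L,
                        min_site_coverage = 0.5, cells = NULL) {
  stopifnot(inherits(gm, "GenotypeMatrix"), tau >= 0)
  cells <- cells %||% tumor_cell_ids(gm)
  if (length(cells) < min_cells) stop2("fewer tumor cells than min_cells")
  d <- pairwise_distance(gm, cells = cells, min_overlap = min_overlap)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(hc, h = tau)
  sizes <- table(grp)
  keep <- names(sizes)[sizes >= min_cells]
  keep <- keep[order(-sizes[keep], as.integer(keep))]   # big clones first
  assignments <- stats::setNames(rep(NA_character_, length(cells)), cells)
  clones <- list()
  for (k in seq_along(keep)) {
    members <- cells[grp == as.integer(keep[k])]
    id <- paste0("clone", k)
    assignments[members] <- id
    sub <- gm$calls[members, , drop = FALSE]
    n_obs <- colSums(!is.na(sub))
    n_mut <- colSums(sub == 1L, na.rm = TRUE)
    # strict majority with coverage requirement; ties and low coverage -> 0
    consensus <- as.integer(n_mut > n_obs / 2 & n_obs >= min_site_coverage * length(members))
    names(consensus) <- colnames(gm$calls)
    tissue <- gm$cell_meta$tissue[match(members, gm$cell_meta$cell_id)]
    clones[[id]] <- list(clone_id = id, cells = members, consensus = consensus,
                         tissue_counts = table(factor(tissue)))
  }
  if (length(clones) == 0L) warning("all cells unassigned; no cluster reached min_cells")
  structure(list(clones = clones, assignments = assignments,
                 unassigned = names(assignments)[is.na(assignments)]),
            class = "CloneSet")
}

#' @export
print.CloneSet <- function(x, ...) {
  cat("CloneSet:", length(x$clones), "clones,", length(x$unassigned), "unassigned cells\n")
  for (cl in x$clones) {
    cat(sprintf("  %s: %d cells, %d consensus mutations\n",
                cl$clone_id, length(cl$cells), sum(cl$consensus)))
  }
  invisible(x)
}

clone_consensus_matrix <- function(clones) {
  cl <- if (inherits(clones, "CloneSet")) clones$clones else clones
  if (length(cl) == 0L) stop2("no clones")
  do.call(rbind, lapply(cl, function(x) x$consensus))
}

#' Test binary characters for perfect-phylogeny conflicts
#'
#' Under an all-reference ancestral state, two sites are compatible with a
#' tree in which each mutation arises once and never reverts iff their
#' carrying-clone patterns do not contain all three of (1,0), (0,1) and
#' (1,1) (the three-gametes condition on rooted binary characters).
#'
#' @param clones A `CloneSet`, a list of clones, or a binary clones-by-sites
#'   matrix of consensus genotypes.
#' @return `data.frame` with columns `site_a`, `site_b`, one row per
#'   conflicting pair (zero rows when conflict-free).
#' @export
conflict_test <- function(clones) {
  cmat <- if (is.matrix(clones)) clones else clone_consensus_matrix(clones)
  n11 <- crossprod(cmat)
  n10 <- crossprod(cmat, 1 - cmat)     # a = 1, b = 0
  conf <- n11 > 0 & n10 > 0 & t(n10) > 0
  conf[lower.tri(conf, diag = TRUE)] <- FALSE
  idx <- which(conf, arr.ind = TRUE)
  data.frame(site_a = colnames(cmat)[idx[, 1]], site_b = colnames(cmat)[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Greedily remove conflicting sites until the clone set is tree-compatible
#'
#' Repeatedly drops the site involved in the most conflicts; ties are broken
#' toward the site with the lower mutated-cell fraction (more likely noise),
#' then lexicographically by site id. Every removal is logged.
#'
#' @param clones A `CloneSet` (or list of clones).
#' @param fractions Optional named per-site mutated-cell fractions used for
#'   tie-breaking (e.g. from [mutated_cell_fraction()]); missing sites count
#'   as fraction 0.
#' @return List with `clones` (conflict-free, same class as input, dropped
#'   sites removed from every consensus) and `removed` (`data.frame` of
#'   `site_id`, `reason`, `n_conflicts`).
#' @export
resolve_conflicts <- function(clones, fractions = NULL) {
  is_set <- inherits(clones, "CloneSet")
  cmat <- if (is.matrix(clones)) clones else clone_consensus_matrix(clones)
  removed <- data.frame(site_id = character(), reason = character(),
                        n_conflicts = integer(), stringsAsFactors = FALSE)
  repeat {
    conf <- conflict_test(cmat)
    if (nrow(conf) == 0L) break
    counts <- table(c(conf$site_a, conf$site_b))
    worst <- names(counts)[counts == max(counts)]
    if (length(worst) > 1L && !is.null(fractions)) {
      fr <- fractions[worst]
      fr[is.na(fr)] <- 0
      worst <- worst[fr == min(fr)]
    }
    victim <- sort(worst)[1]
    removed <- rbind(removed, data.frame(site_id = victim, reason = "character-conflict",
                                         n_conflicts = as.integer(max(counts)),
                                         stringsAsFactors = FALSE))
    cmat <- cmat[, colnames(cmat) != victim, drop = FALSE]
  }
  if (is.matrix(clones)) return(list(clones = cmat, removed = removed))
  out <- clones
  cl <- if (is_set) out$clones else out
  cl <- lapply(cl, function(x) {
    x$consensus <- x$consensus[!(names(x$consensus) %in% removed$site_id)]
    x
  })
  if (is_set) out$clones <- cl else out <- cl
  list(clones = out, removed = removed)
}

## ---- perfect-phylogeny clone tree -----------------------------------------

# Recursive helper: attach the clones in `idx` (rows of cmat, all of whose
# mutation sets strictly contain `parent_cum`) below node `parent_id`.
# `env` accumulates nodes/edges/cumulative/acquired and the virtual counter.
attach_clones <- function(env, parent_id, parent_cum, idx, cmat, clone_ids) {
  beyond <- lapply(idx, function(i) setdiff(colnames(cmat)[cmat[i, ] == 1L], parent_cum))
  # connected components of the "shares a mutation beyond the parent" graph;
  # conflict-free input makes each component share a common non-empty core
  comp <- seq_along(idx)
  repeat {
    changed <- FALSE
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (comp[a] != comp[b] && length(intersect(beyond[[a]], beyond[[b]])) > 0L) {
        comp[comp == comp[b]] <- comp[a]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (cid in unique(comp)) {
    members <- idx[comp == cid]
    shared <- Reduce(intersect, beyond[comp == cid])
    if (length(members) == 1L) {
      i <- members
      node <- clone_ids[i]
      env$nodes <- rbind(env$nodes, data.frame(id = node, observed = TRUE,
                                               stringsAsFactors = FALSE))
      env$edges <- rbind(env$edges, data.frame(parent = parent_id, child = node,
                                               stringsAsFactors = FALSE))
      env$acquired[[node]] <- sort(beyond[[which(idx == i)]])
      env$cumulative[[node]] <- sort(union(parent_cum, env$acquired[[node]]))
      next
    }
    stopifnot(length(shared) > 0L)   # guaranteed by conflict-freeness
    new_cum <- sort(union(parent_cum, shared))
    exact <- members[vapply(members, function(i) {
      setequal(colnames(cmat)[cmat[i, ] == 1L], new_cum)
    }, TRUE)]
    if (length(exact) > 0L) {
      # an observed clone sits exactly at this ancestor
      node <- clone_ids[exact[1]]
      observed <- TRUE
    } else {
      env$n_virtual <- env$n_virtual + 1L
      node <- paste0("virtual", env$n_virtual)
      observed <- FALSE
    }
    env$nodes <- rbind(env$nodes, data.frame(id = node, observed = observed,
                                             stringsAsFactors = FALSE))
    env$edges <- rbind(env$edges, data.frame(parent = parent_id, child = node,
                                             stringsAsFactors = FALSE))
    env$acquired[[node]] <- sort(shared)
    env$cumulative[[node]] <- new_cum
    # further observed clones with the same consensus hang off as zero-edge children
    for (i in exact[-1][length(exact) > 1]) {
      dup <- clone_ids[i]
      env$nodes <- rbind(env$nodes, data.frame(id = dup, observed = TRUE,
                                               stringsAsFactors = FALSE))
      env$edges <- rbind(env$edges, data.frame(parent = node, child = dup,
                                               stringsAsFactors = FALSE))
      env$acquired[[dup]] <- character()
      env$cumulative[[dup]] <- new_cum
    }
    rest <- setdiff(members, exact)
    if (length(rest) > 0L) attach_clones(env, node, new_cum, rest, cmat, clone_ids)
  }
  invisible(env)
}

#' Reconstruct the clone tree by perfect phylogeny with virtual ancestors
#'
#' Builds the rooted clonal phylogeny from conflict-free clone consensus
#' genotypes, with an all-reference root. Mutations are ordered by
#' containment of their carrying-clone sets; each observed clone becomes a
#' node whose cumulative mutation set equals its consensus. Whenever two or
#' more sibling subtrees share mutations that their parent lacks, an
#' unobserved *virtual ancestor* node carrying exactly that shared set is
#' inserted (the dashed-circle clone of a clonal-evolution diagram). Every
#' edge is labelled with the mutations acquired on it.
#'
#' @param clones A `CloneSet` (or list of clones / binary consensus matrix)
#'   that passes [conflict_test()].
#' @return A `CloneTree`; observed nodes keep their clone ids and tissue
#'   counts, virtual nodes are numbered `virtual1`, `virtual2`, ...
#' @export
build_clone_tree <- function(clones) {
  cmat <- if (is.matrix(clones)) clones else clone_consensus_matrix(clones)
  if (nrow(conflict_test(cmat)) > 0L) {
    stop2("clone genotypes contain character conflicts; run resolve_conflicts() first")
  }
  clone_ids <- rownames(cmat) %||% paste0("clone", seq_len(nrow(cmat)))
  if (anyDuplicated(clone_ids)) stop2("duplicate clone ids")
  env <- new.env()
  env$nodes <- data.frame(id = "root", observed = FALSE, stringsAsFactors = FALSE)
  env$edges <- data.frame(parent = character(), child = character(),
                          stringsAsFactors = FALSE)
  env$cumulative <- list(root = character())
  env$acquired <- list()
  env$n_virtual <- 0L
  # clones identical to the root (no mutations) attach directly under it
  at_root <- which(rowSums(cmat) == 0L)
  for (i in at_root) {
    node <- clone_ids[i]
    env$nodes <- rbind(env$nodes, data.frame(id = node, observed = TRUE,
                                             stringsAsFactors = FALSE))
    env$edges <- rbind(env$edges, data.frame(parent = "root", child = node,
                                             stringsAsFactors = FALSE))
    env$acquired[[node]] <- character()
    env$cumulative[[node]] <- character()
  }
  rest <- setdiff(seq_len(nrow(cmat)), at_root)
  if (length(rest) > 0L) attach_clones(env, "root", character(), rest, cmat, clone_ids)
  tissue_counts <- NULL
  if (inherits(clones, "CloneSet")) {
    tissue_counts <- lapply(clones$clones, function(x) {
      tc <- x$tissue_counts
      stats::setNames(as.integer(tc), names(tc))
    })
    names(tissue_counts) <- vapply(clones$clones, `[[`, "", "clone_id")
  }
  clone_tree(env$nodes, env$edges, env$cumulative, env$acquired, root = "root",
             tissue_counts = tissue_counts)
}

## ---- mutation classification ----------------------------------------------

dominant_tissue <- function(tree, node) {
  tc <- tree$tissue_counts[[node]]
  if (is.null(tc) || sum(tc) == 0L) return(NA_character_)
  names(tc)[which.max(tc)]
}

#' Classify mutations by clonality and tissue distribution
#'
#' Per site, over the observed tumor clones of a clone tree:
#' *trunk* if carried by every observed clone (acquired before the most
#' recent common ancestor of all tumor cells); *tissue-private-clonal* if
#' carried by all clones of exactly one tissue and no clone of any other
#' (e.g. metastasis-private clonal mutations marking early metastatic
#' seeding); *tissue-shared* if carried in at least two tissues but not by
#' all clones; *subclonal* if carried by a proper subset of a single
#' tissue's clones; anything not placed on the tree is *unassigned*.
#'
#' @param tree A `CloneTree` with tissue counts on its observed nodes.
#' @param sites Site ids to classify (default: all mutations on the tree).
#' @return Object of class `MutationClassification`: `data.frame` with
#'   columns `site_id`, `category`, `carrying_clones` (comma-separated).
#' @export
classify_mutations <- function(tree, sites = NULL) {
  stopifnot(inherits(tree, "CloneTree"))
  obs <- tree$nodes$id[tree$nodes$observed]
  if (length(obs) == 0L) stop2("tree has no observed clones")
  sites <- sites %||% sort(unique(unlist(tree$acquired)))
  tissue_of <- vapply(obs, function(n) dominant_tissue(tree, n), character(1))
  tissues <- unique(tissue_of[!is.na(tissue_of)])
  res <- lapply(sites, function(s) {
    carrying <- obs[vapply(obs, function(n) s %in% tree$cumulative[[n]], TRUE)]
    if (length(carrying) == 0L) {
      cat_ <- "unassigned"
    } else if (length(carrying) == length(obs)) {
      cat_ <- "trunk"
    } else {
      carried_tissues <- unique(tissue_of[carrying])
      if (length(carried_tissues) >= 2L) {
        cat_ <- "tissue-shared"
      } else if (setequal(carrying, obs[tissue_of == carried_tissues])) {
        cat_ <- "tissue-private-clonal"
      } else {
        cat_ <- "subclonal"
      }
    }
    data.frame(site_id = s, category = cat_,
               carrying_clones = paste(sort(carrying), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("MutationClassification", "data.frame")
  out
}

#' Write clone assignments and mutation classifications as TSV
#'
#' @param clones A `CloneSet`.
#' @param path Output path.
#' @export
write_clone_assignments <- function(clones, path) {
  stopifnot(inherits(clones, "CloneSet"))
  df <- data.frame(cell_id = names(clones$assignments),
                   clone_id = ifelse(is.na(clones$assignments), "unassigned",
                                     clones$assignments),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @param classification A `MutationClassification`.
#' @rdname write_clone_assignments
#' @export
write_classification <- function(classification, path) {
  utils::write.table(as.data.frame(classification), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(classification)
}
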