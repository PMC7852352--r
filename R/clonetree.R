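#' Construct a clone tree
#'
#' A rooted tree of clones starting from a mutation-free root. Every node
#' carries the cumulative set of mutations present in that clone; every edge
#' carries the mutations acquired on it, so a child's cumulative set is its
#' parent's plus the edge set. Nodes are flagged `observed` (backed by
#' sampled cells) or virtual (inferred unobserved ancestors, the dashed-circle
#' nodes of a clonal-evolution diagram).
#'
#' @param nodes `data.frame` with columns `id` (character) and `observed`
#'   (logical); must contain the root.
#' @param edges `data.frame` with columns `parent` and `child` (node ids).
#' @param cumulative Named list (by node id) of character vectors of site ids.
#' @param acquired Named list (by child node id) of character vectors: the
#'   mutations acquired on the edge into that child.
#' @param root Id of the root node (default `"root"`).
#' @param tissue_counts Optional named list (by node id) of named integer
#'   vectors counting member cells per tissue.
#' @param site_meta Optional site metadata table carried along for
#'   convenience (e.g. by the simulator).
#' @return Object of class `CloneTree`.
#' @export
clone_tree <- function(nodes, edges, cumulative, acquired, root = "root",
                       tissue_counts = NULL, site_meta = NULL) {
  tree <- structure(list(nodes = nodes, edges = edges, cumulative = cumulative,
                         acquired = acquired, root = root,
                         tissue_counts = tissue_counts, site_meta = site_meta),
                    class = "CloneTree")
  validate_clone_tree(tree)
  tree
}

#' Validate the structural invariants of a clone tree
#'
#' Checks: single root with empty mutation set; connected and acyclic (every
#' non-root node has exactly one parent, reachable from the root); each
#' child's cumulative set equals parent's cumulative union the edge's
#' acquired set; acquired sets along any root path are disjoint (each
#' mutation arises once, no back mutation); virtual non-root nodes have at
#' least two children.
#'
#' @param tree A `CloneTree`.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_clone_tree <- function(tree) {
  stopifnot(inherits(tree, "CloneTree"))
  nodes <- tree$nodes
  edges <- tree$edges
  if (anyDuplicated(nodes$id)) stop2("duplicate node ids")
  if (!tree$root %in% nodes$id) stop2("root node missing")
  if (length(tree$cumulative[[tree$root]]) != 0L) stop2("root must carry no mutations")
  if (nrow(edges) > 0L) {
    if (anyDuplicated(edges$child)) stop2("a node has two parents")
    if (tree$root %in% edges$child) stop2("root cannot have a parent")
    if (!all(edges$parent %in% nodes$id) || !all(edges$child %in% nodes$id)) {
      stop2("edge endpoint not among nodes")
    }
  }
  non_root <- setdiff(nodes$id, tree$root)
  if (!setequal(edges$child, non_root)) stop2("tree is not connected (orphan nodes)")
  # reachability from root (also catches cycles)
  reached <- tree$root
  frontier <- tree$root
  while (length(frontier) > 0L) {
    nxt <- edges$child[edges$parent %in% frontier]
    frontier <- setdiff(nxt, reached)
    reached <- c(reached, frontier)
  }
  if (!setequal(reached, nodes$id)) stop2("tree contains a cycle or unreachable node")
  for (i in seq_len(nrow(edges))) {
    p <- edges$parent[i]; ch <- edges$child[i]
    acq <- tree$acquired[[ch]]
    if (length(intersect(acq, tree$cumulative[[p]])) > 0L) {
      stop2("acquired set on edge into '", ch, "' overlaps an ancestral mutation")
    }
    if (!setequal(tree$cumulative[[ch]], union(tree$cumulative[[p]], acq))) {
      stop2("cumulative set of '", ch, "' is not parent's set plus the edge set")
    }
  }
  virt <- nodes$id[!nodes$observed & nodes$id != tree$root]
  for (v in virt) {
    if (sum(edges$parent == v) < 2L) stop2("virtual node '", v, "' has fewer than 2 children")
  }
  invisible(TRUE)
}

#' @export
print.CloneTree <- function(x, ...) {
  n_virtual <- sum(!x$nodes$observed & x$nodes$id != x$root)
  cat("CloneTree:", nrow(x$nodes), "nodes (", n_virtual, "virtual ),",
      nrow(x$edges), "edges\n")
  all_sites <- unique(unlist(x$acquired))
  cat("  mutations placed:", length(all_sites), "\n")
  invisible(x)
}

clone_tree_to_list <- function(tree) {
  list(
    root = tree$root,
    nodes = lapply(seq_len(nrow(tree$nodes)), function(i) {
      id <- tree$nodes$id[i]
      tc <- tree$tissue_counts[[id]]
      list(id = id, observed = tree$nodes$observed[i],
           cumulative = as.list(tree$cumulative[[id]]),
           tissue_counts = if (is.null(tc)) NULL else as.list(tc))
    }),
    edges = lapply(seq_len(nrow(tree$edges)), function(i) {
      list(parent = tree$edges$parent[i], child = tree$edges$child[i],
           acquired = as.list(tree$acquired[[tree$edges$child[i]]]))
    })
  )
}

#' Write / read a clone tree as JSON
#'
#' The JSON layout is `nodes[{id, observed, cumulative[], tissue_counts{}}]`
#' and `edges[{parent, child, acquired[]}]` plus the root id; the round trip
#' preserves the tree exactly.
#'
#' @param tree A `CloneTree`.
#' @param path File path.
#' @return `write_clone_tree_json` returns the path invisibly;
#'   `read_clone_tree_json` returns a `CloneTree`.
#' @export
write_clone_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "CloneTree"))
  jsonlite::write_json(clone_tree_to_list(tree), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_clone_tree_json
#' @export
read_clone_tree_json <- function(path) {
  x <- jsonlite::read_json(path)
  ids <- vapply(x$nodes, `[[`, "", "id")
  nodes <- data.frame(id = ids,
                      observed = vapply(x$nodes, `[[`, TRUE, "observed"),
                      stringsAsFactors = FALSE)
  cumulative <- lapply(x$nodes, function(n) as.character(unlist(n$cumulative)))
  names(cumulative) <- ids
  tc <- lapply(x$nodes, function(n) {
    if (is.null(n$tissue_counts)) NULL else unlist(n$tissue_counts)
  })
  names(tc) <- ids
  if (all(vapply(tc, is.null, TRUE))) tc <- NULL
  edges <- data.frame(parent = vapply(x$edges, `[[`, "", "parent"),
                      child = vapply(x$edges, `[[`, "", "child"),
                      stringsAsFactors = FALSE)
  acquired <- lapply(x$edges, function(e) as.character(unlist(e$acquired)))
  names(acquired) <- edges$child
  clone_tree(nodes, edges, cumulative, acquired, root = x$root, tissue_counts = tc)
}
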