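# Jarvis-Patrick shared-nearest-neighbor reweighting of the contact graph.

#' Jarvis-Patrick shared-nearest-neighbor reweighting
#'
#' Replaces the site-normalized edge weights of a contact graph with
#' shared-nearest-neighbor scores. For each node, its neighborhood `NN(v)`
#' is the set of its top-`k` neighbors ranked by normalized weight
#' (descending; ties broken by contig id ascending); nodes with fewer than
#' `k` neighbors use all of them, and a node is never a member of its own
#' list. Only existing edges are considered. An edge `(u, v)` is removed
#' when `|NN(u) ∩ NN(v)| < min_shared`; otherwise its new weight is
#' `|NN(u) ∩ NN(v)| / k` (mode `"fraction"`, default) or the raw shared
#' count (mode `"count"`).
#'
#' Because neighborhoods depend only on weight *ranks*, the reweighted graph
#' is invariant to per-species scaling of link density — species that are
#' more abundant, or lyse more readily during the Hi-C protocol, contribute
#' proportionally more read pairs without distorting the clustering.
#'
#' @param graph A `contact_graph` (typically after [largest_component()]).
#' @param k Neighborhood size; default 100.
#' @param min_shared Minimum shared-neighbor count for an edge to survive;
#'   default 1 (only zero-overlap edges are removed).
#' @param weight_mode `"fraction"` or `"count"`.
#' @return A `contact_graph` whose edges carry `norm_weight` (the input
#'   weight), `shared_nn` and the new `weight`. Removed edges are kept in
#'   attribute `"jp_removed"` (with their raw link counts, needed for
#'   enrichment curves); nodes stripped of all their edges are listed in
#'   attribute `"jp_isolated"`.
#' @export
jarvis_patrick <- function(graph, k = 100, min_shared = 1,
                           weight_mode = c("fraction", "count")) {
  weight_mode <- match.arg(weight_mode)
  if (length(k) != 1L || is.na(k) || k < 1) abort("k must be an integer >= 1")
  k <- as.integer(k)
  if (min_shared < 0) abort("min_shared must be >= 0")
  edges <- graph$edges
  if (nrow(edges) == 0L) {
    out <- graph
    out$edges <- dplyr::mutate(edges, norm_weight = .data$weight,
                               shared_nn = integer())
    attr(out, "jp") <- list(k = k, min_shared = min_shared, weight_mode = weight_mode)
    attr(out, "jp_removed") <- edges
    attr(out, "jp_isolated") <- character()
    return(out)
  }
  ids <- sort(unique(c(edges$contig1, edges$contig2)))
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)

  # Directed adjacency long form; rank neighbors per node.
  adj <- tibble(
    node = c(idx[edges$contig1], idx[edges$contig2]),
    nb = c(idx[edges$contig2], idx[edges$contig1]),
    w = c(edges$weight, edges$weight)
  )
  ord <- order(adj$node, -adj$w, adj$nb)
  adj <- adj[ord, ]
  rank_in_node <- stats::ave(seq_len(nrow(adj)), adj$node, FUN = seq_along)
  nn <- adj[rank_in_node <= k, ]

  # shared counts via sparse indicator crossproduct: C[u, v] = |NN(u) ∩ NN(v)|
  m <- Matrix::sparseMatrix(i = nn$node, j = nn$nb, x = 1, dims = c(n, n))
  cmat <- Matrix::tcrossprod(m)
  shared <- as.integer(round(cmat[cbind(idx[edges$contig1], idx[edges$contig2])]))

  keep <- shared >= min_shared
  new_w <- if (weight_mode == "fraction") shared / k else as.numeric(shared)
  kept <- edges[keep, ]
  kept$norm_weight <- kept$weight
  kept$shared_nn <- shared[keep]
  kept$weight <- new_w[keep]
  removed <- edges[!keep, ]
  isolated <- setdiff(ids, unique(c(kept$contig1, kept$contig2)))

  out <- graph
  out$edges <- kept
  attr(out, "jp") <- list(k = k, min_shared = min_shared, weight_mode = weight_mode)
  attr(out, "jp_removed") <- removed
  attr(out, "jp_isolated") <- sort(isolated)
  out
}

#' Nodes isolated by Jarvis-Patrick edge removal
#'
#' @param graph Output of [jarvis_patrick()].
#' @return Character vector of contig ids left with no edges.
#' @export
jp_isolated_contigs <- function(graph) {
  attr(graph, "jp_isolated") %||% character()
}
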