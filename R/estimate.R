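# Enrichment-based estimation of the number of species.

#' Estimate the number of clusters from intracluster link enrichment
#'
#' Runs the full agglomeration once and, for every candidate cluster count
#' `N` in `[n_min, n_max]`, computes the intracluster link enrichment
#' `E(N)`: the fraction of all inter-contig Hi-C links that fall within
#' rather than between clusters at the `N`-cluster stage of the merge
#' trace. As clusters merge, `E` can only grow; while merges reunite
#' fragments of the same species the gains are large, whereas merging two
#' distinct species adds only the weak between-species links.
#'
#' The predicted `N` is the elbow of the trace, located on the raw-link
#' *density* of each merge (links joined divided by contig pairs joined):
#' merges within one species run at roughly the within-species link
#' density regardless of cluster size, while the first merge that joins
#' two species drops to the far lower between-species density. The
#' predicted count maximizes the ratio of the density of the merge
#' producing the `N`-cluster stage to the density of the following merge.
#'
#' Enrichment is computed from raw link counts (including links on edges
#' removed by Jarvis-Patrick reweighting, which become intracluster when
#' their endpoints co-cluster), so the curve reflects the observed Hi-C
#' signal rather than the reweighted graph.
#'
#' @param graph A `contact_graph`, typically the output of
#'   [jarvis_patrick()].
#' @param n_min,n_max Scan range for the candidate cluster count;
#'   `2 <= n_min < n_max <=` number of linkable nodes.
#' @return An `nclust_estimate` object: `$predicted_n`, `$curve` (tibble
#'   `n`, `enrichment`, `drop_ratio`), `$n_range`.
#' @export
estimate_n_clusters <- function(graph, n_min = 2, n_max = 30) {
  edges <- graph$edges
  n_nodes <- length(unique(c(edges$contig1, edges$contig2)))
  if (!(2 <= n_min && n_min < n_max && n_max <= n_nodes)) {
    abort(paste0("invalid scan range: need 2 <= n_min < n_max <= ", n_nodes,
                 " (linkable nodes), got [", n_min, ", ", n_max, "]"))
  }
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  full <- agglomerate(graph, 1L)
  total_raw <- full$params$total_raw
  if (total_raw <= 0) abort("graph carries no raw links; cannot score enrichment")

  # E indexed by cluster count: stage N = after (n_nodes - N) merges.
  intra_at <- stats::setNames(rep(NA_real_, n_nodes), seq_len(n_nodes))
  intra_at[as.character(n_nodes)] <- 0
  if (nrow(full$merge_trace) > 0L) {
    intra_at[as.character(full$merge_trace$n_clusters)] <- full$merge_trace$intra_raw
  }
  # Stages below the last reached cluster count keep the final enrichment
  # (no positive-linkage merge remained); stages above the initial count
  # have none.
  last <- min(c(n_nodes, full$merge_trace$n_clusters))
  e_of <- function(N) {
    N <- pmax(N, last)
    out <- unname(intra_at[as.character(N)]) / total_raw
    out[N > n_nodes] <- 0
    out
  }
  scan <- seq.int(n_min, min(n_max, n_nodes))
  curve <- tibble(n = scan, enrichment = e_of(scan))
  # Elbow: score each stage by the raw-link density of the merge that
  # produced it — the raw links joined divided by the number of contig
  # pairs joined. Within-species merges have roughly the within-species
  # link density whether they join large blocks or late stragglers; the
  # first merge that joins two species drops to the (much lower)
  # between-species density, so the ratio of successive densities spikes
  # at the true count.
  dens_at <- stats::setNames(rep(0, n_nodes), seq_len(n_nodes))
  if (nrow(full$merge_trace) > 0L) {
    dens_at[as.character(full$merge_trace$n_clusters)] <-
      full$merge_trace$raw_between / full$merge_trace$size_product
  }
  d_of <- function(N) {
    out <- rep(0, length(N))
    ok <- N >= 1L & N < n_nodes
    out[ok] <- unname(dens_at[as.character(N[ok])])
    out
  }
  d_here <- d_of(scan)
  d_next <- d_of(scan - 1L)
  drop_ratio <- dplyr::case_when(
    d_next > 0 ~ d_here / d_next,
    d_here > 0 ~ Inf,
    TRUE ~ 0
  )
  curve$drop_ratio <- drop_ratio
  predicted <- max(scan[drop_ratio == max(drop_ratio)])  # ties -> finer clustering
  structure(
    list(predicted_n = predicted, curve = curve, n_range = c(n_min, n_max)),
    class = "nclust_estimate"
  )
}

#' @export
print.nclust_estimate <- function(x, ...) {
  cat("<nclust_estimate> predicted N = ", x$predicted_n,
      " (scanned ", x$n_range[1L], "..", x$n_range[2L], ")\n", sep = "")
  invisible(x)
}

#' Tidy an enrichment curve
#'
#' @param x An `nclust_estimate` object.
#' @param ... Unused.
#' @return The curve tibble (`n`, `enrichment`, `drop_ratio`).
#' @export
tidy.nclust_estimate <- function(x, ...) x$curve

#' One-row summary of a cluster-count estimate
#'
#' @param x An `nclust_estimate` object.
#' @param ... Unused.
#' @return Tibble with `predicted_n` and the scan range.
#' @export
glance.nclust_estimate <- function(x, ...) {
  tibble(predicted_n = x$predicted_n,
         n_min = x$n_range[1L], n_max = x$n_range[2L])
}

#' Plot an intracluster link enrichment curve
#'
#' @param object An `nclust_estimate` object.
#' @param ... Unused.
#' @return A ggplot object: enrichment versus candidate cluster count, with
#'   the predicted count marked.
#' @export
autoplot.nclust_estimate <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$n, y = .data$enrichment)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$predicted_n,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "number of clusters N",
      y = "intracluster link enrichment E(N)",
      title = paste0("Predicted N = ", object$predicted_n)
    ) +
    ggplot2::theme_minimal()
}

#' Write an enrichment curve TSV
#'
#' @param x An `nclust_estimate` object.
#' @param path Output TSV path (`n`, `enrichment`, `drop_ratio`).
#' @return `path`, invisibly.
#' @export
write_enrichment_curve <- function(x, path) {
  write_tsv_atomic(x$curve, path)
}
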