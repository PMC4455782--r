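# End-to-end orchestration: filtered pairs -> graph -> largest component ->
# Jarvis-Patrick -> agglomeration -> complete assignment with per-contig
# unclustered reasons.

# Cluster an already-built full contact graph; returns a hic_clusters whose
# unclustered table covers every assembly contig that was not placed.
cluster_graph <- function(graph, contigs, n_clusters,
                          k = 100, min_shared = 1,
                          weight_mode = "fraction",
                          n_range = NULL, restrict_component = TRUE) {
  comp <- if (restrict_component) largest_component(graph) else graph
  jp <- jarvis_patrick(comp, k = k, min_shared = min_shared,
                       weight_mode = weight_mode)
  estimate <- NULL
  if (identical(n_clusters, "auto")) {
    n_linkable <- length(unique(c(jp$edges$contig1, jp$edges$contig2)))
    rng <- n_range %||% c(2L, max(3L, min(30L, n_linkable - 1L)))
    estimate <- estimate_n_clusters(jp, rng[1L], rng[2L])
    n_clusters <- estimate$predicted_n
  }
  result <- agglomerate(jp, n_clusters)

  zero_site <- contigs$id[contigs$site_count == 0L]
  placed <- result$clusters$contig_id
  all_ids <- contigs$id
  reason <- stats::setNames(rep(NA_character_, length(all_ids)), all_ids)
  reason[zero_site] <- "zero_sites"
  reason[discarded_contigs(comp)] <- "outside_component"
  reason[jp_isolated_contigs(jp)] <- "jp_isolated"
  # linkable nodes left as singletons without linkage at the stop point
  leftover <- result$unclustered$contig_id
  reason[leftover[is.na(reason[leftover])]] <- "no_linkage"
  unplaced <- setdiff(all_ids, placed)
  reason[unplaced[is.na(reason[unplaced])]] <- "outside_component"

  result$unclustered <- tibble(contig_id = sort(unplaced),
                               reason = unname(reason[sort(unplaced)]))
  result$params$k <- k
  result$params$min_shared <- min_shared
  result$params$weight_mode <- weight_mode
  attr(result, "estimate") <- estimate
  result
}

#' Deconvolve a metagenome assembly with Hi-C contacts
#'
#' Runs the whole binning pipeline: restriction-site proximity filtering of
#' the read pairs, construction of the site-normalized contact graph,
#' restriction to the largest connected component, Jarvis-Patrick
#' shared-nearest-neighbor reweighting, and average-linkage agglomeration
#' down to `n_clusters` species bins. With `n_clusters = "auto"` the count
#' is first predicted from the intracluster link enrichment curve
#' ([estimate_n_clusters()]).
#'
#' @param pairs Hi-C pairs tibble (see [read_pairs()]); filtered internally
#'   unless `filtered = TRUE`.
#' @param contigs Annotated contig tibble from [annotate_sites()].
#' @param n_clusters Integer target, or `"auto"`.
#' @param site_window Proximity-filter window in bp (default 500).
#' @param normalization Contact-graph normalization (`"product"` or `"sum"`).
#' @param k,min_shared,weight_mode Jarvis-Patrick parameters
#'   (see [jarvis_patrick()]).
#' @param dedup Remove coordinate-level duplicate pairs first.
#' @param filtered Set `TRUE` if `pairs` have already been through
#'   [filter_pairs()].
#' @param n_range Integer vector `c(n_min, n_max)` scanned when
#'   `n_clusters = "auto"`.
#' @return A `hic_clusters` object covering every assembly contig; the
#'   filter report is attached as attribute `"filter_report"` and, for
#'   `"auto"`, the enrichment curve as attribute `"estimate"`.
#' @export
deconvolve <- function(pairs, contigs, n_clusters = "auto",
                       site_window = 500,
                       normalization = c("product", "sum"),
                       k = 100, min_shared = 1,
                       weight_mode = c("fraction", "count"),
                       dedup = FALSE, filtered = FALSE,
                       n_range = NULL) {
  normalization <- match.arg(normalization)
  weight_mode <- match.arg(weight_mode)
  if (!filtered) {
    pairs <- filter_pairs(pairs, contigs, site_window = site_window)
  }
  report <- attr(pairs, "filter_report")
  graph <- build_contact_graph(pairs, contigs, normalization = normalization,
                               dedup = dedup)
  result <- cluster_graph(graph, contigs, n_clusters,
                          k = k, min_shared = min_shared,
                          weight_mode = weight_mode, n_range = n_range)
  result$params$site_window <- site_window
  result$params$normalization <- normalization
  attr(result, "filter_report") <- report
  result
}
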