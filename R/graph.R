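# The contig contact graph: contigs as nodes, Hi-C link counts as edges,
# weights normalized by restriction-site counts.

new_contact_graph <- function(nodes, edges, intra_links = 0L,
                              normalization = "product", extra = list()) {
  g <- structure(
    list(nodes = nodes, edges = edges, intra_links = intra_links,
         normalization = normalization),
    class = "contact_graph"
  )
  for (nm in names(extra)) attr(g, nm) <- extra[[nm]]
  g
}

#' Build the normalized contig contact graph
#'
#' Tallies filtered Hi-C pairs into an undirected graph whose nodes are the
#' site-bearing contigs of the assembly and whose edges carry `raw_links`
#' (the number of read pairs linking the two contigs) and `weight`
#' (`raw_links` normalized by the contigs' restriction-site counts). Site
#' counts absorb the strong dependence of Hi-C signal on the number of
#' ligatable fragment ends a contig exposes, so weights are comparable
#' across contigs of different lengths.
#'
#' Intra-contig pairs create no edge; they are tallied in the graph's
#' `intra_links` field for diagnostics. Contigs with zero restriction sites
#' cannot carry signal and are excluded from the node set.
#'
#' @param pairs Filtered pairs tibble (see [filter_pairs()]).
#' @param contigs Annotated contig tibble from [annotate_sites()].
#' @param normalization `"product"` (default): `weight = raw / (s1 * s2)`;
#'   `"sum"`: `weight = raw / (s1 + s2)`, where `s1`, `s2` are the two
#'   contigs' site counts.
#' @param dedup If `TRUE`, coordinate-level duplicates are removed first.
#' @return A `contact_graph` object: `$nodes` (tibble `contig_id`, `length`,
#'   `site_count`), `$edges` (tibble `contig1 < contig2`, `raw_links`,
#'   `weight`), `$intra_links`, `$normalization`.
#' @export
build_contact_graph <- function(pairs, contigs,
                                normalization = c("product", "sum"),
                                dedup = FALSE) {
  normalization <- match.arg(normalization)
  if (!"site_count" %in% names(contigs)) {
    abort("contigs must be annotated with restriction sites; run annotate_sites()")
  }
  unknown <- setdiff(unique(c(pairs$contig1, pairs$contig2)), contigs$id)
  if (length(unknown) > 0L) {
    abort(paste0("pair references unknown contig(s): ",
                 paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  if (dedup) pairs <- dedup_pairs(pairs)
  nodes <- tibble(
    contig_id = contigs$id,
    length = contigs$length,
    site_count = contigs$site_count
  )
  nodes <- dplyr::arrange(nodes[nodes$site_count >= 1L, ], .data$contig_id)

  intra <- pairs$contig1 == pairs$contig2
  inter <- pairs[!intra, ]
  a <- pmin(inter$contig1, inter$contig2)
  b <- pmax(inter$contig1, inter$contig2)
  edges <- dplyr::count(tibble(contig1 = a, contig2 = b),
                        .data$contig1, .data$contig2, name = "raw_links")
  edges <- edges[edges$contig1 %in% nodes$contig_id &
                   edges$contig2 %in% nodes$contig_id, ]
  s <- stats::setNames(nodes$site_count, nodes$contig_id)
  s1 <- unname(s[edges$contig1])
  s2 <- unname(s[edges$contig2])
  edges$weight <- if (normalization == "product") {
    edges$raw_links / (s1 * s2)
  } else {
    edges$raw_links / (s1 + s2)
  }
  edges <- dplyr::arrange(as_tibble(edges), .data$contig1, .data$contig2)
  new_contact_graph(nodes, edges, intra_links = sum(intra),
                    normalization = normalization)
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("<contact_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", sum(x$edges$raw_links), " inter-contig links, ",
      x$intra_links, " intra-contig), normalization = ", x$normalization,
      "\n", sep = "")
  if (!is.null(attr(x, "jp"))) {
    jp <- attr(x, "jp")
    cat("  Jarvis-Patrick reweighted: k = ", jp$k, ", min_shared = ",
        jp$min_shared, ", mode = ", jp$weight_mode, "; ",
        length(attr(x, "jp_isolated") %||% character()), " isolated node(s)\n",
        sep = "")
  }
  invisible(x)
}

#' Tidy the edge table of a contact graph
#'
#' @param x A `contact_graph`.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.contact_graph <- function(x, ...) x$edges

#' One-row summary of a contact graph
#'
#' @param x A `contact_graph`.
#' @param ... Unused.
#' @return Tibble with node/edge/link counts.
#' @export
glance.contact_graph <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    inter_links = sum(x$edges$raw_links),
    intra_links = x$intra_links,
    normalization = x$normalization
  )
}

#' Write / read a contig-pair link table
#'
#' The link table is a TSV `contig1<TAB>contig2<TAB>raw_links<TAB>weight`
#' and is the on-disk form of the contact graph's edges. [read_link_table()]
#' rebuilds a `contact_graph` from such a table, recomputing weights from
#' the contigs' site counts so the normalization is always consistent with
#' the assembly annotation.
#'
#' @param graph A `contact_graph`.
#' @param path TSV path.
#' @return `path` invisibly (write); a `contact_graph` (read).
#' @export
write_link_table <- function(graph, path) {
  write_tsv_atomic(graph$edges, path)
}

#' @param contigs Annotated contig tibble.
#' @param normalization See [build_contact_graph()].
#' @rdname write_link_table
#' @export
read_link_table <- function(path, contigs, normalization = c("product", "sum")) {
  normalization <- match.arg(normalization)
  x <- readr::read_tsv(path, col_types = readr::cols(
    contig1 = "c", contig2 = "c", raw_links = "i", weight = "d"
  ), progress = FALSE)
  nodes <- tibble(
    contig_id = contigs$id, length = contigs$length, site_count = contigs$site_count
  )
  nodes <- dplyr::arrange(nodes[nodes$site_count >= 1L, ], .data$contig_id)
  unknown <- setdiff(unique(c(x$contig1, x$contig2)), nodes$contig_id)
  if (length(unknown) > 0L) {
    abort(paste0("link table references unknown or zero-site contig(s): ",
                 paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  a <- pmin(x$contig1, x$contig2)
  b <- pmax(x$contig1, x$contig2)
  edges <- tibble(contig1 = a, contig2 = b, raw_links = x$raw_links)
  s <- stats::setNames(nodes$site_count, nodes$contig_id)
  edges$weight <- if (normalization == "product") {
    edges$raw_links / unname(s[edges$contig1] * s[edges$contig2])
  } else {
    edges$raw_links / unname(s[edges$contig1] + s[edges$contig2])
  }
  edges <- dplyr::arrange(edges, .data$contig1, .data$contig2)
  new_contact_graph(nodes, edges, normalization = normalization)
}

#' Restrict a contact graph to its largest connected component
#'
#' Only the largest connected component is clustered; other components are
#' typically isolated contigs with little sequence and are reported as
#' unclustered. Ties on component size (node count) are broken by total
#' sequence length, then by the lexicographically smallest member id.
#'
#' @param graph A `contact_graph`.
#' @return The restricted `contact_graph`, with the discarded contig ids in
#'   attribute `"discarded"` (see [discarded_contigs()]).
#' @export
largest_component <- function(graph) {
  if (nrow(graph$nodes) == 0L) abort("contact graph has no nodes")
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("contig1", "contig2")],
    directed = FALSE,
    vertices = graph$nodes$contig_id
  )
  comp <- igraph::components(ig)
  member <- split(graph$nodes$contig_id, comp$membership[graph$nodes$contig_id])
  len <- stats::setNames(graph$nodes$length, graph$nodes$contig_id)
  stats_tbl <- tibble(
    comp = names(member),
    size = lengths(member),
    total_length = purrr::map_dbl(member, ~ sum(len[.x])),
    min_id = purrr::map_chr(member, min)
  )
  stats_tbl <- dplyr::arrange(stats_tbl, dplyr::desc(.data$size),
                              dplyr::desc(.data$total_length), .data$min_id)
  keep_ids <- member[[stats_tbl$comp[1L]]]
  nodes <- graph$nodes[graph$nodes$contig_id %in% keep_ids, ]
  edges <- graph$edges[graph$edges$contig1 %in% keep_ids &
                         graph$edges$contig2 %in% keep_ids, ]
  out <- new_contact_graph(nodes, edges, intra_links = graph$intra_links,
                           normalization = graph$normalization)
  attr(out, "discarded") <- sort(setdiff(graph$nodes$contig_id, keep_ids))
  out
}

#' Contigs discarded by the largest-component restriction
#'
#' @param graph Output of [largest_component()].
#' @return Character vector of contig ids.
#' @export
discarded_contigs <- function(graph) {
  attr(graph, "discarded") %||% character()
}
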