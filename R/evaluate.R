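# Scoring a cluster assignment against a reference truth table.

#' Length-weighted cluster purity matrix
#'
#' For every (cluster, species) pair, the fraction of the cluster's total
#' contig length contributed by contigs whose truth set contains that
#' species. Because a contig may belong to several species (shared or
#' conserved sequence), rows can sum to more than 1. Contigs without a
#' truth entry are scored under the reserved label `"unknown"`.
#'
#' Each cluster's species call is the argmax of its row, ties broken by
#' label order; calls are attached as attribute `"calls"` (see
#' [cluster_calls()]).
#'
#' @param assignment A `hic_clusters` object.
#' @param truth Truth tibble from [read_truth()].
#' @param contigs Contig tibble (for lengths).
#' @return A `hic_purity` object: a long tibble (`cluster`, `species`,
#'   `fraction`) with attributes `"calls"` and `"cluster_length"`.
#' @export
purity_matrix <- function(assignment, truth, contigs) {
  members <- dplyr::inner_join(
    assignment$clusters,
    tibble(contig_id = contigs$id, length = contigs$length),
    by = "contig_id"
  )
  missing <- setdiff(members$contig_id, truth$contig_id)
  labels <- dplyr::bind_rows(
    truth[, c("contig_id", "species")],
    tibble(contig_id = missing,
           species = rep("unknown", length(missing)))
  )
  cluster_len <- dplyr::summarise(dplyr::group_by(members, .data$cluster),
                                  total = sum(.data$length), .groups = "drop")
  cells <- dplyr::inner_join(members, labels, by = "contig_id",
                             relationship = "many-to-many")
  cells <- dplyr::summarise(
    dplyr::group_by(cells, .data$cluster, .data$species),
    len = sum(.data$length), .groups = "drop"
  )
  cells <- dplyr::left_join(cells, cluster_len, by = "cluster")
  out <- tibble(
    cluster = cells$cluster,
    species = cells$species,
    fraction = cells$len / cells$total
  )
  out <- dplyr::arrange(out, .data$cluster, .data$species)
  calls <- dplyr::slice_head(
    dplyr::group_by(
      dplyr::arrange(out, .data$cluster, dplyr::desc(.data$fraction),
                     .data$species),
      .data$cluster
    ), n = 1L
  )
  calls <- dplyr::ungroup(calls)[, c("cluster", "species")]
  names(calls) <- c("cluster", "called_species")
  structure(out, class = c("hic_purity", class(out)),
            calls = calls, cluster_length = cluster_len)
}

#' Species call per cluster
#'
#' @param pm A `hic_purity` object.
#' @return Tibble with `cluster` and `called_species` (length-weighted
#'   argmax).
#' @export
cluster_calls <- function(pm) {
  attr(pm, "calls")
}

#' Purity matrix in wide (clusters x species) form
#'
#' @param x A `hic_purity` object.
#' @param ... Unused.
#' @return A base matrix with cluster rows and species columns; absent
#'   combinations are 0.
#' @export
as.matrix.hic_purity <- function(x, ...) {
  wide <- tidyr::pivot_wider(as_tibble(x), names_from = "species",
                             values_from = "fraction", values_fill = 0)
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$cluster
  m[, order(colnames(m)), drop = FALSE]
}

#' Plot a purity matrix as a heatmap
#'
#' @param object A `hic_purity` object.
#' @param ... Unused.
#' @return A ggplot tile heatmap of length fractions, clusters by species.
#' @export
autoplot.hic_purity <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$species, y = .data$cluster,
                               fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "species", y = "cluster",
                  fill = "length\nfraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write a purity matrix TSV (clusters x species)
#'
#' @param pm A `hic_purity` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_purity_matrix <- function(pm, path) {
  m <- as.matrix(pm)
  out <- dplyr::bind_cols(tibble(cluster = rownames(m)), as_tibble(m))
  write_tsv_atomic(out, path)
}

#' Clustering accuracy against a truth table
#'
#' A clustered contig is correct when the species called for its cluster
#' (length-weighted argmax of the purity row) is a member of the contig's
#' truth set — so a contig shared between two species is correct in either
#' parent's cluster. Unclustered contigs are excluded from both
#' denominators: accuracy is quoted over placed sequence.
#'
#' @param assignment A `hic_clusters` object.
#' @param truth Truth tibble.
#' @param contigs Contig tibble (for lengths).
#' @param unknown `"include"` (default): contigs without a truth entry are
#'   scored under the `"unknown"` label (and are wrong unless their cluster
#'   is called `"unknown"`); `"exclude"`: such contigs are dropped from the
#'   denominators.
#' @return One-row tibble: `length_weighted_accuracy`,
#'   `count_weighted_accuracy`, `clustered_length`, `clustered_contigs`,
#'   `correct_length`, `correct_contigs`.
#' @export
clustering_accuracy <- function(assignment, truth, contigs,
                                unknown = c("include", "exclude")) {
  unknown <- match.arg(unknown)
  universe_gap <- setdiff(assignment$clusters$contig_id, contigs$id)
  if (length(universe_gap) > 0L) {
    warn(paste0(length(universe_gap),
                " clustered contig(s) missing from the contig table; dropped"))
  }
  pm <- purity_matrix(assignment, truth, contigs)
  calls <- cluster_calls(pm)
  members <- dplyr::inner_join(
    assignment$clusters,
    tibble(contig_id = contigs$id, length = contigs$length),
    by = "contig_id"
  )
  members <- dplyr::left_join(members, calls, by = "cluster")
  truth_sets <- split(truth$species, truth$contig_id)
  has_truth <- members$contig_id %in% names(truth_sets)
  if (unknown == "exclude") {
    members <- members[has_truth, ]
    has_truth <- rep(TRUE, nrow(members))
  }
  correct <- logical(nrow(members))
  known <- which(has_truth)
  correct[known] <- purrr::map2_lgl(
    members$contig_id[known], members$called_species[known],
    ~ .y %in% truth_sets[[.x]]
  )
  correct[!has_truth] <- members$called_species[!has_truth] == "unknown"
  tibble(
    length_weighted_accuracy = sum(members$length[correct]) / sum(members$length),
    count_weighted_accuracy = sum(correct) / nrow(members),
    clustered_length = sum(members$length),
    clustered_contigs = nrow(members),
    correct_length = sum(members$length[correct]),
    correct_contigs = sum(correct)
  )
}

#' Summarise unclustered sequence
#'
#' Reports how much sequence was left out of the species bins and why.
#' Contigs without a restriction site cannot produce Hi-C signal, so on
#' clean data they should dominate the unclustered remainder.
#'
#' @param assignment A `hic_clusters` object.
#' @param contigs Contig tibble (for lengths and site counts).
#' @return An `unclustered_report` object: `$total_length`,
#'   `$zero_site_fraction` (of unclustered length on zero-site contigs),
#'   `$breakdown` (tibble `reason`, `n_contigs`, `length`).
#' @export
unclustered_report <- function(assignment, contigs) {
  uc <- dplyr::inner_join(
    assignment$unclustered,
    tibble(contig_id = contigs$id, length = contigs$length),
    by = "contig_id"
  )
  total <- sum(uc$length)
  zero_frac <- if (total > 0) {
    sum(uc$length[uc$reason == "zero_sites"]) / total
  } else NA_real_
  breakdown <- dplyr::summarise(
    dplyr::group_by(uc, .data$reason),
    n_contigs = dplyr::n(), length = sum(.data$length), .groups = "drop"
  )
  structure(
    list(total_length = total, zero_site_fraction = zero_frac,
         breakdown = dplyr::arrange(breakdown, .data$reason)),
    class = "unclustered_report"
  )
}

#' @export
print.unclustered_report <- function(x, ...) {
  cat("<unclustered_report> total unclustered length: ", x$total_length,
      " bp; fraction on zero-site contigs: ",
      if (is.na(x$zero_site_fraction)) "NA"
      else format(x$zero_site_fraction, digits = 4), "\n", sep = "")
  if (nrow(x$breakdown) > 0L) print(x$breakdown)
  invisible(x)
}

#' Write an accuracy summary as a flat key=value file
#'
#' @param accuracy One-row tibble from [clustering_accuracy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accuracy_summary <- function(accuracy, path) {
  write_atomic(path, function(tmp) {
    writeLines(paste0(names(accuracy), "=",
                      purrr::map_chr(accuracy, ~ format(.x, digits = 15))),
               tmp)
  })
}
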