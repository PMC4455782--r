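# Bootstrap stability of the cluster assignment.

#' Bootstrap stability of a clustering
#'
#' Assesses how robust the species bins are to the sampling noise of the
#' Hi-C library. `B` times, the filtered pair multiset is resampled with
#' replacement to its original size, the contact graph rebuilt and
#' reclustered at the same target `n_clusters`. Each replicate cluster is
#' matched to the original cluster with which it shares the greatest total
#' contig length; a contig is stable in a replicate when it lands in the
#' replicate cluster matched to its original cluster. Per-contig stability
#' is the fraction of replicates in which the contig is stable; the
#' adjusted Rand index of each replicate against the original assignment
#' (over contigs clustered in both) is reported alongside.
#'
#' All randomness flows from `seed`; the same seed reproduces the same
#' stability vector exactly.
#'
#' @param pairs Filtered pairs tibble (see [filter_pairs()]).
#' @param contigs Annotated contig tibble.
#' @param n_clusters Target cluster count used for the original run and
#'   every replicate.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param k,min_shared,weight_mode,normalization Pipeline parameters, as in
#'   [deconvolve()].
#' @return A `hic_bootstrap` object: `$per_contig` (tibble `contig_id`,
#'   `stability`), `$replicates` (tibble `replicate`, `ari`,
#'   `n_clustered`), `$mean_stability`, `$original` (the baseline
#'   `hic_clusters`), `$B`, `$seed`.
#' @export
bootstrap_stability <- function(pairs, contigs, n_clusters, B = 20,
                                seed = 1L,
                                k = 100, min_shared = 1,
                                weight_mode = c("fraction", "count"),
                                normalization = c("product", "sum")) {
  if (length(B) != 1L || is.na(B) || B < 1) abort("B must be an integer >= 1")
  B <- as.integer(B)
  weight_mode <- match.arg(weight_mode)
  normalization <- match.arg(normalization)

  # The bootstrap reclusters the whole graph (no largest-component
  # restriction): resampling perturbs component membership, and discarding
  # components would conflate sampling variance with component churn.
  run_once <- function(p) {
    graph <- build_contact_graph(p, contigs, normalization = normalization)
    cluster_graph(graph, contigs, n_clusters, k = k,
                  min_shared = min_shared, weight_mode = weight_mode,
                  restrict_component = FALSE)
  }
  original <- run_once(pairs)
  orig_assign <- stats::setNames(original$clusters$cluster,
                                 original$clusters$contig_id)
  len <- stats::setNames(contigs$length, contigs$id)
  n <- nrow(pairs)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  stable_count <- stats::setNames(rep(0L, length(orig_assign)), names(orig_assign))
  rep_rows <- vector("list", B)
  for (b in seq_len(B)) {
    res <- run_once(pairs[sample.int(n, n, replace = TRUE), ])
    rep_assign <- stats::setNames(res$clusters$cluster, res$clusters$contig_id)

    common <- intersect(names(orig_assign), names(rep_assign))
    # match each original cluster to the replicate cluster with the
    # greatest shared contig length; ties broken by replicate label order
    overlap <- tibble(
      orig = unname(orig_assign[common]),
      repl = unname(rep_assign[common]),
      len = unname(len[common])
    )
    overlap <- dplyr::summarise(
      dplyr::group_by(overlap, .data$orig, .data$repl),
      shared = sum(.data$len), .groups = "drop"
    )
    overlap <- dplyr::arrange(overlap, .data$orig,
                              dplyr::desc(.data$shared), .data$repl)
    best <- overlap[!duplicated(overlap$orig), ]
    target <- stats::setNames(best$repl, best$orig)

    hit <- rep_assign[common] == target[orig_assign[common]]
    hit[is.na(hit)] <- FALSE
    stable_count[common[hit]] <- stable_count[common[hit]] + 1L

    ari <- if (length(common) > 1L) {
      mclust::adjustedRandIndex(orig_assign[common], rep_assign[common])
    } else NA_real_
    rep_rows[[b]] <- tibble(replicate = b, ari = ari,
                            n_clustered = length(rep_assign))
  }
  per_contig <- tibble(
    contig_id = names(stable_count),
    stability = as.numeric(stable_count) / B
  )
  per_contig <- dplyr::arrange(per_contig, .data$contig_id)
  structure(
    list(per_contig = per_contig,
         replicates = dplyr::bind_rows(rep_rows),
         mean_stability = mean(per_contig$stability),
         original = original, B = B, seed = seed),
    class = "hic_bootstrap"
  )
}

#' @export
print.hic_bootstrap <- function(x, ...) {
  cat("<hic_bootstrap> B = ", x$B, ", mean per-contig stability = ",
      format(x$mean_stability, digits = 4), ", mean ARI = ",
      format(mean(x$replicates$ari, na.rm = TRUE), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Plot the per-contig bootstrap stability distribution
#'
#' @param object A `hic_bootstrap` object.
#' @param ... Unused.
#' @return A ggplot histogram of per-contig stability.
#' @export
autoplot.hic_bootstrap <- function(object, ...) {
  ggplot2::ggplot(object$per_contig, ggplot2::aes(x = .data$stability)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "per-contig stability", y = "contigs",
                  title = paste0("B = ", object$B, ", mean stability = ",
                                 format(object$mean_stability, digits = 4))) +
    ggplot2::theme_minimal()
}

#' Tidy per-contig bootstrap stability
#'
#' @param x A `hic_bootstrap` object.
#' @param ... Unused.
#' @return Tibble with `contig_id` and `stability`.
#' @export
tidy.hic_bootstrap <- function(x, ...) x$per_contig

#' One-row summary of a bootstrap run
#'
#' @param x A `hic_bootstrap` object.
#' @param ... Unused.
#' @return Tibble with `B`, `mean_stability`, and the ARI distribution's
#'   mean and minimum.
#' @export
glance.hic_bootstrap <- function(x, ...) {
  tibble(
    B = x$B,
    mean_stability = x$mean_stability,
    mean_ari = mean(x$replicates$ari, na.rm = TRUE),
    min_ari = suppressWarnings(min(x$replicates$ari, na.rm = TRUE))
  )
}
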