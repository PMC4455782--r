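# Average-linkage agglomerative clustering on the reweighted contact graph.

new_hic_clusters <- function(clusters, unclustered, merge_trace, params) {
  structure(
    list(clusters = clusters, unclustered = unclustered,
         merge_trace = merge_trace, params = params),
    class = "hic_clusters"
  )
}

#' Average-linkage agglomeration of the contact graph
#'
#' Starting from singleton clusters, repeatedly merges the pair of clusters
#' with maximum average linkage, where
#' `linkage(A, B) = sum(weights of edges between A and B) / (|A| * |B|)`
#' and absent edges contribute 0. Merging stops when the number of clusters
#' reaches `n_clusters`, or when no positive-linkage pair remains. Only
#' nodes carrying at least one edge enter the agglomeration, so the target
#' count is never consumed by debris: nodes stripped of all edges (e.g. by
#' Jarvis-Patrick removal) are reported as unclustered rather than
#' force-merged, while disconnected components that merge to completion
#' remain clusters in their own right and count toward the target.
#'
#' Ties between equal linkages are broken deterministically: the pair whose
#' smallest member contig id is lexicographically least is merged first.
#'
#' @param graph A `contact_graph`, typically the output of
#'   [jarvis_patrick()].
#' @param n_clusters Target number of clusters (>= 1).
#' @return A `hic_clusters` object: `$clusters` (tibble `contig_id`,
#'   `cluster`), `$unclustered` (tibble `contig_id`, `reason`),
#'   `$merge_trace` (one row per merge: representative ids, linkage, number
#'   of clusters and connected clusters after the merge, cumulative
#'   intra-cluster raw links), `$params`.
#' @export
agglomerate <- function(graph, n_clusters) {
  if (length(n_clusters) != 1L || is.na(n_clusters) || n_clusters < 1) {
    abort("n_clusters must be a single integer >= 1")
  }
  n_clusters <- as.integer(n_clusters)
  edges <- graph$edges
  ids <- sort(unique(c(edges$contig1, edges$contig2)))
  n <- length(ids)
  if (n_clusters > max(n, 0L)) {
    abort(paste0("n_clusters (", n_clusters, ") exceeds the number of ",
                 "linkable nodes (", n, ")"))
  }
  idx <- stats::setNames(seq_len(n), ids)
  removed <- attr(graph, "jp_removed") %||%
    tibble(contig1 = character(), contig2 = character(),
           raw_links = integer(), weight = double())
  total_raw <- sum(edges$raw_links) + sum(removed$raw_links)

  S <- matrix(0, n, n)
  S[cbind(idx[edges$contig1], idx[edges$contig2])] <- edges$weight
  S[cbind(idx[edges$contig2], idx[edges$contig1])] <- edges$weight
  Rm <- matrix(0, n, n)
  raw_all <- dplyr::bind_rows(
    edges[, c("contig1", "contig2", "raw_links")],
    removed[removed$contig1 %in% ids & removed$contig2 %in% ids,
            c("contig1", "contig2", "raw_links")]
  )
  Rm[cbind(idx[raw_all$contig1], idx[raw_all$contig2])] <- raw_all$raw_links
  Rm[cbind(idx[raw_all$contig2], idx[raw_all$contig1])] <- raw_all$raw_links

  sizes <- rep(1L, n)
  minid <- ids
  active <- rep(TRUE, n)
  members <- as.list(seq_len(n))
  L <- S
  diag(L) <- -Inf
  n_active <- n
  intra_raw <- 0

  # per-row maximum cache so each merge costs O(n) instead of O(n^2)
  rarg <- max.col(L, ties.method = "first")
  rmax <- L[cbind(seq_len(n), rarg)]

  trace <- vector("list", max(n - 1L, 0L))
  step <- 0L
  while (n_active > n_clusters) {
    m <- max(rmax)
    if (!is.finite(m) || m <= 0) break
    rows <- which(rmax == m)
    cand <- do.call(rbind, lapply(rows, function(r) {
      cbind(r, which(L[r, ] == m))
    }))
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    if (nrow(cand) > 1L) {
      ka <- pmin(minid[cand[, 1L]], minid[cand[, 2L]])
      kb <- pmax(minid[cand[, 1L]], minid[cand[, 2L]])
      cand <- cand[order(ka, kb)[1L], , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    # keep the slot whose representative id is smaller
    if (minid[j] < minid[i]) { tmp <- i; i <- j; j <- tmp }

    step <- step + 1L
    intra_raw <- intra_raw + Rm[i, j]
    rec <- list(step = step, cluster_a = minid[i], cluster_b = minid[j],
                linkage = m, raw_between = Rm[i, j],
                size_product = as.numeric(sizes[i]) * sizes[j])

    S[i, ] <- S[i, ] + S[j, ]
    S[, i] <- S[i, ]
    S[i, i] <- 0
    S[j, ] <- 0; S[, j] <- 0
    Rm[i, ] <- Rm[i, ] + Rm[j, ]
    Rm[, i] <- Rm[i, ]
    Rm[i, i] <- 0
    Rm[j, ] <- 0; Rm[, j] <- 0
    sizes[i] <- sizes[i] + sizes[j]
    members[[i]] <- c(members[[i]], members[[j]])
    members[j] <- list(NULL)
    active[j] <- FALSE
    L[j, ] <- -Inf; L[, j] <- -Inf
    li <- ifelse(active, S[i, ] / (sizes[i] * sizes), -Inf)
    li[i] <- -Inf
    L[i, ] <- li
    L[, i] <- li
    n_active <- n_active - 1L

    # refresh the row-max cache: row i and j changed everywhere; any row
    # whose cached argmax pointed at i or j must be rescanned, others only
    # compare against their new entry in column i
    rarg[i] <- which.max(li); rmax[i] <- li[rarg[i]]
    rmax[j] <- -Inf; rarg[j] <- j
    improved <- li > rmax & active
    improved[c(i, j)] <- FALSE
    rmax[improved] <- li[improved]
    rarg[improved] <- i
    stale <- which(active & !improved & (rarg == i | rarg == j))
    stale <- setdiff(stale, c(i, j))
    for (r in stale) {
      rarg[r] <- which.max(L[r, ])
      rmax[r] <- L[r, rarg[r]]
    }

    rec$n_clusters <- n_active
    rec$intra_raw <- intra_raw
    trace[[step]] <- rec
  }
  merge_trace <- if (step > 0L) {
    dplyr::bind_rows(trace[seq_len(step)])
  } else {
    tibble(step = integer(), cluster_a = character(), cluster_b = character(),
           linkage = double(), raw_between = double(), size_product = double(),
           n_clusters = integer(), intra_raw = double())
  }

  # Label final clusters by decreasing total sequence length, ties by
  # smallest member id, for deterministic and stable output.
  len <- stats::setNames(graph$nodes$length, graph$nodes$contig_id)
  groups <- purrr::map(which(active), ~ ids[members[[.x]]])
  ord <- order(-purrr::map_dbl(groups, ~ sum(len[.x], na.rm = TRUE)),
               purrr::map_chr(groups, min))
  groups <- groups[ord]
  width <- max(2L, nchar(length(groups)))
  labels <- sprintf(paste0("cluster_%0", width, "d"), seq_along(groups))
  clusters <- tibble(
    contig_id = unlist(purrr::map(groups, sort), use.names = FALSE),
    cluster = rep(labels, lengths(groups))
  )
  iso <- sort(setdiff(graph$nodes$contig_id, ids))
  jp_iso <- attr(graph, "jp_isolated") %||% character()
  unclustered <- tibble(
    contig_id = iso,
    reason = as.character(ifelse(iso %in% jp_iso, "jp_isolated", "no_linkage"))
  )
  new_hic_clusters(
    clusters, unclustered, merge_trace,
    params = list(n_clusters = n_clusters, n_final = length(groups),
                  n_nodes = n, total_raw = total_raw,
                  jp = attr(graph, "jp"))
  )
}

#' @export
print.hic_clusters <- function(x, ...) {
  sizes <- table(x$clusters$cluster)
  cat("<hic_clusters> ", length(sizes), " cluster(s), ",
      nrow(x$clusters), " contig(s) clustered, ",
      nrow(x$unclustered), " unclustered\n", sep = "")
  if (length(sizes) > 0L) {
    cat("  sizes: ", paste(utils::head(as.integer(sizes), 20L), collapse = ", "),
        if (length(sizes) > 20L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a cluster assignment
#'
#' @param x A `hic_clusters` object.
#' @param ... Unused.
#' @return Tibble with `contig_id`, `cluster` (the sentinel `"unclustered"`
#'   for unplaced contigs), `clustered` and `reason`.
#' @export
tidy.hic_clusters <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$clusters, clustered = TRUE, reason = NA_character_),
    tibble(contig_id = x$unclustered$contig_id, cluster = "unclustered",
           clustered = FALSE, reason = x$unclustered$reason)
  )
}

#' One-row summary of a cluster assignment
#'
#' @param x A `hic_clusters` object.
#' @param ... Unused.
#' @return Tibble with cluster and contig counts and the number of merges.
#' @export
glance.hic_clusters <- function(x, ...) {
  tibble(
    n_clusters = length(unique(x$clusters$cluster)),
    n_clustered = nrow(x$clusters),
    n_unclustered = nrow(x$unclustered),
    n_merges = nrow(x$merge_trace)
  )
}

#' Plot cluster sizes
#'
#' @param object A `hic_clusters` object.
#' @param contigs Optional contig tibble; if given, bars show total contig
#'   length per cluster instead of contig counts.
#' @param ... Unused.
#' @return A ggplot bar chart of cluster sizes.
#' @export
autoplot.hic_clusters <- function(object, contigs = NULL, ...) {
  df <- object$clusters
  if (!is.null(contigs)) {
    df <- dplyr::inner_join(df, tibble(contig_id = contigs$id,
                                       length = contigs$length),
                            by = "contig_id")
    sizes <- dplyr::summarise(dplyr::group_by(df, .data$cluster),
                              size = sum(.data$length), .groups = "drop")
    ylab <- "total contig length (bp)"
  } else {
    sizes <- dplyr::count(df, .data$cluster, name = "size")
    ylab <- "contigs"
  }
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$cluster, y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cluster", y = ylab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write / read a cluster assignment table
#'
#' On-disk form: `contig_id<TAB>cluster_id` with the sentinel
#' `cluster_id = "unclustered"`.
#'
#' @param x A `hic_clusters` object.
#' @param path TSV path.
#' @return `path` invisibly (write); a `hic_clusters` (read; merge trace
#'   empty, unclustered reasons `"unspecified"`).
#' @export
write_cluster_table <- function(x, path) {
  write_tsv_atomic(tidy(x)[, c("contig_id", "cluster")], path, col_names = FALSE)
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  x <- readr::read_tsv(path, col_names = c("contig_id", "cluster"),
                       col_types = "cc", progress = FALSE)
  uncl <- x$cluster == "unclustered"
  new_hic_clusters(
    clusters = x[!uncl, ],
    unclustered = tibble(contig_id = x$contig_id[uncl], reason = "unspecified"),
    merge_trace = tibble(),
    params = list()
  )
}

#' Export clusters as per-cluster FASTA files
#'
#' @param x A `hic_clusters` object.
#' @param contigs Contig tibble retaining `seq`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_cluster_fasta <- function(x, contigs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (cl in unique(x$clusters$cluster)) {
    ids <- x$clusters$contig_id[x$clusters$cluster == cl]
    p <- file.path(dir, paste0(cl, ".fasta"))
    write_assembly(contigs[contigs$id %in% ids, ], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
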