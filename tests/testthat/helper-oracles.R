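# Independent brute-force references used to validate the fast paths.

# O(|s| * |m|) scan for motif occurrences on both strands, 0-based.
bf_sites <- function(seq, motif) {
  seq <- toupper(seq)
  motif <- toupper(motif)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(motif, "")[[1]]), collapse = ""))
  hits <- integer()
  for (m in unique(c(motif, rc))) {
    w <- nchar(m)
    for (i in seq_len(max(nchar(seq) - w + 1L, 0L))) {
      if (substr(seq, i, i + w - 1L) == m) hits <- c(hits, i - 1L)
    }
  }
  sort(unique(hits))
}

# Flood-fill connected components over an edge tibble.
bf_components <- function(node_ids, edges) {
  adj <- stats::setNames(vector("list", length(node_ids)), node_ids)
  for (i in seq_len(nrow(edges))) {
    a <- edges$contig1[i]; b <- edges$contig2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character()
  comps <- list()
  for (v in node_ids) {
    if (v %in% seen) next
    queue <- v
    comp <- character()
    while (length(queue) > 0L) {
      x <- queue[[1L]]; queue <- queue[-1L]
      if (x %in% comp) next
      comp <- c(comp, x)
      queue <- c(queue, setdiff(adj[[x]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Brute-force Jarvis-Patrick: explicit NN lists and pairwise intersections.
bf_jp_shared <- function(graph, k) {
  edges <- graph$edges
  ids <- sort(unique(c(edges$contig1, edges$contig2)))
  nn <- stats::setNames(vector("list", length(ids)), ids)
  for (v in ids) {
    sel <- edges$contig1 == v | edges$contig2 == v
    nb <- ifelse(edges$contig1[sel] == v, edges$contig2[sel], edges$contig1[sel])
    w <- edges$weight[sel]
    ord <- order(-w, nb)
    nn[[v]] <- nb[ord][seq_len(min(k, length(nb)))]
  }
  vapply(seq_len(nrow(edges)), function(i) {
    length(intersect(nn[[edges$contig1[i]]], nn[[edges$contig2[i]]]))
  }, integer(1))
}

# Brute-force average-linkage agglomeration that recomputes the full
# linkage matrix at every step, with the same stopping and tie-break rules.
bf_agglomerate_trace <- function(graph, n_clusters) {
  edges <- graph$edges
  ids <- sort(unique(c(edges$contig1, edges$contig2)))
  wmap <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(edges))) {
    assign(paste(edges$contig1[i], edges$contig2[i]), edges$weight[i],
           envir = wmap)
    assign(paste(edges$contig2[i], edges$contig1[i]), edges$weight[i],
           envir = wmap)
  }
  w <- function(a, b) {
    v <- mget(paste(a, b), envir = wmap, ifnotfound = 0)[[1]]
    v
  }
  clusters <- lapply(ids, identity)
  trace <- list()
  repeat {
    nc <- length(clusters)
    if (nc <= n_clusters) break
    link <- matrix(0, nc, nc)
    for (i in seq_len(nc - 1L)) {
      for (j in seq.int(i + 1L, nc)) {
        s <- 0
        for (a in clusters[[i]]) for (b in clusters[[j]]) s <- s + w(a, b)
        link[i, j] <- link[j, i] <- s / (length(clusters[[i]]) * length(clusters[[j]]))
      }
    }
    m <- max(link)
    if (m <= 0) break
    cand <- which(link == m, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    minids <- vapply(clusters, min, character(1))
    ka <- pmin(minids[cand[, 1]], minids[cand[, 2]])
    kb <- pmax(minids[cand[, 1]], minids[cand[, 2]])
    pick <- cand[order(ka, kb)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    if (minids[j] < minids[i]) { t <- i; i <- j; j <- t }
    trace[[length(trace) + 1L]] <- tibble::tibble(
      cluster_a = minids[i], cluster_b = minids[j], linkage = m
    )
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  list(
    trace = if (length(trace) > 0) dplyr::bind_rows(trace)
    else tibble::tibble(cluster_a = character(), cluster_b = character(),
                        linkage = double()),
    clusters = lapply(clusters, sort)
  )
}

# Exhaustive per-contig purity tally.
bf_purity <- function(assignment, truth, contigs) {
  len <- stats::setNames(contigs$length, contigs$id)
  truth_sets <- split(truth$species, truth$contig_id)
  rows <- list()
  for (cl in sort(unique(assignment$clusters$cluster))) {
    members <- assignment$clusters$contig_id[assignment$clusters$cluster == cl]
    total <- sum(len[members])
    species <- unique(unlist(lapply(members, function(m) {
      if (m %in% names(truth_sets)) truth_sets[[m]] else "unknown"
    })))
    for (s in sort(species)) {
      l <- sum(vapply(members, function(m) {
        sets <- if (m %in% names(truth_sets)) truth_sets[[m]] else "unknown"
        if (s %in% sets) len[[m]] else 0
      }, numeric(1)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cluster = cl, species = s, fraction = l / total
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Canonical form of a partition: sorted list of sorted member vectors.
canonical_partition <- function(clusters_tbl) {
  parts <- lapply(split(clusters_tbl$contig_id, clusters_tbl$cluster), sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1L))])
}
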