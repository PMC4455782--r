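# Programmatic fixtures: everything is built in code at test time.

write_fasta_fixture <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(purrr::imap(records, ~ c(paste0(">", .y), .x))), path)
  path
}

# A minimal annotated contig table built directly (no file round trip).
make_contigs <- function(seqs, motif = "AAGCTT") {
  contigs <- tibble::tibble(
    id = names(seqs), length = unname(nchar(unlist(seqs))),
    seq = unname(unlist(seqs))
  )
  hicdeconv::annotate_sites(contigs, motif)
}

make_pair <- function(c1, p1, c2, p2, read_id = NULL, s1 = "+", s2 = "-") {
  tibble::tibble(
    read_id = read_id %||% paste0("r", stats::runif(1)),
    contig1 = c1, pos1 = as.integer(p1), strand1 = s1,
    contig2 = c2, pos2 = as.integer(p2), strand2 = s2
  )
}

# Construct a contact_graph directly from an edge list (weights given),
# bypassing pair tallying; raw links default to round(weight * 20).
make_graph <- function(edges, lengths = NULL, site_counts = NULL) {
  ids <- sort(unique(c(edges$contig1, edges$contig2)))
  if (!"raw_links" %in% names(edges)) {
    edges$raw_links <- as.integer(pmax(1, round(edges$weight * 20)))
  }
  nodes <- tibble::tibble(
    contig_id = ids,
    length = if (is.null(lengths)) rep(10000L, length(ids)) else lengths[ids],
    site_count = if (is.null(site_counts)) rep(1L, length(ids)) else site_counts[ids]
  )
  a <- pmin(edges$contig1, edges$contig2)
  b <- pmax(edges$contig1, edges$contig2)
  edges$contig1 <- a
  edges$contig2 <- b
  edges <- dplyr::arrange(
    edges[, c("contig1", "contig2", "raw_links", "weight")],
    contig1, contig2
  )
  hicdeconv:::new_contact_graph(nodes, edges)
}

# Random weighted graph with dyadic-rational weights so that linkage sums
# are exact in floating point regardless of summation order.
random_graph <- function(n, p = 0.35, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) pairs <- t(utils::combn(ids, 2))[1, , drop = FALSE]
  make_graph(tibble::tibble(
    contig1 = pairs[, 1], contig2 = pairs[, 2],
    weight = sample(1:64, nrow(pairs), replace = TRUE) / 64,
    raw_links = sample(1:50, nrow(pairs), replace = TRUE)
  ))
}

# Planted S-block graph: dense strong within-block edges, sparse weak
# between-block edges (within/between weight ratio >= `ratio`).
planted_graph <- function(S, m = 10, ratio = 20, seed = 1) {
  set.seed(seed)
  blocks <- lapply(seq_len(S), function(s) sprintf("s%02d_n%02d", s, seq_len(m)))
  within <- dplyr::bind_rows(lapply(blocks, function(ids) {
    pairs <- t(utils::combn(ids, 2))
    tibble::tibble(
      contig1 = pairs[, 1], contig2 = pairs[, 2],
      weight = stats::runif(nrow(pairs), 1, 1.5),
      raw_links = sample(15:25, nrow(pairs), replace = TRUE)
    )
  }))
  between <- dplyr::bind_rows(apply(utils::combn(S, 2), 2, function(ij) {
    a <- sample(blocks[[ij[1]]], 2)
    b <- sample(blocks[[ij[2]]], 2)
    tibble::tibble(
      contig1 = a, contig2 = b,
      weight = stats::runif(2, 0.5, 1) / ratio,
      raw_links = 1L
    )
  }))
  make_graph(dplyr::bind_rows(within, between))
}

# Small simulated community + library shared by several tests.
small_sim <- function(seed = 7, n_species = 4, genome_length = 200000,
                      n_pairs = 40000, noise_fraction = 0, ...) {
  cfg <- hicdeconv::sim_config(
    species = tibble::tibble(
      label = sprintf("sp%d", seq_len(n_species)),
      genome_length = genome_length
    ),
    n_pairs = n_pairs, noise_fraction = noise_fraction, seed = seed, ...
  )
  com <- hicdeconv::simulate_genomes(cfg)
  pairs <- hicdeconv::simulate_hic(cfg, com)
  list(cfg = cfg, com = com, pairs = pairs)
}

`%||%` <- rlang::`%||%`
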