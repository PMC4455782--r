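test_that("edge weights follow the site-count normalization", {
  seqs <- list(
    c1 = paste0(strrep("C", 10), "AAGCTT", strrep("C", 10), "AAGCTT"),
    c2 = paste0(strrep("G", 4), paste(rep("AAGCTTG", 5), collapse = ""))
  )
  contigs <- make_contigs(seqs)
  expect_equal(contigs$site_count, c(2L, 5L))
  pairs <- dplyr::bind_rows(purrr::map(1:10, ~ make_pair("c1", 10, "c2", 5,
                                                         read_id = paste0("r", .x))))
  g <- build_contact_graph(pairs, contigs)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$raw_links, 10L)
  expect_equal(g$edges$weight, 10 / (2 * 5))

  g_sum <- build_contact_graph(pairs, contigs, normalization = "sum")
  expect_equal(g_sum$edges$weight, 10 / (2 + 5))

  one <- make_contigs(list(a = "AAGCTT", b = "AAGCTT"))
  g1 <- build_contact_graph(make_pair("a", 0, "b", 0, read_id = "x"), one)
  expect_equal(g1$edges$weight, 1)  # identity denominator
})

test_that("raw link tallies equal an exhaustive count and links are conserved", {
  set.seed(31)
  ids <- paste0("c", 1:6)
  contigs <- make_contigs(stats::setNames(
    as.list(rep(paste0("AAGCTT", strrep("A", 20)), 6)), ids
  ))
  pairs <- dplyr::bind_rows(purrr::map(1:200, function(i) {
    ab <- sample(ids, 2, replace = TRUE)  # includes intra-contig pairs
    make_pair(ab[1], sample(0:25, 1), ab[2], sample(0:25, 1),
              read_id = paste0("r", i))
  }))
  g <- build_contact_graph(pairs, contigs)

  # brute-force tally of unordered inter-contig pairs
  key <- paste(pmin(pairs$contig1, pairs$contig2),
               pmax(pairs$contig1, pairs$contig2))
  inter <- pairs$contig1 != pairs$contig2
  tally <- table(key[inter])
  expect_equal(nrow(g$edges), length(tally))
  for (i in seq_len(nrow(g$edges))) {
    k <- paste(g$edges$contig1[i], g$edges$contig2[i])
    expect_equal(g$edges$raw_links[i], as.integer(tally[[k]]))
  }
  # conservation: inter edges + intra tally == total input pairs
  expect_identical(sum(g$edges$raw_links) + g$intra_links, nrow(pairs))
  # symmetry: canonical edge orientation means order-independent lookup
  expect_true(all(g$edges$contig1 < g$edges$contig2))
})

test_that("zero-site contigs are excluded from the node set", {
  contigs <- make_contigs(list(a = "AAGCTTAA", b = "AAGCTTAA",
                               z = "CCCCCCCC"))
  pairs <- dplyr::bind_rows(
    make_pair("a", 0, "b", 0, read_id = "r1"),
    make_pair("a", 0, "z", 0, read_id = "r2")
  )
  g <- build_contact_graph(pairs, contigs)
  expect_setequal(g$nodes$contig_id, c("a", "b"))
  expect_equal(nrow(g$edges), 1L)
})

test_that("link table round trip preserves the graph", {
  sim <- small_sim(seed = 3, n_species = 2, genome_length = 50000,
                   n_pairs = 2000)
  kept <- filter_pairs(sim$pairs, sim$com$contigs)
  g <- build_contact_graph(kept, sim$com$contigs)
  path <- tempfile(fileext = ".tsv")
  write_link_table(g, path)
  g2 <- read_link_table(path, sim$com$contigs)
  expect_equal(g2$edges$raw_links, g$edges$raw_links)
  expect_equal(g2$edges$weight, g$edges$weight)
})

test_that("largest_component matches a flood-fill oracle and breaks ties", {
  # two components, sizes 3 and 2
  g <- make_graph(tibble::tibble(
    contig1 = c("a", "b", "a", "x"),
    contig2 = c("b", "c", "c", "y"),
    weight = 1
  ))
  comp <- largest_component(g)
  expect_setequal(comp$nodes$contig_id, c("a", "b", "c"))
  expect_setequal(discarded_contigs(comp), c("x", "y"))

  # identity on a single component
  g1 <- make_graph(tibble::tibble(contig1 = "a", contig2 = "b", weight = 1))
  expect_equal(nrow(largest_component(g1)$nodes), 2L)
  expect_length(discarded_contigs(largest_component(g1)), 0L)

  # random graphs: kept component equals a BFS flood fill's largest
  for (seed in 1:10) {
    rg <- random_graph(sample(5:25, 1), p = 0.12, seed = seed)
    comps <- bf_components(rg$nodes$contig_id, rg$edges)
    sizes <- lengths(comps)
    keep <- largest_component(rg)
    expect_equal(nrow(keep$nodes), max(sizes))
    expect_true(list(sort(keep$nodes$contig_id)) %in% comps)
  }

  # size tie broken by total sequence length, then smallest member id
  lens <- c(a = 10L, b = 10L, x = 500L, y = 500L)
  gt <- make_graph(tibble::tibble(contig1 = c("a", "x"), contig2 = c("b", "y"),
                                  weight = 1), lengths = lens)
  expect_setequal(largest_component(gt)$nodes$contig_id, c("x", "y"))
  lens2 <- c(a = 10L, b = 10L, x = 10L, y = 10L)
  gt2 <- make_graph(tibble::tibble(contig1 = c("x", "a"), contig2 = c("y", "b"),
                                   weight = 1), lengths = lens2)
  expect_setequal(largest_component(gt2)$nodes$contig_id, c("a", "b"))

  expect_error(largest_component(hicdeconv:::new_contact_graph(
    tibble::tibble(contig_id = character(), length = integer(),
                   site_count = integer()),
    tibble::tibble(contig1 = character(), contig2 = character(),
                   raw_links = integer(), weight = double())
  )), "no nodes")
})
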