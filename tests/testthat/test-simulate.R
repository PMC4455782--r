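test_that("fixed binning produces the expected contig layout", {
  cfg <- sim_config(
    species = tibble::tibble(label = c("A", "B"), genome_length = 100000),
    seed = 3
  )
  com <- simulate_genomes(cfg)
  expect_equal(nrow(com$contigs), 20L)
  expect_equal(as.integer(table(com$contigs$species)), c(10L, 10L))
  expect_true(all(com$contigs$length == 10000L))
  # contig sequences tile the replicon
  first <- com$contigs[com$contigs$replicon == "A_chr1", ]
  expect_equal(first$start, seq(0L, 90000L, by = 10000L))
})

test_that("invalid configs are rejected with the offending fields", {
  sp <- tibble::tibble(label = "A", genome_length = 100000)
  expect_error(sim_config(sp, noise_fraction = 2), "noise_fraction")
  expect_error(sim_config(dplyr::mutate(sp, abundance = -1)), "abundance")
  expect_error(
    sim_config(tibble::tibble(label = "A", genome_length = 500,
                              n_chromosomes = 1)),
    "genome_length"
  )
})

test_that("shared segments label exactly the overlapping bins with both species", {
  cfg <- sim_config(
    species = tibble::tibble(label = c("A", "B"), genome_length = 100000),
    shared_segments = tibble::tibble(species_a = "A", species_b = "B",
                                     segment_length = 10000),
    seed = 11
  )
  com <- simulate_genomes(cfg)
  multi <- dplyr::count(com$truth, contig_id)
  multi <- multi$contig_id[multi$n > 1]
  # every multi-label contig overlaps a recorded shared interval
  ov <- dplyr::inner_join(
    com$contigs[com$contigs$id %in% multi, c("id", "replicon", "start", "length")],
    com$shared_intervals, by = "replicon"
  )
  expect_true(all(multi %in% ov$id))
  overlaps <- ov$start.x < ov$end & ov$start.x + ov$length > ov$start.y
  expect_true(all(tapply(overlaps, ov$id, any)))
  # and conversely, contigs overlapping an interval are multi-label
  allov <- dplyr::inner_join(com$contigs[, c("id", "replicon", "start", "length")],
                             com$shared_intervals, by = "replicon")
  hit <- allov$id[allov$start.x < allov$end &
                    allov$start.x + allov$length > allov$start.y]
  expect_setequal(sort(unique(hit)), sort(multi))
  # destination bins carry the source sequence verbatim
  expect_true(length(multi) >= 1)
})

test_that("the same seed reproduces byte-identical outputs", {
  cfg <- sim_config(
    species = tibble::tibble(label = c("A", "B"), genome_length = 50000),
    n_pairs = 500, seed = 21
  )
  d1 <- tempfile(); d2 <- tempfile()
  c1 <- simulate_genomes(cfg)
  write_community(c1, d1, simulate_hic(cfg, c1))
  c2 <- simulate_genomes(cfg)
  write_community(c2, d2, simulate_hic(cfg, c2))
  for (f in c("genomes.fasta", "contigs.fasta", "truth.tsv", "library.pairs")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("the library has the requested size and respects truth structure", {
  sim <- small_sim(seed = 31, n_species = 3, genome_length = 60000,
                   n_pairs = 1000)
  expect_equal(nrow(sim$pairs), 1000L)
  # noise-free: the two contigs of every pair share at least one label
  truth_sets <- split(sim$com$truth$species, sim$com$truth$contig_id)
  shared <- purrr::map2_lgl(sim$pairs$contig1, sim$pairs$contig2,
                            ~ length(intersect(truth_sets[[.x]],
                                               truth_sets[[.y]])) > 0)
  expect_true(all(shared))
})

test_that("endpoints land within the site window of a restriction site", {
  sim <- small_sim(seed = 33, n_species = 2, genome_length = 80000,
                   n_pairs = 2000, site_window = 500)
  # in replicon coordinates every snapped endpoint is within the window of
  # a site (the simulator's guarantee)
  ctg <- sim$com$contigs
  start_of <- stats::setNames(ctg$start, ctg$id)
  rep_of <- stats::setNames(ctg$replicon, ctg$id)
  sites_of <- stats::setNames(sim$com$replicons$sites, sim$com$replicons$replicon)
  check_end <- function(cid, pos) {
    g <- start_of[[cid]] + pos
    sites <- sites_of[[rep_of[[cid]]]]
    length(sites) == 0L || min(abs(g - sites)) <= 500
  }
  ok <- purrr::map2_lgl(sim$pairs$contig1, sim$pairs$pos1, check_end) &
    purrr::map2_lgl(sim$pairs$contig2, sim$pairs$pos2, check_end)
  expect_true(all(ok))
  # and consequently most pairs survive the proximity filter; the losses
  # are zero-site contigs and contig-boundary effects
  kept <- filter_pairs(sim$pairs, sim$com$contigs, site_window = 500)
  expect_gt(filter_report(kept)$kept / filter_report(kept)$total, 0.8)
})

test_that("per-species pair counts follow abundance x lysis x length weights", {
  sp <- tibble::tibble(
    label = c("A", "B", "C"),
    genome_length = c(100000, 100000, 200000),
    abundance = c(1, 2, 1),
    lysis_efficiency = c(1, 1, 0.5)
  )
  cfg <- sim_config(species = sp, n_pairs = 100000, seed = 41,
                    cis_fraction = 0.8)
  com <- simulate_genomes(cfg)
  pairs <- simulate_hic(cfg, com)
  species_of <- stats::setNames(com$contigs$species, com$contigs$id)
  counts <- table(factor(species_of[pairs$contig1], levels = sp$label))
  w <- sp$abundance * sp$lysis_efficiency * sp$genome_length
  p <- stats::chisq.test(as.vector(counts), p = w / sum(w))$p.value
  expect_gt(p, 0.001)
})

test_that("cis separations follow the configured power-law decay", {
  # sampler versus the analytic inverse-CDF law
  set.seed(43)
  smin <- 1000; smax <- 1e6
  s1 <- hicdeconv:::sample_powerlaw(1e5, smin, smax, 1)
  ks1 <- suppressWarnings(stats::ks.test(s1, function(q) log(q / smin) / log(smax / smin)))
  expect_gt(ks1$p.value, 0.001)
  a <- 1.5
  s2 <- hicdeconv:::sample_powerlaw(1e5, smin, smax, a)
  cdf2 <- function(q) (q^(1 - a) - smin^(1 - a)) / (smax^(1 - a) - smin^(1 - a))
  ks2 <- suppressWarnings(stats::ks.test(s2, cdf2))
  expect_gt(ks2$p.value, 0.001)

  # end to end: with no restriction sites the emitted separations are the
  # sampler's draws (single contig, cis only, snapping inert)
  cfg <- sim_config(
    species = tibble::tibble(label = "A", genome_length = 1e6),
    enzyme_motif = "AAGCTTAAGCTTAAGCTT",  # effectively absent from 1 Mb
    contig_mode = list(mode = "fixed_bins", bin = 1e6),
    n_pairs = 20000, cis_fraction = 1, seed = 47
  )
  com <- suppressWarnings(simulate_genomes(cfg))
  pairs <- suppressWarnings(simulate_hic(cfg, com))
  sep <- abs(pairs$pos1 - pairs$pos2)
  L <- 1e6
  ks3 <- suppressWarnings(
    stats::ks.test(sep, function(q) log(q / smin) / log((L - 1) / smin))
  )
  expect_gt(ks3$p.value, 0.001)
})

test_that("a species without sites triggers a warning on noise-free libraries", {
  cfg <- sim_config(
    species = tibble::tibble(label = c("A", "B"), genome_length = 50000),
    enzyme_motif = "AAGCTTAAGCTTAAGCTT",
    n_pairs = 10, seed = 51
  )
  com <- suppressWarnings(simulate_genomes(cfg))
  expect_warning(simulate_hic(cfg, com), "without restriction sites")
})

test_that("planted sites appear at the requested spacing", {
  cfg <- sim_config(
    species = tibble::tibble(label = "A", genome_length = 50000),
    planted_site_spacing = 2000, site_placement_jitter = 200,
    n_pairs = 10, seed = 53
  )
  com <- simulate_genomes(cfg)
  sites <- com$replicons$sites[[1]]
  # at least the ~24 planted sites (natural occurrences add more)
  expect_gte(length(sites), 24L)
  expect_lt(max(diff(sort(sites))), 2500L)
})
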