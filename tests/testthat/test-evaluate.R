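toy_assignment <- function(clusters) {
  hicdeconv:::new_hic_clusters(
    clusters = clusters,
    unclustered = tibble::tibble(contig_id = character(), reason = character()),
    merge_trace = tibble::tibble(), params = list()
  )
}

toy_contigs <- function(lengths) {
  tibble::tibble(id = names(lengths), length = unname(lengths),
                 site_count = 1L)
}

test_that("purity cells are length-weighted with multi-membership", {
  contigs <- toy_contigs(c(c1 = 10000L, c2 = 10000L))
  truth <- tibble::tibble(contig_id = c("c1", "c2", "c2"),
                          species = c("A", "A", "B"))
  asg <- toy_assignment(tibble::tibble(contig_id = c("c1", "c2"),
                                       cluster = "k1"))
  pm <- purity_matrix(asg, truth, contigs)
  m <- as.matrix(pm)
  expect_equal(m["k1", "A"], 1.0)
  expect_equal(m["k1", "B"], 0.5)

  solo <- toy_assignment(tibble::tibble(contig_id = "c1", cluster = "k1"))
  expect_equal(as.matrix(purity_matrix(solo, truth, contigs))["k1", "A"], 1.0)
})

test_that("purity matches an exhaustive per-contig tally on random toys", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    ids <- sprintf("c%02d", 1:n)
    contigs <- toy_contigs(stats::setNames(sample(1000:20000, n), ids))
    truth <- tibble::tibble(
      contig_id = rep(ids, times = sample(1:2, n, replace = TRUE))
    )
    truth$species <- sample(LETTERS[1:4], nrow(truth), replace = TRUE)
    truth <- dplyr::distinct(truth)
    asg <- toy_assignment(tibble::tibble(
      contig_id = ids, cluster = sample(c("k1", "k2", "k3"), n, replace = TRUE)
    ))
    got <- dplyr::arrange(tibble::as_tibble(purity_matrix(asg, truth, contigs)),
                          cluster, species)
    want <- dplyr::arrange(bf_purity(asg, truth, contigs), cluster, species)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE, label = paste("toy", i))
  }
})

test_that("purity rows sum to exactly 1 under single-membership truth", {
  set.seed(52)
  ids <- sprintf("c%02d", 1:12)
  contigs <- toy_contigs(stats::setNames(sample(1000:9999, 12), ids))
  truth <- tibble::tibble(contig_id = ids,
                          species = sample(c("A", "B", "C"), 12, replace = TRUE))
  asg <- toy_assignment(tibble::tibble(
    contig_id = ids, cluster = sample(c("k1", "k2"), 12, replace = TRUE)
  ))
  sums <- rowSums(as.matrix(purity_matrix(asg, truth, contigs)))
  expect_true(all(sums == 1))
})

test_that("accuracy uses membership semantics and excludes unclustered", {
  # perfect single-species clustering -> both accuracies 1.0
  ids <- sprintf("c%02d", 1:10)
  contigs <- toy_contigs(stats::setNames(rep(10000L, 10), ids))
  truth <- tibble::tibble(contig_id = ids,
                          species = rep(c("A", "B"), each = 5))
  asg <- toy_assignment(tibble::tibble(
    contig_id = ids, cluster = rep(c("k1", "k2"), each = 5)
  ))
  acc <- clustering_accuracy(asg, truth, contigs)
  expect_equal(acc$length_weighted_accuracy, 1.0)
  expect_equal(acc$count_weighted_accuracy, 1.0)

  # one of 100 contigs misassigned -> count-weighted 0.99
  ids <- sprintf("c%03d", 1:100)
  contigs <- toy_contigs(stats::setNames(rep(10000L, 100), ids))
  truth <- tibble::tibble(contig_id = ids,
                          species = rep(c("A", "B"), each = 50))
  cl <- rep(c("k1", "k2"), each = 50)
  cl[1] <- "k2"
  asg <- toy_assignment(tibble::tibble(contig_id = ids, cluster = cl))
  acc <- clustering_accuracy(asg, truth, contigs)
  expect_equal(acc$count_weighted_accuracy, 0.99)

  # a contig shared by two species is correct in either parent cluster
  contigs <- toy_contigs(c(a1 = 10000L, a2 = 10000L, b1 = 10000L,
                           b2 = 10000L, sh = 10000L))
  truth <- tibble::tibble(
    contig_id = c("a1", "a2", "b1", "b2", "sh", "sh"),
    species = c("A", "A", "B", "B", "A", "B")
  )
  for (home in c("kA", "kB")) {
    asg <- toy_assignment(tibble::tibble(
      contig_id = c("a1", "a2", "b1", "b2", "sh"),
      cluster = c("kA", "kA", "kB", "kB", home)
    ))
    acc <- clustering_accuracy(asg, truth, contigs)
    expect_equal(acc$count_weighted_accuracy, 1.0, label = home)
    expect_equal(acc$length_weighted_accuracy, 1.0, label = home)
  }

  # unclustered contigs are excluded from denominators
  asg <- toy_assignment(tibble::tibble(contig_id = c("a1", "b1"),
                                       cluster = c("kA", "kB")))
  asg$unclustered <- tibble::tibble(contig_id = c("a2", "b2", "sh"),
                                    reason = "zero_sites")
  acc <- clustering_accuracy(asg, truth, contigs)
  expect_equal(acc$clustered_contigs, 2L)
  expect_equal(acc$clustered_length, 20000L)
})

test_that("contigs without truth entries fall under the unknown label", {
  contigs <- toy_contigs(c(c1 = 10000L, c2 = 30000L))
  truth <- tibble::tibble(contig_id = "c1", species = "A")
  asg <- toy_assignment(tibble::tibble(contig_id = c("c1", "c2"),
                                       cluster = "k1"))
  m <- as.matrix(purity_matrix(asg, truth, contigs))
  expect_equal(m["k1", "unknown"], 0.75)
  acc_incl <- clustering_accuracy(asg, truth, contigs, unknown = "include")
  # cluster called "unknown" (0.75 > 0.25), so only c2 is correct
  expect_equal(acc_incl$count_weighted_accuracy, 0.5)
  acc_excl <- clustering_accuracy(asg, truth, contigs, unknown = "exclude")
  expect_equal(acc_excl$clustered_contigs, 1L)
})

test_that("the unclustered report decomposes by reason and conserves length", {
  contigs <- toy_contigs(c(a = 10000L, z = 5000L, w = 2000L))
  asg <- toy_assignment(tibble::tibble(contig_id = "a", cluster = "k1"))
  asg$unclustered <- tibble::tibble(
    contig_id = c("z", "w"),
    reason = c("zero_sites", "outside_component")
  )
  rep <- unclustered_report(asg, contigs)
  expect_equal(rep$total_length, 7000L)
  expect_equal(rep$zero_site_fraction, 5000 / 7000)
  expect_equal(sum(rep$breakdown$length), rep$total_length)

  all_in <- toy_assignment(tibble::tibble(contig_id = c("a", "z", "w"),
                                          cluster = "k1"))
  rep0 <- unclustered_report(all_in, contigs)
  expect_equal(rep0$total_length, 0L)
})
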