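test_that("unique/enriched fractions are read-weighted with the <=50 rule", {
  set.seed(61)
  cl <- clusters_with_counts(c(60L, 40L))
  expect_equal(unname(classify_clusters(cl)), c(0.4, 0.6))

  # a cluster of exactly 50 reads is unique ("50 sequences or fewer")
  cl50 <- clusters_with_counts(50L)
  expect_equal(unname(classify_clusters(cl50)["unique_fraction"]), 1.0)

  cl_big <- clusters_with_counts(c(200L, 80L))
  expect_equal(unname(classify_clusters(cl_big)["enriched_fraction"]), 1.0)

  empty <- greedy_cluster(round_counts(integer(0)))
  expect_warning(out <- classify_clusters(empty), "no clusters")
  expect_equal(unname(out), c(0, 0))
})

test_that("read-count bins respect the printed band edges", {
  set.seed(62)
  cl <- clusters_with_counts(c(10L, 11L))
  bf <- bin_clusters(cl)
  expect_equal(unname(bf["<=10"]), 10 / 21)
  expect_equal(unname(bf["11-100"]), 11 / 21)
  expect_equal(sum(bf), 1.0)

  expect_equal(unname(bin_clusters(clusters_with_counts(10001L))[">10000"]), 1.0)

  edge <- bin_clusters(clusters_with_counts(c(5000L, 5001L)))
  expect_equal(unname(edge["1001-5000"]), 5000 / 10001)
  expect_equal(unname(edge["5001-10000"]), 5001 / 10001)

  more <- bin_clusters(clusters_with_counts(c(100L, 101L, 1000L, 1001L)))
  expect_equal(unname(more["11-100"]), 100 / 2202)
  expect_equal(unname(more["101-1000"]), 1101 / 2202)
  expect_equal(unname(more["1001-5000"]), 1001 / 2202)
})

test_that("the nucleotide profile is count-weighted with N padding", {
  pa <- strrep("A", 40L); pc <- strrep("C", 40L)
  prof <- nucleotide_profile(round_counts(setNames(5L, pa)))
  expect_true(all(prof[, "A"] == 1))
  expect_true(all(rowSums(prof) == 1))

  half <- nucleotide_profile(round_counts(setNames(c(3L, 3L), c(pa, pc))))
  expect_true(all(half[, "A"] == 0.5 & half[, "C"] == 0.5))

  # fixed 3-sequence tally at var_len = 4
  pool <- round_counts(setNames(c(1L, 2L, 3L), c("AAAA", "ACGT", "TTTT")))
  p4 <- nucleotide_profile(pool, var_len = 4L)
  expect_equal(unname(p4[1L, ]), c(3, 0, 0, 3, 0) / 6)   # A:1+2, T:3
  expect_equal(unname(p4[2L, ]), c(1, 2, 0, 3, 0) / 6)
  expect_equal(unname(p4[3L, ]), c(1, 0, 2, 3, 0) / 6)
  expect_equal(unname(p4[4L, ]), c(1, 0, 0, 5, 0) / 6)

  # 39-mers pad N at the last position; 41-mers are truncated
  mix <- round_counts(setNames(c(1L, 1L), c(strrep("G", 39L), strrep("C", 41L))))
  pm <- nucleotide_profile(mix)
  expect_equal(unname(pm[40L, c("C", "N")]), c(0.5, 0.5))
  expect_equal(unname(pm[39L, c("C", "G")]), c(0.5, 0.5))
  expect_true(all(abs(rowSums(pm) - 1) < 1e-12))
})

test_that("diversity indices match their closed forms and direct evaluation", {
  expect_equal(richness(1), 1L)
  expect_equal(shannon(1), 0)
  expect_equal(inverse_simpson(1), 1)

  u4 <- rep(0.25, 4L)
  expect_equal(shannon(u4), log(4), tolerance = 1e-12)
  expect_equal(inverse_simpson(u4), 4, tolerance = 1e-12)

  p <- c(0.5, 0.3, 0.2)
  # direct evaluation of the printed formulas by hand:
  # H = -(0.5 ln 0.5 + 0.3 ln 0.3 + 0.2 ln 0.2) = 1.0296530140645737
  # S^-1 = 1 / (0.25 + 0.09 + 0.04) = 2.6315789473684212
  expect_equal(shannon(p), 1.0296530140645737, tolerance = 1e-12)
  expect_equal(inverse_simpson(p), 2.6315789473684212, tolerance = 1e-12)

  expect_error(shannon(c(0.5, 0.5, 0)), "> 0")
  expect_error(inverse_simpson(c(0.7, 0.7)), "sum to 1")
})

test_that("diversity indices agree with vegan on random abundances", {
  skip_if_not_installed("vegan")
  set.seed(63)
  for (k in 1:10) {
    x <- runif(sample(2:50, 1L))
    p <- x / sum(x)
    expect_equal(shannon(p), unname(vegan::diversity(p, index = "shannon")),
                 tolerance = 1e-10)
    expect_equal(inverse_simpson(p), unname(vegan::diversity(p, index = "invsimpson")),
                 tolerance = 1e-10)
  }
})

test_that("diversity bounds hold with equality only in the limits", {
  set.seed(64)
  for (k in 1:20) {
    x <- runif(sample(2:100, 1L))
    p <- x / sum(x)
    R <- richness(p)
    expect_true(shannon(p) > 0 & shannon(p) <= log(R) + 1e-12)
    expect_true(inverse_simpson(p) >= 1 & inverse_simpson(p) <= R + 1e-9)
  }
})

test_that("round_stats bundles consistent per-round summaries", {
  set.seed(65)
  pool <- random_pool(12L, 40L)
  cl <- greedy_cluster(pool)
  st <- round_stats(pool, cl)
  expect_equal(st$unique_fraction + st$enriched_fraction, 1.0)
  expect_equal(sum(st$bin_fractions), 1.0)
  expect_true(all(abs(rowSums(st$nt_profile) - 1) < 1e-9))
  expect_equal(st$richness, length(pool$counts))
  expect_lte(st$inverse_simpson, st$richness)
  expect_lte(st$shannon, log(st$richness))
  # cluster-level diversity is computed over cluster abundances
  st_cl <- round_stats(pool, cl, diversity_level = "cluster")
  expect_equal(st_cl$richness, nrow(cl))
})

test_that("pool diversity declines across rounds of a spiked selection", {
  H <- matrix(0, nrow = 50L, ncol = 7L)
  S <- matrix(0, nrow = 50L, ncol = 7L)
  for (s in seq_len(50L)) {
    sim <- simulate_selex(selex_sim_config(rounds = 7L, n_unique = 300L,
                                           sample_depth = 3000L, initial_copies = 30L,
                                           error_rate = 0, indel_rate = 0,
                                           seed = 2000L + s))
    for (r in 1:7) {
      p <- abundance_vector(sim$pools[[r]])
      H[s, r] <- shannon(p)
      S[s, r] <- inverse_simpson(p)
    }
  }
  expect_true(all(diff(colMeans(H)) < 0))
  expect_true(all(diff(colMeans(S)) < 0))
})
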