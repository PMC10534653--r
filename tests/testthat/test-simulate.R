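test_that("generate_library draws distinct variable regions deterministically", {
  spec <- library_spec()
  one <- generate_library(1L, spec, seed = 7L)
  expect_equal(length(one$counts), 1L)
  expect_equal(nchar(names(one$counts)), 40L)

  lib <- generate_library(2000L, spec, seed = 3L)
  expect_equal(length(lib$counts), 2000L)
  expect_false(anyDuplicated(names(lib$counts)) > 0)
  expect_true(all(lib$counts == 1L))

  again <- generate_library(2000L, spec, seed = 3L)
  expect_identical(lib$counts, again$counts)
  expect_error(generate_library(0L), "n_unique")
})

test_that("neutral selection preserves pool frequencies in expectation", {
  pool <- round_counts(setNames(rep(50L, 5L), dissimilar_seqs(5, 20L)))
  model <- affinity_model(background_prob = 1)
  target <- names(pool$counts)[1L]
  set.seed(99)
  freqs <- replicate(100, {
    out <- simulate_round(pool, model, sample_depth = 1000L, amp_noise_cv = 0)
    sum(out$counts[target], na.rm = TRUE) / out$total_reads
  })
  expect_equal(mean(freqs), 0.2, tolerance = 0.05)
})

test_that("a 10x capture advantage lifts the spiked frequency ~10x per round", {
  set.seed(123)
  seqs <- replicate(200, random_seq(40L))
  pool <- round_counts(setNames(rep(50L, 200L), seqs))
  spike <- names(pool$counts)[1L]
  model <- affinity_model(setNames(0.5, spike), background_prob = 0.05)
  # analytic expectation: p' = p * capture / sum(p * capture)
  expected <- 0.5 / (0.5 + 199 * 0.05)
  freqs <- replicate(120, {
    out <- simulate_round(pool, model, sample_depth = 10000L)
    sum(out$counts[spike], na.rm = TRUE) / out$total_reads
  })
  expect_equal(mean(freqs), expected, tolerance = 0.10)
  expect_gt(mean(freqs) / (1 / 200), 8)  # ~9.6x rise from the uniform start
})

test_that("simulate_round rejects bad arguments and reports collapse", {
  pool <- round_counts(c(ACGTACGTAC = 3L))
  model <- affinity_model(background_prob = 0.5)
  expect_error(simulate_round(pool, model, sample_depth = 0L), "sample_depth")
  expect_error(simulate_round(pool, model, 10L, amp_factor = 0.5), "amp_factor")
  dead <- affinity_model(background_prob = 0)
  expect_error(simulate_round(pool, dead, 10L, seed = 1L), "selection collapse")
})

test_that("emit_fastq writes exact reads at zero error rate", {
  spec <- library_spec()
  set.seed(5)
  pool <- round_counts(setNames(c(30L, 12L), c(random_seq(40L), random_seq(40L))))
  path <- tempfile(fileext = ".fastq")
  emit_fastq(pool, spec, path, error_rate = 0, seed = 2L)
  lines <- readLines(path)
  expect_equal(length(lines), 4L * pool$total_reads)
  reads <- lines[seq(2L, length(lines), by = 4L)]
  expect_setequal(unique(reads), paste0(spec$arm5, names(pool$counts), spec$arm3))
  expect_equal(length(reads), 42L)
})

test_that("substitution errors hit the variable region at the binomial rate", {
  spec <- library_spec()
  set.seed(8)
  v <- random_seq(40L)
  pool <- round_counts(setNames(3000L, v))
  path <- tempfile(fileext = ".fastq")
  emit_fastq(pool, spec, path, error_rate = 0.01, seed = 31L)
  reads <- readLines(path)[seq(2L, 4L * 3000L, by = 4L)]
  vars <- substr(reads, nchar(spec$arm5) + 1L, nchar(spec$arm5) + 40L)
  vt <- strsplit(v, "")[[1]]
  nsub <- vapply(strsplit(vars, ""), function(x) sum(x != vt), 0L)
  expect_equal(mean(nsub), 0.4, tolerance = 0.1)  # 40 nt * 0.01
})

test_that("simulate_selex is byte-deterministic and emits one FASTQ per round", {
  cfg <- selex_sim_config(rounds = 3L, n_unique = 200L, sample_depth = 2000L,
                          initial_copies = 20L, seed = 77L)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_selex(cfg, outdir = d1)
  s2 <- simulate_selex(cfg, outdir = d2)
  expect_equal(length(s1$fastq), 3L)
  expect_true(all(file.exists(s1$fastq)))
  expect_identical(unname(tools::md5sum(s1$fastq)), unname(tools::md5sum(s2$fastq)))

  nine <- simulate_selex(selex_sim_config(rounds = 9L, n_unique = 50L,
                                          sample_depth = 500L, initial_copies = 10L,
                                          seed = 4L),
                         outdir = tempfile())
  expect_equal(length(nine$fastq), 9L)
})

test_that("truth frequencies are normalized and neutral truth stays uniform", {
  cfg <- selex_sim_config(rounds = 4L, n_unique = 100L, sample_depth = 1000L,
                          initial_copies = 10L, seed = 12L)
  sim <- simulate_selex(cfg)
  sums <- tapply(sim$truth$expected_frequency, sim$truth$round, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_null(sim$fastq)

  neutral <- simulate_selex(selex_sim_config(rounds = 1L, n_unique = 100L,
                                             sample_depth = 1000L, n_spiked = 0L,
                                             initial_copies = 10L, seed = 2L))
  expect_true(all(abs(neutral$truth$expected_frequency - 1 / 100) < 1e-12))
})

test_that("the spiked frequency is non-decreasing across rounds on average", {
  labels <- paste0("R", 1:4)
  spiked_freq <- matrix(0, nrow = 50L, ncol = 4L)
  for (s in seq_len(50L)) {
    sim <- simulate_selex(selex_sim_config(rounds = 4L, n_unique = 200L,
                                           sample_depth = 2000L, initial_copies = 20L,
                                           error_rate = 0, indel_rate = 0,
                                           seed = 1000L + s))
    for (r in seq_along(labels)) {
      cts <- sim$pools[[labels[r]]]$counts
      spiked_freq[s, r] <- sum(cts[sim$spiked], na.rm = TRUE) /
        sim$pools[[labels[r]]]$total_reads
    }
  }
  means <- colMeans(spiked_freq)
  expect_true(all(diff(means) > -1e-9))
  expect_gt(means[4L], means[1L])
})
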