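test_that("nw_score reproduces known alignment scores", {
  s <- strrep("ACGT", 10L)
  expect_equal(nw_score(s, s), 40)
  # four mismatches beat any gapped path under the default penalties
  expect_equal(nw_score("AAAA", "TTTT"), -4)
  expect_error(nw_score("", s), "non-empty")
  expect_error(tracking_config(match_score = -1, mismatch_score = 1), "exceed")
  expect_error(tracking_config(gap_open = -1), "penalties")
})

test_that("nw_score is symmetric and matches a full-matrix Gotoh DP", {
  set.seed(71)
  cfgs <- list(tracking_config(),
               tracking_config(2, -3, 5, 2),
               tracking_config(1, 0, 1, 1))
  for (cfg in cfgs) {
    for (k in 1:20) {
      a <- random_seq(sample(5:50, 1L))
      b <- random_seq(sample(5:50, 1L))
      ref <- gotoh_r(a, b, cfg$match_score, cfg$mismatch_score,
                     cfg$gap_open, cfg$gap_extend)
      expect_equal(nw_score(a, b, cfg), ref)
      expect_equal(nw_score(a, b, cfg), nw_score(b, a, cfg))
    }
  }
})

test_that("representatives map to the best-scoring next-round cluster", {
  set.seed(72)
  reps <- dissimilar_seqs(4L)
  cl <- greedy_cluster(round_counts(setNames(c(100L, 80L, 60L, 40L), reps)))

  hit <- map_representative(reps[2L], cl)
  expect_false(hit$lost)
  expect_equal(cl$representative[hit$cluster_index], reps[2L])
  expect_equal(hit$score, 40)

  # a stranger aligns below the threshold and is lost
  miss <- map_representative(random_seq(40L), cl)
  expect_true(miss$lost)
  expect_lt(miss$score, 30)
})

test_that("score ties resolve to the higher-count cluster", {
  set.seed(73)
  r <- random_seq(40L)
  t1 <- mutate_seq_at(r, 5L)   # one substitution at position 5
  t2 <- mutate_seq_at(r, 20L)  # one substitution at position 20 -> same score 38
  # cluster at 0.99 so the two near-identical targets stay separate
  cl <- greedy_cluster(round_counts(setNames(c(10L, 20L), c(t1, t2))), threshold = 0.99)
  hit <- map_representative(r, cl)
  expect_false(hit$lost)
  expect_equal(hit$score, 38)
  expect_equal(cl$representative[hit$cluster_index], t2)
})

test_that("lineages persist, appear and die deterministically", {
  set.seed(74)
  reps <- dissimilar_seqs(5L)
  r1 <- greedy_cluster(round_counts(setNames(c(90L, 70L, 50L, 30L, 10L), reps)))
  # identical rounds: every lineage spans both, no births in round 2
  tr <- track_clusters(list(R1 = r1, R2 = r1))
  expect_equal(nrow(tr$lineages), 5L)
  expect_true(all(tr$lineages$n_rounds == 2L))
  expect_equal(unname(first_appearance_histogram(tr)), c(5L, 0L))
  # ids ordered by round-1 abundance
  expect_equal(tr$trajectory$uc_id[tr$trajectory$round == "R1"][1L], "UC1")

  # an unrelated newcomer founds a new lineage at its first appearance
  newcomer <- dissimilar_seqs(1L)
  r2 <- greedy_cluster(round_counts(setNames(c(90L, 70L, 50L, 30L, 10L, 25L),
                                             c(reps, newcomer))))
  tr2 <- track_clusters(list(R1 = r1, R2 = r2))
  born <- tr2$lineages[tr2$lineages$first_round == "R2", ]
  expect_equal(nrow(born), 1L)
  new_rows <- tr2$trajectory[tr2$trajectory$uc_id == born$uc_id, ]
  expect_equal(new_rows$representative, newcomer)

  # reruns are identical (deterministic tie-breaks, stable ids)
  expect_identical(tr2, track_clusters(list(R1 = r1, R2 = r2)))
  expect_false(any(duplicated(tr2$lineages$uc_id)))
})

test_that("trajectory entries mirror the source clusters round by round", {
  set.seed(75)
  pools <- lapply(1:3, function(i) random_pool(8L, 30L, round_label = paste0("R", i)))
  cls <- lapply(pools, greedy_cluster)
  names(cls) <- paste0("R", 1:3)
  tr <- track_clusters(cls)
  for (r in names(cls)) {
    rows <- tr$trajectory[tr$trajectory$round == r, ]
    expect_equal(sort(rows$rpm), sort(cls[[r]]$rpm))
    expect_equal(sum(rows$total_count), sum(cls[[r]]$total_count))
    # every cluster of the round is claimed by exactly one lineage
    expect_equal(nrow(rows), nrow(cls[[r]]))
    expect_false(any(duplicated(rows$uc_id)))
  }
})

test_that("a simulated spiked lineage is recovered against the truth table", {
  sim <- simulate_selex(selex_sim_config(rounds = 3L, n_unique = 150L,
                                         sample_depth = 3000L, initial_copies = 30L,
                                         error_rate = 0, indel_rate = 0, seed = 19L))
  cls <- lapply(sim$pools, greedy_cluster)
  tr <- track_clusters(cls)
  spike_rows <- tr$trajectory[tr$trajectory$representative == sim$spiked, ]
  expect_equal(length(unique(spike_rows$uc_id)), 1L)
  expect_equal(sort(spike_rows$round), paste0("R", 1:3))
  # realized frequency of the spike tracks its truth-table expectation
  truth3 <- sim$truth[sim$truth$round == "R3" & sim$truth$is_spiked, ]
  got3 <- spike_rows$rpm[spike_rows$round == "R3"] / 1e6
  expect_equal(got3, truth3$expected_frequency, tolerance = 0.35)
})

test_that("the round network counts shared lineages with richness node sizes", {
  set.seed(76)
  reps <- dissimilar_seqs(6L)
  r1 <- greedy_cluster(round_counts(setNames(rep(100L, 4L), reps[1:4])))
  g_same <- build_network(track_clusters(list(R1 = r1, R2 = r1)),
                          rounds = list(R1 = r1, R2 = r1))
  expect_equal(igraph::ecount(g_same), 1L)
  expect_equal(igraph::E(g_same)$weight, 4L)
  expect_equal(unname(igraph::V(g_same)$size), c(4, 4))

  r2 <- greedy_cluster(round_counts(setNames(rep(100L, 2L), reps[5:6])))
  g_disjoint <- build_network(track_clusters(list(R1 = r1, R2 = r2)))
  expect_equal(igraph::ecount(g_disjoint), 0L)

  hist1 <- first_appearance_histogram(track_clusters(list(R1 = r1)))
  expect_equal(unname(hist1), 4L)
})
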