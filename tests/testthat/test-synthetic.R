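test_that("planted network respects regulon sizes and the chain contract", {
  cfg <- simulation_config(n_tf = 1L, n_genes = 3L, n_conditions = 10L,
                           regulon_size_range = c(2L, 2L),
                           chain_fraction = 0, perturb_reps = 1L, seed = 5L)
  truth <- simulate_network(cfg)
  expect_equal(nrow(truth$direct_edges), 2L)
  expect_equal(nrow(truth$chain_edges), 0L)

  cfg2 <- simulation_config(n_tf = 2L, n_genes = 12L, n_conditions = 12L,
                            regulon_size_range = c(1L, 1L),
                            chain_fraction = 1, perturb_reps = 1L, seed = 5L)
  truth2 <- simulate_network(cfg2)
  expect_equal(nrow(truth2$chain_edges), 2L)
  # sampled targets are never direct targets: reachable only via the
  # intermediate, and direct/chain edge sets are disjoint
  dk <- paste(truth2$direct_edges$tf, truth2$direct_edges$target)
  ck <- paste(truth2$chain_edges$tf, truth2$chain_edges$target)
  expect_length(intersect(dk, ck), 0L)
  for (i in seq_len(nrow(truth2$chain_edges)))
    expect_true(truth2$chain_edges$intermediate[i] %in%
                  truth2$direct_edges$target[truth2$direct_edges$tf ==
                                               truth2$chain_edges$tf[i]])
})

test_that("generators are pure functions of seed and parameters", {
  cfg <- simulation_config(n_tf = 3L, n_genes = 20L, n_conditions = 30L,
                           regulon_size_range = c(2L, 4L),
                           chain_fraction = 0.5, seed = 11L)
  t1 <- simulate_network(cfg)
  t2 <- simulate_network(cfg)
  expect_identical(t1, t2)
  expect_identical(simulate_expression(t1, cfg), simulate_expression(t2, cfg))
  expect_identical(simulate_signature(t1, 2, seed = 3L),
                   simulate_signature(t2, 2, seed = 3L))
})

test_that("noise-free expression obeys the exact linear relations", {
  cfg <- simulation_config(n_tf = 1L, n_genes = 2L, n_conditions = 20L,
                           regulon_size_range = c(1L, 1L), noise_sd = 0,
                           chain_fraction = 0, perturb_reps = 1L, seed = 2L)
  truth <- simulate_network(cfg)
  m <- simulate_expression(truth, cfg)
  e <- truth$direct_edges
  expect_equal(m[e$target, ], e$weight * m[e$tf, ], tolerance = 1e-12)

  # chain X -> M -> Z with zero noise: Z = w2 * w1 * X exactly
  cfg2 <- simulation_config(n_tf = 1L, n_genes = 6L, n_conditions = 20L,
                            regulon_size_range = c(1L, 1L), noise_sd = 0,
                            chain_fraction = 1, perturb_reps = 1L, seed = 9L)
  truth2 <- simulate_network(cfg2)
  m2 <- simulate_expression(truth2, cfg2)
  ch <- truth2$chain_edges
  w1 <- truth2$parents$weight[truth2$parents$child == ch$intermediate]
  w2 <- truth2$parents$weight[truth2$parents$child == ch$target]
  expect_equal(m2[ch$target, ], w1 * w2 * m2[ch$tf, ], tolerance = 1e-12)
})

test_that("edge weight and noise reproduce the closed-form correlation", {
  # corr(TF, target) = w / sqrt(w^2 + sigma^2); w = 0.9, sigma^2 = 0.19
  # gives population correlation 0.9
  cfg <- simulation_config(n_tf = 1L, n_genes = 2L, n_conditions = 2000L,
                           regulon_size_range = c(1L, 1L),
                           edge_weight_range = c(0.9, 0.9),
                           noise_sd = sqrt(0.19), chain_fraction = 0,
                           perturb_reps = 0L, seed = 4L)
  truth <- simulate_network(cfg)
  m <- simulate_expression(truth, cfg)
  e <- truth$direct_edges
  expect_lt(abs(cor(m[e$tf, ], m[e$target, ]) - 0.9), 0.03)
})

test_that("signature separates the planted regulon when the effect is large", {
  cfg <- simulation_config(n_tf = 4L, n_genes = 60L, n_conditions = 20L,
                           regulon_size_range = c(5L, 8L),
                           chain_fraction = 0, perturb_reps = 1L, seed = 8L)
  truth <- simulate_network(cfg)
  sig <- simulate_signature(truth, effect_size = 10, seed = 8L)
  reg <- planted_regulon(truth)
  expect_setequal(sig$gene[seq_along(reg)], reg)
})

test_that("null signature leaves the regulon at the middle rank on average", {
  cfg <- simulation_config(n_tf = 4L, n_genes = 60L, n_conditions = 20L,
                           regulon_size_range = c(5L, 8L),
                           chain_fraction = 0, perturb_reps = 1L, seed = 8L)
  truth <- simulate_network(cfg)
  reg <- planted_regulon(truth)
  mean_ranks <- vapply(1:100, function(s) {
    sig <- simulate_signature(truth, effect_size = 0, seed = 1000L + s)
    mean(match(reg, sig$gene))
  }, numeric(1))
  N <- nrow(simulate_signature(truth, 0, seed = 1L))
  se <- sd(mean_ranks) / sqrt(length(mean_ranks))
  expect_lt(abs(mean(mean_ranks) - (N + 1) / 2), 3 * se)
})

test_that("promoter simulation writes motif words at the recorded placements", {
  mots <- list(iupac_to_pwm("GGTCAC", motif_id = "m1"),
               iupac_to_pwm("TTAACGGA", motif_id = "m2"))
  sim <- simulate_promoters(mots, n_seqs = 6L, length = 300L,
                            placements_per_seq = 3L, seed = 21L)
  expect_equal(nrow(sim$placements), 18L)
  words <- c(m1 = "GGTCAC", m2 = "TTAACGGA")
  seen_minus <- FALSE
  for (i in seq_len(nrow(sim$placements))) {
    p <- sim$placements[i, ]
    frag <- substr(sim$sequences[[p$sequence_id]], p$start + 1L, p$end)
    w <- words[[p$motif_id]]
    if (p$strand == "+") {
      expect_identical(frag, w)
    } else {
      seen_minus <- TRUE
      expect_identical(
        frag,
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(w))))
    }
  }
  expect_true(seen_minus)  # minus-strand placements occur and carry the RC
  expect_true(all(sim$placements$end <= 300L))

  # zero placements: pure background, empty truth
  sim0 <- simulate_promoters(mots, n_seqs = 1L, length = 50L,
                             placements_per_seq = 0L, seed = 1L)
  expect_equal(nrow(sim0$placements), 0L)

  # impossible packing errors out
  expect_error(simulate_promoters(mots, n_seqs = 1L, length = 20L,
                                  placements_per_seq = 4L, seed = 1L),
               "packing")
})

test_that("configuration validation rejects impossible designs", {
  expect_error(simulation_config(n_tf = 10L, n_genes = 5L), "n_genes")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(n_tf = 5L, n_genes = 100L,
                                 n_conditions = 10L, perturb_reps = 2L),
               "perturbation block")
  expect_error(simulation_config(n_tf = 5L, n_genes = 10L,
                                 regulon_size_range = c(8L, 8L),
                                 n_conditions = 100L),
               "pool")
})
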