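test_that("identical configs give bit-identical simulations, different seeds differ", {
  cfg <- simulation_config(n_isoforms = 50, seed = 42,
                           state_proportions = c(steady = 0.5, derepressed = 0.5))
  s1 <- simulate_polysome_experiment(cfg)
  s2 <- simulate_polysome_experiment(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_polysome_experiment(
    simulation_config(n_isoforms = 50, seed = 43,
                      state_proportions = c(steady = 0.5, derepressed = 0.5)))
  expect_false(identical(s1$abundance, s3$abundance))
})

test_that("simulated design has 2 stages x 3 fractions x n_replicates and complete truth", {
  cfg <- simulation_config(n_isoforms = 30, n_replicates = 4, seed = 7)
  sim <- simulate_polysome_experiment(cfg)
  expect_equal(ncol(sim$abundance), 1 + 2 * 3 * 4)
  expect_equal(nrow(sim$samples), 24)
  expect_equal(dplyr::count(sim$samples, stage, fraction)$n, rep(4, 6))
  # truth covers every isoform exactly once, with states from the vocabulary
  expect_identical(sim$truth$isoform_id, sim$abundance$isoform_id)
  expect_false(anyDuplicated(sim$truth$isoform_id) > 0)
  expect_true(all(sim$truth$state %in%
                    c("steady", "transcription_up", "transcription_down",
                      "repressed", "derepressed", "monosome_shift")))
})

test_that("steady-only simulation has stage mean ratio near 1", {
  cfg <- simulation_config(n_isoforms = 3000, seed = 11)
  sim <- simulate_polysome_experiment(cfg)
  a_cols <- sim$samples$sample_id[sim$samples$stage == "A"]
  b_cols <- sim$samples$sample_id[sim$samples$stage == "B"]
  ratio <- mean(as.matrix(sim$abundance[b_cols])) /
    mean(as.matrix(sim$abundance[a_cols]))
  expect_equal(ratio, 1, tolerance = 0.02)
  expect_true(all(sim$truth$state == "steady"))
})

test_that("empirical cell means match the planted means within 3 standard errors", {
  mu <- 50; fold <- 4; disp <- 0.1
  cfg <- simulation_config(
    n_isoforms = 4000, seed = 5, baseline_mean = mu, dispersion = disp,
    effect_fold = fold,
    state_proportions = c(steady = 0.4, transcription_up = 0.1,
                          transcription_down = 0.1, repressed = 0.15,
                          derepressed = 0.15, monosome_shift = 0.1))
  sim <- simulate_polysome_experiment(cfg)
  long <- tidyr::pivot_longer(sim$abundance, -isoform_id,
                              names_to = "sample_id") |>
    dplyr::left_join(sim$samples, by = "sample_id") |>
    dplyr::left_join(sim$truth, by = "isoform_id")

  # expected means per (state, stage, fraction), written out by hand
  expected <- function(state, stage, fraction) {
    if (stage == "A") return(mu)
    switch(state,
           steady = mu,
           transcription_up = mu * fold,
           transcription_down = mu / fold,
           repressed = if (fraction == "polysome") mu / fold else mu,
           derepressed = if (fraction == "polysome") mu * fold else mu,
           monosome_shift = if (fraction == "monosome") mu * fold else mu)
  }
  cells <- long |>
    dplyr::filter(!below_detection) |>
    dplyr::group_by(state, stage, fraction) |>
    dplyr::summarise(m = mean(value), n = dplyr::n(), .groups = "drop")
  for (i in seq_len(nrow(cells))) {
    mu_exp <- expected(cells$state[i], cells$stage[i], cells$fraction[i])
    if (cells$state[i] == "transcription_up" && cells$stage[i] == "B") {
      mu_exp <- mu * fold
    }
    se <- sqrt((mu_exp + disp * mu_exp^2) / cells$n[i])
    expect_lt(abs(cells$m[i] - mu_exp), 3 * se + 1e-9)
  }
})

test_that("below-detection planting puts input means under the threshold", {
  cfg <- simulation_config(
    n_isoforms = 1000, seed = 13, detection_fraction = 0.2,
    detection_threshold = 1,
    state_proportions = c(steady = 0.7, derepressed = 0.3))
  sim <- simulate_polysome_experiment(cfg)
  n_derep <- sum(sim$truth$state == "derepressed")
  expect_equal(sum(sim$truth$below_detection), round(0.2 * n_derep))
  expect_true(all(sim$truth$state[sim$truth$below_detection] == "derepressed"))
  input_cols <- sim$samples$sample_id[sim$samples$fraction == "input"]
  low_means <- rowMeans(as.matrix(
    sim$abundance[sim$truth$below_detection, input_cols]))
  expect_true(all(low_means < 1))
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(100, seed = 1,
                                 state_proportions = c(steady = 0.7)),
               "sum to 1")
  expect_error(simulation_config(100, seed = 1,
                                 state_proportions = c(frozen = 1)),
               "state")
  expect_error(simulation_config(0, seed = 1), class = "polystate_validation_error")
  expect_error(simulation_config(100, n_replicates = 1, seed = 1),
               class = "polystate_validation_error")
  expect_error(simulation_config(100), "seed")
  expect_error(simulate_polysome_experiment(list()), "simulation_config")
})

test_that("lognormal noise model reproduces the configured means too", {
  cfg <- simulation_config(n_isoforms = 2000, seed = 3, noise_model = "lognormal",
                           baseline_mean = 20, dispersion = 0.2)
  sim <- simulate_polysome_experiment(cfg)
  vals <- as.matrix(sim$abundance[-1])
  expect_true(all(vals >= 0))
  expect_equal(mean(vals), 20, tolerance = 0.02)
})

test_that("mass-conserving mode moves planted polysome mass out of the monosome pool", {
  cfg <- simulation_config(
    n_isoforms = 2000, seed = 9, effect_fold = 2, mass_conserving = TRUE,
    state_proportions = c(steady = 0.5, derepressed = 0.5))
  sim <- simulate_polysome_experiment(cfg)
  mono_b <- sim$samples$sample_id[sim$samples$fraction == "monosome" &
                                    sim$samples$stage == "B"]
  derep <- sim$truth$state == "derepressed"
  m_derep <- mean(as.matrix(sim$abundance[derep, mono_b]))
  m_steady <- mean(as.matrix(sim$abundance[!derep, mono_b]))
  expect_lt(m_derep, m_steady * 0.5)
})

test_that("fraction profile simulation matches its closed-form construction", {
  # no shift, no noise: conditions identical and downstream Welch p = 1
  p0 <- simulate_fraction_profiles(3, c(0.4, 0.3, 0.2, 0.1),
                                   shift_delta = 0, noise_sd = 0, seed = 1)
  c1 <- p0[p0$condition == "ctrl", c("F", "M", "LP", "HP")]
  c2 <- p0[p0$condition == "shifted", c("F", "M", "LP", "HP")]
  expect_equal(c1, c2, ignore_attr = TRUE)
  expect_equal(fraction_difference_test(p0)$p_value, 1)

  # stated shift: condition-2 closed HP - F = 0.1, condition-1 = -0.3
  p1 <- simulate_fraction_profiles(3, c(0.4, 0.3, 0.2, 0.1),
                                   shift_delta = 0.2, noise_sd = 0, seed = 1)
  d <- fraction_difference(p1, "HP", "F")$means
  expect_equal(d$mean_difference[d$condition == "ctrl"], -0.3)
  expect_equal(d$mean_difference[d$condition == "shifted"], 0.1)

  expect_error(simulate_fraction_profiles(3, c(-0.1, 0.5, 0.3, 0.3), seed = 1),
               "non-negative")
  expect_error(simulate_fraction_profiles(3, c(0.4, 0.3, 0.2, 0.1),
                                          shift_delta = 0.5, seed = 1),
               class = "polystate_validation_error")
  # determinism with noise
  expect_identical(
    simulate_fraction_profiles(3, c(0.4, 0.3, 0.2, 0.1), 0.2, 0.05, seed = 8),
    simulate_fraction_profiles(3, c(0.4, 0.3, 0.2, 0.1), 0.2, 0.05, seed = 8))
})

test_that("gene-set simulation plants the requested overlap exactly", {
  for (params in list(c(20, 5, 8, 5), c(50, 10, 10, 0), c(30, 6, 12, 6),
                      c(100, 20, 30, 7))) {
    gs <- simulate_gene_sets(params[1], params[2], params[3], params[4],
                             seed = 21)
    expect_length(gs$universe, params[1])
    expect_length(gs$input_set, params[2])
    expect_length(gs$target_set, params[3])
    expect_length(intersect(gs$input_set, gs$target_set), params[4])
    expect_true(all(c(gs$input_set, gs$target_set) %in% gs$universe))
  }
  # planted_overlap = n_input makes input a subset of target
  gs <- simulate_gene_sets(30, 5, 10, 5, seed = 2)
  expect_true(all(gs$input_set %in% gs$target_set))
  # 10 - 2 = 8 non-target members needed, but only 20 - 15 = 5 exist
  expect_error(simulate_gene_sets(20, 10, 15, 2, seed = 1), "infeasible")
  expect_error(simulate_gene_sets(20, 25, 5, 2, seed = 1),
               class = "polystate_validation_error")
})
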