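test_that("hypergeometric tail matches direct binomial-coefficient arithmetic", {
  expect_equal(hypergeometric_tail(0, 5, 8, 20), 1)
  expect_equal(hypergeometric_tail(5, 5, 8, 20), 56 / 15504,
               tolerance = 1e-12)
  withr::with_seed(2, {
    for (i in 1:30) {
      n_bg <- sample(5:30, 1)
      n_in <- sample(1:n_bg, 1)
      n_tg <- sample(1:n_bg, 1)
      k <- sample(0:min(n_in, n_tg), 1)
      expect_equal(hypergeometric_tail(k, n_in, n_tg, n_bg),
                   hyper_tail_oracle(k, n_in, n_tg, n_bg),
                   tolerance = 1e-12)
      # the overlap pmf (tail differences) sums to 1
      ks <- 0:min(n_in, n_tg)
      tails <- vapply(ks, hypergeometric_tail, 0, n_in, n_tg, n_bg)
      pmf <- tails - c(tails[-1], 0)
      expect_equal(sum(pmf), 1, tolerance = 1e-12)
      # monotone non-increasing in k
      expect_true(all(diff(tails) <= 1e-15))
    }
  })
  expect_error(hypergeometric_tail(6, 5, 8, 20), "Infeasible")
  expect_error(hypergeometric_tail(2, 25, 8, 20), "Infeasible")
})

test_that("saturated and empty targets give p = 1", {
  uni <- sprintf("g%02d", 1:20)
  full <- permutation_enrichment(uni[1:5], uni, uni, n_permutations = 200,
                                 seed = 3)
  expect_equal(full$overlap, 5)
  expect_equal(full$p_perm, 1)
  none <- permutation_enrichment(uni[1:5], character(0), uni,
                                 n_permutations = 200, seed = 3)
  expect_equal(none$overlap, 0)
  expect_equal(none$p_perm, 1)
})

test_that("permutation p agrees with the exact hypergeometric tail", {
  configs <- list(c(20, 5, 8, 5), c(25, 6, 10, 3), c(30, 10, 12, 6),
                  c(18, 4, 9, 2))
  for (cf in configs) {
    gs <- simulate_gene_sets(cf[1], cf[2], cf[3], cf[4], seed = 7)
    res <- permutation_enrichment(gs$input_set, gs$target_set, gs$universe,
                                  n_permutations = 20000, seed = 11)
    expect_equal(res$overlap, cf[4])
    exact <- hypergeometric_tail(cf[4], cf[2], cf[3], cf[1])
    se <- sqrt(exact * (1 - exact) / 20000)
    expect_lt(abs(res$p_perm - exact), 3 * se + 1e-9)
    # p is a multiple of 1 / n_permutations
    expect_equal(res$p_perm * 20000, round(res$p_perm * 20000),
                 tolerance = 1e-9)
  }
})

test_that("permutation p-values are calibrated under the random-set null", {
  uni <- sprintf("g%02d", 1:30)
  target <- uni[1:8]
  withr::with_seed(33, {
    p_null <- vapply(1:150, function(i) {
      inp <- sample(uni, 5)
      permutation_enrichment(inp, target, uni, n_permutations = 400,
                             seed = sample.int(1e6, 1))$p_perm
    }, numeric(1))
  })
  # super-uniformity on the achievable grid: P(p <= tail(k)) ~ tail(k)
  for (k in 2:4) {
    atom <- hypergeometric_tail(k, 5, 8, 30)
    emp <- mean(p_null <= atom + 0.025)
    se <- sqrt(atom * (1 - atom) / length(p_null))
    expect_lt(emp, atom + 3 * se + 0.05)
  }
})

test_that("seeding makes permutation results reproducible", {
  gs <- simulate_gene_sets(30, 6, 10, 4, seed = 5)
  r1 <- permutation_enrichment(gs$input_set, gs$target_set, gs$universe,
                               n_permutations = 500, seed = 99)
  r2 <- permutation_enrichment(gs$input_set, gs$target_set, gs$universe,
                               n_permutations = 500, seed = 99)
  expect_identical(r1, r2)
})

test_that("out-of-universe members error by default and clip on request", {
  uni <- letters[1:10]
  expect_error(permutation_enrichment(c("a", "zz"), c("b"), uni,
                                      n_permutations = 10, seed = 1),
               "zz")
  expect_warning(
    res <- permutation_enrichment(c("a", "zz"), c("a", "b"), uni,
                                  n_permutations = 10, seed = 1,
                                  clip_to_universe = TRUE),
    "Dropping")
  expect_equal(res$n_input, 1)
  expect_equal(res$overlap, 1)
})

test_that("the enrichment grid is consistent, order-invariant and finds the planted pair", {
  gs <- simulate_gene_sets(40, 8, 10, 7, seed = 13)
  withr::with_seed(77, {
    noise1 <- sample(gs$universe, 8)
    noise2 <- sample(gs$universe, 10)
  })
  inputs <- list(planted_in = gs$input_set, random_in = noise1)
  targets <- list(planted_tg = gs$target_set, random_tg = noise2)
  grid <- enrichment_grid(inputs, targets, gs$universe,
                          n_permutations = 2000, seed = 55)
  expect_equal(nrow(grid), 4)

  # 1x1 grid equals the single-pair call with the derived sub-seed
  g11 <- enrichment_grid(inputs["planted_in"], targets["planted_tg"],
                         gs$universe, n_permutations = 2000, seed = 55)
  single <- permutation_enrichment(
    inputs$planted_in, targets$planted_tg, gs$universe,
    n_permutations = 2000, seed = polystate:::derive_seed(55, 1L),
    input_name = "planted_in", target_name = "planted_tg")
  expect_equal(tidy(g11), tidy(single))

  # list order does not change any cell (per-pair sub-seeding)
  grid_rev <- enrichment_grid(rev(inputs), rev(targets), gs$universe,
                              n_permutations = 2000, seed = 55)
  expect_equal(tidy(grid), tidy(grid_rev))

  # the planted pair carries the smallest p / largest -log10 p
  planted_row <- grid$input_set == "planted_in" &
    grid$target_set == "planted_tg"
  expect_equal(grid$p_perm[planted_row], min(grid$p_perm))
  expect_equal(grid$neg_log10_p[planted_row], max(grid$neg_log10_p))
  expect_true(all(grid$neg_log10_p >= 0))
})

test_that("zero exceedance keeps a finite displayed -log10 p and a literal zero p", {
  uni <- sprintf("g%03d", 1:200)
  res <- permutation_enrichment(uni[1:20], uni[1:25], uni,
                                n_permutations = 500, seed = 5)
  expect_equal(res$overlap, 20)
  expect_equal(res$p_perm, 0)
  expect_equal(res$n_exceed, 0)
  expect_lt(res$neg_log10_p, Inf)
  expect_equal(res$neg_log10_p, -log10(1 / 501))
  pseudo <- permutation_enrichment(uni[1:20], uni[1:25], uni,
                                   n_permutations = 500, seed = 5,
                                   pseudocount = TRUE)
  expect_equal(pseudo$p_perm, 1 / 501)
})
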