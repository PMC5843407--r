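test_that("unit d-prime follows the average-SD normalisation and sign convention", {
  expect_equal(unit_dprime(c(4, 6), c(2, 4)), 2 / sqrt(2))
  expect_equal(unit_dprime(c(3, 5, 7), c(3, 5, 7)), 0)
  expect_lt(unit_dprime(c(2, 4), c(6, 8)), 0)
  expect_true(is.nan(unit_dprime(c(2, 2), c(2, 2))))
  expect_error(unit_dprime(1, c(1, 2)), "2 trials")
})

test_that("FLD weights are class-mean differences over pooled diagonal variance", {
  tr <- toy_train(c(8, 10, 12), c(6, 8, 10))  # mu 10 vs 8, var 4 each
  m <- fit_fld(tr)
  expect_equal(m$w, 0.5)
  expect_equal(m$b, 4.5)
  expect_equal(memory_strength(m, 10), 0.5)       # novel side
  expect_equal(strength_to_choice(memory_strength(m, 10)), "novel")
  expect_equal(memory_strength(m, 9), 0)          # class midpoint ties
  expect_equal(strength_to_choice(0), "novel")
  # equal class means give a zero weight vector
  m0 <- fit_fld(toy_train(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(m0$w, 0)
})

test_that("FLD matches an independent per-unit computation on random data", {
  set.seed(13)
  nov <- matrix(rnorm(5 * 30, mean = 2), nrow = 5)
  fam <- matrix(rnorm(5 * 30), nrow = 5)
  m <- fit_fld(list(novel = nov, familiar = fam))
  w_ref <- vapply(1:5, function(u) {
    (mean(nov[u, ]) - mean(fam[u, ])) /
      ((var(nov[u, ]) + var(fam[u, ])) / 2)
  }, numeric(1))
  expect_equal(m$w, w_ref)
  # weight signs equal d-prime signs for every unit
  d_ref <- vapply(1:5, function(u) unit_dprime(nov[u, ], fam[u, ]),
                  numeric(1))
  expect_equal(sign(m$w), sign(d_ref))
})

test_that("SCC weights are 1/N with the FLD-style midpoint criterion", {
  nov <- rbind(c(4, 6), c(10, 14))
  fam <- rbind(c(2, 4), c(6, 10))
  m <- fit_scc(list(novel = nov, familiar = fam))
  expect_equal(m$w, c(0.5, 0.5))
  # hand-computed midpoint projection: w . (mu1 + mu2) / 2
  expect_equal(m$b, 0.5 * (5 + 3) / 2 + 0.5 * (12 + 8) / 2)
  m4 <- fit_scc(list(novel = matrix(rnorm(4 * 6), 4),
                     familiar = matrix(rnorm(4 * 6), 4)))
  expect_equal(m4$w, rep(0.25, 4))
  # class-mean strengths straddle the criterion symmetrically
  s1 <- memory_strength(m, rowMeans(nov))
  s2 <- memory_strength(m, rowMeans(fam))
  expect_equal(s1, -s2)
  # SCC strength is invariant to unit reordering
  x <- c(3, 9)
  expect_equal(memory_strength(m, x), sum(x) / 2 - m$b)
})

test_that("ranked selection puts positive d-prime units first, by magnitude", {
  nov <- rbind(c(10.0, 10.4), c(20, 22), c(5, 7))
  fam <- rbind(c(9.9, 10.3), c(10, 12), c(11, 13))
  idx <- rank_and_select(list(novel = nov, familiar = fam), 2)
  expect_equal(idx, c(2L, 1L))       # both positives, larger first
  expect_equal(sort(rank_and_select(list(novel = nov, familiar = fam), 3)),
               1:3)                  # N = all is the identity set
  expect_error(rank_and_select(list(novel = nov, familiar = fam), 4),
               "exceeds")
})

test_that("ranked selection is enriched for memory-carrying units", {
  seq <- generate_task_sequence(
    task_config(nback_levels = 1L, n_pairs_per_nback = 60L, seed = 15))
  sim <- sim_config(n_units = 40, decrement_by_nback = c(`1` = 0.3),
                    memory_fraction = 0.5, seed = 16)
  sess <- simulate_population(sim, seq)
  pop <- build_pseudopopulation(sess, c(`1` = 50L), seed = 17)
  sp <- resample_split(pop, seed = 18)
  top <- rank_and_select(sp$train, 20)
  frac_carriers <- mean(sess$memory_units[top])
  expect_gt(frac_carriers, 0.75)
})

test_that("FLD strength is unchanged by a zero-variance unit and separates a toy batch", {
  nov <- rbind(c(8, 10, 12)); fam <- rbind(c(6, 8, 10))
  m1 <- fit_fld(list(novel = nov, familiar = fam))
  m2 <- fit_fld(list(novel = rbind(nov, 5), familiar = rbind(fam, 5)))
  expect_equal(length(m2$zero_variance_units), 1L)
  expect_equal(memory_strength(m2, c(10, 5)), memory_strength(m1, 10))
  # mean strengths: novel class positive, familiar negative
  expect_gt(mean(memory_strength(m1, nov)), 0)
  expect_lt(mean(memory_strength(m1, fam)), 0)
  expect_error(memory_strength(m1, c(1, 2)), "mismatch")
})

test_that("two-unit FLD accuracy matches the closed-form Gaussian error rate", {
  set.seed(19)
  nov <- matrix(rnorm(2 * 500, mean = 2), nrow = 2)
  fam <- matrix(rnorm(2 * 500, mean = 0), nrow = 2)
  m <- fit_fld(list(novel = nov, familiar = fam))
  x_nov <- matrix(rnorm(2 * 4000, mean = 2), nrow = 2)
  x_fam <- matrix(rnorm(2 * 4000, mean = 0), nrow = 2)
  acc <- mean(c(memory_strength(m, x_nov) > 0,
                memory_strength(m, x_fam) < 0))
  # population d' = sqrt(2) * 2; accuracy = Phi(d'/2)
  expect_equal(acc, pnorm(sqrt(2)), tolerance = 0.02)
})

test_that("decoder models survive a JSON round trip", {
  m <- fit_fld(toy_train(c(8, 10, 12), c(6, 8, 10)))
  path <- tempfile(fileext = ".json")
  write_decoder_json(m, path)
  m2 <- read_decoder_json(path)
  expect_equal(m2$w, m$w)
  expect_equal(m2$b, m$b)
  expect_equal(m2$kind, m$kind)
})
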