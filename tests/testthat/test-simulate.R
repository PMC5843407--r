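test_that("replication inversion reproduces the multiplicative model exactly", {
  pairs <- tibble::tibble(image_id = c("a", "b"), pair_mean = c(6, 3),
                          nback = 1L)
  u <- make_replication_unit(pairs, c(`1` = 0.10))
  expect_equal(u$expected_novel, 2 * c(6, 3) / 1.9)
  expect_equal(u$expected_familiar, u$expected_novel * 0.9)
  expect_equal(round(u$expected_novel, 2), c(6.32, 3.16))
  expect_equal(round(u$expected_familiar, 2), c(5.68, 2.84))
  # zero decrement is the identity
  u0 <- make_replication_unit(pairs, c(`1` = 0))
  expect_equal(u0$expected_novel, pairs$pair_mean)
  expect_equal(u0$expected_familiar, pairs$pair_mean)
  expect_error(make_replication_unit(pairs, c(`1` = 1)), "\\[0, 1\\)")
})

test_that("replication inversion conserves the pair mean to machine precision", {
  set.seed(5)
  pairs <- tibble::tibble(
    image_id = sprintf("i%02d", 1:40),
    pair_mean = runif(40, 0, 12),
    nback = sample(nb_levels, 40, replace = TRUE))
  d <- default_decrement_profile(d1 = 0.3)
  u <- make_replication_unit(pairs, d)
  expect_equal((u$expected_novel + u$expected_familiar) / 2, pairs$pair_mean)
})

test_that("visual-modulation removal flattens image selectivity but keeps the decrement", {
  pairs <- tibble::tibble(image_id = c("a", "b"), pair_mean = c(2, 8),
                          nback = 1L)
  u <- remove_visual_modulation(pairs, c(`1` = 0.10))
  expect_equal(u$expected_novel, rep(2 * 5 / 1.9, 2))
  expect_equal(u$expected_familiar, rep(2 * 5 / 1.9 * 0.9, 2))
  expect_equal(var(u$expected_novel), 0)
  # per-image proportional decrement unchanged
  expect_equal((u$expected_novel - u$expected_familiar) / u$expected_novel,
               rep(0.10, 2))
  # unit grand mean preserved
  expect_equal(mean(c(u$expected_novel, u$expected_familiar)), 5)
})

test_that("simulated populations honor the no-memory null and seeding", {
  seq <- generate_task_sequence(
    task_config(nback_levels = c(1L, 4L), n_pairs_per_nback = 6L, seed = 3))
  sim0 <- sim_config(n_units = 20, decrement_by_nback = zero_decrements(c(1, 4)),
                     seed = 11)
  s1 <- simulate_population(sim0, seq)
  s2 <- simulate_population(sim0, seq)
  expect_identical(s1$counts, s2$counts)  # bit-reproducible
  # with zero decrements the expectations match across presentations
  fam <- dplyr::filter(s1$trials, presentation == "familiar")
  nov_idx <- match(fam$image_id,
                   s1$trials$image_id[s1$trials$presentation == "novel"])
  nov_cols <- which(s1$trials$presentation == "novel")[nov_idx]
  fam_cols <- which(s1$trials$presentation == "familiar")
  expect_equal(s1$expected[, fam_cols], s1$expected[, nov_cols])
})

test_that("windowed counts are Poisson-dispersed around the configured grand mean", {
  seq <- generate_task_sequence(
    task_config(nback_levels = 1L, n_pairs_per_nback = 400L, seed = 4))
  sim <- sim_config(n_units = 1, grand_mean_counts = 5,
                    selectivity_dispersion = 0,
                    decrement_by_nback = c(`1` = 0), seed = 12)
  s <- simulate_population(sim, seq)
  x <- as.numeric(s$counts)
  expect_equal(mean(x), 5, tolerance = 0.05)
  expect_equal(var(x) / mean(x), 1, tolerance = 0.1)
})

test_that("derived replication populations preserve per-unit pair means in expectation", {
  pop <- make_population(10, 8, decrements = default_decrement_profile(),
                         seed = 21)
  rep_pop <- derive_simulated_population(pop, "replication", seed = 22)
  vr_pop <- derive_simulated_population(pop, "visual_removed", seed = 23)
  expect_equal(dim(rep_pop$responses), dim(pop$responses))
  # grand means agree within Poisson sampling error
  expect_equal(mean(rep_pop$responses), mean(pop$responses), tolerance = 0.05)
  expect_equal(mean(vr_pop$responses), mean(pop$responses), tolerance = 0.05)
})

test_that("strength observers obey limit, symmetry and x-pattern behavior", {
  seq <- generate_task_sequence(task_config(n_pairs_per_nback = 40L,
                                            seed = 6))
  # condition mean far below criterion: familiar reports near 1
  obs_far <- observer_config(
    mean_strength_by_condition = c(novel = 5, setNames(rep(-5, 7),
                                                       as.character(nb_levels))),
    seed = 8)
  beh <- simulate_behavior(obs_far, seq)
  ff <- compute_forgetting_function(beh)
  expect_gt(ff$proportion[ff$condition == "1"], 0.99)
  expect_lt(ff$proportion[ff$condition == "novel"], 0.01)
  # all means at criterion: everything near one half
  obs_sym <- observer_config(
    mean_strength_by_condition = c(novel = 0, setNames(rep(0, 7),
                                                       as.character(nb_levels))),
    seed = 9)
  seq_big <- generate_task_sequence(task_config(n_pairs_per_nback = 100L,
                                                seed = 6))
  ff_sym <- compute_forgetting_function(simulate_behavior(obs_sym, seq_big))
  # three binomial SDs at 100 trials per condition
  expect_true(all(abs(ff_sym$proportion - 0.5) < 0.15))
  # monotone condition means produce the x-shaped RT pattern in expectation
  obs <- observer_config(rt_jitter_sd = 0, seed = 10)
  rt <- compute_rt_pattern(simulate_behavior(obs, seq))
  fam_cor <- dplyr::filter(rt, !is.na(nback), outcome == "correct",
                           !is.na(mean_rt_ms))
  fam_err <- dplyr::filter(rt, !is.na(nback), outcome == "error",
                           !is.na(mean_rt_ms))
  expect_true(all(diff(fam_cor$mean_rt_ms[order(fam_cor$nback)]) > 0))
  expect_true(all(diff(fam_err$mean_rt_ms[order(fam_err$nback)]) < 0))
  expect_error(observer_config(strength_sd = 0), "> 0")
})
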