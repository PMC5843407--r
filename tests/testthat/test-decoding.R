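test_that("decoding runs are bit-reproducible and label conditions correctly", {
  pop <- make_population(10, 6, seed = 51)
  a <- run_decoding(pop, "fld", n_iterations = 5, seed = 3)
  b <- run_decoding(pop, "fld", n_iterations = 5, seed = 3)
  expect_identical(a$samples, b$samples)
  counts <- dplyr::count(a$samples, condition)
  # 2 held-out images x 7 n-backs per iteration: novel pooled, familiar split
  expect_equal(counts$n[counts$condition == "novel"], 5 * 14)
  expect_true(all(counts$n[counts$condition != "novel"] == 5 * 2))
})

test_that("ranked FLD with all units reproduces the regular FLD stream", {
  pop <- make_population(12, 6, decrements = default_decrement_profile(),
                         seed = 52)
  a <- run_decoding(pop, "fld", n_iterations = 5, seed = 4)
  b <- run_decoding(pop, "ranked_fld", size = 12, n_iterations = 5, seed = 4)
  expect_equal(a$samples$strength, b$samples$strength)
})

test_that("strong suppression shifts 1-back strengths far below novel", {
  pop <- make_population(60, 10,
                         decrements = default_decrement_profile(d1 = 0.4),
                         seed = 53)
  sd1 <- run_decoding(pop, "fld", n_iterations = 30, seed = 5)
  s <- sd1$samples
  expect_lt(mean(s$strength[s$condition == "1"]),
            mean(s$strength[s$condition == "novel"]) - 1)
  pf <- predict_forgetting(sd1)
  expect_gt(pf$proportion[pf$condition == "1"], 0.85)
  expect_lt(pf$proportion[pf$condition == "novel"], 0.3)
})

test_that("predicted proportions count the familiar side of the criterion", {
  samples <- tibble::tibble(
    iteration = 1L, condition = c("1", "1", "1", "novel"),
    nback = c(1L, 1L, 1L, NA), strength = c(-1, -0.5, 0.5, 2),
    criterion = 0)
  pf <- predict_forgetting(samples)
  expect_equal(pf$proportion[pf$condition == "1"], 2 / 3)
  expect_equal(pf$proportion[pf$condition == "novel"], 0)
})

test_that("correct and error proportions per condition sum to one", {
  ff <- tibble::tibble(condition = c("novel", "1"), nback = c(NA, 1L),
                       proportion = c(0.2, 0.9))
  po <- proportions_by_outcome(ff)
  sums <- po |> dplyr::group_by(condition) |>
    dplyr::summarise(s = sum(proportion))
  expect_true(all(sums$s == 1))
  # novel correct means reporting novel
  expect_equal(po$proportion[po$condition == "novel" &
                               po$outcome == "correct"], 0.8)
})

test_that("the strength-theory line is recovered from paired points", {
  pred <- tibble::tibble(condition = c("1", "64"), nback = c(1L, 64L),
                         outcome = "correct", proportion = c(0.9, 0.5))
  rts <- tibble::tibble(condition = c("1", "64", "8"),
                        nback = c(1L, 64L, 8L),
                        outcome = "correct",
                        mean_rt_ms = c(250, 330, 290))
  pred3 <- dplyr::bind_rows(pred,
                            tibble::tibble(condition = "8", nback = 8L,
                                           outcome = "correct",
                                           proportion = 0.7))
  map <- fit_rt_map(pred3, rts)
  expect_equal(map$slope, -200)
  expect_equal(map$intercept, 430)
  out <- predict_rt(map, tibble::tibble(condition = "x", nback = NA,
                                        outcome = "correct",
                                        proportion = 0.7))
  expect_equal(out$predicted_rt_ms, 290)
  expect_error(fit_rt_map(pred, rts), "3")
  # constant proportions give a flat line at the mean RT
  predc <- dplyr::mutate(pred3, proportion = 0.5)
  mapc <- fit_rt_map(predc, rts)
  expect_equal(mapc$slope, 0)
  expect_equal(predict_rt(mapc, predc)$predicted_rt_ms,
               rep(mean(c(250, 330, 290)), 3))
})

test_that("observer-generated RT maps recover the configured line", {
  seqs <- generate_task_sequence(task_config(n_pairs_per_nback = 120L,
                                             seed = 54))
  obs <- observer_config(rt_slope = -150, rt_intercept = 400,
                         rt_jitter_sd = 10, seed = 55)
  beh <- simulate_behavior(obs, seqs)
  ff <- compute_forgetting_function(beh)
  rt <- compute_rt_pattern(beh)
  map <- fit_rt_map(proportions_by_outcome(ff), rt)
  expect_equal(map$slope, -150, tolerance = 0.1)
  expect_equal(map$intercept, 400, tolerance = 0.02)
})

test_that("prediction quality anchors at 100, 0, and the worked fraction", {
  beh <- tibble::tibble(
    condition = c("novel", "1", "4"), nback = c(NA, 1L, 4L),
    proportion = c(0.2, 0.95, 0.75), ci_halfwidth = NA,
    n_trials = c(20L, 10L, 10L))
  expect_equal(compute_pq(beh, beh)$pq, 100)
  bench <- benchmark_forgetting(beh)
  expect_equal(compute_pq(beh, bench)$pq, 0)
  # MSE ratio 0.01 / 0.04 maps to PQ 75
  pred <- dplyr::mutate(beh, proportion = proportion + 0.1)
  fake_bench <- dplyr::mutate(beh, proportion = proportion + 0.2)
  expect_equal(compute_pq(beh, pred, benchmark = fake_bench)$pq, 75)
  # PQ is invariant to condition reordering
  expect_equal(compute_pq(beh, pred[c(2, 3, 1), ])$pq,
               compute_pq(beh, pred)$pq)
  expect_error(compute_pq(beh, beh, benchmark = beh), "zero")
})

test_that("PQ strictly decreases as noise corrupts a perfect prediction", {
  set.seed(56)
  beh <- tibble::tibble(
    condition = c("novel", as.character(nb_levels)),
    nback = c(NA, nb_levels),
    proportion = c(0.1, 0.97, 0.92, 0.85, 0.75, 0.65, 0.55, 0.45),
    ci_halfwidth = NA, n_trials = 50L)
  noise <- rnorm(8, 0, 0.01)
  pqs <- vapply(c(0, 1, 3), function(k) {
    pred <- dplyr::mutate(beh,
                          proportion = pmin(pmax(proportion + k * noise, 0),
                                            1))
    compute_pq(beh, pred)$pq
  }, numeric(1))
  expect_true(all(diff(pqs) < 0))
  expect_equal(pqs[1], 100)
})

test_that("the matched-performance benchmark steps at the overall correct rate", {
  beh <- tibble::tibble(
    condition = c("novel", "1"), nback = c(NA, 1L),
    proportion = c(0.16, 0.84), ci_halfwidth = NA, n_trials = c(10L, 10L))
  bench <- benchmark_forgetting(beh)
  expect_equal(bench$proportion[bench$condition == "1"], 0.84)
  expect_equal(bench$proportion[bench$condition == "novel"], 0.16)
})

test_that("reaction-time PQ scores benchmark RTs through the same line", {
  beh <- tibble::tibble(
    condition = c("novel", as.character(nb_levels)),
    nback = c(NA, nb_levels),
    proportion = c(0.1, 0.97, 0.92, 0.85, 0.75, 0.65, 0.55, 0.45),
    ci_halfwidth = NA, n_trials = 50L)
  rts <- predict_rt(
    structure(list(slope = -150, intercept = 400), class = "rt_map"),
    proportions_by_outcome(beh)) |>
    dplyr::rename(mean_rt_ms = predicted_rt_ms)
  res <- compute_rt_pq(rts, beh, beh)
  expect_equal(res$pq, 100, tolerance = 1e-6)
})

test_that("window sweeps refuse windows past the go cue", {
  expect_error(window_sweep(function(w) NULL, c(300), behavior = NULL),
               "400 ms")
})
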