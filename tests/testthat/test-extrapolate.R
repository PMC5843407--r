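make_stats <- function(sizes, mean_fun, sd_fun, crit_fun,
                       conditions = c("novel", "1")) {
  tidyr::expand_grid(size = sizes, condition = conditions) |>
    dplyr::mutate(
      nback = suppressWarnings(as.integer(condition)),
      mean = mean_fun(size, condition),
      sd = sd_fun(size, condition),
      criterion = crit_fun(size),
      kind = "fld")
}

test_that("linear mean and criterion trajectories are recovered exactly", {
  st <- make_stats(c(25, 50, 100, 200),
                   mean_fun = function(s, c) ifelse(c == "novel",
                                                    1 + 0.02 * s,
                                                    -0.5 - 0.01 * s),
                   sd_fun = function(s, c) sqrt(s),
                   crit_fun = function(s) 0.2 + 0.005 * s)
  fit <- fit_mean_trajectory(st)
  nov <- fit$params[fit$params$condition == "novel", ]
  expect_equal(nov$intercept, 1)
  expect_equal(nov$slope, 0.02)
  expect_equal(unname(fit$criterion), c(0.2, 0.005))
  expect_error(fit_mean_trajectory(st[st$size < 60, ]), ">= 3")
})

test_that("flat spike-count-classifier means fit a near-zero slope", {
  st <- make_stats(c(25, 50, 100, 200),
                   mean_fun = function(s, c) 3,
                   sd_fun = function(s, c) 1 / sqrt(s),
                   crit_fun = function(s) 3)
  fit <- fit_mean_trajectory(st)
  expect_true(all(abs(fit$params$slope) < 1e-10))
})

test_that("noisy linear means are recovered within the regression CI", {
  set.seed(61)
  sizes <- c(25, 50, 100, 200, 400)
  st <- make_stats(sizes,
                   mean_fun = function(s, c) 0.5 + 0.03 * s +
                     rnorm(length(s), 0, 0.2),
                   sd_fun = function(s, c) 1,
                   crit_fun = function(s) 0)
  fit <- fit_mean_trajectory(st)
  for (sl in fit$params$slope) expect_equal(sl, 0.03, tolerance = 0.2)
})

test_that("power-law SD trajectories are recovered from their own forms", {
  sizes <- c(25, 50, 100, 200, 400)
  st_fld <- make_stats(sizes, function(s, c) 0,
                       sd_fun = function(s, c) (0.01 * s)^0.5,
                       crit_fun = function(s) 0)
  fit <- fit_sd_trajectory(st_fld, "fld")
  expect_equal(fit$params$a, rep(0.01, 2), tolerance = 1e-4)
  expect_equal(fit$params$b, rep(0.5, 2), tolerance = 1e-4)
  # 1/sqrt(x) decay maps to the SCC form with 1/b = -0.5
  st_scc <- make_stats(sizes, function(s, c) 0,
                       sd_fun = function(s, c) 2 / sqrt(s),
                       crit_fun = function(s) 0)
  fit2 <- fit_sd_trajectory(st_scc, "scc")
  expect_equal(1 / fit2$params$b, rep(-0.5, 2), tolerance = 1e-4)
  expect_equal(fit2$params$a, rep(2, 2), tolerance = 1e-4)
  # constant SDs degenerate to a flagged flat fit
  st_const <- make_stats(sizes, function(s, c) 0,
                         sd_fun = function(s, c) 1.3,
                         crit_fun = function(s) 0)
  fit3 <- fit_sd_trajectory(st_const, "fld")
  expect_true(all(fit3$params$degenerate))
  expect_equal(trajectory_sd_at(fit3, 600), rep(1.3, 2))
  expect_error(fit_sd_trajectory(st_const[st_const$size < 60, ], "fld"),
               ">= 4")
})

test_that("Gaussian extension turns trajectories into tail proportions", {
  sizes <- c(25, 50, 100, 200)
  st <- make_stats(sizes,
                   mean_fun = function(s, c) ifelse(c == "novel", -1, -1),
                   sd_fun = function(s, c) 1.0001 - s * 1e-9,
                   crit_fun = function(s) 0)
  mf <- fit_mean_trajectory(st)
  sf <- fit_sd_trajectory(st, "fld")
  pred <- predict_extended(mf, sf, 200)
  # mean -1, sd 1, criterion 0: familiar mass is Phi(1)
  expect_equal(pred$proportion, rep(pnorm(1), 2), tolerance = 1e-3)
  st2 <- make_stats(sizes, function(s, c) 0.7,
                    sd_fun = function(s, c) 2.0001 - s * 1e-9,
                    crit_fun = function(s) 0.7)
  pred2 <- predict_extended(fit_mean_trajectory(st2),
                            fit_sd_trajectory(st2, "fld"), 100)
  expect_equal(pred2$proportion, rep(0.5, 2), tolerance = 1e-6)
  expect_error(predict_extended(mf, sf, 1000), "1.5x")
})

test_that("extended FLD means grow without bound while SCC means stay flat", {
  st_fld <- make_stats(c(25, 50, 100, 200),
                       mean_fun = function(s, c) 0.01 * s,
                       sd_fun = function(s, c) (0.02 * s)^0.4,
                       crit_fun = function(s) 0.005 * s)
  mf <- fit_mean_trajectory(st_fld)
  expect_gt(abs(mf$params$slope[1]), 1e-4)
  st_scc <- make_stats(c(25, 50, 100, 200),
                       mean_fun = function(s, c) 3,
                       sd_fun = function(s, c) 2 / sqrt(s),
                       crit_fun = function(s) 3)
  ms <- fit_mean_trajectory(st_scc)
  expect_lt(max(abs(ms$params$slope)), 1e-10)
})
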