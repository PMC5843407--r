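#' Cross-validated decoding of memory strength distributions
#'
#' Runs the iterative resampling loop: on each iteration the
#' pseudopopulation is shuffled within n-back, two images per n-back are
#' held out with both presentations, a linear decoder is trained on the
#' remaining pairs (all n-backs pooled, regardless of behavioral outcome)
#' and memory strengths `w . x - b` are evaluated on the held-out trials.
#' Strengths are pooled per condition (novel, and each n-back for familiar
#' presentations) across iterations.
#'
#' For `"fld"`/`"scc"` with `size` below the population, units are randomly
#' subsampled each iteration; for `"ranked_fld"`/`"ranked_scc"` the top
#' `size` units by training-data signed d' are selected each iteration.
#'
#' @param pop A [build_pseudopopulation()] result.
#' @param kind One of `"fld"`, `"scc"`, `"ranked_fld"`, `"ranked_scc"`.
#' @param size Population size to decode with (default: all units).
#' @param n_iterations Resampling iterations (default 1000).
#' @param n_test_images_per_nback Held-out images per n-back (default 2).
#' @param seed Integer seed for the whole loop.
#' @return An object of class `strength_distributions`: list with `samples`
#'   (tibble `iteration`, `condition`, `nback`, `strength`, `criterion`),
#'   `kind`, `size`, `n_iterations`, `seed`.
#' @export
run_decoding <- function(pop,
                         kind = c("fld", "scc", "ranked_fld", "ranked_scc"),
                         size = NULL, n_iterations = 1000L,
                         n_test_images_per_nback = 2L, seed = 1L) {
  stopifnot(inherits(pop, "pseudopopulation"))
  kind <- match.arg(kind)
  nu <- n_units(pop)
  if (is.null(size)) size <- nu
  assert_that(size >= 1 && size <= nu,
              "`size` must lie between 1 and the number of units")
  set.seed(seed)
  acc <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    res <- tryCatch(
      decode_once(pop, kind, size, nu, n_test_images_per_nback),
      error = function(e) abort(sprintf("iteration %d: %s", it,
                                        conditionMessage(e))))
    res$iteration <- it
    acc[[it]] <- res
  }
  samples <- dplyr::bind_rows(acc)
  structure(
    list(samples = samples, kind = kind, size = size,
         n_iterations = as.integer(n_iterations),
         n_test_images_per_nback = as.integer(n_test_images_per_nback),
         seed = as.integer(seed)),
    class = "strength_distributions")
}

decode_once <- function(pop, kind, size, nu, n_test) {
  split <- resample_split(pop, n_test)
  if (kind %in% c("fld", "scc") && size < nu) {
    sub <- sample.int(nu, size)
  } else if (kind %in% c("ranked_fld", "ranked_scc")) {
    sub <- rank_and_select(split$train, size)
  } else {
    sub <- seq_len(nu)
  }
  train <- list(novel = split$train$novel[sub, , drop = FALSE],
                familiar = split$train$familiar[sub, , drop = FALSE])
  model <- if (kind %in% c("fld", "ranked_fld")) fit_fld(train)
           else fit_scc(train)
  s_nov <- memory_strength(model, split$test$novel[sub, , drop = FALSE])
  s_fam <- memory_strength(model, split$test$familiar[sub, , drop = FALSE])
  tibble::tibble(
    condition = c(rep("novel", length(s_nov)),
                  as.character(split$test$test_nback)),
    nback = c(rep(NA_integer_, length(s_nov)), split$test$test_nback),
    strength = c(s_nov, s_fam),
    criterion = model$b)
}

#' @export
print.strength_distributions <- function(x, ...) {
  cat(sprintf(
    "<strength_distributions> %s, %d units, %d iterations, %d samples\n",
    x$kind, x$size, x$n_iterations, nrow(x$samples)))
  invisible(x)
}

#' Neural prediction of the forgetting function
#'
#' The predicted proportion of "familiar" reports per condition: the
#' fraction of each strength distribution falling on the familiar (negative)
#' side of the criterion.
#'
#' @param strengths A [run_decoding()] result (or its `samples` tibble).
#' @return A `forgetting_function` tibble (`ci_halfwidth` is `NA`; the
#'   prediction is a pooled fraction, not a session mean).
#' @export
predict_forgetting <- function(strengths) {
  samples <- if (inherits(strengths, "strength_distributions"))
    strengths$samples else tibble::as_tibble(strengths)
  assert_that(nrow(samples) > 0, "no strength samples")
  lv <- condition_levels(unique(samples$nback[!is.na(samples$nback)]))
  out <- samples |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(proportion = mean(.data$strength < 0),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(ci_halfwidth = NA_real_,
                  nback = suppressWarnings(as.integer(.data$condition))) |>
    dplyr::arrange(match(.data$condition, lv)) |>
    dplyr::select("condition", "nback", "proportion", "ci_halfwidth",
                  "n_trials")
  new_forgetting_function(out)
}

#' Per-condition correct/error proportions implied by a forgetting function
#'
#' Familiar conditions are correct when reported familiar; novel trials are
#' correct when reported novel. Correct and error proportions per condition
#' sum to one.
#'
#' @param ff A `forgetting_function` (empirical or predicted).
#' @return Tibble `condition`, `nback`, `outcome`, `proportion`.
#' @export
proportions_by_outcome <- function(ff) {
  p_correct <- ifelse(ff$condition == "novel", 1 - ff$proportion,
                      ff$proportion)
  tibble::tibble(
    condition = rep(ff$condition, 2),
    nback = rep(ff$nback, 2),
    outcome = rep(c("correct", "error"), each = nrow(ff)),
    proportion = c(p_correct, 1 - p_correct))
}

#' Fit the strength-theory proportion-to-reaction-time line
#'
#' Least-squares line through the paired points (predicted outcome
#' proportion, observed mean RT) across all condition x outcome cells with a
#' measured RT, converting neural proportion predictions into reaction
#' times.
#'
#' @param predicted_proportions Tibble from [proportions_by_outcome()]
#'   (typically on a predicted forgetting function).
#' @param observed_rts An [compute_rt_pattern()] result.
#' @return An object of class `rt_map`: list with the `lm` fit, `slope` (ms
#'   per unit proportion), `intercept` (ms) and the paired `data`.
#' @export
fit_rt_map <- function(predicted_proportions, observed_rts) {
  dat <- dplyr::inner_join(
    tibble::as_tibble(predicted_proportions),
    dplyr::select(tibble::as_tibble(observed_rts),
                  "condition", "outcome", "mean_rt_ms"),
    by = c("condition", "outcome")) |>
    dplyr::filter(!is.na(.data$mean_rt_ms))
  assert_that(nrow(dat) >= 3, "need at least 3 (proportion, RT) points")
  fit <- lm(mean_rt_ms ~ proportion, data = dat)
  cf <- coef(fit)
  if (is.na(cf[2])) cf[2] <- 0  # constant proportions: flat line at mean RT
  structure(
    list(fit = fit, slope = unname(cf[2]), intercept = unname(cf[1]),
         data = dat),
    class = "rt_map")
}

#' Predict mean reaction times from outcome proportions
#'
#' @param map An [fit_rt_map()] result.
#' @param proportions Tibble from [proportions_by_outcome()].
#' @return The input with a `predicted_rt_ms` column.
#' @export
predict_rt <- function(map, proportions) {
  stopifnot(inherits(map, "rt_map"))
  dplyr::mutate(tibble::as_tibble(proportions),
                predicted_rt_ms = map$intercept +
                  map$slope * .data$proportion)
}

#' Step benchmark for prediction quality
#'
#' The worst admissible forgetting-function fit under the constraints that
#' performance is continuous, non-increasing in n-back and centered on
#' chance: a step at the behavior's overall proportion correct, assigning
#' that value to every familiar condition and its complement to novel
#' trials.
#'
#' @param behavior An empirical `forgetting_function` with `n_trials`.
#' @param weighted Weight the overall proportion correct by per-condition
#'   trial counts (default `TRUE` when counts are available).
#' @return A `forgetting_function` tibble for the benchmark.
#' @export
benchmark_forgetting <- function(behavior, weighted = TRUE) {
  p_correct <- ifelse(behavior$condition == "novel",
                      1 - behavior$proportion, behavior$proportion)
  w <- if (weighted && !any(is.na(behavior$n_trials)))
    behavior$n_trials else rep(1, nrow(behavior))
  pbar <- sum(p_correct * w) / sum(w)
  out <- dplyr::mutate(
    tibble::as_tibble(behavior),
    proportion = ifelse(.data$condition == "novel", 1 - pbar, pbar),
    ci_halfwidth = NA_real_)
  new_forgetting_function(out)
}

#' Prediction quality of a neural forgetting-function prediction
#'
#' Benchmarks the mean squared error between behavior and prediction against
#' the step benchmark: `PQ = 100 * (MSE_benchmark - MSE_neural) /
#' MSE_benchmark`, so a perfect prediction scores 100 and a benchmark-equal
#' prediction scores 0.
#'
#' @param behavior Empirical `forgetting_function`.
#' @param prediction Predicted `forgetting_function` on the same condition
#'   grid.
#' @param benchmark Optional benchmark (default [benchmark_forgetting()]).
#' @return An object of class `pq_result`: `pq` (percent), `mse_neural`,
#'   `mse_benchmark`, `benchmark`.
#' @export
compute_pq <- function(behavior, prediction, benchmark = NULL) {
  assert_that(setequal(behavior$condition, prediction$condition),
              "behavior and prediction must share a condition grid")
  if (is.null(benchmark)) benchmark <- benchmark_forgetting(behavior)
  m <- match(behavior$condition, prediction$condition)
  mb <- match(behavior$condition, benchmark$condition)
  mse_neural <- mean((behavior$proportion - prediction$proportion[m])^2)
  mse_benchmark <- mean((behavior$proportion -
                           benchmark$proportion[mb])^2)
  assert_that(mse_benchmark > 0, "benchmark MSE is zero")
  structure(
    list(pq = 100 * (mse_benchmark - mse_neural) / mse_benchmark,
         mse_neural = mse_neural, mse_benchmark = mse_benchmark,
         benchmark = benchmark, kind = "forgetting"),
    class = "pq_result")
}

#' Prediction quality for reaction-time patterns
#'
#' Passes both the neural prediction and the step benchmark through the
#' strength-theory RT line fitted on the neural prediction's proportions,
#' then scores the predicted RTs against the observed ones with the same
#' fractional-MSE formula as [compute_pq()].
#'
#' @param observed_rts An [compute_rt_pattern()] result.
#' @param prediction Predicted `forgetting_function`.
#' @param behavior Empirical `forgetting_function` (for the benchmark step).
#' @param map Optional pre-fitted [fit_rt_map()]; default fitted here.
#' @return A `pq_result` (kind `"rt"`) with the fitted `map` attached.
#' @export
compute_rt_pq <- function(observed_rts, prediction, behavior, map = NULL) {
  pred_cells <- proportions_by_outcome(prediction)
  if (is.null(map)) map <- fit_rt_map(pred_cells, observed_rts)
  bench_cells <- proportions_by_outcome(benchmark_forgetting(behavior))
  pred_rt <- predict_rt(map, pred_cells)
  bench_rt <- predict_rt(map, bench_cells)
  obs <- dplyr::filter(tibble::as_tibble(observed_rts),
                       !is.na(.data$mean_rt_ms))
  key <- function(d) paste(d$condition, d$outcome)
  mp <- match(key(obs), key(pred_rt))
  mbv <- match(key(obs), key(bench_rt))
  mse_neural <- mean((obs$mean_rt_ms - pred_rt$predicted_rt_ms[mp])^2)
  mse_benchmark <- mean((obs$mean_rt_ms - bench_rt$predicted_rt_ms[mbv])^2)
  assert_that(mse_benchmark > 0, "benchmark MSE is zero")
  structure(
    list(pq = 100 * (mse_benchmark - mse_neural) / mse_benchmark,
         mse_neural = mse_neural, mse_benchmark = mse_benchmark,
         map = map, kind = "rt"),
    class = "pq_result")
}

#' @export
print.pq_result <- function(x, ...) {
  cat(sprintf("<pq_result> %s: PQ = %.1f%% (MSE neural %.4g, benchmark %.4g)\n",
              x$kind, x$pq, x$mse_neural, x$mse_benchmark))
  invisible(x)
}

#' Per-condition Gaussian summary of strength distributions
#'
#' Means and SDs of the raw linear projections `w . x` (strength plus
#' criterion) per condition, together with the mean criterion -- the
#' statistics whose growth with population size drives the extrapolation to
#' larger populations.
#'
#' @param strengths A [run_decoding()] result.
#' @return Tibble `size`, `kind`, `condition`, `nback`, `mean`, `sd`,
#'   `criterion`.
#' @export
decoding_stats <- function(strengths) {
  stopifnot(inherits(strengths, "strength_distributions"))
  strengths$samples |>
    dplyr::mutate(raw = .data$strength + .data$criterion) |>
    dplyr::group_by(.data$condition, .data$nback) |>
    dplyr::summarise(mean = mean(.data$raw), sd = sd(.data$raw),
                     .groups = "drop") |>
    dplyr::mutate(criterion = mean(strengths$samples$criterion),
                  size = strengths$size, kind = strengths$kind) |>
    dplyr::select("size", "kind", "condition", "nback", "mean", "sd",
                  "criterion")
}

#' Pooled population d-prime from strength samples
#'
#' Separation of the pooled novel versus pooled familiar strength samples
#' (all n-backs), using the same mean-difference-over-average-SD form as
#' [unit_dprime()].
#'
#' @param strengths A [run_decoding()] result.
#' @return A single d' value.
#' @export
population_dprime <- function(strengths) {
  s <- strengths$samples
  unit_dprime(s$strength[s$condition == "novel"],
              s$strength[s$condition != "novel"])
}

#' Sweep decoded behavioral-prediction error over population size
#'
#' For each size, runs the cross-validated decoding loop, predicts the
#' forgetting function and scores it against behavior by mean squared error;
#' also reports the pooled population d'. Sizes beyond the recorded
#' population (up to 1.5x) are handled by Gaussian extrapolation of the
#' per-condition strength statistics fitted on the measured sizes.
#'
#' @param pop A [build_pseudopopulation()] result.
#' @param behavior Empirical `forgetting_function` to score against.
#' @param kind Decoder kind, as in [run_decoding()].
#' @param sizes Increasing vector of population sizes (must not exceed the
#'   recorded population; default a near-doubling grid up to all units).
#' @param extended_sizes Optional sizes beyond the population, each at most
#'   1.5x the recorded size, predicted via [predict_extended()].
#' @param n_iterations Iterations per size (default 100).
#' @param n_test_images_per_nback Held-out images per n-back.
#' @param seed Base seed; size `i` uses `seed + i`.
#' @param min_fit_size Smallest size used when fitting extrapolation
#'   trajectories (default 25; smaller populations are unstable).
#' @return An object of class `size_sweep_result`: `results` tibble (`size`,
#'   `mse`, `pop_dprime`, `extrapolated`), `best_size`, `stats`, and the
#'   trajectory `fits` when extrapolation was used.
#' @export
population_size_sweep <- function(pop, behavior, kind = "fld", sizes = NULL,
                                  extended_sizes = NULL,
                                  n_iterations = 100L,
                                  n_test_images_per_nback = 2L, seed = 1L,
                                  min_fit_size = 25L) {
  nu <- n_units(pop)
  if (is.null(sizes)) {
    sizes <- unique(pmin(2^(2:ceiling(log2(nu))), nu))
  }
  assert_that(length(sizes) > 0, "empty size grid")
  assert_that(all(diff(sizes) > 0), "`sizes` must be strictly increasing")
  assert_that(max(sizes) <= nu, "`sizes` may not exceed the population")
  runs <- vector("list", length(sizes))
  rows <- vector("list", length(sizes))
  stats <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    sd_i <- run_decoding(pop, kind = kind, size = sizes[i],
                         n_iterations = n_iterations,
                         n_test_images_per_nback = n_test_images_per_nback,
                         seed = seed + i)
    pred <- predict_forgetting(sd_i)
    m <- match(behavior$condition, pred$condition)
    rows[[i]] <- tibble::tibble(
      size = sizes[i],
      mse = mean((behavior$proportion - pred$proportion[m])^2),
      pop_dprime = population_dprime(sd_i),
      extrapolated = FALSE)
    stats[[i]] <- decoding_stats(sd_i)
    runs[[i]] <- sd_i
  }
  stats <- dplyr::bind_rows(stats)
  fits <- NULL
  if (!is.null(extended_sizes)) {
    assert_that(all(extended_sizes > max(sizes)),
                "`extended_sizes` must exceed the measured sizes")
    assert_that(all(extended_sizes <= 1.5 * nu),
                "extrapolation is limited to 1.5x the recorded size")
    fit_stats <- dplyr::filter(stats, .data$size >= min_fit_size)
    fits <- list(mean = fit_mean_trajectory(fit_stats),
                 sd = fit_sd_trajectory(fit_stats, kind))
    ext <- lapply(extended_sizes, function(sz) {
      pred <- predict_extended(fits$mean, fits$sd, sz)
      m <- match(behavior$condition, pred$condition)
      tibble::tibble(
        size = sz,
        mse = mean((behavior$proportion - pred$proportion[m])^2),
        pop_dprime = extended_dprime(fits$mean, fits$sd, sz),
        extrapolated = TRUE)
    })
    rows <- c(rows, ext)
  }
  results <- dplyr::bind_rows(rows)
  structure(
    list(results = results,
         best_size = results$size[which.min(results$mse)],
         stats = stats, fits = fits, kind = kind,
         last_run = runs[[length(runs)]]),
    class = "size_sweep_result")
}

#' @export
print.size_sweep_result <- function(x, ...) {
  cat(sprintf("<size_sweep_result> %s over %d sizes; best size %d (MSE %.4g)\n",
              x$kind, nrow(x$results), x$best_size,
              min(x$results$mse)))
  invisible(x)
}

#' Sweep decoding error over spike-count windows
#'
#' Rebuilds the pseudopopulation with spike counts taken in a sliding
#' 150 ms window and reports, for each window start, the minimal
#' forgetting-function MSE across the requested population sizes. Windows
#' may not extend past the go cue at 400 ms.
#'
#' @param pop_builder Function taking `window = c(start, end)` (ms) and
#'   returning a `pseudopopulation`.
#' @param window_starts Window start times (ms re stimulus onset).
#' @param behavior Empirical `forgetting_function`.
#' @param width Window width in ms (default 150).
#' @param kind Decoder kind.
#' @param sizes Population sizes to consider (default: full population).
#' @param n_iterations Iterations per size per window.
#' @param seed Base seed.
#' @return Tibble `window_start`, `window_end`, `mse` (minimum across
#'   sizes), `best_size`.
#' @export
window_sweep <- function(pop_builder, window_starts, behavior, width = 150,
                         kind = "fld", sizes = NULL, n_iterations = 50L,
                         seed = 1L) {
  assert_that(all(window_starts + width <= 400),
              "windows may not extend past 400 ms")
  out <- lapply(seq_along(window_starts), function(i) {
    w0 <- window_starts[i]
    pop <- pop_builder(c(w0, w0 + width))
    sz <- sizes %||% n_units(pop)
    mses <- vapply(seq_along(sz), function(j) {
      sd_j <- run_decoding(pop, kind = kind, size = sz[j],
                           n_iterations = n_iterations,
                           seed = seed + 1000L * i + j)
      pred <- predict_forgetting(sd_j)
      m <- match(behavior$condition, pred$condition)
      mean((behavior$proportion - pred$proportion[m])^2)
    }, numeric(1))
    tibble::tibble(window_start = w0, window_end = w0 + width,
                   mse = min(mses), best_size = sz[which.min(mses)])
  })
  dplyr::bind_rows(out)
}
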