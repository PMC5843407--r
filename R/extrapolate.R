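#' Fit linear size trajectories of strength means and the criterion
#'
#' Per-condition least-squares lines for the mean raw projection as a
#' function of population size, plus a line for the criterion. FLD means
#' grow linearly with size (weighted sums); SCC means are grand mean counts
#' and stay approximately flat.
#'
#' @param stats_by_size Tibble from [decoding_stats()] rows over >= 3 sizes
#'   (columns `size`, `condition`, `mean`, `criterion`).
#' @return An object of class `trajectory_fit` (kind `"mean"`): per-condition
#'   `params` tibble (`condition`, `intercept`, `slope`), `criterion`
#'   intercept/slope, `fit_range`, and residual-SD `goodness`.
#' @export
fit_mean_trajectory <- function(stats_by_size) {
  sizes <- sort(unique(stats_by_size$size))
  assert_that(length(sizes) >= 3, "need >= 3 population sizes")
  params <- stats_by_size |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(d, g) {
      f <- lm(mean ~ size, data = d)
      tibble::tibble(intercept = unname(coef(f)[1]),
                     slope = unname(coef(f)[2]),
                     resid_sd = sd(stats::residuals(f)))
    }) |>
    dplyr::ungroup()
  crit <- stats_by_size |>
    dplyr::distinct(.data$size, .data$criterion)
  cfit <- lm(criterion ~ size, data = crit)
  structure(
    list(kind = "mean", params = params,
         criterion = c(intercept = unname(coef(cfit)[1]),
                       slope = unname(coef(cfit)[2])),
         fit_range = range(sizes),
         goodness = mean(params$resid_sd)),
    class = "trajectory_fit")
}

# Two-parameter power-form fit with a log-log initialisation and
# multi-start Levenberg-Marquardt refinement.
fit_power_form <- function(size, sdv, form = c("fld", "scc"),
                           restarts = 5L) {
  form <- match.arg(form)
  ok <- sdv > 0
  assert_that(sum(ok) >= 3, "need >= 3 positive SDs")
  ll <- lm(log(sdv[ok]) ~ log(size[ok]))
  slope <- unname(coef(ll)[2]); inter <- unname(coef(ll)[1])
  if (form == "fld") {
    # sd = (a x)^b : log sd = b log a + b log x
    b0 <- slope
    a0 <- if (abs(b0) > 1e-8) exp(inter / b0) else NA_real_
    degenerate <- abs(b0) < 1e-3
    if (degenerate || !is.finite(a0)) {
      return(list(a = mean(sdv), b = 0, degenerate = TRUE,
                  resid_sd = sd(sdv)))
    }
    fn <- function(a, b, x) (a * x)^b
  } else {
    # sd = a x^(1/b) : log sd = log a + (1/b) log x
    a0 <- exp(inter)
    b0 <- if (abs(slope) > 1e-8) 1 / slope else Inf
    degenerate <- !is.finite(b0)
    if (degenerate) {
      return(list(a = a0, b = Inf, degenerate = TRUE,
                  resid_sd = sd(sdv - a0)))
    }
    fn <- function(a, b, x) a * x^(1 / b)
  }
  best <- list(a = a0, b = b0)
  best_rss <- sum((sdv - fn(a0, b0, size))^2)
  for (r in seq_len(restarts)) {
    st <- list(a = a0 * exp(rnorm(1, 0, 0.1 * (r > 1))),
               b = b0 * (1 + rnorm(1, 0, 0.1 * (r > 1))))
    fit <- tryCatch(
      minpack.lm::nlsLM(sdv ~ fn(a, b, size), start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) {
        best <- as.list(coef(fit)); best_rss <- rss
      }
    }
  }
  list(a = best$a, b = best$b, degenerate = FALSE,
       resid_sd = sqrt(best_rss / length(sdv)))
}

#' Fit the size trajectory of strength standard deviations
#'
#' Per-condition two-parameter fits of SD versus population size:
#' `SD(x) = (a x)^b` for the FLD family and `SD(x) = a x^(1/b)` for the SCC
#' family (with `b` typically negative, so the SD falls and plateaus).
#' A log-log linear fit initialises a multi-start Levenberg-Marquardt
#' refinement; a near-flat trajectory is flagged `degenerate` and treated as
#' constant.
#'
#' @param stats_by_size Tibble from [decoding_stats()] over >= 4 sizes.
#' @param decoder_kind `"fld"`, `"scc"`, `"ranked_fld"` or `"ranked_scc"`
#'   (ranked variants use their base family's form).
#' @param restarts Multi-start refinement attempts per condition.
#' @return A `trajectory_fit` (kind `"sd_fld"` or `"sd_scc"`) with
#'   per-condition `params` (`a`, `b`, `degenerate`).
#' @export
fit_sd_trajectory <- function(stats_by_size, decoder_kind = "fld",
                              restarts = 5L) {
  sizes <- sort(unique(stats_by_size$size))
  assert_that(length(sizes) >= 4, "need >= 4 population sizes")
  form <- if (grepl("scc", decoder_kind)) "scc" else "fld"
  params <- stats_by_size |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(d, g) {
      f <- fit_power_form(d$size, d$sd, form, restarts)
      tibble::tibble(a = f$a, b = f$b, degenerate = f$degenerate,
                     resid_sd = f$resid_sd)
    }) |>
    dplyr::ungroup()
  structure(
    list(kind = paste0("sd_", form), params = params,
         fit_range = range(sizes), goodness = mean(params$resid_sd)),
    class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> %s over sizes [%d, %d], %d conditions\n",
              x$kind, x$fit_range[1], x$fit_range[2], nrow(x$params)))
  invisible(x)
}

trajectory_sd_at <- function(sd_fit, size) {
  p <- sd_fit$params
  if (sd_fit$kind == "sd_fld") {
    ifelse(p$degenerate, p$a, (p$a * size)^p$b)
  } else {
    ifelse(is.finite(p$b), p$a * size^(1 / p$b), p$a)
  }
}

#' Gaussian-extrapolated forgetting function at a population size
#'
#' Models each condition's strength distribution as Gaussian with mean and
#' SD given by the fitted size trajectories; the predicted proportion of
#' "familiar" reports is the Gaussian mass below the extrapolated criterion.
#'
#' @param mean_fit A [fit_mean_trajectory()] result.
#' @param sd_fit A [fit_sd_trajectory()] result.
#' @param size Population size (at most 1.5x the largest fitted size).
#' @return A `forgetting_function` tibble.
#' @export
predict_extended <- function(mean_fit, sd_fit, size) {
  stopifnot(inherits(mean_fit, "trajectory_fit"),
            inherits(sd_fit, "trajectory_fit"))
  assert_that(size <= 1.5 * mean_fit$fit_range[2] + 1e-9,
              "extrapolation is limited to 1.5x the fitted size range")
  mp <- dplyr::arrange(mean_fit$params,
                       match(.data$condition,
                             condition_levels(setdiff(
                               mean_fit$params$condition, "novel"))))
  sp <- sd_fit$params[match(mp$condition, sd_fit$params$condition), ]
  mu <- mp$intercept + mp$slope * size
  sdv <- trajectory_sd_at(
    structure(list(kind = sd_fit$kind, params = sp), class = "trajectory_fit"),
    size)
  assert_that(all(sdv > 0), "nonpositive extrapolated SD")
  crit <- mean_fit$criterion[["intercept"]] +
    mean_fit$criterion[["slope"]] * size
  out <- tibble::tibble(
    condition = mp$condition,
    nback = suppressWarnings(as.integer(mp$condition)),
    proportion = pnorm(crit, mean = mu, sd = sdv),
    ci_halfwidth = NA_real_,
    n_trials = NA_integer_)
  new_forgetting_function(out)
}

# Pooled novel-vs-familiar d' implied by the extrapolated Gaussians.
extended_dprime <- function(mean_fit, sd_fit, size) {
  mp <- mean_fit$params
  sp <- sd_fit$params[match(mp$condition, sd_fit$params$condition), ]
  mu <- mp$intercept + mp$slope * size
  sdv <- trajectory_sd_at(
    structure(list(kind = sd_fit$kind, params = sp), class = "trajectory_fit"),
    size)
  nov <- mp$condition == "novel"
  (mu[nov] - mean(mu[!nov])) / ((sdv[nov] + mean(sdv[!nov])) / 2)
}
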