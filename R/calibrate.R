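#' Asymptotic decoded forgetting function of a synthetic population
#'
#' Closed-form Gaussian approximation of what the cross-validated FLD
#' pipeline decodes from a [sim_config()] population in the large-sample
#' limit, assuming every unit carries the memory signal
#' (`memory_fraction = 1`). With per-unit grand mean `G`, per-image gain
#' variance `v = exp(s^2) - 1` and decrements `d_k`, the asymptotic decoder
#' projects all units equally, the criterion sits midway between the novel
#' and pooled-familiar class means, and the predicted proportion of
#' "familiar" reports at n-back `k` is
#' `pnorm((d_k - dbar/2) * sqrt(N) * G / sqrt((1-d_k)^2 G^2 v + (1-d_k) G))`
#' with `dbar` the pair-count-weighted mean decrement; novel trials use
#' `-dbar/2` in place of `d_k - dbar/2` (and no decrement in the variance).
#'
#' This is the independent oracle against which the resampling pipeline can
#' be checked on synthetic data; it ignores finite-sample weight-estimation
#' noise, which compresses decoded proportions slightly toward chance when
#' training pairs are few.
#'
#' @param sim A [sim_config()] with `memory_fraction = 1`.
#' @param pair_counts Named integer vector of pairs per n-back (weights for
#'   the pooled familiar class; default equal).
#' @return A `forgetting_function` tibble of asymptotic proportions.
#' @export
expected_decoded_forgetting <- function(sim, pair_counts = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  assert_that(sim$memory_fraction == 1,
              "the closed form assumes memory_fraction = 1")
  d <- sim$decrement_by_nback
  lv <- as.integer(names(d))
  if (is.null(pair_counts)) pair_counts <- setNames(rep(1, length(d)),
                                                    names(d))
  pw <- pair_counts[names(d)] / sum(pair_counts[names(d)])
  dbar <- sum(pw * d)
  G <- sim$grand_mean_counts
  v <- exp(sim$selectivity_dispersion^2) - 1
  N <- sim$n_units
  noise_sd <- function(dk) sqrt((1 - dk)^2 * G^2 * v + (1 - dk) * G)
  p_fam <- pnorm((d - dbar / 2) * sqrt(N) * G / noise_sd(d))
  p_nov <- pnorm(-(dbar / 2) * sqrt(N) * G / noise_sd(0))
  out <- tibble::tibble(
    condition = c("novel", as.character(lv)),
    nback = c(NA_integer_, lv),
    proportion = c(p_nov, unname(p_fam)),
    ci_halfwidth = NA_real_,
    n_trials = NA_integer_)
  new_forgetting_function(out)
}

#' Calibrate decrements to a target forgetting function
#'
#' Finds the per-n-back multiplicative decrements for which the asymptotic
#' decoded forgetting function of [expected_decoded_forgetting()] matches a
#' target, by least squares over all conditions (the novel false-alarm rate
#' is determined by the criterion placement, so targets whose conditions are
#' mutually inconsistent are matched as closely as possible).
#'
#' @param target A `forgetting_function` (or tibble with `condition`,
#'   `proportion`) covering `"novel"` plus each n-back.
#' @param sim A [sim_config()] template supplying `n_units`,
#'   `grand_mean_counts` and `selectivity_dispersion`; its decrements are
#'   ignored.
#' @param pair_counts Pairs per n-back (weights; default equal).
#' @return A `sim_config` equal to `sim` but with calibrated
#'   `decrement_by_nback` and `memory_fraction = 1`.
#' @export
calibrate_decrements <- function(target, sim, pair_counts = NULL) {
  lv <- sort(target$nback[!is.na(target$nback)])
  p_t <- target$proportion[match(c("novel", as.character(lv)),
                                 target$condition)]
  obj <- function(d) {
    s <- sim
    s$decrement_by_nback <- setNames(d, as.character(lv))
    s$memory_fraction <- 1
    pred <- expected_decoded_forgetting(s, pair_counts)
    sum((pred$proportion - p_t)^2)
  }
  # analytic fixed-point initialisation: z_k = (d_k - dbar/2) * kappa_k
  G <- sim$grand_mean_counts
  v <- exp(sim$selectivity_dispersion^2) - 1
  N <- sim$n_units
  w <- if (is.null(pair_counts)) rep(1 / length(lv), length(lv)) else {
    pc <- pair_counts[as.character(lv)]; pc / sum(pc)
  }
  z <- qnorm(pmin(pmax(p_t[-1], 1e-4), 1 - 1e-4))
  d <- rep(0.1, length(lv))
  for (i in 1:50) {
    dbar <- sum(w * d)
    kappa <- sqrt(N) * G / sqrt((1 - d)^2 * G^2 * v + (1 - d) * G)
    d <- pmin(pmax(z / kappa + dbar / 2, 0), 0.8)
  }
  fit <- stats::optim(d, obj, method = "L-BFGS-B",
                      lower = rep(0, length(lv)),
                      upper = rep(0.8, length(lv)))
  out <- sim
  out$decrement_by_nback <- setNames(fit$par, as.character(lv))
  out$memory_fraction <- 1
  out
}
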