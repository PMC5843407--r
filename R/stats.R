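#' Bootstrap test for a difference in means
#'
#' Resamples both groups with replacement, recomputes the difference of
#' means, and reports the p value as the fraction of iterations on which the
#' resampled difference flips sign relative to the observed difference --
#' one-tailed by construction. Doubling for a two-tailed report is available
#' behind `two_tailed`.
#'
#' @param a,b Nonempty numeric vectors.
#' @param n_iterations Bootstrap iterations (default 1000).
#' @param seed Optional seed.
#' @param two_tailed Double the sign-flip fraction (capped at 1)?
#' @return An object of class `bootstrap_result`: `p`, `observed_diff`,
#'   `n_iterations`, `seed`. A zero observed difference is flagged and
#'   reported as `p = 1` (there is no sign to flip).
#' @export
bootstrap_mean_diff <- function(a, b, n_iterations = 1000L, seed = NULL,
                                two_tailed = FALSE) {
  assert_that(length(a) > 0 && length(b) > 0, "both samples must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(a) - mean(b)
  if (obs == 0) {
    return(structure(list(p = 1, observed_diff = 0, undefined_sign = TRUE,
                          n_iterations = as.integer(n_iterations),
                          seed = seed),
                     class = "bootstrap_result"))
  }
  ra <- matrix(sample(a, length(a) * n_iterations, replace = TRUE),
               ncol = n_iterations)
  rb <- matrix(sample(b, length(b) * n_iterations, replace = TRUE),
               ncol = n_iterations)
  diffs <- colMeans(ra) - colMeans(rb)
  p <- mean(sign(diffs) == -sign(obs))
  if (two_tailed) p <- min(1, 2 * p)
  structure(list(p = p, observed_diff = obs, undefined_sign = FALSE,
                 n_iterations = as.integer(n_iterations), seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> diff = %.4g, p = %.4g (%d iterations)\n",
              x$observed_diff, x$p, x$n_iterations))
  invisible(x)
}

#' Visual responsiveness screen for one unit
#'
#' Bootstrap comparison of per-trial spike counts in the pre-stimulus
#' (-150--0 ms) versus evoked (75--225 ms) windows; a unit is responsive
#' when the sign-flip p value falls strictly below the criterion (default
#' 0.01).
#'
#' @param baseline_counts Per-trial counts in the pre-stimulus window.
#' @param evoked_counts Per-trial counts in the evoked window.
#' @param alpha Criterion (strict `<`; default 0.01).
#' @param n_iterations Bootstrap iterations.
#' @param seed Optional seed.
#' @return List: `responsive` (logical), `p`, and the full
#'   `bootstrap_result`.
#' @export
visual_responsiveness <- function(baseline_counts, evoked_counts,
                                  alpha = 0.01, n_iterations = 1000L,
                                  seed = NULL) {
  assert_that(length(baseline_counts) > 0,
              "pre-stimulus counts are missing")
  res <- bootstrap_mean_diff(evoked_counts, baseline_counts,
                             n_iterations = n_iterations, seed = seed)
  list(responsive = res$p < alpha, p = res$p, result = res)
}

#' Wilcoxon signed-rank test of a d' distribution against zero
#'
#' Two-sided one-sample rank test of median zero, for testing whether a
#' population of unit d' values is shifted away from zero (net repetition
#' suppression when the mean is positive).
#'
#' @param dprimes Numeric vector (>= 6 values; `NaN`s dropped).
#' @return The p value; an all-zero input returns 1.
#' @export
signed_rank_test <- function(dprimes) {
  dprimes <- dprimes[is.finite(dprimes)]
  assert_that(length(dprimes) >= 6, "need at least 6 d' values")
  if (all(dprimes == 0)) return(1)
  suppressWarnings(wilcox.test(dprimes, mu = 0,
                               alternative = "two.sided")$p.value)
}

#' Per-unit novelty and responsiveness statistics table
#'
#' Convenience summary over a pseudopopulation: each unit's novel/familiar
#' d' and the bootstrap p value for its novel-versus-familiar mean
#' difference.
#'
#' @param pop A [build_pseudopopulation()] result.
#' @param n_iterations Bootstrap iterations per unit.
#' @param seed Seed.
#' @return Tibble `unit`, `dprime`, `novelty_p`.
#' @export
unit_statistics <- function(pop, n_iterations = 1000L, seed = 1L) {
  set.seed(seed)
  nu <- n_units(pop)
  out <- lapply(seq_len(nu), function(u) {
    nov <- pop$responses[u, , 1]; fam <- pop$responses[u, , 2]
    tibble::tibble(
      unit = u,
      dprime = unit_dprime(nov, fam),
      novelty_p = bootstrap_mean_diff(nov, fam,
                                      n_iterations = n_iterations)$p)
  })
  dplyr::bind_rows(out)
}
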