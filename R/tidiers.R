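#' Tidy a decoder model into per-unit rows
#'
#' @param x A `decoder_model`.
#' @param ... Unused.
#' @return Tibble `unit`, `weight`, `selected`.
#' @export
tidy.decoder_model <- function(x, ...) {
  tibble::tibble(unit = seq_along(x$w), weight = x$w,
                 selected = seq_along(x$w) %in% x$selected)
}

#' @rdname tidy.decoder_model
#' @return For `glance()`: one-row tibble `kind`, `n_units`, `n_selected`,
#'   `criterion`.
#' @export
glance.decoder_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_units = length(x$w),
                 n_selected = length(x$selected), criterion = x$b)
}

#' Tidy strength distributions into their sample table
#'
#' @param x A `strength_distributions`.
#' @param ... Unused.
#' @return The samples tibble.
#' @export
tidy.strength_distributions <- function(x, ...) x$samples

#' @rdname tidy.strength_distributions
#' @export
glance.strength_distributions <- function(x, ...) {
  tibble::tibble(kind = x$kind, size = x$size,
                 n_iterations = x$n_iterations,
                 n_samples = nrow(x$samples),
                 pop_dprime = population_dprime(x))
}

#' One-row summary of a prediction-quality result
#'
#' @param x A `pq_result`.
#' @param ... Unused.
#' @return Tibble `kind`, `pq`, `mse_neural`, `mse_benchmark`.
#' @export
glance.pq_result <- function(x, ...) {
  tibble::tibble(kind = x$kind, pq = x$pq, mse_neural = x$mse_neural,
                 mse_benchmark = x$mse_benchmark)
}

#' Tidy the strength-theory reaction-time line
#'
#' @param x An `rt_map`.
#' @param ... Unused.
#' @return Two-row tibble `term`, `estimate`.
#' @export
tidy.rt_map <- function(x, ...) {
  tibble::tibble(term = c("intercept_ms", "slope_ms_per_proportion"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.rt_map
#' @export
glance.rt_map <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = summary(x$fit)$r.squared,
                 n_points = nrow(x$data))
}

#' Tidy a population-size sweep
#'
#' @param x A `size_sweep_result`.
#' @param ... Unused.
#' @return The per-size results tibble.
#' @export
tidy.size_sweep_result <- function(x, ...) x$results

#' @rdname tidy.size_sweep_result
#' @export
glance.size_sweep_result <- function(x, ...) {
  tibble::tibble(kind = x$kind, best_size = x$best_size,
                 min_mse = min(x$results$mse),
                 n_sizes = nrow(x$results))
}

#' Tidy a fitted size trajectory
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return The per-condition parameter tibble.
#' @export
tidy.trajectory_fit <- function(x, ...) x$params
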