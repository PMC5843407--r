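#' @export
autoplot.forgetting_function <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     x = ifelse(is.na(.data$nback), 0.5, .data$nback))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$proportion)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_line(data = dplyr::filter(d, !is.na(.data$nback))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$proportion - .data$ci_halfwidth,
                   ymax = .data$proportion + .data$ci_halfwidth),
      width = 0.05, na.rm = TRUE) +
    ggplot2::scale_x_continuous(
      trans = "log2", breaks = c(0.5, d$nback[!is.na(d$nback)]),
      labels = c("N", d$nback[!is.na(d$nback)])) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "n-back (N = novel)",
                  y = "proportion chose familiar")
}

#' @export
autoplot.rt_pattern <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$mean_rt_ms)) |>
    dplyr::mutate(x = ifelse(is.na(.data$nback), 0.5, .data$nback))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$mean_rt_ms,
                                  color = .data$outcome)) +
    ggplot2::geom_line(data = dplyr::filter(d, !is.na(.data$nback))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_rt_ms - .data$ci_halfwidth,
                   ymax = .data$mean_rt_ms + .data$ci_halfwidth),
      width = 0.05, na.rm = TRUE) +
    ggplot2::scale_x_continuous(
      trans = "log2", breaks = c(0.5, unique(d$nback[!is.na(d$nback)])),
      labels = c("N", unique(d$nback[!is.na(d$nback)]))) +
    ggplot2::labs(x = "n-back (N = novel)", y = "mean RT (ms, from go cue)",
                  color = NULL)
}

#' @export
autoplot.psth <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_ms, y = .data$rate,
                               color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time re stimulus onset (ms)",
                  y = "grand mean rate (spikes/s)", color = NULL)
}

#' @export
autoplot.strength_distributions <- function(object, ...) {
  lv <- condition_levels(unique(
    object$samples$nback[!is.na(object$samples$nback)]))
  d <- dplyr::mutate(object$samples,
                     condition = factor(.data$condition, levels = lv))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$strength,
                                  color = .data$condition)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_density() +
    ggplot2::labs(x = "memory strength (w·x − b)",
                  y = "density", color = NULL)
}

#' @export
autoplot.size_sweep_result <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size, y = .data$mse,
                                  linetype = .data$extrapolated)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = d[d$size == object$best_size, ],
                        color = "red", size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "population size (units)",
                  y = "forgetting-function MSE",
                  linetype = "extrapolated")
}
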