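#' Empirical forgetting function
#'
#' The proportion of trials reported "familiar" per condition (novel trials
#' plus each n-back), pooled across all trials and sessions, with 97.5%
#' confidence halfwidths computed as 2.2 times the standard error of the
#' per-session mean traces. Choice proportions, not accuracies: error trials
#' stay in the denominator. Off-n-back residual pairs are excluded.
#'
#' @param trials Trial table with columns `session_id`, `presentation`,
#'   `nback`, `off_nback`, `choice`.
#' @param nback_levels Conditions that must be present (default: the n-backs
#'   observed among on-n-back trials). A configured level with zero trials is
#'   an error.
#' @param ci_factor Multiplier on the SEM (default 2.2, a 97.5% CI).
#' @return Tibble of class `forgetting_function` with columns `condition`,
#'   `nback`, `proportion`, `ci_halfwidth`, `n_trials`.
#' @export
compute_forgetting_function <- function(trials, nback_levels = NULL,
                                        ci_factor = 2.2) {
  trials <- dplyr::filter(tibble::as_tibble(trials), !.data$off_nback,
                          !is.na(.data$choice))
  assert_that(nrow(trials) > 0, "no analysable trials")
  if (is.null(nback_levels))
    nback_levels <- sort(unique(trials$nback[!is.na(trials$nback)]))
  lv <- condition_levels(nback_levels)
  trials <- dplyr::mutate(
    trials, condition = condition_of(.data$presentation, .data$nback),
    chose_familiar = as.integer(.data$choice == "familiar"))
  missing <- setdiff(lv, unique(trials$condition))
  assert_that(length(missing) == 0,
              paste0("conditions with zero trials: ",
                     paste(missing, collapse = ", ")))
  pooled <- trials |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(proportion = mean(.data$chose_familiar),
                     n_trials = dplyr::n(), .groups = "drop")
  per_session <- trials |>
    dplyr::group_by(.data$session_id, .data$condition) |>
    dplyr::summarise(p = mean(.data$chose_familiar), .groups = "drop") |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      ci_halfwidth = if (dplyr::n() > 1)
        ci_factor * sd(.data$p) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop")
  out <- pooled |>
    dplyr::left_join(per_session, by = "condition") |>
    dplyr::mutate(nback = suppressWarnings(as.integer(.data$condition))) |>
    dplyr::arrange(match(.data$condition, lv)) |>
    dplyr::select("condition", "nback", "proportion", "ci_halfwidth",
                  "n_trials")
  new_forgetting_function(out)
}

new_forgetting_function <- function(tbl) {
  class(tbl) <- c("forgetting_function", setdiff(class(tbl),
                                                 "forgetting_function"))
  tbl
}

#' Mean reaction times by condition and outcome
#'
#' Mean RT per (condition x correct/error) cell across all trials and
#' sessions, with 97.5% confidence halfwidths (2.2 x SEM over trials). Cells
#' with no trials are retained with `NA` means; single-trial cells have an
#' undefined CI. RTs are measured from the go cue (400 ms after stimulus
#' onset).
#'
#' @param trials Trial table with columns `presentation`, `nback`,
#'   `off_nback`, `correct`, `rt_ms`.
#' @param nback_levels Conditions to tabulate (default: observed).
#' @param ci_factor Multiplier on the SEM (default 2.2).
#' @return Tibble of class `rt_pattern` with `condition`, `nback`, `outcome`,
#'   `mean_rt_ms`, `ci_halfwidth`, `n_trials`.
#' @export
compute_rt_pattern <- function(trials, nback_levels = NULL, ci_factor = 2.2) {
  trials <- dplyr::filter(tibble::as_tibble(trials), !.data$off_nback,
                          !is.na(.data$rt_ms), !is.na(.data$correct))
  assert_that(nrow(trials) > 0, "no analysable trials")
  if (is.null(nback_levels))
    nback_levels <- sort(unique(trials$nback[!is.na(trials$nback)]))
  lv <- condition_levels(nback_levels)
  trials <- dplyr::mutate(
    trials, condition = condition_of(.data$presentation, .data$nback),
    outcome = ifelse(.data$correct == 1, "correct", "error"))
  grid <- tidyr::expand_grid(condition = lv,
                             outcome = c("correct", "error"))
  cells <- trials |>
    dplyr::group_by(.data$condition, .data$outcome) |>
    dplyr::summarise(
      mean_rt_ms = mean(.data$rt_ms),
      ci_halfwidth = if (dplyr::n() > 1)
        ci_factor * sd(.data$rt_ms) / sqrt(dplyr::n()) else NA_real_,
      n_trials = dplyr::n(), .groups = "drop")
  out <- grid |>
    dplyr::left_join(cells, by = c("condition", "outcome")) |>
    dplyr::mutate(
      n_trials = dplyr::coalesce(.data$n_trials, 0L),
      nback = suppressWarnings(as.integer(.data$condition))) |>
    dplyr::arrange(match(.data$condition, lv), .data$outcome) |>
    dplyr::select("condition", "nback", "outcome", "mean_rt_ms",
                  "ci_halfwidth", "n_trials")
  class(out) <- c("rt_pattern", class(out))
  out
}

#' Peri-stimulus time histogram
#'
#' Grand mean firing rate per condition in 1 ms bins, smoothed by a centered
#' 50 ms boxcar. Bins where the smoothing window runs off the data are
#' trimmed, so a trace spanning -150 to 400 ms is reported on
#' (-125, 375) ms bin centers.
#'
#' @param counts Trials x time-bins matrix of spike counts (one unit, or the
#'   unit-averaged counts for a grand mean).
#' @param time_ms Numeric vector of bin start times (ms re stimulus onset),
#'   length `ncol(counts)`.
#' @param conditions Character vector, length `nrow(counts)`; trace grouping
#'   (e.g. `"novel"`, `"1"`, ...).
#' @param bin_ms Bin width; must be 1 unless `allow_other_bins`.
#' @param smooth_ms Boxcar width in ms (default 50).
#' @param allow_other_bins Permit bin widths other than 1 ms.
#' @return Tibble of class `psth`: `condition`, `time_ms` (bin center),
#'   `rate` (spikes/s).
#' @export
compute_psth <- function(counts, time_ms, conditions, bin_ms = 1,
                         smooth_ms = 50, allow_other_bins = FALSE) {
  assert_that(bin_ms == 1 || allow_other_bins,
              "PSTHs use 1 ms bins; set `allow_other_bins` to override")
  assert_that(ncol(counts) == length(time_ms),
              "`time_ms` must match the number of bins")
  assert_that(nrow(counts) == length(conditions),
              "`conditions` must match the number of trials")
  k <- round(smooth_ms / bin_ms)
  kern <- rep(1 / k, k)
  out <- lapply(unique(conditions), function(cd) {
    rate <- colMeans(counts[conditions == cd, , drop = FALSE]) /
      (bin_ms / 1000)
    sm <- as.numeric(stats::filter(rate, kern, sides = 2))
    keep <- !is.na(sm)
    tibble::tibble(condition = cd,
                   time_ms = time_ms[keep] + bin_ms / 2,
                   rate = sm[keep])
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("psth", class(out))
  out
}

#' Repetition-suppression magnitude by n-back
#'
#' The proportional decrement of the familiar grand mean response relative to
#' novel, `(novel - familiar) / novel`, computed per n-back on grand mean
#' spike counts in the analysis window (150--400 ms). Negative values denote
#' repetition enhancement. Novel and familiar grand means are taken over the
#' same image pairs at each n-back, so image-selectivity sampling noise
#' cancels in the ratio.
#'
#' @param x A `session_data` or `pseudopopulation`.
#' @param ... Unused.
#' @return Tibble with `nback`, `novel_mean`, `familiar_mean`, `suppression`.
#' @export
suppression_magnitude <- function(x, ...) UseMethod("suppression_magnitude")

#' @export
suppression_magnitude.pseudopopulation <- function(x, ...) {
  lv <- sort(unique(x$pair_nback))
  out <- lapply(lv, function(k) {
    idx <- which(x$pair_nback == k)
    nov <- mean(x$responses[, idx, 1])
    fam <- mean(x$responses[, idx, 2])
    assert_that(nov > 0, "novel grand mean is zero")
    tibble::tibble(nback = k, novel_mean = nov, familiar_mean = fam,
                   suppression = (nov - fam) / nov)
  })
  dplyr::bind_rows(out)
}

#' @export
suppression_magnitude.session_data <- function(x, ...) {
  tr <- x$trials
  keep <- !tr$off_nback & !is.na(tr$nback)
  lv <- sort(unique(tr$nback[keep]))
  out <- lapply(lv, function(k) {
    at <- keep & tr$nback == k
    nov <- mean(x$counts[, which(at & tr$presentation == "novel"),
                         drop = FALSE])
    fam <- mean(x$counts[, which(at & tr$presentation == "familiar"),
                         drop = FALSE])
    assert_that(nov > 0, "novel grand mean is zero")
    tibble::tibble(nback = k, novel_mean = nov, familiar_mean = fam,
                   suppression = (nov - fam) / nov)
  })
  dplyr::bind_rows(out)
}
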