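#' Simulate a time-resolved synthetic session (1 ms binned counts)
#'
#' Inhomogeneous-Poisson version of [simulate_population()] for analyses
#' that need spike counts at arbitrary windows (PSTHs, window sweeps). Each
#' unit fires at a baseline rate before its visual response onset, steps to
#' its image-specific evoked rate afterwards, and -- on familiar trials of
#' memory-carrying units -- is multiplicatively suppressed from
#' `memory_onset_ms` onwards. The evoked rate is scaled so that counts in
#' the 150--400 ms window match the [sim_config()] expectations.
#'
#' @param sim A [sim_config()].
#' @param seq A [generate_task_sequence()] sequence.
#' @param baseline_rate Pre-stimulus rate in spikes/s (default 5).
#' @param visual_onset_ms Visual response latency (default 75 ms).
#' @param memory_onset_ms Earliest time the memory signal is expressed
#'   (default 150 ms).
#' @param t_range Time axis range in ms re stimulus onset (default -150 to
#'   400).
#' @return Object of class `timecourse_data`: `counts` (units x trials x
#'   bins integer array), `time_ms` (bin starts), `trials` tibble,
#'   `memory_units`, and the config.
#' @export
simulate_timecourse <- function(sim, seq, baseline_rate = 5,
                                visual_onset_ms = 75, memory_onset_ms = 150,
                                t_range = c(-150, 400)) {
  stopifnot(inherits(sim, "sim_config"), inherits(seq, "trial_sequence"))
  set.seed(sim$seed)
  images <- unique(seq$image_id)
  nu <- sim$n_units
  s <- sim$selectivity_dispersion
  gains <- matrix(rlnorm(nu * length(images), meanlog = -s^2 / 2, sdlog = s),
                  nrow = nu, dimnames = list(NULL, images))
  gains <- gains / rowMeans(gains)
  evoked_rate <- sim$grand_mean_counts / 0.250 * gains  # spikes/s, 150-400 ms

  n_mem <- round(sim$memory_fraction * nu)
  memory_units <- logical(nu)
  if (n_mem > 0) memory_units[sample.int(nu, n_mem)] <- TRUE
  d_trial <- lookup_decrement(sim$decrement_by_nback, seq$nback)
  d_trial[seq$presentation == "novel"] <- 0

  time_ms <- seq(t_range[1], t_range[2] - 1L)
  nb <- length(time_ms)
  nt <- nrow(seq)
  pre <- time_ms < visual_onset_ms
  memo <- time_ms >= memory_onset_ms
  counts <- array(0L, c(nu, nt, nb))
  rate_tr <- evoked_rate[, seq$image_id, drop = FALSE]  # units x trials
  for (bin in seq_len(nb)) {
    if (pre[bin]) {
      counts[, , bin] <- rpois(nu * nt, baseline_rate / 1000)
    } else {
      lam <- rate_tr
      if (memo[bin]) {
        lam <- lam * outer(memory_units, d_trial, function(m, d) 1 - m * d)
      }
      counts[, , bin] <- rpois(nu * nt, lam / 1000)
    }
  }
  trials <- tibble::tibble(
    session_id = sprintf("tc_seed%03d", sim$seed),
    trial_idx = seq$trial_idx, image_id = seq$image_id,
    presentation = seq$presentation, nback = seq$nback,
    off_nback = seq$off_nback,
    choice = NA_character_, correct = NA_integer_, rt_ms = NA_real_)
  structure(
    list(counts = counts, time_ms = time_ms, trials = trials,
         memory_units = memory_units, baseline_rate = baseline_rate,
         visual_onset_ms = visual_onset_ms,
         memory_onset_ms = memory_onset_ms, config = sim),
    class = "timecourse_data")
}

#' Spike counts of a time-resolved session in an arbitrary window
#'
#' @param tc A [simulate_timecourse()] result.
#' @param start,end Window bounds in ms (start inclusive, end exclusive).
#' @return Units x trials integer matrix.
#' @export
window_counts <- function(tc, start, end) {
  stopifnot(inherits(tc, "timecourse_data"))
  keep <- tc$time_ms >= start & tc$time_ms < end
  assert_that(any(keep), "window contains no bins")
  apply(tc$counts[, , keep, drop = FALSE], c(1, 2), sum)
}

#' Convert a time-resolved session to windowed session data
#'
#' @param tc A [simulate_timecourse()] result.
#' @param window `c(start, end)` in ms (default 150--400).
#' @return A `session_data` whose counts are taken in the window.
#' @export
as_session_data <- function(tc, window = c(150, 400)) {
  structure(
    list(trials = tc$trials,
         counts = window_counts(tc, window[1], window[2]),
         expected = NULL, window = window,
         memory_units = tc$memory_units, config = tc$config),
    class = "session_data")
}

#' Grand-mean PSTH of a time-resolved session by condition
#'
#' @param tc A [simulate_timecourse()] result.
#' @param ... Passed to [compute_psth()] (e.g. `smooth_ms`).
#' @return A `psth` tibble (conditions: `"novel"` plus each n-back).
#' @export
timecourse_psth <- function(tc, ...) {
  keep <- !tc$trials$off_nback
  unit_mean <- apply(tc$counts[, keep, , drop = FALSE], c(2, 3), mean)
  compute_psth(unit_mean, tc$time_ms,
               condition_of(tc$trials$presentation[keep],
                            tc$trials$nback[keep]), ...)
}

#' Responsiveness screen across the units of a time-resolved session
#'
#' Applies [visual_responsiveness()] per unit with the standard windows:
#' per-trial counts at -150--0 ms versus 75--225 ms.
#'
#' @param tc A [simulate_timecourse()] result.
#' @param alpha Criterion (default 0.01).
#' @param n_iterations Bootstrap iterations per unit.
#' @param seed Seed.
#' @return Tibble `unit`, `p`, `responsive`.
#' @export
screen_responsive_units <- function(tc, alpha = 0.01, n_iterations = 1000L,
                                    seed = 1L) {
  set.seed(seed)
  base <- window_counts(tc, -150, 0)
  evoked <- window_counts(tc, 75, 225)
  out <- lapply(seq_len(nrow(base)), function(u) {
    r <- visual_responsiveness(base[u, ], evoked[u, ], alpha = alpha,
                               n_iterations = n_iterations)
    tibble::tibble(unit = u, p = r$p, responsive = r$responsive)
  })
  dplyr::bind_rows(out)
}
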