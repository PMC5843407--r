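#' Strength-theory behavioral observer configuration
#'
#' A signal-detection observer for the novel/familiar judgment: on each trial
#' a noisy memory strength is drawn from the condition's Gaussian and
#' compared to a criterion (strength below criterion reads "familiar", the
#' same sign convention as the population decoders). Strength theory adds
#' that mean reaction time is inversely (here linearly) related to the
#' proportion of trials sharing that condition-and-outcome cell, producing
#' the characteristic x-shaped correct/error RT pattern.
#'
#' Default condition means place 1-back performance near 0.96 proportion
#' chose familiar, declining to 0.40 at 64-back, with a 0.10 novel false-alarm
#' rate -- a realistic monkey forgetting function for this task.
#'
#' @param mean_strength_by_condition Named numeric vector of mean strengths:
#'   one entry `"novel"` plus one per n-back level (names are the levels).
#' @param strength_sd Common strength SD (> 0).
#' @param criterion Decision criterion.
#' @param rt_slope Reaction-time slope in ms per unit outcome proportion
#'   (negative: common outcomes are fast).
#' @param rt_intercept Reaction-time intercept in ms (measured from the go
#'   cue, 400 ms after stimulus onset).
#' @param rt_jitter_sd Trial-level Gaussian RT jitter SD in ms (default 30).
#' @param seed Integer seed.
#' @return An object of class `observer_config`.
#' @export
observer_config <- function(
    mean_strength_by_condition = c(
      novel = 1.28, `1` = -1.75, `2` = -1.48, `4` = -1.17, `8` = -0.77,
      `16` = -0.41, `32` = -0.15, `64` = 0.25),
    strength_sd = 1, criterion = 0,
    rt_slope = -150, rt_intercept = 400, rt_jitter_sd = 30,
    seed = 1L) {
  assert_that(strength_sd > 0, "`strength_sd` must be > 0")
  assert_that("novel" %in% names(mean_strength_by_condition),
              "condition means must include a 'novel' entry")
  structure(
    list(mean_strength_by_condition = mean_strength_by_condition,
         strength_sd = strength_sd, criterion = criterion,
         rt_slope = rt_slope, rt_intercept = rt_intercept,
         rt_jitter_sd = rt_jitter_sd, seed = as.integer(seed)),
    class = "observer_config")
}

# Mean strength for each trial's condition; off-nback familiar conditions are
# interpolated on the log2 n-back scale (these trials are excluded from
# analyses but still need a simulated report).
observer_trial_means <- function(obs, presentation, nback) {
  m <- obs$mean_strength_by_condition
  fam <- m[names(m) != "novel"]
  lv <- as.numeric(names(fam))
  o <- order(lv); lv <- lv[o]; fv <- as.numeric(fam)[o]
  out <- numeric(length(presentation))
  for (i in seq_along(out)) {
    if (presentation[i] == "novel") { out[i] <- m[["novel"]]; next }
    hit <- match(as.character(nback[i]), names(fam))
    if (!is.na(hit)) { out[i] <- fam[[hit]]; next }
    out[i] <- if (length(lv) == 1) fv else
      stats::approx(log2(lv), fv,
                    xout = log2(max(min(nback[i], max(lv)), min(lv))))$y
  }
  out
}

#' Analytic outcome proportions of a strength observer
#'
#' Closed-form Gaussian-tail proportions per condition: the probability of a
#' "familiar" report is `pnorm(criterion, mean, sd)`; correct means choosing
#' familiar on familiar trials and novel on novel trials.
#'
#' @param obs An [observer_config()].
#' @return Tibble with `condition`, `nback`, `p_familiar`, `p_correct`.
#' @export
observer_proportions <- function(obs) {
  m <- obs$mean_strength_by_condition
  cond <- names(m)
  p_fam <- pnorm(obs$criterion, mean = as.numeric(m), sd = obs$strength_sd)
  tibble::tibble(
    condition = cond,
    nback = suppressWarnings(as.integer(cond)),
    p_familiar = p_fam,
    p_correct = ifelse(cond == "novel", 1 - p_fam, p_fam))
}

#' Simulate behavioral reports for a trial sequence
#'
#' Draws per-trial memory strengths, reports "familiar" when strength falls
#' below the criterion, and assigns reaction times as the linear
#' strength-theory map applied to the analytic proportion of the trial's
#' condition-and-outcome cell, plus Gaussian jitter.
#'
#' @param obs An [observer_config()].
#' @param seq A [generate_task_sequence()] trial sequence.
#' @return Tibble: the sequence columns plus `choice`, `correct` (0/1) and
#'   `rt_ms`.
#' @export
simulate_behavior <- function(obs, seq) {
  stopifnot(inherits(obs, "observer_config"), inherits(seq, "trial_sequence"))
  assert_that(obs$strength_sd > 0, "`strength_sd` must be > 0")
  set.seed(obs$seed)
  mu <- observer_trial_means(obs, seq$presentation, seq$nback)
  strength <- rnorm(nrow(seq), mu, obs$strength_sd)
  choice <- ifelse(strength < obs$criterion, "familiar", "novel")
  correct <- as.integer(choice == seq$presentation)
  # analytic proportion of each (condition, outcome) cell through the map
  p_fam_cell <- pnorm(obs$criterion, mu, obs$strength_sd)
  p_chosen <- ifelse(choice == "familiar", p_fam_cell, 1 - p_fam_cell)
  rt <- obs$rt_intercept + obs$rt_slope * p_chosen +
    rnorm(nrow(seq), 0, obs$rt_jitter_sd)
  dplyr::mutate(tibble::as_tibble(seq),
                choice = choice, correct = correct, rt_ms = rt,
                session_id = sprintf("obs_seed%03d", obs$seed))
}

#' Simulate a full session: spike counts plus behavioral reports
#'
#' Convenience wrapper generating a trial sequence, a synthetic population
#' and a strength-observer behavioral table for the same trials.
#'
#' @param sim A [sim_config()].
#' @param obs An [observer_config()].
#' @param task A [task_config()].
#' @return A `session_data` whose `trials` carry choices, outcomes and RTs.
#' @export
simulate_session <- function(sim, obs, task = task_config(seed = sim$seed)) {
  seq <- generate_task_sequence(task)
  session <- simulate_population(sim, seq)
  beh <- simulate_behavior(obs, seq)
  session$trials$choice <- beh$choice
  session$trials$correct <- beh$correct
  session$trials$rt_ms <- beh$rt_ms
  session
}
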