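#' Default repetition-suppression profile
#'
#' Proportional response decrement as a function of n-back: a power-law decay
#' anchored at an 11% decrement for an immediately repeated image
#' (the magnitude of net IT repetition suppression at 1-back), falling off
#' smoothly with n-back.
#'
#' @param nback_levels Integer n-back separations.
#' @param d1 Decrement at 1-back (default 0.11).
#' @param decay Power-law exponent (default 0.25); decrement is
#'   `d1 * nback^(-decay)`.
#' @return Named numeric vector of decrements, one per level.
#' @export
default_decrement_profile <- function(nback_levels = c(1, 2, 4, 8, 16, 32, 64),
                                      d1 = 0.11, decay = 0.25) {
  setNames(d1 * nback_levels^(-decay), as.character(nback_levels))
}

#' Simulation configuration for a synthetic IT population
#'
#' Parameterises a population of Poisson spike-count units with per-image
#' visual selectivity (log-normal gains with unit mean) and multiplicative
#' n-back-dependent repetition suppression carried by a configurable fraction
#' of units.
#'
#' @param n_units Number of units.
#' @param grand_mean_counts Per-unit expected spike count in the 150--400 ms
#'   window (spikes; default 3, i.e. 12 spikes/s over 250 ms).
#' @param selectivity_dispersion `sdlog` of the per-image log-normal gain
#'   (unitless; 0 = untuned units).
#' @param decrement_by_nback Named numeric vector mapping n-back to the
#'   proportional response decrement in `[0, 1)` for familiar presentations.
#' @param memory_fraction Fraction of units that carry memory modulation
#'   (default 0.5, reflecting signal carried by roughly half the IT
#'   population); the rest respond identically to novel and familiar images.
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_units = 800L,
                       grand_mean_counts = 3,
                       selectivity_dispersion = 1,
                       decrement_by_nback = default_decrement_profile(),
                       memory_fraction = 0.5,
                       seed = 1L) {
  assert_that(n_units >= 1, "`n_units` must be >= 1")
  assert_that(grand_mean_counts > 0, "`grand_mean_counts` must be > 0")
  assert_that(selectivity_dispersion >= 0,
              "`selectivity_dispersion` must be >= 0")
  assert_that(all(decrement_by_nback >= 0 & decrement_by_nback < 1),
              "decrements must lie in [0, 1)")
  assert_that(!is.null(names(decrement_by_nback)),
              "`decrement_by_nback` must be named by n-back")
  assert_that(memory_fraction >= 0 && memory_fraction <= 1,
              "`memory_fraction` must lie in [0, 1]")
  structure(
    list(n_units = as.integer(n_units),
         grand_mean_counts = grand_mean_counts,
         selectivity_dispersion = selectivity_dispersion,
         decrement_by_nback = decrement_by_nback,
         memory_fraction = memory_fraction,
         seed = as.integer(seed)),
    class = "sim_config")
}

# Decrement applicable at an arbitrary n-back: exact map entry when present,
# otherwise interpolated on the log2(n-back) scale (clamped at the ends).
# Off-nback pairs are excluded from analyses, so interpolation only shapes
# trials that are discarded downstream.
lookup_decrement <- function(decrements, nback) {
  lv <- as.numeric(names(decrements))
  o <- order(lv); lv <- lv[o]; dv <- as.numeric(decrements)[o]
  out <- numeric(length(nback))
  for (i in seq_along(nback)) {
    n <- nback[i]
    if (is.na(n)) { out[i] <- 0; next }
    hit <- match(as.character(n), names(decrements))
    if (!is.na(hit)) { out[i] <- decrements[[hit]]; next }
    if (length(lv) == 1) { out[i] <- dv; next }
    out[i] <- stats::approx(log2(lv), dv, xout = log2(max(min(n, max(lv)),
                                                          min(lv))))$y
  }
  out
}

#' Simulate an IT recording session for a trial sequence
#'
#' Draws per-unit per-image gains from a log-normal with unit mean and the
#' configured dispersion, normalised so each unit's grand mean novel response
#' equals `grand_mean_counts`; familiar-presentation expectations are the
#' novel expectation times `1 - decrement(nback)` for memory-carrying units;
#' observed spike counts are Poisson.
#'
#' @param sim A [sim_config()].
#' @param seq A [generate_task_sequence()] trial sequence.
#' @return An object of class `session_data`: a list with `trials` (tibble:
#'   `session_id`, `trial_idx`, `image_id`, `presentation`, `nback`,
#'   `off_nback`, `choice`, `correct`, `rt_ms`), `counts` (units x trials
#'   integer matrix), `expected` (units x trials expectations), `window`
#'   (c(150, 400) ms), `memory_units` (logical per unit), and the config.
#' @export
simulate_population <- function(sim, seq) {
  stopifnot(inherits(sim, "sim_config"), inherits(seq, "trial_sequence"))
  set.seed(sim$seed)
  images <- unique(seq$image_id)
  nu <- sim$n_units
  s <- sim$selectivity_dispersion
  gains <- matrix(rlnorm(nu * length(images), meanlog = -s^2 / 2, sdlog = s),
                  nrow = nu, dimnames = list(NULL, images))
  gains <- gains / rowMeans(gains)  # unit grand mean = grand_mean_counts
  lambda_novel <- sim$grand_mean_counts * gains

  n_mem <- round(sim$memory_fraction * nu)
  memory_units <- logical(nu)
  if (n_mem > 0) memory_units[sample.int(nu, n_mem)] <- TRUE

  d_trial <- lookup_decrement(sim$decrement_by_nback, seq$nback)
  d_trial[seq$presentation == "novel"] <- 0
  lam <- lambda_novel[, seq$image_id, drop = FALSE]
  mod <- outer(memory_units, d_trial, function(m, d) 1 - m * d)
  lam <- lam * mod
  assert_that(all(lam >= 0), "negative expected spike count")

  counts <- matrix(rpois(length(lam), lam), nrow = nu)
  trials <- tibble::tibble(
    session_id = sprintf("sim_seed%03d", sim$seed),
    trial_idx = seq$trial_idx, image_id = seq$image_id,
    presentation = seq$presentation, nback = seq$nback,
    off_nback = seq$off_nback,
    choice = NA_character_, correct = NA_integer_, rt_ms = NA_real_)
  structure(
    list(trials = trials, counts = counts, expected = lam,
         window = c(150, 400), memory_units = memory_units, config = sim),
    class = "session_data")
}

#' Replication-model prediction for one unit
#'
#' Inverts the multiplicative repetition-suppression model for a unit given
#' only novel/familiar pair-average responses per image: with proportional
#' decrement `d`, familiar = novel x (1 - d) and (novel + familiar)/2 equals
#' the pair mean, so novel = 2 x mean / (2 - d). A pair mean of 6 spikes at
#' d = 0.10 predicts 6.32 spikes novel and 5.68 familiar; a pair mean of 3
#' predicts 3.16 and 2.84.
#'
#' @param unit_pairs Tibble (or data frame) with columns `image_id`,
#'   `pair_mean` (spikes, >= 0) and `nback`.
#' @param decrements Named numeric vector mapping n-back to proportional
#'   decrement in `[0, 1)`.
#' @param sample_counts Draw Poisson observed counts around the expectations?
#' @param n_trials_per_presentation Poisson draws per cell when sampling.
#' @return Tibble of class `simulated_unit` with per-image `expected_novel`,
#'   `expected_familiar` (and `observed_*` when sampled), tagged
#'   `provenance = "replication"`.
#' @export
make_replication_unit <- function(unit_pairs, decrements,
                                  sample_counts = FALSE,
                                  n_trials_per_presentation = 1L) {
  unit_pairs <- tibble::as_tibble(unit_pairs)
  assert_that(all(c("image_id", "pair_mean", "nback") %in% names(unit_pairs)),
              "`unit_pairs` needs columns image_id, pair_mean, nback")
  assert_that(all(unit_pairs$pair_mean >= 0), "pair means must be >= 0")
  assert_that(all(decrements >= 0 & decrements < 1),
              "decrements must lie in [0, 1)")
  d <- lookup_decrement(decrements, unit_pairs$nback)
  novel <- 2 * unit_pairs$pair_mean / (2 - d)
  familiar <- novel * (1 - d)
  out <- dplyr::mutate(unit_pairs,
                       expected_novel = novel, expected_familiar = familiar,
                       provenance = "replication")
  if (sample_counts) out <- add_poisson_draws(out, n_trials_per_presentation)
  class(out) <- c("simulated_unit", class(out))
  out
}

#' Visual-modulation-removed prediction for one unit
#'
#' As [make_replication_unit()], but memory modulation is applied around the
#' unit's grand mean spike count across all images instead of each image's
#' own pair mean, removing visual selectivity while preserving the per-n-back
#' proportional decrement and the unit's grand mean.
#'
#' @inheritParams make_replication_unit
#' @return Tibble of class `simulated_unit`, tagged
#'   `provenance = "visual_removed"`.
#' @export
remove_visual_modulation <- function(unit_pairs, decrements,
                                     sample_counts = FALSE,
                                     n_trials_per_presentation = 1L) {
  unit_pairs <- tibble::as_tibble(unit_pairs)
  assert_that(all(c("image_id", "pair_mean", "nback") %in% names(unit_pairs)),
              "`unit_pairs` needs columns image_id, pair_mean, nback")
  grand <- mean(unit_pairs$pair_mean)
  flat <- dplyr::mutate(unit_pairs, pair_mean = grand)
  out <- make_replication_unit(flat, decrements,
                               sample_counts = sample_counts,
                               n_trials_per_presentation =
                                 n_trials_per_presentation)
  out$provenance <- "visual_removed"
  out
}

add_poisson_draws <- function(tbl, n_rep) {
  tbl$observed_novel <- lapply(tbl$expected_novel,
                               function(l) rpois(n_rep, l))
  tbl$observed_familiar <- lapply(tbl$expected_familiar,
                                  function(l) rpois(n_rep, l))
  tbl
}

#' Derive a simulated pseudopopulation from a recorded one
#'
#' Rebuilds every unit of a pseudopopulation from its measured statistics:
#' the per-unit proportional decrement at each n-back and either each image's
#' novel/familiar pair-average response (`"replication"`) or the unit's grand
#' mean alone (`"visual_removed"`). Expectations follow the pair-mean
#' inversion of [make_replication_unit()]; observed counts are fresh Poisson
#' draws. This isolates how much of decoder performance rides on visual
#' selectivity versus the memory signal itself.
#'
#' @param pop A [build_pseudopopulation()] result.
#' @param mode `"replication"` or `"visual_removed"`.
#' @param seed Integer seed for the Poisson draws.
#' @return A new `pseudopopulation` with the same shape and n-back template.
#' @export
derive_simulated_population <- function(pop,
                                        mode = c("replication",
                                                 "visual_removed"),
                                        seed = 1L) {
  stopifnot(inherits(pop, "pseudopopulation"))
  mode <- match.arg(mode)
  set.seed(seed)
  resp <- pop$responses
  nu <- dim(resp)[1]
  expected <- array(0, dim(resp))
  for (u in seq_len(nu)) {
    nov <- resp[u, , 1]; fam <- resp[u, , 2]
    pair_mean <- (nov + fam) / 2
    # measured mean proportional decrement per n-back across the unit's pairs
    d_by <- vapply(split(seq_along(pop$pair_nback), pop$pair_nback),
                   function(idx) {
                     mn <- mean(nov[idx]); mf <- mean(fam[idx])
                     if (mn <= 0) 0 else max(min((mn - mf) / mn, 0.999), 0)
                   }, numeric(1))
    if (mode == "visual_removed") pair_mean <- rep(mean(pair_mean),
                                                   length(pair_mean))
    d <- lookup_decrement(d_by, pop$pair_nback)
    expected[u, , 1] <- 2 * pair_mean / (2 - d)
    expected[u, , 2] <- expected[u, , 1] * (1 - d)
  }
  out <- pop
  out$responses <- array(rpois(length(expected), expected), dim(expected))
  out$provenance_mode <- mode
  out
}
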