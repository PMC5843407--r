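#' Task configuration for the single-exposure recognition-memory task
#'
#' Describes one session of the novel/familiar judgment task: each image is
#' shown exactly twice, once as novel and once as familiar, separated by an
#' n-back delay (the number of intervening trials) drawn uniformly from
#' `nback_levels`.
#'
#' @param nback_levels Strictly increasing positive integers; the n-back
#'   separations at which image repeats are scheduled. Default `2^(0:6)`,
#'   i.e. 1--64 trials.
#' @param n_pairs_per_nback Target number of novel/familiar image pairs at
#'   each n-back level.
#' @param mean_trial_interval_s Mean trial-to-trial interval in seconds; used
#'   only to convert n-back separations into mean delays (default 4.5 s, so a
#'   64-back repeat occurs after 4.8 min on average).
#' @param seed Integer seed for sequence generation.
#'
#' @return An object of class `task_config`.
#' @export
task_config <- function(nback_levels = c(1L, 2L, 4L, 8L, 16L, 32L, 64L),
                        n_pairs_per_nback = 15L,
                        mean_trial_interval_s = 4.5,
                        seed = 1L) {
  nback_levels <- as.integer(nback_levels)
  assert_that(length(nback_levels) >= 1 && all(nback_levels > 0),
              "`nback_levels` must be positive integers")
  assert_that(all(diff(nback_levels) > 0),
              "`nback_levels` must be strictly increasing")
  assert_that(n_pairs_per_nback >= 1, "`n_pairs_per_nback` must be >= 1")
  assert_that(mean_trial_interval_s > 0, "`mean_trial_interval_s` must be > 0")
  structure(
    list(nback_levels = nback_levels,
         n_pairs_per_nback = as.integer(n_pairs_per_nback),
         mean_trial_interval_s = mean_trial_interval_s,
         seed = as.integer(seed)),
    class = "task_config")
}

#' Mean delay between novel and familiar presentations at each n-back
#'
#' @param config A [task_config()].
#' @return A tibble with columns `nback`, `mean_delay_s`, `mean_delay_min`.
#' @export
nback_delays <- function(config) {
  tibble::tibble(
    nback = config$nback_levels,
    mean_delay_s = config$nback_levels * config$mean_trial_interval_s,
    mean_delay_min = config$nback_levels * config$mean_trial_interval_s / 60)
}

#' Generate a trial sequence with a uniform distribution of n-back
#'
#' Builds one session's trial order by iteratively placing novel images and
#' their repeats. The hardest (largest) n-back pairs are inserted first; a
#' quota of `ceiling(0.83 * n_pairs_per_nback)` pairs per level is placed in
#' the first pass (restarting on failure), remaining open slots are then
#' backfilled from the n-back list (largest first) up to the per-level
#' target, and residual slots are filled with "off n-back" pairs that are
#' flagged for exclusion from analysis. The sequence is 1.2 times the minimum
#' length (2 trials per pair).
#'
#' @param config A [task_config()].
#' @param max_restarts Bound on first-pass restarts before erroring.
#' @return A tibble of class `trial_sequence` with columns `trial_idx`,
#'   `image_id`, `presentation` ("novel"/"familiar"), `nback` (the pair's
#'   separation; `NA` for an unpaired residual novel trial) and `off_nback`
#'   (logical; `TRUE` for residual fills excluded downstream).
#' @export
generate_task_sequence <- function(config, max_restarts = 200L) {
  stopifnot(inherits(config, "task_config"))
  levels_desc <- rev(config$nback_levels)
  n_per <- config$n_pairs_per_nback
  total_pairs <- length(levels_desc) * n_per
  len <- ceiling(1.2 * 2 * total_pairs)
  assert_that(max(levels_desc) < len,
              "largest n-back does not fit in the sequence length")
  quota <- ceiling(0.83 * n_per)
  set.seed(config$seed)

  place_pair <- function(occ, lvl) {
    # candidate novel slots whose familiar slot is also free
    cand <- which(!occ)
    cand <- cand[cand + lvl <= len & !occ[cand + lvl]]
    if (length(cand) == 0) return(NULL)
    cand[sample.int(length(cand), 1L)]
  }

  for (attempt in seq_len(max_restarts)) {
    occ <- logical(len)
    pair_novel <- integer(0); pair_lvl <- integer(0)
    ok <- TRUE
    # first pass: fixed quota per level, hardest first
    for (lvl in levels_desc) {
      for (k in seq_len(min(quota, n_per))) {
        i <- place_pair(occ, lvl)
        if (is.null(i)) { ok <- FALSE; break }
        occ[c(i, i + lvl)] <- TRUE
        pair_novel <- c(pair_novel, i); pair_lvl <- c(pair_lvl, lvl)
      }
      if (!ok) break
    }
    if (!ok) next
    # backfill remaining slots from the n-back list, largest first
    for (lvl in levels_desc) {
      while (sum(pair_lvl == lvl) < n_per) {
        i <- place_pair(occ, lvl)
        if (is.null(i)) break
        occ[c(i, i + lvl)] <- TRUE
        pair_novel <- c(pair_novel, i); pair_lvl <- c(pair_lvl, lvl)
      }
    }
    counts <- vapply(levels_desc, function(l) sum(pair_lvl == l), integer(1))
    if (all(counts >= ceiling(0.9 * n_per))) {
      return(finish_sequence(len, occ, pair_novel, pair_lvl, config))
    }
  }
  abort(sprintf("could not build a balanced sequence in %d attempts",
                max_restarts))
}

# Fill residual slots with off-nback pairs and assemble the tibble.
finish_sequence <- function(len, occ, pair_novel, pair_lvl, config) {
  off_novel <- integer(0); off_lvl <- integer(0); lone <- integer(0)
  free <- which(!occ)
  # pair residual free slots greedily: each earliest free slot with the next
  while (length(free) >= 2) {
    i <- free[1]; j <- free[2]
    off_novel <- c(off_novel, i); off_lvl <- c(off_lvl, j - i)
    free <- free[-c(1, 2)]
  }
  if (length(free) == 1) lone <- free

  image_id <- character(len); presentation <- character(len)
  nback <- rep(NA_integer_, len); off <- logical(len)
  all_novel <- c(pair_novel, off_novel)
  all_lvl <- c(pair_lvl, off_lvl)
  all_off <- c(rep(FALSE, length(pair_novel)), rep(TRUE, length(off_novel)))
  ord <- order(all_novel)
  all_novel <- all_novel[ord]; all_lvl <- all_lvl[ord]; all_off <- all_off[ord]
  for (p in seq_along(all_novel)) {
    id <- sprintf("img_%04d", p)
    i <- all_novel[p]; j <- i + all_lvl[p]
    image_id[c(i, j)] <- id
    presentation[i] <- "novel"; presentation[j] <- "familiar"
    nback[c(i, j)] <- all_lvl[p]; off[c(i, j)] <- all_off[p]
  }
  if (length(lone) == 1) {
    image_id[lone] <- sprintf("img_%04d", length(all_novel) + 1L)
    presentation[lone] <- "novel"; off[lone] <- TRUE
  }
  out <- tibble::tibble(
    trial_idx = seq_len(len), image_id = image_id,
    presentation = presentation, nback = nback, off_nback = off)
  class(out) <- c("trial_sequence", class(out))
  attr(out, "config") <- config
  out
}

#' Summarise pair counts of a trial sequence by n-back
#'
#' @param seq A [generate_task_sequence()] result.
#' @param include_off_nback Count residual off-nback pairs too?
#' @return Tibble with columns `nback`, `n_pairs`.
#' @export
sequence_pair_counts <- function(seq, include_off_nback = FALSE) {
  dat <- dplyr::filter(seq, .data$presentation == "familiar")
  if (!include_off_nback) dat <- dplyr::filter(dat, !.data$off_nback)
  dplyr::count(dat, .data$nback, name = "n_pairs")
}
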