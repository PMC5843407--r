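#' Default end-to-end pipeline configuration
#'
#' Mirrors the standard analysis parameters: a 150--400 ms spike-count
#' window, 1000 resampling iterations, 2 held-out images per n-back and
#' 2.2 x SEM confidence intervals; the demo scale (units, sessions,
#' iterations, size grid) is adjustable.
#'
#' @param n_units Units per simulated session.
#' @param n_sessions Number of simulated sessions.
#' @param n_pairs_per_nback Image pairs per n-back per session.
#' @param nback_levels N-back levels.
#' @param n_iterations Decoding iterations.
#' @param sizes Population size grid for the sweep (`NULL` = default grid).
#' @param decoders Decoder kinds to run.
#' @param window Spike-count window (ms).
#' @param seed Master seed; stage seeds derive from it.
#' @return A named list (class `run_config`).
#' @export
pipeline_config <- function(n_units = 50L, n_sessions = 2L,
                            n_pairs_per_nback = 18L,
                            nback_levels = c(1L, 2L, 4L, 8L, 16L, 32L, 64L),
                            n_iterations = 100L, sizes = NULL,
                            decoders = "fld", window = c(150, 400),
                            seed = 1L) {
  assert_that(window[1] >= 0 && window[1] < window[2] && window[2] <= 400,
              "window must satisfy 0 <= start < end <= 400")
  structure(
    list(n_units = n_units, n_sessions = n_sessions,
         n_pairs_per_nback = n_pairs_per_nback,
         nback_levels = nback_levels, n_iterations = n_iterations,
         sizes = sizes, decoders = decoders, window = window,
         seed = as.integer(seed)),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of [pipeline_config()] fields.
#' @return A `run_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in intersect(names(y), names(cfg))) cfg[[nm]] <- y[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full synthetic pipeline end to end
#'
#' simulate -> summarise behavior -> build pseudopopulation -> decode ->
#' predict forgetting and reaction times -> score prediction quality.
#' All outputs (per-condition CSVs, decoder JSON, a manifest with the
#' config hash and every derived seed) are written under `out_dir`; a rerun
#' with the same config is bit-identical.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return Invisibly, a list with `behavior`, `rt`, `pop`, and per-decoder
#'   `predictions` (strengths, predicted forgetting function, PQ, RT-PQ).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "run_config"))
  stage_seed <- function(k) config$seed * 1000L + k

  template <- setNames(
    rep(min(config$n_pairs_per_nback - 3L, 15L),
        length(config$nback_levels)),
    as.character(config$nback_levels))
  # align the synthetic memory signal with the observer's forgetting
  # function so neural predictions are on the behavioral scale
  obs <- observer_config(seed = stage_seed(100L))
  target <- observer_proportions(obs) |>
    dplyr::transmute(condition = .data$condition, nback = .data$nback,
                     proportion = .data$p_familiar)
  sim <- calibrate_decrements(
    target,
    sim_config(n_units = config$n_units * config$n_sessions,
               seed = stage_seed(1L)),
    template)
  sessions <- lapply(seq_len(config$n_sessions), function(si) {
    sim_i <- sim
    sim_i$n_units <- config$n_units
    sim_i$seed <- stage_seed(si)
    obs_i <- obs
    obs_i$seed <- stage_seed(100L + si)
    simulate_session(
      sim_i, obs_i,
      task_config(nback_levels = config$nback_levels,
                  n_pairs_per_nback = config$n_pairs_per_nback,
                  seed = stage_seed(200L + si)))
  })
  trials <- dplyr::bind_rows(lapply(sessions, `[[`, "trials"))
  behavior <- compute_forgetting_function(trials, config$nback_levels)
  rt <- compute_rt_pattern(trials, config$nback_levels)
  pop <- build_pseudopopulation(sessions, template, seed = stage_seed(300L))

  predictions <- lapply(config$decoders, function(kind) {
    strengths <- run_decoding(pop, kind = kind,
                              n_iterations = config$n_iterations,
                              seed = stage_seed(400L))
    pred <- predict_forgetting(strengths)
    pq <- compute_pq(behavior, pred)
    rt_pq <- compute_rt_pq(rt, pred, behavior)
    list(kind = kind, strengths = strengths, prediction = pred,
         pq = pq, rt_pq = rt_pq)
  })
  names(predictions) <- config$decoders

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trials_csv(trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(behavior, file.path(out_dir, "forgetting_function.csv"),
                     row.names = FALSE)
    utils::write.csv(rt, file.path(out_dir, "rt_pattern.csv"),
                     row.names = FALSE)
    for (p in predictions) {
      utils::write.csv(p$prediction,
                       file.path(out_dir, sprintf("prediction_%s.csv",
                                                  p$kind)),
                       row.names = FALSE)
      jsonlite::write_json(
        list(kind = p$kind, pq = p$pq$pq, rt_pq = p$rt_pq$pq,
             mse_neural = p$pq$mse_neural,
             mse_benchmark = p$pq$mse_benchmark),
        file.path(out_dir, sprintf("pq_%s.json", p$kind)),
        auto_unbox = TRUE, digits = NA)
    }
    manifest <- list(
      config = unclass(config),
      config_hash = rlang::hash(unclass(config)),
      stage_seeds = list(task = stage_seed(0L),
                         sessions = stage_seed(seq_len(config$n_sessions)),
                         pseudopop = stage_seed(300L),
                         decoding = stage_seed(400L)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(behavior = behavior, rt = rt, pop = pop,
                 predictions = predictions, config = config))
}
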