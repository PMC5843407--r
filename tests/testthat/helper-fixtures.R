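# Shared fixture builders; everything is generated in code at test time.

nb_levels <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L)

uniform_template <- function(n_pairs, levels = nb_levels) {
  setNames(rep(as.integer(n_pairs), length(levels)), as.character(levels))
}

zero_decrements <- function(levels = nb_levels) {
  setNames(rep(0, length(levels)), as.character(levels))
}

# A synthetic pseudopopulation straight from the generator.
make_population <- function(n_units, n_pairs, decrements = zero_decrements(),
                            memory_fraction = 1, dispersion = 1,
                            grand_mean = 3, seed = 1L,
                            levels = nb_levels) {
  seq <- generate_task_sequence(
    task_config(nback_levels = levels,
                n_pairs_per_nback = n_pairs + 3L, seed = seed))
  sim <- sim_config(n_units = n_units, grand_mean_counts = grand_mean,
                    selectivity_dispersion = dispersion,
                    decrement_by_nback = decrements,
                    memory_fraction = memory_fraction, seed = seed + 1L)
  build_pseudopopulation(simulate_population(sim, seq),
                         uniform_template(n_pairs, levels),
                         seed = seed + 2L)
}

# Train split with exactly controlled per-unit class statistics.
toy_train <- function(novel, familiar) {
  list(novel = rbind(novel), familiar = rbind(familiar))
}

# A minimal hand-built pseudopopulation (constant responses).
constant_population <- function(n_units, pairs_per_level, novel_value,
                                familiar_values, levels = names(familiar_values)) {
  lv <- as.integer(levels)
  n_pairs <- pairs_per_level * length(lv)
  resp <- array(0, c(n_units, n_pairs, 2))
  pair_nback <- rep(lv, each = pairs_per_level)
  resp[, , 1] <- novel_value
  for (k in seq_along(lv)) {
    resp[, pair_nback == lv[k], 2] <- familiar_values[[k]]
  }
  structure(
    list(responses = resp, pair_nback = pair_nback,
         unit_provenance = tibble::tibble(session = 1L,
                                          unit = seq_len(n_units)),
         behavior = NULL, window = c(150, 400),
         template = uniform_template(pairs_per_level, lv), seed = 0L),
    class = "pseudopopulation")
}
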