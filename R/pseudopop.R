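#' Default n-back pair-count template
#'
#' Pair counts per n-back used to align sessions into the pooled
#' pseudopopulation: 15, 15, 16, 17, 17, 15 and 12 image pairs at 1, 2, 4,
#' 8, 16, 32 and 64-back (107 pairs in total).
#'
#' @return Named integer vector (names are n-back levels).
#' @export
default_pair_template <- function() {
  setNames(c(15L, 15L, 16L, 17L, 17L, 15L, 12L),
           c("1", "2", "4", "8", "16", "32", "64"))
}

#' Build an n-back-aligned pseudopopulation from sessions
#'
#' Concatenates units across sessions into a units x pairs x presentation
#' response tensor, aligned so that pair slots at a given n-back carry
#' novel/familiar responses to the same image within each session. Only
#' completed on-n-back pairs with both presentations (and, when behavior is
#' recorded, a report on both) enter; sessions with more eligible pairs than
#' the template requires contribute a random subset. Cross-session responses
#' are treated as uncorrelated.
#'
#' @param sessions A `session_data` or list of them.
#' @param template Named integer vector of pair counts per n-back (default
#'   [default_pair_template()] restricted to levels present).
#' @param seed Seed for the random subsampling of excess pairs.
#' @return An object of class `pseudopopulation`: list with `responses`
#'   (units x pairs x 2 array; slice 1 novel, slice 2 familiar),
#'   `pair_nback`, `unit_provenance` (tibble `session`, `unit`), `behavior`
#'   (per-pair choices/RTs when available, else `NULL`), `window`.
#' @export
build_pseudopopulation <- function(sessions, template = NULL, seed = 1L) {
  if (inherits(sessions, "session_data")) sessions <- list(sessions)
  stopifnot(all(vapply(sessions, inherits, logical(1), "session_data")))
  if (is.null(template)) {
    lv <- sort(unique(unlist(lapply(sessions, function(s)
      s$trials$nback[!s$trials$off_nback]))))
    tpl <- default_pair_template()
    template <- tpl[as.character(lv)]
    template[is.na(template)] <- 15L
    names(template) <- as.character(lv)
  }
  lv <- as.integer(names(template))
  set.seed(seed)

  chosen <- vector("list", length(sessions))
  deficits <- character(0)
  for (si in seq_along(sessions)) {
    tr <- sessions[[si]]$trials
    has_beh <- !all(is.na(tr$choice))
    eligible <- tr |>
      dplyr::filter(!.data$off_nback, !is.na(.data$nback)) |>
      (\(d) if (has_beh) dplyr::filter(d, !is.na(.data$choice)) else d)() |>
      dplyr::group_by(.data$image_id) |>
      dplyr::filter(dplyr::n() == 2) |>
      dplyr::ungroup()
    pick <- list()
    for (k in seq_along(lv)) {
      imgs <- unique(eligible$image_id[eligible$nback == lv[k]])
      need <- template[[k]]
      if (length(imgs) < need) {
        deficits <- c(deficits, sprintf(
          "session %d (%s): %d/%d pairs at %d-back",
          si, tr$session_id[1], length(imgs), need, lv[k]))
        next
      }
      pick[[k]] <- sample(imgs, need)
    }
    chosen[[si]] <- pick
  }
  assert_that(length(deficits) == 0,
              paste0("sessions with too few pairs:\n  ",
                     paste(deficits, collapse = "\n  ")))

  n_pairs <- sum(template)
  pair_nback <- rep(lv, times = as.integer(template))
  units_per <- vapply(sessions, function(s) nrow(s$counts), integer(1))
  nu <- sum(units_per)
  resp <- array(NA_real_, c(nu, n_pairs, 2))
  beh_rows <- list()
  u0 <- 0L
  for (si in seq_along(sessions)) {
    s <- sessions[[si]]; tr <- s$trials
    has_beh <- !all(is.na(tr$choice))
    pos <- setNames(seq_len(nrow(tr)),
                    paste(tr$image_id, tr$presentation))
    p0 <- 0L
    rows <- u0 + seq_len(units_per[si])
    for (k in seq_along(lv)) {
      for (img in chosen[[si]][[k]]) {
        p0 <- p0 + 1L
        i_nov <- pos[[paste(img, "novel")]]
        i_fam <- pos[[paste(img, "familiar")]]
        resp[rows, p0, 1] <- s$counts[, i_nov]
        resp[rows, p0, 2] <- s$counts[, i_fam]
        if (has_beh) beh_rows[[length(beh_rows) + 1L]] <- tibble::tibble(
          pair = p0, nback = lv[k], image_id = img,
          session_id = tr$session_id[1],
          novel_choice = tr$choice[i_nov], familiar_choice = tr$choice[i_fam],
          novel_rt_ms = tr$rt_ms[i_nov], familiar_rt_ms = tr$rt_ms[i_fam])
      }
    }
    u0 <- u0 + units_per[si]
  }
  behavior <- if (length(beh_rows)) dplyr::bind_rows(beh_rows) else NULL
  structure(
    list(responses = resp, pair_nback = pair_nback,
         unit_provenance = tibble::tibble(
           session = rep(seq_along(sessions), units_per),
           unit = unlist(lapply(units_per, seq_len))),
         behavior = behavior, window = sessions[[1]]$window,
         template = template, seed = seed),
    class = "pseudopopulation")
}

#' Number of units in a pseudopopulation
#' @param pop A `pseudopopulation`.
#' @return Integer unit count.
#' @export
n_units <- function(pop) dim(pop$responses)[1]

#' Shuffle-and-holdout resampling split
#'
#' One iteration of the cross-validated resampling scheme: each unit's pairs
#' are independently permuted within their matched n-back (destroying the
#' artificial cross-unit correlations of the pseudopopulation alignment while
#' preserving every per-unit per-condition marginal), then `n_test` images at
#' each n-back are held out with both their presentations for testing.
#'
#' @param pop A [build_pseudopopulation()] result.
#' @param n_test_images_per_nback Held-out images per n-back (default 2, i.e.
#'   4 held-out trials per n-back).
#' @param seed Optional seed; by default the split consumes the current RNG
#'   stream so that an outer seeded loop is reproducible.
#' @return List with `train` (list `novel`, `familiar`: units x pairs
#'   matrices), `test` (tibble-compatible list: `novel`, `familiar` matrices
#'   units x held-out pairs and `test_nback` per held-out pair).
#' @export
resample_split <- function(pop, n_test_images_per_nback = 2L, seed = NULL) {
  stopifnot(inherits(pop, "pseudopopulation"))
  if (!is.null(seed)) set.seed(seed)
  resp <- pop$responses
  nu <- dim(resp)[1]
  lv <- sort(unique(pop$pair_nback))
  test_idx <- integer(0)
  for (k in lv) {
    idx <- which(pop$pair_nback == k)
    m <- length(idx)
    assert_that(m > n_test_images_per_nback,
                sprintf("holdout exhausts %d-back (%d pairs)", k, m))
    # independent within-n-back permutation per unit, both presentations
    perm <- vapply(seq_len(nu), function(u) sample.int(m), integer(m))
    take <- cbind(rep(seq_len(nu), each = m), as.vector(perm))
    for (pres in 1:2) {
      M <- resp[, idx, pres]
      resp[, idx, pres] <- matrix(M[take], nrow = nu, byrow = TRUE)
    }
    test_idx <- c(test_idx, sample(idx, n_test_images_per_nback))
  }
  train_idx <- setdiff(seq_along(pop$pair_nback), test_idx)
  slice <- function(idx, pres) matrix(resp[, idx, pres], nrow = nu)
  list(
    train = list(novel = slice(train_idx, 1),
                 familiar = slice(train_idx, 2)),
    test = list(novel = slice(test_idx, 1),
                familiar = slice(test_idx, 2),
                test_nback = pop$pair_nback[test_idx]))
}
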