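#' Unit d-prime for novel versus familiar responses
#'
#' Difference of the mean responses to images presented as novel versus
#' familiar, divided by the average of the two sample standard deviations.
#' Positive values denote repetition suppression (novel > familiar).
#'
#' @param novel_counts,familiar_counts Numeric vectors (>= 2 trials each).
#' @return A single d' value; `NaN` (flagged undefined) when both SDs are 0.
#' @export
unit_dprime <- function(novel_counts, familiar_counts) {
  assert_that(length(novel_counts) >= 2 && length(familiar_counts) >= 2,
              "need at least 2 trials per class")
  s <- (sd(novel_counts) + sd(familiar_counts)) / 2
  d <- mean(novel_counts) - mean(familiar_counts)
  if (s == 0) return(NaN)
  d / s
}

# Per-unit class statistics from a train split (units x pairs matrices).
train_stats <- function(train) {
  list(mu1 = rowMeans(train$novel), mu2 = rowMeans(train$familiar),
       v1 = apply(train$novel, 1, var), v2 = apply(train$familiar, 1, var))
}

new_decoder_model <- function(w, b, kind, selected, N) {
  structure(list(w = w, b = b, kind = kind, selected = selected, N = N),
            class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model> kind=%s  units=%d  selected=%d  b=%.4g\n",
              x$kind, length(x$w), length(x$selected), x$b))
  invisible(x)
}

#' Fit a diagonal-covariance Fisher linear discriminant
#'
#' Each unit's weight is its class-mean difference over the pooled per-unit
#' variance, `w_i = (mu1_i - mu2_i) / ((var1_i + var2_i)/2)` -- the Fisher
#' discriminant with off-diagonal covariance terms set to zero, equivalent to
#' weighting each unit by its d'. The criterion is the midpoint projection
#' `b = w . (mu1 + mu2)/2` (class 1 novel, class 2 familiar). Units with zero
#' pooled variance receive weight 0 and are recorded in the model.
#'
#' @param train List with `novel` and `familiar` units x pairs matrices.
#' @param selected Optional unit index set to restrict the decoder to (other
#'   units get weight 0); default all units.
#' @return A `decoder_model` (kind `"fld"`).
#' @export
fit_fld <- function(train, selected = NULL) {
  st <- train_stats(train)
  nu <- length(st$mu1)
  if (is.null(selected)) selected <- seq_len(nu)
  pooled <- (st$v1 + st$v2) / 2
  w <- numeric(nu)
  ok <- pooled > 0
  w[ok] <- (st$mu1[ok] - st$mu2[ok]) / pooled[ok]
  w[setdiff(seq_len(nu), selected)] <- 0
  b <- sum(w * (st$mu1 + st$mu2) / 2)
  m <- new_decoder_model(w, b, "fld", selected, nu)
  m$zero_variance_units <- which(!ok)
  m
}

#' Fit a spike-count classifier
#'
#' Every selected unit receives the same weight `1/N` (N = number of selected
#' units), so the decoded value is the mean spike count -- the strictest
#' read-out of the repetition-suppression hypothesis. The criterion is the
#' midpoint projection of the two class means under these fixed weights.
#'
#' @inheritParams fit_fld
#' @return A `decoder_model` (kind `"scc"`).
#' @export
fit_scc <- function(train, selected = NULL) {
  st <- train_stats(train)
  nu <- length(st$mu1)
  if (is.null(selected)) selected <- seq_len(nu)
  w <- numeric(nu)
  w[selected] <- 1 / length(selected)
  b <- sum(w * (st$mu1 + st$mu2) / 2)
  new_decoder_model(w, b, "scc", selected, nu)
}

#' Rank units by signed d' and select the top N
#'
#' Ranking uses training data only. All positive-d' units (descending
#' magnitude) precede all negative-d' units (then descending magnitude), so
#' repetition-suppressed units are preferred; the top `N` indices are
#' returned.
#'
#' @param train List with `novel` and `familiar` units x pairs matrices.
#' @param N Number of units to select.
#' @return Integer vector of unit indices, best first.
#' @export
rank_and_select <- function(train, N) {
  st <- train_stats(train)
  nu <- length(st$mu1)
  assert_that(N <= nu, "`N` exceeds the number of units")
  sbar <- (sqrt(st$v1) + sqrt(st$v2)) / 2
  d <- ifelse(sbar > 0, (st$mu1 - st$mu2) / sbar, 0)
  ord <- order(d < 0, -abs(d))  # positives first, then by magnitude
  ord[seq_len(N)]
}

#' Decoded memory strength
#'
#' The linear read-out `s = w . x - b`. Test vectors with `s < 0` are
#' predicted "familiar" (the familiar side of the criterion); ties predict
#' novel.
#'
#' @param model A `decoder_model`.
#' @param x Numeric vector (length = units) or units x trials matrix.
#' @return Numeric strength(s), one per trial.
#' @export
memory_strength <- function(model, x) {
  if (is.matrix(x)) {
    assert_that(nrow(x) == length(model$w), "unit dimension mismatch")
    as.numeric(crossprod(x, model$w)) - model$b
  } else {
    assert_that(length(x) == length(model$w), "unit dimension mismatch")
    sum(model$w * x) - model$b
  }
}

#' Predicted labels from memory strengths
#'
#' @param strength Numeric strengths from [memory_strength()].
#' @return Character vector: `"familiar"` where strength < 0, else
#'   `"novel"`.
#' @export
strength_to_choice <- function(strength) {
  ifelse(strength < 0, "familiar", "novel")
}
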