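#' Logit and inverse-logit
#'
#' `logit()` maps a probability to log-odds; `expit()` is its inverse.
#' `expit()` is computed in a numerically stable branch-free form so that
#' large positive and negative logits saturate at 1 and 0 without overflow.
#'
#' @param p Probabilities, strictly inside (0, 1) for `logit()`.
#' @param x Real-valued log-odds.
#' @return Numeric vector of the same length.
#' @examples
#' expit(logit(0.1))
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p))
  log(p) - log1p(-p)
}

#' @rdname logit
#' @export
expit <- function(x) {
  stopifnot(is.numeric(x))
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  out
}

#' Weighted quantile (left-continuous inverse of the weighted ECDF)
#'
#' Returns the smallest observed value `v` such that the cumulative weight of
#' observations `<= v` reaches `prob` of the total weight. This is the
#' weighted analogue of `quantile(type = 1)` and is used for detection-rate
#' thresholds, calibration bin edges and quintile cut-points.
#'
#' @param x Numeric values.
#' @param w Non-negative weights, same length as `x`.
#' @param prob Probabilities in \[0, 1\] at which to evaluate.
#' @return Numeric vector, one value per element of `prob`.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), prob) {
  stopifnot(length(x) == length(w), all(w >= 0), all(prob >= 0 & prob <= 1))
  keep <- !is.na(x) & !is.na(w)
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) stop("weighted_quantile: no non-missing values")
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(prob, function(p) {
    if (p <= 0) return(x[1L])
    # left-continuous inverse: first value whose cumulative weight >= p
    x[which(cw >= p - 1e-12)[1L]]
  }, numeric(1))
}

#' Derive a reproducible sub-stream seed
#'
#' Expands one user-facing seed into deterministic per-stage / per-study
#' sub-seeds so that any single simulation stage can be reproduced in
#' isolation. Kept within the 32-bit signed-integer range.
#'
#' @param seed Integer master seed.
#' @param index Non-negative integer identifying the sub-stream.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index), index >= 0)
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

# internal: assert a numeric vector is strictly inside (0,1)
check_prob_open <- function(p, what = "probability") {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop(sprintf("%s must lie strictly inside (0, 1); use clip = TRUE to clip boundary values", what),
         call. = FALSE)
  }
  invisible(p)
}
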