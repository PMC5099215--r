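#' Follow-up rescaling factor for observed events
#'
#' Studies followed for less than the prediction horizon have their
#' observed event counts scaled up linearly to the horizon at the study
#' level: factor = horizon / followup_years. A 5-year follow-up with a
#' 10-year horizon doubles the observed events. A follow-up already at or
#' beyond the horizon passes through with factor 1 (with a message),
#' since events beyond the horizon are not subtracted.
#'
#' @param followup_years Positive follow-up duration(s), years.
#' @param horizon Prediction horizon, years (default 10).
#' @return Numeric rescaling factor(s) >= 1.
#' @export
followup_scale_factor <- function(followup_years, horizon = 10) {
  if (any(followup_years <= 0)) stop("followup_years must be positive")
  f <- horizon / followup_years
  if (any(f < 1)) {
    message("follow-up exceeds horizon for some studies; factor capped at 1")
    f <- pmax(f, 1)
  }
  f
}

#' Decile calibration table
#'
#' Bins individuals into `bins` groups at weighted quantiles of the
#' predicted risk, then compares the weighted observed event proportion
#' (after follow-up rescaling) with the weighted mean predicted risk in
#' each bin. Massive ties that would leave a bin empty cause adjacent bins
#' to be merged; merges are recorded.
#'
#' @param pred Predicted 10-year risk probabilities.
#' @param y Event indicators in \{0, 1\}.
#' @param w Sampling weights (default 1).
#' @param bins Number of bins (default 10, i.e. deciles; >= 2).
#' @param followup_years Per-individual follow-up (a study-level constant
#'   expanded per individual); default equal to `horizon`.
#' @param horizon Prediction horizon in years.
#' @return A `data.frame` of class `calibration_table` with one row per
#'   (possibly merged) bin: `bin`, weighted `n`, `mean_pred`, `obs_prop`
#'   (rescaled), `expected` (sum of `w * pred`), `observed` (rescaled
#'   weighted event count); attribute `merged` records any bin merges.
#' @seealso [hosmer_lemeshow()]
#' @export
decile_calibration <- function(pred, y, w = rep(1, length(y)), bins = 10,
                               followup_years = rep(horizon, length(y)),
                               horizon = 10) {
  stopifnot(bins >= 2, length(pred) == length(y), length(w) == length(y),
            length(followup_years) == length(y))
  check_prob_open(pred, "predicted risk")
  fac <- followup_scale_factor(followup_years, horizon)
  edges <- weighted_quantile(pred, w, seq_len(bins - 1) / bins)
  bin <- findInterval(pred, unique(edges), left.open = TRUE) + 1L
  # merge bins emptied by ties: findInterval over unique edges already
  # collapses duplicate cut-points; relabel to consecutive integers
  lev <- sort(unique(bin))
  merged <- length(lev) < bins
  bin <- match(bin, lev)
  rows <- lapply(seq_along(lev), function(b) {
    i <- bin == b
    data.frame(bin = b,
               n = sum(w[i]),
               mean_pred = sum(w[i] * pred[i]) / sum(w[i]),
               obs_prop = sum(w[i] * y[i] * fac[i]) / sum(w[i]),
               expected = sum(w[i] * pred[i]),
               observed = sum(w[i] * y[i] * fac[i]))
  })
  out <- do.call(rbind, rows)
  attr(out, "merged") <- merged
  attr(out, "assignments") <- bin
  class(out) <- c("calibration_table", class(out))
  out
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Chi-square comparison of observed and expected events across bins of
#' predicted risk:
#' \deqn{\chi^2 = \sum_b \frac{(O_b - E_b)^2}{E_b (1 - E_b / n_b)}}
#' with `df = bins - 2` degrees of freedom (the conventional reference
#' distribution for grouped predictions from a fitted model) and an
#' upper-tail chi-square p-value. Sampling weights enter both O and E via
#' the calibration table.
#'
#' @param table A [decile_calibration()] table (>= 3 bins).
#' @return List with `chi2`, `df`, `p`.
#' @export
hosmer_lemeshow <- function(table) {
  stopifnot(inherits(table, "calibration_table"))
  if (nrow(table) < 3) stop("Hosmer-Lemeshow needs at least 3 bins")
  denom <- table$expected * (1 - table$expected / table$n)
  if (any(denom <= 0)) stop("zero expected count in a bin; refit with fewer bins")
  chi2 <- sum((table$observed - table$expected)^2 / denom)
  df <- nrow(table) - 2
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}
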