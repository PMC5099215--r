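#' Construct a two-stage screening flow from population-scale counts
#'
#' Low-level constructor for the sequential screening strategy: a
#' population is screened with the phenotypic score; only the
#' intermediate-risk band receives the genetic score; those reclassified as
#' high risk are treated with statins at an assumed relative risk
#' reduction. Events prevented are kept fractional internally
#' (`rrr * expected_events_high`); the displayed count truncates to an
#' integer while the number needed to screen divides the population scale
#' by the *fractional* value and truncates:
#' `NNS = trunc(scale / (rrr * expected_events_high))`.
#'
#' @param intermediate Count (at `scale`) at intermediate risk under the
#'   phenotypic score.
#' @param reclass_high,reclass_low,remaining Counts reclassified high / low
#'   / left intermediate once the genetic score is added; must sum to
#'   `intermediate`.
#' @param expected_events_high Expected 10-year events (untreated) among
#'   those reclassified high, at `scale`.
#' @param rrr Relative risk reduction from treatment, in \[0, 1\]
#'   (default 0.20).
#' @param scale Population scale (default 100 000).
#' @return A list of class `screening_flow` with the inputs plus
#'   `events_prevented` (fractional), `events_prevented_display`
#'   (truncated) and `nns` (`Inf` when no events are prevented).
#' @seealso [two_stage_flow()]
#' @export
screening_flow <- function(intermediate, reclass_high, reclass_low, remaining,
                           expected_events_high, rrr = 0.20, scale = 100000) {
  stopifnot(rrr >= 0, rrr <= 1, scale > 0)
  if (abs(reclass_high + reclass_low + remaining - intermediate) > 1e-6 * max(1, intermediate)) {
    stop("flow not conserved: reclass_high + reclass_low + remaining must equal intermediate")
  }
  prevented <- rrr * expected_events_high
  structure(list(
    scale = scale, intermediate = intermediate,
    reclass_high = reclass_high, reclass_low = reclass_low,
    remaining = remaining,
    expected_events_high = expected_events_high,
    rrr = rrr,
    events_prevented = prevented,
    events_prevented_display = trunc(prevented),
    nns = if (prevented > 0) trunc(scale / prevented) else Inf
  ), class = "screening_flow")
}

#' Two-stage screening strategy on individual-level data
#'
#' Selects the weighted subpopulation whose phenotypic risk lies in the
#' intermediate band, classifies it by the combined (phenotypic + genetic)
#' score against the same band and the high-risk cut-off, scales the
#' weighted proportions to a population of `scale` people, and projects the
#' events prevented if everyone reclassified as high risk received
#' treatment with relative risk reduction `rrr`. Expected 10-year events
#' among the reclassified-high use observed events with the follow-up
#' rescaling rule of the calibration stage.
#'
#' @param p_pheno,p_combined Paired risk probabilities.
#' @param y Event indicators in \{0, 1\}.
#' @param w Sampling weights.
#' @param band Intermediate-risk band `[lo, hi)` under the phenotypic score
#'   (default `c(0.10, 0.20)`).
#' @param high Combined-score cut-off for reclassification to high risk
#'   (default 0.20).
#' @param scale Population scale (default 100 000).
#' @param rrr Relative risk reduction (default 0.20).
#' @param followup_years Per-individual follow-up for event rescaling.
#' @param horizon Prediction horizon, years.
#' @return A `screening_flow` (see [screening_flow()]).
#' @export
two_stage_flow <- function(p_pheno, p_combined, y, w = rep(1, length(y)),
                           band = c(0.10, 0.20), high = 0.20,
                           scale = 100000, rrr = 0.20,
                           followup_years = rep(horizon, length(y)),
                           horizon = 10) {
  stopifnot(length(p_pheno) == length(p_combined),
            length(p_pheno) == length(y),
            band[1] < band[2], band[1] > 0, band[2] < 1)
  mid <- p_pheno >= band[1] & p_pheno < band[2]
  if (!any(mid)) stop("no individuals in the intermediate-risk band")
  W <- sum(w)
  fac <- followup_scale_factor(followup_years, horizon)
  hi <- mid & p_combined >= high
  lo <- mid & p_combined < band[1]
  st <- mid & !hi & !lo
  per <- scale / W
  screening_flow(
    intermediate = per * sum(w[mid]),
    reclass_high = per * sum(w[hi]),
    reclass_low = per * sum(w[lo]),
    remaining = per * sum(w[st]),
    expected_events_high = per * sum(w[hi] * y[hi] * fac[hi]),
    rrr = rrr, scale = scale
  )
}

#' Render a screening flow as text and structured summary
#'
#' Re-asserts flow conservation and returns both a printable text rendering
#' of the five-box flow chart and a plain list suitable for JSON export.
#'
#' @param flow A `screening_flow`.
#' @return List with elements `text` (character vector of lines) and
#'   `summary` (named list of the counts and derived quantities).
#' @export
flow_report <- function(flow) {
  stopifnot(inherits(flow, "screening_flow"))
  stopifnot(abs(flow$reclass_high + flow$reclass_low + flow$remaining -
                  flow$intermediate) <= 1e-6 * max(1, flow$intermediate))
  fmt <- function(x) format(round(x), big.mark = " ", trim = TRUE)
  text <- c(
    sprintf("Population screened with phenotypic score: %s", fmt(flow$scale)),
    sprintf("  Intermediate risk (genetic score applied): %s", fmt(flow$intermediate)),
    sprintf("    Reclassified high risk: %s", fmt(flow$reclass_high)),
    sprintf("    Reclassified low risk:  %s", fmt(flow$reclass_low)),
    sprintf("    Remain intermediate:    %s", fmt(flow$remaining)),
    sprintf("  Expected 10-year events among reclassified high (untreated): %s",
            fmt(flow$expected_events_high)),
    sprintf("  Events prevented at %.0f%% relative risk reduction: %d",
            100 * flow$rrr, flow$events_prevented_display),
    if (is.finite(flow$nns)) {
      sprintf("  Number needed to screen to postpone one event: %d", flow$nns)
    } else {
      "  Number needed to screen: infinite (no events prevented)"
    }
  )
  summary <- flow[c("scale", "intermediate", "reclass_high", "reclass_low",
                    "remaining", "expected_events_high", "rrr",
                    "events_prevented", "events_prevented_display", "nns")]
  list(text = text, summary = summary)
}

#' @export
print.screening_flow <- function(x, ...) {
  cat(paste(flow_report(x)$text, collapse = "\n"), "\n")
  invisible(x)
}
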