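#' Assign risk categories from ascending cut-points
#'
#' Categories are half-open, lower-inclusive intervals: with cut-points
#' (t1, t2) the categories are \[0, t1), \[t1, t2), \[t2, 1\]. So with the
#' conventional 10% / 20% cut-points, a predicted risk of exactly 10% is
#' intermediate and exactly 20% is high ("20% or higher").
#'
#' @param p Risk probabilities in \[0, 1\].
#' @param thresholds Strictly ascending cut-points inside (0, 1); default
#'   `c(0.10, 0.20)`.
#' @return Integer category index, 0-based (0 = lowest category).
#' @export
categorize_risk <- function(p, thresholds = c(0.10, 0.20)) {
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0 & thresholds < 1))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probabilities must lie in [0, 1]")
  findInterval(p, thresholds)  # lower-inclusive: p == t goes up
}

#' Construct a reclassification table from weighted counts
#'
#' Low-level constructor used both by [cross_tabulate()] and directly when
#' the weighted up/down-crossing counts are already known (e.g. from a
#' published cross-tabulation). Derived quantities:
#' `net_event = (up_e - down_e) / N_e`,
#' `net_nonevent = (down_ne - up_ne) / N_ne`,
#' `NRI = net_event + net_nonevent`.
#'
#' @param n_event,up_event,down_event Weighted total, upward-crossing and
#'   downward-crossing counts among individuals who experienced an event.
#' @param n_nonevent,up_nonevent,down_nonevent Same among non-events.
#' @param thresholds The category cut-points used.
#' @param transitions Optional full transition tables (list of matrices).
#' @return A list of class `reclass_table`.
#' @seealso [nri()]
#' @export
reclass_counts <- function(n_event, up_event, down_event,
                           n_nonevent, up_nonevent, down_nonevent,
                           thresholds = c(0.10, 0.20), transitions = NULL) {
  stopifnot(n_event > 0, n_nonevent > 0,
            up_event + down_event <= n_event + 1e-8,
            up_nonevent + down_nonevent <= n_nonevent + 1e-8)
  structure(list(
    thresholds = thresholds,
    n_event = n_event, up_event = up_event, down_event = down_event,
    n_nonevent = n_nonevent, up_nonevent = up_nonevent,
    down_nonevent = down_nonevent,
    net_event = (up_event - down_event) / n_event,
    net_nonevent = (down_nonevent - up_nonevent) / n_nonevent,
    transitions = transitions
  ), class = "reclass_table")
}

#' Weighted cross-tabulation of risk categories before vs after
#'
#' Tabulates, separately for events and non-events, the weighted flow of
#' individuals between risk categories under two paired risk scores
#' (typically a phenotypic score alone versus the same score with a genetic
#' risk score added). Any upward category move counts as "up" regardless of
#' distance, and likewise for "down".
#'
#' @param p_before,p_after Paired risk probabilities on identical
#'   individuals.
#' @param y Event indicators in \{0, 1\}.
#' @param w Sampling weights (cases 1, upweighted controls > 1).
#' @param thresholds Ascending category cut-points (default 10% / 20%).
#' @return A `reclass_table` (see [reclass_counts()]) whose `transitions`
#'   element holds the weighted category-by-category matrices for events
#'   and non-events.
#' @export
cross_tabulate <- function(p_before, p_after, y, w = rep(1, length(y)),
                           thresholds = c(0.10, 0.20)) {
  if (length(p_before) != length(p_after) || length(p_before) != length(y)) {
    stop("p_before, p_after and y must have equal lengths")
  }
  cb <- categorize_risk(p_before, thresholds)
  ca <- categorize_risk(p_after, thresholds)
  k <- length(thresholds) + 1
  tab <- function(sel) {
    m <- matrix(0, k, k, dimnames = list(before = 0:(k - 1), after = 0:(k - 1)))
    for (i in which(sel)) m[cb[i] + 1, ca[i] + 1] <- m[cb[i] + 1, ca[i] + 1] + w[i]
    m
  }
  te <- tab(y == 1); tn <- tab(y == 0)
  up <- function(m) sum(m[upper.tri(m)])
  down <- function(m) sum(m[lower.tri(m)])
  reclass_counts(
    n_event = sum(te), up_event = up(te), down_event = down(te),
    n_nonevent = sum(tn), up_nonevent = up(tn), down_nonevent = down(tn),
    thresholds = thresholds,
    transitions = list(event = te, nonevent = tn)
  )
}

#' Net reclassification improvement with standard error
#'
#' NRI = net_event + net_nonevent, where net_event is the net weighted
#' proportion of events moved *up* and net_nonevent the net weighted
#' proportion of non-events moved *down*. The standard error follows the
#' standard first-order (Pencina-type) multinomial variance applied to the
#' weighted counts:
#' \deqn{SE^2 = \frac{u_e + d_e}{N_e^2} - \frac{(u_e - d_e)^2}{N_e^3}
#'   + \frac{u_n + d_n}{N_n^2} - \frac{(d_n - u_n)^2}{N_n^3}}
#' with a Wald confidence interval and two-sided normal p-value.
#'
#' @param table A `reclass_table` from [cross_tabulate()] or
#'   [reclass_counts()].
#' @param conf_level Confidence level (default 0.95).
#' @return List with `nri`, `net_event`, `net_nonevent`, `se`, `ci`, `p`.
#' @export
nri <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "reclass_table"))
  ue <- table$up_event; de <- table$down_event; ne <- table$n_event
  un <- table$up_nonevent; dn <- table$down_nonevent; nn <- table$n_nonevent
  est <- table$net_event + table$net_nonevent
  v <- (ue + de) / ne^2 - (ue - de)^2 / ne^3 +
    (un + dn) / nn^2 - (dn - un)^2 / nn^3
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(nri = est, net_event = table$net_event,
       net_nonevent = table$net_nonevent, se = se,
       ci = c(est - z * se, est + z * se),
       p = 2 * stats::pnorm(-abs(est) / se))
}

#' @export
print.reclass_table <- function(x, ...) {
  cat(sprintf("Reclassification at cut-point(s) %s\n",
              paste(format(x$thresholds), collapse = ", ")))
  cat(sprintf("  events     (N = %.2f): up %.2f, down %.2f, net %+.2f%%\n",
              x$n_event, x$up_event, x$down_event, 100 * x$net_event))
  cat(sprintf("  non-events (N = %.2f): up %.2f, down %.2f, net %+.2f%%\n",
              x$n_nonevent, x$up_nonevent, x$down_nonevent,
              100 * x$net_nonevent))
  r <- nri(x)
  cat(sprintf("  NRI = %.2f%% (%.2f to %.2f), p = %.2g\n",
              100 * r$nri, 100 * r$ci[1], 100 * r$ci[2], r$p))
  invisible(x)
}

#' Fixed-effects meta-analysis of per-study NRIs
#'
#' Inverse-variance pooling of per-study NRI estimates, identical in form
#' to [meta_fixed()].
#'
#' @param estimates Per-study NRI estimates.
#' @param ses Per-study standard errors.
#' @param conf_level Confidence level.
#' @return List with `estimate`, `se`, `ci` (see [meta_fixed()]).
#' @export
meta_nri <- function(estimates, ses, conf_level = 0.95) {
  meta_fixed(estimates, ses, conf_level = conf_level)
}
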