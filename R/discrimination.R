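#' Sampling-weighted AUROC
#'
#' The area under the receiver operating characteristic curve as the
#' weighted Mann-Whitney probability that a random case outscores a random
#' control, counting ties as one half:
#' \deqn{AUROC = \frac{\sum_{i \in cases}\sum_{j \in controls} w_i w_j
#'   [1(s_i > s_j) + \tfrac12 1(s_i = s_j)]}{(\sum w_{case})(\sum w_{ctrl})}}
#' Computed in O(n log n) via cumulative control weights over the sorted
#' unique scores, which equals the exhaustive pair count exactly.
#'
#' @param scores Numeric risk scores (any monotone scale).
#' @param y Event indicators in \{0, 1\}.
#' @param w Positive sampling weights (default 1).
#' @return AUROC in \[0, 1\].
#' @export
weighted_auroc <- function(scores, y, w = rep(1, length(y))) {
  stopifnot(length(scores) == length(y), length(w) == length(y))
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]; w <- w[keep]
  if (!any(y == 1) || !any(y == 0)) {
    stop("AUROC needs at least one case and one control")
  }
  u <- sort(unique(scores))
  pos <- match(scores, u)
  wc <- tapply_sum(pos[y == 0], w[y == 0], length(u))   # control weight per score
  below <- cumsum(wc) - wc                               # control weight strictly below
  num <- sum(w[y == 1] * (below[pos[y == 1]] + 0.5 * wc[pos[y == 1]]))
  num / (sum(w[y == 1]) * sum(w[y == 0]))
}

# internal: sum weights by integer position 1..k
tapply_sum <- function(pos, w, k) {
  out <- numeric(k)
  agg <- rowsum(w, pos)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Hanley-McNeil standard error of an AUROC
#'
#' Uses the Hanley & McNeil (1982) variance formula with effective sample
#' sizes. For weighted data the case and control counts are replaced by
#' Kish effective sizes `(sum w)^2 / sum w^2`, so upweighted controls do not
#' masquerade as independent observations.
#'
#' @inheritParams weighted_auroc
#' @param auc Optionally, a precomputed AUROC for these data.
#' @return Standard error of the AUROC.
#' @export
auroc_se <- function(scores, y, w = rep(1, length(y)), auc = NULL) {
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]; w <- w[keep]
  if (is.null(auc)) auc <- weighted_auroc(scores, y, w)
  n1 <- sum(w[y == 1])^2 / sum(w[y == 1]^2)
  n0 <- sum(w[y == 0])^2 / sum(w[y == 0]^2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
    (n1 * n0)
  sqrt(max(v, 0))
}

#' Detection rate at a fixed false-positive rate
#'
#' The proportion of all cases detected when the score threshold is set so
#' that a fraction `fpr` of controls screen positive: the threshold is the
#' weighted (1 - fpr) quantile of the control scores (left-continuous
#' inverse of the weighted ECDF) and the detection rate is the weighted
#' proportion of cases strictly above it.
#'
#' @inheritParams weighted_auroc
#' @param fpr Target false-positive rate in (0, 1), e.g. 0.05 or 0.10.
#' @param conf_level Level for the Wilson score confidence interval
#'   (computed on the Kish effective number of cases).
#' @return A list with `dr`, `threshold`, `ci` (length-2) and `fpr`.
#' @export
detection_rate <- function(scores, y, w = rep(1, length(y)), fpr = 0.05,
                           conf_level = 0.95) {
  stopifnot(fpr > 0, fpr < 1)
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]; w <- w[keep]
  if (!any(y == 1) || !any(y == 0)) {
    stop("detection rate needs at least one case and one control")
  }
  thr <- weighted_quantile(scores[y == 0], w[y == 0], 1 - fpr)
  dr <- sum(w[y == 1] * (scores[y == 1] > thr)) / sum(w[y == 1])
  n_eff <- sum(w[y == 1])^2 / sum(w[y == 1]^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  centre <- (dr + z^2 / (2 * n_eff)) / (1 + z^2 / n_eff)
  half <- z * sqrt(dr * (1 - dr) / n_eff + z^2 / (4 * n_eff^2)) / (1 + z^2 / n_eff)
  list(dr = dr, threshold = thr, ci = c(max(0, centre - half), min(1, centre + half)),
       fpr = fpr)
}

#' Bootstrap comparison of two AUROCs on paired scores
#'
#' Resamples individuals with replacement, stratified by case status, and
#' recomputes both AUROCs in each replicate. Returns the observed
#' difference (`a - b`), the percentile confidence interval of the
#' difference and a two-sided p-value from the bootstrap normal
#' approximation. A replicate that degenerates to a single outcome class is
#' redrawn.
#'
#' @param score_a,score_b Paired scores on identical individuals.
#' @inheritParams weighted_auroc
#' @param B Number of bootstrap replicates (>= 100 recommended).
#' @param seed Integer seed.
#' @param conf_level Confidence level for the percentile interval.
#' @return List with `diff`, `ci`, `p`, `boot` (the replicate differences),
#'   `auc_a`, `auc_b`.
#' @export
bootstrap_auroc_diff <- function(score_a, score_b, y, w = rep(1, length(y)),
                                 B = 1000L, seed = 1L, conf_level = 0.95) {
  stopifnot(length(score_a) == length(y), length(score_b) == length(y))
  if (B < 100) warning("fewer than 100 bootstrap replicates; CI will be unstable")
  auc_a <- weighted_auroc(score_a, y, w)
  auc_b <- weighted_auroc(score_b, y, w)
  cases <- which(y == 1); ctrls <- which(y == 0)
  set.seed(seed)
  boot <- numeric(B)
  for (b in seq_len(B)) {
    idx <- c(sample(cases, length(cases), replace = TRUE),
             sample(ctrls, length(ctrls), replace = TRUE))
    boot[b] <- weighted_auroc(score_a[idx], y[idx], w[idx]) -
      weighted_auroc(score_b[idx], y[idx], w[idx])
  }
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 1))
  d <- auc_a - auc_b
  sd_b <- stats::sd(boot)
  p <- if (sd_b == 0) as.numeric(d != 0) else 2 * stats::pnorm(-abs(d) / sd_b)
  list(diff = d, ci = ci, p = p, boot = boot, auc_a = auc_a, auc_b = auc_b)
}

#' Fixed-effects (inverse-variance) meta-analysis
#'
#' Pools per-study estimates with weights `1/se^2`:
#' pooled = sum(theta/se^2)/sum(1/se^2), se = sqrt(1/sum(1/se^2)).
#'
#' @param estimates Per-study estimates.
#' @param ses Per-study standard errors (> 0).
#' @param conf_level Confidence level for the Wald interval.
#' @return List with `estimate`, `se`, `ci`.
#' @export
meta_fixed <- function(estimates, ses, conf_level = 0.95) {
  stopifnot(length(estimates) == length(ses))
  if (any(ses <= 0)) stop("all standard errors must be positive")
  wi <- 1 / ses^2
  est <- sum(wi * estimates) / sum(wi)
  se <- sqrt(1 / sum(wi))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = est, se = se, ci = c(est - z * se, est + z * se))
}

#' Random-effects (DerSimonian-Laird) meta-analysis
#'
#' Estimates the between-study variance tau^2 by the DerSimonian-Laird
#' moment estimator (truncated at zero), then pools with weights
#' `1/(se^2 + tau^2)`. With a single study, tau^2 is 0 and the result
#' equals the fixed-effects pool. The random-effects CI is never narrower
#' than the fixed-effects CI.
#'
#' @inheritParams meta_fixed
#' @return List with `estimate`, `se`, `ci`, `tau2`.
#' @export
meta_random <- function(estimates, ses, conf_level = 0.95) {
  stopifnot(length(estimates) == length(ses))
  if (any(ses <= 0)) stop("all standard errors must be positive")
  k <- length(estimates)
  wi <- 1 / ses^2
  fixed <- sum(wi * estimates) / sum(wi)
  if (k < 2) {
    tau2 <- 0
  } else {
    Q <- sum(wi * (estimates - fixed)^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(wi) - sum(wi^2) / sum(wi)))
  }
  wr <- 1 / (ses^2 + tau2)
  est <- sum(wr * estimates) / sum(wr)
  se <- sqrt(1 / sum(wr))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = est, se = se, ci = c(est - z * se, est + z * se), tau2 = tau2)
}

#' Per-study discrimination with meta-analytic pooling
#'
#' Computes AUROC (with Hanley-McNeil SE) and detection rates at the
#' requested false-positive rates separately within each study, then pools
#' the AUROCs across studies by both fixed- and random-effects
#' meta-analysis.
#'
#' @inheritParams weighted_auroc
#' @param study Study labels.
#' @param fpr Vector of false-positive rates for detection rates.
#' @return A list of class `discrimination_result`: `per_study`
#'   (`data.frame` of AUROC, SE, DRs), `pooled_fixed`, `pooled_random`
#'   (from [meta_fixed()] / [meta_random()]), and `detection` (`data.frame`
#'   of pooled-data detection rates with Wilson CIs).
#' @export
discrimination_by_study <- function(scores, y, w = rep(1, length(y)),
                                    study = rep("all", length(y)),
                                    fpr = c(0.05, 0.10)) {
  study <- as.character(study)
  per <- lapply(unique(study), function(s) {
    i <- study == s
    auc <- weighted_auroc(scores[i], y[i], w[i])
    row <- data.frame(study = s, n = sum(i),
                      events = sum(y[i] == 1),
                      auroc = auc,
                      se = auroc_se(scores[i], y[i], w[i], auc = auc),
                      stringsAsFactors = FALSE)
    for (f in fpr) {
      row[[sprintf("dr%g", 100 * f)]] <- detection_rate(scores[i], y[i], w[i], f)$dr
    }
    row
  })
  per <- do.call(rbind, per)
  pooled_f <- meta_fixed(per$auroc, per$se)
  pooled_r <- meta_random(per$auroc, per$se)
  det <- do.call(rbind, lapply(fpr, function(f) {
    d <- detection_rate(scores, y, w, f)
    data.frame(fpr = f, dr = d$dr, lo = d$ci[1], hi = d$ci[2])
  }))
  structure(list(per_study = per, pooled_fixed = pooled_f,
                 pooled_random = pooled_r, detection = det),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat("Per-study AUROC:\n")
  print(x$per_study, row.names = FALSE, digits = 3)
  cat(sprintf("Pooled AUROC (fixed):  %.3f (%.3f to %.3f)\n",
              x$pooled_fixed$estimate, x$pooled_fixed$ci[1], x$pooled_fixed$ci[2]))
  cat(sprintf("Pooled AUROC (random): %.3f (%.3f to %.3f), tau2 = %.4g\n",
              x$pooled_random$estimate, x$pooled_random$ci[1],
              x$pooled_random$ci[2], x$pooled_random$tau2))
  cat("Pooled-data detection rates:\n")
  print(x$detection, row.names = FALSE, digits = 3)
  invisible(x)
}
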