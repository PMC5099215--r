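#' Standardise a genetic risk score
#'
#' Centres and scales to mean 0, SD 1 over the analysis sample, so that the
#' logistic coefficient on the result is the log odds ratio per SD of the
#' score.
#'
#' @param grs Numeric scores; SD must be positive.
#' @return Standardised scores.
#' @export
standardize_grs <- function(grs) {
  s <- stats::sd(grs, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) stop("cannot standardise a constant score")
  (grs - mean(grs, na.rm = TRUE)) / s
}

#' Assign weighted quintile groups
#'
#' Groups by weighted quintile cut-points (left-continuous inverse of the
#' weighted ECDF); values tied with a cut-point go to the lower group.
#'
#' @param grs Numeric scores (n >= 5).
#' @param w Optional weights.
#' @param groups Number of groups (default 5).
#' @return Integer group index 1..`groups`.
#' @export
quintile_categorize <- function(grs, w = rep(1, length(grs)), groups = 5) {
  stopifnot(length(grs) >= groups)
  cuts <- unique(weighted_quantile(grs, w, seq_len(groups - 1) / groups))
  findInterval(grs, cuts, left.open = TRUE) + 1L
}

#' Logistic association of a score with events, with study fixed effects
#'
#' Fits a maximum-likelihood logistic regression of the event indicator on
#' the standardised score and on quintile indicators (lowest quintile as
#' reference), with study indicator covariates, on the combined data set.
#' Sampling weights enter as frequency weights, mirroring the control
#' upweighting of the nested case-control design. Studies in which only one
#' outcome class occurs are dropped with a message. Wald confidence
#' intervals are reported on the odds-ratio scale.
#'
#' @param y Event indicators in \{0, 1\}.
#' @param grs Genetic risk scores.
#' @param study Study labels (a single label means no study adjustment).
#' @param w Sampling weights used as frequency weights.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `association_result`: `or_per_sd` (list with
#'   `or`, `ci`, `p`), `quintile_or` (`data.frame` with OR = 1 reference
#'   row), and `meta` (n, events, studies used).
#' @export
logistic_fixed_effects <- function(y, grs, study = rep("all", length(y)),
                                   w = rep(1, length(y)), conf_level = 0.95) {
  stopifnot(length(y) == length(grs), length(study) == length(y))
  if (length(unique(y)) < 2) stop("outcome has a single class")
  study <- as.character(study)
  ok_study <- names(which(tapply(y, study, function(v) length(unique(v)) > 1)))
  dropped <- setdiff(unique(study), ok_study)
  if (length(dropped)) {
    message("dropping study(ies) with a single outcome class: ",
            paste(dropped, collapse = ", "))
  }
  keep <- study %in% ok_study
  y <- y[keep]; grs <- grs[keep]; study <- study[keep]; w <- w[keep]
  z <- standardize_grs(grs)
  dat <- data.frame(y = y, z = z, study = factor(study), w = w)
  form <- if (nlevels(dat$study) > 1) y ~ z + study else y ~ z
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = dat, weights = w))
  if (!fit$converged || abs(stats::coef(fit)["z"]) > 15) {
    stop("logistic fit did not converge (possible separation on the score)")
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- stats::coef(fit)["z"]; se <- sqrt(diag(stats::vcov(fit)))["z"]
  or_per_sd <- list(or = unname(exp(b)),
                    ci = unname(exp(c(b - zq * se, b + zq * se))),
                    p = unname(2 * stats::pnorm(-abs(b / se))))
  # quintile model
  dat$q <- factor(quintile_categorize(grs, w))
  formq <- if (nlevels(dat$study) > 1) y ~ q + study else y ~ q
  fitq <- suppressWarnings(stats::glm(formq, family = stats::binomial(),
                                      data = dat, weights = w))
  cq <- stats::coef(fitq); vq <- sqrt(diag(stats::vcov(fitq)))
  qn <- grep("^q", names(cq), value = TRUE)
  quint <- data.frame(
    quintile = c(1L, as.integer(sub("^q", "", qn))),
    or = c(1, exp(cq[qn])),
    lo = c(NA, exp(cq[qn] - zq * vq[qn])),
    hi = c(NA, exp(cq[qn] + zq * vq[qn])),
    row.names = NULL
  )
  structure(list(
    or_per_sd = or_per_sd,
    quintile_or = quint,
    meta = list(n = length(y), events = sum(y == 1),
                studies = length(ok_study), dropped = dropped)
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("OR per SD of the score: %.3f (%.3f to %.3f), p = %.3g\n",
              x$or_per_sd$or, x$or_per_sd$ci[1], x$or_per_sd$ci[2],
              x$or_per_sd$p))
  cat("Quintile ORs (reference = lowest):\n")
  print(x$quintile_or, row.names = FALSE, digits = 3)
  cat(sprintf("n = %d, events = %d, studies = %d\n",
              x$meta$n, x$meta$events, x$meta$studies))
  invisible(x)
}
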