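#' Simulation configuration for multi-study synthetic cohorts
#'
#' Describes a set of prospective studies with the statistical structure the
#' downstream evaluation assumes: Hardy-Weinberg genotypes at configurable
#' allele frequencies, a phenotypic 10-year risk score whose logit is
#' normally distributed within study, events generated from a logit-additive
#' model combining the phenotypic logit with a mean-centred genetic risk
#' score, per-study additive logit miscalibration, and nested case-control
#' subsampling of controls in a subset of studies.
#'
#' The defaults describe a seven-study UK-consortium-like design: study
#' sizes 2138, 1631, 1121, 632, 1184, 2330 and 2815 (total 11 851); 10-year
#' follow-up everywhere except study 5 (5 years, exercising the follow-up
#' rescaling rule); nested case-control sampling of controls at fraction 0.8
#' in studies 1, 2 and 5; mean phenotypic risks between 8% and 30%; and 53
#' SNPs with allele frequencies spread over (0.1, 0.9) whose weights are
#' scaled so that the population SD of the weighted score is log(1.09) —
#' i.e. one SD of the score multiplies the odds by about 1.09 under the
#' event model.
#'
#' @param n_studies Number of studies.
#' @param n_per_study Integer vector of per-study sample sizes.
#' @param allele_freqs Effect-allele frequencies, strictly inside (0, 1).
#' @param snp_weights Per-allele log odds ratios, one per SNP. The default
#'   is a fixed increasing pattern rescaled to `grs_sd_target`.
#' @param grs_sd_target Population SD of the weighted GRS used to scale the
#'   default `snp_weights`; ignored when `snp_weights` is supplied.
#' @param baseline_risk Per-study mean phenotypic 10-year risk probability.
#' @param baseline_logit_sd Per-study SD of the phenotypic logit.
#' @param calibration_offset Per-study additive logit miscalibration of the
#'   true event model relative to the phenotypic score (0 = calibrated).
#' @param followup_years Per-study follow-up, years.
#' @param age_mean,age_sd Per-study age distribution (years); ages define
#'   the 10-year age bands used as control-sampling strata.
#' @param casecontrol_studies Indices of studies using the nested
#'   case-control design.
#' @param control_sampling_fraction Probability that a control in a
#'   case-control study is retained; 1 means a full-cohort design.
#' @param seed Master seed; expanded into per-stage sub-streams.
#' @return A list of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_studies = 7,
                       n_per_study = c(2138L, 1631L, 1121L, 632L, 1184L, 2330L, 2815L),
                       allele_freqs = seq(0.1, 0.9, length.out = 53),
                       snp_weights = NULL,
                       grs_sd_target = log(1.09),
                       baseline_risk = c(0.084, 0.267, 0.181, 0.206, 0.302, 0.107, 0.082),
                       baseline_logit_sd = rep(1.0, n_studies),
                       calibration_offset = rep(0, n_studies),
                       followup_years = c(10, 10, 10, 10, 5, 10, 10),
                       age_mean = c(48.9, 70.7, 56.7, 64.2, 71.5, 53.0, 48.8),
                       age_sd = c(5.6, 5.3, 4.4, 5.7, 8.5, 0.5, 6.0),
                       casecontrol_studies = c(1L, 2L, 5L),
                       control_sampling_fraction = 0.8,
                       seed = 1L) {
  stopifnot(n_studies >= 1,
            length(n_per_study) == n_studies,
            length(baseline_risk) == n_studies,
            length(baseline_logit_sd) == n_studies,
            length(calibration_offset) == n_studies,
            length(followup_years) == n_studies,
            all(followup_years > 0),
            length(age_mean) == n_studies,
            length(age_sd) == n_studies)
  if (any(allele_freqs <= 0) || any(allele_freqs >= 1)) {
    stop("allele_freqs must lie strictly inside (0, 1)")
  }
  if (control_sampling_fraction <= 0 || control_sampling_fraction > 1) {
    stop("control_sampling_fraction must lie in (0, 1]")
  }
  check_prob_open(baseline_risk, "baseline_risk")
  if (is.null(snp_weights)) {
    # fixed increasing pattern, rescaled so sd(GRS) = grs_sd_target under HWE
    pattern <- seq(0.5, 1.5, length.out = length(allele_freqs))
    v <- sum(pattern^2 * 2 * allele_freqs * (1 - allele_freqs))
    snp_weights <- pattern * grs_sd_target / sqrt(v)
  }
  stopifnot(length(snp_weights) == length(allele_freqs),
            all(is.finite(snp_weights)))
  structure(list(
    n_studies = n_studies, n_per_study = as.integer(n_per_study),
    allele_freqs = allele_freqs, snp_weights = snp_weights,
    baseline_logit_mean = logit(baseline_risk),
    baseline_logit_sd = baseline_logit_sd,
    calibration_offset = calibration_offset,
    followup_years = followup_years,
    age_mean = age_mean, age_sd = age_sd,
    casecontrol_studies = as.integer(casecontrol_studies),
    control_sampling_fraction = control_sampling_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Each dosage is drawn independently as Binomial(2, p_j), the genotype
#' distribution implied by Hardy-Weinberg equilibrium at effect-allele
#' frequency p_j.
#'
#' @param freqs Effect-allele frequencies in \[0, 1\] (degenerate 0 / 1
#'   allowed, producing constant columns).
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param ids Optional individual ids (default `"ind1"...`).
#' @param rsids Optional SNP ids (default `"snp1"...`).
#' @return A [genotype_matrix()] with counted allele "A" and other allele
#'   "G" at every SNP (an unambiguous pair).
#' @export
simulate_genotypes <- function(freqs, n, seed = 1L, ids = NULL, rsids = NULL) {
  if (any(freqs < 0) || any(freqs > 1)) stop("allele frequencies must lie in [0, 1]")
  stopifnot(n >= 1)
  set.seed(seed)
  m <- vapply(freqs, function(p) stats::rbinom(n, 2L, p), numeric(n))
  m <- matrix(m, nrow = n)
  rownames(m) <- if (is.null(ids)) paste0("ind", seq_len(n)) else ids
  colnames(m) <- if (is.null(rsids)) paste0("snp", seq_along(freqs)) else rsids
  genotype_matrix(m,
                  counted_allele = rep("A", length(freqs)),
                  other_allele = rep("G", length(freqs)))
}

#' Simulate events from the logit-additive risk model
#'
#' The true 10-year risk of individual i is
#' `expit(logit(p_i) + (GRS_i - mean(GRS)) + offset_study)`, where `p_i` is
#' the phenotypic risk and the genetic score is mean-centred so that the
#' per-study `calibration_offset` alone controls marginal miscalibration.
#' Observed events are Bernoulli draws from that risk scaled linearly to
#' the observation window: if the cohort carries a `followup_years` column
#' shorter than the 10-year horizon, the event probability is
#' `true_risk * followup_years / 10`, so the study-level follow-up
#' rescaling rule applied downstream recovers the 10-year risk without
#' bias.
#'
#' @param cohort `data.frame` with columns `id`, `study` and `p_pheno`
#'   (phenotypic risk in (0, 1)).
#' @param genotypes A [genotype_matrix()] whose rows cover `cohort$id`.
#' @param config A [sim_config()] providing `snp_weights` and
#'   `calibration_offset`.
#' @param seed Integer seed.
#' @return `cohort` with columns `grs`, `true_risk` and event indicator `y`
#'   added.
#' @export
simulate_events <- function(cohort, genotypes, config, seed = 1L) {
  stopifnot(all(c("id", "study", "p_pheno") %in% names(cohort)))
  idx <- match(as.character(cohort$id), rownames(genotypes))
  if (anyNA(idx)) {
    stop(sprintf("no genotypes for individual '%s'",
                 as.character(cohort$id)[which(is.na(idx))[1L]]))
  }
  wtab <- data.frame(rsid = colnames(genotypes), weight = config$snp_weights)
  grs <- weighted_grs(genotypes, wtab)[idx]
  study_index <- match(cohort$study, unique(cohort$study))
  offset <- config$calibration_offset[study_index]
  true_risk <- expit(logit(cohort$p_pheno) + (grs - mean(grs)) + offset)
  window <- if (is.null(cohort$followup_years)) 1 else pmin(cohort$followup_years / 10, 1)
  set.seed(seed)
  cohort$grs <- grs
  cohort$true_risk <- true_risk
  cohort$y <- stats::rbinom(nrow(cohort), 1L, true_risk * window)
  cohort
}

#' Nested case-control subsampling with inverse-fraction control weights
#'
#' Retains every case with sampling weight 1; within each stratum, retains
#' controls independently with probability `fraction` and assigns retained
#' controls weight `1/fraction`, so weighted control totals are unbiased for
#' the full cohort. With `fraction = 1` the cohort is returned unchanged
#' with all weights 1 (full-cohort design). Sampling at 80%
#' (`fraction = 0.8`) gives every retained control weight 1.25 (= 100/80).
#'
#' @param cohort `data.frame` with event indicator column `y`.
#' @param fraction Control sampling fraction in (0, 1\].
#' @param strata Stratum labels, one per row (e.g. study x 10-year age
#'   band); a single value recycles.
#' @param seed Integer seed.
#' @return The sampled cohort with columns `stratum` and sampling weight
#'   `w` added.
#' @export
nested_case_control_sample <- function(cohort, fraction, strata = "all",
                                       seed = 1L) {
  if (fraction <= 0) stop("control sampling fraction must be positive (0 would retain no controls)")
  if (fraction > 1) stop("control sampling fraction cannot exceed 1")
  stopifnot("y" %in% names(cohort))
  strata <- rep_len(as.character(strata), nrow(cohort))
  cohort$stratum <- strata
  if (fraction == 1) {
    cohort$w <- 1
    return(cohort)
  }
  set.seed(seed)
  keep <- cohort$y == 1L
  for (s in unique(strata)) {
    ctrl <- which(cohort$y == 0L & strata == s)
    keep[ctrl] <- stats::runif(length(ctrl)) < fraction
  }
  out <- cohort[keep, , drop = FALSE]
  out$w <- ifelse(out$y == 1L, 1, 1 / fraction)
  rownames(out) <- NULL
  out
}

#' Simulate a complete multi-study cohort
#'
#' Runs the full generator: per-study ages and phenotypic risks, HWE
#' genotypes, events from the logit-additive model, and nested case-control
#' subsampling of controls (stratified by study x 10-year age band) in the
#' designated case-control studies. Every stage draws from a deterministic
#' sub-stream of `config$seed`, so any stage is reproducible in isolation.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`:
#'   \describe{
#'     \item{cohort}{`data.frame` with columns `id`, `study`, `age`,
#'       `p_pheno`, `grs`, `true_risk`, `y`, `followup_years`, `stratum`,
#'       `w`.}
#'     \item{genotypes}{[genotype_matrix()] for the *sampled* individuals.}
#'     \item{weights}{weights table (`rsid`, `effect_allele`,
#'       `other_allele`, `weight`) matching the generating model.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  studies <- paste0("study", seq_len(config$n_studies))
  parts <- vector("list", config$n_studies)
  geno_parts <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    n <- config$n_per_study[s]
    set.seed(substream_seed(config$seed, 10L * s))
    age <- stats::rnorm(n, config$age_mean[s], config$age_sd[s])
    lp <- stats::rnorm(n, config$baseline_logit_mean[s], config$baseline_logit_sd[s])
    ids <- sprintf("%s_%05d", studies[s], seq_len(n))
    base <- data.frame(id = ids, study = studies[s], age = age,
                       p_pheno = expit(lp),
                       followup_years = config$followup_years[s],
                       stringsAsFactors = FALSE)
    geno <- simulate_genotypes(config$allele_freqs, n,
                               seed = substream_seed(config$seed, 10L * s + 1L),
                               ids = ids)
    base <- simulate_events(base, geno, config,
                            seed = substream_seed(config$seed, 10L * s + 2L))
    strata <- paste0(studies[s], "_age", 10 * floor(base$age / 10))
    if (s %in% config$casecontrol_studies) {
      base <- nested_case_control_sample(base, config$control_sampling_fraction,
                                         strata = strata,
                                         seed = substream_seed(config$seed, 10L * s + 3L))
    } else {
      base$stratum <- strata
      base$w <- 1
    }
    parts[[s]] <- base
    geno_parts[[s]] <- unclass(geno)[match(base$id, rownames(geno)), , drop = FALSE]
  }
  cohort <- do.call(rbind, parts)
  rownames(cohort) <- NULL
  geno <- genotype_matrix(do.call(rbind, geno_parts),
                          counted_allele = rep("A", length(config$allele_freqs)),
                          other_allele = rep("G", length(config$allele_freqs)))
  weights <- data.frame(
    rsid = colnames(geno),
    effect_allele = "A", other_allele = "G",
    weight = config$snp_weights,
    stringsAsFactors = FALSE
  )
  structure(list(cohort = cohort, genotypes = geno, weights = weights,
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  co <- x$cohort
  cat(sprintf("sim_cohort: %d individuals in %d studies, %d SNPs\n",
              nrow(co), length(unique(co$study)), ncol(x$genotypes)))
  cat(sprintf("  events: %d (crude rate %.1f%%, weighted rate %.1f%%)\n",
              sum(co$y), 100 * mean(co$y),
              100 * sum(co$w * co$y) / sum(co$w)))
  invisible(x)
}
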