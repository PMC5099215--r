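#' Pipeline configuration
#'
#' Collects the analysis settings with their conventional defaults: risk
#' category cut-points 10% and 20%, detection rates at 5% and 10%
#' false-positive rates, a 10-year prediction horizon, a 20% relative risk
#' reduction from statin treatment, a population scale of 100 000, 1000
#' bootstrap replicates. Can be loaded from a YAML file; unknown keys are
#' rejected.
#'
#' @param thresholds Risk category cut-points.
#' @param fpr False-positive rates for detection rates.
#' @param horizon Prediction horizon, years.
#' @param rrr Relative risk reduction in the screening model.
#' @param scale Population scale for the screening model.
#' @param bootstrap_B Bootstrap replicates for the AUROC comparison.
#' @param seed Master seed.
#' @param centre Mean-centre the GRS before combining.
#' @param unweighted Use the unweighted (allele-count) score.
#' @param clip Clip boundary probabilities before the logit.
#' @return A list of class `run_config`.
#' @export
run_config <- function(thresholds = c(0.10, 0.20), fpr = c(0.05, 0.10),
                       horizon = 10, rrr = 0.20, scale = 100000,
                       bootstrap_B = 1000L, seed = 1L, centre = FALSE,
                       unweighted = FALSE, clip = FALSE) {
  structure(list(thresholds = thresholds, fpr = fpr, horizon = horizon,
                 rrr = rrr, scale = scale, bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed), centre = isTRUE(centre),
                 unweighted = isTRUE(unweighted), clip = isTRUE(clip)),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML configuration file.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full evaluation pipeline
#'
#' Orchestrates score construction, discrimination, calibration,
#' reclassification and the two-stage screening model on a cohort with
#' genotypes and a weights table, writing tidy CSV/JSON outputs when
#' `out_dir` is given. Inputs may be in-memory objects or file paths
#' (weights TSV, genotypes VCF/TSV, cohort CSV).
#'
#' @param weights Weights table or path (see [read_weights()]).
#' @param genotypes [genotype_matrix()] or path (see [read_genotypes()]).
#' @param cohort Cohort `data.frame` or CSV path (see [read_cohort()]).
#' @param config A [run_config()].
#' @param out_dir Optional output directory, created if needed.
#' @param assume_aligned Passed to [align_effect_alleles()] for allele-free
#'   dosage matrices.
#' @return A list of class `grs_report` with elements `scores`,
#'   `discrimination` (both scores), `auroc_comparison`, `calibration`
#'   (tables and Hosmer-Lemeshow for both scores), `reclassification`
#'   (pooled and per-study meta), `screening`, `association`, `config`.
#' @export
run_pipeline <- function(weights, genotypes, cohort, config = run_config(),
                         out_dir = NULL, assume_aligned = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(weights)) weights <- read_weights(weights)
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.null(cohort$w)) cohort$w <- 1
  if (is.null(cohort$followup_years)) cohort$followup_years <- config$horizon

  message("stage: score construction")
  idx <- match(as.character(cohort$id), rownames(genotypes))
  if (anyNA(idx)) stop(sprintf("no genotypes for individual '%s'",
                               cohort$id[which(is.na(idx))[1]]))
  ali <- align_effect_alleles(genotypes, weights, assume_aligned = assume_aligned)
  grs <- if (config$unweighted) {
    unweighted_grs(ali, study = NULL)[idx]
  } else {
    weighted_grs(ali, weights, study = NULL)[idx]
  }
  sc <- combine_with_phenotypic(cohort$p_pheno, grs, centre = config$centre,
                                clip = config$clip, id = cohort$id)

  message("stage: discrimination")
  disc_pheno <- discrimination_by_study(cohort$p_pheno, cohort$y, cohort$w,
                                        cohort$study, fpr = config$fpr)
  disc_comb <- discrimination_by_study(sc$combined_probability, cohort$y,
                                       cohort$w, cohort$study, fpr = config$fpr)
  cmp <- bootstrap_auroc_diff(sc$combined_probability, cohort$p_pheno,
                              cohort$y, cohort$w, B = config$bootstrap_B,
                              seed = config$seed)

  message("stage: calibration")
  cal <- lapply(list(phenotypic = cohort$p_pheno,
                     combined = sc$combined_probability), function(p) {
    tab <- decile_calibration(p, cohort$y, cohort$w,
                              followup_years = cohort$followup_years,
                              horizon = config$horizon)
    list(table = tab, hl = hosmer_lemeshow(tab))
  })

  message("stage: reclassification")
  pooled_tab <- cross_tabulate(cohort$p_pheno, sc$combined_probability,
                               cohort$y, cohort$w, config$thresholds)
  pooled_nri <- nri(pooled_tab)
  per_study <- lapply(split(seq_len(nrow(cohort)), cohort$study), function(i) {
    if (length(unique(cohort$y[i])) < 2) return(NULL)
    nri(cross_tabulate(cohort$p_pheno[i], sc$combined_probability[i],
                       cohort$y[i], cohort$w[i], config$thresholds))
  })
  per_study <- Filter(Negate(is.null), per_study)
  meta <- meta_nri(vapply(per_study, `[[`, numeric(1), "nri"),
                   vapply(per_study, `[[`, numeric(1), "se"))

  message("stage: screening model")
  flow <- two_stage_flow(cohort$p_pheno, sc$combined_probability, cohort$y,
                         cohort$w, band = config$thresholds[1:2],
                         high = config$thresholds[2], scale = config$scale,
                         rrr = config$rrr,
                         followup_years = cohort$followup_years,
                         horizon = config$horizon)

  message("stage: association")
  assoc <- logistic_fixed_effects(cohort$y, grs, cohort$study, cohort$w)

  report <- structure(list(
    scores = sc,
    discrimination = list(phenotypic = disc_pheno, combined = disc_comb),
    auroc_comparison = cmp[c("diff", "ci", "p", "auc_a", "auc_b")],
    calibration = cal,
    reclassification = list(table = pooled_tab, pooled = pooled_nri,
                            per_study = per_study, meta = meta),
    screening = flow,
    association = assoc,
    config = config
  ), class = "grs_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sc, file.path(out_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(disc_comb$per_study,
                     file.path(out_dir, "discrimination_per_study.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cal$combined$table),
                     file.path(out_dir, "calibration_deciles.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      config = unclass(config),
      auroc = list(phenotypic = disc_pheno$pooled_fixed$estimate,
                   combined = disc_comb$pooled_fixed$estimate,
                   difference = cmp$diff, ci = cmp$ci, p = cmp$p),
      hosmer_lemeshow = lapply(cal, function(x) x$hl),
      nri = pooled_nri, nri_meta = meta,
      screening = flow_report(flow)$summary,
      or_per_sd = assoc$or_per_sd
    ), file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
    writeLines(flow_report(flow)$text, file.path(out_dir, "screening_flow.txt"))
  }
  report
}

#' @export
print.grs_report <- function(x, ...) {
  cat(sprintf("Combined-score AUROC (fixed-effects pooled): %.3f; phenotypic: %.3f\n",
              x$discrimination$combined$pooled_fixed$estimate,
              x$discrimination$phenotypic$pooled_fixed$estimate))
  cat(sprintf("AUROC difference (combined - phenotypic): %+.4f (%.4f to %.4f), p = %.2g\n",
              x$auroc_comparison$diff, x$auroc_comparison$ci[1],
              x$auroc_comparison$ci[2], x$auroc_comparison$p))
  cat(sprintf("Hosmer-Lemeshow: phenotypic chi2_%d = %.1f; combined chi2_%d = %.1f\n",
              x$calibration$phenotypic$hl$df, x$calibration$phenotypic$hl$chi2,
              x$calibration$combined$hl$df, x$calibration$combined$hl$chi2))
  cat(sprintf("NRI (pooled): %.2f%%; meta-analysed: %.2f%%\n",
              100 * x$reclassification$pooled$nri,
              100 * x$reclassification$meta$estimate))
  print(x$screening)
  invisible(x)
}
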