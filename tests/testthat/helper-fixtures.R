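# shared fixture builders and independent oracles

# brute-force O(n_case * n_ctrl) weighted pair-counting AUROC
pair_count_auroc <- function(scores, y, w = rep(1, length(y))) {
  ci <- which(y == 1); cj <- which(y == 0)
  num <- 0
  for (i in ci) for (j in cj) {
    num <- num + w[i] * w[j] *
      ((scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j]))
  }
  num / (sum(w[ci]) * sum(w[cj]))
}

# small genotype matrix with explicit alleles
toy_genotypes <- function(dosages, counted, other) {
  genotype_matrix(dosages, counted_allele = counted, other_allele = other)
}

# tiny well-formed cohort for io / pipeline smoke tests
small_sim <- function(seed = 42, n = c(400, 300, 300)) {
  simulate_cohort(sim_config(
    n_studies = 3, n_per_study = n,
    allele_freqs = seq(0.2, 0.8, length.out = 10),
    baseline_risk = c(0.10, 0.20, 0.15),
    baseline_logit_sd = rep(1, 3),
    calibration_offset = rep(0, 3),
    followup_years = c(10, 10, 5),
    age_mean = c(50, 60, 65), age_sd = c(5, 5, 5),
    casecontrol_studies = 2L,
    control_sampling_fraction = 0.8,
    seed = seed
  ))
}

published_reclass_counts <- function() {
  read.csv(system.file("extdata", "published_reclassification_counts.csv",
                       package = "grseval"))
}

published_flow <- function() {
  read.csv(system.file("extdata", "published_screening_flow.csv",
                       package = "grseval"))
}
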