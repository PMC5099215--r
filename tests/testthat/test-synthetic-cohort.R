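test_that("degenerate allele frequencies give constant dosages", {
  g <- simulate_genotypes(c(0, 1), n = 25, seed = 1)
  expect_true(all(g[, 1] == 0))
  expect_true(all(g[, 2] == 2))
  expect_error(simulate_genotypes(c(0.5, 1.2), 10), "frequencies")
})

test_that("simulated genotypes recover the configured frequency under HWE", {
  n <- 10000
  g <- simulate_genotypes(0.3, n = n, seed = 5)
  se <- sqrt(2 * 0.3 * 0.7 / n)
  expect_lt(abs(mean(g[, 1]) - 0.6), 3 * se)
  # HWE chi-square on genotype counts vs binomial(2, p-hat) expectation
  obs <- tabulate(g[, 1] + 1, nbins = 3)
  phat <- mean(g[, 1]) / 2
  exp_cnt <- n * c((1 - phat)^2, 2 * phat * (1 - phat), phat^2)
  chi2 <- sum((obs - exp_cnt)^2 / exp_cnt)
  expect_gt(pchisq(chi2, df = 1, lower.tail = FALSE), 0.001)
})

test_that("null gene score leaves the event rate at the phenotypic mean", {
  n <- 20000
  cfg <- sim_config(n_studies = 1, n_per_study = n,
                    allele_freqs = rep(0.5, 5), snp_weights = rep(0, 5),
                    baseline_risk = 0.15, baseline_logit_sd = 1,
                    calibration_offset = 0, followup_years = 10,
                    age_mean = 55, age_sd = 5, casecontrol_studies = integer(0))
  set.seed(2)
  p <- expit(rnorm(n, logit(0.15), 1))
  cohort <- data.frame(id = as.character(1:n), study = "s1", p_pheno = p)
  geno <- simulate_genotypes(cfg$allele_freqs, n, seed = 3,
                             ids = cohort$id)
  out <- simulate_events(cohort, geno, cfg, seed = 4)
  mc_se <- sqrt(mean(p * (1 - p)) / n)
  expect_lt(abs(mean(out$y) - mean(p)), 4 * mc_se)
})

test_that("a huge positive calibration offset saturates events", {
  cfg <- sim_config(n_studies = 1, n_per_study = 100,
                    allele_freqs = 0.5, snp_weights = 0,
                    baseline_risk = 0.1, baseline_logit_sd = 1,
                    calibration_offset = 50, followup_years = 10,
                    age_mean = 55, age_sd = 5, casecontrol_studies = integer(0))
  cohort <- data.frame(id = as.character(1:100), study = "s1",
                       p_pheno = runif(100, 0.05, 0.2))
  geno <- simulate_genotypes(0.5, 100, seed = 1, ids = cohort$id)
  out <- simulate_events(cohort, geno, cfg, seed = 1)
  expect_true(all(out$y == 1))
})

test_that("event rate increases across dosage groups for a strong SNP", {
  n <- 50000
  cfg <- sim_config(n_studies = 1, n_per_study = n,
                    allele_freqs = 0.5, snp_weights = 1.5,
                    baseline_risk = 0.15, baseline_logit_sd = 0.5,
                    calibration_offset = 0, followup_years = 10,
                    age_mean = 55, age_sd = 5, casecontrol_studies = integer(0))
  set.seed(9)
  cohort <- data.frame(id = as.character(1:n), study = "s1",
                       p_pheno = expit(rnorm(n, logit(0.15), 0.5)))
  geno <- simulate_genotypes(0.5, n, seed = 10, ids = cohort$id)
  out <- simulate_events(cohort, geno, cfg, seed = 11)
  rates <- tapply(out$y, unclass(geno)[, 1], mean)
  expect_true(all(diff(rates[c("0", "1", "2")]) > 0))
})

test_that("misaligned ids fail naming the first missing individual", {
  cfg <- sim_config(n_studies = 1, n_per_study = 5, allele_freqs = 0.5,
                    snp_weights = 0.1, baseline_risk = 0.1,
                    baseline_logit_sd = 1, calibration_offset = 0,
                    followup_years = 10, age_mean = 55, age_sd = 5,
                    casecontrol_studies = integer(0))
  cohort <- data.frame(id = c("a", "b", "zz"), study = "s1",
                       p_pheno = c(0.1, 0.2, 0.3))
  geno <- simulate_genotypes(0.5, 2, seed = 1, ids = c("a", "b"))
  expect_error(simulate_events(cohort, geno, cfg), "zz")
})

test_that("nested case-control weighting follows the inverse sampling fraction", {
  co <- data.frame(id = 1:50, y = rep(c(1, 0), c(10, 40)))
  s <- nested_case_control_sample(co, 0.8, seed = 3)
  expect_true(all(s$w[s$y == 1] == 1))
  expect_true(all(s$w[s$y == 0] == 1.25))
  # full sampling leaves the cohort unchanged with unit weights
  full <- nested_case_control_sample(co, 1, seed = 3)
  expect_equal(nrow(full), nrow(co))
  expect_true(all(full$w == 1))
  expect_error(nested_case_control_sample(co, 0), "positive")
})

test_that("weighted control totals are unbiased for the full cohort", {
  n_ctrl <- 20000
  co <- data.frame(id = seq_len(n_ctrl + 500),
                   y = rep(c(1, 0), c(500, n_ctrl)))
  s <- nested_case_control_sample(co, 0.5, seed = 8)
  wtot <- sum(s$w[s$y == 0])
  se <- sqrt(n_ctrl * 0.5 * 0.5) / 0.5   # sd of (kept count)/fraction
  expect_lt(abs(wtot - n_ctrl), 3 * se)
})

test_that("weighted event rate is conserved under subsampling", {
  sim <- small_sim(seed = 21)
  co <- sim$cohort
  w_rate <- sum(co$w * co$y) / sum(co$w)
  crude_rate <- mean(co$y)
  # upweighting pulls the weighted rate below the crude rate of the sample
  expect_lt(w_rate, crude_rate)
  # and repetition over seeds keeps the weighted rate near the design rate
  rates <- vapply(1:5, function(s) {
    x <- small_sim(seed = 100 + s)$cohort
    sum(x$w * x$y) / sum(x$w)
  }, numeric(1))
  expect_lt(diff(range(rates)), 0.04)
})

test_that("the full generator is reproducible and well-formed", {
  a <- small_sim(seed = 5)
  b <- small_sim(seed = 5)
  expect_identical(a$cohort, b$cohort)
  expect_identical(unclass(a$genotypes), unclass(b$genotypes))
  co <- a$cohort
  expect_true(all(co$p_pheno > 0 & co$p_pheno < 1))
  expect_true(all(co$y %in% 0:1))
  expect_true(all(co$w[co$y == 1] == 1))
  expect_true(all(co$w[co$y == 0 & co$study == "study2"] == 1.25))
  expect_true(all(co$w[co$study != "study2"] == 1))
  # allele-frequency recovery within binomial error
  freqs <- colMeans(unclass(a$genotypes)[co$study != "study2", ]) / 2
  cfg_f <- a$config$allele_freqs
  n_full <- sum(co$study != "study2")
  expect_true(all(abs(freqs - cfg_f) < 4 * sqrt(cfg_f * (1 - cfg_f) / (2 * n_full))))
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(allele_freqs = c(0.5, 1)), "strictly inside")
  expect_error(sim_config(control_sampling_fraction = 0), "\\(0, 1\\]")
  expect_error(sim_config(control_sampling_fraction = 1.2), "\\(0, 1\\]")
})
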