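---
title: "Methods: evaluating a genetic risk score added to a phenotypic cardiovascular risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating a genetic risk score added to a phenotypic cardiovascular risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grseval)
```

## The problem

Phenotype-based 10-year cardiovascular risk equations (QRISK-2 and its
relatives) drive statin prescribing decisions at conventional cut-points of
10% and 20% predicted risk. Genome-wide association studies supply dozens of
common variants reliably associated with coronary disease and stroke, and a
natural question is whether a polygenic score built from them sharpens those
decisions — either population-wide, or selectively for people the phenotypic
score places in the intermediate band (10% to <20%), where treatment
decisions are most contested.

`grseval` implements the full evaluation chain for that question on
multi-study prospective data: score construction, discrimination,
calibration, reclassification, meta-analytic pooling across studies, and a
two-stage screening model with number needed to screen. Because consortium
individual-level data cannot be redistributed, the package also ships a
synthetic cohort generator with the same statistical structure, so that
every stage is exercised end to end by code anyone can run.

## Score construction

Each SNP $j$ carries a published per-allele log odds ratio $\beta_j$ and an
effect allele. With effect-allele dosages $g_{ij} \in [0, 2]$, the weighted
genetic risk score is

$$\mathrm{GRS}_i = \sum_j \beta_j\, g_{ij},$$

and the unweighted variant is the plain risk-allele count ($\beta_j \equiv
1$), offered as a sensitivity analysis against winner's-curse inflation of
the published coefficients. The combined score adds the GRS to the
phenotypic score on the log-odds scale:

$$\mathrm{logit}(p^{\text{comb}}_i) = \mathrm{logit}(p^{\text{pheno}}_i) + \mathrm{GRS}_i,$$

mapped back to a probability with the inverse logit.

**Allele harmonisation.** Dosages counted on the opposite allele are flipped
($g \mapsto 2 - g$). Strand-ambiguous SNPs (A/T or C/G pairs) cannot be
oriented from allele labels and are rejected unless explicitly allowed.
Missing dosages are imputed as the mean dosage (twice the estimated
effect-allele frequency) among non-missing individuals, within study when
study labels are available — the standard mean-dosage rule.

**Centring.** Whether the GRS should be mean-centred before addition is a
genuinely open design choice. Published log odds ratios are positive almost
everywhere, so the raw GRS has a substantial positive mean (on the order of
1 logit for a 53-SNP score); adding it uncentred shifts every combined
probability upward and degrades marginal calibration, while centring
preserves the phenotypic score's average logit. Both options are exposed
(`centre` argument); the default leaves the score uncentred, the form in
which external weights are usually added. Centring cannot change any
rank-based quantity: centred and uncentred combined scores give identical
orderings and therefore identical AUROC and detection rates. For
simulation-based evaluation in this package we use `centre = TRUE`, because
the generator's event model is itself defined with a mean-centred GRS (see
below), and the uncentred shift would otherwise swamp reclassification with
a constant offset that carries no information.

Treated blood pressures are adjusted upward (+15 mm Hg systolic, +10 mm Hg
diastolic) to approximate untreated values before any phenotypic equation is
applied; the package provides this adjustment as a small preprocessing
helper.

## The synthetic cohort generator

The generator emulates a UK-consortium-like design of seven prospective
studies. Its defaults are fixed study conditions, chosen once:

* **Study sizes** 2138, 1631, 1121, 632, 1184, 2330, 2815 (total 11 851) —
  the scale of the motivating consortium.
* **Phenotypic score**: within study $s$, $\mathrm{logit}(p^{\text{pheno}})
  \sim N(\mu_s, 1)$ with $\mathrm{expit}(\mu_s)$ set to per-study mean
  predicted risks between 8% and 30%. An SD of 1 logit gives the realistic
  wide spread of predicted risk in middle-aged UK cohorts.
* **Genotypes**: 53 independent SNPs in Hardy-Weinberg equilibrium, dosages
  $\sim \mathrm{Binomial}(2, p_j)$ with frequencies spread evenly over
  (0.1, 0.9).
* **Weights**: a fixed increasing pattern rescaled so the population SD of
  the GRS is $\log 1.09$. Under the event model below the log odds ratio
  per SD of the GRS is then 0.09 — the scale of effect reported for 53-SNP
  cardiovascular scores, and small relative to the phenotypic score.
* **Event model**: true 10-year risk
  $r_i = \mathrm{expit}(\mathrm{logit}(p^{\text{pheno}}_i) +
  (\mathrm{GRS}_i - \overline{\mathrm{GRS}}) + \delta_s)$. The GRS is
  mean-centred *inside* the event model so that the per-study offset
  $\delta_s$ alone controls marginal miscalibration; with $\delta_s = 0$ the
  phenotypic score is calibrated by construction and the genetic score adds
  only within-decile dispersion.
* **Follow-up**: 10 years everywhere except study 5 (5 years). Observed
  events are drawn with probability $r_i \times \text{follow-up}/10$, the
  linear-rate approximation, so the downstream study-level doubling rule
  recovers the 10-year risk without bias and the rescaling code path is
  genuinely exercised.
* **Nested case-control subsampling**: studies 1, 2 and 5 retain all cases
  and sample controls at fraction 0.8 within study × 10-year age band;
  retained controls get weight $1/0.8 = 1.25$. The 10-year band is the
  natural reading of sampling "within an age group"; the fraction is a free
  parameter because real per-study fractions are not public.
* **Seeding**: one master seed expands into deterministic per-study,
  per-stage sub-streams (`substream_seed`), so any stage can be reproduced
  in isolation; all derived seeds stay below $2^{31}$.

What the generator deliberately does **not** emulate: linkage
disequilibrium between SNPs, genotyping or imputation error, ancestry
structure, non-proportional event hazards, or competing risks. Passing
tests on this generator therefore demonstrate correctness of the
*estimators* under the assumed structure, not the field performance of any
particular score on real data.

## Discrimination

The AUROC is computed as the sampling-weighted Mann-Whitney probability
that a random case outscores a random control, ties counted half:

$$\hat A = \frac{\sum_{i \in \text{cases}}\sum_{j \in \text{controls}}
w_i w_j\left[\mathbb 1(s_i > s_j) + \tfrac12 \mathbb 1(s_i = s_j)\right]}
{\left(\sum_{\text{cases}} w_i\right)\left(\sum_{\text{controls}} w_j\right)},$$

evaluated in $O(n \log n)$ by accumulating control weight over the sorted
unique scores; the result equals the exhaustive pair count exactly (this is
asserted against a brute-force oracle in the tests). The standard error
uses the Hanley-McNeil formula with Kish effective sample sizes
$(\sum w)^2/\sum w^2$ in place of raw counts, so that upweighted controls
are not treated as independent observations; for unweighted data the
DeLong-style variance from standard ROC software agrees and is used as a
cross-check in the test suite.

The detection rate DR$_\alpha$ is the weighted proportion of cases strictly
above the weighted $(1-\alpha)$ quantile of the control scores. All
weighted quantiles in the package use the left-continuous inverse of the
weighted empirical CDF (the weighted analogue of `quantile(type = 1)`);
ties at the threshold count as *not* detected. Detection-rate confidence
intervals are Wilson intervals on the effective number of cases — whether
a binomial or bootstrap interval is the "right" choice is not settled, and
Wilson is the conservative, closed-form default.

Per-study AUROCs are pooled by inverse-variance fixed-effects and
DerSimonian-Laird random-effects meta-analysis (both implemented directly;
the test suite cross-checks against `metafor`). Differences between two
scores are assessed per study by stratified bootstrap (cases and controls
resampled separately; default 1000 replicates), with a percentile CI and a
normal-approximation p-value.

## Calibration

Predicted risks are binned into tenths of the (pooled) predicted-risk
distribution at weighted quantile edges. Observed event proportions are
compared with mean predicted risk per bin, after study-level follow-up
rescaling: a study followed $t < 10$ years has its observed events
multiplied by $10/t$ (the 5-year study is doubled). Pooled rather than
per-study deciles match the single calibration curve such analyses
present.

The Hosmer-Lemeshow statistic is

$$\chi^2 = \sum_b \frac{(O_b - E_b)^2}{E_b\,(1 - E_b/n_b)},
\qquad \mathrm{df} = \text{bins} - 2,$$

with weights entering both $O$ and $E$ — the consistent choice under the
weighted design. Two numerical points deserve note. First, the
$\text{bins}-2$ degrees of freedom follow the grouped-prediction
convention for models fitted to the same data; when the predicted
probabilities are *known* (taken as external inputs rather than refitted),
the null mean of the statistic is close to the number of bins, not
$\text{bins}-2$. The package's null-distribution test therefore refits an
intercept-and-slope logistic model per replicate — the setting in which
the $\chi^2_{\text{bins}-2}$ reference applies — rather than asserting a
false null for known probabilities. Second, massive ties that would empty
a bin cause adjacent bins to merge (duplicate quantile edges collapse);
the merge is recorded on the returned table, and a constant prediction
degenerates to a single bin.

## Reclassification

Risk categories are half-open, lower-inclusive intervals: with cut-points
(0.10, 0.20), the categories are $[0, 0.10)$, $[0.10, 0.20)$ and
$[0.20, 1]$ — a predicted risk of exactly 20% is high risk. Any upward
category move counts as "up" regardless of distance. With weighted counts
$u_e, d_e$ (events moved up/down of $N_e$) and $u_n, d_n$ (non-events of
$N_n$):

$$\mathrm{NRI} = \frac{u_e - d_e}{N_e} + \frac{d_n - u_n}{N_n},$$

with the first-order multinomial (Pencina-type) variance

$$\mathrm{SE}^2 = \frac{u_e + d_e}{N_e^2} - \frac{(u_e-d_e)^2}{N_e^3}
 + \frac{u_n + d_n}{N_n^2} - \frac{(d_n-u_n)^2}{N_n^3},$$

applied to the *weighted* counts, Wald CI, two-sided normal p-value.
Per-study NRIs are combined by fixed-effects meta-analysis; on homogeneous
simulated studies the pooled-data and meta-analysed NRIs agree closely, as
expected.

## The two-stage screening model

Individuals whose phenotypic risk falls in $[0.10, 0.20)$ receive the
genetic score; those whose combined risk reaches 0.20 are reclassified
high risk and assumed treated with statins at a relative risk reduction of
0.20. Weighted proportions are scaled to a population of 100 000.
Expected 10-year events among the reclassified-high use observed events
with the same follow-up rescaling rule as calibration.

Events prevented are kept fractional internally
($\mathrm{RRR} \times \text{expected events}$); the *displayed* count
truncates to an integer, while the number needed to screen divides the
population scale by the fractional value and truncates:

$$\mathrm{NNS} = \left\lfloor \frac{\text{scale}}{\mathrm{RRR} \times
\text{expected events}} \right\rfloor.$$

This is the only rounding convention under which a flow with 1082 expected
events at scale 100 000 and a 20% risk reduction displays both "216 events
prevented" ($\lfloor 216.4 \rfloor$) and "NNS 462"
($\lfloor 100000/216.4 \rfloor = \lfloor 462.1 \rfloor$) simultaneously.
Flow conservation (high + low + remaining = intermediate) is enforced at
construction and re-asserted when a flow is rendered.

## Association

The log odds ratio per SD of the GRS and per-quintile odds ratios (lowest
quintile as reference) come from maximum-likelihood logistic regression —
iteratively reweighted least squares as implemented in `stats::glm` — on
the combined data with study indicator covariates. Sampling weights enter
as frequency weights, mirroring the control-upweighting scheme; studies
with a single outcome class are dropped with a message. Quintile
cut-points use the same weighted left-continuous quantile as everywhere
else, ties going to the lower group.

## Problem sizes and tolerances

The package's statistical tests run at sizes chosen to make Monte-Carlo
error small relative to the assertion: oracle-equivalence checks on
fixtures of up to 50 individuals (where exhaustive enumeration is exact);
null detection-rate and association checks at 20 000; parameter recovery
at 100 000; calibration null behaviour over 200 replicates of 1500. Null
hypothesis checks use 3–4 standard-error bands; closed-form comparisons
use machine-precision tolerances. The default simulated cohort (11 851
before subsampling) evaluates end to end in a few seconds.

## Known limitations

* The phenotypic risk equation itself is consumed as an input probability;
  the package neither implements nor validates it.
* Calibration is binomial, not survival-based: follow-up rescaling is a
  linear-rate approximation applied at the study level, and censoring
  within a study is not modelled.
* The NRI's known sensitivity to miscalibration and category placement is
  inherited, not corrected; category-free NRI and integrated discrimination
  improvement are out of scope.
* The bootstrap for AUROC differences resamples individuals within study
  and outcome stratum; it does not propagate uncertainty in the published
  SNP weights.
* Simulated genotypes are independent across SNPs; scores built on
  correlated panels will show different small-sample behaviour.
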