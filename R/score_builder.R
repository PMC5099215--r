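#' Construct a genotype matrix
#'
#' Bundles an individuals-by-SNPs dosage matrix with per-SNP allele
#' annotation. Dosages count copies of the *counted allele* and must lie in
#' \[0, 2\] (fractional values are allowed for imputed data). Missing dosages
#' stay `NA`; they are never silently zeroed.
#'
#' @param dosages Numeric matrix, rows = individuals, columns = SNPs.
#'   Row names are individual ids, column names are SNP ids (rsids).
#' @param counted_allele,other_allele Character vectors, one entry per SNP:
#'   the allele whose copies the dosage counts, and the alternative allele.
#'   May be `NA` when the source format carries no allele annotation, in
#'   which case [align_effect_alleles()] will require `assume_aligned`.
#' @return An object of class `genotype_matrix`: the dosage matrix with a
#'   `snp_info` attribute (`data.frame` with columns `rsid`,
#'   `counted_allele`, `other_allele`).
#' @seealso [align_effect_alleles()], [weighted_grs()]
#' @export
genotype_matrix <- function(dosages,
                            counted_allele = rep(NA_character_, ncol(dosages)),
                            other_allele = rep(NA_character_, ncol(dosages))) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(colnames(dosages))) stop("dosage matrix must have SNP ids as column names")
  if (is.null(rownames(dosages))) rownames(dosages) <- as.character(seq_len(nrow(dosages)))
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2]")
  }
  stopifnot(length(counted_allele) == ncol(dosages),
            length(other_allele) == ncol(dosages))
  attr(dosages, "snp_info") <- data.frame(
    rsid = colnames(dosages),
    counted_allele = toupper(as.character(counted_allele)),
    other_allele = toupper(as.character(other_allele)),
    stringsAsFactors = FALSE
  )
  class(dosages) <- c("genotype_matrix", class(dosages))
  dosages
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Per-SNP allele annotation of a genotype matrix
#' @param g A `genotype_matrix`.
#' @return `data.frame` with columns `rsid`, `counted_allele`, `other_allele`.
#' @export
snp_info <- function(g) attr(g, "snp_info")

#' Harmonise genotype dosages with a weights table
#'
#' Re-expresses dosages as counts of each SNP's *effect allele* as defined by
#' the weights table. SNPs whose counted allele equals the effect allele pass
#' through; SNPs counted on the other allele are flipped (`g -> 2 - g`).
#' Strand-ambiguous SNPs (allele pair A/T or C/G) cannot be oriented from
#' allele labels alone and raise an error unless `allow_ambiguous = TRUE`.
#'
#' @param g A [genotype_matrix()] with allele annotation.
#' @param weights A weights table as returned by [read_weights()] (columns
#'   `rsid`, `effect_allele`, `other_allele`, `weight`).
#' @param allow_ambiguous Keep strand-ambiguous SNPs, trusting that the data
#'   are on the same strand as the weights. Default `FALSE`.
#' @param assume_aligned Treat SNPs without allele annotation as already
#'   counted on the effect allele. Default `FALSE`.
#' @return A `genotype_matrix` restricted to the weighted SNPs, in the order
#'   of the weights table, with an `alignment` attribute: a `data.frame`
#'   listing each SNP's status (`matched`, `flipped`, `missing`,
#'   `ambiguous`).
#' @export
align_effect_alleles <- function(g, weights, allow_ambiguous = FALSE,
                                 assume_aligned = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  info <- snp_info(g)
  idx <- match(weights$rsid, info$rsid)
  status <- character(nrow(weights))
  out <- matrix(NA_real_, nrow = nrow(g), ncol = nrow(weights),
                dimnames = list(rownames(g), weights$rsid))
  for (j in seq_len(nrow(weights))) {
    k <- idx[j]
    if (is.na(k)) { status[j] <- "missing"; next }
    ca <- info$counted_allele[k]
    ea <- toupper(weights$effect_allele[j])
    oa <- toupper(weights$other_allele[j])
    pair <- sort(c(ea, oa))
    ambiguous <- identical(pair, c("A", "T")) || identical(pair, c("C", "G"))
    if (is.na(ca)) {
      if (!assume_aligned) {
        stop(sprintf("SNP %s has no allele annotation; set assume_aligned = TRUE to accept dosages as effect-allele counts",
                     weights$rsid[j]))
      }
      status[j] <- "matched"
      out[, j] <- g[, k]
    } else if (ambiguous && !allow_ambiguous) {
      stop(sprintf("SNP %s has a strand-ambiguous allele pair (%s/%s); set allow_ambiguous = TRUE to keep it",
                   weights$rsid[j], ea, oa))
    } else if (ca == ea) {
      status[j] <- "matched"
      out[, j] <- g[, k]
    } else if (ca == oa) {
      status[j] <- "flipped"
      out[, j] <- 2 - g[, k]
    } else {
      stop(sprintf("SNP %s: counted allele %s matches neither effect allele %s nor other allele %s",
                   weights$rsid[j], ca, ea, oa))
    }
  }
  res <- genotype_matrix(out,
                         counted_allele = toupper(weights$effect_allele),
                         other_allele = toupper(weights$other_allele))
  attr(res, "alignment") <- data.frame(rsid = weights$rsid, status = status,
                                       stringsAsFactors = FALSE)
  res
}

#' Weighted and unweighted genetic risk scores
#'
#' `weighted_grs()` computes, for each individual, the sum over SNPs of the
#' per-allele log odds ratio times the effect-allele dosage
#' (`GRS_i = sum_j beta_j g_ij`). `unweighted_grs()` is the risk-allele
#' count, i.e. the same sum with all weights equal to 1.
#'
#' Missing dosages are, by default, imputed as twice the effect-allele
#' frequency estimated from non-missing individuals (within study when
#' `study` is supplied, otherwise pooled) — standard mean-dosage imputation.
#' With `impute_missing = FALSE` an individual missing any weighted SNP gets
#' an `NA` score. Individuals missing every SNP always get `NA`.
#'
#' @param g A [genotype_matrix()] already aligned to the effect alleles
#'   (see [align_effect_alleles()]).
#' @param weights Weights table with columns `rsid` and `weight`; must cover
#'   the columns of `g` in order.
#' @param impute_missing Impute missing dosages by the mean dosage rule.
#' @param study Optional study labels (length = individuals) for
#'   within-study imputation.
#' @return Named numeric vector of scores, one per individual.
#' @export
weighted_grs <- function(g, weights, impute_missing = TRUE, study = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  w <- weights$weight[match(colnames(g), weights$rsid)]
  if (anyNA(w)) {
    stop(sprintf("no weight for SNP(s): %s",
                 paste(colnames(g)[is.na(w)], collapse = ", ")))
  }
  stopifnot(all(is.finite(w)))
  m <- unclass(g)
  attr(m, "snp_info") <- NULL
  attr(m, "alignment") <- NULL
  all_missing <- rowSums(!is.na(m)) == 0L
  if (any(all_missing)) {
    warning(sprintf("%d individual(s) missing all dosages; GRS set to NA",
                    sum(all_missing)))
  }
  if (impute_missing && anyNA(m)) {
    groups <- if (is.null(study)) rep("all", nrow(m)) else as.character(study)
    for (gr in unique(groups)) {
      rows <- groups == gr
      mm <- m[rows, , drop = FALSE]
      miss <- is.na(mm)
      if (any(miss)) {
        colmean <- colMeans(mm, na.rm = TRUE)  # mean dosage = 2 * allele freq
        colmean[is.nan(colmean)] <- NA_real_
        mm[miss] <- rep(colmean, each = nrow(mm))[miss]
        m[rows, ] <- mm
      }
    }
  }
  score <- as.vector(m %*% w)
  score[all_missing] <- NA_real_
  names(score) <- rownames(g)
  score
}

#' @rdname weighted_grs
#' @export
unweighted_grs <- function(g, impute_missing = TRUE, study = NULL) {
  unit <- data.frame(rsid = colnames(g), weight = 1)
  weighted_grs(g, unit, impute_missing = impute_missing, study = study)
}

#' Combine a genetic risk score with a phenotypic risk probability
#'
#' Adds the GRS to the logit of the phenotypic 10-year risk probability and
#' maps the sum back to a probability: `combined_logit = logit(p) + grs`
#' (optionally mean-centring the GRS first), and
#' `combined_probability = expit(combined_logit)`.
#'
#' The default leaves the GRS uncentred, so a score built from published
#' log odds ratios shifts the combined risk upward for carriers of more risk
#' alleles than the population average; `centre = TRUE` removes the mean GRS
#' so the combined score preserves the phenotypic score's average logit.
#' Both give identical rankings, hence identical AUROC and detection rates.
#'
#' @param p Phenotypic risk probabilities, strictly inside (0, 1).
#' @param grs Genetic risk scores, same length as `p`.
#' @param centre Subtract `mean(grs)` before adding. Default `FALSE`.
#' @param clip Clip `p` into `[1e-9, 1 - 1e-9]` instead of erroring on
#'   boundary values. Default `FALSE`.
#' @param id Optional individual ids.
#' @return A `data.frame` of class `risk_scores` with columns `id`, `grs`,
#'   `combined_logit`, `combined_probability`.
#' @export
combine_with_phenotypic <- function(p, grs, centre = FALSE, clip = FALSE,
                                    id = NULL) {
  stopifnot(length(p) == length(grs))
  if (clip) p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  check_prob_open(p, "phenotypic risk probability")
  centre_term <- if (centre) mean(grs, na.rm = TRUE) else 0
  cl <- logit(p) + (grs - centre_term)
  out <- data.frame(
    id = if (is.null(id)) seq_along(p) else id,
    grs = grs,
    combined_logit = cl,
    combined_probability = expit(cl),
    stringsAsFactors = FALSE
  )
  class(out) <- c("risk_scores", class(out))
  out
}

#' Adjust measured blood pressure for antihypertensive treatment
#'
#' Individuals on blood-pressure-lowering medication have their measured
#' pressures adjusted upward to approximate untreated values: +15 mm Hg
#' systolic, +10 mm Hg diastolic. Untreated individuals pass through
#' unchanged.
#'
#' @param sbp,dbp Systolic / diastolic blood pressure in mm Hg (positive).
#' @param treated Logical vector: on treatment?
#' @return `data.frame` with columns `sbp`, `dbp` (adjusted).
#' @export
adjust_bp_for_treatment <- function(sbp, dbp, treated) {
  stopifnot(length(sbp) == length(dbp), length(sbp) == length(treated))
  if (any(sbp <= 0, na.rm = TRUE) || any(dbp <= 0, na.rm = TRUE)) {
    stop("blood pressures must be positive")
  }
  treated <- as.logical(treated)
  data.frame(sbp = sbp + 15 * treated, dbp = dbp + 10 * treated)
}
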