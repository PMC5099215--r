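test_that("allele alignment keeps matches and flips complements", {
  g <- toy_genotypes(matrix(c(2, 1, 0, 2, 0, 1), nrow = 3,
                            dimnames = list(c("i1", "i2", "i3"),
                                            c("rs1", "rs2"))),
                     counted = c("A", "C"), other = c("G", "T"))
  w <- data.frame(rsid = c("rs1", "rs2"),
                  effect_allele = c("A", "T"), other_allele = c("G", "C"),
                  weight = c(0.1, 0.2))
  ali <- align_effect_alleles(g, w)
  expect_equal(unclass(ali)[, "rs1"], c(i1 = 2, i2 = 1, i3 = 0))  # identity
  expect_equal(unclass(ali)[, "rs2"], c(i1 = 0, i2 = 2, i3 = 1))  # complement
  st <- attr(ali, "alignment")
  expect_equal(st$status, c("matched", "flipped"))
})

test_that("mixed five-SNP panel with two flips matches a hand-flipped score", {
  set.seed(3)
  dos <- matrix(sample(0:2, 15, replace = TRUE), nrow = 3,
                dimnames = list(paste0("i", 1:3), paste0("rs", 1:5)))
  counted <- c("A", "C", "A", "C", "A")
  other   <- c("G", "T", "G", "T", "G")
  g <- toy_genotypes(dos, counted, other)
  # SNPs 2 and 4 weighted on the opposite allele -> flips
  w <- data.frame(rsid = paste0("rs", 1:5),
                  effect_allele = c("A", "T", "A", "T", "A"),
                  other_allele  = c("G", "C", "G", "C", "G"),
                  weight = c(0.05, -0.1, 0.2, 0.15, -0.05))
  ali <- align_effect_alleles(g, w)
  manual <- dos
  manual[, c(2, 4)] <- 2 - manual[, c(2, 4)]
  expect_equal(unname(weighted_grs(ali, w)),
               unname(as.vector(manual %*% w$weight)))
})

test_that("alignment errors are specific", {
  g <- toy_genotypes(matrix(1, 1, 1, dimnames = list("i1", "rs9")),
                     counted = "A", other = "G")
  w_bad <- data.frame(rsid = "rs9", effect_allele = "C", other_allele = "T",
                      weight = 0.1)
  expect_error(align_effect_alleles(g, w_bad), "matches neither")
  g_at <- toy_genotypes(matrix(1, 1, 1, dimnames = list("i1", "rs8")),
                        counted = "A", other = "T")
  w_at <- data.frame(rsid = "rs8", effect_allele = "A", other_allele = "T",
                     weight = 0.1)
  expect_error(align_effect_alleles(g_at, w_at), "strand-ambiguous")
  expect_silent(align_effect_alleles(g_at, w_at, allow_ambiguous = TRUE))
  # absent SNP is reported missing, not an error
  g1 <- toy_genotypes(matrix(1, 1, 1, dimnames = list("i1", "rs1")),
                      counted = "A", other = "G")
  w2 <- data.frame(rsid = c("rs1", "rs_absent"),
                   effect_allele = c("A", "A"), other_allele = c("G", "G"),
                   weight = c(0.1, 0.2))
  ali <- align_effect_alleles(g1, w2)
  expect_equal(attr(ali, "alignment")$status, c("matched", "missing"))
  expect_true(all(is.na(unclass(ali)[, "rs_absent"])))
})

test_that("weighted score equals brute-force product-and-sum", {
  set.seed(7)
  n <- 40; m <- 53
  dos <- matrix(sample(0:2, n * m, replace = TRUE), nrow = n,
                dimnames = list(paste0("i", 1:n), paste0("rs", 1:m)))
  g <- toy_genotypes(dos, rep("A", m), rep("G", m))
  w <- data.frame(rsid = colnames(dos), weight = rnorm(m, 0, 0.05))
  oracle <- vapply(seq_len(n),
                   function(i) sum(dos[i, ] * w$weight), numeric(1))
  expect_equal(unname(weighted_grs(g, w)), oracle)
  # null weights, single-term product
  expect_true(all(weighted_grs(g, transform(w, weight = 0)) == 0))
  g1 <- toy_genotypes(matrix(2, 1, 1, dimnames = list("i", "rs1")), "A", "G")
  expect_equal(unname(weighted_grs(g1, data.frame(rsid = "rs1", weight = 0.1))),
               0.2)
})

test_that("unweighted score is the risk-allele count", {
  dos <- matrix(c(0, 1, 2, 0, 0, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), paste0("rs", 1:3)))
  g <- toy_genotypes(dos, rep("A", 3), rep("G", 3))
  expect_equal(unname(unweighted_grs(g)), c(3, 0))
  set.seed(8)
  dos2 <- matrix(sample(0:2, 60, replace = TRUE), nrow = 6,
                 dimnames = list(paste0("i", 1:6), paste0("rs", 1:10)))
  g2 <- toy_genotypes(dos2, rep("A", 10), rep("G", 10))
  unit <- data.frame(rsid = colnames(dos2), weight = 1)
  expect_equal(unweighted_grs(g2), weighted_grs(g2, unit))
})

test_that("missing dosages follow the mean-imputation policy", {
  dos <- matrix(c(0, 2, NA, 2, 0, 2), nrow = 3,
                dimnames = list(paste0("i", 1:3), c("rs1", "rs2")))
  g <- toy_genotypes(dos, c("A", "A"), c("G", "G"))
  w <- data.frame(rsid = c("rs1", "rs2"), weight = c(1, 1))
  out <- weighted_grs(g, w)
  expect_equal(unname(out[3]), mean(c(0, 2)) + 2)  # imputed rs1 = column mean
  # all-missing individual flagged and NA
  dos2 <- matrix(c(1, NA, 1, NA), nrow = 2,
                 dimnames = list(c("ok", "gone"), c("rs1", "rs2")))
  g2 <- toy_genotypes(dos2, c("A", "A"), c("G", "G"))
  expect_warning(out2 <- weighted_grs(g2, w), "missing all")
  expect_true(is.na(out2["gone"]))
  expect_false(is.na(out2["ok"]))
})

test_that("combining with the phenotypic score follows the logit-additive form", {
  p <- c(0.05, 0.1, 0.3, 0.5, 0.8)
  # null genetic score returns the phenotypic probability exactly
  out0 <- combine_with_phenotypic(p, rep(0, 5))
  expect_equal(out0$combined_probability, p, tolerance = 1e-12)
  expect_equal(combine_with_phenotypic(0.5, 0)$combined_probability, 0.5)
  # closed form at p = 0.1, grs = 0.5
  out <- combine_with_phenotypic(0.1, 0.5)
  expect_equal(out$combined_probability, plogis(log(1 / 9) + 0.5),
               tolerance = 1e-12)
  expect_equal(out$combined_probability, expit(out$combined_logit))
  # boundary probabilities demand an explicit clip
  expect_error(combine_with_phenotypic(c(0.2, 1), c(0, 0)), "clip")
  clipped <- combine_with_phenotypic(c(0.2, 1), c(0, 0), clip = TRUE)
  expect_lt(clipped$combined_probability[2], 1)
})

test_that("centring changes probabilities but never the ranking", {
  set.seed(12)
  p <- runif(200, 0.02, 0.6)
  grs <- rnorm(200, 0.5, 0.3)
  a <- combine_with_phenotypic(p, grs, centre = FALSE)
  b <- combine_with_phenotypic(p, grs, centre = TRUE)
  expect_equal(order(a$combined_probability), order(b$combined_probability))
  y <- rbinom(200, 1, p)
  if (any(y == 1) && any(y == 0)) {
    expect_equal(weighted_auroc(a$combined_probability, y),
                 weighted_auroc(b$combined_probability, y))
  }
})

test_that("non-negative weights make the score monotone in dosage", {
  set.seed(13)
  m <- 8
  w <- data.frame(rsid = paste0("rs", 1:m),
                  weight = abs(rnorm(m, 0, 0.1)))
  base <- sample(0:1, m, replace = TRUE)
  for (j in 1:m) {
    more <- base; more[j] <- more[j] + 1
    dos <- rbind(base, more)
    dimnames(dos) <- list(c("lo", "hi"), w$rsid)
    g <- toy_genotypes(dos, rep("A", m), rep("G", m))
    s <- weighted_grs(g, w)
    expect_gte(s["hi"], s["lo"])
    pr <- combine_with_phenotypic(c(0.1, 0.1), s)$combined_probability
    expect_gte(pr[2], pr[1])
  }
})

test_that("blood pressure treatment adjustment adds 15/10 mm Hg", {
  out <- adjust_bp_for_treatment(c(140, 140, 120), c(90, 90, 80),
                                 c(TRUE, FALSE, TRUE))
  expect_equal(out$sbp, c(155, 140, 135))
  expect_equal(out$dbp, c(100, 90, 90))
  expect_error(adjust_bp_for_treatment(-120, 80, TRUE), "positive")
})
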