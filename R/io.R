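#' Read a SNP weights table
#'
#' Tab-separated file with header columns `rsid`, `effect_allele`,
#' `other_allele`, `weight` (per-effect-allele log odds ratio). Duplicate
#' rsids, missing columns and non-numeric weights are rejected with named
#' errors.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with the four validated columns.
#' @export
read_weights <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("rsid", "effect_allele", "other_allele", "weight")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("weights file missing column(s): ", paste(miss, collapse = ", "))
  dup <- tab$rsid[duplicated(tab$rsid)]
  if (length(dup)) stop("duplicated rsid(s) in weights file: ",
                        paste(unique(dup), collapse = ", "))
  wnum <- suppressWarnings(as.numeric(tab$weight))
  bad <- which(!is.finite(wnum))
  if (length(bad)) stop(sprintf("non-numeric or missing weight at row %d (rsid %s)",
                                bad[1], tab$rsid[bad[1]]))
  data.frame(rsid = tab$rsid,
             effect_allele = toupper(tab$effect_allele),
             other_allele = toupper(tab$other_allele),
             weight = wnum, stringsAsFactors = FALSE)
}

#' Read genotype dosages from VCF or a TSV dosage matrix
#'
#' VCF files (4.x) are read with the `vcfR` package; per-sample dosages
#' come from the `DS` FORMAT field when present, otherwise from `GT` as the
#' count of ALT alleles. By convention the counted allele is ALT and the
#' other allele REF. Multi-allelic sites raise an error unless
#' `multiallelic = "drop"`. TSV dosage matrices have an `id` first column
#' and one column per SNP; they carry no allele annotation (use
#' [align_effect_alleles()] with `assume_aligned = TRUE`, or a VCF).
#'
#' @param path Path to a `.vcf` or `.tsv` file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param multiallelic `"error"` (default) or `"drop"` multi-allelic sites.
#' @return A [genotype_matrix()]; missing dosages are `NA`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           multiallelic = c("error", "drop")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcf@fix   # keep matrix shape even for a single variant
    alt <- fix[, "ALT"]
    multi <- grepl(",", alt)
    if (any(multi)) {
      if (multiallelic == "error") {
        stop(sprintf("multi-allelic site(s) in VCF (first: %s); use multiallelic = \"drop\"",
                     fix[which(multi)[1], "ID"]))
      }
      message(sprintf("dropping %d multi-allelic site(s)", sum(multi)))
      vcf <- vcf[!multi, ]
      fix <- vcf@fix
      alt <- fix[, "ALT"]
    }
    fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
    if ("DS" %in% fmt) {
      d <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    } else if ("GT" %in% fmt) {
      gt <- vcfR::extract.gt(vcf, element = "GT")
      d <- apply(gt, c(1, 2), function(g) {
        if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
        sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
      })
    } else {
      stop("VCF has neither GT nor DS FORMAT fields")
    }
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
    m <- t(d)
    colnames(m) <- ids
    genotype_matrix(m, counted_allele = alt, other_allele = fix[, "REF"])
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                             na.strings = c("NA", "."))
    if (!"id" %in% names(tab)) stop("TSV dosage matrix must have an 'id' first column")
    m <- as.matrix(tab[, setdiff(names(tab), "id"), drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(tab$id)
    genotype_matrix(m)
  }
}

#' Write a genotype matrix as a TSV dosage matrix
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(g, path) {
  tab <- data.frame(id = rownames(g), unclass(g), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Write a genotype matrix as a minimal biallelic VCF (GT field)
#'
#' Integer dosages only; the counted allele is written as ALT and the
#' dosage encoded as the unphased genotype (0 -> 0/0, 1 -> 0/1, 2 -> 1/1,
#' missing -> ./.). Intended for small simulated fixtures.
#'
#' @param g A [genotype_matrix()] with allele annotation and integer
#'   dosages.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  info <- snp_info(g)
  if (anyNA(info$counted_allele)) stop("VCF output needs allele annotation")
  m <- round(unclass(g))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  for (j in seq_len(ncol(g))) {
    gt <- ifelse(is.na(m[, j]), "./.", gt_code[as.character(m[, j])])
    lines <- c(lines, paste(c("1", j, info$rsid[j], info$other_allele[j],
                              info$counted_allele[j], ".", "PASS", ".", "GT",
                              gt), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write cohort phenotype tables
#'
#' Comma-separated with header; required columns `id`, `study`, `p_pheno`
#' (phenotypic 10-year risk in (0, 1)), `y` (event indicator 0/1),
#' `followup_years`; optional `stratum` and sampling weight `w` (default 1,
#' must be >= 1). Missing values are written as ".".
#'
#' @param path File path.
#' @return `read_cohort()`: a validated `data.frame`.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", "."))
  need <- c("id", "study", "p_pheno", "y", "followup_years")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("cohort file missing column(s): ", paste(miss, collapse = ", "))
  check_prob_open(tab$p_pheno, "p_pheno")
  if (!all(tab$y %in% c(0, 1))) stop("y must be 0/1")
  if (is.null(tab$w)) tab$w <- 1
  if (any(tab$w < 1)) stop("sampling weights must be >= 1")
  tab
}

#' @rdname read_cohort
#' @param cohort Cohort `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = ".")
  invisible(path)
}
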