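#' Pearson chi-squared test for Hardy-Weinberg equilibrium
#'
#' From genotype counts (n_AA, n_Aa, n_aa) among designated unrelated
#' individuals, estimates the allele frequency and compares observed counts
#' with the Hardy-Weinberg expectations \eqn{(p^2, 2pq, q^2) n} by Pearson's
#' chi-squared statistic on 1 df, without continuity correction. The test is
#' invariant to swapping the allele labels. A monomorphic SNP has no defined
#' test and is flagged rather than raising an error.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts; alternatively pass a
#'   length-3 vector as \code{n_AA}.
#' @return list with \code{chi2}, \code{p}, and logical \code{monomorphic}.
#' @export
#' @examples
#' hwe_chisq(50, 40, 10)$chi2   # ~0.2268
hwe_chisq <- function(n_AA, n_Aa = NULL, n_aa = NULL) {
  if (is.null(n_Aa)) {
    stopifnot(length(n_AA) == 3L)
    counts <- as.numeric(n_AA)
  } else {
    counts <- c(n_AA, n_Aa, n_aa)
  }
  stopifnot(all(counts >= 0), sum(counts) > 0)
  n <- sum(counts)
  q <- (counts[2L] + 2 * counts[3L]) / (2 * n)
  if (q == 0 || q == 1)
    return(list(chi2 = NA_real_, p = NA_real_, monomorphic = TRUE))
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2,
       p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Filter SNPs on Hardy-Weinberg and minor-allele frequency
#'
#' A SNP is excluded when its HWE p-value is smaller than
#' \code{hwe_p_threshold} or its MAF is smaller than \code{maf_threshold};
#' values exactly at a threshold are kept (exclusion is strict
#' less-than). The filter is idempotent. Missing HWE p-values (e.g.
#' monomorphic SNPs, which the MAF rule removes anyway) do not trigger the
#' HWE exclusion.
#'
#' @param snps data.frame with columns \code{snp}, \code{hwe_p}, \code{maf}.
#' @param hwe_p_threshold,maf_threshold thresholds in (0, 1); defaults
#'   1e-4 and 0.001.
#' @return list with \code{kept} (the retained rows) and \code{log}
#'   (data.frame of \code{snp}, \code{reason}, \code{value} per exclusion;
#'   a SNP failing both rules is logged once per rule).
#' @export
filter_snps <- function(snps, hwe_p_threshold = 1e-4, maf_threshold = 0.001) {
  stopifnot(all(c("snp", "hwe_p", "maf") %in% names(snps)),
            hwe_p_threshold > 0, hwe_p_threshold < 1,
            maf_threshold > 0, maf_threshold < 1)
  bad_hwe <- !is.na(snps$hwe_p) & snps$hwe_p < hwe_p_threshold
  bad_maf <- !is.na(snps$maf) & snps$maf < maf_threshold
  log <- rbind(
    if (any(bad_hwe)) data.frame(snp = snps$snp[bad_hwe], reason = "hwe",
                                 value = snps$hwe_p[bad_hwe]),
    if (any(bad_maf)) data.frame(snp = snps$snp[bad_maf], reason = "maf",
                                 value = snps$maf[bad_maf])
  )
  if (is.null(log))
    log <- data.frame(snp = character(0), reason = character(0),
                      value = numeric(0))
  list(kept = snps[!(bad_hwe | bad_maf), , drop = FALSE], log = log)
}

#' Adjust a trait for antihypertensive medication
#'
#' Medication status (BPMED) is a consequence of the trait level, so
#' including it as an ordinary covariate would overcorrect. Instead the
#' medication effect is estimated from a regression restricted to
#' hypertensive individuals (among whom medication was assigned at random,
#' so the estimate is not confounded with trait level), and the estimated
#' effect times the medication indicator is subtracted from every
#' individual's trait. Unmedicated individuals' traits are returned
#' bit-identical.
#'
#' @param pheno data.frame with columns \code{TRAIT}, \code{BPMED},
#'   \code{HTN}, and any columns named in \code{covariates}.
#' @param covariates character vector of covariate columns to include
#'   alongside BPMED in the hypertensive-only regression; \code{"AGE:SEX"}
#'   denotes the elementwise AGE-by-SEX product. Default
#'   \code{c("AGE", "SEX", "AGE:SEX")}.
#' @return list with \code{adjusted} (trait vector), \code{med_effect}
#'   (estimated BPMED coefficient, trait units), and \code{n_htn}.
#' @export
adjust_bpmed <- function(pheno, covariates = c("AGE", "SEX", "AGE:SEX")) {
  stopifnot(all(c("TRAIT", "BPMED", "HTN") %in% names(pheno)))
  htn <- pheno[pheno$HTN == 1, , drop = FALSE]
  tab <- table(factor(htn$BPMED, levels = 0:1))
  if (any(tab < 2L))
    stop(sprintf(paste0("cannot estimate the medication effect: need at ",
                        "least 2 hypertensive individuals in each BPMED ",
                        "group (have %d unmedicated, %d medicated)"),
                 tab[1L], tab[2L]))
  Z <- .covariate_columns(htn, covariates)
  est <- stats::lm.fit(cbind(1, BPMED = htn$BPMED, Z), htn$TRAIT)
  med_effect <- unname(est$coefficients["BPMED"])
  list(adjusted = pheno$TRAIT - med_effect * pheno$BPMED,
       med_effect = med_effect, n_htn = nrow(htn))
}

# build a covariate matrix from column names; "A:B" is the elementwise
# product of columns A and B (optionally centering AGE first)
.covariate_columns <- function(pheno, covariates, center_age = FALSE) {
  if (!length(covariates)) return(NULL)
  cols <- lapply(covariates, function(nm) {
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
      Reduce(`*`, lapply(parts, function(p) .covariate_columns(pheno, p, center_age)))
    } else {
      v <- pheno[[nm]]
      if (is.null(v)) stop(sprintf("covariate column '%s' not found", nm))
      if (nm == "AGE" && center_age) v <- v - mean(v, na.rm = TRUE)
      as.numeric(v)
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Tie-aware p-value ranks
#'
#' Ascending ranks with mid-rank handling of ties (tied p-values share the
#' average of the ranks they span, so ranks like 1.5 appear), plus relative
#' ranks as a percentage of the number of SNPs ranked.
#'
#' @param pvals numeric vector of finite p-values.
#' @return data.frame with columns \code{rank} and \code{relative_rank}
#'   (percent). Ranks sum to \eqn{n(n+1)/2}.
#' @export
#' @examples
#' rank_pvalues(c(0.1, 0.1, 0.5))$rank   # 1.5 1.5 3
rank_pvalues <- function(pvals) {
  stopifnot(all(is.finite(pvals)))
  r <- rank(pvals, ties.method = "average")
  data.frame(rank = r, relative_rank = r / length(pvals) * 100)
}
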