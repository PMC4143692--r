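#' Read a genotype dose matrix
#'
#' Reads genotype doses either from a plain dose TSV (rows = SNPs, columns =
#' individuals, entries 0/1/2/NA, with leading columns \code{snp} and
#' \code{pos}) or from an uncompressed VCF (requires the \pkg{vcfR}
#' package; GT fields are converted to ALT-allele counts, multi-allelic
#' records are skipped with a logged count). In both cases doses are then
#' re-oriented so that X counts the \emph{minor} allele on the analysis
#' subset: if the ALT/counted allele has frequency above 1/2, doses are
#' flipped to \code{2 - dose} and the flip is recorded. Positions are
#' 1-based throughout.
#'
#' @param file path to a \code{.tsv}/\code{.txt} dose table or a
#'   \code{.vcf} file (format chosen by extension, override with
#'   \code{format}).
#' @param ped a [pedigree()]; columns are aligned to pedigree order.
#'   Individuals present in the genotype file but absent from the pedigree
#'   raise an error naming them; pedigree individuals absent from the file
#'   get missing doses.
#' @param format \code{"tsv"} or \code{"vcf"}; default from extension.
#' @return list with \code{doses} (individuals x SNPs matrix),
#'   \code{snps} (data.frame: snp, pos, flipped), and
#'   \code{n_skipped} (non-biallelic records dropped).
#' @export
read_doses <- function(file, ped, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.vcf$", file, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    raw <- .read_vcf_doses(file)
  } else {
    tab <- utils::read.table(file, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    meta_cols <- intersect(c("snp", "pos"), names(tab))
    ids <- setdiff(names(tab), meta_cols)
    doses <- t(as.matrix(tab[, ids, drop = FALSE]))
    colnames(doses) <- tab$snp
    raw <- list(doses = doses,
                snps = data.frame(snp = tab$snp,
                                  pos = if ("pos" %in% meta_cols) tab$pos
                                        else seq_len(nrow(tab))),
                n_skipped = 0L)
  }
  extra <- setdiff(rownames(raw$doses), ped$id)
  if (length(extra))
    stop(sprintf("individual(s) in genotype data but not in pedigree: %s",
                 paste(extra, collapse = ", ")))
  doses <- matrix(NA_real_, length(ped$id), ncol(raw$doses),
                  dimnames = list(ped$id, colnames(raw$doses)))
  doses[rownames(raw$doses), ] <- raw$doses
  # orient to the minor allele on the analysis subset
  freq <- colMeans(doses, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  doses[, flip] <- 2 - doses[, flip]
  raw$snps$flipped <- flip
  list(doses = doses, snps = raw$snps, n_skipped = raw$n_skipped)
}

.read_vcf_doses <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE) & fix[, "ALT"] != "."
  n_skipped <- sum(!biallelic)
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  alt_count <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  doses <- t(apply(gt, 2L, alt_count))
  if (ncol(gt) == 1L) doses <- t(doses)   # apply() drops dims for one sample
  rownames(doses) <- colnames(gt)
  ids <- fix[biallelic, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[biallelic, "CHROM"], ":",
                                         fix[biallelic, "POS"])[is.na(ids) | ids == "."]
  colnames(doses) <- ids
  list(doses = doses,
       snps = data.frame(snp = ids,
                         pos = as.integer(fix[biallelic, "POS"])),
       n_skipped = n_skipped)
}

#' Write a dose matrix as a TSV
#'
#' Writes the transposed layout [read_doses()] expects: one row per SNP,
#' leading columns \code{snp} and \code{pos}, then one column per
#' individual. Round-trips bit-identically through [read_doses()].
#'
#' @param doses individuals x SNPs matrix with dimnames.
#' @param file output path.
#' @param pos optional positions (default 1..n_snps).
#' @export
write_doses <- function(doses, file, pos = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(doses))
  out <- data.frame(snp = colnames(doses), pos = pos,
                    t(doses), check.names = FALSE)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a phenotype/covariate table
#'
#' Tab-delimited with named columns; \code{IID} plus trait and covariate
#' columns (typically TRAIT, AGE, SEX, BPMED, HTN).
#'
#' @param file path.
#' @return data.frame.
#' @export
read_phenotypes <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Per-SNP family-based association scan
#'
#' The package's central fitting function: preprocesses the phenotype
#' (optional medication adjustment) and the SNP panel (Hardy-Weinberg and
#' minor-allele-frequency filters), fits the covariate-only trait model,
#' and runs the configured association test at every retained SNP, ranking
#' the resulting p-values with mid-rank tie handling.
#'
#' Test modes:
#' \describe{
#'   \item{"genedrop"}{unconditional gene-dropping test,
#'     \eqn{t = u^2 / (4 R'\Psi R f(1-f))} against \eqn{\chi^2_1}.}
#'   \item{"unrelated"}{classical score test restricted to the individuals
#'     in \code{unrelated_ids} (which the caller asserts are unrelated).}
#'   \item{"conditional"}{test conditional on the inheritance vector, with
#'     \eqn{R'\Phi R} averaged over inheritance vectors sampled given the
#'     observed genotypes; also reports the linkage/association
#'     decomposition.}
#'   \item{"linkage"}{Monte-Carlo linkage test per SNP: the observed
#'     residual-weighted IBD sharing (averaged over sampled inheritance
#'     vectors) against its gene-dropping null.}
#' }
#' Individuals with a missing dose at a SNP are dropped for that SNP and the
#' trait model is refit on the complete cases, so the residual identities
#' the variance formulas rely on hold exactly per locus.
#'
#' @param ped a [pedigree()].
#' @param doses individuals x SNPs dose matrix (minor-allele counts),
#'   rows aligned to (a subset of) \code{ped$id}.
#' @param pheno phenotype data.frame with an \code{IID} column.
#' @param mode test mode, see Details.
#' @param trait name of the trait column (default \code{"TRAIT"}).
#' @param covariates covariate column names (\code{"A:B"} = product);
#'   default AGE, SEX and their interaction.
#' @param adjust_medication subtract the estimated BPMED effect first
#'   (needs BPMED and HTN columns).
#' @param hwe_p,maf_threshold filter thresholds (strict less-than
#'   exclusion).
#' @param unrelated_ids ids of the designated unrelated subset used for the
#'   HWE test (default: pedigree founders) and for mode "unrelated".
#' @param n_reps Monte-Carlo replicates for mode "linkage".
#' @param n_s inheritance vectors sampled per family for modes
#'   "conditional"/"linkage".
#' @param maf_founders_only estimate per-SNP MAF from founders only.
#' @param bh append a Benjamini-Hochberg adjusted p-value column.
#' @param seed optional seed for the Monte-Carlo modes.
#' @return object of class \code{gdscan}: list with \code{results}
#'   (one row per retained SNP: snp, pos, maf, n_used, u, v, t, p,
#'   association_component, linkage_component, flag, rank, relative_rank),
#'   \code{excluded} (filter log), \code{mode}, \code{med_effect},
#'   \code{n_individuals}, \code{call}.
#' @seealso [gd_test()], [conditional_test()], [linkage_test_mc()],
#'   [run_pipeline()]
#' @export
gd_scan <- function(ped, doses, pheno, mode = c("genedrop", "unrelated",
                                                "conditional", "linkage"),
                    trait = "TRAIT", covariates = c("AGE", "SEX", "AGE:SEX"),
                    adjust_medication = TRUE,
                    hwe_p = 1e-4, maf_threshold = 0.001,
                    unrelated_ids = NULL, n_reps = 999L, n_s = 20L,
                    maf_founders_only = TRUE, bh = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  cl <- match.call()

  pheno <- pheno[match(ped$id, pheno$IID), , drop = FALSE]
  if (anyNA(pheno$IID))
    stop(sprintf("pedigree individual(s) missing from phenotype table: %s",
                 paste(ped$id[is.na(pheno$IID)], collapse = ", ")))
  y <- pheno[[trait]]
  med_effect <- NA_real_
  if (adjust_medication && all(c("BPMED", "HTN") %in% names(pheno))) {
    ph <- pheno; ph$TRAIT <- y
    adj <- adjust_bpmed(ph, covariates = intersect(covariates,
                                                   c("AGE", "SEX", "AGE:SEX")))
    y <- adj$adjusted
    med_effect <- adj$med_effect
  }
  names(y) <- ped$id
  Z <- .covariate_columns(pheno, covariates)

  doses <- doses[intersect(rownames(doses), ped$id), , drop = FALSE]
  full <- matrix(NA_real_, length(ped$id), ncol(doses),
                 dimnames = list(ped$id, colnames(doses)))
  full[rownames(doses), ] <- doses
  doses <- full

  if (is.null(unrelated_ids)) unrelated_ids <- ped$id[ped$founder]
  unrelated_ids <- intersect(unrelated_ids, ped$id)

  # SNP-level preprocessing
  maf <- apply(doses, 2L, function(x) {
    estimate_maf(x, ped, founders_only = maf_founders_only)
  })
  hwe <- apply(doses[unrelated_ids, , drop = FALSE], 2L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_chisq(sum(x == 0), sum(x == 1), sum(x == 2))$p
  })
  panel <- data.frame(snp = colnames(doses), hwe_p = hwe, maf = maf)
  filt <- filter_snps(panel, hwe_p_threshold = hwe_p,
                      maf_threshold = maf_threshold)
  kept <- filt$kept$snp

  psi <- kinship_matrix(ped)
  fit_all <- fit_trait_model(y, Z)

  rows <- lapply(kept, function(sn) {
    x <- doses[, sn]
    ok <- !is.na(x)
    f <- maf[[sn]]
    if (mode == "unrelated") ok <- ok & ped$id %in% unrelated_ids
    if (all(ok) && mode != "unrelated") {
      fit <- fit_all
    } else {
      fit <- fit_trait_model(y[ok], Z[ok, , drop = FALSE])
    }
    xs <- x[ok]
    base <- data.frame(snp = sn, maf = f, n_used = sum(ok))
    if (mode == "unrelated") {
      u <- score_statistic(xs, fit)
      v <- variance_unrelated(xs, fit)
      res <- .assoc_result(u, v, "unrelated", f, sum(ok))
      cbind(base, u = res$u, v = res$v, t = res$t, p = res$p,
            association_component = NA_real_, linkage_component = NA_real_,
            flag = res$flag)
    } else if (mode == "genedrop") {
      res <- gd_test(xs, fit, psi[ok, ok, drop = FALSE], f)
      cbind(base, u = res$u, v = res$v, t = res$t, p = res$p,
            association_component = NA_real_, linkage_component = NA_real_,
            flag = res$flag)
    } else {
      phis <- .sample_phi_list(ped, x, f, n_s)
      phis_ok <- lapply(phis, function(p) p[ok, ok, drop = FALSE])
      if (mode == "conditional") {
        res <- conditional_test(xs, fit, phis_ok, f)
        phibar <- Reduce(`+`, phis_ok) / length(phis_ok)
        dec <- gd_decompose(xs, fit, psi[ok, ok, drop = FALSE], phibar, f)
        cbind(base, u = res$u, v = res$v, t = res$t, p = res$p,
              association_component = dec$association_component,
              linkage_component = dec$linkage_component, flag = res$flag)
      } else {  # linkage
        r <- fit$residuals
        obs <- mean(vapply(phis_ok, function(p) linkage_statistic(r, p),
                           numeric(1)))
        # observed statistic vs uniform-inheritance-vector null
        null <- vapply(seq_len(n_reps), function(k) {
          s <- sample_inheritance_vector(ped)
          phi <- ibd_matrix(ped, s)[ok, ok, drop = FALSE]
          linkage_statistic(r, phi)
        }, numeric(1))
        p <- (1 + sum(null >= obs)) / (n_reps + 1)
        cbind(base, u = NA_real_, v = NA_real_, t = obs, p = p,
              association_component = NA_real_, linkage_component = NA_real_,
              flag = "ok")
      }
    }
  })
  results <- do.call(rbind, rows)
  pos <- filt$kept$pos
  results$pos <- if (!is.null(pos)) pos else seq_len(nrow(results))
  ok_p <- is.finite(results$p)
  results$rank <- NA_real_; results$relative_rank <- NA_real_
  if (any(ok_p)) {
    rk <- rank_pvalues(results$p[ok_p])
    results$rank[ok_p] <- rk$rank
    results$relative_rank[ok_p] <- rk$relative_rank
  }
  if (bh && any(ok_p))
    results$p_bh <- ifelse(ok_p, stats::p.adjust(results$p, "BH"), NA_real_)
  results <- results[, c("snp", "pos", setdiff(names(results),
                                               c("snp", "pos")))]
  structure(list(results = results, excluded = filt$log, mode = mode,
                 med_effect = med_effect, n_individuals = length(ped$id),
                 call = cl),
            class = "gdscan")
}

# sample n_s inheritance vectors given genotypes, family by family
# (families are independent), returning block-diagonal IBD matrices
.sample_phi_list <- function(ped, x, maf, n_s) {
  n <- length(ped$id)
  phis <- replicate(n_s, matrix(0L, n, n,
                                dimnames = list(ped$id, ped$id)),
                    simplify = FALSE)
  for (f in unique(ped$fid)) {
    idx <- which(ped$fid == f)
    sub <- .subset_family(ped, f)
    S <- sample_s_given_genotypes(sub, x[idx], maf, n_s)
    for (k in seq_len(n_s)) {
      phis[[k]][idx, idx] <- ibd_matrix(sub, S[k, ])
    }
  }
  phis
}

.subset_family <- function(ped, f) {
  idx <- which(ped$fid == f)
  pedigree(id = ped$id[idx],
           father = ifelse(is.na(ped$father[idx]), "0", ped$id[ped$father[idx]]),
           mother = ifelse(is.na(ped$mother[idx]), "0", ped$id[ped$mother[idx]]),
           sex = ped$sex[idx], fid = ped$fid[idx])
}

#' @export
print.gdscan <- function(x, ...) {
  cat(sprintf("gdscan (%s mode): %d SNPs tested, %d excluded, %d individuals\n",
              x$mode, nrow(x$results), length(unique(x$excluded$snp)),
              x$n_individuals))
  if (is.finite(x$med_effect))
    cat(sprintf("  medication effect adjusted: %.3f trait units\n",
                x$med_effect))
  top <- utils::head(x$results[order(x$results$p), ], 5L)
  cat("  top SNPs:\n")
  print(top[, c("snp", "pos", "maf", "t", "p", "rank")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.gdscan <- function(object, alpha = 0.05, ...) {
  r <- object$results
  cat(sprintf("gdscan (%s mode)\n", object$mode))
  cat(sprintf("  SNPs tested: %d; untestable: %d; excluded upstream: %d\n",
              nrow(r), sum(r$flag != "ok"),
              length(unique(object$excluded$snp))))
  cat(sprintf("  p < %.3g: %d SNPs; minimum p = %.3g\n", alpha,
              sum(r$p < alpha, na.rm = TRUE), min(r$p, na.rm = TRUE)))
  invisible(object)
}

#' Manhattan-style plot of a scan
#'
#' @param x a \code{gdscan} object.
#' @param ... passed to [plot()].
#' @export
plot.gdscan <- function(x, ...) {
  r <- x$results[is.finite(x$results$p), ]
  plot(r$pos, -log10(r$p), pch = 20,
       xlab = "position", ylab = expression(-log[10](p)),
       main = sprintf("gene-dropping scan (%s)", x$mode), ...)
  graphics::abline(h = -log10(0.05 / nrow(r)), lty = 2, col = "grey40")
  invisible(x)
}

#' Write scan results as a TSV
#'
#' @param x a \code{gdscan} object.
#' @param file output path for the results; the exclusion log is written
#'   alongside as \code{<file>.excluded.tsv} when non-empty.
#' @export
write_gdscan <- function(x, file) {
  utils::write.table(x$results, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(x$excluded))
    utils::write.table(x$excluded, paste0(file, ".excluded.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Run the full file-to-file pipeline
#'
#' Reads pedigree, genotypes, and phenotypes from disk, runs [gd_scan()],
#' and writes the ranked results (and exclusion log) to \code{out_dir}.
#' Deterministic for a fixed seed.
#'
#' @param ped_file PED/FAM-style pedigree file.
#' @param geno_file dose TSV or VCF.
#' @param pheno_file phenotype TSV with named columns.
#' @param out_dir output directory (created if needed).
#' @param ... passed to [gd_scan()] (mode, thresholds, seed, ...).
#' @return the \code{gdscan} object, invisibly; results are written to
#'   \code{out_dir/results.tsv}.
#' @export
run_pipeline <- function(ped_file, geno_file, pheno_file, out_dir, ...) {
  ped <- read_pedigree(ped_file)
  geno <- read_doses(geno_file, ped)
  pheno <- read_phenotypes(pheno_file)
  scan <- gd_scan(ped, geno$doses, pheno, ...)
  scan$results$pos <- geno$snps$pos[match(scan$results$snp, geno$snps$snp)]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_gdscan(scan, file.path(out_dir, "results.tsv"))
  invisible(scan)
}
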