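#' Fit the covariate-only trait model
#'
#' Regresses the quantitative trait on the measured covariates (plus an
#' intercept) by least squares, without any genotype term: the trait model is
#' \deqn{E[Y] = \mu + \sum_k \alpha_k Z_k + X_\tau \beta_\tau,}
#' and the score test of \eqn{\beta_\tau = 0} only needs the residuals
#' \eqn{R = Y - \hat Y} and the residual variance from the reduced fit.
#' Because an intercept is present, the residuals sum to zero and are
#' orthogonal to every covariate column (so \eqn{R'JR = 0} for the all-ones
#' matrix J).
#'
#' @param y numeric trait vector (optionally named by individual id).
#' @param covariates numeric matrix (or data.frame) of covariate columns
#'   \eqn{Z_k}, without the intercept; \code{NULL} for an intercept-only fit.
#' @return An object of class \code{trait_fit}: list with \code{residuals},
#'   \code{fitted}, \code{s_yy} (residual variance, denominator
#'   \eqn{n - K - 1}), \code{design} (the matrix Z including the intercept
#'   column), \code{qr} (its QR decomposition), \code{n_used}, and
#'   \code{n_dropped} (rows removed for missingness).
#' @export
#' @examples
#' fit <- fit_trait_model(c(1, 2, 3))
#' residuals(fit)   # -1 0 1
#' fit$s_yy         # 1
fit_trait_model <- function(y, covariates = NULL) {
  y <- as.numeric(unlist(y))
  ids <- names(y)
  if (is.null(covariates)) {
    Z <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("Z", seq_len(ncol(covariates)))
    Z <- cbind("(Intercept)" = 1, covariates)
  }
  keep <- stats::complete.cases(y, Z)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    y <- y[keep]; Z <- Z[keep, , drop = FALSE]
    if (!is.null(ids)) ids <- ids[keep]
  }
  n <- length(y)
  if (n <= ncol(Z))
    stop(sprintf("need more observations (%d) than design columns (%d)",
                 n, ncol(Z)))
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- colnames(Z)[qz$pivot[(qz$rank + 1L):ncol(Z)]]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  fitted <- qr.fitted(qz, y)
  r <- y - fitted
  names(r) <- ids
  structure(list(residuals = r, fitted = fitted,
                 s_yy = sum(r^2) / (n - ncol(Z)),
                 design = Z, qr = qz,
                 n_used = n, n_dropped = n_dropped),
            class = "trait_fit")
}

#' @export
residuals.trait_fit <- function(object, ...) object$residuals

#' @export
fitted.trait_fit <- function(object, ...) object$fitted

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf("trait_fit: %d individuals, %d covariate column(s), s_yy = %.4g\n",
              x$n_used, ncol(x$design) - 1L, x$s_yy))
  if (x$n_dropped) cat(sprintf("  (%d rows dropped for missingness)\n", x$n_dropped))
  invisible(x)
}

#' Score statistic for genotype-trait association
#'
#' The score statistic for testing \eqn{\beta_\tau = 0} in the trait model is
#' \eqn{u = X_\tau' R}, the inner product of genotype doses with the
#' residuals of the covariate-only regression. Adding a constant to every
#' dose leaves u unchanged, since the residuals sum to zero.
#'
#' @param x numeric dose vector.
#' @param fit a [fit_trait_model()] object (or a bare residual vector).
#' @return the scalar score statistic u.
#' @export
score_statistic <- function(x, fit) {
  r <- if (inherits(fit, "trait_fit")) fit$residuals else fit
  if (length(x) != length(r))
    stop(sprintf("dose vector length (%d) does not match residuals (%d)",
                 length(x), length(r)))
  sum(as.numeric(x) * r)
}

#' Score-test variance for unrelated individuals
#'
#' The classical score-test variance
#' \deqn{v = s_{YY} \, X_\tau'(X_\tau - Z(Z'Z)^{-1}Z'X_\tau),}
#' valid when the individuals are unrelated so the components of
#' \eqn{X_\tau} are independent.
#'
#' @param x numeric dose vector aligned with the fit.
#' @param fit a [fit_trait_model()] object.
#' @param tol variances at or below \code{tol} are flagged untestable
#'   (x lies in the covariate span).
#' @return list with \code{v} and logical \code{untestable}.
#' @export
variance_unrelated <- function(x, fit, tol = 1e-12) {
  stopifnot(inherits(fit, "trait_fit"))
  x <- as.numeric(x)
  if (length(x) != fit$n_used)
    stop("dose vector length does not match the fitted model")
  xres <- x - qr.fitted(fit$qr, x)
  v <- fit$s_yy * sum(x * xres)
  list(v = v, untestable = v <= tol)
}

#' Unconditional gene-dropping variance of the score statistic
#'
#' Under gene dropping the residuals R are fixed and the doses are random
#' with \eqn{E[X_\tau X_\tau'] = 4\Psi(f - f^2) + 4Jf^2}; since
#' \eqn{R'JR = 0}, the variance of u unconditional on the inheritance vector
#' is \deqn{v_{gd} = 4\, R'\Psi R\, f(1 - f).}
#'
#' @param fit a [fit_trait_model()] object (or residual vector).
#' @param psi kinship matrix aligned with the residuals.
#' @param maf minor-allele frequency f in (0, 1).
#' @return list with \code{v} and logical \code{untestable}.
#' @seealso [kinship_matrix()], [gd_test()]
#' @export
variance_genedrop <- function(fit, psi, maf) {
  .check_maf(maf)
  r <- if (inherits(fit, "trait_fit")) fit$residuals else fit
  q <- drop(crossprod(r, psi %*% r))
  v <- 4 * q * maf * (1 - maf)
  list(v = v, untestable = v <= .v_tol(r))
}

# variances indistinguishable from zero (e.g. all-zero residuals up to
# floating-point dust) are untestable, never divided by
.v_tol <- function(r) 1e-12 * max(1, sum(r^2))

#' Conditional (inheritance-vector-fixed) variance of the score statistic
#'
#' Holding the inheritance vector fixed, \eqn{E[X_\tau X_\tau' | S_\tau] =
#' \Phi(S_\tau)(f - f^2) + 4Jf^2}, so
#' \deqn{v_\tau = R'\Phi(S_\tau)R \, f(1 - f).}
#' When several sampled IBD matrices are supplied (a list, e.g. from
#' [sample_s_given_genotypes()]), \eqn{R'\Phi R} is averaged over them
#' before scaling — a plug-in estimate of the conditional variance given the
#' observed genotypes.
#'
#' @param fit a [fit_trait_model()] object (or residual vector).
#' @param phi an IBD count matrix from [ibd_matrix()], or a list of them.
#' @param maf minor-allele frequency f in (0, 1).
#' @return list with \code{v} and logical \code{untestable}.
#' @export
variance_conditional <- function(fit, phi, maf) {
  .check_maf(maf)
  r <- if (inherits(fit, "trait_fit")) fit$residuals else fit
  if (is.list(phi)) {
    q <- mean(vapply(phi, function(p) drop(crossprod(r, p %*% r)), numeric(1)))
  } else {
    q <- drop(crossprod(r, phi %*% r))
  }
  v <- q * maf * (1 - maf)
  list(v = v, untestable = v <= .v_tol(r))
}

# assemble a classed association result from u and a variance
.assoc_result <- function(u, var, which, maf, n_used) {
  if (var$untestable) {
    t <- NA_real_; p <- NA_real_; flag <- "untestable"
  } else {
    t <- u^2 / var$v
    p <- stats::pchisq(t, df = 1L, lower.tail = FALSE)
    flag <- "ok"
  }
  structure(list(u = u, v = var$v, variance = which, t = t, p = p,
                 maf = maf, n_used = n_used, flag = flag),
            class = "gd_assoc")
}

#' @export
print.gd_assoc <- function(x, ...) {
  cat(sprintf("gene-dropping score test (%s variance)\n", x$variance))
  cat(sprintf("  u = %.6g, v = %.6g, t = u^2/v = %.6g, p = %.4g  [%s]\n",
              x$u, x$v, x$t, x$p, x$flag))
  cat(sprintf("  maf = %.4g, n = %d\n", x$maf, x$n_used))
  invisible(x)
}

#' Unconditional gene-dropping association test
#'
#' Approximates the gene-dropping null distribution of the score statistic u
#' by a normal with mean 0 and variance \eqn{v_{gd} = 4R'\Psi R f(1-f)}, and
#' compares \eqn{t = u^2/v_{gd}} with a chi-squared distribution on 1 df
#' (two-sided by construction).
#'
#' @param x dose vector aligned with the fit.
#' @param fit a [fit_trait_model()] object.
#' @param psi kinship matrix.
#' @param maf minor-allele frequency.
#' @return object of class \code{gd_assoc} with fields \code{u}, \code{v},
#'   \code{t}, \code{p}, \code{maf}, \code{n_used}, \code{flag}.
#' @export
gd_test <- function(x, fit, psi, maf) {
  u <- score_statistic(x, fit)
  .assoc_result(u, variance_genedrop(fit, psi, maf), "genedrop",
                maf, fit$n_used)
}

#' Association test conditional on the inheritance vector
#'
#' Tests association in the presence of linkage by conditioning on the
#' inheritance vector at the test locus: the variance of u given the
#' realized IBD sharing is \eqn{v_\tau = R'\Phi R f(1-f)}, and
#' \eqn{t = u^2/v_\tau} is compared with a chi-squared on 1 df. When the
#' inheritance vector is not observed, pass a list of IBD matrices sampled
#' by [sample_s_given_genotypes()]; their quadratic forms are averaged.
#'
#' @inheritParams gd_test
#' @param phi IBD count matrix (or list of sampled IBD matrices).
#' @return object of class \code{gd_assoc}.
#' @export
conditional_test <- function(x, fit, phi, maf) {
  u <- score_statistic(x, fit)
  .assoc_result(u, variance_conditional(fit, phi, maf), "conditional",
                maf, fit$n_used)
}

#' Decompose the gene-dropping statistic into association and linkage parts
#'
#' The unconditional statistic factors exactly as
#' \deqn{\frac{u^2}{4R'\Psi R f(1-f)} =
#'   \frac{u^2}{R'\Phi R f(1-f)} \cdot \frac{R'\Phi R}{4 R'\Psi R}.}
#' The first factor tests association in the presence of linkage (fine
#' mapping under a linkage peak); the second compares realized IBD sharing,
#' weighted by residual similarity, against its pedigree expectation and
#' carries the linkage information.
#'
#' @inheritParams conditional_test
#' @param psi kinship matrix.
#' @return object of class \code{gd_decomposition}: list with
#'   \code{association_component}, \code{linkage_component},
#'   \code{product} (their product, equal to \eqn{u^2/v_{gd}}), and
#'   \code{flag}.
#' @export
gd_decompose <- function(x, fit, psi, phi, maf) {
  .check_maf(maf)
  r <- if (inherits(fit, "trait_fit")) fit$residuals else fit
  u <- score_statistic(x, r)
  q_phi <- drop(crossprod(r, phi %*% r))
  q_psi <- drop(crossprod(r, psi %*% r))
  if (q_phi <= .v_tol(r) || q_psi <= .v_tol(r)) {
    return(structure(list(association_component = NA_real_,
                          linkage_component = NA_real_,
                          product = NA_real_, flag = "untestable"),
                     class = "gd_decomposition"))
  }
  assoc <- u^2 / (q_phi * maf * (1 - maf))
  link <- q_phi / (4 * q_psi)
  structure(list(association_component = assoc,
                 linkage_component = link,
                 product = assoc * link, flag = "ok"),
            class = "gd_decomposition")
}

#' @export
print.gd_decomposition <- function(x, ...) {
  cat(sprintf("decomposition: association = %.6g, linkage = %.6g, product (u^2/v_gd) = %.6g [%s]\n",
              x$association_component, x$linkage_component, x$product, x$flag))
  invisible(x)
}

#' Linkage statistic: residual-weighted IBD sharing
#'
#' \eqn{R'\Phi R = \sum_{ij} r_i r_j \phi_{ij}} measures the correlation
#' between trait-value similarity \eqn{r_i r_j} and IBD sharing
#' \eqn{\phi_{ij}} across all pairs; it is large when phenotypically similar
#' relatives share excess IBD, as expected near a locus linked to a causal
#' variant. It resembles the quantities driving Haseman-Elston regression
#' and variance-component linkage methods.
#'
#' @param fit a [fit_trait_model()] object or residual vector.
#' @param phi IBD count matrix.
#' @return scalar \eqn{R'\Phi R}.
#' @export
linkage_statistic <- function(fit, phi) {
  r <- if (inherits(fit, "trait_fit")) fit$residuals else fit
  drop(crossprod(r, phi %*% r))
}

# fast R' Phi(s) R without forming Phi: group residual slot-sums by
# founder-allele label, R'PhiR = sum over labels of (sum of r over slots)^2
.linkage_stat_s <- function(ped, r, s) {
  lab <- allele_labels(ped, s)
  sums <- rowsum(c(r, r), c(lab[, 1L], lab[, 2L]))
  sum(sums^2)
}

#' Monte-Carlo linkage test from gene dropping
#'
#' Compares the observed linkage statistic \eqn{R'\Phi(s_{obs})R} with its
#' gene-dropping null distribution: inheritance vectors are resampled
#' uniformly, as if from a marker unlinked to any causal locus, and the
#' one-sided upper-tail p-value is computed with the add-one estimator
#' \eqn{p = (1 + \#\{sim \ge obs\})/(n_{reps} + 1)} (never exactly zero, so
#' ranks are stable).
#'
#' @param fit a [fit_trait_model()] object or residual vector.
#' @param ped a [pedigree()] aligned with the residuals.
#' @param s_obs observed inheritance vector, or an observed IBD count matrix.
#' @param n_reps number of Monte-Carlo replicates (>= 100).
#' @return list with \code{p}, \code{observed}, and the simulated null
#'   statistics \code{null}.
#' @export
linkage_test_mc <- function(fit, ped, s_obs, n_reps = 999L) {
  stopifnot(n_reps >= 100L)
  r <- if (inherits(fit, "trait_fit")) fit$residuals else fit
  obs <- if (is.matrix(s_obs)) linkage_statistic(r, s_obs)
         else .linkage_stat_s(ped, r, s_obs)
  null <- vapply(seq_len(n_reps), function(k) {
    .linkage_stat_s(ped, r, sample_inheritance_vector(ped))
  }, numeric(1))
  list(p = (1 + sum(null >= obs)) / (n_reps + 1), observed = obs, null = null)
}

#' Exact null moments of the score statistic by full enumeration
#'
#' Brute-force oracle for small pedigrees: enumerates every founder-allele
#' configuration (weighted by the Bernoulli(f) law of each allele slot)
#' crossed with every inheritance vector (uniform), computes
#' \eqn{u = \sum_i X_i r_i} in each state, and returns the exact mean and
#' variance of u together with the exact conditional variance given each
#' inheritance vector. Intended as an independent check of the analytic
#' formulas \eqn{E[u] = 0}, \eqn{Var[u] = 4R'\Psi R f(1-f)} and
#' \eqn{Var[u|s] = R'\Phi(s)R f(1-f)}.
#'
#' @param ped a [pedigree()] (founder-allele plus meiosis bits capped at
#'   \code{max_bits}).
#' @param maf minor-allele frequency f.
#' @param r fixed residual vector aligned with the pedigree.
#' @param max_bits enumeration cap on \code{2*n_founders + n_meioses}.
#' @return list with \code{mean}, \code{var}, \code{var_by_s} (conditional
#'   variance of u for each enumerated inheritance vector, in enumeration
#'   order), \code{mean_by_s}, and \code{n_states}.
#' @export
score_null_moments_exact <- function(ped, maf, r, max_bits = 20L) {
  .check_maf(maf)
  nfb <- 2L * sum(ped$founder)
  nb <- n_meioses(ped)
  if (nfb + nb > max_bits)
    stop(sprintf("enumeration needs %d bits, above the cap of %d", nfb + nb, max_bits))
  S <- enumerate_inheritance_vectors(ped)
  A <- .enumerate_bits(nfb)
  wA <- apply(A, 1L, function(a) prod(ifelse(a == 1L, maf, 1 - maf)))
  mean_by_s <- numeric(nrow(S))
  var_by_s <- numeric(nrow(S))
  m1 <- 0; m2 <- 0
  for (k in seq_len(nrow(S))) {
    lab <- allele_labels(ped, S[k, ])
    doses <- A[, lab[, 1L], drop = FALSE] + A[, lab[, 2L], drop = FALSE]
    u <- drop(doses %*% r)
    mu <- sum(wA * u)
    mu2 <- sum(wA * u^2)
    mean_by_s[k] <- mu
    var_by_s[k] <- mu2 - mu^2
    m1 <- m1 + mu / nrow(S)
    m2 <- m2 + mu2 / nrow(S)
  }
  list(mean = m1, var = m2 - m1^2, var_by_s = var_by_s,
       mean_by_s = mean_by_s, n_states = nrow(S) * nrow(A))
}
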