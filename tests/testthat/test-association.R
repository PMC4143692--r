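test_that("the covariate-only trait fit returns centered residuals and s_yy", {
  fit <- fit_trait_model(c(1, 2, 3))
  expect_equal(unname(fit$residuals), c(-1, 0, 1))
  expect_equal(fit$s_yy, 1)
  expect_equal(sum(fit$residuals), 0)

  # constant trait, intercept only: residuals all zero
  expect_equal(unname(fit_trait_model(rep(5, 4))$residuals), rep(0, 4))

  # covariate equal to the trait: residuals and s_yy collapse to zero and
  # downstream variances flag the locus untestable
  y <- c(1, 3, 2, 5)
  fit0 <- fit_trait_model(y, cbind(y = y))
  expect_equal(unname(fit0$residuals), rep(0, 4))
  expect_equal(fit0$s_yy, 0)
  v <- variance_unrelated(c(0, 1, 2, 1), fit0)
  expect_true(v$untestable)

  # residuals orthogonal to every covariate column
  set.seed(1)
  Z <- cbind(age = rnorm(30), sex = rbinom(30, 1, 0.5))
  fit2 <- fit_trait_model(rnorm(30), Z)
  expect_lt(max(abs(crossprod(cbind(1, Z), fit2$residuals))), 1e-10)
})

test_that("trait fit rejects rank-deficient designs and drops missing rows", {
  z <- rnorm(10)
  expect_error(fit_trait_model(rnorm(10), cbind(a = z, b = 2 * z)), "collinear")
  y <- c(1, 2, NA, 4, 5)
  fit <- fit_trait_model(y, cbind(z = c(1, 2, 3, NA, 5)))
  expect_equal(fit$n_used, 3L)
  expect_equal(fit$n_dropped, 2L)
})

test_that("the score statistic is X'R and shift-invariant in the doses", {
  fit <- fit_trait_model(c(1, 2, 3))
  expect_equal(score_statistic(c(0, 1, 2), fit), 2)
  expect_equal(score_statistic(c(5, 6, 7), fit), 2)    # + constant, same u
  expect_equal(score_statistic(c(0, 0, 0), fit), 0)
  expect_equal(score_statistic(c(1, 1, 1), fit_trait_model(rep(2, 3))), 0)
  expect_error(score_statistic(c(1, 2), fit), "length")
})

test_that("the unrelated-individuals variance matches the projection formula", {
  fit <- fit_trait_model(c(1, 2, 3))
  x <- c(0, 1, 2)
  v <- variance_unrelated(x, fit)
  expect_false(v$untestable)
  expect_equal(v$v, 2)                      # s_yy * sum((x - xbar)^2) = 1 * 2
  u <- score_statistic(x, fit)
  expect_equal(u^2 / v$v, 2)
  expect_equal(stats::pchisq(u^2 / v$v, 1, lower.tail = FALSE),
               0.1572992, tolerance = 1e-6)
  # x inside the covariate span is untestable
  expect_true(variance_unrelated(c(1, 1, 1), fit)$untestable)
})

test_that("unconditional gene-dropping variance: arithmetic and Monte-Carlo oracle", {
  # unrelated case reduces to 2 f(1-f) sum(R^2)
  r <- c(-1, 0, 1)
  psi_id <- diag(3) / 2
  expect_equal(variance_genedrop(r, psi_id, 0.5)$v, 1)

  trio <- trio_ped()
  r <- c(dad = -1, mom = 0.25, kid = 0.75)
  psi <- kinship_matrix(trio)
  maf <- 0.3
  v_gd <- variance_genedrop(r, psi, maf)$v
  set.seed(201)
  x <- simulate_null(trio, maf, 50000)
  emp <- stats::var(drop(crossprod(x, r)))
  expect_equal(emp, v_gd, tolerance = 0.03)
})

test_that("conditional variance: averages to v_gd and matches conditional drops", {
  trio <- trio_ped()
  r <- c(dad = -1, mom = 0.25, kid = 0.75)
  maf <- 0.3
  psi <- kinship_matrix(trio)
  S <- enumerate_inheritance_vectors(trio)
  v_taus <- vapply(seq_len(nrow(S)), function(k) {
    variance_conditional(r, ibd_matrix(trio, S[k, ]), maf)$v
  }, numeric(1))
  expect_equal(mean(v_taus), variance_genedrop(r, psi, maf)$v,
               tolerance = 1e-12)

  s <- c(1L, 0L)
  set.seed(202)
  x <- simulate_null(trio, maf, 50000, condition_on = s)
  emp <- stats::var(drop(crossprod(x, r)))
  expect_equal(emp, variance_conditional(r, ibd_matrix(trio, s), maf)$v,
               tolerance = 0.03)

  # a list of sampled IBD matrices averages the quadratic form
  phis <- lapply(seq_len(nrow(S)), function(k) ibd_matrix(trio, S[k, ]))
  expect_equal(variance_conditional(r, phis, maf)$v, mean(v_taus))
})

test_that("exact enumeration confirms E[u] = 0 and both variance formulas", {
  cases <- list(list(ped = trio_ped(), maf = 0.5),
                list(ped = nuclear_ped(), maf = 0.2),
                list(ped = threegen_ped(), maf = 0.05))
  for (cs in cases) {
    ped <- cs$ped
    r <- centered_residuals(ped)
    mom <- score_null_moments_exact(ped, cs$maf, r)
    expect_lt(abs(mom$mean), 1e-12)
    v_gd <- variance_genedrop(r, kinship_matrix(ped), cs$maf)$v
    expect_equal(mom$var, v_gd, tolerance = 1e-10)
    S <- enumerate_inheritance_vectors(ped)
    for (k in seq_len(nrow(S))) {
      v_tau <- variance_conditional(r, ibd_matrix(ped, S[k, ]), cs$maf)$v
      expect_equal(mom$var_by_s[k], v_tau, tolerance = 1e-10)
    }
  }
})

test_that("gd_test builds a chi-squared p-value and flags untestable loci", {
  trio <- trio_ped()
  psi <- kinship_matrix(trio)
  fit <- fit_trait_model(c(3, 1, 2))
  set.seed(7)
  x <- drop_once(trio, 0.4)
  res <- gd_test(x, fit, psi, 0.4)
  expect_s3_class(res, "gd_assoc")
  expect_equal(res$t, res$u^2 / res$v)
  expect_equal(res$p, stats::pchisq(res$t, 1, lower.tail = FALSE))
  expect_gte(res$t, 0)
  expect_true(res$p > 0 && res$p <= 1)

  # u = 0 gives t = 0, p = 1 (doses orthogonal to nonzero residuals)
  res0 <- gd_test(c(1, 2, 1), fit_trait_model(c(1, 2, 3)), psi, 0.4)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  # t at the 5% critical value
  expect_equal(stats::pchisq(3.841459, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-6)

  # zero residuals make the variance zero: flagged, never NaN
  resu <- gd_test(x, fit_trait_model(rep(1, 3)), psi, 0.4)
  expect_equal(resu$flag, "untestable")
  expect_true(is.na(resu$p) && !is.nan(resu$p))
})

test_that("conditional test equals the unconditional one when Phi = 4 Psi", {
  trio <- trio_ped()
  fit <- fit_trait_model(c(3, 1, 2))
  x <- c(dad = 1, mom = 0, kid = 1)
  psi <- kinship_matrix(trio)
  res_gd <- gd_test(x, fit, psi, 0.4)
  res_c <- conditional_test(x, fit, 4 * psi, 0.4)
  expect_equal(res_c$t, res_gd$t)
  expect_equal(res_c$p, res_gd$p)
})

test_that("conditioning on excess sharing among concordant sibs raises the p-value", {
  nuc <- nuclear_ped()
  # sibs with large concordant residuals; parents balance the sum
  r <- c(dad = -2, mom = -2, kid1 = 2, kid2 = 2)
  s_share2 <- c(0L, 0L, 0L, 0L)      # sibs IBD-2
  phi <- ibd_matrix(nuc, s_share2)
  maf <- 0.3
  v_gd <- variance_genedrop(r, kinship_matrix(nuc), maf)$v
  v_tau <- variance_conditional(r, phi, maf)$v
  expect_gt(v_tau, v_gd)
  fit_like <- r    # residual-vector interface
  x <- c(dad = 1, mom = 1, kid1 = 2, kid2 = 2)
  u <- score_statistic(x, r)
  p_gd <- stats::pchisq(u^2 / v_gd, 1, lower.tail = FALSE)
  p_tau <- stats::pchisq(u^2 / v_tau, 1, lower.tail = FALSE)
  expect_gt(p_tau, p_gd)
})

test_that("the decomposition multiplies back to the unconditional statistic", {
  set.seed(301)
  for (k in 1:100) {
    ped <- list(trio_ped(), nuclear_ped(), threegen_ped())[[sample(3, 1)]]
    r <- rnorm(length(ped$id)); r <- r - mean(r)
    names(r) <- ped$id
    maf <- stats::runif(1, 0.05, 0.5)
    x <- drop_once(ped, maf)
    s <- sample_inheritance_vector(ped)
    psi <- kinship_matrix(ped)
    phi <- ibd_matrix(ped, s)
    dec <- gd_decompose(x, r, psi, phi, maf)
    if (dec$flag != "ok") next
    v_gd <- variance_genedrop(r, psi, maf)$v
    u <- score_statistic(x, r)
    expect_equal(dec$product, u^2 / v_gd, tolerance = 1e-10)
  }
  # Phi = 4 Psi makes the linkage component exactly 1
  trio <- trio_ped()
  r <- c(-1, 0, 1); names(r) <- trio$id
  dec1 <- gd_decompose(c(0, 1, 2), r, kinship_matrix(trio),
                       4 * kinship_matrix(trio), 0.3)
  expect_equal(dec1$linkage_component, 1)
})

test_that("the linkage statistic is the residual-weighted IBD double sum", {
  trio <- trio_ped()
  r <- c(dad = 1, mom = -1, kid = 0)
  s <- c(0L, 0L)
  phi <- ibd_matrix(trio, s)
  # independent oracle: explicit double sum
  oracle <- 0
  for (i in 1:3) for (j in 1:3) oracle <- oracle + r[i] * r[j] * phi[i, j]
  expect_equal(linkage_statistic(r, phi), unname(oracle))
  expect_equal(linkage_statistic(r, phi), 4)  # diag 2r^2, spouses share 0

  expect_equal(linkage_statistic(rep(0, 3), phi), 0)
  # singletons: Phi = 2 I so the statistic is 2 sum(r^2)
  sing <- singleton_ped(5)
  r5 <- centered_residuals(sing)
  phi5 <- ibd_matrix(sing, sample_inheritance_vector(sing))
  expect_equal(linkage_statistic(r5, phi5), 2 * sum(r5^2))
})

test_that("the fast label-grouped linkage statistic matches the matrix form", {
  set.seed(302)
  for (k in 1:20) {
    ped <- threegen_ped()
    r <- centered_residuals(ped, seed = k)
    s <- sample_inheritance_vector(ped)
    expect_equal(gdtest:::.linkage_stat_s(ped, r, s),
                 linkage_statistic(r, ibd_matrix(ped, s)))
  }
})

test_that("the Monte-Carlo linkage test detects engineered IBD-residual correlation", {
  fx <- make_linkage_fixture("max-concordant", n_families = 8L)
  set.seed(303)
  lt <- linkage_test_mc(fx$r, fx$ped, fx$s_obs, n_reps = 999L)
  expect_lte(lt$p, 0.05)
  expect_equal(lt$observed, linkage_statistic(fx$r, fx$phi))

  # seed replay reproduces the p-value exactly
  set.seed(303)
  lt2 <- linkage_test_mc(fx$r, fx$ped, fx$s_obs, n_reps = 999L)
  expect_identical(lt$p, lt2$p)

  # singletons: the statistic is constant so p = 1
  sing <- singleton_ped(6)
  rs <- centered_residuals(sing)
  lt3 <- linkage_test_mc(rs, sing, integer(0), n_reps = 199L)
  expect_equal(lt3$p, 1)
})
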