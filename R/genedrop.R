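#' Gene-drop a single locus down a pedigree
#'
#' Simulates one genotype dose vector under the null: each founder allele
#' slot is an independent Bernoulli(\code{maf}) draw of the minor allele, and
#' non-founder slots are copies of parental slots selected by the inheritance
#' vector \code{s}. The dose of individual i is the sum of its paternal and
#' maternal slots, so \eqn{E[X_i] = 2 f} for every individual.
#'
#' Randomness comes from R's global RNG; call \code{set.seed()} for
#' reproducibility.
#'
#' @param ped a [pedigree()].
#' @param maf minor-allele frequency in (0, 1).
#' @param s inheritance vector; sampled uniformly if \code{NULL}.
#' @return named integer vector of doses in \{0, 1, 2\}, with the inheritance
#'   vector used attached as attribute \code{"s"}.
#' @export
#' @examples
#' trio <- pedigree(c("d","m","k"), c("0","0","d"), c("0","0","m"), c(1,2,1))
#' set.seed(1)
#' drop_once(trio, maf = 0.3)
drop_once <- function(ped, maf, s = NULL) {
  .check_maf(maf)
  if (is.null(s)) s <- sample_inheritance_vector(ped)
  lab <- allele_labels(ped, s)
  a <- as.integer(stats::runif(2L * sum(ped$founder)) < maf)
  x <- a[lab[, 1L]] + a[lab[, 2L]]
  names(x) <- ped$id
  attr(x, "s") <- s
  x
}

.check_maf <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) ||
      maf <= 0 || maf >= 1)
    stop("maf must be strictly between 0 and 1 (monomorphic locus is untestable)")
  invisible(maf)
}

#' Simulate null genotype doses by repeated gene dropping
#'
#' Generates \code{n_reps} independent dose vectors under the gene-dropping
#' null. Unconditionally, a fresh inheritance vector is sampled for every
#' replicate, so \eqn{Cov(X_i, X_j) = 4\psi_{ij} f(1-f)}. When
#' \code{condition_on} supplies a fixed inheritance vector, only founder
#' alleles are redrawn and \eqn{Cov(X_i, X_j) = \phi_{ij}(s) f(1-f)}.
#'
#' @param ped a [pedigree()].
#' @param maf minor-allele frequency in (0, 1).
#' @param n_reps number of replicates (>= 1).
#' @param condition_on optional fixed inheritance vector.
#' @return integer matrix of doses, one row per individual (named), one
#'   column per replicate.
#' @seealso [drop_once()], [ibd_matrix()]
#' @export
simulate_null <- function(ped, maf, n_reps, condition_on = NULL) {
  .check_maf(maf)
  stopifnot(n_reps >= 1)
  n <- length(ped$id)
  nf <- sum(ped$founder)
  A <- matrix(as.integer(stats::runif(2L * nf * n_reps) < maf),
              nrow = 2L * nf, ncol = n_reps)
  if (!is.null(condition_on)) {
    lab <- allele_labels(ped, condition_on)
    x <- A[lab[, 1L], , drop = FALSE] + A[lab[, 2L], , drop = FALSE]
    rownames(x) <- ped$id
    return(x)
  }
  # per-replicate inheritance vectors, propagated as allele values
  B <- matrix(as.integer(stats::runif(n_meioses(ped) * n_reps) < 0.5),
              nrow = max(1L, n_meioses(ped)), ncol = n_reps)
  Vp <- matrix(0L, n, n_reps)
  Vm <- matrix(0L, n, n_reps)
  slot <- 1L; bit <- 1L
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      Vp[i, ] <- A[slot, ]
      Vm[i, ] <- A[slot + 1L, ]
      slot <- slot + 2L
    } else {
      f <- ped$father[i]; m <- ped$mother[i]
      bp <- B[bit, ]; bm <- B[bit + 1L, ]
      Vp[i, ] <- ifelse(bp == 0L, Vp[f, ], Vm[f, ])
      Vm[i, ] <- ifelse(bm == 0L, Vp[m, ], Vm[m, ])
      bit <- bit + 2L
    }
  }
  x <- Vp + Vm
  rownames(x) <- ped$id
  x
}

#' Gene drop with permuted (rather than resimulated) founder alleles
#'
#' Takes the observed founder genotypes apart into their \code{2 *
#' n_founders} alleles, permutes those alleles (globally, or within each
#' family when \code{within_family = TRUE}, which makes the test robust to
#' population stratification across families), reassembles founder
#' genotypes, and transmits them down the pedigree along a freshly sampled
#' inheritance vector. The multiset of founder alleles — globally or per
#' family — is conserved in every replicate.
#'
#' @param ped a [pedigree()].
#' @param observed named dose vector with non-missing founder doses.
#' @param within_family restrict the permutation to founder alleles within
#'   each family.
#' @return named integer dose vector with attribute \code{"s"}.
#' @export
permute_founder_alleles <- function(ped, observed, within_family = FALSE) {
  fidx <- which(ped$founder)
  obs <- observed[ped$id]
  if (any(is.na(obs[fidx])))
    stop(sprintf("missing founder genotype for: %s",
                 paste(ped$id[fidx][is.na(obs[fidx])], collapse = ", ")))
  # founder dose d -> alleles (slot pair); heterozygote phase is immaterial
  alle <- unlist(lapply(obs[fidx], function(d) {
    c(as.integer(d >= 1), as.integer(d >= 2))
  }), use.names = FALSE)
  if (within_family) {
    fam <- rep(ped$fid[fidx], each = 2L)
    for (f in unique(fam)) {
      k <- which(fam == f)
      alle[k] <- alle[sample(k)]
    }
  } else {
    alle <- alle[sample(length(alle))]
  }
  s <- sample_inheritance_vector(ped)
  lab <- allele_labels(ped, s)
  x <- alle[lab[, 1L]] + alle[lab[, 2L]]
  names(x) <- ped$id
  attr(x, "s") <- s
  x
}

#' Sample inheritance vectors given observed genotypes
#'
#' Draws inheritance vectors from their conditional distribution given the
#' observed dose vector, \eqn{P(s | X) \propto P(X | s, f)}. On small
#' pedigrees (by default when founder-allele plus meiosis bits total at most
#' \code{exact_bits}) the likelihood of every inheritance vector is computed
#' exactly by enumerating founder-allele configurations, and vectors are
#' sampled from the exact weights. Otherwise rejection sampling is used:
#' propose a uniform inheritance vector and founder alleles, accept when the
#' implied doses reproduce the observation.
#'
#' @param ped a [pedigree()].
#' @param observed named dose vector (entries 0/1/2, NA allowed; NA entries
#'   are unconstrained).
#' @param maf minor-allele frequency used for founder alleles.
#' @param n_samples number of vectors to draw.
#' @param exact_bits use exact enumeration when
#'   \code{2*n_founders + n_meioses <= exact_bits} (default 20).
#' @param budget rejection-sampling attempt budget (default 1e6).
#' @return integer matrix, one sampled inheritance vector per row.
#' @export
sample_s_given_genotypes <- function(ped, observed, maf, n_samples,
                                     exact_bits = 20L, budget = 1e6) {
  .check_maf(maf)
  obs <- observed[ped$id]
  nb <- n_meioses(ped)
  nfb <- 2L * sum(ped$founder)
  if (nfb + nb <= exact_bits) {
    S <- enumerate_inheritance_vectors(ped)
    A <- .enumerate_bits(nfb)
    wA <- apply(A, 1L, function(a) prod(ifelse(a == 1L, maf, 1 - maf)))
    ok_cols <- which(!is.na(obs))
    lik <- vapply(seq_len(nrow(S)), function(k) {
      lab <- allele_labels(ped, S[k, ])
      doses <- A[, lab[, 1L], drop = FALSE] + A[, lab[, 2L], drop = FALSE]
      hit <- rowSums(doses[, ok_cols, drop = FALSE] !=
                       matrix(obs[ok_cols], nrow(A), length(ok_cols),
                              byrow = TRUE)) == 0L
      sum(wA[hit])
    }, numeric(1))
    if (sum(lik) == 0)
      stop("observed genotypes are Mendelian-inconsistent with the pedigree (likelihood 0 for every inheritance vector)")
    idx <- sample.int(nrow(S), n_samples, replace = TRUE, prob = lik)
    return(S[idx, , drop = FALSE])
  }
  # rejection sampling
  out <- matrix(0L, n_samples, nb)
  got <- 0L; tried <- 0
  ok_cols <- which(!is.na(obs))
  while (got < n_samples) {
    if (tried >= budget)
      stop(sprintf(paste0("rejection budget of %g attempts exhausted after ",
                          "%d acceptances (acceptance rate %.2e)"),
                   budget, got, got / tried))
    x <- drop_once(ped, maf)
    tried <- tried + 1
    if (all(x[ok_cols] == obs[ok_cols])) {
      got <- got + 1L
      out[got, ] <- attr(x, "s")
    }
  }
  out
}

#' Estimate minor-allele frequency from a dose vector
#'
#' Estimates f as half the mean dose, by default over founders only (so no
#' allele is counted twice through transmission); missing doses are dropped.
#'
#' @param x named dose vector (0/1/2, NA allowed).
#' @param ped a [pedigree()]; required when \code{founders_only = TRUE}.
#' @param founders_only use founders only (default) or all individuals.
#' @return estimated allele frequency in [0, 1].
#' @export
estimate_maf <- function(x, ped = NULL, founders_only = TRUE) {
  if (founders_only) {
    if (is.null(ped)) stop("founders_only = TRUE requires a pedigree")
    x <- x[ped$id[ped$founder]]
  }
  mean(x, na.rm = TRUE) / 2
}
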