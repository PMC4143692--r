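#' Simulation configuration for synthetic cohorts
#'
#' Collects the parameters of the generative model used for fixtures and
#' calibration studies: pedigrees are built from a family template,
#' genotypes are gene-dropped at SNP-specific allele frequencies
#' (independent loci, no linkage disequilibrium), and the trait follows the
#' linear covariate model with optional causal-SNP effects, an optional
#' shared within-family effect, Gaussian noise, and medication masking
#' (hypertensives are medicated at random and their observed trait is
#' shifted by the medication effect).
#'
#' Defaults emulate a systolic-blood-pressure-like trait in mmHg: baseline
#' 110, age effect 0.4 mmHg/year, sex effect 5 mmHg, a small age-by-sex
#' interaction, residual noise SD 10 mmHg, medication effect -10 mmHg, and a
#' hypertension threshold of 140 mmHg.
#'
#' @param n_families number of families.
#' @param family_template one of \code{"trio"}, \code{"two-gen"},
#'   \code{"three-gen"} (a 3-generation 8-person family: two grandparents,
#'   their two children, two married-in founders, two grandchildren).
#' @param n_kids children per nuclear family for \code{"two-gen"}.
#' @param n_snps number of simulated SNPs.
#' @param maf_range interval in (0, 1) from which each SNP's minor-allele
#'   frequency is drawn uniformly.
#' @param causal optional data.frame with columns \code{snp} (index) and
#'   \code{beta} (per-allele effect, trait units), plus optionally
#'   \code{maf} to pin those SNPs' allele frequencies (so a standardized
#'   effect size is exact rather than depending on the drawn frequency).
#' @param mu baseline trait mean.
#' @param covariate_effects named vector of effects for AGE, SEX and
#'   AGE:SEX.
#' @param noise_sd residual SD, trait units.
#' @param family_effect_sd SD of a shared within-family random effect
#'   (default 0).
#' @param med_effect medication effect added to the observed trait of
#'   medicated individuals (trait units, typically negative).
#' @param htn_threshold trait level above which an individual is
#'   hypertensive.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return list of class \code{sim_config}.
#' @seealso [generate_cohort()]
#' @export
simulation_config <- function(n_families = 20L,
                              family_template = c("three-gen", "trio", "two-gen"),
                              n_kids = 2L,
                              n_snps = 100L,
                              maf_range = c(0.05, 0.5),
                              causal = NULL,
                              mu = 110,
                              covariate_effects = c(AGE = 0.4, SEX = 5,
                                                    "AGE:SEX" = 0.05),
                              noise_sd = 10,
                              family_effect_sd = 0,
                              med_effect = -10,
                              htn_threshold = 140,
                              seed = NULL) {
  family_template <- match.arg(family_template)
  stopifnot(n_families >= 1, n_snps >= 1, n_kids >= 1,
            length(maf_range) == 2L, all(maf_range > 0), all(maf_range < 1),
            noise_sd > 0, family_effect_sd >= 0)
  if (!is.null(causal)) {
    stopifnot(all(c("snp", "beta") %in% names(causal)))
    if (any(causal$snp < 1 | causal$snp > n_snps))
      stop("causal snp index out of range")
  }
  structure(list(n_families = as.integer(n_families),
                 family_template = family_template, n_kids = as.integer(n_kids),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 causal = causal, mu = mu,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd, family_effect_sd = family_effect_sd,
                 med_effect = med_effect, htn_threshold = htn_threshold,
                 seed = seed),
            class = "sim_config")
}

# one family's rows of a pedigree table; ids prefixed by the family id
.family_rows <- function(fid, template, n_kids) {
  p <- function(x) paste0(fid, "_", x)
  switch(template,
    trio = data.frame(
      fid = fid, id = p(c("dad", "mom", "kid")),
      father = c("0", "0", p("dad")), mother = c("0", "0", p("mom")),
      sex = c(1, 2, 1)),
    "two-gen" = {
      kids <- p(paste0("kid", seq_len(n_kids)))
      data.frame(
        fid = fid, id = c(p(c("dad", "mom")), kids),
        father = c("0", "0", rep(p("dad"), n_kids)),
        mother = c("0", "0", rep(p("mom"), n_kids)),
        sex = c(1, 2, rep_len(c(1, 2), n_kids)))
    },
    "three-gen" = data.frame(
      fid = fid,
      id = p(c("gf", "gm", "s1", "s2", "c1", "c2", "g1", "g2")),
      father = c("0", "0", "0", "0", p("gf"), p("gf"), p("c1"), p("s2")),
      mother = c("0", "0", "0", "0", p("gm"), p("gm"), p("s1"), p("c2")),
      sex = c(1, 2, 2, 1, 1, 2, 1, 2)))
}

# generation depth of each individual (founders with no children-in-law
# complications: depth = 1 + max parent depth)
.generation <- function(ped) {
  g <- integer(length(ped$id))
  for (i in seq_along(ped$id)) {
    g[i] <- if (ped$founder[i]) 1L
            else 1L + max(g[ped$father[i]], g[ped$mother[i]])
  }
  # married-in founders sit at their children's generation minus one
  for (i in which(ped$founder)) {
    kids <- which(ped$father == i | ped$mother == i)
    if (length(kids)) g[i] <- max(g[i], max(g[kids]) - 1L)
  }
  g
}

#' Generate a synthetic family cohort
#'
#' Builds pedigrees from the configured template, gene-drops every SNP
#' independently down the pedigrees, and simulates the trait as
#' \deqn{Y = \mu + \alpha_{AGE} AGE + \alpha_{SEX} SEX +
#'   \alpha_{AS} AGE \cdot SEX + \sum \beta X_{causal} + b_{family} +
#'   \epsilon,}
#' with \eqn{\epsilon \sim N(0, noise\_sd^2)}. Hypertension is \eqn{Y}
#' above the threshold; medication is assigned Bernoulli(1/2) among
#' hypertensives only, and the observed trait of medicated individuals is
#' shifted by \code{med_effect}. Ages are drawn uniformly within
#' generation-specific bands (60-80, 35-55, 10-30 years from oldest
#' generation down); sex is taken from the pedigree (coded 1 = male,
#' 0 = female in the phenotype table).
#'
#' @param cfg a [simulation_config()].
#' @return list with \code{ped} (a [pedigree()] over all families),
#'   \code{doses} (individuals x SNPs integer matrix), \code{snps}
#'   (data.frame: snp, pos, maf), \code{pheno} (data.frame: IID, TRAIT,
#'   AGE, SEX, BPMED, HTN), and \code{truth} (every parameter and latent
#'   quantity used).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  rows <- do.call(rbind, lapply(seq_len(cfg$n_families), function(k) {
    .family_rows(sprintf("F%03d", k), cfg$family_template, cfg$n_kids)
  }))
  ped <- pedigree(rows$id, rows$father, rows$mother, rows$sex, rows$fid)
  n <- length(ped$id)

  maf <- stats::runif(cfg$n_snps, cfg$maf_range[1L], cfg$maf_range[2L])
  if (!is.null(cfg$causal) && !is.null(cfg$causal$maf))
    maf[cfg$causal$snp] <- cfg$causal$maf
  doses <- vapply(maf, function(f) drop_once(ped, f), integer(n))
  colnames(doses) <- sprintf("snp%04d", seq_len(cfg$n_snps))
  snps <- data.frame(snp = colnames(doses),
                     pos = seq_len(cfg$n_snps) * 1000L, maf = maf)

  gen <- .generation(ped)
  bands <- list(c(60, 80), c(35, 55), c(10, 30))
  age <- vapply(gen, function(g) {
    b <- bands[[min(g, 3L)]]
    round(stats::runif(1, b[1L], b[2L]))
  }, numeric(1))
  sex01 <- as.integer(ped$sex == 1L)

  ce <- cfg$covariate_effects
  y <- cfg$mu + ce[["AGE"]] * age + ce[["SEX"]] * sex01 +
    ce[["AGE:SEX"]] * age * sex01
  if (!is.null(cfg$causal)) {
    for (k in seq_len(nrow(cfg$causal))) {
      y <- y + cfg$causal$beta[k] * doses[, cfg$causal$snp[k]]
    }
  }
  fam_eff <- if (cfg$family_effect_sd > 0) {
    e <- stats::rnorm(length(unique(ped$fid)), 0, cfg$family_effect_sd)
    e[match(ped$fid, unique(ped$fid))]
  } else rep(0, n)
  y <- unname(y + fam_eff + stats::rnorm(n, 0, cfg$noise_sd))

  htn <- as.integer(y > cfg$htn_threshold)
  bpmed <- integer(n)
  bpmed[htn == 1L] <- stats::rbinom(sum(htn), 1L, 0.5)
  observed <- y + cfg$med_effect * bpmed

  pheno <- data.frame(IID = ped$id, TRAIT = observed, AGE = age,
                      SEX = sex01, BPMED = bpmed, HTN = htn)
  list(ped = ped, doses = doses, snps = snps, pheno = pheno,
       truth = list(config = cfg, maf = maf, latent_trait = y,
                    family_effect = fam_eff))
}

#' Linkage-test stress fixture
#'
#' Builds a cohort of two-parent/two-sib families together with residuals
#' and a realized inheritance vector engineered so the correlation between
#' residual similarity and IBD sharing is maximal, minimal, or absent:
#' \describe{
#'   \item{"null"}{Gaussian residuals centered within each family,
#'     inheritance vector sampled uniformly — no residual/IBD relationship
#'     (continuous residuals keep the Monte-Carlo statistic effectively
#'     tie-free, so its null p-values are uniform).}
#'   \item{"max-concordant"}{sibs share both alleles IBD and have equal
#'     residuals (+1 each, parents -1), the maximum attainable linkage
#'     statistic.}
#'   \item{"max-discordant"}{sibs share both alleles IBD but have opposite
#'     residuals, pushing the statistic below its null median.}
#' }
#'
#' @param pattern one of \code{"null"}, \code{"max-concordant"},
#'   \code{"max-discordant"}.
#' @param n_families number of sib-pair families (default 8).
#' @return list with \code{ped}, \code{r} (residuals summing to zero within
#'   each family), \code{s_obs}, and \code{phi} (the realized IBD matrix).
#' @export
make_linkage_fixture <- function(pattern = c("null", "max-concordant",
                                             "max-discordant"),
                                 n_families = 8L) {
  pattern <- match.arg(pattern)
  rows <- do.call(rbind, lapply(seq_len(n_families), function(k) {
    .family_rows(sprintf("F%03d", k), "two-gen", 2L)
  }))
  ped <- pedigree(rows$id, rows$father, rows$mother, rows$sex, rows$fid)
  is_kid <- !ped$founder
  kid2 <- grepl("kid2$", ped$id)
  if (pattern == "null") {
    r <- stats::rnorm(length(ped$id))
    r <- r - stats::ave(r, ped$fid)      # centered within family
  } else {
    r <- ifelse(is_kid, 1, -1)
    if (pattern == "max-discordant") {
      r[kid2] <- -1 * r[kid2]
      r[ped$founder] <- 0
    }
  }
  s_obs <- if (pattern == "null") {
    sample_inheritance_vector(ped)
  } else {
    # every sib copies the grandpaternal allele in both meioses: sibs IBD-2
    rep(0L, n_meioses(ped))
  }
  list(ped = ped, r = r, s_obs = s_obs, phi = ibd_matrix(ped, s_obs))
}
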