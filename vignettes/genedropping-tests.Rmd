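---
title: "Gene-dropping association tests: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-dropping association tests: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdtest)
```

## The problem and the model

We test whether a SNP is associated with a quantitative trait in a sample
of related individuals drawn from known pedigrees. The trait model is the
usual linear one,

$$E[Y] = \mu + \sum_{k=1}^{K} \alpha_k Z_k + X_\tau \beta_\tau,$$

with $Y$ the trait vector (e.g. systolic blood pressure in mmHg), $Z_k$
measured covariates (age, sex, their interaction), $X_\tau$ the vector of
minor-allele dose counts at SNP $\tau$, and $\beta_\tau$ the per-allele
effect. The score statistic for $H_0:\beta_\tau = 0$ is $u = X_\tau'R$,
where $R$ are the residuals of the covariate-only regression (intercept
included, so $\sum_i R_i = 0$).

With unrelated individuals the classical variance
$v = s_{YY}\,X_\tau'(X_\tau - Z(Z'Z)^{-1}Z'X_\tau)$ applies
(`variance_unrelated()`). With relatives it does not: the components of
$X_\tau$ are correlated through shared descent. Gene dropping supplies the
correct null: hold $R$ fixed, draw each founder allele independently as
Bernoulli($f$) with $f$ the minor-allele frequency, and transmit alleles
down the pedigree by fair coin flips — one inheritance bit per meiosis,
collected in the inheritance vector $S_\tau$.

Writing $X_i = P_i + M_i$ as the sum of the paternal and maternal allele
indicators, every slot has mean $f$, so $E[u] = 2f\sum_i R_i = 0$ exactly.
For the variance, two allele slots are equal with probability 1 when they
are identical by descent (IBD) and independent otherwise. Let $\phi_{ij}$
count the IBD pairs among the four slot pairs of individuals $i,j$; its
expectation over uniformly random inheritance vectors is $4\psi_{ij}$, four
times the kinship coefficient. Since $R'JR = 0$, the cross-product term in
$E[X X']$ drops out and

$$\operatorname{Var}(u \mid S_\tau) = R'\Phi(S_\tau)R\, f(1-f)
  \equiv v_\tau, \qquad
  \operatorname{Var}(u) = 4R'\Psi R\, f(1-f) \equiv v_{gd}.$$

The test refers $t = u^2/v_{gd}$ (or $u^2/v_\tau$) to $\chi^2_1$; the
normal approximation to $u$ is justified by additivity over independent
families. The statistic factors exactly:

$$\frac{u^2}{v_{gd}} \;=\;
  \underbrace{\frac{u^2}{R'\Phi R\, f(1-f)}}_{\text{association given linkage}}
  \times
  \underbrace{\frac{R'\Phi R}{4R'\Psi R}}_{\text{linkage}}.$$

$R'\Phi R = \sum_{ij} R_i R_j \phi_{ij}$ measures the correlation between
trait similarity and IBD sharing — the same quantity that drives
Haseman–Elston-style linkage methods — and `linkage_test_mc()` compares it
against its gene-dropping null.

### Assumptions

* Autosomal, biallelic loci; doses count the minor allele (inputs are
  re-oriented if needed).
* Founders carry independent alleles at frequency $f$: founders are
  non-inbred, mutually unrelated, and drawn from one homogeneous
  population. Cross-family relatedness is zero by construction.
  Population stratification violates this; the founder-allele permutation
  variant restricted to within-family permutations
  (`permute_founder_alleles(within_family = TRUE)`) is the robust
  alternative.
* $R$ is treated as fixed in the gene-dropping null (the randomness is in
  the genotypes), mirroring how the score test conditions on phenotype.
* Pedigree loops (e.g. recorded cousin matings) are allowed — both the
  kinship recursion and allele-label propagation handle them — but only
  individuals with two recorded parents or none are accepted.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `maf` | all tests | estimated from founders | counting transmitted copies twice would bias $f$; `founders_only = FALSE` opts out |
| `hwe_p_threshold` | `filter_snps` | 1e-4 | Pearson HWE test on a designated unrelated subset flags genotyping artifacts; exclusion is *strictly below* the threshold, so equality survives |
| `maf_threshold` | `filter_snps` | 0.001 | rare loci make the normal approximation fragile; below the threshold a locus is flagged untestable rather than given p = 1 |
| `n_reps` | `linkage_test_mc` | 999 | Monte-Carlo resolution 1/(n+1); the add-one estimator $(1+\#\{sim \ge obs\})/(n_{reps}+1)$ never returns 0, keeping ranks stable |
| `n_s` | `gd_scan` conditional/linkage modes | 20 | inheritance vectors sampled per family given genotypes; $R'\Phi R$ is averaged over them (a Rao-Blackwellized plug-in for the unobservable $S_\tau$) |
| `exact_bits` | `sample_s_given_genotypes` | 20 | below this total of founder-allele + meiosis bits the sampler enumerates exactly instead of rejecting |
| `max_bits` | `enumerate_inheritance_vectors` | 24 | a hard cap: enumeration is $2^{bits}$ |

## The synthetic generator

`generate_cohort()` is the package's study-condition generator, not a mere
fixture: families from a template (trio, two-generation with $k$ children,
or a 3-generation 8-person family with 4 founders), SNPs gene-dropped
independently at frequencies drawn from `maf_range`, and the trait built
from the linear model above plus an optional shared family effect and
Gaussian noise. Defaults emulate a blood-pressure-like trait: baseline 110
mmHg, 0.4 mmHg/year of age, 5 mmHg for male sex, a 0.05 mmHg/year
interaction, noise SD 10 mmHg, hypertension above 140 mmHg, medication
effect −10 mmHg. Ages are uniform within generation bands (60–80, 35–55,
10–30 years); medication is Bernoulli(½) *among hypertensives only*, so
the medication effect is estimable without confounding by trait level —
exactly the situation `adjust_bpmed()` is designed for.

What it deliberately does **not** emulate: linkage disequilibrium (SNPs are
independent, so clustering of association signals around causal loci cannot
be studied), population stratification, genotyping error, missing data,
X-linked inheritance, or repeated trait measurements. Passing calibration
and power checks on these cohorts therefore demonstrates the correctness of
the statistics under the stated model, not robustness to the artefacts of
real cohort data.

## Numerical choices

* **Exactness tolerances.** The identities $E[\Phi] = 4\Psi$,
  $E[u] = 0$, and the match between analytic variances and full
  enumeration are exact up to floating point; the suite asserts 1e-12
  (absolute) and 1e-10 (relative) respectively. The decomposition product
  identity is algebraic and asserted to 1e-10 relative.
* **Untestable, never NaN.** Variances within `1e-12 · max(1, ΣR²)` of
  zero (residuals numerically zero, doses in the covariate span,
  monomorphic loci) yield a flagged result with `p = NA`; division never
  produces NaN or p-values of exactly 0.
* **Canonical bit order.** Meiosis bits are ordered by non-founder in
  topological order, paternal gamete before maternal; founder allele slots
  by founder in the same order. This fixes the meaning of a seed and the
  enumeration order everywhere.
* **Per-locus complete cases.** An individual missing a dose at a SNP is
  dropped for that SNP and the trait model is *refit* on the remaining
  individuals, so $\sum R_i = 0$ and the $R'JR = 0$ cancellation hold
  exactly at every locus; the effective n is recorded per SNP.
* **Exact-over-approximate at small scale.** Conditioning on genotypes
  uses exact enumeration weighting whenever the state space is small
  (≤ 2^20 joint bits by default) and falls back to rejection sampling with
  an explicit attempt budget (default 10^6) and a named failure reporting
  the acceptance rate; a Mendelian-inconsistent observation is detected as
  an all-zero likelihood and reported as such, not as a sampling failure.
* **Tie handling.** p-value ranks use mid-ranks (`rank(ties = "average")`),
  so tied SNPs share fractional ranks such as 1.5 and ranks always sum to
  $n(n+1)/2$; relative rank is rank/n × 100.
* **HWE subset.** The Hardy-Weinberg test needs unrelated individuals;
  `gd_scan` defaults to the pedigree founders and accepts an explicit
  unrelated-ids list. Pearson's statistic is used without continuity
  correction.
* **Medication covariates.** The hypertensive-only regression estimating
  the medication effect includes AGE, SEX and AGE:SEX alongside the
  medication indicator by default (configurable). The AGE:SEX column is the
  elementwise product of AGE and 0/1 SEX; age centering is available but
  off by default.

## Verification strategy and problem sizes

The suite cross-checks every analytic formula against an independent
route: kinship recursion vs. enumeration of IBD matrices; analytic
variances vs. exact enumeration of founder alleles × inheritance vectors
(trio, nuclear family, 3-generation 8-person family) and vs. 50,000
Monte-Carlo gene drops (3% tolerance); sampler posteriors vs.
enumeration-weighted exact posteriors. Calibration uses 2,000 null traits
on 20 three-generation families (160 individuals), checking the 5%
rejection rate against [0.04, 0.06]; power uses a causal SNP of
standardized effect 0.3 (MAF pinned at 0.3) among 500 null SNPs on the same
pedigree set, 20 repeats, median causal rank ≤ 10. These sizes were chosen
to make binomial Monte-Carlo error small relative to the tolerance checked
while keeping the full suite runnable in well under a minute per
experiment.

## Known limitations

* The $\chi^2_1$ approximation degrades in the extreme tail; very small
  p-values are approximate (though their ranks are stable). No saddlepoint
  or exact-tail option is provided.
* Conditional machinery is exact-at-small-scale by design; it does not
  replace MCMC samplers over dense marker data for large pedigrees, and
  the enumeration/rejection caps will refuse rather than silently
  approximate.
* Single trait measurement per individual; no longitudinal modelling.
* No principal-component computation for stratification — PCs computed
  elsewhere can be passed as additional covariate columns.
* Estimating $\beta_\tau$ itself is out of scope: these are score tests.
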