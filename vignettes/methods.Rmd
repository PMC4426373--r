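---
title: "Quantitative-genetic models for migratory life history: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative-genetic models for migratory life history: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`smoltqg` implements the statistical machinery for a pedigree-based
quantitative-genetic analysis of migration-related traits in rainbow and
steelhead trout (*Oncorhynchus mykiss*): additive relationship matrices,
Gaussian animal models by REML, Bayesian logit-threshold animal models for
the binary life-history classifications (smolt vs. not, mature vs. not),
geometric morphometrics of 13-landmark body shapes, life-history class
statistics, and a discriminant classifier. A synthetic-data module simulates
the whole study design so that every stage can be exercised and validated
without any external data. This vignette explains the models, the numerical
choices, and the places where the design was genuinely open.

## The animal model

Every quantitative trait is modelled as

y = Xb + Z_f u_f + Z_m u_m + Z_s u_s + Z_a a + e,

where fixed effects (`generation`, `cross_type`, and for relative warps a
`CentroidSize` covariate) absorb cohort and rearing-environment differences,
`u_f` is the full-sib family rearing-tank ("micro") effect, `u_m`/`u_s` are
maternal/paternal environment effects, and `a` is the additive genetic
effect (breeding value) with Var(a) = V_A A. The numerator relationship
matrix A is built recursively from the pedigree (diagonal 1 + F_i); its
sparse inverse uses Henderson's per-individual rules with
Mendelian-sampling variances corrected for parental inbreeding, with F_i
computed by an ancestor-traversal algorithm so the dense matrix is never
needed. Founders are taken to be non-inbred and mutually unrelated, and
unknown parents are treated as founder links.

Narrow-sense heritability is h² = V_A / V_P with V_P the sum of all fitted
variance components; the maternal proportion is m² = V_m / V_P. Genetic
correlations come from bivariate fits as r_A = COV_A / sqrt(V_A1 V_A2).

## REML estimation

Variance components are estimated by average-information (AI) REML on a
general linear covariance structure V(θ) = Σ_c θ_c K_c, which covers the
univariate components and, in bivariate fits, the genetic covariance, the
per-trait residuals, and the residual covariance of individuals measured for
both traits. Numerical choices:

* AI updates with step-halving; when the AI direction fails, a scaled
  gradient (EM-flavoured) step is taken instead. A pure-EM mode exists and
  is used in tests to confirm both iterations find the same optimum.
* Convergence at relative log-likelihood change < 1e-8 and maximum scaled
  parameter change < 1e-6, with a stall detector for boundary-singular
  optima (e.g. perfectly correlated trait pairs) where the likelihood is
  flat while parameters creep along the boundary.
* Variances are kept nonnegative by projection to a small positive floor;
  components that finish on the floor are reported as 0 with a boundary
  flag. A diagonal ridge of 1e-8 times the phenotypic variance keeps
  boundary-singular V evaluable; it is orders of magnitude below the
  estimates' precision.
* The AI step is capped in norm so an ill-conditioned information matrix
  cannot propose unrecoverable jumps.
* Standard errors come from the inverse AI matrix; h² and m² standard
  errors use the delta method.
* A trait paired with an exact copy of itself (or any perfectly correlated
  pair) makes the bivariate model unidentified; this is detected and the
  implied degenerate answer (r_A = ±1) is returned from a univariate fit,
  with a `degenerate_pair` flag.

Fixed effects are tested with incremental Wald F statistics; the
denominator degrees of freedom use the residual approximation n - rank(X),
which can differ from proprietary mixed-model software's adjusted
denominators — p-values for small or strongly unbalanced designs should be
read accordingly. Random effects are tested by likelihood-ratio tests
against a chi-square with 1 df; because the null value lies on the boundary
of the parameter space this is conservative, which the acceptance tests
verify empirically.

Listwise deletion is applied per model, so per-trait sample sizes vary
with trait missingness, as they do in real collections.

## Bayesian threshold models for binary life history

Binary life-history traits are analysed on the liability scale with a logit
link: the latent liability is l = Xb + Zu + e with e ~ N(0, 1) (the
residual variance is fixed at 1 and never sampled — the draws record the
constant) and P(y = 1 | l) = logistic(l). The heritability on this scale is

h² = V_A / (V_f + V_m + V_s + V_A + V_R + π²/3),

the π²/3 being the variance of the logistic link and V_R = 1.

The sampler uses Pólya-Gamma data augmentation, which makes every
conditional conjugate. Beyond the textbook Gibbs updates, two design
choices matter for mixing:

* Variance components are updated by random-walk Metropolis on the log
  scale against the *collapsed* posterior in which the location effects,
  random effects, and (for binary traits) the liabilities are all
  integrated out analytically via the mixed-model equations, conditional on
  the Pólya-Gamma weights. The proposal scale adapts toward ~35%
  acceptance during burn-in and is then frozen, so retained draws come from
  a fixed kernel.
* An ancillarity-sufficiency interweaving step rescales each random term
  and its standard deviation jointly (u = s·w with w held fixed), with a
  Metropolis correction for the prior. This breaks the near-absorbing
  behaviour of centered conditional draws when a variance visits zero.

The mixed-model-equation coefficient matrix is assembled thousands of
times with a fixed sparsity pattern, so the pattern is templated once and
only the numeric values are refreshed; the per-observation weights map to
the W'R⁻¹W entries through a precomputed sparse operator. The correctness
of the collapsed evaluation is checked in the tests against a dense
restricted-likelihood computation, and the sampler's invariant
distribution is checked against exact numerical quadrature on a small
binary mixed model.

Priors are inverse-gamma on each variance with scale V = V_P/(k+1) (the
observed-scale phenotypic variance divided equally among the k random terms
plus residual) and degree of belief ν. The default is ν = 0.002, the
conventional "vague" choice. **An important limitation**: for binary traits
with an individual-level animal effect, the marginal likelihood of V_A
flattens as V_A grows (sufficiently large liabilities saturate the
logistic), so with near-flat priors the posterior upper tail is extremely
heavy at moderate sample sizes. At the full study scale (~15,000
classified fish in families of 88–137) the likelihood dominates; at
reduced sizes it does not. The package therefore leaves the prior fully
configurable, and the test fixtures follow the rule "use the weakest prior
whose posterior on V_A is integrably well-behaved at the fixture's sample
size", which at roughly a thousand classified fish means ν = 2 (ν = 1
still leaves several percent of prior mass in the flat-likelihood region
above V_A ≈ 100, and chains then legitimately spend long stretches there);
the vague default remains for full-scale use. Even so, at a few thousand
observations the posterior of
the liability h² is genuinely diffuse: credible intervals are honest but
wide, and the posterior mode is a poor point summary (it tends to sit near
the upper end). Tests are therefore designed around HPD coverage, not
mode accuracy, and the vague-prior sensitivity check is run on a Gaussian
animal model, where the posterior is data-dominated at test sizes.

Posterior summaries: modes come from a Gaussian-kernel density estimate
with Silverman's rule-of-thumb bandwidth (configurable); a `multimodal`
attribute flags secondary peaks above half the main peak. HPD intervals
use the sorted-window algorithm (narrowest contiguous interval). Chain
quality is reported as lag-1 autocorrelation of retained draws with a
pass mark of 0.1. DIC is computed as the mean posterior
deviance plus the effective parameter count pD; for binary models the
deviance is conditional on the latent liabilities (and pD uses their
posterior mean), a convention that must be held fixed when comparing
models.

The bivariate Gaussian+binary sampler gives the two traits' additive
effects a full 2×2 covariance matrix with an inverse-Wishart prior
(ν_G = 2.002 by default) and conjugate updates; environmental terms are
trait-specific and independent, and the cross-trait *residual* covariance
is fixed at zero — the genetic covariance is identified through the
pedigree. When the two traits share residual-level dependence beyond
genetics (as mutually exclusive classifications do), r_A estimates absorb
it; the synthetic generator's default regime (independent residuals)
matches the assumption.

## Geometric morphometrics

Shapes are 13 two-dimensional landmarks per fish. Centroid size is the
square root of summed squared distances to the centroid. Generalized
Procrustes analysis centres each configuration, scales it to unit centroid
size, and iteratively rotates configurations to the updating consensus
(tolerance 1e-10 on the consensus RMS change, at most 100 iterations;
rotations only, no reflections).

Partial warps come from the thin-plate-spline bending-energy matrix of the
consensus (kernel r² log r²): its k−3 non-trivial eigenvectors give 2k−6
non-uniform scores per individual, and a 2-dimensional uniform (affine)
component is added as an orthonormal basis of the complement of the
similarity directions and the non-uniform space within the tangent space,
for 2k−4 = 22 scores from 13 landmarks. Relative warps are the principal
components of the partial-warp scores with weight α = 0 (plain PCA) —
the choice that makes 22 orthogonal axes an ordinary PCA and matches the
reported axis count; scores are multiplied by 1000 after the PCA, and the
sign of each axis is fixed so its largest-magnitude loading is positive
(signs are intrinsically arbitrary; correlations downstream are
reproducible but may be globally flipped relative to other software).
The first relative warp can be excluded (or any set of warps) without
renumbering the rest, mirroring the treatment of a warp judged to be an
anesthesia artifact in the source analysis.

## Synthetic data

The generator is the package's test bed and emulates the study design:

* Pedigree: 73 wild founders; 75 F1 full/half-sib families (mean 88
  offspring) of cross types A×A, A×R, R×A, R×R; 69 F2 families (mean 137)
  including AR×AR and RA×RA intercrosses whose parents are F1 fish from
  A×R / R×A families. Family sizes are negative-binomial (dispersion 8,
  chosen to give a realistic spread around the design means); half-sib
  structure comes from parent pools smaller than family counts (42/31 in
  F1, 41/53 in F2, the design dam/sire counts).
* Breeding values follow the pedigree exactly: founders N(0, G),
  non-founders parent-average plus Mendelian sampling with covariance
  G/2 · (1 − (F_s + F_d)/2).
* Phenotypes add fixed generation/cross-type shifts, family, maternal and
  paternal effects, the breeding value, and Gaussian residuals, with
  configurable missingness (2% by default, so per-trait sample sizes vary as
  they do in real collections).
* Life history comes from one shared liability with logistic residuals
  (variance π²/3), thresholded in both tails: smolt above the upper
  threshold, mature below the lower one, with thresholds solved to hit the
  configured prevalences (defaults 71.6% smolt, 12.7% mature) and a 4% indeterminate
  fraction assigned within the middle class. One shared liability makes
  LHSmolt/LHMature mutually exclusive and genetically anticorrelated near
  −1, the regime such mutually exclusive classifications occupy, and logistic residuals make
  the logit-scale h² formula exactly the generator's parameter.
* Landmarks are a fish-outline consensus plus Gaussian deviations along
  orthonormal tangent-space axes with configured variances, disguised by
  random rotation, translation and log-normal size (mean 1800 units,
  CV 0.35, a realistic centroid-size scale for juvenile fish images).

What the generator does *not* emulate: selection or mortality between
measurement ages, genotype-environment interaction, measurement error in
landmark placement correlated across landmarks, or non-additive genetic
variance. Passing tests therefore validate the estimation machinery, not
the biological completeness of the model.

## Problem sizes used by the test suite

The full study (16,139 fish) is emulated at reduced sizes so the whole
suite runs on one CPU in minutes: relationship-matrix checks use 20 random
pedigrees of 30–100 individuals against a 200,000-replicate gene-dropping
oracle; REML recovery uses a study-shaped pedigree of ~340 phenotyped fish
with 50 replicates at each of h² ∈ {0.2, 0.4, 0.6}; bivariate recovery
uses ~390 fish per trait; the threshold-model recovery uses 9 families at
the study's real family sizes (88/137; ~1000 fish) with 16,000-iteration
chains and 20 replicates; the LRT null calibration uses 300 replicates of
~180 fish. Chain-length defaults for real analyses remain at the
100,000/10,000 scale with the study's preset (1.1M iterations, burn-in
100,000, thinning 1000) available for the binary traits.

## Known limitations

* Binary-trait posteriors at reduced sample sizes are prior-sensitive and
  diffuse (see above); report HPDs, not just modes.
* Wald denominator df are a residual approximation.
* The dense REML path is intended for up to a few thousand observations;
  larger analyses should use the sparse relationship inverse with the
  Bayesian sampler, which scales with pedigree sparsity.
* Measurement ages use nominal month lengths (30.44 d) unless individual
  ages are supplied; derived growth rates inherit this approximation, and
  the choice is recorded in the `age_source` attribute.
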