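---
title: "Testing environmental filtering with three criteria: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing environmental filtering with three criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the decision rule

Urban land cover changes the resources and microclimates available to
cavity-nesting bees and wasps. If urbanization *filters* these communities —
suppressing species whose traits do not suit a site's environment — three
things must be observable at once:

1. **Criterion I.** Co-occurring species are more functionally similar than
   a community null model expects (trait clustering).
2. **Criterion II.** The degree of clustering varies along the urbanization
   gradient.
3. **Criterion III.** Species traits covary with environmental variables
   through the abundance table (a significant three-table association).

Each criterion alone has alternative explanations (e.g. clustering can arise
from weak competition plus shared habitat preferences), so the package's
verdict is the conjunction: `filtering_supported` only when all three tests
reject at a single global alpha (default 0.05).

## Criterion I: ses.MFD against the frequency null

Functional distance is classic Gower over mixed traits: continuous traits
contribute `|x_i − x_j| / range`, nominal traits contribute a 0/1 mismatch,
and the distance is the weight-averaged contribution, bounded in [0, 1].
Design choices where the convention was genuinely open:

* **Rank and count traits** (trophic rank, number of nesting materials) are
  declared *continuous* by default so their ordering information survives;
  switching them to `nominal` in the `trait_table()` type specification
  recovers the pure-mismatch coding.
* **Multi-material nesters** are coded as a single nominal level per species
  (the level set is whatever the table contains); a per-material binary
  expansion can be emulated by adding binary columns.
* **Zero-range continuous traits** contribute 0 with a warning rather than
  an error; species with *missing* traits must be removed by the study
  filters first — the distance code refuses pairwise deletion.

Per site, `MFD` is the abundance-weighted mean pairwise distance over the
species present (at least two required; otherwise the site is flagged
`undefined`, never silently dropped). The null model shuffles each species'
abundance vector across sites independently, preserving the species'
occupancy count and abundance multiset but not per-site richness. Because a
shuffle can leave a site with fewer than two species, such draws are recorded
as missing for that site and the null moments use the available draws
(`n_null_used` in the output).

The two-tailed p is the add-one permutation rank, ties counted in both
tails: `p = 2·min(1 + #{null ≤ obs}, 1 + #{null ≥ obs})/(n_null + 1)`,
capped at 1. This version is exactly uniform under the null and can never
return 0. A normal-approximation p (`2·pnorm(−|ses|)`) is reported alongside
for comparison, since published analyses do not always say which was used.

## Criterion II: regression, EMMs, Moran's I

The design is `ses.MFD ~ open_green + impervious + ugs_type` with covariates
on the percent scale (0–100), so slopes read "per percentage point" and match
the magnitudes conventionally reported. Closed-green cover is screened out
before modelling (default threshold |r| ≥ 0.7 against any other gradient;
the victim is configurable) because impervious and closed-green cover are
strongly negatively collinear in urban mosaics.

Estimated marginal means fix covariates at their unweighted observed means
and vary the UGS factor; contrast SEs come from the coefficient covariance
and the default multiplicity adjustment is Tukey's studentized range (with
`k` = number of levels and the residual df), matching the convention of
pairwise EMM comparisons in unbalanced designs; Bonferroni and unadjusted
are available.

Moran's *I* on residuals uses the normality-assumption variance and a
two-tailed z test. The original survey's coordinates are withheld as
sensitive, so the weight builder is generic: k-nearest-neighbour (default
k = 8) or inverse-distance, row-standardized. Note that `ape::Moran.I`, used
as a test oracle for the statistic, computes the *randomization* (kurtosis)
variance — the two variances agree only approximately, which is why the test
suite checks the observed statistic against ape but the standard deviation
against a Monte-Carlo oracle over Gaussian draws.

## Criterion III: RLQ and the sequential test

The three tables are coupled in the standard duality-diagram way: the
abundance table L is analysed by correspondence analysis; its row masses
weight a standardization of the environment table R (weighted z-scores,
identity column metric) and its column masses weight a Hill–Smith coding of
the trait table Q (weighted z-scores for quantitative columns;
`indicator/p_m − 1` with column metric `p_m` for each nominal level). The
RLQ eigenvalues are the squared singular values of
`D_mR^{1/2} (Z_R' D_r L₀ D_c Z_Q) D_mQ^{1/2}`; their sum (total co-inertia)
is the permutation statistic. Two reduction properties pin the Hill–Smith
convention down without reference to any implementation's internals: with
all-quantitative columns it equals the weighted PCA transform, and with
all-nominal columns the triplet's eigenvalues equal multiple correspondence
analysis eigenvalues up to the factor K (number of variables), because MCA
conventionally divides each variable block's column weights by K.

Permutation models: Model 2 permutes the pairing of L's columns with Q's
rows (trait link); Model 4 permutes the pairing of L's rows with R
(environment link). The CA masses stay attached to L, so each permuted
statistic re-standardizes R or Q under the re-paired weights. The p-values
are one-tailed upper with the add-one correction, and the sequential
decision is `max(p₂, p₄)` — both links must reject. The pairwise
fourth-corner post-hoc analysis is out of scope (the sequential test is the
gate for it); the single-pair fourth-corner covariance is exposed only
because with one quantitative variable on each side the leading RLQ
eigenvalue equals its square, which makes it a sharp testing oracle.

## Study filters

The analysis-ready tables come from explicit, logged filtering: species
lacking body size, configured exclusions, and species never observed are
dropped first; then sites sampled in fewer than the required years (default
3), uncolonized sites, and sites below the richness minimum (2 for
Criterion I, since pairwise distances need two species; 1 for
Criterion III). Species filters run before site filters deliberately: a site
reduced to one species by a species drop then counts as a singleton, which
reproduces the arithmetic of the motivating study's 136-site / 46-species
Criterion-I set versus its 140-site Criterion-III set. Every removal carries
exactly one reason (the first matching rule).

## The synthetic world

`simulation_spec()` states the world the tests assume:

* 192 sites of four UGS types at relative frequencies 13/67/42/14; 46
  species with the seven-trait schema above.
* Impervious cover is Beta(1.6, 1.6) scaled to [0, 0.97] (the observed
  support of the gradient); closed-green cover is drawn through a Gaussian
  copula and clipped to the cover budget, with the *latent* correlation
  calibrated by bisection so the *achieved* impervious/closed correlation is
  the configured −0.9 (clipping would otherwise strengthen it); open green
  is the remainder, so non-water proportions sum to 1.
* Each species has a baseline log-abundance `a_i ~ N(log 2, 0.8²)` and an
  environmental optimum `μ_i ∈ [0, 1]` coupled to log body size (Gaussian
  copula, default correlation 0.8) so that exactly one trait is filterable.
* Expected abundance is `λ_is = exp(a_i − β_f (μ_i − e_s)²)` with `e_s` the
  site's impervious proportion; counts are Poisson, then occupancy is
  thinned by independent Bernoulli retention per cell, calibrated by
  bisection on the expected richness to average ≈ 6 species per site
  (observed range ~1–13, matching trap-nest sparsity).

With `β_f = 0`, each species' column is i.i.d. across sites — exactly the
exchangeability the frequency null assumes — so the null-calibration
acceptance test (ses mean ≈ 0, SD ≈ 1, 5% two-tailed rejections, uniform p)
checks the inference machinery, not a tuned generator. What the generator
does **not** emulate: spatial autocorrelation of sites, interannual
dynamics, parasitoid guilds, and multi-trait filtering. A green test
therefore establishes correctness of the computations under the stated
world, not robustness to those complications.

Two empirical properties of this world are worth knowing when reading the
test suite. First, because the filtered trait is one of seven, per-site
clustering (Criterion I) and the Model-2 trait link are heavily diluted:
power of the sequential test rises steeply from `β_f = 0` to 5 and then
saturates near 0.3 at the 48-site/16-species test size (Model 4 alone is
near 1.0; Model 2 is the bottleneck). The power-monotonicity acceptance
check therefore reuses the same study seeds across strengths (paired
batches), which removes study-level noise from the comparison. Second, the
parameter-recovery check for negative mean ses.MFD is run at the full
192×46 default size, where the species-pool noise that dominates small
communities averages out.

## Numerical choices

* Permutation p-values always use add-one corrections; ties count toward
  both tails (conservative).
* `ses` is undefined (NA, class `undefined`) when the null SD is zero, e.g.
  for constant distance matrices.
* OLS uses QR least squares; the coefficient covariance is
  `σ̂²(X'X)⁻¹` via Cholesky; rank-deficient designs error naming the
  collinear columns rather than dropping them silently.
* CA eigenvalues below 1e-12 are treated as null axes.
* All randomness flows from one root seed per entry point; sub-stages of
  `run_all()` derive fixed offsets from it, so a rerun with the same
  configuration is byte-identical.
* Buffer extraction uses the pixel-centre-in-circle rule; the error versus
  exact area weighting is O(pixel/radius) and negligible at the intended
  0.6 m-pixel / 250 m-radius regime. Water pixels leave both numerator and
  denominator, so non-water proportions sum to 1.

## Known limitations

* The Criterion-II "met" rule is operationalized as a significant
  impervious-surface slope; the qualitative published judgement ("is
  clustering associated with the gradient?") has no unique formalization.
  Similarly Criterion I uses a one-sided binomial test of the significant
  fraction against alpha.
* Only the community-matrix null is implemented (no trait-shuffle,
  independent-swap or trial-swap nulls) — deliberate, since abundance-
  weighted indices make the matrix-based null the informative one here.
* The Moran weight scheme behind the published residual diagnostics is not
  recoverable (coordinates withheld); results with knn vs inverse-distance
  weights can differ, and both are exposed.
* Replication of the published headline numbers (site/species counts,
  clustering counts, coefficients, sequential p-values) requires the
  archived data deposit and is therefore not part of the offline test
  suite.
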