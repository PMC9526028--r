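# traitfilter

Tests of whether urbanization acts as an **environmental filter** on
cavity-nesting bee and wasp communities sampled with trap nests. A filter, in
the community-assembly sense, is an environment that depresses the growth of
species whose traits do not suit it, leaving communities of ecologically
similar species. `traitfilter` implements the three criteria that must *all*
hold before filtering can be claimed, plus a synthetic-study generator with a
tunable filtering strength so every stage can be validated against known
ground truth.

## The three criteria

**Criterion I — trait clustering.** For each site, functional alpha diversity
is the abundance-weighted mean pairwise functional distance over the species
present,

    MFD = Σ_{i<j} d_ij a_i a_j / Σ_{i<j} a_i a_j ,

where `d_ij` is the Gower distance between species *i* and *j* over seven
mixed-type traits (body size as intertegular span in mm, native status, diet
type, diet specialization, trophic rank, nesting material, number of nesting
materials) and `a_i` are brood-cell counts. Observed MFD is compared with a
frequency-preserving null model — each species' abundances are shuffled
across sites, conserving that species' occupancy and abundance values — via
the standardized effect size

    ses.MFD = (MFD_obs − mean(MFD_null)) / sd(MFD_null) .

`ses.MFD < 0` indicates clustering; significance is a two-tailed permutation
test (4999 randomizations in the study configuration).

**Criterion II — clustering tracks the gradient.** OLS regression
`ses.MFD ~ % open green + % impervious + UGS type` (UGS = urban green space:
community garden, home garden, public park, green roof), with
estimated-marginal-mean Tukey contrasts between UGS types, a collinearity
screen that removes closed-green cover (it tracks impervious cover, target
r ≈ −0.9), and Moran's *I* on residuals as a spatial diagnostic.

**Criterion III — traits covary with environment.** RLQ ordination couples
the environment table R (land-cover at a buffer scale), the abundance table L
and the trait table Q through a generalized SVD of the cross matrix
`Z_R' D_r L₀ D_c Z_Q` (CA masses `D_r`, `D_c`; weighted PCA of R; Hill–Smith
coding of Q). Significance uses ter Braak's sequential test: Model 2 permutes
species (trait link), Model 4 permutes sites (environment link), the combined
p is `max(p₂, p₄)` — both links must reject (49,999 permutations in the study
configuration).

## Worked example

```r
library(traitfilter)
cfg <- run_config(sim = simulation_spec(beta_f = 20),   # strong filtering
                  n_null = 999, n_perm = 999, seed = 42)
report <- run_all(cfg)
cat(report_render(report), sep = "\n")
```

```
Three-criterion environmental filtering report
alpha = 0.05, scale = 250 m, seed = 42

Criterion I (trait clustering): 112/188 sites ses<0, 9 significantly clustered, 2 overdispersed -> not met
Criterion II (clustering ~ gradient): beta_imp = 0.005286 (p = 0.204), Moran's I = -0.00703 (p = 0.962) -> not met
Criterion III (trait-environment association): p_model2 = 0.001, p_model4 = 0.001, combined = 0.001 -> MET

Verdict: filtering_not_supported
```

Even at strong filtering strength (`beta_f = 20`), only the RLQ criterion
detects the trait–environment association decisively here: the filtered trait
(body size) is one of seven entering the Gower distance, so per-site
clustering is diluted — exactly the kind of behaviour the conjunction rule is
designed to expose. Per-site results live in `report$criterion1$ses`:

```
   site_id   mfd_obs         ses         p   classification
1 site_001 0.4680419  0.40598589 0.5969543 overdispersed_ns
2 site_002 0.3939890 -0.71221739 0.3983740     clustered_ns
```

A thin CLI wraps the same pipeline:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","traitfilter.R",package="traitfilter"))')" \
    all --seed 1 --n-null 199 --n-perm 199 --outdir out/
```

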