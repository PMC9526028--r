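Package: traitfilter
Title: Three-Criterion Environmental Filtering Tests for Trap-Nest Communities
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for testing whether urbanization acts as an environmental
    filter on cavity-nesting bee and wasp communities sampled with trap nests.
    Implements the three-criterion workflow: (I) trait clustering via the
    standardized effect size of abundance-weighted mean pairwise functional
    distance (ses.MFD) against a frequency-preserving community null model,
    with Gower distances over mixed traits; (II) linear regression of ses.MFD
    on land-cover gradients and green-space type, with estimated-marginal-mean
    pairwise contrasts, collinearity screening and Moran's I residual
    diagnostics; (III) RLQ three-table ordination with the Model-2/Model-4
    sequential permutation tests. Includes a synthetic study generator with a
    tunable trait-environment filtering strength, and a simplified land-cover
    buffer extraction for site covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ade4,
    cluster,
    ape,
    withr,
    optparse
Config/testthat/edition: 3
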