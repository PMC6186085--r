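Package: p53flow
Title: Logical Steady-State and Score-Flow Analysis of Signed p53 Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Qualitative and semi-quantitative superimposition of transcriptomic
    data onto signed, directed p53 interaction networks. Implements three-valued
    logical steady-state analysis (LSSA) with per-node change predictions between
    simulation scenarios, signal-transduction score-flow analysis (STSFA) that
    propagates expression-derived node scores along signed edges, validation of
    model predictions against differential-expression calls with a
    correct/small/large-error statistic and an exact binomial significance value,
    per-patient score-based stratification with Pearson survival correlations and
    univariate Cox proportional-hazards regression, tumour-stage comparisons by
    one-way ANOVA, and seeded synthetic-data generators (networks, two-condition
    expression experiments with controlled concordance, survival cohorts) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
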