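---
title: "Methods: logical steady states, score flow, and score-based stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: logical steady states, score flow, and score-based stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53flow)
```

# The modelling problem

Signed interaction networks of the p53 pathway describe genes, stimuli and
cellular outcomes as nodes and activating/inhibiting interactions as
directed edges. Such a network is a predictive model: perturbing its
DNA-damage input, or deleting the p53 node, implies qualitative changes in
downstream node activity that can be checked against transcriptomic data.
`p53flow` implements the full superimposition workflow: predict per-node
changes between two simulation scenarios, call per-gene changes from
expression data, score how often the two agree, and carry per-patient node
scores into survival and tumour-stage analyses.

A *scenario* has two controllable dimensions: p53 genotype (`wt` or `null`)
and the DNA-damage input (`ON`/`OFF`). The damage input stands for a
DNA-damaging exposure such as etoposide or gemcitabine; the `null` genotype
mimics loss-of-function mutation.

# Three-valued logical steady states

Each node takes a state in {0 (inactive), NaN (undetermined), 1 (active)}.
The input node is clamped by the damage flag; under `null` the p53 node is
clamped to 0. Knockout is implemented as a clamp rather than node deletion:
downstream logic sees a permanently inactive node, node indexing stays
stable, and for signed-graph logic the two are behaviourally identical.

Every regulated node is updated as

```
state(v) = OR(activator states)  AND  NOT OR(inhibitor states)
```

with Kleene three-valued connectives (NaN = unknown; `OR` of an empty set
is 0, so a node whose known regulators are all inactive is inactive).
Source nodes other than the input have no regulators and no evidence either
way; they stay NaN rather than defaulting to 0. The steady state is the
least fixpoint of this update started from all-NaN. Because the update is
monotone in the information ordering (NaN below both 0 and 1), the fixpoint
exists, is unique, and is reached in at most one sweep per node; cycles
that are not forced by their inputs — e.g. the TP53–MDM2 negative feedback
loop when p53 is intact — resolve to NaN, which is the honest answer for a
steady-state formalism without timing information.

One design point deserves emphasis. An *inhibitor-dominant* phrasing of the
rule ("active if some activator is active and no inhibitor is active") is
not monotone: an inhibitor later resolving from unknown to active would
flip a determined state, and a plain negative-feedback loop then has no
fixpoint at all. The Kleene reading used here is the closest monotone
semantics — it differs only in being cautious when an inhibitor is still
unknown (the node stays undetermined instead of being declared active). The
choice is documented rather than claimed to be bit-identical to any
particular legacy implementation; all tests and oracles use it
consistently.

The prediction for node *i* between scenarios 1 and 2 is the nine-case
table over (S(i)₁, S(i)₂): any move toward activity (0→NaN, 0→1, NaN→1) is
E_mod = +1, any move away (1→NaN, 1→0, NaN→0) is −1, and the three
diagonal cases are 0. With NaN ranked between 0 and 1 this is simply the
sign of the rank change, and it is anti-symmetric under swapping the
scenarios.

# Score-flow analysis

The qualitative analysis discards expression magnitudes; the score-flow
analysis keeps them. Initial scores are `100 * log2(expression)` for mapped
genes (`log2(x + 1)` for counts; the factor 100, exposed as
`scale_factor`, is the conventional scaling that turns log-intensities into
integer-sized scores). The DNA-damage node is initialised with the mean of
the mapped scores when damage is ON and their minimum when OFF — the input
is maximally stimulated or baseline, on the scale of the data itself — and
unmapped nodes get the minimum mapped score.

Scores then flow along edges to the fixpoint

```
final(v) = clamp0( init(v) + sum over u->v of sign(u->v) * final(u) / outdeg(u) )
```

The three choices the flow heuristic has to make are explicit in
`stsfa_config()`:

* **normalisation** (`"outdegree"`, default): a node's influence is split
  equally over its outgoing edges, so total signal is conserved rather than
  amplified by fan-out; `"none"` sends the full score down every edge.
* **clamping** (`clamp_negative`, default `TRUE`): node activity cannot go
  negative; inhibition can at most silence a node.
* **damping** (`damping`, default 0.5): on cyclic networks the fixpoint is
  found by damped iteration `x <- (1 - d) x + d F(x)` started from the
  initial scores; on acyclic networks the solver instead evaluates nodes
  once in topological order, which is exact. The iteration stops when the
  maximum relative per-node change has stayed below `tolerance` (default
  1e-9) for ten consecutive iterations — the extra "polish" iterations push
  the remaining geometric tail of the error well below the step size — and
  raises an error with the residual if `max_iterations` (default
  `max(100, 10 |V|)`) is exhausted.

Between two scenarios, each gene's log₁₀ final-score fold change is
computed with a pseudocount of 1 (clamped zero scores must not produce
infinities). Genes strictly above the mean + SD of the fold-change
distribution are predicted up, strictly below mean − SD down, otherwise
unchanged. This classifier is deliberately relative: in a roughly Gaussian
fold-change distribution only ~16% of genes can fall in each tail, so most
predictions are "unchanged" and the analysis is conservative about calling
direction.

# Differential expression and validation

The experimental call E_exp uses the standard filtered-DE rule: +1 if
log₂FC ≥ log₂ 1.5 and raw p < 0.05, −1 for the mirrored case, 0 otherwise.
The fold-change bound is inclusive and the p-value strict; no
multiple-testing correction is applied because the validation statistic is
defined on raw-p filtered lists. On synthetic data the p-value comes from a
Welch two-sample t-test on log2 values — the analysis here sits downstream
of DE fitting, and externally computed DE tables (limma, edgeR, ...) can be
ingested directly, which preserves fidelity on real data. Degenerate cases
are made total: single-sample groups give a fold change but an undefined
p-value (and a 0 call); zero variance in both groups gives p = 1 when the
means are equal and p = 0 otherwise.

The per-gene error |E_mod − E_exp| ∈ {0, 1, 2} is labelled correct / small
error / large error. The significance of k correct among n genes is the
exact binomial point probability at success probability 1/3 — the
probability of that exact score if every gene independently landed in one
of three equiprobable classes — computed in log space. An upper-tail
variant P(X ≥ k) is available (`tail = "upper"`); the point mass is the
default because it is what the published validation tables for this kind of
analysis report (seven of eight published values reproduce it to printed
precision; the eighth appears to transpose two digits). The point-mass
computation is confirmed in the test suite against a brute-force
enumeration oracle.

# Survival and staging analyses

Per-patient score maps are computed with the same machinery (damage ON for
chemotherapy-treated patients, OFF otherwise; the p53 clamp from the
patient's TP53 status), and patients are stratified into the four TP53 ×
chemotherapy groups. Pearson correlation of a gene's score with survival
time in days ignores censoring — a documented limitation of that simple
screen — while the univariate Cox regression honours the event flag. If
the metadata has no event column every time is treated as an observed
death, with a loud warning, since silently inventing censoring would be
worse. The Cox fit itself is `survival::coxph()` with Breslow tie handling
(ties are rare at day resolution; Efron is switchable); the package reports
beta, HR = exp(beta), the 95% Wald interval and the Wald p-value, and
labels HR < 1 / > 1 as good / bad prognostic factors. The test suite
cross-checks the fit against an independent grid-search maximisation of
the partial likelihood.

Stage comparisons run a one-way ANOVA of each gene's scores across stages
with at least two patients (smaller stages are excluded and logged), with a
direction flag from the stage-4 vs stage-3 medians. A gene with identical
scores everywhere gets p = 1 — "no evidence of a difference" — rather than
an undefined statistic, keeping pipelines total.

# Synthetic data: what it does and does not emulate

The generators define the study conditions for all end-to-end tests.

`generate_expression_experiment()` emulates a two-condition cell-line
experiment over the network's genes: for each gene it computes E_mod
between the scenario pair, keeps it with probability `concordance` or
replaces it with one of the two other calls chosen uniformly, then draws
log2 expression with the implied group-mean difference. Defaults —
triplicate samples, within-group SD 0.25 on the log2 scale, a 2-fold
effect, concordance 0.75 — reflect a typical small microarray experiment
and the ~75% correct-prediction rates typical of this kind of model
superimposition. Because the discordant replacement is uniform over the
two wrong classes, the expected correct/small/large mix is analytic and
testable.

`generate_cohort()` emulates a surgical cohort with RNA-seq: default
composition 27/26/1/17 over wild-type/mutant × treated/untreated patients
(n = 71), per-patient counts around gene-specific baselines, survival
times exponential with hazard `base_hazard * exp(sum beta_g z_g)` over the
driver genes' *standardised* score-flow scores (so beta is per score SD
and comparable across genes), uniform censoring of a requested fraction,
and optional stage-4 expression shifts for designated genes. The scores
that drive survival are computed by the package's own scoring machinery,
so parameter-recovery tests exercise the full path.

What the generators do **not** emulate: probe-level microarray structure,
RNA-seq count dispersion and library-size effects, correlated gene-gene
expression beyond what network scoring induces, informative censoring, or
competing risks. Passing tests therefore demonstrate that the algorithms
are implemented correctly and recover known structure under clean
conditions — not that any particular biological claim holds on real data.

# Problem sizes and numerical choices

The test and acceptance runs use problem sizes chosen to make the
statistical checks sharp while staying comfortably interactive: 100 random
12-node acyclic networks for the logical-fixpoint oracle comparison,
20 random 25-node networks for the solver equivalence (agreement within
1e-6), ~220-gene networks for concordance recovery (99% binomial
intervals), a 500-patient cohort for Cox coefficient recovery (±0.15
around a true beta of 0.5), 1000 null genes for the Wald type-I-error and
ANOVA calibration checks (both ≈5%). All generators take explicit integer
seeds and are fully reproducible.

Remaining deliberate choices: case-sensitive exact gene-id matching (no
silent symbol aliasing; mapping failures are loud); duplicate identical
edges collapse with a warning while opposite-sign parallel edges are
retained (both occur in curated networks); the DNA-damage mean over mapped
genes includes the p53 node (only the input itself is excluded); DE tables
are restricted to model genes *before* computing score-flow fold-change
limits, so the mean ± SD limits are formed on the gene set actually being
validated.

# Known limitations

* The logical semantics is a documented reconstruction; legacy tools may
  handle cycles differently (e.g. resolving feedback by case-splitting
  rather than returning NaN).
* The score-flow heuristic's normalisation/clamping/damping choices are
  likewise reconstructions exposed as configuration, not a bit-exact port
  of any plugin.
* Pearson-vs-survival ignores censoring by design; interpret it as a
  ranking screen and rely on the Cox column for inference.
* The mean ± SD fold-change classifier adapts its thresholds to the
  comparison at hand; scores from different comparisons should not share
  limits.
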