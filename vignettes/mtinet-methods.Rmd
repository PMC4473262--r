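---
title: "Methods: metabolite-transcript interface networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolite-transcript interface networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Fasting blood carries two simultaneously measurable molecular layers:
serum metabolite concentrations, a footprint of whole-body metabolism, and
whole-blood transcript levels, dominated by white-blood-cell expression.
`mtinet` reconstructs the interface between them from population-cohort
data as a bipartite correlation network, and then interrogates that
network mechanistically (metabolic reaction distances), causally
(Mendelian randomization), functionally (pathway aggregation), at the
regulatory level (promoter motif enrichment), and clinically (lipid-trait
projection). Because the kind of cohort data this is designed for is
access-restricted, the package ships a synthetic-cohort generator with the
statistical structure every stage assumes, so the whole pipeline is
testable offline.

## Models and procedures

### Preprocessing

Metabolites with more than 50% missing values are excluded (strictly
greater than: a feature missing in exactly half of the samples is kept).
Observed concentrations are natural-log transformed — rank statistics
downstream are invariant to the base — and adjusted feature-by-feature by
ordinary least squares on intercept + age + sex, using each feature's
observed samples (complete-case per feature; the adjustment model for
missing data is not constrained by the data sources this emulates, so the
simplest defensible choice is made). Array probes mapping to the same gene
are collapsed to the probe with the largest `max |rho|` against any
metabolite; ties within `1e-12` break on the lexicographically smallest
probe ID so the collapse is deterministic. Significance thresholds
downstream still use the pre-collapse test count (the `m` argument of
`threshold_and_build()`), because all probe-level tests were in fact
performed.

### The bipartite network

Every metabolite x transcript pair is scored by Spearman rank correlation
on the samples where the metabolite is observed, with the two-sided
p-value from `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df. At the
cohort sizes this targets (hundreds of samples) the t approximation is
accurate far into the tail; pairs with fewer than 10 complete samples are
flagged and never thresholded. Benjamini–Hochberg control at FDR 0.01 over
the full test family defines the edge set; the implied absolute-rho cutoff
and a network-density curve (fraction of pairs above a cutoff grid, step
0.005) are reported so the threshold can be judged against the density
criterion used in co-expression practice. Replication in a second cohort
re-tests each mappable edge and reports nominal (p < 0.05) and
BH-FDR < 0.05 fractions, the FDR family being the tested edges.

### Mendelian randomization

For an edge and a direction, a SNP instrument for the exposure gives the
Wald ratio `beta_causal = beta(SNP->outcome) / beta(SNP->exposure)`, both
stages being OLS with age and sex. Instruments are screened by BH FDR 0.05
on their exposure association and LD-pruned on pairwise genotype r²,
greedily dropping the weaker-associated member of a violating pair.
Inference is by nonparametric bootstrap over individuals: both stages are
re-fit per replicate, the percentile interval gives the 95% CI (the CI
flavor is a package choice; percentile is the least parametric), and the
two-sided p is `2 * min(P(ratio <= 0), P(ratio >= 0))` floored at
`1/n_boot`. Replicates with `|beta_exposure| < 1e-8` are dropped; if they
exceed 5% the result is flagged unstable — the Wald ratio has no moments
when the instrument is weak, and a flag is more honest than a winsorized
number. BH q-values run across all tested (edge, direction) pairs.

### Reaction-step distances

A metabolic reconstruction is reduced before distance calculation:
compartment suffixes are stripped (configurable regex; Recon-style `_c` /
`[c]` by default) and same-base species merged, pure transport reactions
collapse to self-loops and are dropped, duplicate reactions (identical
participant sets) merge their gene sets, and currency metabolites — an
input list, not a hard-coded one — are deleted with all their incidences.
Distance between a metabolite and a gene is computed on the undirected
metabolite-reaction incidence graph as the minimal number of reactions
over any path to a reaction the gene catalyzes: 0 means direct reactant.
Unmapped endpoints give NA ("not mapped"), disconnected ones Inf. Boolean
gene-association logic is flattened to the gene set, and paths may
traverse reactions with no measured enzyme — the biology of interest is
proximity, not flux feasibility. Enrichment of network edges at short
distances uses one-tailed Fisher tests per distance and per cumulative
band; the cumulative test at the maximum finite distance is 1 by
construction, a useful self-check.

### Pathway aggregation (PIN)

Gene categories (GO-slim-like) and metabolite pathways (MP) are filtered
(roots and empty terms out; MPs need >= 2 metabolites). For each (GO, MP)
pair, members are *edge-constrained*: only transcripts with a network edge
into the partner MP and metabolites with an edge into the partner GO
enter the pair's aggregated z-score, the per-sample mean of member
z-scores (missing metabolite values fall back to the mean of observed
members, preserving the "average" semantics). Pair association is the
Spearman correlation of the two aggregated scores. The Bonferroni
denominator is the number of *testable* pairs and is recorded in the
output — the emulated study's printed cutoff does not reconstruct from
any natural family size, so the denominator is made explicit rather than
guessed. A second, ad-hoc stringent cutoff (`viz_p = 1e-11`) yields the
sparser visualization network, always a subset of the full PIN.

### Regulatory signatures

Promoter scanning itself is out of scope; the contract is a precomputed
gene x motif occurrence table over promoter windows (-2000..+200 bp
around the TSS). Gene sets are the transcript neighborhoods of metabolites
with degree >= 3, plus subpathway/superpathway unions of those
neighborhoods; each set's background is all remaining genes. The default
backend tests, per motif, the count of set genes with >= 1 occurrence
against the background by a one-sided hypergeometric test, with the
significance contract fixed at p <= 1e-7. Sharing matrices count
significant motifs common to set pairs at each level. A *triad* is a
metabolite M and a TF t whose transcript neighbors M while t's motif is
enriched in M's other neighbors — the TF gene is removed from its own
test set (and joins the background), otherwise the TF would vote for
itself.

### Phenotype projection

Each trait (HDL-C, LDL-C, TG, raw mg/dl) is regressed on each feature or
category score with age and sex; the node score is
`-log10(p) * sign(beta1)`. The feature-level Bonferroni denominator is the
number of features tested per trait (metabolites + transcripts): of the
two contradictory forms printed in the emulated study, the *value*
corroborated twice in its text corresponds to this family, so the value is
followed and the denominator recorded. Cross-trait structure is the
Spearman correlation of node scores between two traits over shared
network nodes.

## The synthetic world

`synth_config()` defaults *are* the emulated conditions: 712 individuals,
age truncated-normal 68.82 ± 4.31 on [55, 85], sexes ~1:1, log-normal
metabolite concentrations with per-feature MCAR missingness drawn from
[0.05, 0.6], HDL/LDL/TG rescaled to 55.8 ± 13.95 / 140.6 ± 35.97 /
132.64 ± 75.70 mg/dl. Correlation blocks come from a shared Gaussian
latent factor on the log scale, with latent Pearson
`r = 2 sin(pi * rho_s / 6)` so the *population Spearman* of a planted pair
equals `module_rho` exactly under bivariate normality; exponentiation to
concentrations changes neither ranks nor the target. Causal chains set
`exposure = beta_gx * G + N(0,1)` and `outcome = beta_xy * exposure +
N(0,1)`; SNPs are independent with MAF uniform on [0.1, 0.5] — no LD
structure, by design.

Two deliberate coherence choices:

* **Planted correlations are defined on the covariate-adjusted scale.**
  Age and sex effects are injected additively on every feature, which
  inflates raw-scale pair correlations by a shared-covariate term
  (~+0.06 at the defaults). The planted target refers to the latent block,
  which is exactly what survives the pipeline's own adjustment — tests
  measure it there.
* **Planted hub metabolites cap their missingness at 50%**, the filter
  threshold, so the planted truth cannot be silently deleted by the
  quality filter it is meant to pass through. One non-planted feature is
  still forced above 50% so the filter is always exercised.

What a green test does *not* establish: robustness to non-MCAR
missingness, LC-MS-like heteroscedastic noise, LD between instruments,
population stratification, or the fidelity of any real reconstruction —
the toy metabolic model has linear chains, two currency metabolites and
one duplicated compartment species, enough to exercise merging, currency
removal and distance semantics, not to imitate Recon's topology.

## Numerical choices

* BH is implemented with an explicit family size `m >= length(p)` (needed
  for pre-collapse families); verified against a quadratic brute-force
  oracle on 10^4 random vectors.
* Spearman p-values use the t approximation everywhere in the pipeline;
  exact enumeration appears only in test oracles.
* Probe-collapse ties break lexicographically; degenerate (constant)
  score vectors in the PIN are skipped and flagged, not scored.
* `|rho| = 1` maps to p ~ 0 through a machine-eps floor on `1 - rho^2`
  rather than a special case.
* The one-test-family choices (replication FDR over tested edges; PIN
  Bonferroni over testable pairs; phenotype Bonferroni over features per
  trait) are recorded in each function's output metadata.

## Known limitations

Single-instrument Wald ratios only (no MR-Egger/median, no multi-SNP
meta-analysis); no intra-omics networks (out of scope by design); the
promoter backend is a hit-table contract, not a scanner; SBML support is
the subset needed for species/reactions/gene associations/subsystems.
Under the default stated world the MR stage, like the study class it
emulates at n ~ 700, is under-powered for modest causal effects — the
type-I simulations verify calibration, not power.
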