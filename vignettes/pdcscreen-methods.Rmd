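---
title: "Methods behind pdcscreen: from raw plates to stable biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind pdcscreen: from raw plates to stable biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcscreen)
library(dplyr)
```

pdcscreen implements the analysis chain used in pharmacogenomic studies of
patient-derived tumor cell (PDC) drug screens: raw luminescence plates are
turned into per-(sample, drug) sensitivity scores, sample genomics into an
alteration matrix with molecular subtypes, and the two are crossed in
association screens and a bootstrapped elastic-net biomarker search. This
vignette explains each model, its assumptions, the tunable parameters, and
the choices made where the underlying procedures are conventionally left
under-specified.

## Dose-response model and AUC

Each drug is screened in a descending geometric dilution series — by
default seven fourfold steps from 20 µM down to 4.88 nM
(`make_dilution_series(20, 4, 7)`). Raw well signals are converted to
relative viability by dividing by the mean signal of the same plate's DMSO
vehicle wells, so viability is dimensionless and the DMSO wells average
exactly 1. Replicate treated wells are averaged on the viability scale
before fitting; per-condition duplicates are the norm on these plates, and
averaging (rather than pooling as extra points) keeps the per-curve
residual model homoscedastic.

Viability is modeled as a four-parameter logistic (4PL) in log10
concentration,

$$v(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
  {1 + 10^{\,h\,(\log_{10} c - \log_{10}\mathrm{IC}_{50})}},$$

oriented so that a positive Hill slope $h$ means viability decreases with
dose. The fit is bounded least squares (Levenberg–Marquardt) with
data-driven starts (top = max viability, bottom = min viability, IC50 at
the median log dose, $h = 1$); the first start occasionally presents an
exactly collinear Jacobian, so two perturbed fallback starts are tried
before a curve is declared non-convergent.

The sensitivity score is the **window-normalized AUC**: the trapezoidal
integral of the *fitted* curve on a 101-point grid over the observed
log-dose window, divided by the window width. This makes AUC a mean
relative viability in roughly $[0, 1]$ — 1 for an inert drug, 0 for
complete kill, and directly comparable across drugs sharing a window.
Lower AUC always means more sensitive, a convention used consistently in
every downstream screen.

Curves that carry no usable dose-response information are **excluded, not
repaired**, and propagate an explicit status instead of a number:

* `excluded_nonconvergent` — the optimizer failed from every start;
* `excluded_ambiguous` — fitted span `top − bottom < 0.05` (no response),
  non-positive Hill slope (viability not decreasing), or a log10 IC50
  standard error above one log unit (location essentially unidentified).

The "ambiguous" definition is this package's operationalization: the
upstream screening literature excludes "ambiguous" fits as judged by
commercial software whose rule is not public, so explicit, reproducible
flags are used instead.

Plate quality is gated by the Z'-factor,
$Z' = 1 - 3(\sigma_{pos} + \sigma_{neg}) / |\mu_{pos} - \mu_{neg}|$,
comparing positive (killed) and negative (DMSO) control wells; plates
below the threshold (default 0.3) are dropped with a warning. $Z'$ is at
most 1 and invariant under affine rescaling of the signal, so it does not
depend on detector gain.

### IC50 recovery study

The parameter-recovery simulation used in the acceptance suite mirrors the
screen protocol: duplicate wells with per-well Gaussian viability noise
(SD 0.05) averaged before fitting, and true IC50s bracketed by at least
two dilution points on each side of the window — the situation a
well-designed dilution series is meant to produce. This bracketing matters
statistically, not just practically: for a curve whose IC50 sits at the
window edge, one plateau is essentially unobserved and the Fisher
information for $\log_{10}\mathrm{IC}_{50}$ collapses, so no estimator can
localize it tightly. Within the bracketed regime the 4PL fit recovers
log10 IC50 within ±0.2 in the large majority of usable fits, which is
what the suite asserts (500 curves per run).

## Mutation filtering, alteration matrix, subtypes

Mutation calls are kept when VAF > 5% **and** depth > 20 reads, with
strict inequalities — boundary records are dropped. The alteration matrix
is ternary: a sample is `altered` for a feature when a surviving record
matches it, `wild-type` when the sample was sequenced and nothing matches,
and `unknown` when the sample has no genomic data. Unknown is never
conflated with wild-type: unknown-status samples are excluded per feature
from every denominator and every test. Features come at three
granularities — gene-level mutation (`TP53`), exact protein change
(`PIK3CA-E542K`), and gene-level CNA call (`KRAS-amp`) — because drug
interactions can be allele-specific.

Molecular subtype is assigned by a transparent decision tree in the order
EBV flag → MSI flag → copy-number burden: samples whose fraction of
assayed genes with a non-neutral CNA call is at least 0.2 are HCNA
(chromosomal instability), the rest LCNA (genomically stable). The
original cohorts derive these labels from unsupervised clustering of
molecular profiles that cannot be reproduced without the controlled-access
data; the rule-based classifier is a deliberate stand-in, with the burden
threshold exposed in `run_config()`. Samples with no CNA assay rows have
zero burden and fall to LCNA, and samples missing from the metadata are
labelled unknown and excluded downstream.

Per-subtype mutation frequencies are computed over known-status samples
only and normalized to ternary coordinates for the EBV/LCNA/HCNA
landscape diagram; tissue–PDC concordance counts shared and private
mutations keyed by (gene, protein change), so two different hotspots in
one gene remain distinct events.

## Association screens

All two-group comparisons use the two-sided Wilcoxon rank-sum test: exact
enumeration when the pooled size is ≤ 20 without ties, otherwise mid-ranks
with the tie-corrected normal approximation and continuity correction.
Effects are reported both as the difference and the ratio of group mean
AUCs, since volcano plots conventionally show fold-change while the
underlying distributions are compared nonparametrically; the mean (not
median) is used for both and recorded as such. Co-occurrence of two
alterations uses the two-sided Fisher exact test on the samples with known
status for both features.

Pairs with fewer than 3 samples in either arm are skipped rather than
tested — tiny groups produce meaningless p-values that only dilute the
multiple-testing correction. Benjamini–Hochberg adjustment is applied
within each screen and significance calls use `q` at a configurable level
(default 0.1); the source studies report raw p-values only and state no
threshold, so both `p` and `q` are emitted. The chromosomal-instability
grouping (HCNA versus rest) is included as a first-class one-vs-rest
screen so claims like "high-CNA tumors are more sensitive to PARP
inhibition" are expressible as a test.

## ssGSEA

Single-sample gene-set enrichment is implemented directly (it is the one
statistical primitive in this pipeline without a canonical contract in the
installed toolchain and is cross-checked against a literal brute-force
recomputation in the tests). Genes are ranked by expression with mid-ranks
for ties — RPKM-like data tie heavily at zero, and mid-ranks keep the
score deterministic — and walked in decreasing order with gene name as the
tie-break. The enrichment score is the running sum of the weighted in-set
ECDF minus the uniform out-of-set ECDF, with in-set weights
$\mathrm{rank}^{\alpha}$ normalized to sum 1. The exponent defaults to
the canonical $\alpha = 0.25$. The raw sum form is reported by default;
normalization by (universe − set size) is available by flag and the choice
is recorded in the output attributes, because published uses of ssGSEA
frequently omit which variant they ran. The score depends on expression
only through ranks, so any monotone transform of the input (log, linear
rescaling) leaves it unchanged.

## Bootstrapped elastic-net stability selection

For each drug, response (AUC) is regressed on a combined feature matrix:
per-gene expression log2(x+1)-transformed and z-scored over the analysis
samples, plus 0/1 alteration indicators. Alteration features with more
than 20% unknown status are dropped; below that, unknowns are imputed as
wild-type with a reported count. Constant columns are removed.

The procedure repeats B = 100 times: draw 80% of the tumors **without
replacement** — the literal reading of "randomly selected 80% of the
tumors", i.e. subsampling rather than a classical with-replacement
bootstrap — fit an elastic net (mixing parameter 0.5 by default), choose
the penalty by 5-fold cross-validation *within the subsample*
(`lambda.min`; whether tuning is per-subsample or global is conventionally
unstated, and per-subsample tuning is recorded in the result attributes),
and mark every feature with a nonzero coefficient as "appearing". The
final ranking is appearance count out of B, then absolute average weight,
then name. The average weight is taken over the bootstraps where the
feature was selected; averaging zeros in is available by flag since
"average weight" is ambiguous on this point. Subsample streams are seeded
per bootstrap index, so any single bootstrap is reproducible in isolation
and the whole table is bit-stable for a given seed. When the subsample is
too small for stable cross-validation (< 15 samples) a fixed point a
quarter of the way down the default lambda path is used and a message is
emitted.

The direct single-gene analysis is the Pearson correlation between a
transcript and a drug's AUC, with the t-distribution p-value on n − 2
degrees of freedom.

## The synthetic cohort generator

`simulate_cohort()` produces complete cohorts with a serialized ground
truth, and `full_scale_preset()` fixes the study-scale conditions: 131
tumor samples (about 20% left unsequenced), 41 expression-profiled
samples, 60 drugs in the 20 µM / fourfold / 7-point series, duplicate
treated wells with viability noise SD 0.05, and 16 DMSO plus 16
positive-control wells per plate. Subtypes are drawn from a mixture (EBV
9%, MSI 20%, HCNA 45%, LCNA 26%, the familiar proportions for gastric
adenocarcinoma); mutations are per-(gene, subtype) Bernoulli draws with
TP53 enriched in HCNA, CDH1 and NF1 in LCNA, and PIK3CA/ARID1A in
EBV-positive tumors, with hotspot protein changes for PIK3CA and KRAS;
CNA burden is elevated in HCNA samples so the rule-based classifier has
signal to recover; expression is per-gene log-normal.

Two details make the generator a genuine end-to-end test rather than a
pass-through:

* **Planted effects act on the noiseless AUC scale** (additive shifts for
  alteration and subtype effects, a standardized linear link for the
  planted predictive transcript, default slope 0.7 with residual SD 0.7).
  The per-cell 4PL parameters are then *solved backwards* — log10 IC50 is
  obtained by inverting the window-normalized AUC by root-finding given
  the drawn top/bottom/Hill — and raw plates are synthesized from those
  curves. The dose-response stage therefore has to re-estimate every AUC
  through normalization and refitting, a real lossy step. With plate
  noise set to zero the chain reproduces the ground-truth AUC to better
  than 1e−3, which the tests assert.
* **Ground truth is serialized in full** (realized subtypes, carriers,
  4PL parameters, noiseless AUCs, planted-effect manifest), so every
  downstream claim can be audited without re-deriving hidden state.

Planted shifts whose magnitude would push a drug's mean AUC outside
[0, 1] are rejected as a configuration error; per-sample values are
clamped to [0.02, 0.98] as viability saturation. The preset's planted
effects are one predictive transcript (an RNF11-like gene linked to one
EGFR-inhibitor-like drug) and one alteration sensitivity (PIK3CA-E542K
carriers shifted −0.2 AUC on one drug).

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: gene–gene co-expression structure
(genes are independent log-normals), mutational signatures and
co-mutation patterns beyond subtype conditioning, batch and edge effects
on plates, drug–drug correlation from shared targets, and measurement
error in the genomics tables themselves. Results on real cohorts will be
noisier in ways this generator cannot predict.

## Numerical and degenerate-input conventions

* Concentrations are stored in µM; log transforms are always computed,
  never stored.
* Flat viability input (range < 1e−8) short-circuits the 4PL fit to a
  flat curve flagged ambiguous rather than an optimizer error.
* Degenerate 2×2 tables (an empty margin) return p = 1 with a warning
  rather than an error, so screens over sparse features do not abort.
* All result tables have deterministic sorts (stated in each function's
  documentation), and `write_results()` re-sorts on the character key
  columns so repeated runs are byte-identical.
* Wilcoxon/Fisher exactness switches follow the standard rules of the
  underlying implementations and are cross-checked against enumeration
  oracles in the test suite to 1e−12.

## Problem sizes used by the test suite

The suite exercises the statistical guarantees at these sizes, chosen to
give stable Monte-Carlo estimates while keeping a default run fast: null
calibration of the gene–drug screen on 50 cohorts of n = 100 with 2000
feature–drug pairs each; detection power on 100 planted cohorts (1.5
pooled-SD shift, prevalence 0.3, n = 100); 500 noisy dose-response curves
for IC50 recovery; 20 replicate stability-selection designs (n = 41, one
planted predictor, 200 decoys, B = 100) plus a pure-noise design; and one
full study-scale cohort (131 × 60) run end to end through every stage.
The acceptance script (`scripts/acceptance.R`) recomputes the same
quantities from scratch at slightly reduced replicate counts and writes
them as JSON.

## Known limitations

* The HCNA/LCNA split is a thresholded burden rule, not a clustering of
  molecular profiles; its boundary (0.2) is a convention, configurable
  but not learned.
* IC50 itself is not a primary endpoint; curves are summarized by AUC,
  and IC50s outside the tested window are reported as fitted but should
  not be over-interpreted.
* The elastic-net stage models each drug independently; no information is
  shared across correlated drugs.
* Statistical calibration (FDR control, p-value uniformity) is
  demonstrated on the generator's null, which has independent features;
  strongly correlated alteration features on real data make BH
  conservative rather than anti-conservative, but power claims do not
  transfer automatically.
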