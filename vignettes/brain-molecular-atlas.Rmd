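---
title: "Methods: adjusted molar concentrations from heterogeneous brain omics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adjusted molar concentrations from heterogeneous brain omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amcpipe)
```

## The problem

Quantitative models of brain metabolism and signalling need molar
concentrations, but published measurements of brain proteins and metabolites
are scattered across studies that differ in acquisition type (LFQ, iBAQ,
TMT, SILAC, or directly reported concentrations), units, gene nomenclature,
species, brain region, cell type and age. `amcpipe` converts such
heterogeneous tables into one comparable quantity — an adjusted molar
concentration in µM — and provides the statistical machinery to judge how
comparable the result actually is.

## Nomenclature alignment

Gene names are vertices of a graph; names co-listed on one data entry or on
one row of an offline UniProt-derived synonym table are joined by an edge.
Every connected component is a synonym set, and all of its members map to
one canonical symbol: the member that occurs in the largest number of data
entries. Comparison is case-insensitive and canonical output is uppercase,
so `Stxbp1` and `STXBP1` unify.

The frequency rule does not define a winner when counts tie. We break ties
deterministically: names present in the (mouse) synonym table outrank names
that are not, and remaining ties fall to the lexicographically smallest
name. The table-membership preference encodes a bias toward curated mouse
identifiers; the lexicographic step is purely a reproducibility device and
carries no biological meaning.

Components that co-list names whose UniProt accession sets are disjoint are
*flagged* as conflicts and reported, never auto-split: resolving them is a
curation decision, not an algorithmic one. Isoform-level resolution is out
of scope — information from different isoforms of one gene is merged under
the gene symbol.

## Detectability correction by in-silico digestion

MS signal scales with how many peptides a protein can contribute.
Sequences are cut immediately C-terminal to every K and R (trypsin) or K
(lysC), with zero missed cleavages and no proline exception, and fragments
of 6–29 residues (inclusive) are counted. LFQ/TMT/SILAC signals are divided
by this count; iBAQ values already carry the correction, so their factor
is 1. Proteins with a zero count cannot be detectability-scaled and are
excluded with a logged count rather than silently assigned a value.

Molecular weights use average residue masses plus one water; `X` wildcards
get the mean residue mass, other ambiguity codes are rejected. The
initiator methionine is kept: the digestion convention does not state its
removal, and dropping it would change counts by at most one short fragment.

## Concentration estimation (total-protein-mass approach)

For one study with detectability-corrected signals $s_i/d_i$ and molecular
weights $m_i$:

$$W = \sum_i \frac{s_i}{d_i} m_i, \qquad
  N_i = \frac{s_i}{d_i}\,\frac{P\,N_A}{W}, \qquad
  V = \frac{\sum_i N_i m_i / N_A}{C}, \qquad
  c_i = \frac{N_i}{V\,N_A}$$

with $P$ = 200 pg protein per cell, $C$ = 200 g/L total cellular protein
concentration, $N_A$ Avogadro's number. Two algebraic identities make good
self-checks and are enforced in the tests: $V \equiv P/C$ (1 pL at the
defaults) whatever the inputs, and $\sum_i c_i m_i = C$ exactly. Because
only signal *shares* enter, any per-study global scale factor cancels — the
estimator is invariant under multiplying all signals by a constant. $P$ and
$C$ are population-level defaults, exposed in the configuration because
cell-type-specific values would be better wherever they exist.

Replicate columns are estimated independently (each column is one cellular
proteome), preserving within-study variance for the statistics downstream.
Zero or missing signals are dropped before the sums: they carry no
quantification, and dropping keeps coverage reports honest.

## Housekeeping normalization

Residual between-study scale (sample preparation, instrument response) is
removed multiplicatively: every concentration in a study is scaled by
`reference_median / median(study's housekeeping concentrations)`, on the
linear µM scale. The reference median is computed over housekeeping entries
from healthy, young-to-middle-aged mouse data (cell lines included);
organelle-only datasets are normalized *with* the reference but never
contribute *to* it, since their scale is not cellular. After normalization
every study's housekeeping median equals the reference exactly, which makes
the operation idempotent. The reference median itself is a run-time
artifact of whichever data are integrated, not a constant.

## Metabolites

Measurements are converted to µM with a brain density of 1.04 g/mL and 80%
water content. The dry-to-wet bridge follows from the water content alone:
1 mg dry ↔ 5 mg wet, so 1 nmol/mg dry = 0.2 µmol/g wet = 208 µM at the
default density. All conversions are linear and exactly invertible, which
the tests exploit as round-trip identities. MRS and MS values keep a method
tag and are not cross-corrected (the method affects variance more than
location); species is flagged, not corrected.

Tissue concentrations are predicted from compartments by volume-fraction
mixing: extracellular 0.19, vasculature 0.03, neuronal somas 0.10, neurites
0.60, glia 0.08 (fractions must sum to 1). The neuronal concentration
supplies both soma and neurite fractions; the glia term uses the astrocytic
concentration, imputed from the neuronal one when missing — without that
imputation almost no compound has complete compartment coverage. No
analogous imputation exists for blood or extracellular values, so compounds
missing those are excluded and reported rather than guessed. The
prediction is a convex combination, hence always within the range of its
inputs.

## Validation battery

* **Variability score** — |CV| of the raw (linear) values divided by the
  number of measurements. "Scaled to the number of measurements" is read as
  division by $n$: it yields a dimensionless, coverage-penalized score and
  preserves the stated zero case (score 0 iff CV 0). Division by $\sqrt n$
  would be equally defensible; the choice is isolated in one function.
* **Specificity index** — difference of mean ln-concentrations between a
  target location and all others pooled; antisymmetric under swapping.
* **Correlation tables** — pairwise Pearson $r$ of ln-concentrations over
  the proteins common to each pair only, with the common count reported
  alongside, since an $r$ over 12 shared proteins does not mean what an $r$
  over 1200 does.
* **Median equality** — Kruskal–Wallis across studies; on rejection at
  α = 0.05, the Conover all-pairs post hoc (tie-corrected rank
  t-statistic, implemented here and cross-checked in the tests against an
  independent transcription of the formula) with Holm adjustment.
* **Two-group battery** — DBM/OVS effect size (distance between medians
  over the span of both groups' 1.5×IQR boxplot whiskers — "overall visible
  spread" is boxplot vocabulary), two-sided Mann–Whitney and
  Kolmogorov–Smirnov, Brown–Forsythe (median-centered Levene, via
  `car::leveneTest`) and Fligner–Killeen. The KS test uses the exact
  two-sample distribution when both groups are ≤ 100 and tie-free,
  because the asymptotic approximation is conservative at these sizes.
* **Permutation calibration** — to control for unequal sample sizes,
  1000 draws of n = 100 per group, rejection rates at α = 0.05 recorded
  per test; in control mode both samples come from the pooled data, so
  every rate should sit near 0.05. One caveat found while validating:
  Fligner–Killeen's chi-square approximation is anti-conservative on
  strongly right-skewed (e.g. raw lognormal) data at these sample sizes —
  base R's `fligner.test` alone shows ~16% type-I error on iid lognormal
  groups of 100. The battery is therefore calibrated and applied on the
  ln-concentration scale, which is also the scale the median-equality
  interfaces consume.
* **Differential concentration** — per-gene fold change of group means
  with a two-sided Welch t-test on ln-concentrations (the minimal standard
  choice for a "basic" differential analysis; the test function is isolated
  so it can be substituted). Linear-mode thresholds 1.15 (up) and 0.87
  (down), log2 mode ±2, all at p < 0.05.

## RNA-to-protein ratios

From a paired reference, `ratio = protein / expression` per gene (zero
expression excluded and reported); prediction multiplies the ratios into
new expression values. Replicates are averaged per gene before fitting.
Ratios are deliberately not smoothed, shrunk, or made tissue-specific:
cross-cell-type degradation of the prediction is an expected, reported
finding, not something the model corrects.

## What the synthetic generator does and does not emulate

`generate_proteome()` draws sequences with lognormal lengths (median ~400
residues, clamped to 60–3000), ~11% K+R content — so >90% of proteins have
at least one detectable tryptic peptide — and true copy numbers lognormal
over about four orders of magnitude (median 10^5 copies/cell), with a ~5%
housekeeping subset and an invertible synonym registry.
`simulate_study()` emits `truth × detectability × batch × lognormal noise`
with label corruption and dropout (guarded so housekeeping genes never
vanish entirely). These choices are the standard lognormal abundance/noise
model for MS proteomics and suffice to exercise every pipeline stage.

They do **not** emulate peptide-level identification, shared peptides,
intensity-dependent missingness, replicate correlation structure, or
biological differences between regions and cell types. Passing the
recovery tests therefore shows the pipeline's transformations are correct
and invertible under their own model assumptions — not that real
inter-study biology is captured.

Default study conditions used throughout the tests and the acceptance
script: 5 studies, 2000 genes, batch scale factors 0.2–5, measurement noise
CV 20%, 20% synonym corruption. At these conditions the per-study Pearson
correlation between ln(normalized concentration) and ln(truth) is ~0.996,
consistent with the noise floor $\sigma_{\ln} \approx 0.198$ against a
truth spread of ~2.3 ln-units. Smaller fixtures (100–400 genes, 3–5
studies) are used for unit-level checks; the permutation battery runs its
full 1000 × n=100 protocol.

## Numerical choices and degenerate inputs

Quantiles use linear interpolation of the empirical distribution (R type
7), with strictly-greater-than selection for top-percentile membership, so
an all-equal sample selects nothing. Zero boxplot spread makes DBM/OVS
undefined (flagged `NA`, not 0). All-zero studies, empty reference pools,
studies with no housekeeping coverage, unresolved names/CIDs, fractions
not summing to 1, unknown units, and non-numeric table values all fail
loudly with the offending item named; unresolved identifiers and
unmixable compounds are retained-and-counted rather than erroring, since
partial coverage is the normal state of literature data.

## Known limitations

Single $(P, C)$ constants for all cell types; no isoform resolution; no
missed-cleavage or PTM modelling; housekeeping stability is an assumption
that can fail in disease states; normalization requires each study to
cover some of the housekeeping set; metabolite method/species differences
are flagged, not corrected; RTP ratios ignore cell-specific regulation.
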