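---
title: "Methods: plate-based metabolomics for hepatotoxicity MoA profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate-based metabolomics for hepatotoxicity MoA profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moaplate)
```

# The workflow

`moaplate` implements the analysis side of a 96-well HepG2 screening
platform for hepatotoxicity mode-of-action (MoA) profiling by targeted
LC-MS/MS metabolomics. The stages, in their fixed order:

1. **Dose selection** from ATP-viability range finders via the
   three-parameter Weibull model;
2. **Per-metabolite quality control** (coverage, blank contribution,
   reference-series linearity, technical variability);
3. **Two-tier normalization** — same-plate reference-sample ratios, then
   within-sample median scaling;
4. **Univariate profiling** — Welch tests on log10 ratios, fold changes,
   ontology-class enrichment counts;
5. **Multivariate profiling** — PCA with standard scaling, hierarchical
   clustering (Ward.D2 linkage, Manhattan distance) with bootstrap
   cluster probabilities;
6. **MoA fingerprints** — direction-consistent intersections of
   significant metabolites across the substances of a MoA, general
   (MoA-nonspecific) hepatotoxicity markers, and nearest-centroid
   classification of new compounds in PC space.

Because instrument data for such screens are rarely public, the package
ships a first-class synthetic generator that emulates the experimental
design, so every stage is exercised end-to-end by code alone.

# Dose-response model

ATP-based viability is modelled by the three-parameter Weibull (W1.3)
curve with the lower asymptote fixed at zero:

$$f(x) = d \, \exp\!\big(-\exp(b(\ln x - \ln e))\big),$$

with slope $b$ (dimensionless), upper asymptote $d$ (% of vehicle
control, typically near 100) and scale concentration $e$ (µM), the
concentration at which the curve has fallen to $d/\mathrm{e}$. The
effective concentration for a $p$% effect has the closed form

$$\mathrm{EC}_p = e \, \exp\!\big(\ln(-\ln(1 - p/100))/b\big),$$

so that $f(\mathrm{EC}_p) = d(1 - p/100)$ exactly; at
$p = 100(1 - 1/\mathrm{e}) \approx 63.2$ the EC equals $e$. Fitting is
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with a
self-start heuristic: $d$ from the top of the curve, $e$ from the dose
nearest half-maximal response, $b$ from a complementary log-log
regression on log dose. The five metabolome doses are
EC1/EC5/EC15/EC50/EC85 rounded half-up to the nearest integer; a
rounding collision is an error prompting a manual grid rather than a
silent duplicate dose.

Two dose-selection rules exist in this platform's practice. Screening
doses come from the rounded EC grid. The *MoA analysis* concentration is
the highest tested level whose mean ATP viability remains at least 80%
of the vehicle control (an ATP decrease of less than 20%) — strong
enough to perturb the metabolome, below overt cytotoxicity. The 80%
threshold is the one that reproduces the published level choices for all
seven reference compounds (level 3 everywhere except level 2 for Aroclor
1254); a stricter 90% reading would contradict the published selection
for pendimethalin (C3 at 82.4% viability), so it is rejected. The
threshold is configurable.

# Quality control

Per analyte, computed on raw signals:

* **coverage** — fraction of *study* samples (treatment, vehicle and
  positive-control wells; blanks excluded from the denominator, which
  the platform description leaves open) with a present value. Missing is
  an empty field, never 0 — zero is a legal signal and coverage counts
  missingness.
* **blank contribution** — median blank signal over median study
  signal. Medians, not means: robust to single-well spikes (the
  estimator is otherwise unspecified).
* **slope, linearity R²** — ordinary least squares of the reference
  concentration-series signal on nominal amount, linear scale with
  intercept (configuration hook left for a forced-origin variant).
* **variability RSD** — back-transformed from the log10-scale SD of the
  lyophilized reference replicates: $\mathrm{RSD} = 1 - 10^{-SD_{\log}}$.

The gate passes an analyte iff coverage > 80%, blank contribution
< 40%, slope > 0, and any of four linearity/variability conditions
holds: (a) R² > 0.8 ∧ RSD < 0.3, (b) R² > 0.64 ∧ RSD < 0.3,
(c) R² > 0.8 ∧ RSD < 0.6, (d) R² > 0.64 ∧ RSD < 0.6. As printed these
four are mutually redundant — the disjunction is logically condition (d)
— and the implementation keeps them verbatim while recording which
condition fired, rather than guessing at intended distinct tiers; the
test suite proves the collapse by exhaustive grid. All inequalities are
strict. A non-computable metric (no blanks, no series, fewer than two
positive reference replicates) fails the analyte with a named reason.

# Normalization

Tier 1 divides every study value by the median of the same analyte
across the lyophilized reference samples of the same plate. Since the
reference aliquots ride through the same analytical batch, any per-plate
multiplicative factor cancels exactly; the test suite verifies this by
paired simulations with and without batch factors. Tier 2 divides each
sample by its own median across the included analytes, cancelling the
per-well cell-number factor (a single multiplier common to all analytes
of a well). After tier 2 every sample median is exactly 1; the step is
idempotent and scale invariant.

Choices the platform description leaves open, decided here: the
within-sample median is computed over QC-passing analytes only (after
exclusions the passing set stands in for "all measured analytes"), even
counts use the mean of the central pair, and missing values are excluded
from medians, never imputed — downstream statistics handle missingness
pairwise. The order (reference first, then within-sample) is fixed;
reversing it changes provenance but, because both steps are
multiplicative, not the final values when medians are taken over the
same included set.

# Statistics

Differential testing is the heteroscedastic (Welch) two-sample t test on
log10 normalized ratios, treated wells versus same-plate vehicle wells,
two-sided, with Welch–Satterthwaite degrees of freedom. Significance
defaults to raw p < 0.05 — the platform describes no multiple-testing
correction, so fidelity comes first — with Benjamini–Hochberg available
by configuration. Fold change is $10^{\Delta}$ for the mean log10
difference $\Delta$; base 10 is used throughout (the RSD back-transform
and the multivariate input are both base-10). Groups with fewer than two
values or zero variance are flagged untestable and excluded from
significance sets rather than raising.

PCA uses column-wise mean centering and unit-variance scaling of the
log10 ratios (the convention for sample-level data, where each analyte
contributes comparably). Hierarchical clustering uses Ward.D2 linkage on
Manhattan distances of treatment-mean profiles, with ordinary bootstrap
probabilities (BP): analytes (columns) are resampled with replacement —
the resampling unit of the clustering literature this follows — and each
original node's probability is the fraction of replicate trees
containing its exact leaf set. The default is 10,000 replicates; the
multiscale/AU approximation is deliberately out of scope. Missing values
are mean-imputed (column mean of log10 ratio) for PCA/HCA only, with the
imputation count logged.

# Fingerprints and classification

A MoA fingerprint is the strict intersection, over the member
substances at their MoA-analysis concentrations, of significantly
increased (respectively decreased) analytes. Strictness makes the
operation anti-monotone — adding a substance can only shrink the set —
which is both the natural reading of "commonly changed" and a testable
property. Markers appearing with the same direction in *every* MoA
fingerprint are reported separately as general hepatotoxicity markers
and removed from the specific view. Single-substance fingerprints are
permitted but flagged: with one member, "common change" is vacuous.

Classification projects a new compound's treatment-mean profile into a
reference PC space and assigns the nearest MoA centroid (Euclidean, 3
components by default, mirroring the PC1–PC3 separation of the three
reference MoAs). The reference PCA is *centered but not autoscaled*:
treatment-mean profiles already share one dimensionless scale, and
autoscaling would inflate the majority of analytes that carry no
treatment signal into pure-noise dimensions — in simulation this single
choice moves leave-one-out accuracy from roughly three quarters to
essentially perfect. A profile must cover at least 80% of the reference
analytes; held-out analytes fall back to the center (contributing
nothing). An optional null-distance threshold (e.g. the 95th percentile
of no-effect profile distances) flags low-confidence calls.

# The synthetic generator

The generator emulates the study design: one 96-well plate per
substance with the outer ring unused (PBS in the wet-lab design), and
54 used interior wells — 6 treatment replicates at each of 5 levels, 12
vehicle controls, 6 positive controls (bezafibrate 1000 µM) and 6
blanks; per plate, 6 lyophilized reference replicates and a reference
concentration series (nominal amounts 0.25/0.5/1/2/4, duplicates). The
panel has 221 analytes (156 annotated, 65 unknown) in 12 ontology
classes, with the signature-referenced metabolites curated by name.

A study-well signal is generated on the log10 scale as baseline +
per-plate batch factor + per-well cell-number factor + scaled treatment
effect + cytotoxicity term + Gaussian noise. All noise is log10-normal
(multiplicative), matching the log-scale analysis and the RSD
back-transform. Defaults, chosen once as plausible for a well-behaved
targeted platform and then left alone: technical SD 0.040, biological SD
0.018 (so vehicle-well RSD lands near 9–10%, inside the 8–11% band
reported for such screens, and technical RSD near 9%), batch SD 0.05,
cell-number SD 0.03, blanks at 5% of baseline (blank signal structure is
otherwise undocumented). Effect signatures encode the published
*directions* of the characteristic metabolite changes per MoA — no
quantitative per-metabolite effect sizes exist to copy — with default
magnitudes of 0.2–0.3 log10 units at the intermediate level, scaled by
a non-decreasing per-level multiplier (0.25/0.5/1/1.5/2) plus a steep
logistic cytotoxicity gate centred between levels 3 and 4 that
reproduces the qualitative change of metabolome direction at overtly
toxic doses. Viability replicates are drawn around each substance's
ground-truth W1.3 curve with 3-percentage-point noise.

What the generator does *not* emulate: chromatographic drift and
retention-time shifts, heteroscedastic (intensity-dependent) noise,
censoring at the detection limit, correlated analyte families, plate
position effects, or real annotation ambiguity. Passing tests therefore
demonstrate that the *analysis* behaves correctly under the design's
statistical assumptions — factor cancellation, calibration, recovery of
planted structure — not that any real compound would classify
correctly.

# Numerical choices and degenerate inputs

* Rounding of ECs is half-up (`floor(x + 0.5)`), the everyday
  "nearest integer" convention; base R's round-half-even would disagree
  at `.5` boundaries.
* `fit_w13` refuses fewer than 4 distinct doses or constant responses;
  `ec_from_fit` refuses unconverged fits, `b = 0`, and p outside (0,100).
* Reference medians of zero, samples with fewer than 3 analytes, and
  constant PCA columns are dropped with logged reasons, never silently
  imputed.
* The pipeline fans a single seed out to per-stage substreams so
  toggling one stage does not perturb another's randomness, and the
  generator draws standard normals scaled by the SD so paired
  simulations (a factor on versus off) share their noise realization
  exactly.

# Problem sizes in the test suite

The suite verifies stochastic claims at sizes chosen to keep the default
run fast while leaving comfortable statistical margins: Welch
calibration on 10,000 null replicates (unit tests use 2,000), W1.3
parameter recovery on 200 simulated range finders, 20-seed bands for the
control-RSD calibration, 100-seed leave-one-substance-out classification
(with HCA partition recovery checked on the first 5 seeds), and 25–1,000
bootstrap replicates for dendrogram probabilities (the analysis default
remains 10,000). The oracles are independent implementations: textbook
Welch formulas, numeric root-finding against the EC closed form, a naive
Lance–Williams Ward.D2 agglomerator, and exhaustive truth tables for the
QC gate.

# Known limitations

* Ordinary bootstrap probabilities are reported for dendrogram nodes;
  AU (multiscale) probabilities are not implemented.
* The enzyme-inhibition MoA has a single reference substance, so its
  fingerprint is not a common-change set (flagged in output) and it
  cannot be evaluated by leave-one-substance-out classification.
* Coverage denominators, blank estimators, linearity scale and the
  within-sample median set are platform conventions decided here and
  exposed as configuration; other reasonable readings exist.
* The class-enrichment over-representation test (hypergeometric) is off
  by default: the platform reports counts per ontology class, not
  enrichment p values.
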