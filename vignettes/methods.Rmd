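---
title: "Methods: sulfate-focused screening and route classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sulfate-focused screening and route classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulfoscreen)
```

This vignette is the package's account of its science: the models each
stage assumes, the tunable parameters and why their defaults are what
they are, what the synthetic study does and does not emulate, and the
design choices made where the method description left the design open.

## Mass arithmetic

All m/z values are computed from embedded CODATA/NIST monoisotopic
element masses (carbon-12 exactly 12 Da; electron 5.4858e-4 Da), so the
package needs no network access and every reported mass is reproducible
to the last digit. Negative ions follow the electron-inclusive
convention: a deprotonated molecule is `M - m(H) + m(e)`, an anion with
an explicit elemental formula (HSO4-, or the radical anions SO3-.,
SO4-.) is `m(formula) + m(e)`. Under this convention the four
diagnostic fragment ions and two neutral losses reproduce their
standard printed reference values at four decimal places, with one
caveat: SO3-. computes to 79.95736 Da, which rounds to 79.9574 rather
than the commonly printed 79.9573. The discrepancy is a rounding
convention at the fifth decimal, two orders of magnitude below any
matching tolerance used here, and the tests therefore assert agreement
within 0.0002 Da for that one ion instead of exact 4 d.p. equality.

## Diagnostic annotation: IR and MA

A spectrum is screened with two match rules: fragment-ion entries match
peaks within an absolute window of the reference m/z, and neutral-loss
entries match peaks whose distance below the precursor is within the
same window of the loss mass. The fragment tolerance defaults to
±0.005 Da (absolute rather than ppm, because the diagnostics sit at
m/z 80–97 where a 5 ppm window would be under half a millidalton —
tighter than instrument reality). The electron-mass asymmetry in the
neutral-loss comparison (< 1 mDa) is ignored.

Per diagnostic, the most intense qualifying peak is recorded. One
physical peak may satisfy several diagnostics (e.g. a fragment that is
also precursor-minus-SO3); when the intensity ratio
`IR = (sum of matched peaks) / (sum of all peaks)` is formed, each
physical peak is counted **once**. Counting per-diagnostic instead
would let a single peak push IR above 1; the distinct-peak rule keeps
IR in [0, 1] by construction and is the interpretation used throughout.
`MA = 100 * largest matched peak / base peak` lies in [0, 100], and
`IR = 0` exactly when `MA = 0`.

Spectra are assigned to aligned features within ±3 s retention time and
±5 ppm precursor mass — the alignment tolerances of the upstream
processing — choosing the minimal-|ppm| candidate, with ties broken by
RT distance and then feature ID so assignment is deterministic. A
feature collecting several spectra keeps the one with the largest base
peak, a proxy for precursor abundance.

## Preprocessing

*Imputation.* Missing areas are left-censored non-detects; each is
replaced by 20% of the feature's minimum observed positive area, the
small-value substitution standard in biomarker workflows.

*LOWESS normalization.* Instrument response drifts smoothly over an
acquisition sequence. Pooled-QC injections — aliquots of one pooled
sample injected throughout — should be constant, so per feature a
LOWESS curve of QC intensity versus injection order is the drift
estimate; every sample is divided by the curve at its own injection
position, rescaled to preserve the feature's QC median. The span
defaults to 0.5 with 2 robustifying iterations: wide enough that a
20-QC sequence is not overfit, and the robust iterations guard against
a single aberrant QC injection. At least 4 QC anchors are required;
features whose QC signal cannot support a fit pass through unchanged
and are flagged in the normalization report. The QC-median target (per
feature) rather than a global total-ion target keeps the operation
feature-wise and testable.

*PCA.* Scores are computed on log10(x + 1), feature-centered data (peak
areas are heavy-tailed), with a fixed sign convention — the
largest-magnitude loading of each component is positive — so repeated
runs are identical.

## Sulfate classification

Features are clustered on eight parameters: the six diagnostic channel
intensities plus IR and MA. Columns are z-scored first; the raw
channels span orders of magnitude while IR is a fraction, and without
standardization the intensity channels would dominate the distance.
(The alternative — clustering raw intensities — was rejected for that
reason.) k-means with k = 2 uses Lloyd's algorithm, best of 10 random
restarts under a fixed seed (k-means is sensitive to initialization;
on small instances the restart scheme attains the exhaustive-partition
optimum, which the tests verify). Features with no MS/MS spectrum enter
as all-zero rows rather than being excluded, so every aligned feature
receives a class and downstream counts are well defined.

Cluster numbering from k-means is arbitrary, so the semantic label is
derived from the centroids: the cluster whose centroid has the larger
mean of the standardized IR and MA coordinates is *sulfated* and
reported as cluster 1, the other as cluster 2. This makes the sulfated
call invariant to label permutation, which is property-tested.

## Differential analysis

Per feature, a two-group linear model on log2 areas gives the effect
(difference of group means), a pooled residual variance and `n - 2`
degrees of freedom. The default contrast is all pre-administration
(0 h) injections against all post-administration injections. Variances
are then moderated empirically: residual variances are modeled as
scaled inverse-chi-square draws around a prior `(d0, s0^2)`, estimated
by the method of moments on `log(s2)` — the spread of `log(s2)` beyond
the chi-square sampling component determines `d0` through trigamma
inversion (Newton iteration on the monotone trigamma function), and the
location determines `s0^2`. When the observed spread does not exceed
the sampling component, `d0` is infinite and all posteriors collapse to
`s0^2`; note the estimator applies the chi-square bias correction
`exp(log(df/2) - digamma(df/2))` on the log scale, so with perfectly
homogeneous variances `s0^2` sits slightly above the common value — the
same behavior as the reference empirical-Bayes implementation, against
which the estimator is cross-checked in the tests. Moderated t uses
`d0 + df` degrees of freedom (normal in the infinite-`d0` limit;
ordinary pooled t at `d0 = 0`). A feature with zero variance and zero
effect is reported `t = 0, p = 1` by convention.

Multiple testing uses Benjamini–Hochberg. The method description that
motivated this package never names its adjustment; BH is the default of
the differential-analysis tooling it invokes and is the standard FDR
control in metabolomics, so BH it is.

The volcano categorization is three-tiered on the adjusted scale:
non-significant when `-log10(adj p) < 1`; mid-significant when the p
criterion passes and `|log2FC| < 3`; significant when both pass
(fold change beyond ±8). Two boundary decisions were open and are fixed
here: threshold values count as passing (determinism at the boundary),
and the *significant* tier requires the p criterion as well as the fold
change — a fold-change-only red tier would color features with no
statistical support, which the plot geometry this rule reproduces does
not show.

## Steroid-sulfate search

Sulfate-labeled features are matched against a theoretical list of
deprotonated steroid-sulfate m/z at ±5 ppm, boundary inclusive. Every
qualifying (feature, compound) pair is emitted — isomeric sulfates
share a formula, so one feature legitimately carries several candidate
names, ranked by |ppm| for manual review. The shipped list has 26
entries: the five compounds validated in the administration work plus
21 representative steroid sulfates of equine steroid-hormone
metabolism. The original screening list is unpublished, so the extended
entries are documented stand-ins; laboratories should substitute their
own validated list. The cross-dataset consistency filter retains a
compound only when it was hit in at least `min_datasets` of the
per-horse search runs, the guard against one-off matches.

## Biomarker evaluation

Univariate screening reports, per marker: rank-based AUC (Mann–Whitney
with midranks, oriented to at least 0.5 with the direction recorded), a
two-sided Welch t-test on log2 areas, `log2FC = log2(mean positive) -
log2(mean negative)`, and a behavior-cluster id from average-linkage
hierarchical clustering of `1 - |Spearman rho|` — absolute correlation,
because an anticorrelated marker pair carries the same classification
information and should co-cluster.

The multivariate stage is Monte-Carlo cross-validation of a random
forest: 30 stratified 2/3 train – 1/3 holdout splits, 300 trees per
forest, library defaults otherwise, all under one seed (the full report
is byte-identical across reruns). Stratification prevents single-class
holdouts. Reported are the pooled ROC over all holdout class
probabilities across runs with its trapezoidal AUC; a 95% band from the
2.5/97.5 percentiles of per-run holdout AUCs (the upstream tool reports
a "95% confidence" band without a method; percentiles over runs are the
transparent choice); a confusion matrix from per-sample majority vote
over the runs in which the sample was held out, with probability 0.5
and tied votes resolving positive (IM), documented rather than left to
chance; and permutation importance (mean decrease in accuracy) averaged
over runs. No scaling or transformation precedes the forest, matching
standard practice for tree ensembles. With very few runs a sample may
never be held out; such samples are excluded from the confusion matrix
with a warning (at the default 30 runs this is vanishingly rare).

## The synthetic administration study

The generator reproduces the *design* of the administration study the
analysis assumes, with known truth:

* **Schedule** — daily collections over 21 days (0–504 h) plus
  frequent-sampling days (2, 4, 6, 8, 12 h after dosing) on the first
  and last administration day of each route (days 0/14 oral, days 0/7
  IM): 32 time points per horse. The default design is one oral and one
  IM horse in technical triplicate with the oral horse's 480 h
  collection missing, which yields exactly 183 post-administration data
  points once time zero is removed — the shape of the classification
  dataset.
* **Abundances** — log-normal around group means (multiplicative error
  guarantees positivity, the standard model for peak areas). Markers
  shift by a shared post-administration log2 effect and by ± half the
  planted IM-vs-oral log2 effect; the five default markers carry the
  reported route effects (+1.15, −0.936, −3.35, 0.109, −3.05) at the
  reported retention times. Technical triplicates share one biological
  draw and differ only by technical CV. Biological CV 0.4 and technical
  CV 0.1 for markers (0.3/0.1 for background), base abundances, and the
  shared post-administration shifts are generator choices — the source
  study reports no abundance distributions — declared once here and
  used as the package's study conditions everywhere.
* **QCs and controls** — pooled QC is the per-feature mean of the first
  horse's study samples (a pooled aliquot of a single administered
  horse) plus technical noise, injected at the sequence head and every
  10 study injections; two external controls are baseline-level draws
  from unrelated horses.
* **Drift and missingness** — every injection is multiplied by a
  monotone 0.8 → 1.2 linear drift over injection order (detectable, and
  correctable by LOWESS) with 2% lognormal injection noise; 2% of study
  cells are censored missing at random.
* **Spectra** — one DDA spectrum per feature. Sulfated features carry
  diagnostic peaks (all six channels, strong, for markers; 2–4 channels
  at moderate intensity for the 18% of background features flagged
  sulfated) with Poisson intensity jitter and sub-millidalton mass
  error. All features carry 5–12 decoy fragments drawn uniformly over
  m/z 100–400 but kept at least 0.05 Da away from every diagnostic
  fragment m/z and neutral-loss position, so a non-sulfated feature's
  profile is exactly zero; background feature m/z are likewise kept
  0.05 Da away from every entry of the reference list, so no decoy can
  hit the searcher at 5 ppm.

What the simulation deliberately does **not** model: pharmacokinetic
time-course structure (abundances fluctuate around a single post-
administration level rather than rising and clearing), between-horse
variation beyond the two simulated animals, correlated drift across
features, chimeric spectra, isotope clusters, and adduct ambiguity.
Passing tests therefore demonstrate that each stage recovers what it
assumes — planted effects, planted sulfation, planted markers — not
that real horse urine is this clean; on real data the univariate AUCs
and the pooled forest AUC will be lower than the near-ceiling values
the synthetic study produces, because real within-horse time dynamics
add variance the generator omits.

## Interfaces and the end-to-end run

The stages are plain functions over a `feature_table` container and
tidy tibbles, so any subset can be scripted directly; `run_pipeline()`
executes simulate → annotate → normalize → cluster → differential →
search → biomarker, writing each stage's output as delimited text plus
a JSON manifest (package version, seed, full configuration, per-stage
row counts). Report files open with a one-line provenance header; the
feature-table and MGF files keep their interchange formats unadorned —
their provenance lives in the manifest — because the table dialect
reserves row one for sample IDs. Configuration is a validated nested
list, YAML-loadable, with unknown keys rejected by name. Fixed-seed
reruns into a clean directory are byte-identical, which the acceptance
checks verify.

Problem sizes used throughout the tests and the acceptance script — 305
features (5 markers + 300 background), 211 injections, 30 MCCV runs of
300 trees — are the package's default desk-scale study; they keep a
full run in seconds while preserving the 183-point classification
dataset shape.

## Known limitations

* The 26-entry search list is a documented stand-in beyond its five
  validated compounds.
* Sulfate isomers are not distinguished; the searcher reports all
  formula matches and defers isomer resolution to retention time and
  reference standards.
* The differential stage models two groups only (no time-course splines
  or mixed effects across horses).
* Glucuronide diagnostics, positive-mode adducts and charge states
  beyond 1− are out of scope; the screen is negative-mode sulfates.
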