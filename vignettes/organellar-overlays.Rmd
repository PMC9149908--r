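---
title: "Organellar map overlays: models, parameters and design choices"
author: "orgmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organellar map overlays: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgmap)
```

## The reference map and its vocabulary

`orgmap` consumes a fixed 2-D organellar reference map: one protein per
row with a UniProt-style accession, t-SNE x/y coordinates (unitless) and
one of 13 assignment labels. The map is immutable input — the package
never re-embeds, refines or re-assigns coordinates; all spatial reasoning
is a join by accession.

Two deliberate distinctions run through the whole package:

* **`"unknown"` is an assignment, not an absence.** Proteins that spread
  over multiple density-gradient fractions receive the `unknown` label in
  LOPIT maps and occupy the diffuse centre of the embedding. They are
  tallied like any other compartment.
* **"Not in map" is an absence, not an assignment.** A detected protein
  whose accession has no map entry is kept in a separate `unmapped`
  ledger; `compartmentOf()` returns `NA` for it and it never enters a
  tally. Overlay points plus unmapped accessions always partition the
  detected input — a conservation invariant asserted by the test suite.

The label vocabulary is closed. Input spellings are resolved
case-insensitively and through an explicit alias table
(`compartmentAliases()`, e.g. `"ER"`); anything unresolvable is an error.
Fuzzy matching was rejected because silent label coercion would corrupt
compartment tallies irrecoverably.

Accessions are normalized on every boundary: uppercase, trimmed, and
isoform suffixes (`Q96NT5-2`) collapsed to the primary accession by
default, matching how organellar maps are keyed. There is no gene-symbol
fallback; cross-naming heuristics silently mis-map paralogues.

## Abundance binning

Label-free MS intensities span orders of magnitude and are roughly
log-normal, so overlays size-code a protein's value through
`binValues()`: log10 transform, then split into `nBins` (default 5) bins.
The default scheme is equal-frequency (`"quantile-log10"`, type-7
quantile breaks); `"equal-width-log10"` is available when absolute
dynamic range matters more than rank. Tie and edge rules are fixed so
that binning is a deterministic, monotone function of the data: intervals
are right-closed (a value on an internal break falls in the lower bin),
duplicated quantile breaks are collapsed (so heavily tied data occupy
fewer than `nBins` bins), and an all-equal input collapses to bin 1. A
naive sort-and-scan oracle reproduces the implementation bin-for-bin in
the tests.

## Proximity-labeling enrichment

The enrichment statistic is the plain abundance ratio
`Elute / W-2` per protein, with no between-fraction normalization — none
is part of the workflow this package implements, and silently rescaling
fractions would change the benchmark's meaning. Presence is handled
explicitly: each protein is `both`, `numerator_only`,
`denominator_only` or `neither`, and a ratio exists only for `both`.

* **Cutoff rule.** `applyCutoff()` passes a protein iff
  (`both` and ratio ≥ cutoff) or (`numerator_only` and
  `includeNumeratorOnly`). The boundary is inclusive ("at least
  *k*-fold"). Numerator-only proteins — detected in the eluate, absent
  from the wash — are included by default: absence from the wash is the
  strongest enrichment signal, and imputing a pseudo-count denominator
  would manufacture a fake ratio. They remain distinguishable by status
  in every output.
* **Carboxylase benchmark.** The four endogenously biotinylated human
  carboxylases act as positive controls for streptavidin selection.
  `carboxylaseBenchmark()` reports per-control ratios, their min/max and
  the total-abundance ratio Σnum/Σden over controls detected in both
  fractions; controls missing from a fraction are excluded and reported,
  never imputed. `suggestCutoff()` turns the benchmark into a cutoff
  under three policies: `fixed` (default value 3, the conventional
  choice), `min_control` (the weakest genuine binder sets the floor) or
  `total`.
* **Missing values.** Blank, `NA` and zero abundances are all treated as
  "not quantified": a label-free zero ordinarily means not detected, and
  the ratio logic presumes detection. This single missing-value
  convention is applied at load time so every downstream operation sees
  one representation.
* **Duplicates.** Supplementary tables sometimes repeat isoform-collapsed
  accessions; the loader's default policy is an error, with opt-in
  per-fraction `max` or `sum` aggregation, always logged.

## EV marker evaluation

`categoryRecovery()` is an exact set intersection between the detected
proteome and each of the five marker categories, reported as counts and
percentages (1 decimal; undefined for an empty category). Categories are
disjoint by construction — an accession in two categories is a load-time
error — so recoveries are well defined. Roles follow categories
(1, 2, 5 = ev-marker; 3 = contaminant; 4 = subtype).

`preparationReport()` adds the mapped fraction and the marker-region
versus contaminant-region shares of the mapped detected proteome. The
region sets default to plasma membrane/lysosome/ER/cytosol versus
mitochondria/nucleus/nucleus-chromatin/ribosomes and are configurable.
The report is descriptive: vesicle-preparation quality judgments are
qualitative in practice, so no good/poor verdict is issued unless the
user configures a contaminant-share threshold (off by default).

## Region ellipses

Published overlay figures annotate regions (P, U, N, R, M, C, ER) with
drawn ellipses, but no construction rule accompanies them, so the package
defines one deterministically: an ellipse for a compartment set has
centre = mean of member coordinates and covariance = sample covariance
scaled by `kSigma²`. The default `kSigma = 2` covers the bulk of a
Gaussian cluster. Fewer than 3 members is an error; identical member
coordinates yield a zero-covariance ellipse with a warning rather than an
error, so collapsed synthetic clusters remain drawable. Region roles
(marker/contaminant/neutral) are configuration, never inferred.

## The synthetic-data generators

The generators exist so the full pipeline — load, overlay, fold change,
benchmark, cutoff, marker evaluation — runs against data with known
ground truth, deterministically under a fixed seed.

* **Map** (`generateReferenceMap`): 12 Gaussian clusters evenly spaced on
  a circle (radius 30, σ = 2.5) plus a broad central `unknown` cloud
  (σ = 12), ~1065 proteins with cluster sizes roughly proportional to a
  real organellar map but scaled down so simulations complete in seconds.
  The four carboxylase accessions are placed in the mitochondria cluster.
* **BioID** (`generateBioidExperiment`): defaults of 60 planted
  interactors in the plasma-membrane bait compartment at a 10× elute/wash
  effect, 400 background proteins at 1×, multiplicative log-normal noise
  with σ = 0.2 in log10 units per measurement (a typical label-free
  spread; the elute/wash ratio then carries σ√2 ≈ 0.28), and carboxylase
  controls with configured ratios spanning 2.1–68.8, the kind of range
  such controls display in practice. In the control group (unfused
  ligase) interactors behave as background. With noise σ = 0 every
  planted ratio is exact, which the tests exploit.
* **EV** (`generateEvExperiment`): a disjoint marker set of the MISEV2018
  category sizes 110/55/195/41/160 (561 total) drawn from the
  appropriate regions, and two preparations differing in
  contaminant-region detection probability (0.9 × `contaminationLevel`
  for preparation B; a level of 0 admits no contaminant-region protein).

These defaults are the package's study conditions and are not tuned per
analysis. What the generators deliberately do **not** emulate: peptide
level effects (shared peptides, protein inference), intensity-dependent
missingness (dropout exists only as an optional abundance floor, default
off), correlated noise between fractions, and the unassigned fringe of
real maps (every synthetic protein has a compartment, though `unknown`
plays that role spatially). Passing tests on synthetic data therefore
demonstrate the correctness of the computations and the recoverability of
planted structure — not that any particular real preparation is clean.

## Numerical and I/O choices

Quantile breaks use R's type-7 default; coordinates are validated finite;
percentages are reported at 1 decimal alongside an integer display value
(mirroring how mapped fractions are quoted in the field); tallies always
carry all 13 compartments, zeros included, in a fixed row order; TSV/CSV
writers quote nothing and encode missing as empty cells, and identical
configurations reproduce byte-identical tabular outputs (asserted in the
tests). Image output via cairo (`svg`, `png`, `pdf`) is deterministic for
fixed inputs. Every pipeline run writes a provenance JSON with the
config, package version and input MD5 checksums.

Problem sizes throughout the test suite and acceptance script — a ~1000
protein map, hundreds of pulldown proteins, 400-instance oracle sweeps —
were chosen as the smallest sizes at which the statistical checks are
stable across seeds.

## Known limitations

* The reference map is treated as ground truth; proteins that relocalize
  under the experimental condition will be judged against their
  resting-state coordinates.
* Mapped-fraction statistics depend on map coverage (~5000 proteins in
  current LOPIT maps versus ~10000 expressed), so low mapped fractions
  can reflect map depth rather than sample quality.
* The enrichment statistic uses single-point abundances; replicate-aware
  variance modelling is out of scope.
* Region ellipses summarise coordinates of *assigned* proteins and may be
  misleading for compartments with long tails into the unknown centre.
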