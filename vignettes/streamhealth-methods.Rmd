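---
title: "Methods: guild-based stream health assessment with streamhealth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guild-based stream health assessment with streamhealth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamhealth)
```

## The assessment model

`streamhealth` assesses the ecological health of wadable rivers and
streams by linking fish community structure to chemical water quality.
The premise is the standard one in bioassessment: communities at
chemically disturbed sites differ systematically from those at clean
reference sites, so a well-chosen summary of community composition is an
indicator of chemical condition.

The package's central summary is the **fish ecological entity** (FE): the
group of species whose three guild labels — trophic (omnivore,
insectivore, carnivore), habitat (benthic, riffle-benthic,
riffle-benthic-and-water-column, water column), and tolerance (sensitive,
intermediate, tolerant) — match exactly. Entities translate taxonomy into
function: a riffle-dwelling sensitive insectivore entity responds to
siltation and organic pollution regardless of which particular species
carries the labels. Site-by-entity relative abundances feed a nonmetric
multidimensional scaling (NMDS) on Bray–Curtis dissimilarities, and the
resulting **NMDS1 site scores** are the continuous health ordinates that
are regressed on chemical indicators.

Alongside the ordination route sit two discrete multimetric indices:

* the **mWPI** (multimetric water pollution index) over seven chemical
  metrics — TN, TP, TN:TP, BOD, TSS, EC, sestonic chlorophyll-a — each
  scored 5/3/1 and summed (range 7–35, higher = cleaner);
* the **mIBI-F** (fish index of biotic integrity) over eight community
  metrics — native species richness, riffle-benthic species, sensitive
  species, %tolerant individuals, %omnivores, %native insectivores,
  native individuals, %anomalies — scored 5/3/1 and summed (range 8–40).

## Entity construction choices

Entity numbering is not inherent in the definition, so the package fixes
it deterministically: descending member count, ties broken by the
lexicographic order of the (trophic, habitat, tolerance) triple. Species
present in abundance data but absent from the guild table are a hard
error rather than a silent drop, because silent drops would break the
conservation invariant (total individuals identical before and after
entity aggregation) that several downstream quantities rely on. Relative
abundance and occupancy are reported to one decimal with half-up
rounding, the convention of the field's summary tables. The native flag
is carried through entity construction untouched; it only matters to the
mIBI-F metrics.

## Index scoring choices

The exact numeric criteria behind published 5/3/1 scorings are
programme-specific and typically live in supplementary material, so the
package makes criteria fully config-driven (`metric_criterion()`,
`read_criteria()`), with documented defaults chosen as round numbers
inside published monitoring ranges for wadable streams. Two conventions
the defaults encode:

* **Boundary values take the better score.** Published criteria are
  silent on ties; awarding the better bin is the generous and, more
  importantly, documented choice.
* **Directions.** %tolerant, %omnivore and %anomalies degrade upward and
  score lower-is-better; TN:TP scores higher-is-better because a high
  ratio indicates phosphorus-poor, cleaner water; all other chemical
  metrics are pollutant-like.

The mWPI class bands default to very poor 7–13, poor 14–19, fair 20–25,
good 26–30, excellent 31–35, consistent with the published narrative that
scores above 30 are excellent and 13 or below very poor. No comparable
published banding exists for the mIBI-F total, so its default bands
trisect 8–40 the same way and should be treated as placeholders for
programme calibration. Sites with zero fish get no fabricated score: the
biological metrics are undefined there, the site is excluded from
biological stages with a logged warning, and it remains in all chemical
stages.

## Ordination: a from-scratch Kruskal NMDS

The NMDS is implemented in the package rather than delegated, because the
ordination is the method's core and its every numerical choice needs to
be inspectable:

* **Stress.** Kruskal stress-1,
  `sqrt(Σ(d − d̂)² / Σ d²)`, the standard reported form.
* **Disparities.** Pool-adjacent-violators isotonic regression over pairs
  ordered by ascending dissimilarity, with *primary* (weak) tie
  treatment: within blocks of tied dissimilarities the configuration
  distances are taken in ascending order, so ties are free to differ
  without penalty. The PAV fit preserves the (weighted) sum and is the
  exact least-squares monotone fit.
* **Optimiser.** Alternating isotonic fit and steepest descent on the
  analytic stress gradient (disparities held fixed), with step halving:
  a step is accepted only if the fully re-fitted stress strictly
  decreases, which makes the per-iteration stress trace non-increasing by
  construction. Convergence is declared at a relative stress change below
  `tol` (default 1e-7), with `max_iter` 300.
* **Starts.** Best of `n_starts` (default 20): start 1 is a classical
  metric scaling (cmdscale) configuration with tiny jitter, the rest are
  seeded uniform draws scaled to the distance range. Everything is
  deterministic given `seed`.
* **Orientation.** NMDS solutions are arbitrary up to rotation and
  reflection, so results are centred, rotated to principal axes (axis 1 =
  maximum variance), and sign-fixed so each axis correlates non-negatively
  with a reference covariate (by default the site totals of the first
  feature column, carried on the dissimilarity matrix). Mirrored or
  rotated inputs therefore produce identical outputs.
* **Degeneracy.** Near-zero stress with coincident points is flagged in
  the result record rather than hidden.

The minimum problem size is `k + 1` sites (the smallest embeddable
configuration, e.g. a triangle in two dimensions). Entity ordinations use
per-site relative abundances; mIBI-F ordinations use raw metric values
range-standardised to [0, 1] per metric, since Bray–Curtis needs
non-negative commensurate features. Wisconsin/sqrt auto-transformation is
deliberately off; both inputs are already proportions or standardised.

## Chemistry clustering

Sites are clustered on log10-transformed chemistry (all 13 variables,
including TN:TP; a flag can drop it if collinearity with TN and TP is a
concern). The offset rule for zeros is half the smallest positive
observed value of the column, applied only when zeros are present. No
z-scoring is applied by default — the log transform is the only published
standardisation — though the distance step accepts any matrix if a user
standardises first. Agglomeration is Ward.D2 (Lance–Williams on squared
Euclidean distances, square-root heights) via `stats::hclust`, verified
in the test suite against a brute-force implementation that recomputes
within-cluster variance from raw coordinates. `k` is a user parameter
(no automatic selection is offered, as no published criterion exists);
cluster ids are renumbered by descending mean mWPI so cluster 1 is always
the cleanest — the `SC-1 … SC-k` convention.

## Gradient statistics

Pearson correlations use pairwise-complete observations with
t-distribution p-values (n − 2 df); simple OLS reports slope, intercept,
R² (identically the squared Pearson r) and the two-sided slope p-value,
with 95% confidence bands available from the attached fit. Chemical
indicators are log10-transformed before regression — once, recorded in a
metadata flag. The correlation screen reports raw p < 0.05 significance
with no multiplicity correction by default (matching common
correlation-plot practice); Holm adjustment is available. Stream order is
treated as numeric.

## What the synthetic generator emulates — and what it does not

The generator plants a single pollution gradient `g` uniform over sites:

* **Chemistry.** Each variable follows
  `10^(log10(baseline) + slope·g + N(0, sd²))` — log-linear trend with
  lognormal noise. Baselines and slopes are calibrated so simulated
  ranges span published monitoring ranges for wadable streams
  (EC ≈ 113–607 µS/cm, TP ≈ 7–208 µg/L, Chl-a ≈ 0.5–143 µg/L, …);
  pollutants rise with `g`, WT/DO/TN stay near-flat, and TN:TP is
  computed from TN and TP so it falls as phosphorus accumulates.
* **Community.** 50 species in the 19-entity guild plan of the bundled
  regional survey (member counts 8,6,5,4,3,3,3,2×6,1×6). Counts are
  negative-binomial (dispersion 4 by default — overdispersion is the
  ecological norm; `Inf` gives the Poisson limit) with log-mean linear in
  `g`. Response slopes are set at the entity level, because that is where
  the signal lives: sensitive entities −3, riffle-benthic −2, tolerant
  omnivores +2.5, other tolerant +1.5, the ubiquitous generalist 0, the
  rest −0.5, with small per-species jitter (sd 0.2). Anomaly counts are
  binomial per cell with probability `0.002 + 0.03·g`.
* **Covariates.** Elevation falls linearly with `g` (≈360 m to ≈15 m),
  stream order rises, forest cover falls while urban and agricultural
  cover rise, rescaled to keep the three proportions within 100%.

Not emulated: spatial autocorrelation between sites, river-network
topology, seasonal dynamics, species turnover unrelated to the gradient,
and multi-stressor interactions. Passing the recovery tests therefore
shows the chain detects a clean monotone chemical gradient at realistic
noise — not that it would resolve confounded real-world gradients.

A note on problem sizes: the default scenario is 41 sites × 50 species,
matching the survey scale the method targets; the test suite's oracle
comparisons run on instances of up to 8 points (where brute-force
enumeration of monotone partitions and Ward merges is exact) and the null
calibration uses 100 generator seeds.

## Numerical details and edge cases

* Rounding of reported percentages is arithmetic half-up, not banker's.
* A value equal to a scoring threshold takes the better score.
* Metric scoring rejects non-finite values; classification rejects totals
  outside the band coverage; band configurations must tile the range with
  no gaps or overlaps.
* OLS with a constant response returns slope 0, R² 0 and an NA p-value
  rather than the numerically unstable `summary.lm` output.
* Bray–Curtis rejects all-zero rows by site name; relative abundance
  rejects all-zero scope units the same way.
* All generator randomness is routed through integer seeds (per-stage
  offsets below 2^31), so bundles are bit-reproducible across platforms.

## Known limitations

* The shipped scoring criteria and mIBI-F bands are defaults, not a
  calibrated standard; programmes must supply their own criteria files
  for regulatory use.
* The NMDS optimiser is a careful but plain steepest-descent scheme; on
  very large site sets (hundreds) a specialised ordination package will
  be faster.
* Cluster renumbering by mean mWPI presumes the mWPI is computable for
  every site; with missing chemistry the raw merge-order ids are kept.
* The bundled survey summary carries one internal inconsistency of its
  source table (the dominant entity's printed relative abundance reflects
  double rounding); the package reports the arithmetically correct value.
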