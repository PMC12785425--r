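---
title: "Methods: behavioral emotionality and marker co-expression networks under graded chronic restraint stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral emotionality and marker co-expression networks under graded chronic restraint stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crsnet)
```

## The study design this package models

crsnet analyzes duration-graded chronic restraint stress (CRS) cohorts:
six stress durations (0, 7, 14, 21, 28, 35 days), two sexes, eight animals
per cell (96 at study start). Each animal contributes (a) weekly behavioral
measures — coat state, weight gain, sucrose preference, and overnight
PhenoTyper zone-time traces around a 1 h light challenge — and (b) an
11-marker prefrontal-cortex panel quantified post-mortem: eight proteins by
Western blot and three interneuron transcripts (SST, PV, VIP) by qPCR. The
panel partitions into GABAergic (GAD67, SST, PV, VIP), synaptic (VGLUT1,
PSD95, SYN1, GPHN) and astroglial (GLT1, GFAP, GS) compartments, and the
scientific question is how the *joint* correlation structure of these
markers — the local tripartite-synapse network — reorganizes with stress
duration, separately in males and females.

## Behavioral scoring

**Residual avoidance (RA).** The exact historical formula for RA is
defined in the PhenoTyper literature rather than restated in most papers
that use it; this package implements a reconstruction that satisfies every
published contract: per animal, the zone-time total `T` over the five 1 h
bins following the light challenge (clock bins `[h, h+1)`, hours 0–4 for a
challenge at 23:00–24:00) is compared to the mean of sex- and week-matched
controls, `RA = s·100·(T − T̄c)/T̄c`, with sign `s = +1` for the shelter
zone and `−1` for the food zone so that avoidance is always positive. This
makes the control mean identically zero — a construction the test suite
asserts for every simulated cohort — and leaves RA invariant to zone time
outside the post-challenge window. Whether the original formula divides by
the control mean of a lit-zone *deficit* rather than the raw zone total
cannot be established from the published constraints alone; the
reconstruction is switchable through the `challenge_start`/`post_hours`
arguments if a different windowing is required.

The reference population is the *same-sex, same-week* control cell. A
sex-pooled reference would also satisfy the cohort-level zero-mean
property, but only sex stratification gives a zero mean within each sex,
which is what the downstream sex-split analyses assume.

**Z-emotionality.** Five measures are z-scored against sex-matched
controls and direction-aligned so higher = greater deficit: coat state,
shelter RA and food-zone RA enter with +1; weight gain and sucrose
preference with −1 (chronic stress blunts both). The per-animal score is
the mean of the *available* aligned z-scores, so a missing measure (e.g.
an animal excluded from sucrose testing that week) reduces the divisor
rather than biasing the score. A control measure with zero variance (which
does happen for the 0.5-step coat score in small control cells) is dropped
with a warning rather than producing infinite z-values.

## Marker quantification and cleaning

Western-blot bands are divided by each lane's total-protein signal; qPCR
targets use `rel = 2^−(Ct − geomean(Ct_refs))` with the *geometric* mean
of the three reference-gene threshold cycles (actin, GAPDH, cyclophilin
G). Both are expressed as percent of the control-group mean, so CRS0
averages 100 by construction. The percent-of-control reference pools the
sexes (matching how such panels are usually plotted); sex-stratified
normalization is a one-argument change. Note one numerical subtlety: with
a geometric reference mean, shifting all cycle values by a constant is
only *approximately* neutral (it is exact for an arithmetic mean); the
package follows the geometric-mean definition and the test suite asserts
the exact invariance that does hold (a uniform shift of the target Ct).

Outliers are screened per marker and group with a two-sided Grubbs test at
α = 0.05, at most one removal per (marker, group) — the appropriate
small-sample single-outlier policy for n ≈ 8–16, and the screen's
false-positive rate is verified against α on simulated null data. Which
outlier test the original StatView-era analyses used is not documented;
Grubbs is this package's documented choice. Missing and removed values are
imputed with the group × sex mean. Stratifying imputation by sex prevents
a sex effect from leaking into the sex-split networks; imputation
preserves each stratum's mean exactly.

## Association analyses

Marker–marker and marker–behavior correlations use Pearson's r, except
that any pair involving the ordinal coat-state score is forced to
Spearman's ρ (midrank ties, t-approximation for p — standard at n ≈ 90).
The 55 marker–marker tests are corrected as one Benjamini–Hochberg family;
marker–behavior results carry their BH q alongside the raw p for
transparency, since published analyses of this kind typically report raw p
for the behavior correlations. PCA standardizes each marker (the markers
are on heterogeneous percent scales), and each component is oriented so
its largest-magnitude loading is positive, making scores and loadings
deterministic across platforms.

## Co-expression networks and module preservation

Within each duration × sex cell (n = 8 animals), the network is the
Pearson correlation matrix over animals; Fisher z = atanh(r) matrices are
carried for completeness (perfect correlations are clamped at
atanh(1 − 1e−12)); the weighted adjacency is `|r|` with zero diagonal.

**Module detection.** Markers are clustered by average linkage on the
signed dissimilarity `d = 1 − r` (so strongly anti-correlated markers are
*distant* — the signed-network convention). On an 11-node dendrogram,
adaptive tree-cutting routines add no discriminating power, so the package
cuts at a fixed fraction of the maximum merge height and keeps branches of
at least `min_size = 3` markers as modules; smaller branches stay
unassigned. The default `cut_fraction = 0.7` was chosen from the geometry
of the planted-structure recovery problem: within-module merges sit far
below the cut (d ≈ 1 − r_within) while between-module merges sit near
d ≈ 1, and a 0.7 fraction leaves a wide margin on both sides. Fractions
near 1 are unreliable because the two highest merges of equally separated
modules differ only by sampling noise — average linkage's min-selection
biases the first between-block merge low — so a 0.99 cut splits only the
top join in a substantial share of replicates. Recovery of 4/4/3 planted
blocks (within-r 0.8, between-r 0, n = 200) is exact in 100/100 seeded
replicates at the default.

**Preservation statistic.** For each module M of group A, preservation in
group B is `max_N |M ∩ N|/|M|` over B's modules (unassigned markers never
count), ties broken toward the larger candidate then the lower label.

**Permutation test.** The null hypothesis — modules identical across the
two groups — is exactly exchangeability of animals between the cells, so
the test pools the two cells' animals, re-splits them at random into
pseudo-cells of the original sizes, and rebuilds *both* networks and
partitions per draw. (Schemes that keep one observed partition fixed are
not exchangeable: pseudo-cells share animals with the cell that defined
the observed modules, biasing null preservation upward.) Per-draw module
preservations are matched to observed modules by rank (size descending,
then label); a draw whose pseudo-partition lacks a given rank contributes
preservation 1, which is neutral-to-conservative for the one-sided
low-preservation alternative. Empirical p-values use the add-one
(permutation-floor) estimator `(#{null ≤ obs} + 1)/(n_perm + 1)`, so the
smallest attainable p at the conventional 10,000 permutations is
≈ 1 × 10⁻⁴ — the "p < 0.0001" floor. Module p-values are combined per
group pair with Fisher's method (−2Σln p on 2k df) and the 15 pair-level
p-values per sex are BH-corrected. Combining before BH (rather than the
reverse) is the order that yields one (p, q) pair per group comparison,
which is how such results are reported; with a single module — the common
case on an 11-marker panel — the two orders coincide. Degenerate draws
(a constant marker in a pseudo-cell) are redrawn and counted.

Calibration is verified empirically: on null cohorts (no group effects)
the pair-level Fisher p rejects at α = 0.05 at a rate statistically
compatible with 0.05 over 200 replicate datasets (slightly conservative,
as expected from the rank-1-dominated Fisher combination), and the same
holds marker-wise for the hub-change test below.

## Hubness

Kleinberg's hub score is the principal eigenvector of the symmetric
non-negative adjacency (for undirected graphs hub and authority scores
coincide), computed by power iteration to relative tolerance 1e−10 and
max-normalized to 1. The iteration runs on the spectrally shifted matrix
`A + sI` with `s = max row sum`: the shift preserves eigenvectors but
makes the top eigenvalue strictly dominant even on bipartite graphs (±λ
pairs), where plain power iteration oscillates. Hub scores are computed on
the *full* weighted adjacency over all 11 markers — no module restriction
and no edge threshold — because the network measures are extracted from
the network as a whole; the degree metric alone uses an inclusion
threshold (default |r| ≥ 0.3, configurable) so that degree is not
trivially n − 1 on a dense correlation graph.

Hub-score change versus the same-sex control cell is tested by the same
label-permutation scheme (both networks rebuilt per draw), two-sided on
the absolute difference, add-one estimator; the direction is carried
separately. Compartment-level effects combine a compartment's marker
p-values with unweighted Stouffer meta-analysis on signed normal quantiles
`z_i = d_i·Φ⁻¹(1 − p_i/2)`, `Z = Σz_i/√k` — unweighted because the
markers enter as equal members of the compartment; the observed hub-score
difference supplies each marker's sign.

## The synthetic-cohort generator

Because the underlying animal data are not publicly deposited, the
generator is a first-class module that reproduces the *design* and the
*qualitative effect structure*: 6 × 2 × 8 animals; marker vectors
`100 + effect(marker, group) + sex offset + ε` with multivariate Gaussian
ε (SD 15 percent-units, a typical immunoblot coefficient of variation),
truncated at 0, and compartment-block correlation (within 0.5, between
0.1 by default); missingness at 2%. Default marker effects are graded
declines of round magnitude (−5 to −30%) with the presynaptic marker
VGLUT1 affected early and SYN1/PSD95 late; behavioral effects ramp with
cumulative stress exposure, with the shelter-time increase present from
the first stressed week and the sucrose deficit programmed only for the
35-day group. These profiles are *fixtures shaped like the reported
qualitative findings, not estimates* of any real effect size.

Mean shifts cannot change within-group correlation structure, so network
reorganization is emulated separately: `network_effects` multiplies the
within-compartment correlation per group × sex, and the default degrades
female coherence at 28–35 days (×0.6, ×0.3) to mimic late network
fragmentation in females. PhenoTyper traces draw per-bin zone minutes from
scaled Beta(2, 2) distributions over a 7 p.m.–8 a.m. session (the
published session description contains a daytime/overnight inconsistency;
an overnight session is the only reading compatible with an 11 p.m.
challenge), with stress adding shelter minutes only in the post-challenge
window.

What the generator does **not** model: litter, cage and estrous effects;
heteroskedastic or heavy-tailed assay noise; correlated missingness;
attrition; non-Gaussian behavioral distributions. Passing tests therefore
demonstrate correctness and calibration of the *statistics* under a
plausible data-generating process, not recovery of the original study's
numerical results — the published group-level numbers depend on raw data
available only on request and are out of scope here.

## Numerical choices and problem sizes

- Permutation defaults: n_perm = 10,000 for final analyses; the pipeline
  demo and the test suite use 100–500, and calibration checks use 200
  replicate null datasets at n_perm = 500 — sizes chosen so the full
  suite runs in minutes on one CPU while keeping binomial confidence
  intervals tight enough to detect miscalibration.
- Planted-recovery checks use 4/4/3 blocks, within-r 0.8, n = 200, 100
  seeds; oracle-equivalence checks compare BH, Fisher, Stouffer,
  preservation and hub scores against brute-force implementations on
  1,000 random instances at 1e−8 relative tolerance.
- Determinism: every stochastic routine takes an explicit seed; the
  pipeline derives per-stage sub-seeds from one global seed, and
  identical configurations produce byte-identical CSV outputs.
- Degenerate inputs: constant markers abort network construction by name;
  zero-variance control measures are dropped from Z with a warning;
  zero-total-fluid weeks yield missing sucrose preference; empty CSV
  cells are the only missing-data encoding.

## Known limitations

- n = 8 animals per cell makes single-cell correlation estimates noisy;
  module partitions are correspondingly unstable, and the permutation
  test's power at this n is modest. This mirrors the scale of the
  motivating design rather than a recommendation.
- The static-height tree cut is a deliberate simplification for an
  11-node dendrogram; for panels of hundreds of nodes an adaptive cut
  would be preferable.
- The RA formula is a reconstruction (see above); absolute RA magnitudes
  may differ from implementations that normalize to a lit-zone deficit,
  though the zero-mean-control property and sign conventions agree.
- Fisher combination treats module p-values as independent; with multiple
  modules from one partition they are positively dependent, making the
  pair-level p slightly conservative (verified empirically, never
  anti-conservative in calibration runs).
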