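---
title: "Karyomorphometric methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyomorphometric methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyomorph)
```

This vignette documents the models behind the package, the conventions it
adopts where the cytogenetics literature leaves room, and the numerical
and design choices a maintainer would want spelled out.

## Measurement model and data invariants

The unit of observation is one chromosome in one metaphase spread, with
long arm L, short arm S and total length TL in micrometres. The package
enforces `L >= S > 0` (raw measurement tables frequently record arms in
arbitrary order, so rows with `L < S` are swapped by default and the
repair counted; a strict mode rejects instead — Levan's arm ratio
`r = L/S` presupposes the ordering). Where TL is supplied it is treated as
an independently measured quantity and only checked against `L + S`
within a tolerance (default 0.05 um, roughly the digitizing resolution of
measurement software on a well-spread metaphase); where absent it is
`L + S` by construction.

Within a metaphase, chromosomes are ranked by descending TL and
*homologue pairs are consecutive ranks* (1–2, 3–4, ...). This is a
modelling decision, not a measurement: in a karyotype whose chromosomes
all share one morphology class there is no banding or arm-ratio signal to
pair by, and size rank is the only information available. For karyotypes
with mixed morphologies a pairing that respects class before size would
be preferable; the package does not implement one.

## Morphometric statistics

* Arm ratio `r = L/S`, classified by lower-inclusive Levan bounds
  M `[1, 1.7)`, SM `[1.7, 3)`, ST `[3, 7)`, A `[7, Inf)`. The bounds are a
  `levan_scheme()` object and can be replaced; lower-inclusivity makes the
  classification a right-continuous step function of `r`, so a chromosome
  sitting exactly on a bound takes the more acrocentric class.
* Relative length `RL = TL * 100 / sum(TL)`, with the diploid metaphase
  as the default reference set (idiograms use the haploid per-pair
  representation instead, where the ten pair RLs again sum to 100).
* Asymmetry index `AI = sum(L) / sum(TL) * 100`, bounded in `[50, 100]`
  with the floor attained exactly when every chromosome has equal arms.
* Karyotype length `KL = sum(TL)` per metaphase, or the sum of per-rank
  mean lengths for a population summary; population summaries use the
  sample (n − 1) SD, appropriate at the small n (about 10 metaphases)
  typical of karyomorphometric studies.
* The karyotype formula renders diploid class counts in fixed order
  (`"2K = 10M + 10SM"`); the diploid arm number 2AN counts two arms for
  M and SM, one for ST and A. That convention is configurable because the
  literature is not unanimous about submetacentric and subtelocentric
  arms; the default matches common usage in ant cytogenetics.
* Measurement repeatability: the CV of per-specimen KL values, with a
  one-sample-SD outlier rule (`cv_validation()`). With only two
  specimens the rule can never fail, since `|x - mean| = |x1 - x2|/2`
  while the sample SD is `|x1 - x2|/sqrt(2)`.

## Population comparison: analysis of deviance with level pooling

Lengths are compared across populations with a Gaussian identity-link GLM,
whose deviance is the residual sum of squares; the analysis of deviance is
therefore exactly one-way ANOVA, and the explained deviance is the
between-group sum of squares tested by
`F = (deviance/df_factor) / (residual/df_residual)`. The Gaussian family
is the right default for a response that is a physical length several SDs
away from zero.

When the population effect is significant, levels are pooled by an
iterative contrast procedure: candidate pairs of current blocks are
examined in ascending order of their absolute mean difference, and the
first merge whose deviance increase is non-significant (F test with 1
numerator df against the current model, at `alpha = 0.05` by default) is
accepted; the blocks are then recomputed and the scan repeats until no
merge is acceptable. The literature describes level pooling procedurally
without fixing an algorithm; this greedy closest-means-first order was
chosen because it is deterministic, oracle-checkable by brute force (the
test suite re-derives it from explicit sum-of-squares arithmetic over all
candidate pairs), and has the two right limits: `alpha -> 0` pools
everything into one block, `alpha -> 1` pools nothing. Blocks get compact
letters in order of descending mean ("a" = largest), and degenerate
zero-variance data collapse to a single flagged block.

Per-chromosome tests use both homologues of each metaphase as
observations, so five populations of ten metaphases give 100 observations
and df (4, 95), while the karyotype-length test on per-metaphase KL gives
df (4, 45). The ten per-chromosome p-values are reported raw by default —
matching how such tables are conventionally published — with Holm
correction available behind a flag.

## Genome size from fluorescence histograms

Peak detection works on binned (channel, count) histograms: a bin is an
apex candidate if it holds the maximum count within ± one window
half-width (default 30 channels on a 1024-channel axis — wide enough to
cover ± 3 SD of a 2%-CV G0/G1 peak anywhere above channel ~120, narrow
enough to separate sample from standard peaks a hundred channels apart);
candidates whose windowed event count falls below `min_fraction` of total
events (default 5%) are discarded, and each surviving peak is summarized
by the event-weighted mean and SD of channels in its window. The truncated
window slightly deflates the SD estimate (by ~1–2% of the CV at the
default geometry), which is immaterial for the 5% QC rule.

The unknown's DNA content is `1C = (F_sample / F_standard) * 1C_standard`
(0.18 pg for the default *Drosophila* standard), the standard linear
internal-standard form; because it is a ratio of peak locations it is
invariant under any positive rescaling of the channel axis (instrument
gain). The standard peak is identified as the lowest-fluorescence
qualifying peak by default — correct whenever the sample genome exceeds
the standard's — or by proximity to a user-supplied expected channel.
Whether one ratios the 2C (G0/G1) peaks or doubles a 1C ratio is
immaterial under this linear model; the package reports 1C, 2C = 2·1C and
Mbp = pg × 978 together. QC fails a run when any used peak has CV > 5% or
fewer than 10,000 nuclei were acquired; population estimates average at
least three QC-passing replicates.

Debris modelling, doublet discrimination and cell-cycle deconvolution are
out of scope: the estimator assumes reasonably clean two-peak histograms.

## The synthetic-data generators

`table1_params()` exposes the packaged per-homologue mean ± SD total
lengths of the five ant populations (CI, TO, BG, MC, CC; 2n = 20) that
serve as the reference study conditions; `simulate_measurements()` draws
each homologue's TL independently from a Normal with those moments
(truncated at 0.1 um, negligible at these parameter values), an arm ratio
uniformly from `[1.0, 1.3]` (comfortably inside the metacentric class, as
appropriate for an all-metacentric karyotype), sets `L = TL·r/(1+r)`,
`S = TL/(1+r)`, and re-ranks by descending TL — the defaults (10
metaphases per population) mirror the reference design. All generators
are pure functions of (parameters, seed) and restore the caller's RNG
state.

Two deliberate simplifications matter for interpreting test results.
First, homologue lengths are drawn independently, with no within-pair or
within-metaphase correlation (none is published); real spreads share
condensation state, so real per-metaphase KL dispersion is likely larger
than the `sqrt(sum(SD^2))` the independence model gives. Second,
re-ranking after noise injection makes the per-rank summary means *order
statistics* of the generating distribution: the extreme ranks are biased
outward (up to ~2.7 SE at rank 20 under the reference parameters) while
central ranks and aggregate quantities (KL, rank-1 mean) are essentially
unbiased. Parameter-recovery tests therefore assert recovery on the
rank-1 mean and on KL, where the property genuinely holds, not on every
rank. Passing tests demonstrate that the pipeline recovers what the
generator encodes — not that real measurement error is Normal,
uncorrelated, or free of observer effects.

`simulate_histogram()` places the standard peak at a configurable channel
(default 200) and the sample peak at the DNA-content ratio times that,
each Gaussian with 2% CV by default, split 10,000 events evenly, with
optional uniform background, binned onto a 1024-channel grid so recovery
tests include realistic quantization error.

## Problem sizes and numerical notes

The test suite and acceptance script run at the reference design size —
5 populations × 10 metaphases × 20 chromosomes, 10,000-event histograms —
with 200-seed batteries for stochastic recovery claims and a 2000-run
null battery for type-I-error calibration of the deviance test; the whole
suite completes in well under a minute. Deviance comparisons treat values
below `1e-12 × (mean squared response + 1)` as zero to keep degenerate
(zero-variance) inputs from dividing by rounding noise; those inputs are
reported with explicit flags (`p = 1` for no explained deviance, `p = 0`
with a degeneracy flag for a perfect fit). SVG idiogram rendering writes
fixed-precision coordinates so identical inputs yield byte-identical
files, which the golden tests rely on; report stamping is opt-in for the
same reason.
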