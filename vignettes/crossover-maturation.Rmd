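---
title: "Estimating crossover maturation probabilities from germline cytology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating crossover maturation probabilities from germline cytology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioquant)
```

## The biological question and the model

In *C. elegans* meiosis, each of the six chromosome pairs normally receives
exactly one crossover-designated site, visible as a COSA-1 focus at late
pachytene; chromosome-wide interference limits designation to at most one
site per pair. A designated site that matures becomes a chiasma, the
physical link that holds a homolog pair together as one bivalent at
diakinesis. Diakinesis nuclei are scored by counting DAPI-stained bodies:
with 6 pairs, a nucleus shows between 6 bodies (all bivalent) and 12 (all
univalent), so the chiasma count is `12 - bodies`.

In mutants where designation and maturation are both compromised, the
focus-count distribution no longer predicts the DAPI-body distribution: the
number of designated sites exceeds the number of chiasmata realised. The
model in this package accounts for the discrepancy with one parameter. Each
designated site is assumed to mature independently with a common success
probability $p$, so a nucleus with $m$ foci contributes chiasma counts by
binomial thinning:

$$N'_k \;=\; \sum_{m \ge k} N_m \binom{m}{k} p^k (1-p)^{m-k},$$

where $N_m$ is the (possibly fractional) number of nuclei with $m$ foci and
$N'_k$ the adjusted number expected to show $k$ chiasmata. The estimate
$\hat p$ minimises the sum of squared differences between the adjusted
distribution and the chiasma distribution inferred from DAPI bodies.

### Preprocessing

Two scoring conventions precede the fit, in this order:

1. **Clamping.** Focus counts above 6 (miscounts of adjacent signals —
   interference allows at most one designation per pair) have their weight
   moved onto 6 (`clamp_counts()`).
2. **Normalization.** The focus-scored population is rescaled so its total
   equals the number of nuclei scored for DAPI bodies
   (`normalize_total()`); weights become fractional and are carried exactly,
   never rounded.

The order (clamp, then rescale) matters only at the third decimal of a
weight, but it is fixed and tested. The SSD is computed over the full
support $k = 0..6$ inclusive, on counts rather than proportions; since the
focus distribution is pre-normalised to the chiasma total the two choices
give the same minimiser.

### The estimator

`fit_maturation()` evaluates the SSD on a grid over $[0, 1]$ (default step
0.01, matching the whole-percent resolution at which maturation rates are
reported) and returns the minimising $p$, breaking ties toward the smaller
value — the conservative direction, attributing no more maturation than the
data require. Grid search is exact at the reporting resolution, has no
convergence or initialisation concerns, and makes the full objective curve
available for inspection (`plot()` of the fit draws it with the minimum
arrowed). On any distribution produced by the analytic forward map the
estimator returns the generating $p$ exactly at grid resolution; this
inversion property is part of the test suite.

```{r fit-example}
cosa <- count_dist(k = 0:6, weight = c(30, 10, 25, 40, 25, 60, 500))
fit <- fit_maturation(cosa, adjust_distribution(cosa, 0.39))
coef(fit)
```

The fitted object answers the usual model-object verbs: `summary()` tabulates
observed and adjusted distributions, `predict()` thins at any probability,
`residuals()` gives per-count discrepancies at the optimum, and `simulate()`
draws replicate per-nucleus data sets under the fitted model.

No confidence interval is reported by default: the original analysis makes
no interval claim, and the grid SSD objective has no exact sampling theory.
`simulate()` supports a parametric bootstrap for users who want one, clearly
as an extension.

## What the synthetic data emulate

`sim_config()` fixes the generative conditions; `simulate_cosa_and_dapi()`
draws, per nucleus:

- designated foci $k \sim \mathrm{Binomial}(6, p_\mathrm{designate})$ — the
  simplest generator respecting complete interference (at most one per
  pair). The designation mechanism itself is not modelled; in mutants where
  both designation and maturation degrade, the two knobs move independently.
- matured chiasmata $\sim \mathrm{Binomial}(k, p_\mathrm{success})$ — the
  model's own assumption, so estimator tests are exact parameter-recovery
  checks, not model-adequacy checks.
- observed DAPI bodies $= 12 - \text{matured}$, optionally degraded by a
  touching artifact: each of the $\lfloor d/2 \rfloor$ disjoint body pairs
  merges with probability `p_merge` (default 0). Chiasma inference ignores
  the artifact deliberately, matching scoring practice; no de-merging
  correction is applied.

Defaults describe a wild-type-like scoring effort: 6 gonads, 250 nuclei per
gonad, complete designation and maturation. Validation scenarios set the
probabilities explicitly; the estimator-recovery simulations use 1360
nuclei, a realistic total scoring depth for this kind of experiment.

`simulate_pairing_gonad()` places nuclei uniformly along a normalised gonad
axis and draws each nucleus's paired state from a per-zone probability
curve (default `(0.1, 0.3, 0.6, 0.9, 1.0)` over 5 zones, the wild-type
autosomal pattern of pairing rising to completion). Paired loci are placed
within the 0.75 µm calling threshold, unpaired loci beyond 1.5× of it —
the generator leaves a deliberate gap around the threshold so that calls are
unambiguous and round-trip tests are sharp.

`simulate_focus_gonad()` + `render_image_stack()` produce image stacks for
the counting pipeline: nuclei as filled spheres in a DNA-stain channel, foci
as anisotropic 3D Gaussians (σ 130 nm lateral, 300 nm axial) over a uniform
background, with every voxel drawn from a Poisson law — the standard
shot-noise model. Voxels default to 125 nm axially (the
structured-illumination Z spacing) and 100 nm laterally. Two generator
choices deserve emphasis:

- nuclei are laid on a jittered grid, spatially well separated; crowded,
  touching nuclei — common in real gonads — are *not* emulated, so the
  segmentation accuracy demonstrated here does not transfer to dense tissue.
- focus positions are rejection-sampled to a minimum pairwise separation of
  0.45 µm in PSF units (axial distances count for less by the lateral/axial
  sigma ratio), because counting is only defined on optically resolvable
  signals; a pair of true foci closer than the PSF is one spot in any image.
  Consequently the detection validation measures the pipeline's performance
  on resolvable foci, not the (undefined) ability to split sub-resolution
  pairs.

More generally, passing tests on these synthetics show correctness of the
quantitation machinery under the stated statistical structure; they do not
certify performance on real stacks with autofluorescence, anisotropic
aberrations, bleaching gradients, or segmentation-defying nuclear crowding.

## Pairing profiles

`pairing_profile()` divides the distal gonad into equal-length zones
(half-open intervals, last zone closed; 5 zones by convention) and computes
the paired fraction per gonad per zone. The *gonad* is the replicate unit:
profile means and SDs are taken across per-gonad fractions, and
`compare_profiles()` runs the per-zone two-tailed two-sample t tests on the
same per-gonad values. A fused single signal counts as paired; two signals
are paired at 3D distance ≤ 0.75 µm. That threshold is the conventional
cytological criterion — it is exposed as an argument, not hard-coded, and
the profile is monotone in it. A gonad-zone with no scoreable nuclei is
excluded from that zone's mean/SD rather than imputed. Sub-threshold
two-spot signals and genuinely fused signals are indistinguishable in this
representation; both are paired, which matches scoring practice but slightly
inflates pairing if unresolved unpaired loci exist.

## Focus counting

`segment_nuclei()` smooths (Gaussian, 200 nm), thresholds (Otsu by default,
overridable), labels 3D-connected components (6-connectivity) and filters
them by physical volume (defaults 1–50 µm³ around the ~4 µm³ of a 1 µm
radius nucleus). Out-of-bounds components land in `flagged` — the
semi-automated workflow's "needs manual review" list. `detect_foci()`
band-passes the focus channel with a difference of Gaussians at the PSF
scale (σ vs 1.6σ, the standard Laplacian-of-Gaussian approximation), takes
3D local maxima above an absolute response threshold (default 6× the
response MAD, a robust noise floor; echoed in `params_used` for
provenance), suppresses maxima closer than 0.4 µm in PSF-scaled distance,
and applies the containment constraint: a candidate outside the 3D convex
hull of every nucleus's voxel cloud is discarded, and survivors are assigned
to the containing nucleus.

Point-in-hull is decided by Frank–Wolfe minimisation of the distance from
the point to the hull (over convex-combination weights on the voxel cloud),
with containment declared below a 0.05 µm tolerance — half a voxel edge.
The distance formulation needs no facet enumeration and handles degenerate
(coplanar or collinear) clouds with the same tolerance, which is why it was
chosen over an explicit hull construction with a planar fallback. Most
candidates sit on labelled voxels and short-circuit the test.

Manual correction enters through `counts_by_zone()`'s `override` table
(nucleus id → corrected count), merged before zone summaries.
`compare_zone_counts()` compares per-zone count multisets with a two-sided
rank-sum test that enumerates the exact permutation null (average ranks for
ties) whenever `choose(n1 + n2, n1)` ≤ 50 000, falling back to the
tie-corrected normal approximation beyond that; exactness matters at
cytology-scale samples with heavy ties, where the approximation can be off
severalfold. `double_focus_test()` wraps the two-sided Fisher exact test
(point-probability convention) for the 2×2 interference table of
double-designation events.

## Progression extents

`columnize()` bins nuclei into consecutive equal-width columns (default
width 0.05 of the axis, roughly two nucleus diameters — the column geometry
is a free choice and is exposed; halving it moves the extent by at most one
original column). `column_majority()` applies the strict rule: a column is
marker-positive when *more than half* its nuclei are positive — a tie is
not a majority; empty columns inherit the preceding state.
`extent_fraction()` measures from the start point (transition-zone entry
where it exists, else the first positive column) to the end of the first
contiguous positive run, divided by the meiotic length (start point to
cellularization onset), as a percentage. Marker reappearing proximally is a
real phenomenon; later positive runs are recorded in `later_runs` but never
extend the measured span, preserving the single-span convention without
discarding the information.

## Numerical choices, in one place

| choice | value | why |
|---|---|---|
| SSD grid step | 0.01 | exact at whole-percent reporting resolution |
| SSD tie-break | smaller $p$ | conservative; deterministic |
| SSD support | $k = 0..6$ inclusive | fixed convention, tested |
| clamp/normalize order | clamp first | fixed convention, tested |
| weight conservation | $10^{-9}$ relative | binomial rows sum to 1 exactly |
| pairing threshold | 0.75 µm, ≤ | boundary counts as paired |
| zone bins | half-open, last closed | position 1.0 falls in the last zone |
| hull tolerance | 0.05 µm | half a voxel edge |
| detection threshold default | 6 × MAD of response | robust; override for provenance-critical runs |
| NMS separation | 0.4 µm PSF-scaled | below the generator's 0.45 µm resolvability floor |
| column width default | 0.05 | ~2 nucleus diameters; sensitivity bounded by one column |

Validation problem sizes (all generated in code at run time): estimator
recovery at 1360 nuclei × 100 replicates per probability; a $10^6$-draw
Monte-Carlo thinning oracle; pairing round-trips on 6 gonads × 250 nuclei
and 1000-replicate null calibrations of the zone t test; one rendered stack
of 50 well-separated nuclei at ~5 foci/nucleus and peak-SNR ≳ 7 for the
detection precision/recall harness; 3000-nucleus gonads for progression
round-trips.

## Known limitations

- The maturation model assumes one shared $p$ across nuclei and foci;
  inter-nucleus heterogeneity is deliberately not modelled, and the fit
  cannot distinguish it from binomial thinning.
- Chiasma inference from DAPI bodies assumes no chromosome fragmentation
  (counts > 12 are rejected, not modelled) and no touching-body merges; the
  generator can produce merges (`p_merge`) precisely so users can see the
  bias, but no correction is applied.
- The image pipeline is validated on well-separated spherical nuclei;
  crowded germline tissue will need externally tuned segmentation
  parameters and manual correction via the override path.
- Stage labels and marker booleans for progression analysis arrive as
  annotations; no morphology classification from images is attempted.
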