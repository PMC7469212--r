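---
title: "Measuring climatic niche shifts in environmental space: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring climatic niche shifts in environmental space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheshift)
```

## The model

A species' *climatic niche* in a range is described here not in geographic
space but in a two-dimensional environmental space. For a pair of ranges
(native and invaded), the package:

1. pools the climate values of all grid cells inside both ranges'
   *backgrounds* (the accessible area of each range: the minimum convex
   polygon of its occurrence records dilated by a dispersion buffer),
2. standardizes each climatic variable by its mean and standard deviation
   over those pooled cells and takes the first two principal components of
   their correlation matrix,
3. projects both the occurrence records and the background cells of each
   range into this PC1–PC2 plane, and
4. rasterizes the plane into an R × R grid carrying three surfaces per
   range: the kernel-smoothed occurrence density `o`, the kernel-smoothed
   availability of environments `e`, and the corrected occupancy
   `z ∝ o / e` (zero wherever the environment does not exist), each
   normalized to unit mass.

The availability correction is the crux: raw occurrence density confounds
*preference* with *supply*. A species may sit mostly in mild climates simply
because its region is mostly mild. Dividing by `e` measures occupancy
relative to what the range offers, which is also what makes estimates
comparable between a densely sampled native range and a sparse invasion.

Niche overlap between the corrected surfaces is Schoener's

$$D = 1 - \tfrac12 \sum_{ij} |z^{(1)}_{ij} - z^{(2)}_{ij}| \in [0, 1],$$

0 for disjoint niches and 1 for identical ones. Two randomization tests
attach inference to D:

* **Equivalency** — are the two sets of occurrences interchangeable? The
  pooled occurrences are randomly re-split into the original group sizes
  and D recomputed (default 100 times). The availability surfaces and the
  PCA space stay fixed: the test permutes organisms, not environments. The
  one-sided p-value `(#{null ≤ D_obs} + 1)/(reps + 1)` rejects equivalency
  when the observed overlap is lower than re-splitting can explain.
* **Similarity** — is the observed overlap more than the ranges'
  environments would produce by chance? Each replicate rigidly relocates
  one range's observed occupancy so its center of mass sits on a uniformly
  drawn cell of that range's available environment, truncates mass falling
  off the support, renormalizes and recomputes D. With
  `p = (#{null ≥ D_obs} + 1)/(reps + 1)`, p < α means the niches are *more
  similar than expected by chance* given their backgrounds — evidence of
  conservatism. The test is directional (relocating the invasive niche
  against the native grid, or vice versa) and both directions are reported.
  The relocation moves the whole observed density rather than resampling
  points, so the niche's shape is preserved and only its position is
  randomized.

Niche dynamics summarize where the invasion sits relative to home:
expansion `E` is the share of invasive corrected occupancy outside the
native occupied niche, stability `S = 1 − E`, and unfilling `U` (reported
as "Uninvaded") is the share of native occupancy the invasion has not yet
reached. `E + S = 1` is definitional and the package enforces it; published
tables that violate it are treated as typographical. By default the indices
are computed over *analogue* environments only — cells where both
backgrounds offer the climate — so that "expansion" cannot be manufactured
by climates one range simply does not contain.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `thinning_km` | 5 | km | minimum great-circle distance between retained records |
| `buffer_deg` | 1 | degrees | dispersion buffer on the convex-hull background |
| `R` | 100 | cells/axis | occupancy grid resolution |
| `bandwidth` | `"reference"` | PC units | kernel sd rule (below) |
| `q` | 0.1 | mass quantile | marginal density trimmed from occupied masks |
| `intersection_mode` | analogue-only | — | scope of the dynamics indices |
| `n_reps` | 100 | — | randomizations per test |
| `alpha` | 0.05 | — | significance level for starring similarity p |
| `betas` | 1…6 | — | regularization multipliers scanned by selection |
| `corr_threshold` | 0.7 | \|Pearson r\| | redundancy cut among candidate variables |
| `contrib_threshold` | 0.05 | share | minimum variable contribution retained |

The thinning distance and buffer mirror common practice for forest-pest
compilations; the grid resolution, randomization count and α follow the
originating ordination method's convention. All are exposed in
`analysis_config()` / the YAML config.

## Numerical choices

**Kernel bandwidth.** The default `"reference"` rule sets the kernel sd per
axis to `1.8 · σ_j · n^{-1/6}` from the occurrence scores — the bivariate
normal-reference (Silverman) rate with an oversmoothing factor of 1.8. The
factor was calibrated once, by simulation against the package's own
generative overlap oracle: two *independently* estimated densities of the
same niche never reach D = 1, and at the reference rate the variance-induced
deficit exceeds 0.1 at realistic sample sizes; 1.8 balances that deficit
against the smoothing-induced inflation of D for well-separated niches
(both ends then sit within ≈ 0.1 of truth at n = 500, R = 100). The
univariate `"silverman"` rule and fixed numeric bandwidths remain
available. Degenerate score sets (zero variance) fall back to one grid
cell.

**Support truncation.** Kernel mass below 1e-12 of the surface maximum is
truncated to zero in both `o` and `e`, making "available" and "occupied"
finite supports rather than infinite Gaussian tails; `z` is defined only on
`e > 0`. The ratio `o/e` is volatile where very little environment exists —
at the edge of environmental space a handful of cells can dominate the
corrected surface. This is a property of the availability-corrected metric
itself, not of the implementation; it is mildest when occurrences sit well
inside the background cloud, which holds for real ranges by construction.

**Ties and tie-breaks.** Occupied masks sort cells by density and trim the
lowest cells holding quantile `q` of total mass (with a 1e-12 relative
tolerance so exact ties at the threshold resolve deterministically).
Variable selection breaks exact AICc ties toward fewer variables, then the
later (more reduced) iteration. PCA loading signs are fixed by making the
largest-magnitude loading of each axis positive.

**Grid conventions.** Rasters are row-major from the north-west corner with
half-open cells (a point on a boundary belongs to the south-east cell, with
a 1e-9-cell tolerance so exact boundaries survive floating-point
representation). Extraction is nearest-cell, never interpolated, and grids
are never silently resampled — co-registration mismatches are hard errors.
Both grids of a comparison share one extent (the joint bounding box of all
scores plus a 10% margin) and one R by construction.

## Variable selection

The "selected variables" mode re-specifies the AICc-based selection
workflow as a documented equivalent: an L1-penalized logistic model of
occurrences against background cells on linear + quadratic features of the
background-standardized variables, with the penalty mapped from the
regularization multiplier as `λ = β / (4 √n)` (per-feature penalty
∝ β/√n for unit-variance features, independent of how many candidates are
in play, as in Maxent). The reported log-likelihood is the point-process
convention: the log-probability of each occurrence's cell under the
exponential model normalized over the background, so AICc
(`−2ℓ + 2k + 2k(k+1)/(n−k−1)`, k = nonzero coefficients, n = occurrences)
is comparable across variable sets. Selection iterates: fit every β,
compute per-variable contributions (share of absolute coefficient mass),
drop the lower-contribution member of every correlated pair and any
variable under the contribution floor, refit; the winner is the
minimum-AICc model among those satisfying both rules. Backgrounds are
capped at 10,000 cells by a seeded subsample.

## The synthetic study system

`make_climate_stack()` produces independent Gaussian random fields (white
noise convolved with a Gaussian kernel via FFT; circular convolution, so
opposite map edges correlate — irrelevant at the autocorrelation lengths
used), standardized to mean 0, sd 1. `sample_occurrences()` draws grid
cells with probability proportional to a Gaussian niche density evaluated
at the cell's climate, then jitters each record uniformly within its cell;
the invasive niche is the native one translated by `shift_vector` and
scaled by `spread_scale`. `true_overlap()` evaluates both generating
Gaussians on a fine grid and returns their Schoener's D — the recovery
target.

Two emulation choices matter for interpreting test results. First, cells
are drawn by *niche × availability*, which is exactly the sampling process
the corrected occupancy `z` inverts — so D recovery checks estimator and
correction together; it also means raw occurrence centroids are slightly
shrunk toward availability-rich climates, noticeably for broad niches
(tests of centroid recovery therefore either compare against the exact
sampling expectation or keep the niche tight). Second, the generator makes
climate surfaces *independent*, occurrence records independent given the
niche, and niches exactly Gaussian. Real bioclim variables are strongly
collinear, real records cluster with survey effort beyond what 5-km
thinning removes, and real niches are skewed and multimodal. Passing tests
therefore demonstrate correctness of the machinery and statistical
calibration under the stated generative model — not that any particular
real invasion is measured without bias.

Default study conditions mirror a realistic invasion survey: a well-sampled
native range (n = 116) against sparse invasions (n = 12–53), niche sd of
0.5 environmental units against availability sd 1, shifts of 0–3 niche sd.
Problem sizes in the test suite (grids of R = 50–100, 100-cell-wide
synthetic maps, 200 calibration simulations at 49 randomizations) were
chosen so the whole suite exercises every claim at desk scale.

## Design decisions on open points

* **Per-pair PCA.** The environmental space is calibrated on the pooled
  backgrounds of the *two* compared ranges, not on one global space across
  all ranges of a species: pairwise contrasts are the reporting unit, and a
  global space would let a third range's climates rotate the axes of an
  unrelated comparison. A user wanting one global space can pass the same
  pooled background to `fit_pca()` manually.
* **Corrected surfaces everywhere.** D, both tests and the dynamics indices
  all operate on the availability-corrected `z` (the uncorrected `o` is
  computed and kept alongside), because correcting for available
  environment is the point of the method.
* **Similarity-test reading.** One-sided, high tail: p < α ⇒ niches more
  similar than chance. The complementary reading (rejection = less similar)
  appears in parts of the literature; the package fixes the interpretation
  that matches the test's construction and flags significance accordingly.
* **Thinning.** Seeded randomized-greedy removal of the most-conflicted
  record (ties broken randomly) until no pair violates the distance — a
  maximum-retention heuristic matching the published family of thinning
  algorithms, deterministic under a seed, idempotent on thinned sets.
* **Geometry.** Haversine distances for the thinning rule (km are km
  regardless of latitude); plain-degree buffering for the background
  polygon, matching how dispersion buffers are specified in this
  literature. Antimeridian-crossing hulls are rejected rather than
  mis-buffered.

## Known limitations

* Two retained axes only; Gaussian kernels only.
* The o/e correction is noisy at the margin of environmental space (see
  above); indices involving supports (`E`, `S`, `U`) are accordingly more
  stable at `q > 0` than at `q = 0`.
* WGS84 geographic grids only; no reprojection, no multi-band rasters.
* The variable-selection model uses linear + quadratic features only (no
  hinge/product features), so it is an equivalent of, not a drop-in for,
  full Maxent-based selection.
* Similarity-test relocation is a rigid translation; it does not rotate or
  reshape the niche, and relocations that would place all mass off the
  support are redrawn.
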