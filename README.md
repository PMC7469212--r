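# nicheshift

Quantifying climatic niche shifts of invasive species between their native
and invaded ranges.

## The problem

When a forest pest or pathogen establishes outside its native range, a basic
question for risk assessment is whether it occupies the *same climate* as at
home (niche conservatism) or has moved into novel conditions (a niche shift).
Answering it from occurrence records is subtle: the climates a species uses
can only be judged against the climates its region *offers*, sampling effort
differs wildly between ranges, and the answer depends on which climatic
variables define the niche.

`nicheshift` implements the ordination-based workflow used for such
comparisons in invasion biology, for analysts comparing a native range
against one or more invaded ranges from point occurrences and gridded
bioclimatic variables:

1. **Spatial thinning** of occurrence records (no retained pair closer than a
   minimum great-circle distance, default 5 km) and **backgrounds** built as
   the minimum convex polygon of each range's records buffered by a
   dispersion distance (default 1°).
2. Optional **variable selection** by AICc over L1-regularized
   occurrence-versus-background models (linear + quadratic features,
   regularization multipliers β = 1…6), discarding redundant
   (|r| > 0.7) and low-contribution (< 5%) variables.
3. **PCA-env**: a two-axis environmental space from a PCA calibrated on the
   pooled background cells of the two compared ranges.
4. **Occupancy grids**: Gaussian kernel density of the occurrence scores on
   an R × R grid (R = 100), corrected by the density of *available*
   environments, `z_ij ∝ o_ij / e_ij`.
5. **Niche overlap**: Schoener's
   `D = 1 − ½ Σ_ij |z1_ij − z2_ij| ∈ [0, 1]`
   (0 = disjoint niches, 1 = identical), with randomization-based
   **equivalency** (pooled occurrences re-split, 100 reps) and
   **similarity** (observed niche relocated randomly within the other
   background, both directions) tests; p = (b + 1)/(reps + 1).
6. **Niche dynamics**: expansion *E* (invasive occupancy outside the native
   niche), stability *S = 1 − E*, and unfilling *U* ("uninvaded": native
   occupancy the invasion has not reached).

Because public occurrence compilations for any particular species are not
shipped, the package includes a first-class synthetic-data module:
spatially autocorrelated climate-like surfaces and occurrence sets drawn
from Gaussian niches with a controllable centroid shift, plus a
ground-truth overlap oracle (`true_overlap()`) every estimate can be tested
against.

## Worked example

Simulate a native range (n = 116) and an invaded range (n = 40) whose niche
centroid is shifted by two niche standard deviations, then run the full
comparison:

```r
library(nicheshift)

stack <- make_climate_stack(n_vars = 2, extent = c(0, 10, 40, 50),
                            cell_size = 0.1, autocorr_length = 8, seed = 3)
scenario <- niche_scenario(
  native_centroid = c(-0.5, 0), native_spread = diag(2) * 0.25,
  shift_vector = c(1, 0),        # a 2-niche-sd shift along bio1
  n_native = 116, n_invasive = 40, seed = 11)

occ_native <- sample_occurrences(scenario, stack, "native")
occ_invasive <- sample_occurrences(scenario, stack, "invasive")
occ_invasive$range_label <- "EU"

cfg <- analysis_config(
  species = "example", native_range = "native",
  occurrences = list(native = occ_native, EU = occ_invasive),
  climate = stack, variable_mode = "all",
  thinning_km = 5, buffer_deg = 1, R = 100, n_reps = 100, seed = 11)
cmp <- run_comparison(cfg, "EU")
cmp
#> <niche_comparison> example: native vs EU
#>  region variables direction         D similarity_p unfilling expansion
#>      EU       all      1->2 0.4285824    0.1485149 0.3315727 0.5109295
#>      EU       all      2->1 0.4285824    0.1089109 0.3315727 0.5109295
#>  stability
#>  0.4890705
#>  0.4890705
true_overlap(scenario)
#> [1] 0.3172443
```

Reading the output: the two niches overlap moderately (D ≈ 0.43, against a
generative truth of 0.32 at these sample sizes); the similarity test does
not reject randomness in either direction (p ≈ 0.11–0.15 at 100
randomizations); about half of the invaded occupancy lies outside the native
niche (expansion 0.51) and a third of the native niche is not yet used in
the invasion (unfilling 0.33). `render_report(cmp, "out/")` writes the
seven-column table (`Region, Variables, Overlap (D), Similarity Test,
Uninvaded, Expansion, Stability`, significant similarity p starred), a JSON
report, and the niche density figures.

The numbered scripts under `analysis/` run the full simulated study:
`01_simulate_data.R` (ranges with a conserved, a moderately shifted and a
strongly shifted niche at realistic sample sizes), `02_variable_selection.R`
(4 drivers recovered from 19 candidates), `03_niche_comparisons.R`
(overlap/tests/dynamics tables plus recovery against the oracle) and
`04_figures.R`. A template configuration for users with their own rasters
and occurrence CSVs is in `inst/extdata/example_config.yaml`.

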