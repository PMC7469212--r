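#!/usr/bin/env Rscript
# Density figures for the simulated comparisons: per invasive range, the
# corrected occupancy of both niches in PC1-PC2 space with the 50%-densest
# (solid) and full available (dashed) contours, plus the PCA correlation
# circle. Writes PNGs under results/figures/.
#
# Requires results/simdata/ from 01_simulate_data.R.

library(nicheshift)

sim <- "results/simdata"
out <- "results/figures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- analysis_config(
  species = "synthetic",
  occurrences = file.path(sim, "occurrences.csv"),
  climate = file.path(sim, "climate", paste0("bio", 1:6, ".asc")),
  native_range = "native",
  variable_mode = "all",
  thinning_km = 5, buffer_deg = 1, R = 100,
  q = 0.1, n_reps = 20, alpha = 0.05, seed = 11)

for (rg in c("Oceania", "EU", "NA")) {
  cmp <- run_comparison(cfg, rg)
  render_report(cmp, out, figures = TRUE)
  cat("rendered", rg, "\n")
}
cat("figures in", out, "\n")
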