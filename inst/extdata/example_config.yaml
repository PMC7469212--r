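# Template analysis configuration for a real species.
#
# Point occurrence_csv at a CSV with header species,range,lon,lat (WGS84
# decimal degrees; one row per record, range labels free-form) and
# climate_paths at co-registered single-band ASCII grid rasters (.asc), one
# per bioclimatic variable on a shared grid. Relative paths are resolved
# against this file's directory. Load with read_config() and run each
# invasive range with run_comparison().

species: my_species
occurrence_csv: occurrences.csv
climate_paths:
  - climate/bio1.asc
  - climate/bio2.asc
  # ... one entry per variable, e.g. all 19 bioclim surfaces
native_range: native          # must match a range label in the CSV
variable_mode: [all, selected]
thinning_km: 5                # minimum distance between retained records
buffer_deg: 1                 # dispersion buffer around the convex hull
R: 100                        # occupancy grid resolution per axis
bandwidth: reference          # kernel rule; or a numeric kernel sd
q: 0.1                        # occupied-mask trim quantile for dynamics
intersection_mode: analogue-only
n_reps: 100                   # randomizations for both tests
alpha: 0.05
seed: 1
directions: ["1->2", "2->1"]
# variable-selection controls
betas: [1, 2, 3, 4, 5, 6]
corr_threshold: 0.7
contrib_threshold: 0.05
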