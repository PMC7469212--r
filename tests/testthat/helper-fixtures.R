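# Shared fixtures, built in code once per test run.

# small 2-variable climate stack: 50x50 cells over a 5x5 degree box
fix_stack2 <- make_climate_stack(n_vars = 2, extent = c(0, 5, 40, 45),
                                 cell_size = 0.1, autocorr_length = 5,
                                 seed = 3)

# region covering (almost) the whole extent of a stack
full_extent_region <- function(stack, buffer = 0.5) {
  ext <- stack_extent(stack)
  eps <- stack$cell_size / 2
  corners <- occurrence_set(
    "fixture", "full",
    lon = c(ext[1] + eps, ext[2] - eps, ext[2] - eps, ext[1] + eps),
    lat = c(ext[3] + eps, ext[3] + eps, ext[4] - eps, ext[4] - eps))
  build_background(corners, buffer)
}

fix_bg_env2 <- background_sites(full_extent_region(fix_stack2), fix_stack2)
fix_pca2 <- fit_pca(fix_bg_env2)
fix_bg_scores2 <- project_scores(fix_pca2, fix_bg_env2)

# occurrence scores + grids for a native/invasive pair on fix_stack2
simulate_pair <- function(shift = 0, n = 150, seed = 7, spread = 0.25,
                          spread_scale = 1, R = 60,
                          stack = fix_stack2, pca = fix_pca2,
                          bg_scores = fix_bg_scores2) {
  sc <- niche_scenario(c(0, 0), diag(2) * spread, shift_vector = c(shift, 0),
                       spread_scale = spread_scale,
                       n_native = n, n_invasive = n, seed = seed)
  occ_n <- sample_occurrences(sc, stack, "native")
  occ_i <- sample_occurrences(sc, stack, "invasive")
  sn <- project_scores(pca, extract_env(stack, occ_n$points))
  si <- project_scores(pca, extract_env(stack, occ_i$points))
  ex <- score_extent(sn, si, bg_scores)
  list(scenario = sc, occ_native = occ_n, occ_invasive = occ_i,
       scores_native = sn, scores_invasive = si, bg_scores = bg_scores,
       extent = ex,
       grid_native = build_niche_grid(sn, bg_scores, ex, R),
       grid_invasive = build_niche_grid(si, bg_scores, ex, R))
}

# lag-1 spatial autocorrelation of a matrix (mean of row/col neighbour cors)
lag1_autocorr <- function(m) {
  mean(c(stats::cor(as.numeric(m[, -ncol(m)]), as.numeric(m[, -1])),
         stats::cor(as.numeric(m[-nrow(m), ]), as.numeric(m[-1, ]))))
}

# random lon/lat points within a box
random_points <- function(n, lon = c(0, 1), lat = c(45, 46), seed = 1) {
  set.seed(seed)
  data.frame(lon = runif(n, lon[1], lon[2]), lat = runif(n, lat[1], lat[2]))
}

# background env matrix of k independent standard-normal variables, plus
# occurrence rows resampled from it with Gaussian weights on chosen columns
weighted_occ_bg <- function(n_bg = 2000, n_occ = 200, k = 5,
                            driver_cols = 1, driver_mean = 0.5,
                            driver_sd = 0.3, seed = 42) {
  set.seed(seed)
  bg <- matrix(rnorm(n_bg * k), n_bg, k,
               dimnames = list(NULL, paste0("bio", seq_len(k))))
  w <- rep(1, n_bg)
  for (j in driver_cols) w <- w * dnorm(bg[, j], driver_mean, driver_sd)
  occ <- bg[sample.int(n_bg, n_occ, replace = TRUE, prob = w), , drop = FALSE]
  list(bg = bg, occ = occ)
}
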