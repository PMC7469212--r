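# Synthetic study system: spatially autocorrelated climate-like surfaces and
# occurrence sets drawn from Gaussian niches with a known centroid shift, so
# every downstream estimate can be checked against ground truth.

#' Define a synthetic niche scenario
#'
#' A scenario fixes the generative geometry of a native/invasive range pair in
#' environmental space: the native niche is Gaussian with centroid
#' `native_centroid` and dispersion `native_spread`; the invasive niche has
#' centroid `native_centroid + shift_vector` and dispersion
#' `spread_scale^2 * native_spread`.
#'
#' @param native_centroid numeric vector, niche optimum in environment units
#'   (one entry per selected climate variable).
#' @param native_spread symmetric positive-definite dispersion matrix of the
#'   native niche (same dimension as the centroid).
#' @param shift_vector displacement of the invasive centroid, same units.
#' @param spread_scale multiplicative factor on the invasive niche's standard
#'   deviations (1 = same dispersion; >1 = broader invasive niche).
#' @param n_native,n_invasive occurrence counts per range (>= 1).
#' @param seed integer RNG seed; identical seed and parameters give
#'   byte-identical outputs.
#' @return an object of class `niche_scenario`.
#' @export
niche_scenario <- function(native_centroid, native_spread, shift_vector,
                           spread_scale = 1, n_native, n_invasive, seed = 1L) {
  k <- length(native_centroid)
  native_spread <- as.matrix(native_spread)
  if (!is_spd(native_spread))
    stop("`native_spread` must be symmetric positive-definite", call. = FALSE)
  if (nrow(native_spread) != k)
    stop("`native_spread` dimension must match the centroid", call. = FALSE)
  if (length(shift_vector) != k)
    stop("`shift_vector` must match the centroid dimension", call. = FALSE)
  stopifnot(spread_scale > 0, n_native >= 1, n_invasive >= 1)
  structure(
    list(native_centroid = as.numeric(native_centroid),
         native_spread = native_spread,
         shift_vector = as.numeric(shift_vector),
         spread_scale = as.numeric(spread_scale),
         n_native = as.integer(n_native),
         n_invasive = as.integer(n_invasive),
         seed = as.integer(seed)),
    class = "niche_scenario")
}

# centroid and covariance of one range's generating Gaussian
scenario_params <- function(scenario, which_range) {
  which_range <- match.arg(which_range, c("native", "invasive"))
  if (which_range == "native") {
    list(mean = scenario$native_centroid, sigma = scenario$native_spread)
  } else {
    list(mean = scenario$native_centroid + scenario$shift_vector,
         sigma = scenario$spread_scale^2 * scenario$native_spread)
  }
}

#' Write / read a scenario as YAML
#' @param scenario a `niche_scenario`.
#' @param path file path.
#' @export
write_scenario <- function(scenario, path) {
  obj <- unclass(scenario)
  obj$native_spread <- apply(scenario$native_spread, 1, as.numeric,
                             simplify = FALSE)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  niche_scenario(
    native_centroid = as.numeric(obj$native_centroid),
    native_spread = do.call(rbind, obj$native_spread),
    shift_vector = as.numeric(obj$shift_vector),
    spread_scale = obj$spread_scale,
    n_native = obj$n_native, n_invasive = obj$n_invasive,
    seed = obj$seed)
}

#' Generate a stack of spatially autocorrelated climate-like surfaces
#'
#' Each variable is an independent Gaussian random field: white noise convolved
#' with an isotropic Gaussian kernel of standard deviation `autocorr_length`
#' cells (FFT circular convolution), then standardized to mean 0, sd 1 over the
#' grid. The surfaces emulate gridded bioclimatic variables; they carry no
#' physical units.
#'
#' @param n_vars number of variables (e.g. 19 for a bioclim-style stack).
#' @param extent numeric length-4, c(xmin, xmax, ymin, ymax) in degrees.
#' @param cell_size cell edge in degrees.
#' @param autocorr_length kernel standard deviation in cells (>= 1).
#' @param seed integer RNG seed.
#' @param var_names optional variable names; defaults to bio1..bioN.
#' @return a `climate_stack`.
#' @export
make_climate_stack <- function(n_vars = 19, extent = c(0, 10, 40, 50),
                               cell_size = 0.1, autocorr_length = 5,
                               seed = 1L, var_names = NULL) {
  stopifnot(n_vars >= 1, autocorr_length >= 1, length(extent) == 4)
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("degenerate extent: xmax must exceed xmin and ymax must exceed ymin",
         call. = FALSE)
  nc <- max(1L, round((extent[2] - extent[1]) / cell_size))
  nr <- max(1L, round((extent[4] - extent[3]) / cell_size))
  if (nr < 2 || nc < 2)
    stop("degenerate extent: fewer than 2 cells on one axis", call. = FALSE)
  if (is.null(var_names)) var_names <- paste0("bio", seq_len(n_vars))
  stopifnot(length(var_names) == n_vars)

  # frequency-domain Gaussian filter, shared across variables
  kern <- gaussian_kernel_fft(nr, nc, autocorr_length)
  values <- with_seed(seed, {
    lapply(seq_len(n_vars), function(i) {
      noise <- matrix(stats::rnorm(nr * nc), nr, nc)
      sm <- Re(stats::fft(stats::fft(noise) * kern, inverse = TRUE)) / (nr * nc)
      (sm - mean(sm)) / stats::sd(sm)
    })
  })
  names(values) <- var_names
  climate_stack(values, origin = c(extent[1], extent[4]), cell_size = cell_size)
}

# FFT of a periodic, centered 2-D Gaussian kernel (unit sum)
gaussian_kernel_fft <- function(nr, nc, len) {
  ri <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)
  ci <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)
  kr <- exp(-ri^2 / (2 * len^2))
  kc <- exp(-ci^2 / (2 * len^2))
  k <- outer(kr, kc)
  stats::fft(k / sum(k))
}

#' Sample occurrences from a scenario over a climate stack
#'
#' Grid cells are drawn with probability proportional to the range's Gaussian
#' niche density evaluated at the cell's values of `selected_vars`; each drawn
#' point is jittered uniformly within its cell. Sampling is with replacement
#' (several records may share a cell, as real occurrence databases do).
#'
#' @param scenario a `niche_scenario`.
#' @param climate a `climate_stack`.
#' @param which_range `"native"` or `"invasive"`.
#' @param selected_vars climate variables spanning the niche space; must match
#'   the scenario's dimension.
#' @return an `occurrence_set` with `n_native` or `n_invasive` points.
#' @export
sample_occurrences <- function(scenario, climate,
                               which_range = c("native", "invasive"),
                               selected_vars = NULL) {
  which_range <- match.arg(which_range)
  k <- length(scenario$native_centroid)
  if (is.null(selected_vars)) selected_vars <- stack_vars(climate)[seq_len(k)]
  miss <- setdiff(selected_vars, stack_vars(climate))
  if (length(miss))
    stop("selected_vars not in the climate stack: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(selected_vars) != k)
    stop("scenario has dimension ", k, " but ", length(selected_vars),
         " variables were selected", call. = FALSE)

  tab <- stack_cell_table(climate)
  env <- as.matrix(tab[, selected_vars, drop = FALSE])
  ok <- stats::complete.cases(env)
  par <- scenario_params(scenario, which_range)
  logd <- rep(-Inf, nrow(env))
  logd[ok] <- dmvnorm_log(env[ok, , drop = FALSE], par$mean, par$sigma)
  best <- suppressWarnings(max(logd[is.finite(logd)]))
  # density must be representable in double precision somewhere on the grid
  if (!any(is.finite(logd)) || best < log(.Machine$double.xmin))
    stop("niche centroid (", paste(signif(par$mean, 4), collapse = ", "),
         ") is unreachable: density is numerically zero over all valid cells",
         call. = FALSE)
  w <- exp(logd - best)
  if (sum(w) == 0)
    stop("niche centroid (", paste(signif(par$mean, 4), collapse = ", "),
         ") is unreachable: density is numerically zero over all valid cells",
         call. = FALSE)
  n <- if (which_range == "native") scenario$n_native else scenario$n_invasive
  pts <- with_seed(child_seed(scenario$seed, which_range), {
    i <- sample.int(nrow(tab), n, replace = TRUE, prob = w)
    jit_lon <- stats::runif(n, -0.5, 0.5) * climate$cell_size
    jit_lat <- stats::runif(n, -0.5, 0.5) * climate$cell_size
    data.frame(lon = tab$lon[i] + jit_lon, lat = tab$lat[i] + jit_lat)
  })
  occurrence_set(species = "synthetic", range_label = which_range,
                 lon = pts$lon, lat = pts$lat,
                 provenance = sprintf("simulated (seed %d)", scenario$seed))
}

#' Ground-truth niche overlap of a scenario
#'
#' Evaluates both generating Gaussian densities on a regular grid in
#' environment space, normalizes each to sum 1, and returns Schoener's D
#' (1 - 0.5 * sum |z1 - z2|). This is the recovery target for the
#' occurrence-based estimator.
#'
#' @param scenario a `niche_scenario`.
#' @param grid_spec list with `extent` (k x 2 matrix of axis ranges, or NULL
#'   for centroids +/- 6 sd) and `n` (cells per axis, default 200).
#' @return overlap in `[0, 1]`.
#' @export
true_overlap <- function(scenario, grid_spec = NULL) {
  p1 <- scenario_params(scenario, "native")
  p2 <- scenario_params(scenario, "invasive")
  k <- length(p1$mean)
  n <- if (!is.null(grid_spec$n)) grid_spec$n else if (k <= 2) 200L else 60L
  if (is.null(grid_spec$extent)) {
    sd1 <- sqrt(diag(p1$sigma)); sd2 <- sqrt(diag(p2$sigma))
    lo <- pmin(p1$mean - 6 * sd1, p2$mean - 6 * sd2)
    hi <- pmax(p1$mean + 6 * sd1, p2$mean + 6 * sd2)
    extent <- cbind(lo, hi)
  } else {
    extent <- grid_spec$extent
    if (is.null(dim(extent))) extent <- matrix(extent, nrow = k, byrow = TRUE)
  }
  axes <- lapply(seq_len(k), function(j) {
    seq(extent[j, 1], extent[j, 2], length.out = n + 1)[-1] -
      (extent[j, 2] - extent[j, 1]) / (2 * n)
  })
  grid <- as.matrix(expand.grid(axes))
  cellvol <- prod((extent[, 2] - extent[, 1]) / n)
  d1 <- exp(dmvnorm_log(grid, p1$mean, p1$sigma))
  d2 <- exp(dmvnorm_log(grid, p2$mean, p2$sigma))
  if (sum(d1) * cellvol < 0.999 || sum(d2) * cellvol < 0.999)
    stop("grid too coarse or too small: it holds < 99.9% of a niche's mass",
         call. = FALSE)
  z1 <- d1 / sum(d1); z2 <- d2 / sum(d2)
  1 - 0.5 * sum(abs(z1 - z2))
}
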