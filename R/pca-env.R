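# Two-axis environmental space (PCA calibrated on pooled backgrounds) and the
# kernel-smoothed, availability-corrected occupancy grids built in it.

#' Calibrate the environmental PCA space
#'
#' Standardizes each variable by its mean and standard deviation over the
#' calibration sites (the pooled background cells of the compared ranges) and
#' eigendecomposes the correlation matrix. Loading signs are fixed so the
#' largest-magnitude loading on each axis is positive.
#'
#' @param env_pooled calibration environment matrix (>= 3 rows, >= 2 columns).
#' @return an object of class `pca_space`: `loadings` (variables x axes),
#'   `center`, `scale`, `explained_fraction`, `calibration_n`.
#' @export
fit_pca <- function(env_pooled) {
  x <- as.matrix(env_pooled)
  if (nrow(x) < 3 || ncol(x) < 2)
    stop("need >= 3 sites and >= 2 variables to calibrate a PCA space",
         call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  flat <- which(scl == 0 | !is.finite(scl))
  if (length(flat))
    stop("constant column over the calibration sites: ",
         paste(colnames(x)[flat], collapse = ", "), call. = FALSE)
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  corr <- crossprod(z) / (nrow(z) - 1)
  eig <- eigen(corr, symmetric = TRUE)
  load <- eig$vectors
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  ev <- pmax(eig$values, 0)
  structure(
    list(loadings = load, center = ctr, scale = scl,
         explained_fraction = ev / sum(ev),
         calibration_n = nrow(x)),
    class = "pca_space")
}

#' @export
print.pca_space <- function(x, ...) {
  cat("<pca_space> ", length(x$center), " variables, calibrated on ",
      x$calibration_n, " sites\n  PC1+PC2 explain ",
      round(100 * sum(x$explained_fraction[1:2]), 2), "% of variance\n",
      sep = "")
  invisible(x)
}

#' Project sites into the PCA space
#'
#' @param space a `pca_space`.
#' @param env environment matrix whose columns cover the calibration
#'   variables.
#' @param axes number of leading axes to return (default 2).
#' @return numeric score matrix, sites x axes.
#' @export
project_scores <- function(space, env, axes = 2) {
  vars <- rownames(space$loadings)
  miss <- setdiff(vars, colnames(env))
  if (length(miss))
    stop("environment matrix lacks calibration variable(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  x <- as.matrix(env[, vars, drop = FALSE])
  z <- sweep(sweep(x, 2, space$center), 2, space$scale, "/")
  z %*% space$loadings[, seq_len(axes), drop = FALSE]
}

#' Joint extent of score sets, with a margin
#'
#' Both grids of a niche comparison must share one extent; this helper takes
#' the bounding box of all supplied score tables plus a fractional margin so
#' kernel tails are not clipped.
#'
#' @param ... score matrices (sites x 2).
#' @param margin fractional padding per side.
#' @return list with `xlim`, `ylim`.
#' @export
score_extent <- function(..., margin = 0.1) {
  all_sc <- do.call(rbind, lapply(list(...), function(s) as.matrix(s)[, 1:2]))
  xr <- range(all_sc[, 1]); yr <- range(all_sc[, 2])
  pad <- function(r) {
    w <- diff(r)
    if (w == 0) w <- max(abs(r), 1)
    r + c(-1, 1) * margin * w
  }
  list(xlim = pad(xr), ylim = pad(yr))
}

# Kernel sd per axis from the occurrence scores. "reference" is the bivariate
# normal-reference rule sigma_j * n^(-1/6) times an oversmoothing factor of
# 1.8, calibrated by simulation against the generative overlap oracle so the
# overlap estimator stays accurate across the whole overlap range (two
# independently estimated densities otherwise never reach D = 1);
# "silverman" is the univariate rule applied per axis. Degenerate score sets
# fall back to one grid cell.
occurrence_bandwidth <- function(scores, extent, R, method = "reference") {
  n <- nrow(scores)
  vapply(1:2, function(j) {
    v <- scores[, j]
    s <- stats::sd(v)
    h <- if (method == "silverman") {
      iqr <- stats::IQR(v)
      1.06 * min(s, if (iqr > 0) iqr / 1.34 else s) * n^(-1 / 5)
    } else {
      1.8 * s * n^(-1 / 6)
    }
    if (!is.finite(h) || h <= 0) {
      lims <- if (j == 1) extent$xlim else extent$ylim
      h <- diff(lims) / R
    }
    h
  }, numeric(1))
}

#' Build an availability-corrected niche occupancy grid
#'
#' Gaussian kernel density of the occurrence scores gives the raw occupancy
#' `o`; the same kernel applied to the background scores gives the
#' availability `e`; the corrected occupancy is `z = o / e` where the
#' environment exists (`e > 0` after truncating negligible kernel mass) and 0
#' elsewhere. All three surfaces are normalized to sum 1 over the grid.
#'
#' @param occ_scores occurrence score matrix (>= 2 rows x 2 axes).
#' @param bg_scores background score matrix (same axes).
#' @param extent list with `xlim`, `ylim`; must cover all scores of both
#'   grids being compared (see [score_extent()]).
#' @param R grid resolution (cells per axis).
#' @param bandwidth `"reference"` (default: oversmoothed bivariate
#'   normal-reference rule on the occurrence scores), `"silverman"`
#'   (univariate rule per axis), or a numeric kernel sd, length 1 or 2.
#' @return an object of class `niche_grid`: matrices `o`, `e`, `z` (R x R,
#'   rows = x axis), axis centers `x`, `y`, plus `R`, `bandwidth`, `extent`.
#' @export
build_niche_grid <- function(occ_scores, bg_scores, extent, R = 100,
                             bandwidth = "reference") {
  occ_scores <- as.matrix(occ_scores)
  bg_scores <- as.matrix(bg_scores)
  if (nrow(occ_scores) < 2)
    stop("need at least 2 occurrence scores for a density grid", call. = FALSE)
  if (nrow(bg_scores) < 2)
    stop("background has no mass: need at least 2 background scores",
         call. = FALSE)
  out_of <- occ_scores[, 1] < extent$xlim[1] | occ_scores[, 1] > extent$xlim[2] |
    occ_scores[, 2] < extent$ylim[1] | occ_scores[, 2] > extent$ylim[2]
  if (any(out_of))
    stop(sum(out_of), " occurrence score(s) outside the grid extent",
         call. = FALSE)
  h <- if (is.character(bandwidth))
    occurrence_bandwidth(occ_scores, extent, R,
                         match.arg(bandwidth, c("reference", "silverman")))
  else rep(as.numeric(bandwidth), length.out = 2)
  stopifnot(all(h > 0))

  o <- kde_grid(occ_scores, extent, R, h)
  e <- kde_grid(bg_scores, extent, R, h)
  # truncate negligible kernel mass so "available" and "occupied" supports
  # are finite sets rather than the kernel's infinite tails
  o[o < 1e-12 * max(o)] <- 0
  e[e < 1e-12 * max(e)] <- 0
  if (sum(e) == 0) stop("background has no kernel mass on the grid",
                        call. = FALSE)
  z <- matrix(0, R, R)
  pos <- e > 0
  z[pos] <- o[pos] / e[pos]
  norm1 <- function(m) if (sum(m) > 0) m / sum(m) else m
  structure(
    list(o = norm1(o), e = norm1(e), z = norm1(z),
         x = axis_centers(extent$xlim, R), y = axis_centers(extent$ylim, R),
         R = R, bandwidth = h, extent = extent,
         n_occ = nrow(occ_scores), n_bg = nrow(bg_scores)),
    class = "niche_grid")
}

axis_centers <- function(lim, R) {
  seq(lim[1], lim[2], length.out = R)
}

# Gaussian product-kernel density on an R x R grid; h is the kernel sd per
# axis (MASS::kde2d divides its h by 4, hence the rescaling)
kde_grid <- function(scores, extent, R, h) {
  MASS::kde2d(scores[, 1], scores[, 2], h = 4 * h, n = R,
              lims = c(extent$xlim, extent$ylim))$z
}

# corrected occupancy for new occurrence scores against a fixed availability
# surface (used by the equivalency loop: only occurrence densities change)
corrected_surface <- function(occ_scores, e, extent, R, bandwidth) {
  h <- if (is.character(bandwidth))
    occurrence_bandwidth(occ_scores, extent, R,
                         match.arg(bandwidth, c("reference", "silverman")))
  else rep(as.numeric(bandwidth), length.out = 2)
  o <- kde_grid(occ_scores, extent, R, h)
  o[o < 1e-12 * max(o)] <- 0
  z <- matrix(0, R, R)
  pos <- e > 0
  z[pos] <- o[pos] / e[pos]
  if (sum(z) > 0) z / sum(z) else z
}

#' @export
print.niche_grid <- function(x, ...) {
  cat("<niche_grid> ", x$R, "x", x$R, " cells, ", x$n_occ, " occurrences, ",
      x$n_bg, " background sites, bandwidth (",
      paste(signif(x$bandwidth, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}
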