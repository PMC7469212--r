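# Schoener's D niche overlap and the randomization-based niche equivalency and
# similarity tests.

#' Schoener's D overlap between two normalized density grids
#'
#' `D = 1 - 0.5 * sum |z1 - z2|`, ranging from 0 (no overlap) to 1 (identical
#' niches). Operates on the availability-corrected occupancy surfaces by
#' default when given `niche_grid` objects.
#'
#' @param z1,z2 `niche_grid` objects or numeric arrays of equal shape, each
#'   nonnegative and summing to 1.
#' @param surface which surface of a `niche_grid` to compare: corrected
#'   occupancy `"z"` (default) or uncorrected occurrence density `"o"`.
#' @return overlap in `[0, 1]`.
#' @export
schoener_d <- function(z1, z2, surface = c("z", "o")) {
  surface <- match.arg(surface)
  if (inherits(z1, "niche_grid")) z1 <- z1[[surface]]
  if (inherits(z2, "niche_grid")) z2 <- z2[[surface]]
  if (!identical(dim(z1), dim(z2)) || length(z1) != length(z2))
    stop("grids differ in shape: ", paste(dim(z1), collapse = "x"), " vs ",
         paste(dim(z2), collapse = "x"), call. = FALSE)
  for (z in list(z1, z2)) {
    if (any(z < 0)) stop("density grid has negative cells", call. = FALSE)
    if (abs(sum(z) - 1) > 1e-6)
      stop("density grid is not normalized (sum = ", format(sum(z)), ")",
           call. = FALSE)
  }
  d <- 1 - 0.5 * sum(abs(z1 - z2))
  min(max(d, 0), 1)
}

#' Niche equivalency test
#'
#' Asks whether the two niches are interchangeable: pools both occurrence
#' score sets, randomly re-splits them into the original group sizes, rebuilds
#' both corrected occupancy grids (same PCA space, extent, resolution), and
#' recomputes D for each of `n_reps` randomizations. The one-sided p-value for
#' "observed overlap lower than the null" is `(#{null <= D_obs} + 1) /
#' (n_reps + 1)`; small p rejects niche equivalency.
#'
#' @param occ1_scores,occ2_scores occurrence score matrices of the two ranges.
#' @param bg1_scores,bg2_scores background score matrices of the two ranges
#'   (fixed across randomizations; only occurrences are permuted).
#' @param extent shared grid extent (default: joint extent of all scores).
#' @param R grid resolution.
#' @param bandwidth bandwidth rule or value, as in [build_niche_grid()].
#' @param n_reps number of randomizations (>= 1).
#' @param seed integer seed.
#' @return an object of class `overlap_test` with `D`, `p`, `null` (length
#'   `n_reps`), `n_reps`, `seed`, `type = "equivalency"`.
#' @export
equivalency_test <- function(occ1_scores, occ2_scores, bg1_scores, bg2_scores,
                             extent = NULL, R = 100,
                             bandwidth = "reference", n_reps = 100,
                             seed = 1L) {
  stopifnot(n_reps >= 1)
  occ1_scores <- as.matrix(occ1_scores); occ2_scores <- as.matrix(occ2_scores)
  n1 <- nrow(occ1_scores); n2 <- nrow(occ2_scores)
  if (n1 < 2 || n2 < 2) stop("each range needs >= 2 occurrences", call. = FALSE)
  if (is.null(extent))
    extent <- score_extent(occ1_scores, occ2_scores, bg1_scores, bg2_scores)

  g1 <- build_niche_grid(occ1_scores, bg1_scores, extent, R, bandwidth)
  g2 <- build_niche_grid(occ2_scores, bg2_scores, extent, R, bandwidth)
  # availability surfaces are fixed across randomizations: only the
  # occurrence densities are recomputed inside the loop
  d_of_split <- function(s1, s2) {
    z1 <- corrected_surface(s1, g1$e, extent, R, bandwidth)
    z2 <- corrected_surface(s2, g2$e, extent, R, bandwidth)
    schoener_d(z1, z2)
  }
  d_obs <- schoener_d(g1, g2)
  pooled <- rbind(occ1_scores, occ2_scores)
  null <- with_seed(child_seed(seed, "equivalency"), {
    vapply(seq_len(n_reps), function(r) {
      idx <- sample.int(n1 + n2, n1)
      d_of_split(pooled[idx, , drop = FALSE], pooled[-idx, , drop = FALSE])
    }, numeric(1))
  })
  p <- (sum(null <= d_obs) + 1) / (n_reps + 1)
  structure(list(D = d_obs, p = p, null = null, n_reps = n_reps,
                 seed = seed, type = "equivalency"),
            class = "overlap_test")
}

#' Niche similarity test
#'
#' Asks whether the observed overlap exceeds what randomly placed niches in
#' the other range's environment would produce: each randomization rigidly
#' relocates range 2's observed corrected occupancy so its center of mass sits
#' on a uniformly drawn cell of range 2's background support, zeroes mass
#' falling outside the support, renormalizes, and recomputes D against range
#' 1's grid. The one-sided p-value for "observed overlap higher than random"
#' is `(#{null >= D_obs} + 1) / (n_reps + 1)`; p below alpha means the niches
#' are more similar than expected by chance given the available environments.
#'
#' @param grid1,grid2 `niche_grid` objects sharing extent and resolution;
#'   `grid2` is the relocated one, so the conventional directions are
#'   native->invasive (`grid1` = native) and invasive->native.
#' @param direction free-text label stored on the result (e.g. `"1->2"`).
#' @param n_reps number of randomizations.
#' @param seed integer seed.
#' @return an `overlap_test` with `type = "similarity"` and `direction`.
#' @export
similarity_test <- function(grid1, grid2, direction = "1->2", n_reps = 100,
                            seed = 1L) {
  stopifnot(inherits(grid1, "niche_grid"), inherits(grid2, "niche_grid"),
            n_reps >= 1)
  if (grid1$R != grid2$R ||
      !isTRUE(all.equal(grid1$extent, grid2$extent)))
    stop("grids must share extent and resolution", call. = FALSE)
  d_obs <- schoener_d(grid1, grid2)
  support <- which(grid2$e > 0, arr.ind = TRUE)
  if (nrow(support) < 2)
    stop("background support too small to relocate the niche", call. = FALSE)
  z2 <- grid2$z
  w <- sum(z2)
  com <- c(sum(row(z2) * z2), sum(col(z2) * z2)) / w
  null <- with_seed(child_seed(seed, paste0("similarity", direction)), {
    vapply(seq_len(n_reps), function(r) {
      for (try in 1:50) {
        target <- support[sample.int(nrow(support), 1), ]
        shifted <- shift_grid(z2, round(target[1] - com[1]),
                              round(target[2] - com[2]))
        shifted[grid2$e == 0] <- 0
        s <- sum(shifted)
        if (s > 0) return(schoener_d(grid1$z, shifted / s))
      }
      stop("could not place a relocated niche with positive mass",
           call. = FALSE)
    }, numeric(1))
  })
  p <- (sum(null >= d_obs) + 1) / (n_reps + 1)
  structure(list(D = d_obs, p = p, null = null, n_reps = n_reps,
                 seed = seed, type = "similarity", direction = direction),
            class = "overlap_test")
}

# rigid integer translation of a matrix, zero fill
shift_grid <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - di; src_c <- seq_len(nc) - dj
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  if (any(ok_r) && any(ok_c))
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("<overlap_test> ", x$type,
      if (!is.null(x$direction)) paste0(" (", x$direction, ")"), ": D = ",
      signif(x$D, 4), ", p = ", signif(x$p, 4), " (", x$n_reps,
      " randomizations)\n", sep = "")
  invisible(x)
}
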