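# Niche dynamics between a native and an invasive occupancy grid: expansion,
# stability, and unfilling ("uninvaded") proportions.

#' Occupied-cell mask of a niche grid
#'
#' Cells are sorted by corrected occupancy; the lowest-density cells jointly
#' holding quantile `q` of the total mass are trimmed as marginal, and the
#' rest are marked occupied. `q = 0` keeps every cell with positive density.
#'
#' @param grid a `niche_grid` (or a density matrix).
#' @param q trimmed mass quantile, `0 <= q < 1`.
#' @return logical matrix of occupied cells.
#' @export
occupied_mask <- function(grid, q = 0.1) {
  stopifnot(q >= 0, q < 1)
  z <- if (inherits(grid, "niche_grid")) grid$z else grid
  if (q == 0) return(z > 0)
  ord <- order(z)
  cum <- cumsum(z[ord])
  tot <- sum(z)
  occ_sorted <- z[ord] > 0 & cum > q * tot + 1e-12 * tot
  out <- matrix(FALSE, nrow(z), ncol(z))
  out[ord] <- occ_sorted
  out
}

#' Niche expansion, stability and unfilling indices
#'
#' With `M_n`, `M_i` the occupied masks of the native and invasive grids at
#' trim quantile `q`:
#' * expansion `E` — share of the invasive corrected occupancy falling outside
#'   the native occupied niche;
#' * stability `S = 1 - E` — share inside it;
#' * unfilling `U` (the "uninvaded" proportion) — share of the native
#'   corrected occupancy outside the invasive occupied niche.
#'
#' In `analogue-only` mode the computation is restricted to cells where both
#' backgrounds offer the environment (`e > 0` in both grids), so the indices
#' compare niches over climates both ranges actually contain.
#'
#' @param native_grid,invasive_grid `niche_grid` objects sharing extent and
#'   resolution.
#' @param q trim quantile for the occupied masks (see [occupied_mask()]).
#' @param intersection_mode `"analogue-only"` (default) or `"full-extent"`.
#' @return an object of class `dynamics_result` with `expansion`,
#'   `stability`, `unfilling`, `q`, `intersection_mode`.
#' @export
dynamics_indices <- function(native_grid, invasive_grid, q = 0.1,
                             intersection_mode = c("analogue-only",
                                                   "full-extent")) {
  intersection_mode <- match.arg(intersection_mode)
  stopifnot(inherits(native_grid, "niche_grid"),
            inherits(invasive_grid, "niche_grid"))
  if (native_grid$R != invasive_grid$R ||
      !isTRUE(all.equal(native_grid$extent, invasive_grid$extent)))
    stop("grids must share extent and resolution", call. = FALSE)
  scope <- if (intersection_mode == "analogue-only")
    native_grid$e > 0 & invasive_grid$e > 0
  else matrix(TRUE, native_grid$R, native_grid$R)
  m_nat <- occupied_mask(native_grid, q)
  m_inv <- occupied_mask(invasive_grid, q)
  if (!any(m_nat & scope) || !any(m_inv & scope))
    stop("empty occupied mask within the comparison scope", call. = FALSE)
  z_nat <- native_grid$z; z_inv <- invasive_grid$z
  tot_inv <- sum(z_inv[scope]); tot_nat <- sum(z_nat[scope])
  if (tot_inv == 0 || tot_nat == 0)
    stop("a grid carries no density within the comparison scope",
         call. = FALSE)
  expansion <- sum(z_inv[scope & !m_nat]) / tot_inv
  unfilling <- sum(z_nat[scope & !m_inv]) / tot_nat
  structure(
    list(expansion = expansion, stability = 1 - expansion,
         unfilling = unfilling, q = q, intersection_mode = intersection_mode),
    class = "dynamics_result")
}

#' @export
print.dynamics_result <- function(x, ...) {
  cat("<dynamics_result> expansion = ", signif(x$expansion, 4),
      ", stability = ", signif(x$stability, 4),
      ", unfilling = ", signif(x$unfilling, 4),
      " (q = ", x$q, ", ", x$intersection_mode, ")\n", sep = "")
  invisible(x)
}
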