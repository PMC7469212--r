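# Occurrence records: container, CSV I/O, spatial thinning, and
# minimum-convex-polygon backgrounds with a dispersion buffer.

#' Construct an occurrence set
#'
#' @param species species label.
#' @param range_label range label (e.g. "native", "NA", "EU").
#' @param lon,lat coordinates in decimal degrees (WGS84).
#' @param provenance free-text source tag.
#' @return an object of class `occurrence_set`.
#' @export
occurrence_set <- function(species, range_label, lon, lat, provenance = "") {
  stopifnot(length(lon) == length(lat))
  if (length(lon) == 0) stop("empty occurrence set", call. = FALSE)
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("occurrence coordinates must be finite", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude outside [-90, 90]", call. = FALSE)
  structure(
    list(species = species, range_label = range_label,
         points = data.frame(lon = as.numeric(lon), lat = as.numeric(lat)),
         provenance = provenance),
    class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat("<occurrence_set> ", x$species, " / ", x$range_label, ": ",
      nrow(x$points), " points\n", sep = "")
  invisible(x)
}

#' Number of points in an occurrence set
#' @param occ an `occurrence_set`.
#' @export
n_occurrences <- function(occ) nrow(occ$points)

#' Read / write occurrence CSV (columns species,range,lon,lat)
#'
#' `read_occurrences` returns a named list of `occurrence_set`, one per
#' (species, range) combination present in the file.
#'
#' @param path CSV file path.
#' @export
read_occurrences <- function(path) {
  # "NA" is a legitimate range label (North America), not missing data
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("species", "range", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have header species,range,lon,lat", call. = FALSE)
  sets <- split(df, interaction(df$species, df$range, drop = TRUE, sep = "/"))
  lapply(sets, function(s)
    occurrence_set(s$species[1], s$range[1], s$lon, s$lat, provenance = path))
}

#' @rdname read_occurrences
#' @param occ an `occurrence_set` or list of them.
#' @export
write_occurrences <- function(occ, path) {
  if (inherits(occ, "occurrence_set")) occ <- list(occ)
  df <- do.call(rbind, lapply(occ, function(o)
    data.frame(species = o$species, range = o$range_label,
               lon = o$points$lon, lat = o$points$lat)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Spatially thin occurrence records
#'
#' Removes records until no retained pair is closer than `min_distance_km`
#' (great-circle, haversine). Exact duplicate coordinates are removed first.
#' The reduction is a randomized greedy maximum-retention heuristic: while any
#' pair conflicts, drop the point with the most neighbours within range,
#' breaking ties with a seeded draw — so the result is deterministic for a
#' given seed and tends to keep as many records as possible.
#'
#' @param occ an `occurrence_set`, or a data.frame/matrix with lon, lat.
#' @param min_distance_km minimum allowed pairwise distance in km (> 0).
#' @param seed integer seed for tie-breaking.
#' @return a thinned `occurrence_set` (attribute `n_removed` gives the count
#'   dropped, duplicates included).
#' @export
thin_occurrences <- function(occ, min_distance_km = 5, seed = 1L) {
  stopifnot(min_distance_km > 0)
  if (!inherits(occ, "occurrence_set")) {
    df <- as.data.frame(occ)
    occ <- occurrence_set("unknown", "unknown", df$lon, df$lat)
  }
  pts <- occ$points
  n0 <- nrow(pts)
  pts <- unique(pts)
  keep <- rep(TRUE, nrow(pts))
  if (nrow(pts) > 1) {
    dmat <- geosphere::distm(as.matrix(pts), fun = geosphere::distHaversine) / 1000
    conflict <- dmat < min_distance_km
    diag(conflict) <- FALSE
    keep <- with_seed(child_seed(seed, "thin"), {
      alive <- rep(TRUE, nrow(pts))
      repeat {
        deg <- rowSums(conflict[alive, alive, drop = FALSE])
        if (all(deg == 0)) break
        worst <- which(deg == max(deg))
        drop_local <- if (length(worst) > 1) sample(worst, 1) else worst
        idx_alive <- which(alive)
        alive[idx_alive[drop_local]] <- FALSE
      }
      alive
    })
  }
  out <- occurrence_set(occ$species, occ$range_label,
                        pts$lon[keep], pts$lat[keep], occ$provenance)
  attr(out, "n_removed") <- n0 - sum(keep)
  out
}

#' Build a buffered minimum-convex-polygon background
#'
#' The geographic background of a range: the convex hull of the occurrences
#' dilated by `buffer_deg` plain degrees (the dispersion distance). One- and
#' two-point sets degenerate to a buffered disc / stadium. Hulls crossing the
#' antimeridian are not supported.
#'
#' @param occ an `occurrence_set`.
#' @param buffer_deg buffer radius in degrees (>= 0).
#' @param circle_segments number of segments used to discretize the buffer arc.
#' @return an object of class `background_region` with fields `polygon`
#'   (closed lon/lat ring), `buffer_deg` and `source_occurrences`.
#' @export
build_background <- function(occ, buffer_deg = 1, circle_segments = 72) {
  stopifnot(inherits(occ, "occurrence_set"), buffer_deg >= 0)
  pts <- as.matrix(occ$points)
  if (diff(range(pts[, "lon"])) > 180)
    stop("occurrences span > 180 degrees of longitude: ",
         "antimeridian-crossing hulls are not supported", call. = FALSE)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  if (buffer_deg > 0) {
    # Minkowski sum of a convex hull with a disc = convex hull of circles
    # centered on the hull vertices (up to arc discretization)
    theta <- seq(0, 2 * pi, length.out = circle_segments + 1)[-1]
    ring <- cbind(cos(theta), sin(theta)) * buffer_deg
    cloud <- do.call(rbind, lapply(seq_len(nrow(hull)), function(i)
      cbind(hull[i, 1] + ring[, 1], hull[i, 2] + ring[, 2])))
    colnames(cloud) <- c("lon", "lat")
    hull <- cloud[grDevices::chull(cloud), , drop = FALSE]
  }
  polygon <- rbind(hull, hull[1, , drop = FALSE])  # closed ring
  structure(
    list(polygon = as.data.frame(polygon), buffer_deg = buffer_deg,
         source_occurrences = occ),
    class = "background_region")
}

#' @export
print.background_region <- function(x, ...) {
  cat("<background_region> ", nrow(x$polygon) - 1, " vertices, buffer ",
      x$buffer_deg, " deg\n", sep = "")
  invisible(x)
}

#' Test whether points fall inside a background region
#' @param region a `background_region`.
#' @param lon,lat point coordinates.
#' @return logical vector (boundary counts as inside).
#' @export
point_in_region <- function(region, lon, lat) {
  sp::point.in.polygon(lon, lat, region$polygon$lon, region$polygon$lat) > 0
}

#' Planar area of a region polygon in square degrees
#' @param region a `background_region`.
#' @export
region_area <- function(region) {
  x <- region$polygon$lon; y <- region$polygon$lat
  n <- length(x)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Environmental values of all background cells
#'
#' Returns the environment of every valid (non-nodata) cell whose center falls
#' inside the region — the availability sample against which occurrence
#' densities are corrected.
#'
#' @param region a `background_region`.
#' @param stack a `climate_stack`.
#' @return numeric matrix, cells x variables, `site_kind = "background"`.
#' @export
background_sites <- function(region, stack) {
  tab <- stack_cell_table(stack)
  inside <- point_in_region(region, tab$lon, tab$lat)
  env <- as.matrix(tab[, stack_vars(stack), drop = FALSE])
  keep <- inside & stats::complete.cases(env)
  if (!any(keep))
    stop("no valid climate cells inside the background region", call. = FALSE)
  out <- env[keep, , drop = FALSE]
  attr(out, "site_kind") <- "background"
  attr(out, "cell_lonlat") <- tab[keep, c("lon", "lat")]
  out
}

#' Write a background region as GeoJSON
#' @param region a `background_region`.
#' @param path output file.
#' @export
write_background_geojson <- function(region, path) {
  coords <- lapply(seq_len(nrow(region$polygon)), function(i)
    c(region$polygon$lon[i], region$polygon$lat[i]))
  obj <- list(
    type = "Feature",
    properties = list(buffer_deg = region$buffer_deg,
                      species = region$source_occurrences$species,
                      range = region$source_occurrences$range_label),
    geometry = list(type = "Polygon", coordinates = list(coords)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
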