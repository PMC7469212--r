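# Co-registered gridded climate variables: container, plain-text raster I/O,
# masking, and point extraction.
#
# Grid convention: WGS84 decimal degrees, north-up, row-major from the
# north-west corner. Cells are half-open: a point exactly on a cell boundary
# belongs to the cell to its south-east. Missing data are NA internally and a
# nodata sentinel on disk.

#' Construct a climate stack
#'
#' A climate stack is an ordered set of gridded environmental variables sharing
#' one grid: identical dimensions, origin (north-west corner), cell size and
#' missing-data convention.
#'
#' @param values named list of numeric matrices (rows = latitude bands from the
#'   north, columns = longitude from the west). `NA` marks nodata cells.
#' @param origin numeric length-2, lon/lat of the grid's north-west corner.
#' @param cell_size cell edge in decimal degrees.
#' @param crs_label coordinate reference label (informational).
#' @return an object of class `climate_stack`.
#' @export
climate_stack <- function(values, origin, cell_size,
                          crs_label = "WGS84 (EPSG:4326)") {
  if (!is.list(values) || length(values) == 0)
    stop("`values` must be a non-empty named list of matrices", call. = FALSE)
  nms <- names(values)
  if (is.null(nms) || any(nms == ""))
    stop("every variable in a climate stack must be named", call. = FALSE)
  if (anyDuplicated(nms))
    stop("duplicate variable name: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  dims <- vapply(values, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all variables must share the same grid dimensions", call. = FALSE)
  for (nm in nms) {
    v <- values[[nm]]
    if (!is.matrix(v) || !is.numeric(v))
      stop("variable '", nm, "' is not a numeric matrix", call. = FALSE)
    if (any(!is.finite(v) & !is.na(v)))
      stop("variable '", nm, "' contains non-finite values other than NA",
           call. = FALSE)
  }
  stopifnot(length(origin) == 2, is.finite(origin), cell_size > 0)
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), crs_label = crs_label),
    class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  d <- dim(x$values[[1]])
  cat("<climate_stack> ", length(x$values), " variables, ",
      d[1], "x", d[2], " cells @ ", x$cell_size, " deg (", x$crs_label, ")\n",
      sep = "")
  cat("  variables: ", paste(names(x$values), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Variable names of a stack
#' @param stack a `climate_stack`.
#' @export
stack_vars <- function(stack) names(stack$values)

#' Extent of a stack as c(xmin, xmax, ymin, ymax)
#' @param stack a `climate_stack`.
#' @export
stack_extent <- function(stack) {
  d <- dim(stack$values[[1]])
  c(stack$origin[1], stack$origin[1] + d[2] * stack$cell_size,
    stack$origin[2] - d[1] * stack$cell_size, stack$origin[2])
}

# lon/lat of the center of cell (row, col); vectorized
cell_center <- function(stack, row, col) {
  cbind(lon = stack$origin[1] + (col - 0.5) * stack$cell_size,
        lat = stack$origin[2] - (row - 0.5) * stack$cell_size)
}

# containing cell of a lon/lat point under the half-open convention;
# returns NA row/col for points outside the extent
cell_index <- function(stack, lon, lat) {
  d <- dim(stack$values[[1]])
  # small tolerance so exact cell boundaries resolve to the south-east cell
  # despite floating-point representation of coordinates
  col <- floor((lon - stack$origin[1]) / stack$cell_size + 1e-9) + 1
  row <- floor((stack$origin[2] - lat) / stack$cell_size + 1e-9) + 1
  bad <- row < 1 | row > d[1] | col < 1 | col > d[2]
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# per-cell table: row, col, lon, lat and one column per variable
stack_cell_table <- function(stack) {
  d <- dim(stack$values[[1]])
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  ll <- cell_center(stack, rc$row, rc$col)
  env <- vapply(stack$values, function(m) m[cbind(rc$row, rc$col)],
                numeric(nrow(rc)))
  env <- matrix(env, nrow = nrow(rc),
                dimnames = list(NULL, names(stack$values)))
  cbind(rc, as.data.frame(ll), as.data.frame(env))
}

#' Read co-registered single-band rasters into a climate stack
#'
#' Accepts ESRI ASCII grid files (`.asc`), one per variable; the variable name
#' is the file name without extension. Files must be strictly co-registered:
#' mismatched dimensions, corner or cell size are an error (no resampling).
#'
#' @param paths character vector of raster file paths.
#' @return a `climate_stack`.
#' @export
read_stack <- function(paths) {
  if (length(paths) == 0) stop("no raster paths given", call. = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("raster file not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rasters <- lapply(paths, read_asc)
  nms <- sub("\\.[^.]+$", "", basename(paths))
  if (anyDuplicated(nms))
    stop("duplicate variable name: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  ref <- rasters[[1]]
  tol <- 1e-9 * ref$cell_size
  for (i in seq_along(rasters)[-1]) {
    r <- rasters[[i]]
    if (!identical(dim(r$grid), dim(ref$grid)))
      stop("grid mismatch in '", paths[i], "': dimensions differ from '",
           paths[1], "'", call. = FALSE)
    if (abs(r$cell_size - ref$cell_size) > tol)
      stop("grid mismatch in '", paths[i], "': cell size differs", call. = FALSE)
    if (any(abs(r$origin - ref$origin) > tol))
      stop("grid mismatch in '", paths[i], "': origin differs", call. = FALSE)
  }
  values <- lapply(rasters, `[[`, "grid")
  names(values) <- nms
  climate_stack(values, origin = ref$origin, cell_size = ref$cell_size)
}

#' Write a climate stack as one ASCII grid per variable
#'
#' @param stack a `climate_stack`.
#' @param dir output directory (created if needed).
#' @param nodata_value sentinel written for NA cells.
#' @return invisibly, the written file paths.
#' @export
write_stack <- function(stack, dir, nodata_value = -9999) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(names(stack$values), ".asc"))
  for (i in seq_along(stack$values)) {
    write_asc(stack$values[[i]], stack$origin, stack$cell_size,
              paths[i], nodata_value)
  }
  invisible(paths)
}

# -- ESRI ASCII grid reader/writer (plain-text single-band raster) -----------

read_asc <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("'", path, "' is not an ASCII grid: header lacks ",
         paste(setdiff(need, names(hdr)), collapse = "/"), call. = FALSE)
  vals <- scan(con, what = numeric(), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("'", path, "' has ", length(vals), " cells, expected ", nr * nc,
         call. = FALSE)
  grid <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) grid[grid == hdr$nodata_value] <- NA
  if (!is.null(hdr$xllcorner)) {
    xll <- hdr$xllcorner; yll <- hdr$yllcorner
  } else {
    xll <- hdr$xllcenter - hdr$cellsize / 2
    yll <- hdr$yllcenter - hdr$cellsize / 2
  }
  list(grid = grid,
       origin = c(xll, yll + nr * hdr$cellsize),  # north-west corner
       cell_size = hdr$cellsize)
}

write_asc <- function(grid, origin, cell_size, path, nodata_value = -9999) {
  nr <- nrow(grid); nc <- ncol(grid)
  out <- grid
  out[is.na(out)] <- nodata_value
  hdr <- c(paste("ncols", nc), paste("nrows", nr),
           paste("xllcorner", format(origin[1], digits = 15)),
           paste("yllcorner", format(origin[2] - nr * cell_size, digits = 15)),
           paste("cellsize", format(cell_size, digits = 15)),
           paste("NODATA_value", nodata_value))
  body <- apply(out, 1, function(r) paste(format(r, digits = 10, trim = TRUE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# -- extraction and masking ---------------------------------------------------

#' Extract environmental values at points
#'
#' Nearest-cell (containing-cell) lookup, no interpolation. Points outside the
#' grid extent or falling on nodata cells are dropped; the number dropped is
#' attached as attribute `n_dropped`. Row order follows the input order of the
#' retained points.
#'
#' @param stack a `climate_stack`.
#' @param points matrix or data.frame with columns lon, lat.
#' @param site_kind label stored on the result (`"occurrence"` or
#'   `"background"`).
#' @return numeric matrix, sites x variables, with attributes `n_dropped` and
#'   `site_kind`.
#' @export
extract_env <- function(stack, points, site_kind = "occurrence") {
  pts <- as.matrix(as.data.frame(points)[, c("lon", "lat")])
  if (nrow(pts) == 0) stop("no points to extract", call. = FALSE)
  if (any(!is.finite(pts))) stop("points must be finite lon/lat", call. = FALSE)
  idx <- cell_index(stack, pts[, "lon"], pts[, "lat"])
  inside <- !is.na(idx[, "row"])
  env <- matrix(NA_real_, nrow = nrow(pts), ncol = length(stack$values),
                dimnames = list(NULL, names(stack$values)))
  if (any(inside)) {
    sub <- idx[inside, , drop = FALSE]
    for (j in seq_along(stack$values))
      env[inside, j] <- stack$values[[j]][sub]
  }
  keep <- inside & !apply(env, 1, anyNA)
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop("all ", nrow(pts), " points fall outside the grid or on nodata cells",
         call. = FALSE)
  out <- env[keep, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  attr(out, "site_kind") <- site_kind
  out
}

#' Mask a stack to a background region
#'
#' Cells whose centers fall outside the region polygon are set to nodata in
#' every variable; the grid geometry is unchanged.
#'
#' @param stack a `climate_stack`.
#' @param region a `background_region` (see [build_background()]).
#' @return a masked `climate_stack`.
#' @export
mask_to_region <- function(stack, region) {
  d <- dim(stack$values[[1]])
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  ll <- cell_center(stack, rc$row, rc$col)
  inside <- point_in_region(region, ll[, "lon"], ll[, "lat"])
  if (!any(inside))
    stop("region does not intersect the stack extent: no cell centers inside",
         call. = FALSE)
  values <- lapply(stack$values, function(m) {
    m[cbind(rc$row, rc$col)[!inside, , drop = FALSE]] <- NA
    m
  })
  climate_stack(values, stack$origin, stack$cell_size, stack$crs_label)
}
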