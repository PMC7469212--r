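# Raster stack I/O, co-registration checks, masking, and point extraction.

test_that("ASCII grid stack round-trips through disk", {
  dir <- tempfile(); dir.create(dir)
  st <- make_climate_stack(3, c(0, 2, 40, 42), 0.1, 3, seed = 4)
  st$values[[2]][5, 7] <- NA  # a nodata cell survives the round trip
  paths <- write_stack(st, dir)
  back <- read_stack(paths)
  expect_equal(stack_vars(back), stack_vars(st))
  expect_equal(back$origin, st$origin)
  expect_equal(back$cell_size, st$cell_size)
  for (v in stack_vars(st))
    expect_equal(back$values[[v]], st$values[[v]], tolerance = 1e-8)
})

test_that("mis-registered or duplicate rasters are rejected by name", {
  dir <- tempfile(); dir.create(dir)
  a <- make_climate_stack(1, c(0, 2, 40, 42), 0.1, 3, seed = 1,
                          var_names = "a")
  b <- make_climate_stack(1, c(0.5, 2.5, 40, 42), 0.1, 3, seed = 1,
                          var_names = "b")
  write_stack(a, dir)
  write_stack(b, dir)
  expect_error(read_stack(file.path(dir, c("a.asc", "b.asc"))),
               "b\\.asc.*origin")
  # differing cell size
  cs <- make_climate_stack(1, c(0, 4, 40, 44), 0.2, 3, seed = 1,
                           var_names = "c")
  write_stack(cs, dir)
  expect_error(read_stack(file.path(dir, c("a.asc", "c.asc"))), "cell size")
  # duplicate variable names
  dir2 <- file.path(dir, "dup"); dir.create(dir2)
  write_stack(a, dir2)
  expect_error(read_stack(c(file.path(dir, "a.asc"),
                            file.path(dir2, "a.asc"))), "duplicate")
  expect_error(climate_stack(list(x = matrix(0, 2, 2), x = matrix(0, 2, 2)),
                             c(0, 1), 0.5), "duplicate")
})

test_that("extraction is an exact cell-center lookup", {
  st <- fix_stack2
  # every cell center maps back to its own cell (random sample of cells)
  set.seed(2)
  rows <- sample(nrow(st$values[[1]]), 25, replace = TRUE)
  cols <- sample(ncol(st$values[[1]]), 25, replace = TRUE)
  centers <- nicheshift:::cell_center(st, rows, cols)
  env <- extract_env(st, as.data.frame(centers))
  expect_equal(attr(env, "n_dropped"), 0)
  for (i in seq_along(rows))
    expect_identical(unname(env[i, 1]), st$values[[1]][rows[i], cols[i]])
})

test_that("points outside the extent are dropped and counted", {
  st <- fix_stack2
  pts <- data.frame(lon = c(2.05, 99), lat = c(42.05, 42.05))
  env <- extract_env(st, pts)
  expect_equal(nrow(env), 1)
  expect_equal(attr(env, "n_dropped"), 1)
  expect_error(extract_env(st, data.frame(lon = 99, lat = 0)), "outside")
})

test_that("extracted occurrence means recover the scenario centroid", {
  sc <- niche_scenario(c(0.2, -0.1), diag(2) * 0.04, c(0, 0),
                       n_native = 800, n_invasive = 2, seed = 13)
  env <- extract_env(fix_stack2,
                     sample_occurrences(sc, fix_stack2, "native")$points)
  for (j in 1:2)
    expect_lt(abs(mean(env[, j]) - sc$native_centroid[j]), 0.05)
})

test_that("masking keeps geometry and respects the polygon", {
  st <- fix_stack2
  whole <- full_extent_region(st, buffer = 1)
  expect_equal(mask_to_region(st, whole)$values, st$values)
  # half-plane polygon: valid-cell count halves within one row of cells
  ext <- stack_extent(st)
  half <- build_background(occurrence_set(
    "f", "h",
    lon = c(ext[1] - 1, mean(ext[1:2]), mean(ext[1:2]), ext[1] - 1),
    lat = c(ext[3] - 1, ext[3] - 1, ext[4] + 1, ext[4] + 1)), 0)
  masked <- mask_to_region(st, half)
  n_valid <- sum(!is.na(masked$values[[1]]))
  n_total <- length(st$values[[1]])
  expect_lt(abs(n_valid - n_total / 2), nrow(st$values[[1]]) + 1)
  # tiny polygon inside one cell -> exactly 1 valid cell
  ctr <- nicheshift:::cell_center(st, 10, 10)
  eps <- st$cell_size / 10
  tiny <- build_background(occurrence_set(
    "f", "t", lon = ctr[1] + c(-eps, eps, eps, -eps),
    lat = ctr[2] + c(-eps, -eps, eps, eps)), 0)
  expect_equal(sum(!is.na(mask_to_region(st, tiny)$values[[1]])), 1)
  # empty intersection is an error
  far <- build_background(occurrence_set("f", "x", c(90, 91), c(10, 11)), 0.1)
  expect_error(mask_to_region(st, far), "intersect")
})

test_that("extract after mask equals mask-then-extract for interior points", {
  st <- fix_stack2
  ext <- stack_extent(st)
  region <- build_background(occurrence_set(
    "f", "r", lon = c(1, 4, 4, 1), lat = c(41, 41, 44, 44)), 0.2)
  masked <- mask_to_region(st, region)
  pts <- data.frame(lon = runif(40, 1.5, 3.5), lat = runif(40, 41.5, 43.5))
  expect_equal(extract_env(masked, pts), extract_env(st, pts))
})

test_that("boundary points assign to the south-east cell", {
  st <- fix_stack2
  # a point exactly on the shared corner of four cells
  lon <- st$origin[1] + 3 * st$cell_size
  lat <- st$origin[2] - 3 * st$cell_size
  idx <- nicheshift:::cell_index(st, lon, lat)
  expect_equal(as.integer(idx), c(4L, 4L))
})
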