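# Spatial thinning and buffered minimum-convex-polygon backgrounds.

test_that("thinning enforces the minimum distance with maximal retention", {
  # two points ~3 km apart against a 5 km rule: exactly one survives
  two <- occurrence_set("sp", "r", lon = c(0, 0.027), lat = c(45, 45))
  expect_equal(n_occurrences(thin_occurrences(two, 5)), 1)
  # a single point is returned unchanged
  one <- occurrence_set("sp", "r", lon = 3, lat = 44)
  expect_equal(thin_occurrences(one, 5)$points, one$points)
  # 30 random points: all-pairs audit + at least naive-sequential retention
  pts <- random_points(30, lon = c(0, 0.3), lat = c(45, 45.3), seed = 8)
  occ <- occurrence_set("sp", "r", pts$lon, pts$lat)
  thinned <- thin_occurrences(occ, 5, seed = 2)
  d <- geosphere::distm(as.matrix(thinned$points)) / 1000
  expect_true(all(d[upper.tri(d)] >= 5))
  naive <- local({
    kept <- 1L
    for (i in 2:nrow(pts)) {
      dd <- geosphere::distm(as.matrix(pts[i, ]),
                             as.matrix(pts[kept, , drop = FALSE])) / 1000
      if (all(dd >= 5)) kept <- c(kept, i)
    }
    length(kept)
  })
  expect_gte(n_occurrences(thinned), naive)
})

test_that("thinning is idempotent and deterministic", {
  pts <- random_points(60, lon = c(0, 0.4), lat = c(44.8, 45.2), seed = 3)
  occ <- occurrence_set("sp", "r", pts$lon, pts$lat)
  t1 <- thin_occurrences(occ, 5, seed = 10)
  t2 <- thin_occurrences(t1, 5, seed = 99)  # already thinned: unchanged
  expect_identical(t2$points, t1$points)
  expect_identical(thin_occurrences(occ, 5, seed = 10)$points, t1$points)
  # duplicate coordinates are removed even when otherwise isolated
  dup <- occurrence_set("sp", "r", lon = c(1, 1, 2), lat = c(45, 45, 45))
  expect_equal(n_occurrences(thin_occurrences(dup, 5)), 2)
})

test_that("background is a buffered convex hull containing all occurrences", {
  tri <- occurrence_set("sp", "r", lon = c(0, 2, 1), lat = c(45, 45, 46.5))
  region <- build_background(tri, buffer_deg = 1)
  # every hull vertex sits >= 1 degree inside the region boundary
  poly <- region$polygon
  seg_dist <- function(p, a, b) {
    ab <- b - a; t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }
  for (i in seq_len(3)) {
    v <- c(tri$points$lon[i], tri$points$lat[i])
    dmin <- min(vapply(seq_len(nrow(poly) - 1), function(k)
      seg_dist(v, as.numeric(poly[k, ]), as.numeric(poly[k + 1, ])),
      numeric(1)))
    expect_gte(dmin, 1 - 0.01)  # circle discretization tolerance
  }
  # single point degenerates to a disc of radius 1
  disc <- build_background(occurrence_set("sp", "r", 5, 45), 1)
  r <- sqrt((disc$polygon$lon - 5)^2 + (disc$polygon$lat - 45)^2)
  expect_equal(mean(r), 1, tolerance = 1e-6)
  expect_equal(region_area(disc), pi, tolerance = 0.01)
})

test_that("buffering dilates the hull and keeps every occurrence inside", {
  pts <- random_points(50, lon = c(0, 3), lat = c(44, 47), seed = 5)
  occ <- occurrence_set("sp", "r", pts$lon, pts$lat)
  hull <- build_background(occ, 0)
  region <- build_background(occ, 1)
  expect_gte(region_area(region), region_area(hull))
  expect_true(all(point_in_region(region, pts$lon, pts$lat)))
  # monotonicity: a larger buffer never removes background cells
  small <- background_sites(build_background(occ, 0.3), fix_stack2)
  large <- background_sites(build_background(occ, 0.8), fix_stack2)
  expect_gte(nrow(large), nrow(small))
})

test_that("antimeridian-crossing hulls are rejected", {
  occ <- occurrence_set("sp", "r", lon = c(-179, 179), lat = c(0, 1))
  expect_error(build_background(occ, 1), "antimeridian")
})

test_that("background_sites returns every valid in-region cell", {
  st <- fix_stack2
  whole <- full_extent_region(st)
  env <- background_sites(whole, st)
  expect_equal(nrow(env), sum(!is.na(st$values[[1]])))
  expect_identical(attr(env, "site_kind"), "background")
  # identical count through the mask_to_region round trip
  masked <- mask_to_region(st, whole)
  expect_equal(nrow(background_sites(whole, masked)), nrow(env))
  # half-extent region: within one grid row of half the cells
  ext <- stack_extent(st)
  half <- build_background(occurrence_set(
    "f", "h", lon = c(ext[1] - 1, mean(ext[1:2]), mean(ext[1:2]), ext[1] - 1),
    lat = c(ext[3] - 1, ext[3] - 1, ext[4] + 1, ext[4] + 1)), 0)
  expect_lt(abs(nrow(background_sites(half, st)) - nrow(env) / 2),
            nrow(st$values[[1]]) + 1)
})

test_that("occurrence CSV round-trips by species and range", {
  sets <- list(occurrence_set("beetle", "native", c(1, 2), c(45, 46)),
               occurrence_set("beetle", "EU", c(8, 9), c(50, 51)))
  path <- tempfile(fileext = ".csv")
  write_occurrences(sets, path)
  back <- read_occurrences(path)
  expect_length(back, 2)
  ranges <- sort(unname(vapply(back, function(o) o$range_label,
                               character(1))))
  expect_equal(ranges, c("EU", "native"))
  expect_error(read_occurrences(write_occurrences_badheader()), "header")
})

write_occurrences_badheader <- function() {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1, y = 2), p, row.names = FALSE)
  p
}

test_that("background GeoJSON is valid and closed", {
  region <- build_background(occurrence_set("sp", "r", c(0, 1, 2),
                                            c(45, 46, 45)), 0.5)
  path <- tempfile(fileext = ".geojson")
  write_background_geojson(region, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$geometry$type, "Polygon")
  ring <- gj$geometry$coordinates[[1]]
  expect_equal(unlist(ring[[1]]), unlist(ring[[length(ring)]]))
})
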