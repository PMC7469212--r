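# Synthetic climate surfaces and occurrence sets with known niche geometry.

test_that("climate fields are standardized, autocorrelated, and reproducible", {
  st <- make_climate_stack(n_vars = 19, extent = c(0, 10, 40, 50),
                           cell_size = 0.1, autocorr_length = 5, seed = 1)
  expect_length(st$values, 19)
  for (m in st$values) {
    expect_lt(abs(mean(m)), 0.05)
    expect_gt(sd(m), 0.9); expect_lt(sd(m), 1.1)
  }
  # stronger smoothing => strictly larger lag-1 spatial autocorrelation
  rough <- make_climate_stack(1, c(0, 5, 40, 45), 0.1,
                              autocorr_length = 1, seed = 9)
  smooth <- make_climate_stack(1, c(0, 5, 40, 45), 0.1,
                               autocorr_length = 20, seed = 9)
  expect_gt(lag1_autocorr(smooth$values[[1]]),
            lag1_autocorr(rough$values[[1]]))
  # seed determinism, byte identical
  again <- make_climate_stack(19, c(0, 10, 40, 50), 0.1,
                              autocorr_length = 5, seed = 1)
  expect_identical(st$values, again$values)
})

test_that("degenerate extents are rejected", {
  expect_error(make_climate_stack(2, extent = c(0, 0, 40, 50)), "degenerate")
  expect_error(make_climate_stack(2, extent = c(0, 10, 50, 50)), "degenerate")
})

test_that("occurrence sampling matches the generating law", {
  sc0 <- niche_scenario(c(0, 0), diag(2) * 0.25, shift_vector = c(0, 0),
                        n_native = 116, n_invasive = 200, seed = 5)
  occ_n <- sample_occurrences(sc0, fix_stack2, "native")
  occ_i <- sample_occurrences(sc0, fix_stack2, "invasive")
  expect_equal(n_occurrences(occ_n), 116)
  env_n <- extract_env(fix_stack2, occ_n$points)
  env_i <- extract_env(fix_stack2, occ_i$points)
  # zero shift: group means within 3 standard errors on each variable
  for (j in 1:2) {
    se <- sqrt(var(env_n[, j]) / nrow(env_n) + var(env_i[, j]) / nrow(env_i))
    expect_lt(abs(mean(env_n[, j]) - mean(env_i[, j])), 3 * se)
  }
  # large shift (4 native sd on bio1) separates the groups on that variable
  sc4 <- niche_scenario(c(-1, 0), diag(2) * 0.25, shift_vector = c(2, 0),
                        n_native = 200, n_invasive = 200, seed = 5)
  e1 <- extract_env(fix_stack2, sample_occurrences(sc4, fix_stack2,
                                                   "native")$points)
  e2 <- extract_env(fix_stack2, sample_occurrences(sc4, fix_stack2,
                                                   "invasive")$points)
  pooled_sd <- sqrt((var(e1[, 1]) + var(e2[, 1])) / 2)
  expect_gt(abs(mean(e2[, 1]) - mean(e1[, 1])), 2 * pooled_sd)
  # determinism
  expect_identical(sample_occurrences(sc0, fix_stack2, "native")$points,
                   occ_n$points)
})

test_that("sample centroid recovers the scenario centroid within 3 SE", {
  # niche kept tight relative to the availability gradient: cells are drawn
  # by niche density x availability, so broad niches shrink toward the
  # availability mean
  sc <- niche_scenario(c(0.15, -0.1), diag(2) * 0.04, shift_vector = c(0, 0),
                       n_native = 800, n_invasive = 2, seed = 11)
  env <- extract_env(fix_stack2,
                     sample_occurrences(sc, fix_stack2, "native")$points)
  # exact expectation of the sampling law over the climate cells
  tab <- nicheshift:::stack_cell_table(fix_stack2)
  cells <- as.matrix(tab[, c("bio1", "bio2")])
  w <- exp(nicheshift:::dmvnorm_log(cells, sc$native_centroid,
                                    sc$native_spread))
  expected <- colSums(cells * w) / sum(w)
  for (j in 1:2) {
    se <- sd(env[, j]) / sqrt(nrow(env))
    expect_lt(abs(mean(env[, j]) - expected[j]), 3 * se)
    expect_lt(abs(mean(env[, j]) - sc$native_centroid[j]), 0.05)
  }
})

test_that("unreachable centroids raise a descriptive error", {
  sc <- niche_scenario(c(50, 50), diag(2) * 0.01, shift_vector = c(0, 0),
                       n_native = 5, n_invasive = 5, seed = 1)
  expect_error(sample_occurrences(sc, fix_stack2, "native"), "unreachable")
})

test_that("true_overlap matches analytic and quadrature oracles", {
  # identical generating densities
  sc_same <- niche_scenario(c(0, 0), diag(2), c(0, 0),
                            n_native = 5, n_invasive = 5)
  expect_equal(true_overlap(sc_same), 1, tolerance = 1e-6)
  # far-separated centroids
  sc_far <- niche_scenario(c(0, 0), diag(2) * 0.04, c(40, 0),
                           n_native = 5, n_invasive = 5)
  expect_lt(true_overlap(sc_far), 1e-6)
  # 1-D unit-variance Gaussians, gap 2 sd, against trapezoid quadrature
  sc1 <- niche_scenario(0, matrix(1), shift_vector = 2,
                        n_native = 5, n_invasive = 5)
  xs <- seq(-10, 12, length.out = 200001)
  oracle <- 1 - 0.5 * sum(abs(dnorm(xs, 0, 1) - dnorm(xs, 2, 1))) * diff(xs[1:2])
  expect_equal(true_overlap(sc1, list(n = 5000)), oracle, tolerance = 1e-4)
  # symmetry in the two ranges: flipping the shift leaves overlap unchanged
  sc_a <- niche_scenario(c(0, 0), diag(2) * 0.25, c(1, 0.5), n_native = 5,
                         n_invasive = 5)
  sc_b <- niche_scenario(c(1, 0.5), diag(2) * 0.25, c(-1, -0.5),
                         n_native = 5, n_invasive = 5)
  expect_equal(true_overlap(sc_a), true_overlap(sc_b), tolerance = 1e-9)
})

test_that("true_overlap decreases monotonically along a shift ladder", {
  ladder <- vapply(seq(0, 2, by = 0.5), function(s)
    true_overlap(niche_scenario(c(0, 0), diag(2) * 0.25, c(s, 0),
                                n_native = 5, n_invasive = 5)),
    numeric(1))
  expect_true(all(diff(ladder) < 0))
  # a too-coarse grid is rejected rather than silently truncating mass
  sc <- niche_scenario(c(0, 0), diag(2), c(0.5, 0), n_native = 5,
                       n_invasive = 5)
  expect_error(true_overlap(sc, list(extent = cbind(c(-1, -1), c(1, 1)))),
               "mass")
})

test_that("scenario validation and YAML round-trip work", {
  expect_error(niche_scenario(c(0, 0), matrix(c(1, 2, 2, 1), 2), c(0, 0),
                              n_native = 5, n_invasive = 5),
               "positive-definite")
  expect_error(niche_scenario(c(0, 0), diag(2), c(0, 0, 0),
                              n_native = 5, n_invasive = 5), "shift_vector")
  sc <- niche_scenario(c(0.1, -0.4), matrix(c(0.3, 0.1, 0.1, 0.5), 2),
                       c(1, 0), spread_scale = 1.5,
                       n_native = 20, n_invasive = 30, seed = 99)
  path <- tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  expect_equal(read_scenario(path), sc)
})
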