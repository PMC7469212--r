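# Schoener's D and the randomization equivalency/similarity tests.

test_that("schoener_d matches direct evaluation and is symmetric", {
  z1 <- matrix(c(0.5, 0.5, 0, 0), 2)
  z2 <- matrix(0.25, 2, 2)
  expect_equal(schoener_d(z1, z2), 0.5, tolerance = 1e-12)
  expect_identical(schoener_d(z1, z1), 1)
  disjoint <- matrix(c(0, 0, 0.5, 0.5), 2)
  expect_equal(schoener_d(z1, disjoint), 0)
  expect_equal(schoener_d(z1, z2), schoener_d(z2, z1))
  expect_error(schoener_d(z1, matrix(1, 1, 1)), "shape")
  expect_error(schoener_d(z1 * 2, z2), "normalized")
  expect_error(schoener_d(matrix(c(-0.5, 1.5, 0, 0), 2), z2), "negative")
})

test_that("D decreases along a ladder of increasing niche shifts", {
  ds <- vapply(c(0, 0.5, 1, 1.5, 2), function(s) {
    pair <- simulate_pair(shift = s, n = 150, seed = 29)
    schoener_d(pair$grid_native, pair$grid_invasive)
  }, numeric(1))
  expect_true(all(diff(ds) < 0))
})

test_that("equivalency of identical occurrence sets is never rejected", {
  pair <- simulate_pair(shift = 0, n = 60, seed = 41, R = 40)
  res <- equivalency_test(pair$scores_native, pair$scores_native,
                          pair$bg_scores, pair$bg_scores,
                          R = 40, n_reps = 30, seed = 1)
  expect_equal(res$D, 1)
  expect_equal(res$p, 1)
  expect_length(res$null, 30)
})

test_that("well-separated niches give the minimal equivalency p", {
  # tight niches 12 niche-sd apart, both well inside the available space
  pair <- simulate_pair(shift = 2.4, n = 80, seed = 43, spread = 0.04,
                        R = 40)
  res <- equivalency_test(pair$scores_native, pair$scores_invasive,
                          pair$bg_scores, pair$bg_scores,
                          R = 40, n_reps = 100, seed = 5)
  expect_equal(res$p, 1 / 101, tolerance = 1e-12)
  expect_true(all(res$null > res$D))
})

test_that("similarity test ranks the observed overlap against relocations", {
  pair <- simulate_pair(shift = 0.2, n = 120, seed = 47, R = 50)
  res12 <- similarity_test(pair$grid_native, pair$grid_invasive,
                           direction = "1->2", n_reps = 60, seed = 3)
  res21 <- similarity_test(pair$grid_invasive, pair$grid_native,
                           direction = "2->1", n_reps = 60, seed = 3)
  for (res in list(res12, res21)) {
    expect_length(res$null, 60)
    expect_gte(res$p, 1 / 61)
    expect_lte(res$p, 1)
  }
  # strongly overlapping pair: observed overlap beats random placement
  expect_lt(res12$p, 0.05)
  # a grid with observed D below every null value gives p = 1
  fake <- pair$grid_invasive
  fake$z <- matrix(0, fake$R, fake$R)
  corner <- which(fake$e > 0, arr.ind = TRUE)
  corner <- corner[which.max(corner[, 1] + corner[, 2]), ]
  fake$z[corner[1], corner[2]] <- 1
  res_far <- similarity_test(pair$grid_native, fake, n_reps = 40, seed = 9)
  expect_gt(res_far$p, 0.9)
})

test_that("randomization p-values respect their attainable bounds", {
  pair <- simulate_pair(shift = 1, n = 60, seed = 53, R = 40)
  for (reps in c(5, 20)) {
    eq <- equivalency_test(pair$scores_native, pair$scores_invasive,
                           pair$bg_scores, pair$bg_scores,
                           R = 40, n_reps = reps, seed = 7)
    si <- similarity_test(pair$grid_native, pair$grid_invasive,
                          n_reps = reps, seed = 7)
    for (p in c(eq$p, si$p)) {
      expect_gte(p, 1 / (reps + 1))
      expect_lte(p, 1)
    }
  }
})

test_that("tests are deterministic under a fixed seed", {
  pair <- simulate_pair(shift = 0.5, n = 60, seed = 59, R = 40)
  a <- equivalency_test(pair$scores_native, pair$scores_invasive,
                        pair$bg_scores, pair$bg_scores,
                        R = 40, n_reps = 15, seed = 11)
  b <- equivalency_test(pair$scores_native, pair$scores_invasive,
                        pair$bg_scores, pair$bg_scores,
                        R = 40, n_reps = 15, seed = 11)
  expect_identical(a$null, b$null)
  s1 <- similarity_test(pair$grid_native, pair$grid_invasive,
                        n_reps = 15, seed = 11)
  s2 <- similarity_test(pair$grid_native, pair$grid_invasive,
                        n_reps = 15, seed = 11)
  expect_identical(s1$null, s2$null)
})
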