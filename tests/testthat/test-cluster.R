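test_that("NNI reproduces the square worked example and its formulas", {
  # 4 points on the corners of a 10-km square, study area 100 km^2:
  # observed mean NN = 10 km, expected = 0.5/sqrt(4/100) = 2.5, NNI = 4
  sq <- equator_points(c(0, 10, 0, 10), c(0, 0, 10, 10))
  r <- nearest_neighbor_index(sq$lat, sq$lon, area_method = "user_supplied",
                              area_km2 = 100)
  expect_equal(r$mean_observed_km, 10, tolerance = 1e-4)
  expect_equal(r$expected_km, 2.5)
  expect_equal(r$nni, 4, tolerance = 1e-4)
  expect_equal(r$se, 0.26136 / sqrt(16 / 100), tolerance = 1e-12)
  expect_equal(r$z, (r$mean_observed_km - 2.5) / r$se)
  expect_gt(r$z, 1.96)   # dispersed pattern
})

test_that("NNI is scale equivariant when distances and area scale together", {
  x <- c(0, 7, 19, 31, 52, 80)
  p1 <- equator_points(x)
  p2 <- equator_points(3 * x)
  r1 <- nearest_neighbor_index(p1$lat, p1$lon, "user_supplied",
                               area_km2 = 500)
  r2 <- nearest_neighbor_index(p2$lat, p2$lon, "user_supplied",
                               area_km2 = 500 * 9)
  expect_equal(r1$nni, r2$nni, tolerance = 1e-9)
  expect_equal(r1$z, r2$z, tolerance = 1e-9)
})

test_that("duplicate-heavy clustered patterns give NNI << 1 with z << 0", {
  set.seed(31)
  base <- generate_csr(30, km_bbox(20, 78, 500, 500), seed = 31)
  heavy <- base[rep(1:30, each = 8), ]   # co-located stacks of cases
  r <- nearest_neighbor_index(heavy$lat, heavy$lon)
  expect_lt(r$nni, 0.3)
  expect_lt(r$z, -1.96)
  expect_lt(r$p, 0.001)
})

test_that("NNI rejects degenerate input", {
  co <- equator_points(c(0, 0, 0))
  expect_error(nearest_neighbor_index(co$lat, co$lon, "user_supplied",
                                      area_km2 = 10), "coincident")
  expect_error(nearest_neighbor_index(1, 2), "at least 3")
})

test_that("Moran's I matches the two-point antithesis and the null expectation", {
  p2 <- equator_points(c(0, 10))
  W <- inverse_distance_weights(p2, cutoff_km = 50, power = 0)
  r <- morans_i(c(1, -1), W)
  expect_equal(r$I, -1, tolerance = 1e-12)
  expect_equal(r$expectation, -1)

  p5 <- equator_points(c(0, 10, 20, 30, 40))
  W5 <- inverse_distance_weights(p5, cutoff_km = 100, power = 1)
  r5 <- morans_i(c(3, 1, 4, 1, 5), W5)
  expect_equal(r5$expectation, -0.25)
})

test_that("Moran's I and its randomization variance match independent oracles", {
  for (seed in c(12, 13, 14)) {
    pts <- generate_csr(12, km_bbox(18, 77, 100, 100), seed = seed)
    W <- inverse_distance_weights(pts, cutoff_km = 60, power = 1)
    set.seed(seed + 100)
    x <- rpois(12, 4) + runif(12)
    r <- morans_i(x, W)
    M <- as.matrix(weights_matrix(W))
    expect_equal(r$I, oracle_moran(x, M), tolerance = 1e-12)
    expect_equal(r$variance_randomization, oracle_moran_var_rand(x, M),
                 tolerance = 1e-12)
  }
})

test_that("Moran's I is invariant to positive affine transforms of x", {
  pts <- generate_csr(25, km_bbox(22, 80, 150, 150), seed = 17)
  W <- inverse_distance_weights(pts, cutoff_km = 80)
  set.seed(18)
  x <- rnorm(25)
  r0 <- morans_i(x, W)
  r1 <- morans_i(2.5 * x + 7, W)
  expect_lt(abs(r1$I - r0$I), 1e-12)
  expect_equal(r1$z, r0$z, tolerance = 1e-9)
})

test_that("row-standardized Moran's I stays within the loose unit bound", {
  for (seed in 1:5) {
    pts <- generate_csr(30, km_bbox(15, 75, 200, 200), seed = seed)
    W <- suppressMessages(row_standardize(
      inverse_distance_weights(pts, cutoff_km = 100)))
    set.seed(seed)
    x <- rnorm(30)
    r <- morans_i(x, W)
    expect_gte(r$I, -1.05)
    expect_lte(r$I, 1.05)
  }
})

test_that("Moran's I rejects constant x and self-inclusive weights", {
  pts <- generate_csr(10, km_bbox(20, 78, 100, 100), seed = 2)
  W <- inverse_distance_weights(pts, cutoff_km = 100)
  expect_error(morans_i(rep(2, 10), W), "constant")
  Wself <- inverse_distance_weights(pts, cutoff_km = 100,
                                    include_self = TRUE)
  expect_error(morans_i(rnorm(10), Wself), "self")
})

test_that("permutation p follows the counting formula at its floor", {
  # a value surface perfectly aligned with space: no permutation can be as
  # extreme, so p must hit the floor 1/(n_perm + 1)
  pts <- equator_points(seq(0, 110, by = 10))
  W <- inverse_distance_weights(pts, cutoff_km = 15, power = 1)
  x <- seq_along(pts$lat)   # monotone gradient = maximal alignment
  r <- morans_i_permutation(x, W, n_perm = 19, seed = 5)
  expect_equal(r$p_permutation, 1 / 20)
  r2 <- morans_i_permutation(x, W, n_perm = 999, seed = 5)
  expect_equal(r2$p_permutation, 1 / 1000)
  expect_error(morans_i_permutation(x, W, n_perm = 10), "19")
})

test_that("permutation inference is deterministic given the seed", {
  pts <- generate_csr(40, km_bbox(20, 78, 150, 150), seed = 8)
  W <- inverse_distance_weights(pts, cutoff_km = 80)
  set.seed(80)
  x <- rnorm(40)
  a <- morans_i_permutation(x, W, n_perm = 99, seed = 123)
  b <- morans_i_permutation(x, W, n_perm = 99, seed = 123)
  expect_identical(a$p_permutation, b$p_permutation)
  expect_identical(a$null_mean, b$null_mean)
})

test_that("permutation test has power against a smooth distance-decay field", {
  pts <- generate_csr(100, km_bbox(20, 78, 300, 300), seed = 55)
  W <- inverse_distance_weights(pts, cutoff_km = 100)
  # smooth field: decay from the window centre plus mild noise
  d0 <- haversine_km(pts$lat, pts$lon, 20, 78)
  set.seed(56)
  x <- exp(-d0 / 80) + rnorm(100, sd = 0.05)
  r <- morans_i_permutation(x, W, n_perm = 499, seed = 57)
  expect_lte(r$p_permutation, 0.01)
  expect_gt(r$I, 0)
})

test_that("analytical and permutation p agree within a factor of three at n = 100", {
  pts <- generate_csr(100, km_bbox(20, 78, 300, 300), seed = 60)
  W <- inverse_distance_weights(pts, cutoff_km = 100)
  set.seed(61)
  x <- rnorm(100)   # exchangeable: moderate p on both routes
  r <- morans_i_permutation(x, W, n_perm = 999, seed = 62)
  ratio <- r$p / r$p_permutation
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)
})
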