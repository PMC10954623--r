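gistar_fixture <- function(n = 15, seed = 9, box_km = 120, cutoff = 60) {
  pts <- generate_csr(n, km_bbox(20, 78, box_km, box_km), seed = seed)
  set.seed(seed + 1)
  pts$count <- rpois(n, 5) + 1
  W <- inverse_distance_weights(pts, cutoff_km = cutoff, power = 1,
                                include_self = TRUE)
  list(pts = pts, W = W)
}

test_that("Gi* agrees with a dense direct-summation oracle", {
  for (seed in c(9, 19)) {
    f <- gistar_fixture(seed = seed)
    r <- getis_ord_gistar(f$pts, f$W)
    M <- as.matrix(weights_matrix(f$W))
    expect_equal(r$z, oracle_gistar(f$pts$count, M), tolerance = 1e-10)
    expect_equal(r$p, 2 * pnorm(-abs(r$z)), tolerance = 1e-12)
  }
})

test_that("Gi* z-scores respect a mirror-symmetric configuration", {
  # two identical clusters east and west of the origin
  half <- data.frame(x = c(0, 5, 10, 3), y = c(0, 4, -2, 8),
                     count = c(9, 4, 2, 6))
  west <- equator_points(-200 - half$x, half$y)
  east <- equator_points(200 + half$x, half$y)
  pts <- rbind(west, east)
  pts$count <- c(half$count, half$count)
  W <- inverse_distance_weights(pts, cutoff_km = 50, power = 1,
                                include_self = TRUE)
  r <- getis_ord_gistar(pts, W)
  expect_equal(r$z[1:4], r$z[5:8], tolerance = 1e-9)
})

test_that("Gi* enforces its domain: constant counts and self-weights", {
  f <- gistar_fixture()
  flat <- f$pts; flat$count <- rep(3L, nrow(flat))
  expect_error(getis_ord_gistar(flat, f$W), "constant")
  Wnoself <- inverse_distance_weights(f$pts, cutoff_km = 60, power = 1)
  expect_error(getis_ord_gistar(f$pts, Wnoself), "include_self")
})

test_that("isolated locations get NODATA z with a warning", {
  pts <- rbind(generate_csr(10, km_bbox(20, 78, 60, 60), seed = 3),
               data.frame(lat = 30, lon = 95))
  pts$count <- c(rpois(10, 4) + 1, 2)
  W <- inverse_distance_weights(pts, cutoff_km = 40, power = 1,
                                include_self = TRUE)
  expect_warning(r <- getis_ord_gistar(pts, W), "degenerate")
  expect_true(is.na(r$z[11]))
  expect_false(anyNA(r$z[1:10]))
})

test_that("hotspot classification follows the z threshold table", {
  z <- c(2.0, -1.7, 1.0, 2.6, -2.0, -3.0, 1.7, 0, NA)
  cls <- hotspot_class(z)
  expect_equal(as.character(cls),
               c("hot95", "cold90", "not_significant", "hot99", "cold95",
                 "cold99", "hot90", "not_significant", NA))
  expect_equal(as.character(hotspot_class(rep(0, 4))),
               rep("not_significant", 4))
})

test_that("FDR classification is never more liberal than the plain bins", {
  f <- gistar_fixture(n = 40, seed = 23, box_km = 400, cutoff = 80)
  r <- getis_ord_gistar(f$pts, f$W)
  plain <- classify_hotspots(r, fdr = FALSE)
  fdr <- classify_hotspots(r, fdr = TRUE)
  sig <- function(cl) !is.na(cl) & cl != "not_significant"
  expect_true(all(sig(fdr$class) <= sig(plain$class)))
  expect_true(fdr$fdr_applied)
})

test_that("admin tallies count hot95+ locations and can be empty", {
  f <- gistar_fixture(n = 40, seed = 23, box_km = 400, cutoff = 80)
  r <- classify_hotspots(getis_ord_gistar(f$pts, f$W))
  states <- rep(c("A", "B"), each = 20)
  tal <- hotspots_by_admin(r, states)
  hot <- r$class %in% c("hot95", "hot99")
  expect_equal(sum(tal), sum(hot))
  # force an all-flat z: no location can be hot
  r0 <- r
  r0$class <- hotspot_class(rep(0, 40))
  expect_length(hotspots_by_admin(r0, states), 0)
  # three hot locations in one state tally as {state: 3}
  r3 <- r
  r3$class <- hotspot_class(c(rep(3, 3), rep(0, 37)))
  expect_equal(hotspots_by_admin(r3, states), c(A = 3L))
})

test_that("Gi* null calibration: permuted counts rarely exceed |z| = 1.96", {
  f <- gistar_fixture(n = 40, seed = 35, box_km = 300, cutoff = 80)
  set.seed(36)
  exceed <- matrix(NA, 400, 40)
  for (b in 1:400) {
    shuffled <- f$pts
    shuffled$count <- sample(f$pts$count)
    z <- suppressWarnings(getis_ord_gistar(shuffled, f$W)$z)
    exceed[b, ] <- abs(z) > 1.96
  }
  expect_lte(mean(exceed, na.rm = TRUE), 0.07)
})

test_that("IDW interpolation honors its exact-hit and symmetry contracts", {
  pts <- equator_points(c(0, 10, 20))
  z <- c(0, 1, 0)
  # cell on a data point takes that value exactly
  expect_equal(idw_interpolate(pts$lat[2], pts$lon[2],
                               pts$lat, pts$lon, z), 1)
  # equidistant cell between two values averages them for any power
  two <- equator_points(c(0, 10))
  mid <- equator_points(5)
  for (p in c(1, 2, 4))
    expect_equal(idw_interpolate(mid$lat, mid$lon, two$lat, two$lon,
                                 c(0, 4), power = p), 2, tolerance = 1e-9)
  # hand-computed three-point case: weights 1/25, 1/25, 1/225 -> 9/19
  q <- equator_points(5)
  expect_equal(idw_interpolate(q$lat, q$lon, pts$lat, pts$lon, z,
                               power = 2, k = 3), 9 / 19, tolerance = 1e-6)
})

test_that("IDW surface is bounded by its data and NODATA where empty", {
  f <- gistar_fixture(n = 25, seed = 40, box_km = 200, cutoff = 80)
  r <- getis_ord_gistar(f$pts, f$W)
  surf <- idw_surface(f$pts$lat, f$pts$lon, r$z, power = 2, k = 8)
  v <- surf$values[!is.na(surf$values)]
  expect_gte(min(v), min(r$z, na.rm = TRUE) - 1e-9)
  expect_lte(max(v), max(r$z, na.rm = TRUE) + 1e-9)
  # radius rule leaves far cells empty
  surf2 <- idw_surface(f$pts$lat, f$pts$lon, r$z, radius_km = 5, pad = 0.5)
  expect_true(anyNA(surf2$values))
  # grid writes and re-reads through the ESRI ASCII round trip
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(surf, path)
  back <- read_ascii_grid(path)
  expect_equal(back$values, unname(surf$values), tolerance = 1e-8)
})
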