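test_that("haversine matches closed-form reference distances", {
  expect_equal(haversine_km(10, 76, 10, 76), 0)
  expect_equal(haversine_km(0, 0, 1, 0), 111.195, tolerance = 0.001 / 111)
  # quarter great circle: closed form R * pi / 2 at R = 6371.0088
  expect_equal(haversine_km(0, 0, 0, 90), 6371.0088 * pi / 2,
               tolerance = 0.01 / 1e4)
  # symmetry and cross-check against an independent law-of-cosines route
  set.seed(44)
  a <- data.frame(lat = runif(20, -60, 60), lon = runif(20, -170, 170))
  b <- data.frame(lat = runif(20, -60, 60), lon = runif(20, -170, 170))
  d1 <- haversine_km(a$lat, a$lon, b$lat, b$lon)
  d2 <- haversine_km(b$lat, b$lon, a$lat, a$lon)
  expect_equal(d1, d2)
  expect_equal(d1, oracle_haversine(a$lat, a$lon, b$lat, b$lon),
               tolerance = 1e-6)
  expect_error(haversine_km(95, 0, 0, 0), "latitude")
})

test_that("distance matrix matches elementwise calls and nearest <= treating", {
  hosp <- four_hospitals()
  cases <- make_cases(3, lat = c(10.5, 13.5, 15.9), lon = c(76.2, 79, 78.1),
                      hospital_id = c("H1", "H2", "H1"))
  dm <- distance_matrix(cases, hosp[1:2, ])
  expect_equal(dim(dm$matrix), c(3, 2))
  for (i in 1:3) for (j in 1:2)
    expect_equal(dm$matrix[i, j],
                 haversine_km(cases$lat[i], cases$lon[i],
                              hosp$lat[j], hosp$lon[j]))

  # coincident single case/hospital
  one <- distance_matrix(make_cases(1, lat = 10, lon = 76),
                         four_hospitals()[1, ])
  expect_equal(unname(one$matrix), matrix(0, 1, 1))

  full <- distance_matrix(cases, hosp)
  expect_true(all(full$records$nearest_km <=
                    full$records$distance_km + 1e-12))
  expect_error(distance_matrix(make_cases(1, hospital_id = "H9"), hosp),
               "treating hospital_id")
})

test_that("distance bands use half-open contiguous bins", {
  d <- c(0, 9.999, 10, 47, 49.999, 50, 99.9, 100, 249.99, 250, 1000)
  expect_equal(as.character(assign_bands(d)),
               c("lt10", "lt10", "b10_50", "b10_50", "b10_50", "b50_100",
                 "b50_100", "b100_250", "b100_250", "gt250", "gt250"))
  expect_error(assign_bands(c(1, -2)), "non-negative")
})

test_that("band mass only shifts rightward when distances grow", {
  set.seed(47)
  d <- rexp(500, 1 / 45)
  before <- cumsum(table(assign_bands(d)))
  after <- cumsum(table(assign_bands(d * 1.6)))
  expect_true(all(after <= before))
})

test_that("contiguity classification distinguishes same/adjacent/far", {
  adj <- generate_adjacency(1, 3)   # D1_1 - D1_2 - D1_3
  expect_equal(as.character(contiguity_classify("D1_1", "D1_1", adj)),
               "same_district")
  expect_equal(as.character(contiguity_classify("D1_1", "D1_2", adj)),
               "adjacent_district")
  expect_equal(as.character(contiguity_classify("D1_1", "D1_3", adj)),
               "far_district")
  expect_warning(
    cls <- contiguity_classify("D1_1", "UNKNOWN", adj), "absent")
  expect_equal(as.character(cls), "far_district")
})

test_that("region tables conserve episodes across bands and contiguity", {
  cfg <- sim_config(seed = 77, n_children = 400)
  sim <- generate_cases(cfg)
  dm <- distance_matrix(sim$cases, sim$hospitals)
  rec <- dm$records
  rec$region <- sim$cases$region
  rec$band <- assign_bands(rec$distance_km)
  hosp_d <- sim$hospitals$district_id[
    match(rec$hospital_id, sim$hospitals$hospital_id)]
  rec$contiguity <- suppressWarnings(
    contiguity_classify(sim$cases$district_id, hosp_d, sim$adjacency))
  bt <- band_table(rec)
  ct <- contiguity_table(rec)
  n <- nrow(sim$cases)
  expect_equal(sum(bt$counts), n)
  expect_equal(sum(ct$counts), n)
  expect_equal(unname(bt$pooled_counts), unname(colSums(bt$counts)))
  expect_equal(unname(ct$pooled_counts), unname(colSums(ct$counts)))
  expect_equal(unname(rowSums(bt$counts)), unname(bt$region_total))
})

test_that("row percentages reproduce a printed-table arithmetic example", {
  # a region with contiguity counts (158, 211, 232) prints (26.3, 35.1, 38.6)
  rec <- data.frame(
    region = "East",
    contiguity = factor(rep(c("same_district", "adjacent_district",
                              "far_district"), c(158, 211, 232)),
                        levels = c("same_district", "adjacent_district",
                                   "far_district")))
  ct <- contiguity_table(rec)
  expect_equal(unname(ct$percent["East", ]), c(26.3, 35.1, 38.6))
})

test_that("distance summaries report the expected statistics", {
  s <- summarize_distances(c(10, 20, 30))
  expect_equal(s$mean_km, 20)
  expect_equal(s$min_km, 10)
  expect_equal(s$max_km, 30)
  expect_equal(s$median_km, 20)
  expect_error(summarize_distances(numeric(0)), "no distances")

  # exponential recovery: sigma = 25 km at n = 2000
  cfg <- sim_config(seed = 99, n_children = 2000, decay_scale_km = 25,
                    repeat_episode_fraction = 0, proxy_snap_fraction = 0)
  sim <- generate_cases(cfg)
  dm <- distance_matrix(sim$cases, sim$hospitals)
  s2 <- summarize_distances(dm$records)
  expect_lt(abs(s2$mean_km - 25), 3 * 25 / sqrt(2000))
  p0 <- 100 * (1 - exp(-2))
  ci99 <- 100 * 2.576 * sqrt((1 - exp(-2)) * exp(-2) / 2000)
  expect_lt(abs(s2$pct_lt50 - p0), ci99)
})
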