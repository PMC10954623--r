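# Synthetic surveillance data with distance-decay accrual around sentinel
# hospitals and per-episode ground truth, for calibration and recovery tests.
# The generator emulates the structure of a national sentinel network line
# list: a minority of high-accrual referral sites, residences placed by an
# exponential distance-decay kernel, co-located cases at subdistrict proxy
# points, repeat hospitalization episodes and a boy-skewed sex ratio.

#' Synthetic sentinel hospital network
#'
#' A 23-site synthetic network spread over four regions (North 5 sites,
#' South 8, East 7, West 3, with the public/private mix of a national
#' referral network). Coordinates are invented points inside each region's
#' bounding box — they are deliberately not real facilities. Accrual
#' weights are calibrated so that the top site draws ~37% of cases, the
#' top six ~70%, and regional shares are roughly South 51%, East 26%,
#' North 17%, West 5%.
#'
#' @return Data frame of hospital sites with `accrual_weight`.
#' @export
default_hospitals <- function() {
  df <- data.frame(
    hospital_id = sprintf("H%02d", 1:23),
    region = c(rep("South", 8), rep("East", 7), rep("North", 5),
               rep("West", 3)),
    lat = c( 8.50, 13.08, 11.01, 17.70, 9.93, 12.92, 14.45, 16.50,
            20.46, 26.15, 22.57, 25.60, 23.83, 20.30, 24.80,
            34.08, 26.85, 28.64, 28.46, 26.91,
            22.47, 19.07, 22.72),
    lon = c(76.95, 80.27, 76.96, 83.30, 78.12, 79.13, 78.80, 80.64,
            85.88, 91.77, 88.36, 85.10, 91.28, 85.82, 93.90,
            74.80, 80.95, 77.21, 77.03, 75.79,
            70.07, 72.88, 75.86),
    ownership = c("public", "private", "private", "public", "private",
                  "private", "private", "public",
                  "public", "public", "public", "public", "public",
                  "private", "public",
                  "public", "public", "public", "private", "private",
                  "public", "public", "private"),
    accrual_weight = c(36.9, 6.0, 1.35, 1.35, 1.35, 1.35, 1.35, 1.35,
                       11.8, 4.6, 2.0, 2.0, 2.0, 2.0, 2.0,
                       6.7, 4.0, 6.4 / 3, 6.4 / 3, 6.4 / 3,
                       1.8, 1.8, 1.7),
    stringsAsFactors = FALSE
  )
  df$name <- paste("Synthetic sentinel site", df$hospital_id)
  df$district_id <- paste0("D", df$hospital_id)
  df[, c("hospital_id", "name", "lat", "lon", "district_id", "region",
         "ownership", "accrual_weight")]
}

#' Default district adjacency for the synthetic network
#'
#' Each synthetic hospital district is surrounded by four ring districts
#' (one per bearing quadrant) that the generator uses for residences at
#' intermediate distances; the ring is adjacent to the hospital district.
#'
#' @param hospitals Hospital table (defaults to [default_hospitals()]).
#' @return A `district_adjacency` object.
#' @export
default_adjacency <- function(hospitals = default_hospitals()) {
  a <- rep(hospitals$district_id, each = 4)
  b <- paste0(a, ".A", rep(1:4, nrow(hospitals)))
  adjacency_from_edges(a, b)
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic generator. The
#' defaults describe the study conditions the package is calibrated
#' against: 2221 children with 58 repeat-episode children (2279 episodes
#' in expectation), a 66% male share, a 70%/30% retrospective/prospective
#' split, and an exponential distance-decay scale of 45 km (consistent
#' with two-thirds of families living within 50 km of the treating site
#' and a mean travel distance near 47 km).
#'
#' @param seed Integer seed; the generator is deterministic given it.
#' @param n_children Number of distinct children.
#' @param repeat_episode_fraction Probability a child has a second episode.
#' @param hospitals Hospital table with `accrual_weight` column (omega >= 0,
#'   sum > 0).
#' @param decay_scale_km Exponential scale sigma (km) of the residence
#'   distance from the accruing hospital; must be > 0.
#' @param proxy_snap_fraction Probability a residence is replaced by its
#'   subdistrict centroid proxy (co-locating nearby cases).
#' @param sex_male_prob Probability an episode's child is male.
#' @param retrospective_prob Probability a child was captured by the
#'   retrospective arm.
#' @param same_district_km,adjacent_km Generating-distance thresholds (km)
#'   under which the residence is placed in the hospital's own district or
#'   one of its ring districts.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_children = 2221L,
                       repeat_episode_fraction = 58 / 2221,
                       hospitals = default_hospitals(),
                       decay_scale_km = 45,
                       proxy_snap_fraction = 0.35,
                       sex_male_prob = 0.66,
                       retrospective_prob = 1566 / 2221,
                       same_district_km = 25,
                       adjacent_km = 75) {
  stopifnot(is.data.frame(hospitals))
  need(hospitals, c("hospital_id", "lat", "lon", "district_id", "region",
                    "accrual_weight"), "hospitals")
  if (!is.finite(decay_scale_km) || decay_scale_km <= 0)
    stop("decay_scale_km must be > 0", call. = FALSE)
  w <- hospitals$accrual_weight
  if (any(w < 0) || sum(w) <= 0)
    stop("accrual weights must be >= 0 with positive sum", call. = FALSE)
  for (p in c(repeat_episode_fraction, proxy_snap_fraction, sex_male_prob,
              retrospective_prob))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]", call. = FALSE)
  if (n_children < 1) stop("n_children must be >= 1", call. = FALSE)
  structure(list(seed = as.integer(seed), n_children = as.integer(n_children),
                 repeat_episode_fraction = repeat_episode_fraction,
                 hospitals = hospitals, decay_scale_km = decay_scale_km,
                 proxy_snap_fraction = proxy_snap_fraction,
                 sex_male_prob = sex_male_prob,
                 retrospective_prob = retrospective_prob,
                 same_district_km = same_district_km,
                 adjacent_km = adjacent_km),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_children, " children, ",
      nrow(x$hospitals), " hospitals, sigma = ", x$decay_scale_km,
      " km, seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# Independent substream per stage so adding a stage never perturbs the draws
# of earlier stages. Park-Miller style derivation keeps seeds below 2^31.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 2147480000 + 7919 * stage) %% 2147483647L)
}

# spherical direct geodesic step (same radius as haversine_km)
dest_point <- function(lat, lon, bearing_deg, dist_km) {
  p <- geosphere::destPoint(cbind(lon, lat), bearing_deg, dist_km * 1000,
                            a = EARTH_RADIUS_KM * 1000, f = 0)
  list(lat = p[, 2], lon = p[, 1])
}

#' Generate a synthetic case table with ground truth
#'
#' For each child a hospital is drawn proportional to accrual weight, a
#' generating distance is drawn from an exponential with scale
#' `decay_scale_km`, a bearing uniform on `[0, 360)`, and the residence is
#' placed by a spherical direct geodesic step from the hospital. The
#' treating hospital is the generating hospital. A fraction of residences
#' is snapped to subdistrict centroid proxies (a 0.05-degree lattice),
#' co-locating nearby cases. Repeat-episode children contribute a second
#' episode at the same residence. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `cases` (one row per episode, case-table schema),
#'   `hospitals`, `adjacency`, and `truth` (per-episode generating
#'   hospital, distance and bearing).
#' @export
generate_cases <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  h <- config$hospitals
  n <- config$n_children
  sigma <- config$decay_scale_km

  set.seed(stage_seed(config$seed, 1))
  hosp_idx <- sample.int(nrow(h), n, replace = TRUE,
                         prob = h$accrual_weight / sum(h$accrual_weight))
  set.seed(stage_seed(config$seed, 2))
  dist_km <- stats::rexp(n, rate = 1 / sigma)
  set.seed(stage_seed(config$seed, 3))
  bearing <- stats::runif(n, 0, 360)
  res <- dest_point(h$lat[hosp_idx], h$lon[hosp_idx], bearing, dist_km)
  lat <- res$lat; lon <- res$lon

  # subdistrict proxy snap: move to the centre of a 0.05-degree lattice cell
  set.seed(stage_seed(config$seed, 4))
  proxied <- stats::runif(n) < config$proxy_snap_fraction
  cell <- 0.05
  plat <- (floor(lat / cell) + 0.5) * cell
  plon <- (floor(lon / cell) + 0.5) * cell
  lat[proxied] <- plat[proxied]
  lon[proxied] <- plon[proxied]

  district <- h$district_id[hosp_idx]
  quadrant <- pmin(4L, floor(bearing / 90) + 1L)
  ring <- paste0(district, ".A", quadrant)
  far <- paste0(district, ".F", quadrant)
  district <- ifelse(dist_km < config$same_district_km, district,
                     ifelse(dist_km < config$adjacent_km, ring, far))
  subdistrict <- ifelse(proxied,
                        sprintf("SD_%.2f_%.2f", plat, plon),
                        paste0(district, ".s"))

  # region follows the nearest network hospital, not necessarily the
  # treating one (a long-range referral can cross a region boundary)
  dm <- pairwise_km(lat, lon, h$lat, h$lon)
  region <- h$region[max.col(-dm, ties.method = "first")]

  set.seed(stage_seed(config$seed, 5))
  sex <- ifelse(stats::runif(n) < config$sex_male_prob, "M", "F")
  set.seed(stage_seed(config$seed, 6))
  # three quarters of patients under 12 months
  age <- sample(c(2:11, 12:23), n, replace = TRUE,
                prob = c(rep(0.75 / 10, 10), rep(0.25 / 12, 12)))
  set.seed(stage_seed(config$seed, 7))
  mode <- ifelse(stats::runif(n) < config$retrospective_prob,
                 "retrospective", "prospective")
  set.seed(stage_seed(config$seed, 8))
  repeats <- which(stats::runif(n) < config$repeat_episode_fraction)

  child_id <- sprintf("C%05d", seq_len(n))
  first <- data.frame(
    child_id = child_id, episode_index = 1L, lat = lat, lon = lon,
    district_id = district, subdistrict_id = subdistrict, region = region,
    sex = sex, age_months = age, hospital_id = h$hospital_id[hosp_idx],
    surveillance_mode = mode, coord_is_proxy = proxied,
    gen_hospital = h$hospital_id[hosp_idx], gen_distance_km = dist_km,
    gen_bearing = bearing, stringsAsFactors = FALSE
  )
  second <- first[repeats, , drop = FALSE]
  if (nrow(second)) second$episode_index <- 2L
  all <- rbind(first, second)
  all <- all[order(all$child_id, all$episode_index), , drop = FALSE]
  all$episode_id <- sprintf("E%05d", seq_len(nrow(all)))
  rownames(all) <- NULL

  cases <- all[, c("episode_id", "child_id", "episode_index", "lat", "lon",
                   "district_id", "subdistrict_id", "region", "sex",
                   "age_months", "hospital_id", "surveillance_mode",
                   "coord_is_proxy")]
  truth <- all[, c("episode_id", "child_id", "gen_hospital",
                   "gen_distance_km", "gen_bearing")]
  truth$band <- assign_bands(truth$gen_distance_km)
  list(cases = cases, hospitals = h, adjacency = default_adjacency(h),
       truth = truth)
}

#' Generate complete spatial randomness on a lat/lon rectangle
#'
#' Uniform points on the spherical surface patch bounded by the box
#' (longitude uniform, latitude via the sine transform, which is area-true
#' and indistinguishable from planar-uniform at the box sizes used here).
#'
#' @param n Number of points (`>= 2`).
#' @param bbox Numeric vector `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param seed Integer seed.
#' @return Data frame with `lat`, `lon`.
#' @export
generate_csr <- function(n, bbox, seed = 1L) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || bbox[2] <= bbox[1] || bbox[4] <= bbox[3])
    stop("degenerate bbox: need lat_min < lat_max and lon_min < lon_max",
         call. = FALSE)
  set.seed(as.integer(seed))
  lon <- stats::runif(n, bbox[3], bbox[4])
  s <- stats::runif(n, sin(bbox[1] * pi / 180), sin(bbox[2] * pi / 180))
  lat <- asin(s) * 180 / pi
  data.frame(lat = lat, lon = lon)
}

#' Kilometre-sized bounding box around a centre point
#'
#' Convenience for building CSR study windows: converts a width/height in
#' km at a given centre into a lat/lon rectangle.
#'
#' @param center_lat,center_lon Centre coordinates (decimal degrees).
#' @param width_km,height_km Extents in km (east-west, north-south).
#' @return Numeric `c(lat_min, lat_max, lon_min, lon_max)`.
#' @export
km_bbox <- function(center_lat, center_lon, width_km, height_km) {
  kpd <- EARTH_RADIUS_KM * pi / 180            # km per degree of latitude
  dlat <- height_km / 2 / kpd
  dlon <- width_km / 2 / (kpd * cos(center_lat * pi / 180))
  c(center_lat - dlat, center_lat + dlat,
    center_lon - dlon, center_lon + dlon)
}

#' Rook adjacency on a district lattice
#'
#' Builds the adjacency of an `nrow x ncol` lattice of districts under the
#' rook rule (shared edges only), as a test fixture for contiguity logic.
#'
#' @param nrow,ncol Lattice dimensions.
#' @param prefix District id prefix; ids are `<prefix><row>_<col>`.
#' @return A `district_adjacency` object.
#' @export
generate_adjacency <- function(nrow, ncol, prefix = "D") {
  stopifnot(nrow >= 1, ncol >= 1, nrow * ncol >= 2)
  id <- function(r, c) sprintf("%s%d_%d", prefix, r, c)
  a <- character(); b <- character()
  for (r in seq_len(nrow)) for (c in seq_len(ncol)) {
    if (c < ncol) { a <- c(a, id(r, c)); b <- c(b, id(r, c + 1)) }
    if (r < nrow) { a <- c(a, id(r, c)); b <- c(b, id(r + 1, c)) }
  }
  adjacency_from_edges(a, b)
}
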