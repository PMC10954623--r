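# Patient-to-hospital proximity: great-circle distances, distance bands,
# contiguity classification and the region-level tables built from them.

# Mean Earth radius (IUGG R1), km. All great-circle math in the package uses it.
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' radius). Inputs are recycled to a common length, so the function computes
#' elementwise distances between two vectors of coordinates.
#'
#' @param lat1,lon1 Origin coordinates, decimal degrees (WGS84).
#' @param lat2,lon2 Destination coordinates, decimal degrees.
#' @return Numeric vector of distances in kilometres.
#' @examples
#' haversine_km(0, 0, 1, 0)   # one degree of meridian, ~111.195 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  # clamp guards rounding at antipodes
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

check_coords <- function(lat, lon) {
  if (length(lat) == 0 || length(lon) == 0)
    stop("empty coordinate vector", call. = FALSE)
  if (anyNA(lat) || anyNA(lon))
    stop("coordinates contain NA", call. = FALSE)
  if (any(abs(lat) > 90))
    stop("latitude out of [-90, 90]: ", lat[which(abs(lat) > 90)[1]],
         call. = FALSE)
  if (any(abs(lon) > 180))
    stop("longitude out of [-180, 180]: ", lon[which(abs(lon) > 180)[1]],
         call. = FALSE)
  invisible(TRUE)
}

# Pairwise haversine between two coordinate sets; returns length(a) x
# length(b) matrix. Chunked over rows to bound peak memory.
pairwise_km <- function(lat_a, lon_a, lat_b, lon_b, chunk = 512L) {
  na <- length(lat_a)
  nb <- length(lat_b)
  out <- matrix(0, na, nb)
  for (s in seq(1L, na, by = chunk)) {
    e <- min(s + chunk - 1L, na)
    idx <- s:e
    out[idx, ] <- haversine_km(rep(lat_a[idx], times = nb),
                               rep(lon_a[idx], times = nb),
                               rep(lat_b, each = length(idx)),
                               rep(lon_b, each = length(idx)))
  }
  out
}

#' Episode-by-hospital distance matrix (hub analysis)
#'
#' Computes the full great-circle distance matrix from every episode's
#' residence to every hospital, plus the per-episode distance to the treating
#' hospital and to the nearest hospital (the latter for bypass diagnostics:
#' a case treated far from home may still have had a closer network site).
#'
#' @param cases Data frame with `lat`, `lon`, `hospital_id` and (optionally)
#'   `episode_id` columns, one row per episode.
#' @param hospitals Data frame with `hospital_id`, `lat`, `lon`.
#' @return A list with `matrix` (episodes x hospitals, dimnames set),
#'   and `records`: a data frame with `episode_id`, `hospital_id`,
#'   `distance_km` (treating), `nearest_hospital_id`, `nearest_km`.
#' @export
distance_matrix <- function(cases, hospitals) {
  stopifnot(is.data.frame(cases), is.data.frame(hospitals))
  need(cases, c("lat", "lon", "hospital_id"), "cases")
  need(hospitals, c("hospital_id", "lat", "lon"), "hospitals")
  if (anyDuplicated(hospitals$hospital_id))
    stop("duplicate hospital_id in hospital table", call. = FALSE)
  m <- pairwise_km(cases$lat, cases$lon, hospitals$lat, hospitals$lon)
  eid <- if ("episode_id" %in% names(cases)) as.character(cases$episode_id)
         else sprintf("E%05d", seq_len(nrow(cases)))
  dimnames(m) <- list(eid, as.character(hospitals$hospital_id))
  treat_col <- match(as.character(cases$hospital_id),
                     as.character(hospitals$hospital_id))
  if (anyNA(treat_col))
    stop("treating hospital_id absent from hospital table: ",
         cases$hospital_id[which(is.na(treat_col))[1]], call. = FALSE)
  near_col <- max.col(-m, ties.method = "first")
  rec <- data.frame(
    episode_id = eid,
    hospital_id = as.character(cases$hospital_id),
    distance_km = m[cbind(seq_len(nrow(m)), treat_col)],
    nearest_hospital_id = as.character(hospitals$hospital_id)[near_col],
    nearest_km = m[cbind(seq_len(nrow(m)), near_col)],
    stringsAsFactors = FALSE
  )
  list(matrix = m, records = rec)
}

need <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

BAND_LEVELS <- c("lt10", "b10_50", "b50_100", "b100_250", "gt250")
BAND_LABELS <- c("<10 km", "10-50 km", "50-100 km", "100-250 km", ">250 km")
CONTIG_LEVELS <- c("same_district", "adjacent_district", "far_district")

#' Assign distance bands
#'
#' Bins distances into the five catchment bands used for regional reporting.
#' The bins are half-open and contiguous — `[0,10)`, `[10,50)`, `[50,100)`,
#' `[100,250)`, `[250,Inf)` — so every non-negative distance is classified.
#'
#' @param distance_km Numeric vector of distances (km), `>= 0`.
#' @return Factor with levels `lt10`, `b10_50`, `b50_100`, `b100_250`,
#'   `gt250`.
#' @export
assign_bands <- function(distance_km) {
  if (anyNA(distance_km) || any(distance_km < 0))
    stop("distances must be non-negative and non-missing", call. = FALSE)
  cut(distance_km, breaks = c(0, 10, 50, 100, 250, Inf),
      labels = BAND_LEVELS, right = FALSE, include.lowest = TRUE)
}

#' Classify residence-to-hospital district contiguity
#'
#' Labels each episode by whether the residence district equals the treating
#' hospital's district, is adjacent to it, or neither. Districts missing from
#' the adjacency table are classified `far_district` with a warning.
#'
#' @param case_district,hospital_district Character vectors (recycled).
#' @param adjacency A `district_adjacency` object from [read_adjacency()] or
#'   [generate_adjacency()].
#' @return Factor with levels `same_district`, `adjacent_district`,
#'   `far_district`.
#' @export
contiguity_classify <- function(case_district, hospital_district, adjacency) {
  stopifnot(inherits(adjacency, "district_adjacency"))
  n <- max(length(case_district), length(hospital_district))
  cd <- rep_len(as.character(case_district), n)
  hd <- rep_len(as.character(hospital_district), n)
  out <- rep("far_district", n)
  out[cd == hd] <- "same_district"
  unknown <- !(hd %in% names(adjacency$adj)) & cd != hd
  adj_hit <- mapply(function(a, b) {
    !is.na(b) && b %in% names(adjacency$adj) && a %in% adjacency$adj[[b]]
  }, cd, hd)
  out[adj_hit & out == "far_district"] <- "adjacent_district"
  if (any(unknown))
    warning(sum(unknown), " episode(s) with hospital district absent from ",
            "adjacency table; classified far_district", call. = FALSE)
  factor(out, levels = CONTIG_LEVELS)
}

region_levels <- function() c("East", "North", "South", "West")

# shared builder for the two region x category tables
region_category_table <- function(region, category, levels, pooled_digits = 2,
                                  region_digits = 1) {
  region <- factor(as.character(region), levels = region_levels())
  if (anyNA(region))
    stop("unknown region label; expected one of ",
         paste(region_levels(), collapse = ", "), call. = FALSE)
  counts <- table(region = region, category = factor(category, levels = levels))
  counts <- unclass(counts)
  totals <- rowSums(counts)
  pct <- counts / ifelse(totals > 0, totals, NA_real_) * 100
  pct <- round(pct, region_digits)
  pooled <- colSums(counts)
  pooled_pct <- round(pooled / sum(pooled) * 100, pooled_digits)
  list(counts = counts, percent = pct, region_total = totals,
       pooled_counts = pooled, pooled_percent = pooled_pct,
       n_episodes = sum(pooled))
}

#' Region-by-distance-band episode table
#'
#' Tabulates episodes by region and distance band, with row percentages to
#' one decimal per region and pooled percentages to two decimals, mirroring
#' the layout of regional surveillance reporting tables.
#'
#' @param records Data frame with `region` and either a `band` factor from
#'   [assign_bands()] or a `distance_km` column (banded on the fly).
#' @return An object of class `band_table`: counts, percentages, region
#'   totals and the pooled row.
#' @export
band_table <- function(records) {
  need(records, "region", "records")
  band <- if ("band" %in% names(records)) records$band
          else assign_bands(records$distance_km)
  out <- region_category_table(records$region, band, BAND_LEVELS)
  colnames(out$counts) <- colnames(out$percent) <- BAND_LABELS
  names(out$pooled_counts) <- names(out$pooled_percent) <- BAND_LABELS
  structure(out, class = "band_table")
}

#' Region-by-contiguity episode table
#'
#' Same layout as [band_table()] but over the three contiguity classes
#' (same / adjacent / far district relative to the treating hospital).
#'
#' @param records Data frame with `region` and `contiguity` columns
#'   (`contiguity` as produced by [contiguity_classify()]).
#' @return An object of class `contiguity_table`.
#' @export
contiguity_table <- function(records) {
  need(records, c("region", "contiguity"), "records")
  out <- region_category_table(records$region, records$contiguity,
                               CONTIG_LEVELS)
  structure(out, class = "contiguity_table")
}

#' @export
print.band_table <- function(x, ...) {
  cat("Episodes by region and distance band (n =", x$n_episodes, ")\n")
  print(cbind(x$counts, total = x$region_total))
  cat("Row percentages:\n"); print(x$percent)
  cat("Pooled:", paste(sprintf("%s %d (%.2f%%)", names(x$pooled_counts),
                               x$pooled_counts, x$pooled_percent),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.contiguity_table <- function(x, ...) {
  cat("Episodes by region and treating-hospital contiguity (n =",
      x$n_episodes, ")\n")
  print(cbind(x$counts, total = x$region_total))
  cat("Row percentages:\n"); print(x$percent)
  cat("Pooled %:", paste(sprintf("%.2f", x$pooled_percent), collapse = " / "),
      "\n")
  invisible(x)
}

#' Summary statistics of treating-hospital distances
#'
#' Episode-level summary of the residence-to-treating-hospital distance:
#' mean, median, spread, and the shares of episodes within 50 km and 100 km
#' (reported as percentages of all episodes).
#'
#' @param records Data frame with a `distance_km` column (e.g. the `records`
#'   element of [distance_matrix()]), or a bare numeric vector.
#' @return Named list: `n`, `mean_km`, `sd_km`, `min_km`, `q25_km`,
#'   `median_km`, `q75_km`, `max_km`, `pct_lt50`, `pct_lt100`.
#' @export
summarize_distances <- function(records) {
  d <- if (is.data.frame(records)) records$distance_km else records
  if (is.null(d) || length(d) == 0)
    stop("no distances to summarize", call. = FALSE)
  if (anyNA(d) || any(d < 0))
    stop("distances must be non-negative and non-missing", call. = FALSE)
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(d), mean_km = mean(d), sd_km = stats::sd(d),
       min_km = min(d), q25_km = q[1], median_km = q[2], q75_km = q[3],
       max_km = max(d),
       pct_lt50 = 100 * mean(d < 50), pct_lt100 = 100 * mean(d < 100))
}
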