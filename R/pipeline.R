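# Pipeline wiring: simulate -> analyze -> report, with provenance metadata.
# These functions are the programmatic entry points; inst/exec/geoepi is a
# thin Rscript wrapper over them.

# polynomial rolling hash of a deparsed object, for provenance fingerprints
config_hash <- function(obj) {
  s <- paste(deparse(obj), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_provenance <- function(path, seed, config, version =
                               as.character(utils::packageVersion("geoepi"))) {
  jsonlite::write_json(
    list(package = "geoepi", version = version, seed = seed,
         config_hash = config_hash(config)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Analysis parameter bundle
#'
#' Collects every tunable of the analysis stage with its default: snap
#' radius 5 km; candidate cutoffs for the connectivity scan; inverse-
#' distance power 1 for the spatial weights; NNI area method; permutation
#' settings for Moran's I; Gi* FDR flag; IDW power/neighborhood/grid.
#'
#' @param snap_radius_km Collision-snap radius (km).
#' @param candidate_radii_km Candidate cutoffs scanned by
#'   [iterative_distance_scan()]; the chosen cutoff builds the weights.
#' @param weight_power Inverse-distance exponent for the weights.
#' @param area_method NNI study-area convention.
#' @param n_perm,seed Moran permutation settings.
#' @param fdr Apply Benjamini-Hochberg in hotspot classification.
#' @param idw_power,idw_k,grid_ncols IDW surface settings.
#' @return Named list of class `analysis_params`.
#' @export
analysis_params <- function(snap_radius_km = 5,
                            candidate_radii_km = c(25, 50, 75, 100, 150),
                            weight_power = 1,
                            area_method = "bounding_rectangle",
                            n_perm = 199, seed = 1L, fdr = FALSE,
                            idw_power = 2, idw_k = 12, grid_ncols = 100) {
  structure(list(snap_radius_km = snap_radius_km,
                 candidate_radii_km = candidate_radii_km,
                 weight_power = weight_power, area_method = area_method,
                 n_perm = n_perm, seed = as.integer(seed), fdr = fdr,
                 idw_power = idw_power, idw_k = idw_k,
                 grid_ncols = grid_ncols),
            class = "analysis_params")
}

#' Simulate a dataset to disk
#'
#' Runs [generate_cases()] and writes `cases.csv`, `hospitals.csv`,
#' `adjacency.csv`, `truth.csv` and a `provenance.json` (seed + config
#' fingerprint) into `out_dir`. Deterministic given the config seed:
#' rerunning produces byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_cases(config)
  paths <- file.path(out_dir, c("cases.csv", "hospitals.csv",
                                "adjacency.csv", "truth.csv",
                                "provenance.json"))
  utils::write.csv(sim$cases, paths[1], row.names = FALSE)
  utils::write.csv(sim$hospitals, paths[2], row.names = FALSE)
  adj <- sim$adjacency$adj
  edges <- data.frame(
    district_a = rep(names(adj), lengths(adj)),
    district_b = unlist(adj, use.names = FALSE))
  edges <- edges[edges$district_a < edges$district_b, ]
  utils::write.csv(edges, paths[3], row.names = FALSE)
  utils::write.csv(sim$truth, paths[4], row.names = FALSE)
  write_provenance(paths[5], config$seed, unclass(config))
  invisible(paths)
}

#' Run the full spatial analysis
#'
#' Wires the whole method chain over in-memory inputs: collision snapping,
#' connectivity scan for the weight cutoff, NNI on episode points, global
#' Moran's I (analytical + permutation) on snapped counts, Gi* with
#' self-inclusive weights plus confidence classification and admin tally,
#' IDW interpolation of the Gi* z-scores, and the proximity stage
#' (distance records, band table, contiguity table, distance summary).
#'
#' @param cases Validated case table (e.g. `cases` from [read_cases()] or
#'   [generate_cases()]).
#' @param hospitals Hospital table.
#' @param adjacency `district_adjacency` object.
#' @param params An [analysis_params()] bundle.
#' @return List of class `geoepi_analysis` with elements `snapped`,
#'   `scan`, `weights`, `nni`, `moran`, `gistar`, `hot_by_district`,
#'   `surface`, `distances`, `band_table`, `contiguity_table`,
#'   `distance_summary`, `params`.
#' @export
run_analyze <- function(cases, hospitals, adjacency,
                        params = analysis_params()) {
  need(cases, c("episode_id", "lat", "lon", "region", "district_id",
                "hospital_id"), "cases")
  if (nrow(cases) < 8)
    stop("need at least 8 episodes for the analysis chain", call. = FALSE)
  snapped <- snap_collisions(cases$lat, cases$lon,
                             radius_km = params$snap_radius_km,
                             ids = cases$episode_id)
  scan <- iterative_distance_scan(snapped, params$candidate_radii_km)
  W <- inverse_distance_weights(snapped, cutoff_km = scan$radius_km,
                                power = params$weight_power,
                                include_self = FALSE)
  Wstar <- inverse_distance_weights(snapped, cutoff_km = scan$radius_km,
                                    power = params$weight_power,
                                    include_self = TRUE)
  nni <- nearest_neighbor_index(cases$lat, cases$lon,
                                area_method = params$area_method)
  moran <- morans_i_permutation(snapped$count, W, n_perm = params$n_perm,
                                seed = params$seed)
  gi <- classify_hotspots(getis_ord_gistar(snapped, Wstar),
                          fdr = params$fdr)
  # a location inherits the admin ids of its founding episode
  founder <- vapply(snapped$provenance, function(v) v[1], cases$episode_id[1])
  loc_district <- cases$district_id[match(founder, cases$episode_id)]
  loc_region <- cases$region[match(founder, cases$episode_id)]
  hot_tally <- hotspots_by_admin(gi, loc_district)
  surface <- idw_surface(snapped$lat, snapped$lon, gi$z,
                         power = params$idw_power, k = params$idw_k,
                         ncols = params$grid_ncols)
  dm <- distance_matrix(cases, hospitals)
  rec <- dm$records
  rec$region <- cases$region
  rec$band <- assign_bands(rec$distance_km)
  hosp_district <- hospitals$district_id[
    match(rec$hospital_id, hospitals$hospital_id)]
  rec$contiguity <- contiguity_classify(
    cases$district_id, hosp_district, adjacency)
  structure(list(snapped = snapped, scan = scan, weights = W,
                 nni = nni, moran = moran, gistar = gi,
                 loc_region = loc_region, loc_district = loc_district,
                 hot_by_district = hot_tally, surface = surface,
                 distances = rec,
                 band_table = band_table(rec),
                 contiguity_table = contiguity_table(rec),
                 distance_summary = summarize_distances(rec),
                 params = params),
            class = "geoepi_analysis")
}

#' @export
print.geoepi_analysis <- function(x, ...) {
  cat("geoepi analysis of", x$snapped$n_episodes, "episodes /",
      length(x$snapped$lat), "snapped locations\n")
  print(x$nni); print(x$moran)
  cat("Gi* classes:\n"); print(table(x$gistar$class))
  cat(sprintf("Mean treating-hospital distance %.1f km; %.1f%% < 50 km\n",
              x$distance_summary$mean_km, x$distance_summary$pct_lt50))
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' Serializes a [run_analyze()] result: `results.json` (NNI, Moran, Gi*
#' class counts, distance summary, chosen cutoff), `gistar.geojson`
#' (classified locations), `idw.asc` (ESRI ASCII grid of the IDW surface),
#' `band_table.csv`, `contiguity_table.csv`, `distances.csv` and
#' `provenance.json`.
#'
#' @param analysis A `geoepi_analysis`.
#' @param out_dir Output directory.
#' @return Invisibly, the vector of written paths.
#' @export
write_analysis <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "geoepi_analysis"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  a <- analysis
  res <- list(
    n_episodes = a$snapped$n_episodes,
    n_locations = length(a$snapped$lat),
    cutoff_km = a$scan$radius_km,
    nni = unclass(a$nni),
    moran = unclass(a$moran)[c("I", "expectation",
                               "variance_randomization",
                               "variance_normality", "z", "p",
                               "p_permutation", "n_perm", "seed")],
    gistar_classes = as.list(table(a$gistar$class)),
    hot_by_district = as.list(a$hot_by_district),
    distance_summary = a$distance_summary,
    idw_range = range(a$surface$values, na.rm = TRUE)
  )
  paths <- file.path(out_dir, c("results.json", "gistar.geojson", "idw.asc",
                                "band_table.csv", "contiguity_table.csv",
                                "distances.csv", "provenance.json"))
  jsonlite::write_json(res, paths[1], auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  gj <- data.frame(lat = a$gistar$lat, lon = a$gistar$lon,
                   count = a$gistar$x, z = round(a$gistar$z, 6),
                   p = signif(a$gistar$p, 6),
                   class = as.character(a$gistar$class))
  write_geojson(gj, paths[2])
  write_ascii_grid(a$surface, paths[3])
  table_frame <- function(tab) {
    counts <- as.data.frame(tab$counts)
    pct <- as.data.frame(tab$percent)
    names(pct) <- paste0(names(pct), "_pct")
    cbind(region = rownames(tab$counts), counts, pct,
          total = tab$region_total)
  }
  utils::write.csv(table_frame(a$band_table), paths[4], row.names = FALSE)
  utils::write.csv(table_frame(a$contiguity_table), paths[5],
                   row.names = FALSE)
  utils::write.csv(a$distances, paths[6], row.names = FALSE)
  write_provenance(paths[7], a$params$seed, unclass(a$params))
  invisible(paths)
}

#' Analyze a simulated dataset directory
#'
#' Convenience wrapper reading `cases.csv` / `hospitals.csv` /
#' `adjacency.csv` as written by [run_simulate()], running [run_analyze()]
#' and writing the bundle with [write_analysis()]. Fails fast, naming the
#' missing file, if the simulate stage is incomplete.
#'
#' @param in_dir Directory with the dataset files.
#' @param out_dir Output directory for the results bundle.
#' @param params An [analysis_params()].
#' @return The `geoepi_analysis`, invisibly.
#' @export
run_analyze_dir <- function(in_dir, out_dir, params = analysis_params()) {
  files <- file.path(in_dir, c("cases.csv", "hospitals.csv",
                               "adjacency.csv"))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("missing input artifact(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hospitals <- read_hospitals(files[2])
  cc <- read_cases(files[1], hospitals = hospitals,
                   reject_path = file.path(out_dir, "rejections.csv"))
  adjacency <- read_adjacency(files[3])
  analysis <- run_analyze(cc$cases, hospitals, adjacency, params)
  write_analysis(analysis, out_dir)
  invisible(analysis)
}

#' Render a human-readable report from a results bundle
#'
#' Reads `results.json`, `band_table.csv` and `contiguity_table.csv` from
#' an analysis directory and writes `report.md` summarizing the clustering
#' statistics, hotspot tallies and the two region-level tables.
#'
#' @param results_dir Directory written by [write_analysis()].
#' @param out_path Output markdown path (default `report.md` inside
#'   `results_dir`).
#' @return Invisibly, `out_path`.
#' @export
run_report <- function(results_dir,
                       out_path = file.path(results_dir, "report.md")) {
  rj <- file.path(results_dir, "results.json")
  if (!file.exists(rj))
    stop("missing input artifact: ", rj, call. = FALSE)
  res <- jsonlite::read_json(rj, simplifyVector = TRUE)
  md_table <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      vapply(seq_len(nrow(df)), function(i)
        paste0("| ", paste(unlist(df[i, ]), collapse = " | "), " |"), ""))
  }
  lines <- c(
    "# Spatial analysis report", "",
    sprintf("- Episodes: %d at %d snapped locations (cutoff %s km)",
            res$n_episodes, res$n_locations, res$cutoff_km),
    sprintf("- NNI = %.3f (z = %.2f, p = %.3g, area %.1f km2, %s)",
            res$nni$nni, res$nni$z, res$nni$p, res$nni$area_km2,
            res$nni$area_method),
    sprintf("- Moran's I = %.4f (z = %.2f, analytical p = %.3g, permutation p = %.3g)",
            res$moran$I, res$moran$z, res$moran$p, res$moran$p_permutation),
    sprintf("- Gi* hot95+ locations: %d",
            sum(unlist(res$gistar_classes[c("hot95", "hot99")]))),
    sprintf("- Mean treating-hospital distance %.1f km (min %.1f, max %.1f); %.1f%% < 50 km, %.1f%% < 100 km",
            res$distance_summary$mean_km, res$distance_summary$min_km,
            res$distance_summary$max_km, res$distance_summary$pct_lt50,
            res$distance_summary$pct_lt100),
    sprintf("- IDW surface range [%.2f, %.2f]",
            res$idw_range[1], res$idw_range[2]),
    "", "## Episodes by region and distance band", "",
    md_table(file.path(results_dir, "band_table.csv")),
    "", "## Episodes by region and treating-hospital contiguity", "",
    md_table(file.path(results_dir, "contiguity_table.csv")))
  writeLines(lines, out_path)
  invisible(out_path)
}
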