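# Readers/writers and coordinate plumbing: DMS parsing, validated case /
# hospital / adjacency tables, GeoJSON points and ESRI ASCII grids.
# Coordinates are held internally as decimal degrees (WGS84 assumed); DMS
# exists only at the I/O boundary.

DMS_RE <- paste0("^\\s*([0-9]+(?:\\.[0-9]+)?)\\s*[°dD:]\\s*",
                 "([0-9]+(?:\\.[0-9]+)?)\\s*['mM:]\\s*",
                 "([0-9]+(?:\\.[0-9]+)?)\\s*(?:\"|''|s|S)?\\s*([NSEWnsew])\\s*$")
DEC_RE <- "^\\s*[+-]?[0-9]+(\\.[0-9]+)?\\s*$"

#' Parse degree-minute-second coordinate strings
#'
#' Converts coordinates recorded as `D°M'S"H` (hemisphere letter N/S/E/W)
#' into signed decimal degrees. Signed decimal strings pass through
#' unchanged, so a column of mixed provenance parses uniformly.
#'
#' @param text Character vector of DMS or decimal coordinate strings.
#' @return Numeric vector of decimal degrees (negative for S/W).
#' @examples
#' parse_dms("30°30'0\"N")    # 30.5
#' parse_dms("76°15'36\"W")   # -76.26
#' @export
parse_dms <- function(text) {
  text <- as.character(text)
  out <- rep(NA_real_, length(text))
  dec <- grepl(DEC_RE, text)
  out[dec] <- as.numeric(text[dec])
  dms <- !dec & grepl(DMS_RE, text)
  if (any(dms)) {
    m <- regmatches(text[dms], regexec(DMS_RE, text[dms]))
    deg <- vapply(m, function(g) as.numeric(g[2]), 0)
    mins <- vapply(m, function(g) as.numeric(g[3]), 0)
    secs <- vapply(m, function(g) as.numeric(g[4]), 0)
    hemi <- toupper(vapply(m, function(g) g[5], ""))
    bad <- mins >= 60 | secs >= 60
    if (any(bad))
      stop("minutes/seconds >= 60 in DMS coordinate: ",
           dQuote(text[dms][which(bad)[1]]), call. = FALSE)
    val <- deg + mins / 60 + secs / 3600
    val[hemi %in% c("S", "W")] <- -val[hemi %in% c("S", "W")]
    out[dms] <- val
  }
  malformed <- !dec & !dms
  if (any(malformed))
    stop("malformed coordinate string: ", dQuote(text[which(malformed)[1]]),
         call. = FALSE)
  if (any(abs(out) > 180))
    stop("coordinate out of range [-180, 180]: ",
         dQuote(text[which(abs(out) > 180)[1]]), call. = FALSE)
  out
}

#' Format decimal degrees as DMS strings
#'
#' Inverse of [parse_dms()] to within 1e-9 degrees; `axis` selects the
#' hemisphere letters (N/S for latitude, E/W for longitude).
#'
#' @param x Numeric decimal degrees.
#' @param axis `"lat"` or `"lon"`.
#' @return Character vector `D°M'S"H` with fractional seconds.
#' @export
format_dms <- function(x, axis = c("lat", "lon")) {
  axis <- match.arg(axis)
  hemi <- if (axis == "lat") c("N", "S") else c("E", "W")
  h <- ifelse(x < 0, hemi[2], hemi[1])
  ax <- abs(x)
  deg <- floor(ax)
  mins <- floor((ax - deg) * 60)
  secs <- (ax - deg - mins / 60) * 3600
  # roll over rounding at the top of a minute
  secs <- round(secs, 7)
  carry <- secs >= 60
  secs[carry] <- 0; mins[carry] <- mins[carry] + 1
  carry <- mins >= 60
  mins[carry] <- 0; deg[carry] <- deg[carry] + 1
  sprintf("%d°%d'%.7f\"%s", deg, mins, secs, h)
}

read_delim_auto <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    quote = "\"", comment.char = "")
}

# parse a coordinate column that may be decimal or DMS (detected per column)
parse_coord_column <- function(v) {
  v <- trimws(as.character(v))
  parsed <- rep(NA_real_, length(v))
  ok <- rep(TRUE, length(v))
  reason <- rep(NA_character_, length(v))
  nonblank <- !is.na(v) & nzchar(v)
  for (i in which(nonblank)) {
    p <- tryCatch(parse_dms(v[i]), error = function(e) e)
    if (inherits(p, "error")) {
      ok[i] <- FALSE; reason[i] <- conditionMessage(p)
    } else parsed[i] <- p
  }
  list(value = parsed, ok = ok, reason = reason, blank = !nonblank)
}

CASE_COLS <- c("episode_id", "child_id", "lat", "lon", "district_id",
               "subdistrict_id", "region", "sex", "age_months",
               "hospital_id", "surveillance_mode")

#' Read and validate a case table
#'
#' Reads a delimited line list (one row per hospitalization episode),
#' parses coordinates (decimal or DMS, auto-detected per value), and
#' validates every record: coordinate ranges, age 2-23 months, known
#' region/sex/surveillance labels and, when a hospital table is supplied,
#' that the treating `hospital_id` resolves. Rows that fail are collected
#' into a rejection report — never silently dropped — so accepted plus
#' rejected always equals the input row count.
#'
#' Rows with missing residence coordinates are accepted only when proxy
#' coordinates (`proxy_lat`/`proxy_lon`, e.g. subdistrict centroids) are
#' present alongside a `subdistrict_id`; such rows get `coord_is_proxy =
#' TRUE`.
#'
#' @param path Path to a UTF-8 CSV/TSV file with a header.
#' @param hospitals Optional hospital table from [read_hospitals()] used to
#'   check `hospital_id` references.
#' @param sep Field separator; default auto-detects comma vs tab.
#' @param reject_path Optional path; when given, the rejection report is
#'   also written there as CSV (machine-readable audit sidecar).
#' @return List with `cases` (validated data frame, coords numeric,
#'   `age_months` integer, `coord_is_proxy` logical) and `rejections`
#'   (data frame `row`, `episode_id`, `reason`).
#' @export
read_cases <- function(path, hospitals = NULL, sep = NULL,
                       reject_path = NULL) {
  raw <- read_delim_auto(path, sep)
  miss <- setdiff(CASE_COLS, names(raw))
  if (length(miss))
    stop("case table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(raw)
  if (n == 0) {
    empty <- data.frame(row = integer(), episode_id = character(),
                        reason = character())
    return(list(cases = empty_case_frame(), rejections = empty))
  }
  latp <- parse_coord_column(raw$lat)
  lonp <- parse_coord_column(raw$lon)
  has_proxy <- all(c("proxy_lat", "proxy_lon") %in% names(raw))
  if (has_proxy) {
    plat <- parse_coord_column(raw$proxy_lat)
    plon <- parse_coord_column(raw$proxy_lon)
  }
  lat <- latp$value; lon <- lonp$value
  proxy_used <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  flag <- function(cond, msg) {
    hit <- which(cond & is.na(reason))
    reason[hit] <<- msg
  }
  # proxy substitution for blank coordinates with a usable subdistrict proxy
  blank <- latp$blank | lonp$blank
  if (has_proxy) {
    usable <- blank & !plat$blank & !plon$blank & plat$ok & plon$ok &
      nzchar(trimws(raw$subdistrict_id))
    lat[usable] <- plat$value[usable]
    lon[usable] <- plon$value[usable]
    proxy_used[usable] <- TRUE
    blank <- blank & !usable
  }
  flag(blank, "missing coordinates without usable subdistrict proxy")
  flag(!latp$blank & !latp$ok, "unparseable latitude")
  flag(!lonp$blank & !lonp$ok, "unparseable longitude")
  flag(!is.na(lat) & abs(lat) > 90, "latitude out of [-90, 90]")
  flag(!is.na(lon) & abs(lon) > 180, "longitude out of [-180, 180]")
  age <- suppressWarnings(as.integer(raw$age_months))
  flag(is.na(age) | age < 2 | age > 23, "age_months outside 2-23")
  flag(!(raw$region %in% region_levels()), "unknown region")
  flag(!(raw$sex %in% c("M", "F", "unknown")), "unknown sex code")
  flag(!(raw$surveillance_mode %in% c("retrospective", "prospective")),
       "unknown surveillance_mode")
  if (!is.null(hospitals))
    flag(!(raw$hospital_id %in% hospitals$hospital_id),
         "hospital_id not in hospital table")
  key <- paste(raw$child_id, raw$episode_id)
  flag(duplicated(key), "duplicate (child_id, episode_id)")
  keep <- is.na(reason)
  cases <- data.frame(
    episode_id = raw$episode_id[keep], child_id = raw$child_id[keep],
    lat = lat[keep], lon = lon[keep],
    district_id = raw$district_id[keep],
    subdistrict_id = raw$subdistrict_id[keep],
    region = raw$region[keep], sex = raw$sex[keep],
    age_months = age[keep], hospital_id = raw$hospital_id[keep],
    surveillance_mode = raw$surveillance_mode[keep],
    coord_is_proxy = proxy_used[keep] |
      (if ("coord_is_proxy" %in% names(raw))
         tolower(raw$coord_is_proxy[keep]) %in% c("true", "1", "t") else FALSE),
    stringsAsFactors = FALSE
  )
  rejections <- data.frame(row = which(!keep),
                           episode_id = raw$episode_id[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)
  if (!is.null(reject_path))
    utils::write.csv(rejections, reject_path, row.names = FALSE)
  list(cases = cases, rejections = rejections)
}

empty_case_frame <- function() {
  data.frame(episode_id = character(), child_id = character(),
             lat = numeric(), lon = numeric(), district_id = character(),
             subdistrict_id = character(), region = character(),
             sex = character(), age_months = integer(),
             hospital_id = character(), surveillance_mode = character(),
             coord_is_proxy = logical(), stringsAsFactors = FALSE)
}

#' Read a hospital site table
#'
#' @param path CSV/TSV with columns `hospital_id`, `name`, `lat`, `lon`,
#'   `district_id`, `region`, `ownership` (and optionally `accrual_weight`).
#' @param sep Field separator; auto-detected by default.
#' @return Data frame of validated hospital sites.
#' @export
read_hospitals <- function(path, sep = NULL) {
  raw <- read_delim_auto(path, sep)
  need(raw, c("hospital_id", "name", "lat", "lon", "district_id", "region",
              "ownership"), "hospital")
  if (anyDuplicated(raw$hospital_id))
    stop("duplicate hospital_id: ",
         raw$hospital_id[anyDuplicated(raw$hospital_id)], call. = FALSE)
  bad_own <- !(raw$ownership %in% c("public", "private"))
  if (any(bad_own))
    stop("unknown ownership value: ", dQuote(raw$ownership[which(bad_own)[1]]),
         call. = FALSE)
  bad_reg <- !(raw$region %in% region_levels())
  if (any(bad_reg))
    stop("unknown region value: ", dQuote(raw$region[which(bad_reg)[1]]),
         call. = FALSE)
  lat <- parse_dms(raw$lat); lon <- parse_dms(raw$lon)
  check_coords(lat, lon)
  out <- data.frame(hospital_id = raw$hospital_id, name = raw$name,
                    lat = lat, lon = lon, district_id = raw$district_id,
                    region = raw$region, ownership = raw$ownership,
                    stringsAsFactors = FALSE)
  if ("accrual_weight" %in% names(raw))
    out$accrual_weight <- as.numeric(raw$accrual_weight)
  out
}

#' Read a district adjacency edge list
#'
#' Reads an edge list (`district_a`, `district_b`) and closes it under
#' symmetry: if only `a -> b` is listed, `b -> a` is added (with a warning
#' that the input was asymmetric). Self-adjacency rows are dropped.
#'
#' @param path CSV/TSV edge list with a header.
#' @param sep Field separator; auto-detected by default.
#' @return A `district_adjacency` object: list with `adj`, a named list
#'   mapping each district to its character vector of neighbors.
#' @export
read_adjacency <- function(path, sep = NULL) {
  raw <- read_delim_auto(path, sep)
  if (ncol(raw) < 2)
    stop("adjacency table needs two columns (district_a, district_b)",
         call. = FALSE)
  a <- as.character(raw[[1]]); b <- as.character(raw[[2]])
  self <- a == b
  a <- a[!self]; b <- b[!self]
  fwd <- paste(a, b, sep = "\r")
  rev <- paste(b, a, sep = "\r")
  if (!all(rev %in% fwd))
    warning("adjacency input was asymmetric; closed under symmetry",
            call. = FALSE)
  adjacency_from_edges(a, b)
}

adjacency_from_edges <- function(a, b) {
  all_a <- c(a, b); all_b <- c(b, a)
  adj <- split(all_b, all_a)
  adj <- lapply(adj, function(v) sort(unique(v)))
  structure(list(adj = adj), class = "district_adjacency")
}

#' @export
print.district_adjacency <- function(x, ...) {
  deg <- lengths(x$adj)
  cat("District adjacency:", length(x$adj), "districts,",
      sum(deg) / 2, "undirected edges\n")
  invisible(x)
}

#' Write points as a GeoJSON FeatureCollection
#'
#' Emits RFC 7946 GeoJSON: point coordinates in `[longitude, latitude]`
#' order, one feature per row, with any extra columns as properties.
#'
#' @param df Data frame with `lat` and `lon` columns; all other columns
#'   become feature properties.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_geojson <- function(df, path) {
  need(df, c("lat", "lon"), "feature")
  check_coords(df$lat, df$lon)
  props <- df[setdiff(names(df), c("lat", "lon"))]
  features <- lapply(seq_len(nrow(df)), function(i) {
    p <- if (ncol(props)) lapply(props[i, , drop = FALSE], function(v) {
      v <- v[[1]]
      if (is.factor(v)) as.character(v) else v
    }) else stats::setNames(list(), character())
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$lon[i], df$lat[i])),
         properties = p)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Write / read an ESRI ASCII grid
#'
#' `write_ascii_grid()` serializes an [idw_surface()] result (or any object
#' with `values`, `xllcorner`, `yllcorner`, `cellsize`, `nodata`) in ESRI
#' ASCII raster format: a six-line header then rows north to south.
#' `read_ascii_grid()` parses the format back; the pair round-trips values
#' to within 1e-9.
#'
#' @param surface Surface object (see [idw_surface()]); `values` is a matrix
#'   whose first row is the northernmost.
#' @param path File path.
#' @return `write_ascii_grid()`: the path, invisibly. `read_ascii_grid()`:
#'   a list with the header fields and the `values` matrix (NODATA as `NA`).
#' @export
write_ascii_grid <- function(surface, path) {
  v <- surface$values
  stopifnot(is.matrix(v))
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10f", surface$xllcorner),
           sprintf("yllcorner %.10f", surface$yllcorner),
           sprintf("cellsize %.12f", surface$cellsize),
           sprintf("NODATA_value %s", format(surface$nodata)))
  v[is.na(v)] <- surface$nodata
  rows <- apply(v, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  ncols <- as.integer(vals[["ncols"]]); nrows <- as.integer(vals[["nrows"]])
  body <- lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, body)
  stopifnot(nrow(m) == nrows, ncol(m) == ncols)
  nodata <- vals[["nodata_value"]]
  m[m == nodata] <- NA
  list(values = m, xllcorner = vals[["xllcorner"]],
       yllcorner = vals[["yllcorner"]], cellsize = vals[["cellsize"]],
       nodata = nodata, ncols = ncols, nrows = nrows)
}
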