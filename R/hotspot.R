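# Local hotspot detection (Getis-Ord Gi*), confidence-bin classification,
# admin-level tallies, and IDW interpolation of the z-scores onto a grid.

GISTAR_CLASSES <- c("cold99", "cold95", "cold90", "not_significant",
                    "hot90", "hot95", "hot99")

#' Getis-Ord Gi* local hotspot statistic
#'
#' For every location `i`, compares the weighted sum of case counts in its
#' neighborhood (including itself) with the global mean:
#' `z_i = (sum_j w_ij x_j - Xbar W_i) / (S * sqrt((n sum_j w_ij^2 - W_i^2)
#' / (n - 1)))` with `Xbar = sum x / n`, `S = sqrt(sum x^2 / n - Xbar^2)`
#' and `W_i = sum_j w_ij`, `j` running over all locations including `i`.
#' Large positive `z_i` marks a hotspot, large negative a coldspot.
#'
#' @param points `weighted_points` from [snap_collisions()] (the per-location
#'   counts are the analysis variable), or a data frame with `lat`, `lon`
#'   and `count`.
#' @param W `spatial_weights` built with `include_self = TRUE`.
#' @return Object of class `gistar_result`: per-location `z`, `p`
#'   (two-sided normal), `lat`, `lon`, `x`; global `n`, `xbar`, `s`;
#'   `class` is filled by [classify_hotspots()].
#' @export
getis_ord_gistar <- function(points, W) {
  stopifnot(inherits(W, "spatial_weights"))
  if (!W$includes_self)
    stop("Gi* requires self-inclusive weights; rebuild with ",
         "include_self = TRUE", call. = FALSE)
  p <- points_latlon(points)
  x <- points$count
  if (is.null(x)) stop("points must carry per-location counts", call. = FALSE)
  n <- W$n
  if (length(x) != n)
    stop("count vector and weights disagree on n", call. = FALSE)
  if (n < 8) stop("need at least 8 locations", call. = FALSE)
  xbar <- sum(x) / n
  s <- sqrt(sum(x^2) / n - xbar^2)
  if (s == 0)
    stop("constant counts: Gi* is undefined (S = 0)", call. = FALSE)
  Wm <- weights_matrix(W)
  Wi <- as.numeric(Matrix::rowSums(Wm))
  S1i <- as.numeric(Matrix::rowSums(Wm^2))
  num <- as.numeric(Wm %*% x) - xbar * Wi
  inner <- (n * S1i - Wi^2) / (n - 1)
  z <- rep(NA_real_, n)
  ok <- inner > 1e-14
  z[ok] <- num[ok] / (s * sqrt(inner[ok]))
  if (any(!ok))
    warning(sum(!ok), " location(s) with degenerate Gi* denominator set NA",
            call. = FALSE)
  structure(list(z = z, p = 2 * stats::pnorm(-abs(z)),
                 lat = p$lat, lon = p$lon, x = x,
                 n = n, xbar = xbar, s = s,
                 class = NULL, fdr_applied = FALSE),
            class = "gistar_result")
}

#' @export
print.gistar_result <- function(x, ...) {
  cat("Gi*:", x$n, "locations, z range [",
      sprintf("%.2f", min(x$z, na.rm = TRUE)), ",",
      sprintf("%.2f", max(x$z, na.rm = TRUE)), "]\n")
  if (!is.null(x$class)) print(table(x$class))
  invisible(x)
}

#' Confidence class from a Gi* z-score
#'
#' Bins z-scores against the two-sided normal critical values 1.645, 1.960
#' and 2.576 (90/95/99% confidence), signed hot vs cold.
#'
#' @param z Numeric z-scores.
#' @return Factor over `cold99 ... not_significant ... hot99`; `NA` in,
#'   `NA` out.
#' @export
hotspot_class <- function(z) {
  cls <- rep("not_significant", length(z))
  cls[z >= 1.645] <- "hot90"
  cls[z >= 1.960] <- "hot95"
  cls[z >= 2.576] <- "hot99"
  cls[z <= -1.645] <- "cold90"
  cls[z <= -1.960] <- "cold95"
  cls[z <= -2.576] <- "cold99"
  cls[is.na(z)] <- NA
  factor(cls, levels = GISTAR_CLASSES)
}

#' Classify Gi* results into confidence bins
#'
#' Plain classification bins `|z|` against the 90/95/99% normal critical
#' values. With `fdr = TRUE` the significance set is determined first by
#' Benjamini-Hochberg adjustment of the per-location two-sided p-values
#' (adjusted p <= 0.10 / 0.05 / 0.01 for the three bins), which controls
#' the false discovery rate across the many simultaneous local tests.
#'
#' @param result A `gistar_result`.
#' @param fdr Apply Benjamini-Hochberg before binning (default `FALSE`).
#' @return The `gistar_result` with `class` and `fdr_applied` filled in.
#' @export
classify_hotspots <- function(result, fdr = FALSE) {
  stopifnot(inherits(result, "gistar_result"))
  if (!fdr) {
    result$class <- hotspot_class(result$z)
  } else {
    padj <- stats::p.adjust(result$p, method = "BH")
    lvl <- ifelse(padj <= 0.01, 3L,
                  ifelse(padj <= 0.05, 2L, ifelse(padj <= 0.10, 1L, 0L)))
    cls <- rep("not_significant", length(result$z))
    hot <- !is.na(result$z) & result$z > 0
    cold <- !is.na(result$z) & result$z < 0
    cls[hot & lvl == 1L] <- "hot90";  cls[cold & lvl == 1L] <- "cold90"
    cls[hot & lvl == 2L] <- "hot95";  cls[cold & lvl == 2L] <- "cold95"
    cls[hot & lvl == 3L] <- "hot99";  cls[cold & lvl == 3L] <- "cold99"
    cls[is.na(result$z)] <- NA
    result$class <- factor(cls, levels = GISTAR_CLASSES)
  }
  result$fdr_applied <- fdr
  result
}

#' Tally hot locations by administrative unit
#'
#' Counts locations classified `hot95` or stronger, grouped by an admin
#' label (state, district, region ...). An empty tally means no location
#' reached 95% confidence.
#'
#' @param result A classified `gistar_result` (see [classify_hotspots()]).
#' @param admin Character vector of admin labels, one per location.
#' @return Named integer vector of hot-location counts (possibly empty).
#' @export
hotspots_by_admin <- function(result, admin) {
  stopifnot(inherits(result, "gistar_result"))
  if (is.null(result$class))
    stop("classify_hotspots() first", call. = FALSE)
  if (length(admin) != length(result$class))
    stop("admin labels must match the number of locations", call. = FALSE)
  hot <- result$class %in% c("hot95", "hot99")
  tab <- table(admin[hot])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Inverse-distance-weighted interpolation surface
#'
#' Interpolates location values (typically Gi* z-scores) onto a regular
#' lon/lat grid: each cell takes the weighted average
#' `sum z_i d_i^(-power) / sum d_i^(-power)` over its neighborhood — the
#' `k` nearest locations (default 12) or all locations within `radius_km`.
#' A cell coincident with a data location (within 1e-9 km) takes that
#' location's value exactly; a cell with an empty neighborhood is NODATA.
#' Because weights are positive and sum to one, every interpolated value
#' lies within the range of its neighbors' values.
#'
#' Cells are square in degrees (required by the ESRI ASCII grid format);
#' the default grid covers the data bounding box padded by 5%, `ncols`
#' cells wide, with rows added to cover the north-south extent.
#'
#' @param lat,lon Data locations.
#' @param values Values to interpolate (e.g. `z` from [getis_ord_gistar()]);
#'   `NA` values are dropped with their locations.
#' @param power IDW exponent, `>= 1` (default 2).
#' @param k Neighborhood size for the k-nearest rule (default 12).
#' @param radius_km If non-`NULL`, use the radius rule instead of k-nearest.
#' @param ncols Grid width in cells (default 100).
#' @param pad Fractional bounding-box padding (default 0.05).
#' @param nodata NODATA marker for export (default -9999).
#' @return Object of class `idw_surface`: `values` matrix (row 1 = north),
#'   `xllcorner`, `yllcorner`, `cellsize` (degrees), `nodata`, and the
#'   neighborhood rule used.
#' @export
idw_surface <- function(lat, lon, values, power = 2, k = 12,
                        radius_km = NULL, ncols = 100, pad = 0.05,
                        nodata = -9999) {
  check_coords(lat, lon)
  if (power < 1) stop("power must be >= 1", call. = FALSE)
  keep <- !is.na(values)
  lat <- lat[keep]; lon <- lon[keep]; values <- values[keep]
  if (length(values) < 1) stop("no data locations", call. = FALSE)
  xr <- range(lon); yr <- range(lat)
  xpad <- max(diff(xr), 1e-3) * pad; ypad <- max(diff(yr), 1e-3) * pad
  x0 <- xr[1] - xpad; x1 <- xr[2] + xpad
  y0 <- yr[1] - ypad; y1 <- yr[2] + ypad
  cellsize <- (x1 - x0) / ncols
  nrows <- max(1L, ceiling((y1 - y0) / cellsize))
  cx <- x0 + (seq_len(ncols) - 0.5) * cellsize
  cy <- y1 - (seq_len(nrows) - 0.5) * cellsize   # row 1 = northernmost
  grid_lat <- rep(cy, each = ncols)
  grid_lon <- rep(cx, times = nrows)
  vals <- idw_interpolate(grid_lat, grid_lon, lat, lon, values,
                          power = power, k = k, radius_km = radius_km)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  structure(list(values = m, xllcorner = x0, yllcorner = y1 - nrows * cellsize,
                 cellsize = cellsize, ncols = ncols, nrows = nrows,
                 power = power,
                 rule = if (is.null(radius_km)) sprintf("k=%d", k)
                        else sprintf("radius=%gkm", radius_km),
                 nodata = nodata),
            class = "idw_surface")
}

# core IDW evaluation at arbitrary query points (exported for tests and
# point-wise use; the surface wrapper lays the grid)
#' @rdname idw_surface
#' @param query_lat,query_lon Query point coordinates.
#' @export
idw_interpolate <- function(query_lat, query_lon, lat, lon, values,
                            power = 2, k = 12, radius_km = NULL) {
  nq <- length(query_lat)
  np <- length(lat)
  k <- min(k, np)
  out <- rep(NA_real_, nq)
  chunk <- max(1L, floor(2e6 / np))
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(s + chunk - 1L, nq)
    idx <- s:e
    d <- pairwise_km(query_lat[idx], query_lon[idx], lat, lon)
    for (r in seq_along(idx)) {
      dr <- d[r, ]
      hit <- which(dr < 1e-9)
      if (length(hit)) { out[idx[r]] <- values[hit[1]]; next }
      nb <- if (is.null(radius_km)) order(dr)[seq_len(k)]
            else which(dr <= radius_km)
      if (!length(nb)) next
      w <- dr[nb]^(-power)
      out[idx[r]] <- sum(values[nb] * w) / sum(w)
    }
  }
  out
}

#' @export
print.idw_surface <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "idw_surface: %d x %d cells (%.5f deg), value range [%.3f, %.3f], %s\n",
    x$nrows, x$ncols, x$cellsize, min(v, na.rm = TRUE),
    max(v, na.rm = TRUE), x$rule))
  invisible(x)
}
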