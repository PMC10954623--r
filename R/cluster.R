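# Global clustering inference: average nearest-neighbor index against
# complete spatial randomness, and global Moran's I with analytical
# (randomization / normality) and permutation inference.

# Lambert azimuthal equal-area projection (spherical) centred on the point
# cloud; returns planar x/y in km. Used only for area measurement, so the
# equal-area property is the one that matters.
laea_project <- function(lat, lon, center = NULL) {
  rad <- pi / 180
  if (is.null(center)) center <- c(mean(lat), mean(lon))
  phi0 <- center[1] * rad; lam0 <- center[2] * rad
  phi <- lat * rad; lam <- lon * rad
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  k <- sqrt(2 / denom)
  list(x = EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lam0),
       y = EARTH_RADIUS_KM * k *
         (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0)))
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Average nearest-neighbor index (NNI)
#'
#' Compares the observed mean nearest-neighbor distance of a point pattern
#' with its expectation under complete spatial randomness on a study area
#' of `A` km^2: `E[d] = 0.5 / sqrt(n / A)`, with standard error
#' `0.26136 / sqrt(n^2 / A)`. `NNI < 1` indicates clustering; the z-score
#' and two-sided normal p quantify departure from CSR.
#'
#' The study area drives the index, so three conventions are offered: the
#' axis-aligned bounding rectangle of the points in a local equal-area
#' projection (the default, matching common GIS practice), the convex hull
#' area, or a user-supplied area.
#'
#' @param lat,lon Point coordinates (episode-level; duplicates allowed —
#'   co-located cases legitimately drive the observed mean toward zero).
#' @param area_method `"bounding_rectangle"` (default), `"convex_hull"` or
#'   `"user_supplied"`.
#' @param area_km2 Study area in km^2, required for `"user_supplied"`.
#' @return Object of class `nni_result`: `n`, `area_km2`, `area_method`,
#'   `mean_observed_km`, `expected_km`, `nni`, `se`, `z`, `p`.
#' @export
nearest_neighbor_index <- function(lat, lon,
                                   area_method = c("bounding_rectangle",
                                                   "convex_hull",
                                                   "user_supplied"),
                                   area_km2 = NULL) {
  area_method <- match.arg(area_method)
  check_coords(lat, lon)
  n <- length(lat)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  d <- pairwise_km(lat, lon, lat, lon)
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  dbar_obs <- mean(nn)
  if (diff(range(lat)) == 0 && diff(range(lon)) == 0)
    stop("all points coincident: observed mean nearest-neighbor distance ",
         "is zero and CSR inference is undefined", call. = FALSE)
  if (area_method == "user_supplied") {
    if (is.null(area_km2) || area_km2 <= 0)
      stop("area_km2 must be supplied and > 0", call. = FALSE)
    A <- area_km2
  } else {
    pr <- laea_project(lat, lon)
    if (area_method == "bounding_rectangle") {
      A <- diff(range(pr$x)) * diff(range(pr$y))
    } else {
      h <- grDevices::chull(pr$x, pr$y)
      A <- polygon_area(pr$x[h], pr$y[h])
    }
    if (A <= 0)
      stop("degenerate point configuration: study area is zero; supply ",
           "area_km2 explicitly", call. = FALSE)
  }
  dbar_exp <- 0.5 / sqrt(n / A)
  se <- 0.26136 / sqrt(n^2 / A)
  z <- (dbar_obs - dbar_exp) / se
  structure(list(n = n, area_km2 = A, area_method = area_method,
                 mean_observed_km = dbar_obs, expected_km = dbar_exp,
                 nni = dbar_obs / dbar_exp, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z))),
            class = "nni_result")
}

#' @export
print.nni_result <- function(x, ...) {
  cat(sprintf(
    "NNI = %.3f (observed %.3f km / expected %.3f km, n = %d, A = %.1f km2)\n",
    x$nni, x$mean_observed_km, x$expected_km, x$n, x$area_km2))
  cat(sprintf("z = %.2f, p = %.3g [%s]\n", x$z, x$p, x$area_method))
  invisible(x)
}

moran_denominator_check <- function(x, W) {
  stopifnot(inherits(W, "spatial_weights"))
  if (length(x) != W$n)
    stop("length(x) must equal the number of locations in W", call. = FALSE)
  if (W$includes_self)
    stop("Moran's I expects weights without self-loops; rebuild with ",
         "include_self = FALSE", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("x is constant: Moran's I is undefined (zero deviance)",
         call. = FALSE)
  invisible(TRUE)
}

#' Global Moran's I with analytical inference
#'
#' Computes `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2`, its null expectation `E[I] = -1/(n-1)`, and the
#' analytical variance under both the randomization assumption (default,
#' uses the sample kurtosis) and the normality assumption. The z-score and
#' two-sided normal p use the randomization variance.
#'
#' The variance formulas require `n >= 4`; for smaller `n` the statistic
#' and expectation are still returned with `NA` inference.
#'
#' @param x Numeric values on the locations of `W` (typically snapped
#'   per-location case counts).
#' @param W A `spatial_weights` object without self-loops.
#' @return Object of class `moran_result`: `I`, `expectation`,
#'   `variance_randomization`, `variance_normality`, `z`, `p`, plus the
#'   weight sums used (`n`, `S0`, `S1`, `S2`) and `n_isolates`.
#' @export
morans_i <- function(x, W) {
  moran_denominator_check(x, W)
  n <- W$n
  z <- x - mean(x)
  den <- sum(z^2)
  num <- sum(W$w * z[W$i] * z[W$j])
  I <- (n / W$S0) * num / den
  EI <- -1 / (n - 1)
  if (n >= 4) {
    S0 <- W$S0; S1 <- W$S1; S2 <- W$S2
    b2 <- n * sum(z^4) / den^2
    var_norm <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - EI^2
    var_rand <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
                   b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
    zsc <- (I - EI) / sqrt(var_rand)
    p <- 2 * stats::pnorm(-abs(zsc))
  } else {
    var_norm <- var_rand <- zsc <- p <- NA_real_
  }
  structure(list(I = I, expectation = EI,
                 variance_randomization = var_rand,
                 variance_normality = var_norm,
                 z = zsc, p = p, n = n, S0 = W$S0, S1 = W$S1, S2 = W$S2,
                 n_isolates = W$n_isolates),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f)\n", x$I, x$expectation))
  if (!is.na(x$z))
    cat(sprintf("z = %.2f, p = %.3g (randomization variance %.3g)\n",
                x$z, x$p, x$variance_randomization))
  if (!is.null(x$p_permutation) && !is.na(x$p_permutation))
    cat(sprintf("permutation p = %.4g (%d permutations)\n",
                x$p_permutation, x$n_perm))
  invisible(x)
}

#' Permutation test for Moran's I
#'
#' Random-labelling inference: the values are permuted over the locations
#' `n_perm` times and the two-sided p-value is
#' `(1 + #{|I_perm - E[I]| >= |I_obs - E[I]|}) / (1 + n_perm)`.
#' Deterministic given `seed`.
#'
#' @inheritParams morans_i
#' @param n_perm Number of permutations (`>= 19`; default 999).
#' @param seed Integer seed.
#' @return A `moran_result` with `p_permutation`, `n_perm`, `seed` and a
#'   summary of the permutation null (`null_mean`, `null_sd`).
#' @export
morans_i_permutation <- function(x, W, n_perm = 999, seed = 1L) {
  if (n_perm < 19) stop("n_perm must be >= 19", call. = FALSE)
  obs <- morans_i(x, W)
  n <- W$n
  z <- x - mean(x)
  den <- sum(z^2)
  Wm <- weights_matrix(W)
  set.seed(as.integer(seed))
  P <- vapply(seq_len(n_perm), function(k) z[sample.int(n)], numeric(n))
  I_perm <- (n / W$S0) * Matrix::colSums(P * (Wm %*% P)) / den
  EI <- obs$expectation
  p <- (1 + sum(abs(I_perm - EI) >= abs(obs$I - EI))) / (1 + n_perm)
  obs$p_permutation <- p
  obs$n_perm <- as.integer(n_perm)
  obs$seed <- as.integer(seed)
  obs$null_mean <- mean(I_perm)
  obs$null_sd <- stats::sd(I_perm)
  obs
}
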