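# Independent direct-summation oracles for the spatial statistics, written
# against dense matrices with explicit loops. These deliberately share no
# code with the package internals (which work on sparse edge lists), so an
# agreement test exercises two separate derivations of each formula.

oracle_haversine <- function(lat1, lon1, lat2, lon2, R = 6371.0088) {
  to <- pi / 180
  p1 <- lat1 * to; p2 <- lat2 * to
  dl <- (lon2 - lon1) * to
  # spherical law of cosines — different route than the half-angle form
  cosc <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  R * acos(pmin(1, pmax(-1, cosc)))
}

oracle_dense_idw_weights <- function(lat, lon, cutoff, power) {
  n <- length(lat)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- oracle_haversine(lat[i], lon[i], lat[j], lon[j])
    if (d > 0 && d <= cutoff) W[i, j] <- if (power == 0) 1 else d^(-power)
  }
  W
}

oracle_moran <- function(x, W) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
  (n / sum(W)) * num / sum((x - xb)^2)
}

# Cliff-Ord randomization variance, recomputed from scratch with loop sums
oracle_moran_var_rand <- function(x, W) {
  n <- length(x)
  S0 <- sum(W)
  S1 <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    S1 <- S1 + (W[i, j] + W[j, i])^2
  S1 <- S1 / 2
  S2 <- 0
  for (i in seq_len(n))
    S2 <- S2 + (sum(W[i, ]) + sum(W[, i]))^2
  z <- x - mean(x)
  b2 <- n * sum(z^4) / sum(z^2)^2
  EI <- -1 / (n - 1)
  A <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2)
  B <- b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)
  A / ((n - 1) * (n - 2) * (n - 3) * S0^2) -
    B / ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
}

oracle_s1_s2 <- function(W) {
  n <- nrow(W)
  S1 <- 0; S2 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) S1 <- S1 + (W[i, j] + W[j, i])^2
    S2 <- S2 + (sum(W[i, ]) + sum(W[, i]))^2
  }
  c(S1 = S1 / 2, S2 = S2)
}

oracle_gistar <- function(x, Wstar) {
  n <- length(x)
  xb <- sum(x) / n
  s <- sqrt(sum(x^2) / n - xb^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    Wi <- sum(Wstar[i, ])
    num <- sum(Wstar[i, ] * x) - xb * Wi
    den <- s * sqrt((n * sum(Wstar[i, ]^2) - Wi^2) / (n - 1))
    z[i] <- num / den
  }
  z
}

# add Gi*-style self weights (row max, or 1 for binary) to a dense matrix
oracle_add_self <- function(W, binary = FALSE) {
  for (i in seq_len(nrow(W))) {
    m <- max(W[i, ])
    if (m > 0) W[i, i] <- if (binary) 1 else m
  }
  W
}
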