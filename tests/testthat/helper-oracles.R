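# Independent oracles used across tests. These deliberately avoid the package's
# own code paths.

# Pearson correlation from the raw definition (explicit sums)
brute_pearson <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

# Wilson score interval from the closed form
wilson_interval <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lo = center - half, hi = center + half)
}

# exact null distribution of the Mann-Whitney U statistic (larger sample
# labelled y) by exhaustive enumeration of which ranks belong to x
u_distribution <- function(n1, n2) {
  N <- n1 + n2
  combos <- combn(N, n1)
  u <- apply(combos, 2, function(rx) sum(rx) - n1 * (n1 + 1) / 2)
  table(u) / ncol(combos)
}

# two-sided exact p for observed U under the enumerated distribution
# (doubling rule, capped at 1)
u_exact_p <- function(u_obs, dist) {
  u_vals <- as.numeric(names(dist))
  p_lo <- sum(dist[u_vals <= u_obs])
  p_hi <- sum(dist[u_vals >= u_obs])
  min(1, 2 * min(p_lo, p_hi))
}

# voxel-centre membership count for the below-BM stalk + cap solid
brute_protrusion_voxels <- function(spec, L = spec$protrusion$length) {
  d <- spec$grid_shape; vs <- spec$voxel_size
  x0 <- spec$bm_gap$center; z0 <- spec$ac_center[["z"]]
  r <- spec$protrusion$radius; tip <- spec$bm_y + L
  count <- 0L
  for (iz in seq_len(d[1])) for (iy in seq_len(d[2])) for (ix in seq_len(d[3])) {
    z <- (iz - 0.5) * vs[1]; y <- (iy - 0.5) * vs[2]; x <- (ix - 0.5) * vs[3]
    in_stalk <- y >= spec$bm_y && y <= tip && (x - x0)^2 + (z - z0)^2 <= r^2
    in_cap <- y > tip && (x - x0)^2 + (y - tip)^2 + (z - z0)^2 <= r^2
    if (in_stalk || in_cap) count <- count + 1L
  }
  count
}
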