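# Independent oracles and shared fixtures for the test suite.

# Exhaustive halfspace-depth oracle: the minimising closed halfplane can be
# rotated until its boundary is perpendicular to the direction of some data
# point (seen from the query), so it suffices to scan, for every data-point
# direction theta, the unit normals near theta and theta +/- pi/2 (nudged off
# the exact boundary on both sides) and take the minimal count. Coincident
# points lie on every boundary and always count.
depth_oracle <- function(query, cloud) {
  cloud <- as.matrix(cloud)
  d <- cbind(cloud[, 1] - query[1], cloud[, 2] - query[2])
  co <- d[, 1] == 0 & d[, 2] == 0
  m <- sum(co)
  dd <- d[!co, , drop = FALSE]
  if (nrow(dd) == 0) return(m)
  th <- atan2(dd[, 2], dd[, 1])
  cand <- as.vector(outer(c(th, th + pi / 2, th - pi / 2),
                          c(-1e-7, 0, 1e-7), "+"))
  counts <- vapply(cand, function(a) {
    s <- dd[, 1] * cos(a) + dd[, 2] * sin(a)
    sum(s >= -1e-12)
  }, numeric(1))
  m + min(counts)
}

# Point-in-polygon oracle from an established package (boundary counts as in).
in_polygon_oracle <- function(pts, poly) {
  pracma::inpolygon(pts[, 1], pts[, 2], poly[, 1], poly[, 2],
                    boundary = TRUE)
}

# Small, quick simulated dataset used across tests.
small_sim <- function(seed = 1, groups = 2, outliers = 2) {
  simulate_expression(
    sim_config(n_transcripts = 120, groups = groups, samples_per_group = 12,
               outliers_per_group = outliers, n_de_transcripts = 30,
               n_outlier_de_transcripts = 15),
    seed = seed
  )
}

# Frozen validation fixture: bootstrap occurrence/detection count pairs at
# published scale, with the expected two-decimal probability, two-decimal
# one-sided 95% CI lower bound, and p-value rendering ("<0.001" or a rounded
# number). Frozen before implementation; do not regenerate from the code
# under test.
binomial_fixture <- function() {
  tibble::tribble(
    ~n, ~k, ~prob2, ~ci2, ~p_print,
    68L, 68L, 1.00, 0.96, "<0.001",
    64L, 64L, 1.00, 0.95, "<0.001",
    67L, 66L, 0.99, 0.93, "<0.001",
    66L, 65L, 0.98, 0.93, "<0.001",
    66L, 63L, 0.95, 0.89, "<0.001",
    60L, 57L, 0.95, 0.88, "<0.001",
    63L, 59L, 0.94, 0.86, "<0.001",
    57L, 53L, 0.93, 0.85, "<0.001",
    63L, 45L, 0.71, 0.61, "<0.001",
    61L, 43L, 0.70, 0.59, "0.001",
    87L, 59L, 0.68, 0.59, "0.001",
    72L, 43L, 0.60, 0.49, "0.062",
    66L, 38L, 0.58, 0.47, "0.134",
    58L, 33L, 0.57, 0.45, "0.179",
    67L, 37L, 0.55, 0.44, "0.232",
    59L, 31L, 0.53, 0.41, "0.397",
    66L, 33L, 0.50, 0.39, "0.549",
    60L, 29L, 0.48, 0.37, "0.651",
    71L, 55L, 0.77, 0.68, "<0.001",
    66L, 23L, 0.35, 0.25, "0.995",
    68L, 21L, 0.31, 0.22, "1.00",
    69L, 18L, 0.26, 0.18, "1.00",
    62L, 12L, 0.19, 0.12, "1.00",
    62L, 11L, 0.18, 0.10, "1.00",
    64L, 11L, 0.17, 0.10, "1.00",
    62L, 10L, 0.16, 0.09, "1.00",
    61L,  9L, 0.15, 0.08, "1.00",
    64L,  8L, 0.12, 0.06, "1.00"
  )
}
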