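# Independent oracles used across the suite. These deliberately avoid the
# package's own SDF / classification code paths.

# Point-in-union test against the raw primitives (hard union, no blending):
# head sphere, conical neck frustum, shaft cylinder. Mirrors femur_params
# geometry definitions but tests membership per primitive directly.
femur_union_contains <- function(pts, params) {
  stopifnot(params$side == "right")
  theta <- (params$neck_shaft_angle - 90) * pi / 180
  u <- c(-cos(theta), 0, -sin(theta))
  c0 <- params$head_center
  in_sphere <- sqrt(rowSums(sweep(pts, 2, c0)^2)) <= params$head_radius
  t0 <- sqrt(params$head_radius^2 - params$neck_radius^2)
  a <- c0 + t0 * u
  J <- c0 + params$neck_length * u
  h <- sqrt(sum((J - a)^2))
  rel <- sweep(pts, 2, a)
  t <- as.numeric(rel %*% u)
  radial <- sqrt(pmax(rowSums(rel^2) - t^2, 0))
  rcone <- params$neck_radius +
    (params$neck_radius_distal - params$neck_radius) * t / h
  in_cone <- t >= 0 & t <= h & radial <= rcone
  z_top <- J[3] + params$shaft_radius
  z_bot <- J[3] - params$shaft_length
  in_shaft <- pts[, 3] >= z_bot & pts[, 3] <= z_top &
    sqrt((pts[, 1] - J[1])^2 + (pts[, 2] - J[2])^2) <= params$shaft_radius
  in_sphere | in_cone | in_shaft
}

# Monte-Carlo volume of the hard primitive union over a bounding box.
femur_union_volume_mc <- function(params, n = 4e5, seed = 99L) {
  set.seed(seed)
  theta <- (params$neck_shaft_angle - 90) * pi / 180
  u <- c(-cos(theta), 0, -sin(theta))
  J <- params$head_center + params$neck_length * u
  lo <- pmin(params$head_center - params$head_radius,
             c(J[1:2], J[3] - params$shaft_length) - params$shaft_radius)
  hi <- pmax(params$head_center + params$head_radius,
             c(J[1:2], J[3] + params$shaft_radius) + params$shaft_radius)
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  mean(femur_union_contains(pts, params)) * prod(hi - lo)
}

# Euler-Bernoulli + first-order shear correction for an end-loaded
# square-section cantilever.
cantilever_deflection <- function(P, L, E, nu, side_len) {
  I <- side_len^4 / 12
  A <- side_len^2
  G <- E / (2 * (1 + nu))
  P * L^3 / (3 * E * I) + P * L / (5 / 6 * G * A)
}

# Brute-force per-vertex half-space classification of facets (majority of
# the three vertices), used to cross-check the centroid rule.
facet_majority_keep <- function(mesh, facets, hs) {
  tri <- mesh$triangles[facets, , drop = FALSE]
  sgn <- function(ids) {
    s <- sweep(mesh$vertices[ids, , drop = FALSE], 2, hs$point) %*% hs$normal
    hs$keep_sign * s >= 0
  }
  k1 <- sgn(tri[, 1]); k2 <- sgn(tri[, 2]); k3 <- sgn(tri[, 3])
  (k1 + k2 + k3) >= 2
}

# Deterministic per-test RNG scope.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(code)
}
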