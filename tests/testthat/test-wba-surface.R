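test_that("sphere fit is exact on an exact sphere and rejects a plane", {
  head <- unit_sphere_head(n_lat = 40, n_lon = 40)
  expect_equal(head$center, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(head$radius, 1, tolerance = 1e-9)
  expect_lt(head$rms, 1e-9)
  # a planar mesh has no sphere: fit failure
  g <- expand.grid(x = 0:10, y = 0:10)
  verts <- cbind(g$x, g$y, 0)
  idx <- matrix(seq_len(11 * 11), 11, 11)
  tris <- NULL
  for (i in 1:10) for (j in 1:10)
    tris <- rbind(tris, c(idx[i, j], idx[i + 1, j], idx[i, j + 1]),
                  c(idx[i + 1, j], idx[i + 1, j + 1], idx[i, j + 1]))
  plane_mesh <- surface_mesh(verts, tris)
  expect_error(fit_head_sphere(plane_mesh, hint = seq_len(nrow(verts))),
               "sphere fit failed")
})

test_that("inferior-limit trims reproduce spherical closed forms", {
  head <- unit_sphere_head()   # >= 20k facets
  expect_gte(nrow(head$mesh$triangles), 20000)
  # 30-degree inferior limit: hat-box area 2*pi*r*h with h = 1.5 r -> 3*pi
  p30 <- apply_inferior_limit(head$head_facets, head,
                              jrf_direction = c(0, 0, -1), limit_deg = 30)
  expect_lt(abs(p30$area - 3 * pi) / (3 * pi), 0.01)
  # limit 90 keeps the whole sphere: 4*pi
  p90 <- apply_inferior_limit(head$head_facets, head,
                              jrf_direction = c(0, 0, -1), limit_deg = 90)
  expect_lt(abs(p90$area - 4 * pi) / (4 * pi), 0.01)
})

test_that("two margin planes through the centre carve a spherical lune", {
  head <- unit_sphere_head()
  plane <- datum_plane()
  # vertical extruded planes through the centre with a 60-degree dihedral
  theta <- 60 * pi / 180
  lat <- line3d(c(0, 0, 0), c(1, 0, 0))
  med <- line3d(c(0, 0, 0), c(cos(theta), 0, sin(theta)))
  ref <- c(cos(theta / 2), 0, sin(theta / 2))  # inside the wedge
  beta <- trim_by_margin_lines(head, lat, med, plane, reference_point = ref)
  lune <- apply_inferior_limit(beta$facets, head, jrf_direction = -ref,
                               limit_deg = 90, half_spaces = beta$half_spaces)
  expect_lt(abs(lune$area - 2 * theta) / (2 * theta), 0.01)
})

test_that("a margin line through the centre keeps half the sphere", {
  head <- unit_sphere_head()
  plane <- datum_plane()
  lat <- line3d(c(-2, 0, 0), c(0, 0, 1))     # far lateral: no-op
  med <- line3d(c(0, 0, 0), c(0, 0, 1))      # vertical through the centre
  ref <- c(0.5, 0, 0)
  beta <- trim_by_margin_lines(head, lat, med, plane, reference_point = ref)
  kept <- apply_inferior_limit(beta$facets, head, jrf_direction = c(0, 0, -1),
                               limit_deg = 90, half_spaces = beta$half_spaces)
  expect_lt(abs(kept$area - 2 * pi) / (2 * pi), 0.02)
  # both lines far away: the whole head surface survives
  far <- trim_by_margin_lines(head, line3d(c(-2, 0, 0), c(0, 0, 1)),
                              line3d(c(2, 0, 0), c(0, 0, 1)), plane,
                              reference_point = c(0, 0, 0))
  expect_identical(sort(far$facets), sort(head$head_facets))
})

test_that("centroid classification agrees with the per-vertex oracle", {
  head <- unit_sphere_head(n_lat = 100, n_lon = 100)
  hs <- wbafem:::margin_half_space(line3d(c(0.3, 0, 0), c(0.2, 0, 1)),
                                   datum_plane(), c(-1, 0, 0))
  cent <- wbafem:::triangle_centroids(head$mesh$vertices, head$mesh$triangles)
  keep_centroid <- wbafem:::half_space_keep(cent, hs)
  keep_majority <- facet_majority_keep(head$mesh,
                                       seq_len(nrow(head$mesh$triangles)), hs)
  agreement <- mean(keep_centroid == keep_majority)
  expect_gte(agreement, 0.995)
})

test_that("patch area is the exact facet-area sum", {
  tri_mesh <- surface_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
                           rbind(c(1, 2, 3)))
  patch <- list(mesh = tri_mesh, facets = 1L)
  expect_equal(patch_area(patch), 6)
  expect_equal(patch_area(list(mesh = tri_mesh, facets = integer(0))), 0)
})

test_that("facet area agrees with the Monte-Carlo surface oracle", {
  head <- unit_sphere_head()
  plane <- datum_plane()
  lat <- line3d(c(-0.25, 0, 0), c(0.1, 0, 1))
  med <- line3d(c(0.55, 0, 0), c(-0.2, 0, 1))
  beta <- trim_by_margin_lines(head, lat, med, plane,
                               reference_point = c(0.1, 0, 0))
  patch <- apply_inferior_limit(beta$facets, head,
                                jrf_direction = c(-0.2, -0.1, -1),
                                limit_deg = 30,
                                half_spaces = beta$half_spaces)
  mc <- patch_area_mc(patch, n = 4e5, seed = 2L)
  expect_lt(abs(patch$area - mc$area) / mc$area, 0.02)
})

test_that("mirrored trim configurations give equal areas", {
  head <- unit_sphere_head(n_lat = 80, n_lon = 80)
  plane <- datum_plane()
  run_side <- function(m) {
    lat <- line3d(c(m * -0.3, 0, 0), c(m * 0.15, 0, 1))
    med <- line3d(c(m * 0.6, 0, 0), c(m * -0.1, 0, 1))
    beta <- trim_by_margin_lines(head, lat, med, plane,
                                 reference_point = c(m * 0.1, 0, 0.1))
    apply_inferior_limit(beta$facets, head,
                         jrf_direction = c(m * -0.2, 0, -1), limit_deg = 30,
                         half_spaces = beta$half_spaces)$area
  }
  # the sphere tessellation is mirror-symmetric in x up to longitude phase;
  # areas agree to the discretization symmetry
  expect_equal(run_side(1), run_side(-1), tolerance = 1e-9)
})

test_that("empty trims raise errors naming the constraint", {
  head <- unit_sphere_head(n_lat = 20, n_lon = 20)
  plane <- datum_plane()
  all_gone <- line3d(c(3, 0, 0), c(0, 0, 1))
  expect_error(trim_by_margin_lines(head, all_gone,
                                    line3d(c(-3, 0, 0), c(0, 0, 1)), plane,
                                    reference_point = c(5, 0, 0)),
               "lateral")
  expect_error(apply_inferior_limit(integer(0), head), "empty")
})

test_that("patch facets stay connected, on the head, inside all constraints", {
  head <- unit_sphere_head(n_lat = 60, n_lon = 60)
  plane <- datum_plane()
  beta <- trim_by_margin_lines(head, line3d(c(-0.4, 0, 0), c(0, 0, 1)),
                               line3d(c(0.5, 0, 0), c(0.2, 0, 1)), plane,
                               reference_point = c(0, 0, 0.2))
  patch <- apply_inferior_limit(beta$facets, head,
                                jrf_direction = c(0, 0, -1), limit_deg = 40,
                                half_spaces = beta$half_spaces)
  expect_true(all(patch$facets %in% head$head_facets))
  tri <- patch$mesh$triangles[patch$facets, , drop = FALSE]
  expect_identical(max(wbafem:::facet_components(tri)), 1L)
  cent <- wbafem:::triangle_centroids(patch$mesh$vertices, tri)
  expect_true(all(patch_membership(cent, patch$provenance)))
})

test_that("area converges to the closed form as the mesh refines", {
  area_err <- function(n) {
    head <- unit_sphere_head(n_lat = n, n_lon = n)
    p <- apply_inferior_limit(head$head_facets, head,
                              jrf_direction = c(0, 0, -1), limit_deg = 30)
    abs(p$area - 3 * pi)
  }
  e_coarse <- area_err(30)
  e_fine <- area_err(60)
  expect_lt(e_fine, e_coarse / 1.5)
})

test_that("boundary fillet is conservative, idempotent and optional", {
  head <- unit_sphere_head(n_lat = 60, n_lon = 60)
  plane <- datum_plane()
  beta <- trim_by_margin_lines(head, line3d(c(-0.35, 0, 0), c(0, 0, 1)),
                               line3d(c(0.45, 0, 0), c(0, 0, 1)), plane,
                               reference_point = c(0.05, 0, 0.2))
  patch <- apply_inferior_limit(beta$facets, head,
                                jrf_direction = c(0, 0, -1), limit_deg = 35,
                                half_spaces = beta$half_spaces)
  # zero radius: identity
  expect_identical(smooth_patch_boundary(patch, 0)$facets, patch$facets)
  sm <- smooth_patch_boundary(patch, fillet_radius = 0.05)
  expect_lte(sm$area, patch$area)
  expect_equal(sm$fillet$area_before, patch$area)
  # near-idempotence: re-smoothing changes the area by < 0.1 %
  sm2 <- smooth_patch_boundary(sm, fillet_radius = 0.05)
  expect_lt(abs(sm2$area - sm$area) / sm$area, 0.001)
  # an oversized radius is refused with a warning
  expect_warning(big <- smooth_patch_boundary(patch, fillet_radius = 10),
                 "inradius")
  expect_identical(big$facets, patch$facets)
})
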