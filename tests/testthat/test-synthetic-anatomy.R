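test_that("femur parameter invariants are enforced", {
  expect_error(femur_params(head_radius = 10, neck_radius = 12),
               "head_radius > neck_radius")
  expect_error(femur_params(neck_radius = 13, cortical_thickness = 14),
               "cortical_thickness")
  expect_error(femur_params(neck_shaft_angle = 85), "neck_shaft_angle")
  expect_error(femur_params(neck_shaft_angle = 170), "neck_shaft_angle")
  expect_s3_class(femur_params(), "femur_params")
})

test_that("surface generation is deterministic and tags the head sphere", {
  p <- femur_params(head_radius = 24, seed = 3L)
  a <- generate_femur_surface(p, n_lat = 40, n_lon = 48)
  b <- generate_femur_surface(p, n_lat = 40, n_lon = 48)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$triangles, b$mesh$triangles)
  # tagged head vertices recover the generating sphere via least squares
  fit <- fit_head_sphere(a$mesh)
  expect_lt(abs(fit$radius - 24) / 24, 0.005)
  expect_lt(sqrt(sum((fit$center - p$head_center)^2)), 0.005 * 24)
  # closed head+neck and shaft components enclose positive volume
  expect_gt(mesh_volume(a$mesh), 0)
})

test_that("left-side generation mirrors the right side exactly", {
  pr <- femur_params(side = "right")
  pl <- femur_params(side = "left")
  mr <- generate_femur_surface(pr, n_lat = 24, n_lon = 32)
  ml <- generate_femur_surface(pl, n_lat = 24, n_lon = 32)
  expect_equal(ml$mesh$vertices[, 1], -mr$mesh$vertices[, 1])
  expect_equal(ml$mesh$vertices[, 2:3], mr$mesh$vertices[, 2:3])
  expect_equal(mesh_volume(ml$mesh), mesh_volume(mr$mesh), tolerance = 1e-9)
})

test_that("unit voxel splits into five tets whose volumes sum to one", {
  g <- wbafem:::voxel_tet_grid(function(p) rep(TRUE, nrow(p)),
                               c(0, 0, 0), c(1, 1, 1), 1, "five")
  expect_identical(nrow(g$elements), 5L)
  vols <- wbafem:::tet_volumes(g$nodes, g$elements)
  expect_true(all(vols > 0))
  expect_equal(sum(vols), 1, tolerance = 1e-12)
  g6 <- wbafem:::voxel_tet_grid(function(p) rep(TRUE, nrow(p)),
                                c(0, 0, 0), c(2, 2, 2), 1, "kuhn6")
  expect_equal(sum(wbafem:::tet_volumes(g6$nodes, g6$elements)), 8,
               tolerance = 1e-12)
})

test_that("tetrahedralized femur volume matches the primitive-union oracle", {
  # hard union (no blend) so the Monte-Carlo primitive oracle is exact
  p <- femur_params(blend_mm = 0)
  model <- generate_tet_mesh(p, voxel_size = 2)
  vol_tet <- sum(wbafem:::tet_volumes(model$nodes, model$elements))
  vol_mc <- femur_union_volume_mc(p, n = 4e5)
  expect_lt(abs(vol_tet - vol_mc) / vol_mc, 0.05)
  # no inverted elements and a full cortical/cancellous partition
  expect_true(all(wbafem:::tet_volumes(model$nodes, model$elements) > 0))
  expect_true(all(model$labels %in% c("cortical", "cancellous")))
  expect_gt(sum(model$labels == "cortical"), 0)
  expect_gt(sum(model$labels == "cancellous"), 0)
})

test_that("meshing rejects a voxel size wider than the neck", {
  expect_error(generate_tet_mesh(femur_params(), voxel_size = 30),
               "neck diameter")
})

test_that("synthetic radiograph projects, magnifies and jitters as specified", {
  p <- femur_params()
  fem <- generate_femur_surface(p, n_lat = 24, n_lon = 32)
  # noise 0, magnification 1: 2D landmarks are the dropped-y 3D landmarks
  r0 <- generate_radiograph(fem$truth, magnification = 1, noise_sd = 0)
  lm3 <- r0$truth$landmarks_3d
  expect_equal(unname(r0$landmarks$points), unname(lm3[, c(1, 3)]),
               tolerance = 1e-12)
  # magnification scales the marker measurement exactly
  r11 <- generate_radiograph(fem$truth, magnification = 1.1,
                             marker_true_mm = 25)
  expect_equal(r11$landmarks$marker_measured, 27.5)
  # requested CE angle is achieved exactly without noise
  r33 <- generate_radiograph(fem$truth, magnification = 1.2, noise_sd = 0,
                             target_ce_deg = 33)
  lmc <- correct_magnification(r33$landmarks)
  bc <- build_boundary_construction(lmc)
  expect_equal(bc$ce_deg, 33, tolerance = 1e-9)
  # determinism under a fixed seed
  ra <- generate_radiograph(fem$truth, noise_sd = 0.5, seed = 11L)
  rb <- generate_radiograph(fem$truth, noise_sd = 0.5, seed = 11L)
  rc <- generate_radiograph(fem$truth, noise_sd = 0.5, seed = 12L)
  expect_identical(ra$landmarks$points, rb$landmarks$points)
  expect_false(identical(ra$landmarks$points, rc$landmarks$points))
})

test_that("the left-side volunteer yields the same constructions mirrored", {
  p <- femur_params(side = "left")
  fem <- generate_femur_surface(p, n_lat = 24, n_lon = 32)
  r <- generate_radiograph(fem$truth, magnification = 1.1, noise_sd = 0,
                           target_ce_deg = 29)
  bc <- build_boundary_construction(correct_magnification(r$landmarks))
  expect_equal(bc$ce_deg, 29, tolerance = 1e-9)
  # full left-side patch: same crescent, centroid superior and anterior
  hf <- fit_head_sphere(fem$mesh)
  plane <- datum_plane()
  mlm3 <- r$truth$landmarks_3d
  src <- project_to_plane(mlm3, plane); rownames(src) <- rownames(mlm3)
  reg <- register_landmarks(src, correct_magnification(r$landmarks)$points,
                            names = c("p1", "p2", "p3", "p6", "p16", "p19"))
  beta <- trim_by_margin_lines(hf, lift_line(bc$lateral_line, reg, plane),
                               lift_line(bc$medial_line, reg, plane), plane)
  force <- default_jrf("left")
  patch <- apply_inferior_limit(beta$facets, hf, force / sqrt(sum(force^2)),
                                30, beta$half_spaces)
  cen <- patch_centroid(patch)
  expect_gt(cen[3], hf$center[3])
  expect_gt(cen[2], hf$center[2])
})

test_that("magnification round trip restores ground-truth positions", {
  p <- femur_params()
  fem <- generate_femur_surface(p, n_lat = 24, n_lon = 32)
  r <- generate_radiograph(fem$truth, magnification = 1.18, noise_sd = 0)
  corrected <- correct_magnification(r$landmarks)
  expect_equal(unname(corrected$points),
               unname(r$truth$landmarks_3d[, c(1, 3)]), tolerance = 1e-9)
})
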