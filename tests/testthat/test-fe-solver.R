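test_that("Von Mises invariants match the textbook cases", {
  expect_equal(von_mises(diag(c(5, 5, 5))), 0)
  expect_equal(von_mises(c(7, 0, 0, 0, 0, 0)), 7)
  tau <- 3.2
  shear <- matrix(0, 3, 3); shear[1, 2] <- shear[2, 1] <- tau
  expect_equal(von_mises(shear), sqrt(3) * tau)
  expect_error(von_mises(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)), "symmetric")
  # principal values of a uniaxial state
  pr <- wbafem:::symmetric3_eigenvalues(rbind(c(9, 0, 0, 0, 0, 0)))
  expect_equal(as.numeric(pr), c(9, 0, 0))
  # a full tensor against base R's eigensolver
  s <- c(3, -1, 2, 0.5, -0.7, 1.1)
  S <- matrix(c(s[1], s[4], s[6], s[4], s[2], s[5], s[6], s[5], s[3]), 3)
  expect_equal(as.numeric(wbafem:::symmetric3_eigenvalues(rbind(s))),
               sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE),
               tolerance = 1e-12)
})

test_that("zero load produces zero displacement and stress", {
  m <- block_model(dims = c(2, 2, 4))
  fld <- assemble_and_solve(m, material_spec(), matrix(0, nrow(m$nodes), 3))
  expect_equal(max(abs(fld$displacements)), 0)
  expect_equal(max(fld$von_mises), 0)
})

test_that("uniform traction on a bar reproduces the uniaxial closed form", {
  m <- block_model(dims = c(2, 2, 10), h = 1)
  mat <- material_spec(cortical = list(E = 1000, nu = 0))
  f <- top_traction_forces(m, height = 10)   # 1 MPa over a 2 x 2 section
  fld <- assemble_and_solve(m, mat, f)
  expect_equal(range(fld$stress[, 3]), c(1, 1), tolerance = 1e-9)
  expect_equal(range(fld$von_mises), c(1, 1), tolerance = 1e-9)
  top <- m$nodes[, 3] > 10 - 1e-9
  expect_equal(mean(fld$displacements[top, 3]), 10 * 1 / 1000,
               tolerance = 1e-9)
})

test_that("constant-strain states are reproduced exactly on a distorted mesh", {
  with_seed(42, {
    g <- wbafem:::voxel_tet_grid(function(p) rep(TRUE, nrow(p)),
                                 c(0, 0, 0), c(4, 4, 4), 1, "kuhn6")
    nd <- g$nodes
    interior <- apply(nd, 1, function(x) all(x > 0.5 & x < 3.5))
    nd[interior, ] <- nd[interior, ] +
      matrix(runif(sum(interior) * 3, -0.12, 0.12), ncol = 3)
    m <- tet_model(nd, g$elements, rep("cortical", nrow(g$elements)))
    A <- matrix(c(1e-3, 2e-4, -1e-4, 2e-4, -5e-4, 3e-4, -1e-4, 3e-4, 4e-4), 3)
    boundary <- which(!interior)
    fld <- assemble_and_solve(m, material_spec(),
                              matrix(0, nrow(nd), 3), fixed = boundary,
                              fixed_values = nd[boundary, ] %*% A)
    expect_lt(max(abs(fld$displacements - nd %*% A)), 1e-10)
    # stresses constant across all elements
    expect_lt(max(apply(fld$stress, 2, function(s) diff(range(s)))), 1e-9)
  })
})

test_that("the constrained stiffness matrix is symmetric positive definite", {
  m <- block_model(dims = c(2, 2, 2))
  K <- assemble_stiffness(m, material_spec())
  expect_lt(max(abs(K - Matrix::t(K))), 1e-9 * max(abs(K)))
  fixed <- m$node_sets$distal_fixed
  fixed_dofs <- as.vector(t(outer(3 * (fixed - 1), 1:3, "+")))
  free <- setdiff(seq_len(3 * nrow(m$nodes)), fixed_dofs)
  ev <- eigen(as.matrix(K[free, free]), symmetric = TRUE, only.values = TRUE)
  expect_gt(min(ev$values), 0)
})

test_that("cantilever tip deflection matches beam theory with shear correction", {
  m <- block_model(dims = c(2, 2, 20), h = 0.25)   # 8 elements through depth
  mat <- material_spec(cortical = list(E = 1000, nu = 0.3))
  f <- top_traction_forces(m, height = 20, traction = c(0.25, 0, 0)) # P = 1 N
  fld <- assemble_and_solve(m, mat, f)
  tip <- m$nodes[, 3] > 20 - 1e-9
  delta <- mean(fld$displacements[tip, 1])
  delta_beam <- cantilever_deflection(P = 1, L = 20, E = 1000, nu = 0.3,
                                      side_len = 2)
  expect_lt(abs(delta - delta_beam) / delta_beam, 0.10)
  # bending stress decreases from the fixed end toward the tip along an
  # off-axis line, as beam theory requires
  path <- extract_path(fld, m, start_node = which(apply(m$nodes, 1,
                         function(x) isTRUE(all.equal(x, c(0.25, 1, 0.25))))),
                       end_node = which(apply(m$nodes, 1,
                         function(x) isTRUE(all.equal(x, c(0.25, 1, 19.75))))),
                       n_samples = 8)
  bending <- abs(path$samples$s3)
  expect_gt(bending[1], bending[8])
  expect_lt(mean(diff(bending) > 0), 0.35)   # mostly decreasing
})

test_that("load cases resolve their regions and conserve the total force", {
  model <- cache_fixture("coarse_femur", function()
    generate_tet_mesh(femur_params(), voxel_size = 4))
  force <- c(-400, -140, -1750)
  lcC <- build_load_case(model, "C_point", force)
  expect_identical(length(lcC$nodes), 1L)
  expect_equal(as.numeric(lcC$forces), force)
  lcB <- build_load_case(model, "B_circle", force)
  expect_equal(colSums(lcB$forces), force, tolerance = 1e-12)
  expect_gt(length(lcB$nodes), 3)
  # every loaded node sits near the 2 cm circle at the head apex
  apex <- model$nodes[model$node_sets$head_apex, ]
  d <- sqrt(rowSums(sweep(model$nodes[lcB$nodes, , drop = FALSE], 2, apex)^2))
  expect_lt(max(d), 10 + 2 * 4)   # radius + facet reach at this voxel size
  expect_error(build_load_case(model, "B_circle", c(0, 0, 0)), "nonzero")
})

test_that("patch-region load centroid is stable under mesh refinement", {
  head <- unit_sphere_head(n_lat = 40, n_lon = 40)
  # a synthetic patch provenance on the femoral head
  p <- femur_params()
  fem <- generate_femur_surface(p, n_lat = 48, n_lon = 64)
  hf <- fit_head_sphere(fem$mesh)
  patch <- apply_inferior_limit(hf$head_facets, hf,
                                jrf_direction = c(-0.2, -0.1, -1),
                                limit_deg = 0)
  load_centroid <- function(vx) {
    model <- generate_tet_mesh(p, voxel_size = vx)
    lc <- build_load_case(model, "A_patch", c(0, 0, -1000),
                          list(patch = patch))
    w <- sqrt(rowSums(lc$forces^2))
    colSums(model$nodes[lc$nodes, ] * w) / sum(w)
  }
  c_coarse <- load_centroid(4)
  c_fine <- load_centroid(2)
  expect_lt(sqrt(sum((c_fine - c_coarse)^2)), 1)   # mm
})

test_that("solution is invariant under node renumbering", {
  m <- block_model(dims = c(2, 2, 6), h = 1)
  mat <- material_spec(cortical = list(E = 2000, nu = 0.25))
  f <- top_traction_forces(m, height = 6, traction = c(0.3, 0, 0.8))
  fld <- assemble_and_solve(m, mat, f)
  with_seed(13, {
    perm <- sample(nrow(m$nodes))
    inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
    m2 <- tet_model(m$nodes[perm, , drop = FALSE],
                    matrix(inv[m$elements], ncol = 4), m$labels,
                    node_sets = list(distal_fixed = inv[m$node_sets$distal_fixed]))
    fld2 <- assemble_and_solve(m2, mat, f[perm, , drop = FALSE])
    expect_equal(fld2$displacements, fld$displacements[perm, , drop = FALSE],
                 tolerance = 1e-8)
    expect_equal(sort(fld2$von_mises), sort(fld$von_mises), tolerance = 1e-8)
  })
})

test_that("equilibrium and energy consistency hold on the femur model", {
  model <- cache_fixture("coarse_femur", function()
    generate_tet_mesh(femur_params(), voxel_size = 4))
  lc <- build_load_case(model, "B_circle", c(-390, -140, -1750))
  fld <- assemble_and_solve(model, material_spec(), lc)
  res <- colSums(fld$reactions) + colSums(fld$applied)
  expect_lt(sqrt(sum(res^2)) / sqrt(sum(colSums(fld$applied)^2)), 1e-8)
  expect_equal(fld$external_work, 2 * fld$strain_energy,
               tolerance = 1e-8)
})

test_that("identical load cases give identical fields and a sane path", {
  model <- cache_fixture("coarse_femur", function()
    generate_tet_mesh(femur_params(), voxel_size = 4))
  force <- default_jrf("right")
  cases <- list(A1 = build_load_case(model, "B_circle", force),
                A2 = build_load_case(model, "B_circle", force))
  cmp <- compare_load_cases(model, material_spec(), cases)
  expect_identical(cmp$cases$A1$field$displacements,
                   cmp$cases$A2$field$displacements)
  expect_identical(cmp$cases$A1$peak$element, cmp$cases$A2$peak$element)
  tb <- cmp$path_table
  expect_identical(nrow(tb[tb$case == "A1", ]), 12L)
  expect_true(all(diff(tb[tb$case == "A1", "arc_mm"]) > 0))
})

test_that("path sampling handles uniform fields and degenerate counts", {
  m <- block_model(dims = c(2, 2, 10), h = 1)
  mat <- material_spec(cortical = list(E = 1000, nu = 0))
  fld <- assemble_and_solve(m, mat, top_traction_forces(m, 10))
  a <- which(apply(m$nodes, 1, function(x) all(x == c(1, 1, 1))))
  b <- which(apply(m$nodes, 1, function(x) all(x == c(1, 1, 9))))
  sp <- extract_path(fld, m, a, b, n_samples = 12)
  expect_equal(diff(range(sp$samples$von_mises)), 0, tolerance = 1e-9)
  sp1 <- extract_path(fld, m, a, b, n_samples = 1)
  expect_identical(nrow(sp1$samples), 1L)
  expect_equal(sp1$samples$arc_mm, 4)   # midpoint of an 8 mm segment
  expect_error(extract_path(fld, m, a, a), "coincide")
})
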