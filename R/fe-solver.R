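# Small-strain linear-elastic tetrahedral finite elements (4-node,
# constant-strain) with bi-material cortical/cancellous support, distal
# fixation, the three joint-reaction-force loading cases, and Von Mises /
# principal-stress postprocessing along a head-to-neck path.
#
# Unit system: N - mm - MPa.

#' Labeled tetrahedral volume model
#'
#' @param nodes `n x 3` node coordinates (mm).
#' @param elements `m x 4` 1-based connectivity (positive orientation).
#' @param labels character vector of length `m`, `"cortical"` or
#'   `"cancellous"` per element.
#' @param node_sets named list of integer node-index vectors (e.g.
#'   `distal_fixed`, `head_apex`).
#' @param validate check orientation, labels and node-set validity.
#' @return an object of class `tet_model`.
#' @export
tet_model <- function(nodes, elements, labels, node_sets = list(),
                      validate = TRUE) {
  nodes <- as_point_matrix(nodes, 3L)
  elements <- matrix(as.integer(as.matrix(elements)), ncol = 4L)
  labels <- as.character(labels)
  if (validate) {
    if (nrow(elements) == 0L) stop("model has no elements", call. = FALSE)
    if (min(elements) < 1L || max(elements) > nrow(nodes))
      stop("element connectivity out of range", call. = FALSE)
    if (length(labels) != nrow(elements))
      stop("one material label per element required", call. = FALSE)
    if (!all(labels %in% c("cortical", "cancellous")))
      stop("labels must be 'cortical' or 'cancellous'", call. = FALSE)
    vol <- tet_volumes(nodes, elements)
    if (any(vol <= 0))
      stop(sprintf("mesh error: %d inverted or degenerate element(s)",
                   sum(vol <= 0)), call. = FALSE)
    for (nm in names(node_sets)) {
      ns <- node_sets[[nm]]
      if (length(ns) && (min(ns) < 1L || max(ns) > nrow(nodes)))
        stop(sprintf("node set '%s' references invalid nodes", nm), call. = FALSE)
    }
  }
  structure(list(nodes = nodes, elements = elements, labels = labels,
                 node_sets = node_sets),
            class = "tet_model")
}

#' @export
print.tet_model <- function(x, ...) {
  cat(sprintf("tet_model: %d nodes, %d C3D4 elements (%d cortical, %d cancellous)\n",
              nrow(x$nodes), nrow(x$elements),
              sum(x$labels == "cortical"), sum(x$labels == "cancellous")))
  if (length(x$node_sets))
    cat("  node sets:", paste(sprintf("%s (%d)", names(x$node_sets),
                                      lengths(x$node_sets)), collapse = ", "), "\n")
  invisible(x)
}

tet_volumes <- function(nodes, elements) {
  p1 <- nodes[elements[, 1L], , drop = FALSE]
  d2 <- nodes[elements[, 2L], , drop = FALSE] - p1
  d3 <- nodes[elements[, 3L], , drop = FALSE] - p1
  d4 <- nodes[elements[, 4L], , drop = FALSE] - p1
  rowSums(d2 * cross3_rows(d3, d4)) / 6
}

tet_centroids <- function(model) {
  (model$nodes[model$elements[, 1L], ] + model$nodes[model$elements[, 2L], ] +
     model$nodes[model$elements[, 3L], ] + model$nodes[model$elements[, 4L], ]) / 4
}

#' Material constants per label
#'
#' Defaults are conventional literature values for adult bone (cortical
#' E = 16800 MPa, nu = 0.3; cancellous E = 840 MPa, nu = 0.2), configurable
#' per label.
#'
#' @param cortical,cancellous lists with elements `E` (MPa) and `nu`.
#' @return an object of class `material_spec`.
#' @export
material_spec <- function(cortical = list(E = 16800, nu = 0.3),
                          cancellous = list(E = 840, nu = 0.2)) {
  for (m in list(cortical, cancellous)) {
    if (!(m$E > 0)) stop("Young's modulus must be positive", call. = FALSE)
    if (!(m$nu > -1 && m$nu < 0.5))
      stop("Poisson ratio must lie in (-1, 0.5)", call. = FALSE)
  }
  structure(list(cortical = cortical, cancellous = cancellous),
            class = "material_spec")
}

# Assembled-and-factorized system for a given model/materials/constraint
# combination, reusable across load cases (the stiffness does not depend on
# the load).
fe_system <- function(model, materials, fixed) {
  K <- assemble_stiffness(model, materials)
  n <- nrow(model$nodes)
  fixed_dofs <- as.vector(t(outer(3L * (as.integer(fixed) - 1L), 1:3, "+")))
  free <- setdiff(seq_len(3L * n), fixed_dofs)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  chol <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE),
                   error = function(e)
                     stop("rigid-body-mode error: singular system after constraints (",
                          conditionMessage(e), ")", call. = FALSE))
  list(K = K, chol = chol, free = free, fixed_dofs = fixed_dofs,
       fixed = as.integer(fixed))
}

# Shape-function gradients and volumes for all elements.
# Returns volumes (m) and a list g[[a]] of m x 3 gradient matrices.
tet_gradients <- function(nodes, elements) {
  p1 <- nodes[elements[, 1L], , drop = FALSE]
  d2 <- nodes[elements[, 2L], , drop = FALSE] - p1
  d3 <- nodes[elements[, 3L], , drop = FALSE] - p1
  d4 <- nodes[elements[, 4L], , drop = FALSE] - p1
  v6 <- rowSums(d2 * cross3_rows(d3, d4))
  g2 <- cross3_rows(d3, d4) / v6
  g3 <- cross3_rows(d4, d2) / v6
  g4 <- cross3_rows(d2, d3) / v6
  g1 <- -(g2 + g3 + g4)
  list(volumes = v6 / 6, g = list(g1, g2, g3, g4))
}

lame_constants <- function(model, materials) {
  stopifnot(inherits(materials, "material_spec"))
  E <- ifelse(model$labels == "cortical", materials$cortical$E,
              materials$cancellous$E)
  nu <- ifelse(model$labels == "cortical", materials$cortical$nu,
               materials$cancellous$nu)
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

#' Assemble the global stiffness matrix
#'
#' Standard isoparametric constant-strain tetrahedron stiffness, assembled
#' into a sparse symmetric matrix with 3 displacement DOFs per node.
#'
#' @param model a [tet_model()].
#' @param materials a [material_spec()].
#' @return a `dgCMatrix` of dimension `3n x 3n`.
#' @export
assemble_stiffness <- function(model, materials) {
  grads <- tet_gradients(model$nodes, model$elements)
  lam <- lame_constants(model, materials)
  m <- nrow(model$elements)
  V <- grads$volumes
  nnz_block <- m * 9L
  total <- nnz_block * 16L
  ii <- integer(total); jj <- integer(total); xx <- numeric(total)
  pos <- 0L
  for (a in 1:4) {
    ga <- grads$g[[a]]
    rows_base <- 3L * (model$elements[, a] - 1L)
    for (b in 1:4) {
      gb <- grads$g[[b]]
      cols_base <- 3L * (model$elements[, b] - 1L)
      gagb <- rowSums(ga * gb)
      for (i in 1:3) {
        for (j in 1:3) {
          val <- V * (lam$lambda * ga[, i] * gb[, j] +
                        lam$mu * ga[, j] * gb[, i] +
                        (if (i == j) lam$mu * gagb else 0))
          idx <- pos + seq_len(m)
          ii[idx] <- rows_base + i
          jj[idx] <- cols_base + j
          xx[idx] <- val
          pos <- pos + m
        }
      }
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(3L * nrow(model$nodes), 3L * nrow(model$nodes)))
}

#' Von Mises equivalent stress
#'
#' Computed from the second deviatoric invariant,
#' \eqn{\sqrt{\tfrac12[(\sigma_1-\sigma_2)^2 + (\sigma_2-\sigma_3)^2 +
#' (\sigma_3-\sigma_1)^2]}}.
#'
#' @param stress a symmetric `3 x 3` tensor, a 6-vector, or an `n x 6`
#'   matrix with columns `(xx, yy, zz, xy, yz, zx)` (MPa).
#' @return Von Mises stress (MPa), one value per tensor.
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress) && nrow(stress) == 3L && ncol(stress) == 3L) {
    if (max(abs(stress - t(stress))) > 1e-8 * max(1, max(abs(stress))))
      stop("stress tensor must be symmetric", call. = FALSE)
    stress <- c(stress[1L, 1L], stress[2L, 2L], stress[3L, 3L],
                stress[1L, 2L], stress[2L, 3L], stress[3L, 1L])
  }
  s <- as_point_matrix(stress, 6L)
  as.numeric(sqrt(0.5 * ((s[, 1L] - s[, 2L])^2 + (s[, 2L] - s[, 3L])^2 +
                           (s[, 3L] - s[, 1L])^2) +
                    3 * (s[, 4L]^2 + s[, 5L]^2 + s[, 6L]^2)))
}

#' Solve the linear elastic problem
#'
#' Assembles the sparse symmetric stiffness, applies homogeneous Dirichlet
#' constraints on all three DOFs of the fixed nodes, solves by sparse
#' Cholesky factorization, and evaluates element-centroid strains, stresses,
#' Von Mises and sorted principal stresses, plus the reaction forces at the
#' fixed nodes.
#'
#' @param model a [tet_model()].
#' @param materials a [material_spec()].
#' @param load a `load_case` from [build_load_case()], or an `n x 3` nodal
#'   force matrix (N).
#' @param fixed integer node indices to constrain (defaults to the model's
#'   `distal_fixed` node set).
#' @param fixed_values optional `length(fixed) x 3` matrix of prescribed
#'   displacements (mm) at the fixed nodes; zero when omitted.
#' @return an object of class `stress_field`: `displacements` (n x 3, mm),
#'   `stress` (m x 6, MPa), `von_mises`, `principal` (m x 3, descending),
#'   `reactions` (n x 3, N; nonzero at fixed nodes), `strain_energy`,
#'   `external_work` (N mm), and solve metadata.
#' @export
assemble_and_solve <- function(model, materials = material_spec(), load,
                               fixed = NULL, fixed_values = NULL,
                               system = NULL) {
  stopifnot(inherits(model, "tet_model"))
  if (is.null(fixed)) fixed <- model$node_sets$distal_fixed
  if (!is.null(system)) fixed <- system$fixed
  if (is.null(fixed) || length(fixed) == 0L)
    stop("rigid-body-mode error: no fixed nodes given", call. = FALSE)
  n <- nrow(model$nodes)
  f <- matrix(0, n, 3L)
  extra <- NULL
  if (inherits(load, "load_case")) {
    f[load$nodes, ] <- f[load$nodes, , drop = FALSE] + load$forces
    extra <- load$extra
  } else if (is.matrix(load)) {
    if (nrow(load) != n) stop("nodal force matrix must be n x 3", call. = FALSE)
    f <- load
  } else stop("load must be a load_case or an n x 3 matrix", call. = FALSE)
  if (!is.null(extra)) {
    for (ex in extra) {
      ids <- as.integer(ex$nodes)
      per <- matrix(as.numeric(ex$force), length(ids), 3L, byrow = TRUE) / length(ids)
      f[ids, ] <- f[ids, , drop = FALSE] + per
    }
  }
  if (is.null(system)) system <- fe_system(model, materials, fixed)
  K <- system$K
  free <- system$free; fixed_dofs <- system$fixed_dofs
  fvec <- as.numeric(t(f))                      # DOF order (x1,y1,z1,x2,...)
  u <- numeric(3L * n)
  rhs <- fvec[free]
  if (!is.null(fixed_values)) {
    uc <- as.numeric(t(as_point_matrix(fixed_values, 3L)))
    if (length(uc) != length(fixed_dofs))
      stop("fixed_values must be length(fixed) x 3", call. = FALSE)
    u[fixed_dofs] <- uc
    rhs <- rhs - as.numeric(K[free, fixed_dofs, drop = FALSE] %*% uc)
  }
  u[free] <- as.numeric(Matrix::solve(system$chol, rhs))
  reactions_vec <- as.numeric(K %*% u) - fvec
  U <- matrix(u, ncol = 3L, byrow = TRUE)
  Rm <- matrix(reactions_vec, ncol = 3L, byrow = TRUE)
  Rm[setdiff(seq_len(n), fixed), ] <- 0         # clamp roundoff off the supports
  field <- element_stresses(model, materials, U)
  structure(list(displacements = U, stress = field$stress,
                 von_mises = field$von_mises, principal = field$principal,
                 reactions = Rm, applied = f,
                 strain_energy = 0.5 * sum(u * as.numeric(K %*% u)),
                 external_work = sum(fvec * u),
                 fixed_nodes = as.integer(fixed),
                 element_centroids = tet_centroids(model),
                 metadata = list(element_type = "C3D4",
                                 solver = "sparse Cholesky",
                                 coupling = "distributed tributary-area nodal forces")),
            class = "stress_field")
}

element_stresses <- function(model, materials, U) {
  grads <- tet_gradients(model$nodes, model$elements)
  lam <- lame_constants(model, materials)
  m <- nrow(model$elements)
  exx <- eyy <- ezz <- exy <- eyz <- ezx <- numeric(m)
  for (a in 1:4) {
    g <- grads$g[[a]]
    ua <- U[model$elements[, a], , drop = FALSE]
    exx <- exx + g[, 1L] * ua[, 1L]
    eyy <- eyy + g[, 2L] * ua[, 2L]
    ezz <- ezz + g[, 3L] * ua[, 3L]
    exy <- exy + 0.5 * (g[, 2L] * ua[, 1L] + g[, 1L] * ua[, 2L])
    eyz <- eyz + 0.5 * (g[, 3L] * ua[, 2L] + g[, 2L] * ua[, 3L])
    ezx <- ezx + 0.5 * (g[, 1L] * ua[, 3L] + g[, 3L] * ua[, 1L])
  }
  tr <- exx + eyy + ezz
  stress <- cbind(xx = lam$lambda * tr + 2 * lam$mu * exx,
                  yy = lam$lambda * tr + 2 * lam$mu * eyy,
                  zz = lam$lambda * tr + 2 * lam$mu * ezz,
                  xy = 2 * lam$mu * exy,
                  yz = 2 * lam$mu * eyz,
                  zx = 2 * lam$mu * ezx)
  list(stress = stress, von_mises = von_mises(stress),
       principal = symmetric3_eigenvalues(stress))
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf("stress_field: %d nodes, %d elements (%s)\n",
              nrow(x$displacements), nrow(x$stress), x$metadata$element_type))
  cat(sprintf("  max |u| %.4g mm, max Von Mises %.4g MPa\n",
              max(sqrt(rowSums(x$displacements^2))), max(x$von_mises)))
  res <- colSums(x$reactions) + colSums(x$applied)
  cat(sprintf("  equilibrium residual (N): (%.3g, %.3g, %.3g)\n",
              res[1L], res[2L], res[3L]))
  invisible(x)
}

# Boundary faces (appearing in exactly one element) of a tet model.
# Returns the face node triples, the owning element, and face areas.
boundary_faces <- function(model) {
  el <- model$elements
  faces <- rbind(el[, c(1L, 3L, 2L)], el[, c(1L, 2L, 4L)],
                 el[, c(2L, 3L, 4L)], el[, c(1L, 4L, 3L)])
  owner <- rep.int(seq_len(nrow(el)), 4L)
  key <- paste(pmin.int(faces[, 1L], faces[, 2L], faces[, 3L]),
               faces[, 1L] + faces[, 2L] + faces[, 3L] -
                 pmin.int(faces[, 1L], faces[, 2L], faces[, 3L]) -
                 pmax.int(faces[, 1L], faces[, 2L], faces[, 3L]),
               pmax.int(faces[, 1L], faces[, 2L], faces[, 3L]), sep = "-")
  cnt <- table(key)
  keep <- cnt[key] == 1L
  faces <- faces[keep, , drop = FALSE]
  list(faces = faces, owner = owner[keep],
       areas = triangle_areas(model$nodes, faces),
       centroids = triangle_centroids(model$nodes, faces))
}

#' Build a loading case with resolved nodal forces
#'
#' Distributes the total joint reaction force over the loading region:
#' case `A_patch` over the quantified weight-bearing patch (resolved on the
#' volume-mesh boundary by the patch's own half-space tests), case
#' `B_circle` over a circular region of given diameter at the top of the
#' femoral head, case `C_point` onto the single apex node. For A and B the
#' nodal forces are tributary-area weighted (each boundary facet assigns a
#' third of its area to each of its nodes) along the force direction; the
#' nodal forces sum to the total force exactly.
#'
#' @param model a [tet_model()].
#' @param kind `"A_patch"`, `"B_circle"` or `"C_point"`.
#' @param total_force 3-vector, N.
#' @param params case parameters: for A, `patch` (a `wba_patch`) or
#'   `provenance` + `head` (centre/radius); for B, optionally `center` (3D,
#'   defaults to the head apex node) and `diameter_mm` (default 20); for C,
#'   optionally `node` (defaults to the `head_apex` node set). `tol_mm`
#'   controls how close to the head sphere a boundary facet must be to
#'   belong to the articular surface (default: half the voxel size if
#'   known, else 1.5 mm). `extra` is an optional list of muscle-force point
#'   loads, each `list(nodes=, force=)` (the force vector is split evenly
#'   over the nodes).
#' @return an object of class `load_case` with `nodes`, `forces`
#'   (length(nodes) x 3, N), `region_faces`, and metadata.
#' @export
build_load_case <- function(model, kind = c("A_patch", "B_circle", "C_point"),
                            total_force, params = list()) {
  kind <- match.arg(kind)
  total_force <- as.numeric(total_force)
  if (vec_norm(total_force) <= 0)
    stop("total force must be nonzero", call. = FALSE)
  tol <- params$tol_mm %||% (if (!is.null(model$voxel_size)) 0.75 * model$voxel_size else 1.5)
  if (kind == "C_point") {
    node <- params$node %||% model$node_sets$head_apex
    if (is.null(node) || length(node) != 1L)
      stop("region error: no apex node identified for case C", call. = FALSE)
    return(structure(list(kind = kind, total_force = total_force,
                          nodes = as.integer(node),
                          forces = matrix(total_force, 1L, 3L),
                          region_faces = NULL, extra = params$extra,
                          metadata = list(coupling = "single-node point load")),
                     class = "load_case"))
  }
  bf <- boundary_faces(model)
  if (kind == "A_patch") {
    patch <- params$patch
    provenance <- params$provenance %||% patch$provenance
    head <- params$head %||% patch$head
    if (is.null(provenance) || is.null(head))
      stop("region error: case A needs a patch (or its provenance and head fit)",
           call. = FALSE)
    on_head <- abs(sqrt(rowSums(sweep(bf$centroids, 2L, head$center)^2)) -
                     head$radius) <= tol
    keep <- on_head & patch_membership(bf$centroids, provenance)
    if (!any(keep))
      stop("region error: patch region resolves to no boundary facets", call. = FALSE)
  } else {
    anatomy <- model$anatomy
    center <- params$center
    if (is.null(center)) {
      apex <- model$node_sets$head_apex
      if (is.null(apex))
        stop("region error: no circle centre and no head_apex node set", call. = FALSE)
      center <- model$nodes[apex, ]
    }
    diameter <- params$diameter_mm %||% 20
    within <- sqrt(rowSums(sweep(bf$centroids, 2L, as.numeric(center))^2)) <=
      diameter / 2
    if (!is.null(anatomy)) {
      on_head <- abs(sqrt(rowSums(sweep(bf$centroids, 2L, anatomy$head_center)^2)) -
                       anatomy$head_radius) <= tol
      within <- within & on_head
    }
    keep <- within
    if (!any(keep))
      stop("region error: circular region resolves to no boundary facets",
           call. = FALSE)
  }
  faces <- bf$faces[keep, , drop = FALSE]
  areas <- bf$areas[keep]
  w <- numeric(nrow(model$nodes))
  for (cix in 1:3) {
    acc <- tapply(areas / 3, faces[, cix], sum)
    ids <- as.integer(names(acc))
    w[ids] <- w[ids] + as.numeric(acc)
  }
  nodes <- which(w > 0)
  wn <- w[nodes] / sum(w[nodes])
  structure(list(kind = kind, total_force = total_force, nodes = nodes,
                 forces = outer(wn, total_force), region_faces = faces,
                 region_area = sum(areas), extra = params$extra,
                 metadata = list(coupling = "distributed tributary-area nodal forces")),
            class = "load_case")
}

#' @export
print.load_case <- function(x, ...) {
  cat(sprintf("load_case %s: total force (%.1f, %.1f, %.1f) N over %d node(s)",
              x$kind, x$total_force[1L], x$total_force[2L], x$total_force[3L],
              length(x$nodes)))
  if (!is.null(x$region_area)) cat(sprintf(", region area %.1f mm^2", x$region_area))
  cat("\n")
  invisible(x)
}

#' Sample stresses along a straight path (path alpha)
#'
#' Samples the straight segment from the start to the end node at
#' `n_samples` arc-length-uniform stations (station k at fraction
#' `(k - 1/2)/n`), reporting the nearest-centroid element's principal
#' stresses and Von Mises at each station, ordered by arc length.
#'
#' @param field a [assemble_and_solve()] result.
#' @param model the [tet_model()].
#' @param start_node,end_node node indices (e.g. head apex and head-neck
#'   junction).
#' @param n_samples number of stations (default 12).
#' @return an object of class `stress_path`: a data frame with columns
#'   `station`, `arc_mm`, `element`, `s1`, `s2`, `s3`, `von_mises`, plus the
#'   endpoints.
#' @export
extract_path <- function(field, model, start_node, end_node, n_samples = 12L) {
  stopifnot(inherits(field, "stress_field"), inherits(model, "tet_model"))
  a <- model$nodes[start_node, ]; b <- model$nodes[end_node, ]
  L <- vec_norm(b - a)
  if (L < 1e-9) stop("path endpoints coincide", call. = FALSE)
  t_frac <- (seq_len(n_samples) - 0.5) / n_samples
  stations <- sweep(outer(t_frac, b - a), 2L, a, "+")
  cent <- field$element_centroids
  elem <- vapply(seq_len(n_samples), function(k) {
    which.min(rowSums(sweep(cent, 2L, stations[k, ])^2))
  }, integer(1))
  df <- data.frame(station = seq_len(n_samples), arc_mm = t_frac * L,
                   element = elem,
                   s1 = field$principal[elem, 1L],
                   s2 = field$principal[elem, 2L],
                   s3 = field$principal[elem, 3L],
                   von_mises = field$von_mises[elem])
  structure(list(samples = df, start_node = start_node, end_node = end_node,
                 length_mm = L),
            class = "stress_path")
}

#' @export
print.stress_path <- function(x, ...) {
  cat(sprintf("stress_path: %d stations over %.1f mm\n",
              nrow(x$samples), x$length_mm))
  print(x$samples, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.stress_path <- function(x, component = c("s3", "s1", "von_mises"), ...) {
  component <- match.arg(component)
  graphics::plot(x$samples$arc_mm, x$samples[[component]], type = "b",
                 xlab = "arc length (mm)", ylab = paste(component, "(MPa)"), ...)
  invisible(x)
}

#' Compare the three loading cases
#'
#' Runs the solver for each supplied case, reports the per-case maximum
#' cortical Von Mises stress and its element location (excluding a
#' Saint-Venant zone near the fixed nodes, where a fully clamped boundary
#' produces artificial concentrations), the path-alpha stress profiles side
#' by side, and the qualitative classifier contrasting a peak inside the
#' loaded region with a peak at the neck-body junction.
#'
#' @param model a [tet_model()].
#' @param materials a [material_spec()].
#' @param cases named list of `load_case` objects (typically `A`, `B`, `C`).
#' @param fixed fixed node indices (default: `distal_fixed` node set).
#' @param path optional list with `start`, `end` node indices for path
#'   alpha; when the model carries its generating anatomy the default runs
#'   from the head apex to the head-neck junction.
#' @param n_samples stations along the path (default 12).
#' @param exclude_mm exclusion distance from fixed nodes for peak reporting
#'   (default 3 voxel edges when known, else 7.5 mm).
#' @return an object of class `fe_comparison`: per-case summaries, a
#'   combined path table, and equilibrium residuals.
#' @export
compare_load_cases <- function(model, materials = material_spec(), cases,
                               fixed = NULL, path = NULL, n_samples = 12L,
                               exclude_mm = NULL) {
  stopifnot(inherits(model, "tet_model"), length(cases) >= 1L)
  if (is.null(fixed)) fixed <- model$node_sets$distal_fixed
  if (is.null(exclude_mm))
    exclude_mm <- if (!is.null(model$voxel_size)) 3 * model$voxel_size else 7.5
  if (is.null(path)) path <- default_path_alpha(model)
  cent <- tet_centroids(model)
  fixed_xyz <- model$nodes[fixed, , drop = FALSE]
  # distance from each element centroid to the nearest fixed node (coarse:
  # to the fixed-region bounding z-slab, adequate for a distal cut plane)
  zmax_fixed <- max(fixed_xyz[, 3L])
  near_fixed <- cent[, 3L] <= zmax_fixed + exclude_mm
  cortical <- model$labels == "cortical"
  eligible <- cortical & !near_fixed
  if (!any(eligible)) eligible <- cortical
  system <- fe_system(model, materials, fixed)
  results <- list()
  path_tables <- list()
  for (nm in names(cases)) {
    lc <- cases[[nm]]
    field <- assemble_and_solve(model, materials, lc, fixed, system = system)
    vm <- field$von_mises
    peak_elem <- which(eligible)[which.max(vm[eligible])]
    peak <- list(element = peak_elem, von_mises = vm[peak_elem],
                 location = cent[peak_elem, ])
    if (!is.null(lc$nodes) && length(lc$nodes)) {
      loaded_xyz <- model$nodes[lc$nodes, , drop = FALSE]
      d_loaded <- sqrt(min(rowSums(sweep(loaded_xyz, 2L, peak$location)^2)))
    } else d_loaded <- NA_real_
    d_junction <- if (!is.null(path)) {
      vec_norm(peak$location - model$nodes[path$end, ])
    } else NA_real_
    classifier <- if (!is.na(d_loaded) && !is.na(d_junction) &&
                      d_loaded <= d_junction) {
      "peak within loaded region"
    } else "peak at neck-body junction"
    res <- colSums(field$reactions) + colSums(field$applied)
    sp <- if (!is.null(path))
      extract_path(field, model, path$start, path$end, n_samples) else NULL
    results[[nm]] <- list(case = nm, kind = lc$kind, field = field, peak = peak,
                          distance_to_loaded_mm = d_loaded,
                          distance_to_junction_mm = d_junction,
                          classifier = classifier,
                          equilibrium_residual_N = res,
                          path = sp)
    if (!is.null(sp)) {
      tb <- sp$samples; tb$case <- nm
      path_tables[[nm]] <- tb
    }
  }
  structure(list(cases = results,
                 path_table = if (length(path_tables))
                   do.call(rbind, path_tables) else NULL,
                 path = path, exclude_mm = exclude_mm),
            class = "fe_comparison")
}

# Default path alpha on a generated femur: head apex node down to the
# head-neck junction node (the sphere-neck intersection centre), taken from
# the model's node sets, or recomputed from the generating anatomy.
default_path_alpha <- function(model) {
  apex <- model$node_sets$head_apex
  if (is.null(apex)) return(NULL)
  end <- model$node_sets$head_neck_junction
  if (is.null(end)) {
    anat <- model$anatomy
    if (is.null(anat)) return(NULL)
    fr <- femur_frame(anat)
    jc <- anat$head_center +
      sqrt(anat$head_radius^2 - anat$neck_radius^2) * fr$u_neck
    if (anat$side == "left") jc[1L] <- 2 * anat$head_center[1L] - jc[1L]
    end <- which.min(rowSums(sweep(model$nodes, 2L, jc)^2))
  }
  list(start = as.integer(apex[1L]), end = as.integer(end[1L]))
}

#' @export
print.fe_comparison <- function(x, ...) {
  cat("fe_comparison:\n")
  for (r in x$cases) {
    cat(sprintf("  case %s (%s): max cortical Von Mises %.3f MPa at (%.1f, %.1f, %.1f) mm -- %s\n",
                r$case, r$kind, r$peak$von_mises, r$peak$location[1L],
                r$peak$location[2L], r$peak$location[3L], r$classifier))
    cat(sprintf("    equilibrium residual %.3g N\n",
                vec_norm(r$equilibrium_residual_N)))
  }
  invisible(x)
}

#' @export
plot.fe_comparison <- function(x, component = "s3", ...) {
  if (is.null(x$path_table)) {
    warning("no path data to plot"); return(invisible(x))
  }
  tb <- x$path_table
  cases <- unique(tb$case)
  cols <- grDevices::hcl.colors(max(3L, length(cases)), "Dark 3")
  graphics::plot(range(tb$arc_mm), range(tb[[component]]), type = "n",
                 xlab = "arc length along path (mm)",
                 ylab = paste(component, "(MPa)"), ...)
  for (k in seq_along(cases)) {
    sub <- tb[tb$case == cases[k], ]
    graphics::lines(sub$arc_mm, sub[[component]], type = "b", col = cols[k],
                    pch = 16)
  }
  graphics::legend("topright", legend = cases, col = cols[seq_along(cases)],
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}
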