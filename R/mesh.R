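#' Triangulated surface mesh
#'
#' Constructs a `surface_mesh`: an indexed triangle mesh in millimetres with a
#' tagged coordinate frame. The package-wide frame convention is
#' `x` medial-lateral, `y` anterior-posterior (the AP projection direction) and
#' `z` inferior-superior, with `+x` medial (for a right hip), `+y` anterior and
#' `+z` superior.
#'
#' @param vertices numeric `n x 3` matrix of vertex coordinates (mm).
#' @param triangles integer `m x 3` matrix of 1-based vertex indices, oriented
#'   counter-clockwise seen from outside.
#' @param frame character tag describing the coordinate frame.
#' @param head_vertices optional integer vector: indices of vertices lying on
#'   the femoral-head sphere (used to seed the sphere fit downstream).
#' @param validate check index validity and reject degenerate triangles.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles,
                         frame = "x: medial-lateral, y: anterior-posterior, z: inferior-superior",
                         head_vertices = NULL, validate = TRUE) {
  vertices <- as_point_matrix(vertices, 3L)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L)
  if (validate) {
    if (nrow(triangles) > 0L) {
      rng <- range(triangles)
      if (rng[1L] < 1L || rng[2L] > nrow(vertices))
        stop("triangle indices out of range", call. = FALSE)
      areas <- triangle_areas(vertices, triangles)
      scale <- max(1e-12, max(abs(vertices)))
      if (any(areas <= 1e-10 * scale^2))
        stop("degenerate (zero-area) triangles present", call. = FALSE)
    }
    if (!is.null(head_vertices)) {
      head_vertices <- as.integer(head_vertices)
      if (length(head_vertices) && (min(head_vertices) < 1L ||
                                    max(head_vertices) > nrow(vertices)))
        stop("head_vertices indices out of range", call. = FALSE)
    }
  }
  structure(list(vertices = vertices, triangles = triangles, frame = frame,
                 head_vertices = head_vertices),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  cat("  frame:", x$frame, "\n")
  if (!is.null(x$head_vertices))
    cat(sprintf("  head-sphere vertex tag: %d vertices\n", length(x$head_vertices)))
  invisible(x)
}

#' Total surface area of a mesh
#' @param mesh a `surface_mesh`.
#' @return total triangle area (mm^2).
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$triangles) == 0L) return(0)
  sum(triangle_areas(mesh$vertices, mesh$triangles))
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem volume; positive when triangle winding gives outward
#' normals. Meaningful only for (a union of) closed surfaces.
#' @param mesh a `surface_mesh`.
#' @return signed volume (mm^3).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1L], , drop = FALSE]
  b <- v[tr[, 2L], , drop = FALSE]
  cc <- v[tr[, 3L], , drop = FALSE]
  sum(rowSums(a * cross3_rows(b, cc))) / 6
}

#' Latitude-longitude sphere mesh
#'
#' UV sphere triangulation used as an analytic test surface and as the head
#' component of the parametric femur. Poles along `axis`.
#'
#' @param center sphere centre (3-vector, mm).
#' @param radius sphere radius (mm).
#' @param n_lat number of latitude bands (>= 3).
#' @param n_lon number of longitude segments (>= 3).
#' @param axis polar axis (defaults to +z).
#' @param theta_range polar-angle interval `[min, max]` in radians measured
#'   from `axis`; the default spans the full sphere. Open caps are left
#'   unfilled when the range does not reach a pole.
#' @return a `surface_mesh`; every vertex lies exactly on the sphere.
#' @export
uv_sphere_mesh <- function(center = c(0, 0, 0), radius = 1,
                           n_lat = 48L, n_lon = 64L, axis = c(0, 0, 1),
                           theta_range = c(0, pi)) {
  stopifnot(radius > 0, n_lat >= 3L, n_lon >= 3L)
  axis <- unitize(axis)
  basis <- orthonormal_basis(axis)
  th0 <- theta_range[1L]; th1 <- theta_range[2L]
  stopifnot(th0 >= 0, th1 <= pi, th1 > th0)
  pole0 <- th0 <= 1e-12
  pole1 <- th1 >= pi - 1e-12
  thetas <- seq(th0, th1, length.out = n_lat + 1L)
  ring_thetas <- thetas
  if (pole0) ring_thetas <- ring_thetas[-1L]
  if (pole1) ring_thetas <- ring_thetas[-length(ring_thetas)]
  phis <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  ring_pts <- function(theta) {
    st <- sin(theta); ct <- cos(theta)
    sweep(radius * (st * outer(cos(phis), basis$u) + st * outer(sin(phis), basis$v) +
                      ct * matrix(axis, n_lon, 3L, byrow = TRUE)),
          2L, center, "+")
  }
  verts <- do.call(rbind, lapply(ring_thetas, ring_pts))
  ring_index <- function(i) (i - 1L) * n_lon + seq_len(n_lon)  # i-th ring block
  n_rings <- length(ring_thetas)
  tris <- list()
  offset <- 0L
  if (pole0) {
    verts <- rbind(center + radius * axis, verts)
    offset <- 1L
    r1 <- ring_index(1L) + offset
    tris[[length(tris) + 1L]] <-
      cbind(rep(1L, n_lon), r1, r1[c(2:n_lon, 1L)])
  }
  for (i in seq_len(n_rings - 1L)) {
    a <- ring_index(i) + offset
    b <- ring_index(i + 1L) + offset
    an <- a[c(2:n_lon, 1L)]; bn <- b[c(2:n_lon, 1L)]
    tris[[length(tris) + 1L]] <- rbind(cbind(a, b, bn), cbind(a, bn, an))
  }
  if (pole1) {
    verts <- rbind(verts, center - radius * axis)
    pole_id <- nrow(verts)
    r_last <- ring_index(n_rings) + offset
    tris[[length(tris) + 1L]] <-
      cbind(r_last, rep(pole_id, n_lon), r_last[c(2:n_lon, 1L)])
  }
  surface_mesh(verts, do.call(rbind, tris))
}

# Two unit vectors completing `axis` to a right-handed orthonormal frame.
orthonormal_basis <- function(axis) {
  axis <- unitize(axis)
  helper <- if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(cross3(helper, axis))
  v <- cross3(axis, u)
  list(u = u, v = v)
}

# Open cylinder wall between two rings of n points; returns mesh pieces to be
# assembled by the caller. `ring_a`, `ring_b`: n x 3 matrices in matching
# angular order; triangles oriented so outward normals point away from the
# axis when ring_a is "proximal" and ordering is counter-clockwise about it.
cylinder_wall_triangles <- function(idx_a, idx_b) {
  n <- length(idx_a)
  an <- idx_a[c(2:n, 1L)]; bn <- idx_b[c(2:n, 1L)]
  rbind(cbind(idx_a, idx_b, bn), cbind(idx_a, bn, an))
}

disk_fan_triangles <- function(center_idx, ring_idx, flip = FALSE) {
  n <- length(ring_idx)
  nxt <- ring_idx[c(2:n, 1L)]
  if (flip) cbind(rep(center_idx, n), nxt, ring_idx)
  else cbind(rep(center_idx, n), ring_idx, nxt)
}
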