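# 2D-3D linkage: orthogonal projection of the mesh onto the coronal datum
# plane, closed-form planar similarity registration between the projected
# mesh landmarks and the radiograph landmarks, and lifting of radiograph
# constructions back onto the datum plane in 3D.

#' Coronal datum plane
#'
#' The plane onto which the mesh is projected and radiograph constructions
#' are lifted. The default is the canonical coronal plane through the origin:
#' normal `+y` (the AP projection direction), in-plane basis `(x, z)`.
#'
#' @param origin 3D point on the plane (mm).
#' @param normal plane normal = projection direction; normalized internally.
#' @param basis optional `2 x 3` matrix whose rows are the in-plane basis
#'   vectors; must be orthonormal and orthogonal to `normal`. Derived
#'   automatically when omitted.
#' @return an object of class `datum_plane`.
#' @export
datum_plane <- function(origin = c(0, 0, 0), normal = c(0, 1, 0), basis = NULL) {
  normal <- unitize(as.numeric(normal))
  if (is.null(basis)) {
    if (isTRUE(all.equal(normal, c(0, 1, 0)))) {
      basis <- rbind(c(1, 0, 0), c(0, 0, 1))   # canonical coronal: (x, z)
    } else {
      b <- orthonormal_basis(normal)
      basis <- rbind(b$u, b$v)
    }
  } else {
    basis <- as_point_matrix(basis, 3L)
    if (nrow(basis) != 2L) stop("basis must be a 2 x 3 matrix", call. = FALSE)
    g <- basis %*% t(basis)
    if (max(abs(g - diag(2))) > 1e-9 || max(abs(basis %*% normal)) > 1e-9)
      stop("basis must be orthonormal and orthogonal to the normal", call. = FALSE)
  }
  structure(list(origin = as.numeric(origin), normal = normal, basis = basis),
            class = "datum_plane")
}

#' Orthogonal projection onto a datum plane
#'
#' Projects 3D points along `plane$normal` and expresses them in the plane's
#' in-plane basis. The normal component is discarded, so adding any multiple
#' of the normal to a point does not change its projection.
#'
#' @param points 3D point or `n x 3` matrix (mm).
#' @param plane a [datum_plane()].
#' @return `n x 2` matrix of in-plane coordinates (mm).
#' @export
project_to_plane <- function(points, plane = datum_plane()) {
  stopifnot(inherits(plane, "datum_plane"))
  points <- as_point_matrix(points, 3L)
  rel <- sweep(points, 2L, plane$origin)
  rel %*% t(plane$basis)
}

# Embed in-plane 2D coordinates back into 3D on the plane.
plane_to_3d <- function(points2, plane) {
  points2 <- as_point_matrix(points2, 2L)
  sweep(points2 %*% plane$basis, 2L, plane$origin, "+")
}

#' Planar similarity registration parameters
#'
#' In-plane transform `T(x) = scale * R(rotation) x + translation` linking
#' the projected-mesh frame (source) to the radiograph frame (target).
#'
#' @param rotation_deg in-plane rotation (degrees, counter-clockwise).
#' @param translation 2-vector (mm).
#' @param scale positive scale factor.
#' @param rms_error root-mean-square residual over the correspondences (mm).
#' @param correspondences character vector of landmark names used.
#' @param residuals optional named per-point residual lengths (mm).
#' @return an object of class `planar_registration`.
#' @export
planar_registration <- function(rotation_deg = 0, translation = c(0, 0),
                                scale = 1, rms_error = 0,
                                correspondences = character(0),
                                residuals = NULL) {
  if (!(scale > 0)) stop("scale must be positive", call. = FALSE)
  if (rms_error < 0) stop("rms_error must be non-negative", call. = FALSE)
  structure(list(rotation_deg = rotation_deg,
                 translation = as.numeric(translation), scale = scale,
                 rms_error = rms_error, correspondences = correspondences,
                 residuals = residuals),
            class = "planar_registration")
}

#' @export
print.planar_registration <- function(x, ...) {
  cat(sprintf("planar_registration: rotation %.4f deg, translation (%.3f, %.3f) mm, scale %.6f\n",
              x$rotation_deg, x$translation[1L], x$translation[2L], x$scale))
  cat(sprintf("  rms error %.4g mm over %d correspondences\n",
              x$rms_error, length(x$correspondences)))
  invisible(x)
}

registration_matrix <- function(reg) {
  a <- deg2rad(reg$rotation_deg)
  reg$scale * rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
}

#' Apply a planar registration to 2D points
#' @param reg a [planar_registration()].
#' @param points 2D point or `n x 2` matrix.
#' @return transformed `n x 2` matrix.
#' @export
apply_registration <- function(reg, points) {
  points <- as_point_matrix(points, 2L)
  sweep(points %*% t(registration_matrix(reg)), 2L, reg$translation, "+")
}

#' Invert a planar registration
#' @param reg a [planar_registration()].
#' @return the inverse transform as a [planar_registration()].
#' @export
invert_registration <- function(reg) {
  Rinv <- t(registration_matrix(reg)) / reg$scale^2   # (sR)^-1 = R^T / s
  planar_registration(rotation_deg = -reg$rotation_deg,
                      translation = as.numeric(-Rinv %*% reg$translation),
                      scale = 1 / reg$scale,
                      rms_error = reg$rms_error,
                      correspondences = reg$correspondences)
}

#' Least-squares planar similarity registration on named landmarks
#'
#' Closed-form (Procrustes/Umeyama) estimate of the in-plane similarity (or
#' rigid, with `allow_scale = FALSE`) transform minimizing
#' \eqn{\sum_i \|T(x_i) - y_i\|^2} over the landmark names shared by source
#' and target. This replaces the manual visual overlay of mesh and radiograph
#' with a reproducible algorithmic registration.
#'
#' @param source_2d,target_2d named 2D point matrices (row names are landmark
#'   names); typically the projected-mesh landmarks (source) and the
#'   magnification-corrected radiograph landmarks (target).
#' @param allow_scale estimate a scale factor (default) or fix scale = 1.
#' @param names optional character vector restricting the correspondences.
#' @return a [planar_registration()] with the RMS residual and per-point
#'   residuals over the correspondences used.
#' @export
register_landmarks <- function(source_2d, target_2d, allow_scale = TRUE,
                               names = NULL) {
  source_2d <- as_point_matrix(as.matrix(source_2d), 2L)
  target_2d <- as_point_matrix(as.matrix(target_2d), 2L)
  sn <- rownames(source_2d); tn <- rownames(target_2d)
  if (is.null(sn) || is.null(tn))
    stop("source and target points must be named", call. = FALSE)
  if (anyDuplicated(sn) || anyDuplicated(tn))
    stop("duplicate landmark names", call. = FALSE)
  shared <- intersect(sn, tn)
  if (!is.null(names)) shared <- intersect(shared, names)
  if (length(shared) < 2L)
    stop("insufficient data: need at least 2 shared landmark names", call. = FALSE)
  X <- source_2d[shared, , drop = FALSE]
  Y <- target_2d[shared, , drop = FALSE]
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx); Yc <- sweep(Y, 2L, my)
  var_x <- sum(Xc^2)
  if (var_x < 1e-20)
    stop("degenerate data: all source points coincide", call. = FALSE)
  S <- crossprod(Yc, Xc)            # 2x2 covariance
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, d))
  Rm <- sv$u %*% D %*% t(sv$v)
  s <- if (allow_scale) sum(diag(D) * sv$d) / var_x else 1
  t_vec <- my - s * as.numeric(Rm %*% mx)
  fitted <- sweep(s * X %*% t(Rm), 2L, t_vec, "+")
  res <- sqrt(rowSums((fitted - Y)^2))
  planar_registration(rotation_deg = rad2deg(atan2(Rm[2L, 1L], Rm[1L, 1L])),
                      translation = t_vec, scale = s,
                      rms_error = sqrt(mean(res^2)),
                      correspondences = shared,
                      residuals = stats::setNames(res, shared))
}

#' 3D line on a datum plane
#' @param point 3D anchor point (on the plane).
#' @param direction 3D unit direction (in the plane).
#' @return object of class `line3d`.
#' @export
line3d <- function(point, direction) {
  structure(list(point = as.numeric(point),
                 direction = unitize(as.numeric(direction))),
            class = "line3d")
}

#' Lift a radiograph line onto the 3D datum plane
#'
#' Applies the inverse registration to express a radiograph-frame 2D line in
#' the mesh-projection frame, then embeds it in 3D via the datum plane basis.
#' The lifted line lies exactly in the plane.
#'
#' @param line a [line2d()] in the radiograph frame.
#' @param reg the [planar_registration()] mapping mesh-projection to
#'   radiograph coordinates.
#' @param plane the [datum_plane()].
#' @return a [line3d()] in the plane.
#' @export
lift_line <- function(line, reg, plane = datum_plane()) {
  stopifnot(inherits(line, "line2d"), inherits(reg, "planar_registration"),
            inherits(plane, "datum_plane"))
  inv <- invert_registration(reg)
  p0 <- as.numeric(apply_registration(inv, line$anchor))
  Rinv <- registration_matrix(inv)
  d0 <- unitize(as.numeric(Rinv %*% line$direction))
  line3d(as.numeric(plane_to_3d(p0, plane)),
         as.numeric(d0 %*% plane$basis))
}

# Project a 3D line lying in the plane back to a 2D line in the radiograph
# frame (inverse of lift_line); used for round-trip checks.
project_line <- function(line3, reg, plane = datum_plane()) {
  p2 <- as.numeric(project_to_plane(line3$point, plane))
  d2 <- as.numeric(plane$basis %*% line3$direction)
  p2t <- as.numeric(apply_registration(reg, p2))
  d2t <- as.numeric(registration_matrix(reg) %*% d2)
  line2d(p2t, d2t)
}
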