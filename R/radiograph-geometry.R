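# 2D constructions on the magnification-corrected AP pelvis radiograph:
# the 19-landmark model, the lateral (bisector) and medial (sourcil-to-W)
# margin lines of the weight-bearing area, and the center-edge angle.
#
# Image frame convention: x increases toward the patient's left, y is
# superior. On an AP view the lateral direction is therefore -x for a right
# hip and +x for a left hip. Readers of top-left-origin pixel coordinates
# must flip the vertical axis before constructing a landmark set.

#' AP-radiograph landmark set
#'
#' @param points numeric matrix (or data frame) of 2D landmark positions in
#'   image millimetres with row names among `p1..p19`; `p19` is the femoral
#'   head centre. Subsets are allowed for single constructions; the full
#'   boundary construction requires all 19.
#' @param side `"left"` or `"right"` hip.
#' @param marker_measured,marker_true measured and true diameter (mm) of the
#'   magnification marker (a coin of known size imaged with the pelvis).
#' @return an object of class `radiograph_landmarks`.
#' @export
radiograph_landmarks <- function(points, side = c("right", "left"),
                                 marker_measured, marker_true = 25) {
  side <- match.arg(side)
  points <- as_point_matrix(as.matrix(points), 2L)
  colnames(points) <- NULL
  nm <- rownames(points)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("landmark points must have row names (p1..p19)", call. = FALSE)
  bad <- setdiff(nm, paste0("p", 1:19))
  if (length(bad))
    stop("unknown landmark names: ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate landmark names", call. = FALSE)
  if (!(marker_measured > 0 && marker_true > 0))
    stop("marker diameters must be positive", call. = FALSE)
  structure(list(points = points, side = side,
                 marker_measured = as.numeric(marker_measured),
                 marker_true = as.numeric(marker_true)),
            class = "radiograph_landmarks")
}

#' @export
print.radiograph_landmarks <- function(x, ...) {
  cat(sprintf("radiograph_landmarks (%s hip): %d of 19 points, marker %.2f/%.2f mm (scale %.4f)\n",
              x$side, nrow(x$points), x$marker_measured, x$marker_true,
              x$marker_true / x$marker_measured))
  invisible(x)
}

landmark_point <- function(lm, name) {
  if (!name %in% rownames(lm$points))
    stop(sprintf("missing landmark '%s'", name), call. = FALSE)
  as.numeric(lm$points[name, ])
}

#' Correct radiographic magnification
#'
#' Scales every landmark by `s = marker_true / marker_measured` about the
#' image origin and updates the marker fields so that a second application is
#' the identity. All downstream constructions are translation-equivariant, so
#' the origin choice does not matter.
#'
#' @param lm a [radiograph_landmarks()] set.
#' @return the corrected landmark set (scale factor in attribute `"scale"`).
#' @export
correct_magnification <- function(lm) {
  stopifnot(inherits(lm, "radiograph_landmarks"))
  s <- lm$marker_true / lm$marker_measured
  lm$points <- lm$points * s
  lm$marker_measured <- lm$marker_true
  attr(lm, "scale") <- s
  lm
}

#' 2D line (anchor + unit direction)
#' @param anchor 2-vector (mm).
#' @param direction 2-vector; normalized internally.
#' @return an object of class `line2d`.
#' @export
line2d <- function(anchor, direction) {
  structure(list(anchor = as.numeric(anchor),
                 direction = unitize(as.numeric(direction))),
            class = "line2d")
}

#' @export
print.line2d <- function(x, ...) {
  cat(sprintf("line2d: anchor (%.3f, %.3f), direction (%.6f, %.6f)\n",
              x$anchor[1L], x$anchor[2L], x$direction[1L], x$direction[2L]))
  invisible(x)
}

# Signed perpendicular distance of `point` from the line (positive on the
# counter-clockwise side of the direction).
line2d_signed_distance <- function(line, point) {
  rel <- as.numeric(point) - line$anchor
  line$direction[1L] * rel[2L] - line$direction[2L] * rel[1L]
}

#' Lateral margin line of the weight-bearing area (line 4-M)
#'
#' The internal bisector of the angle 7-4-11, anchored at the lateral
#' acetabular edge (p4): the direction is the normalized sum of the unit
#' vectors along the rays 4->7 and 4->11, which makes equal angles with both.
#'
#' @param p4,p7,p11 2D points (mm): lateral acetabular edge, inferior
#'   teardrop margin, posterior-wall / inferior-head-margin intersection.
#' @param tol degeneracy tolerance.
#' @return a [line2d()] anchored at `p4`.
#' @export
lateral_margin_line <- function(p4, p7, p11, tol = 1e-9) {
  p4 <- as.numeric(p4); p7 <- as.numeric(p7); p11 <- as.numeric(p11)
  r1 <- p7 - p4; r2 <- p11 - p4
  if (vec_norm(r1) < tol || vec_norm(r2) < tol)
    stop("degenerate geometry: p7 or p11 coincides with p4", call. = FALSE)
  u1 <- r1 / vec_norm(r1); u2 <- r2 / vec_norm(r2)
  s <- u1 + u2
  if (vec_norm(s) < tol)
    stop("degenerate geometry: rays 4->7 and 4->11 are opposite", call. = FALSE)
  cross_z <- abs(u1[1L] * u2[2L] - u1[2L] * u2[1L])
  if (cross_z < tol)
    stop("degenerate geometry: angle 7-4-11 is (near-)zero", call. = FALSE)
  line2d(p4, s)
}

#' Medial margin line of the weight-bearing area (line 5-W)
#'
#' Connects the medial sourcil point (p5) with W, the midpoint of the most
#' medial femoral-head point (p6) and the lateral teardrop margin (p18).
#'
#' @param p5,p6,p18 2D points (mm).
#' @param tol degeneracy tolerance.
#' @return a list with components `line` (a [line2d()] anchored at `p5`,
#'   directed toward `W`) and `W` (the midpoint).
#' @export
medial_margin_line <- function(p5, p6, p18, tol = 1e-9) {
  p5 <- as.numeric(p5)
  W <- (as.numeric(p6) + as.numeric(p18)) / 2
  if (vec_norm(W - p5) < tol)
    stop("degenerate geometry: p5 coincides with W", call. = FALSE)
  list(line = line2d(p5, W - p5), W = W)
}

#' Center-edge angle of Wiberg
#'
#' Angle between the superior vertical ray from the femoral head centre (p19)
#' and the ray to the lateral acetabular edge (p4), signed positive when p4
#' lies lateral of the vertical (lateral sense depends on `side`; see the
#' image frame convention in the module header).
#'
#' @param p19,p4 2D points (mm): head centre and lateral acetabular edge.
#' @param side `"left"` or `"right"`.
#' @return signed CE angle in degrees.
#' @export
ce_angle <- function(p19, p4, side = c("right", "left")) {
  side <- match.arg(side)
  p19 <- as.numeric(p19); p4 <- as.numeric(p4)
  r <- p4 - p19
  if (vec_norm(r) < 1e-12)
    stop("degenerate geometry: p4 coincides with p19", call. = FALSE)
  lateral_sign <- if (side == "right") -1 else 1
  rad2deg(atan2(lateral_sign * r[1L], r[2L]))
}

#' Fit a circle to the head-contour landmarks
#'
#' Optional cross-check of the given head-centre landmark p19: algebraic
#' (Kasa) circle fit through the head contour points p3, p6 and p16.
#'
#' @param lm a [radiograph_landmarks()] set containing p3, p6, p16.
#' @return list with `center` (2-vector), `radius`, and `rms` residual (mm).
#' @export
fit_head_circle <- function(lm) {
  pts <- do.call(rbind, lapply(c("p3", "p6", "p16"), function(n) landmark_point(lm, n)))
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sol <- qr.solve(A, b)
  center <- sol[1:2]
  radius <- sqrt(sol[3L] + sum(center^2))
  rms <- sqrt(mean((sqrt(rowSums(sweep(pts, 2L, center)^2)) - radius)^2))
  list(center = as.numeric(center), radius = radius, rms = rms)
}

#' Assemble the full boundary construction
#'
#' Builds the lateral and medial margin lines, W, the head centre and the
#' magnification scale from a full, magnification-corrected landmark set, and
#' checks the consistency condition that the head centre lies strictly
#' between the two margin lines (it defines the patch side of each). Failure
#' of the consistency check is a warning, not an error.
#'
#' @param lm a [radiograph_landmarks()] set (all 19 points present).
#' @return an object of class `boundary_construction` with elements
#'   `lateral_line`, `medial_line`, `W`, `head_center`, `scale`, `ce_deg`,
#'   and the signed distances of the head centre to each line.
#' @export
build_boundary_construction <- function(lm) {
  stopifnot(inherits(lm, "radiograph_landmarks"))
  needed <- paste0("p", 1:19)
  missing <- setdiff(needed, rownames(lm$points))
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "), call. = FALSE)
  lat <- lateral_margin_line(landmark_point(lm, "p4"), landmark_point(lm, "p7"),
                             landmark_point(lm, "p11"))
  med <- medial_margin_line(landmark_point(lm, "p5"), landmark_point(lm, "p6"),
                            landmark_point(lm, "p18"))
  hc <- landmark_point(lm, "p19")
  d_lat <- line2d_signed_distance(lat, hc)
  d_med <- line2d_signed_distance(med$line, hc)
  if (abs(d_lat) < 1e-6 || abs(d_med) < 1e-6)
    warning("head centre lies on a margin line; patch side is ill-defined",
            call. = FALSE)
  structure(list(lateral_line = lat, medial_line = med$line, W = med$W,
                 head_center = hc,
                 scale = lm$marker_true / lm$marker_measured,
                 ce_deg = ce_angle(hc, landmark_point(lm, "p4"), lm$side),
                 center_distance_lateral = d_lat,
                 center_distance_medial = d_med,
                 side = lm$side),
            class = "boundary_construction")
}

#' @export
print.boundary_construction <- function(x, ...) {
  cat(sprintf("boundary_construction (%s hip): CE angle %.2f deg\n", x$side, x$ce_deg))
  cat(sprintf("  head centre (%.2f, %.2f); %.2f mm from lateral line, %.2f mm from medial line\n",
              x$head_center[1L], x$head_center[2L],
              abs(x$center_distance_lateral), abs(x$center_distance_medial)))
  invisible(x)
}

#' Mirror a landmark set across a vertical axis
#'
#' Utility for left/right symmetry checks: reflects all points across the
#' vertical line `x = x0` and flips the side label.
#'
#' @param lm a [radiograph_landmarks()] set.
#' @param x0 reflection axis abscissa (mm).
#' @return the mirrored landmark set.
#' @export
mirror_landmarks <- function(lm, x0 = 0) {
  stopifnot(inherits(lm, "radiograph_landmarks"))
  lm$points[, 1L] <- 2 * x0 - lm$points[, 1L]
  lm$side <- if (lm$side == "right") "left" else "right"
  lm
}
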