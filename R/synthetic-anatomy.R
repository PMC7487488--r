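# Parametric proximal-femur generator: spherical head, cylindrical neck and
# shaft. Stands in for CT-derived anatomy so the whole pipeline (radiograph
# construction, registration, patch trimming, FE) can be exercised against a
# known ground truth.

#' Parametric proximal-femur description
#'
#' All lengths in mm, angles in degrees. The canonical frame is `+x` medial,
#' `+y` anterior, `+z` superior for a right femur; `side = "left"` mirrors the
#' geometry across the sagittal plane through the head centre.
#'
#' @param head_radius femoral-head sphere radius.
#' @param head_center head centre (3-vector).
#' @param neck_radius neck radius at the head end; must be `< head_radius`.
#'   The neck is a conical frustum flaring from this radius at the head to
#'   `neck_radius_distal` at the trochanteric junction, as the anatomical
#'   neck does.
#' @param neck_radius_distal neck radius at the shaft junction; defaults to
#'   `1.05 * shaft_radius`.
#' @param neck_length distance from head centre to the neck-shaft junction
#'   along the neck axis.
#' @param neck_shaft_angle angle between neck axis and shaft axis, in
#'   `(90, 160)` degrees.
#' @param shaft_radius,shaft_length proximal shaft (diaphysis) cylinder.
#' @param blend_mm smooth-union blending radius between the primitives
#'   (mm). The real proximal femur has a broad concave flare where the neck
#'   meets the shaft (the calcar region); a hard union of primitives would
#'   leave a sharp re-entrant crease there that acts as an artificial stress
#'   riser.
#' @param cortical_thickness cortex thickness used to label neck/shaft
#'   elements cortical in the volume mesh.
#' @param head_shell subchondral shell thickness used for the head region;
#'   anatomically the plate under the joint surface is much thinner than the
#'   diaphyseal cortex.
#' @param side `"left"` or `"right"`.
#' @param seed integer seed recorded with the parameters; the surface and
#'   volume generators are fully deterministic, the seed feeds the synthetic
#'   radiograph's landmark jitter.
#' @return an object of class `femur_params`.
#' @export
femur_params <- function(head_radius = 24, head_center = c(0, 0, 0),
                         neck_radius = 13, neck_radius_distal = NULL,
                         neck_length = 45, neck_shaft_angle = 128,
                         shaft_radius = 14.5, shaft_length = 80,
                         blend_mm = 14, cortical_thickness = 4, head_shell = 2,
                         side = c("right", "left"), seed = 1L) {
  side <- match.arg(side)
  if (is.null(neck_radius_distal)) neck_radius_distal <- 1.05 * shaft_radius
  if (!(is.numeric(head_radius) && head_radius > 0))
    stop("head_radius must be positive", call. = FALSE)
  if (!(neck_radius > 0 && neck_radius < head_radius))
    stop("invalid parameters: require head_radius > neck_radius > 0", call. = FALSE)
  if (!(cortical_thickness > 0 && cortical_thickness < neck_radius))
    stop("cortical_thickness must be in (0, neck_radius)", call. = FALSE)
  if (!(head_shell > 0 && head_shell <= head_radius))
    stop("head_shell must be positive and at most head_radius", call. = FALSE)
  if (!(neck_shaft_angle > 90 && neck_shaft_angle < 160))
    stop("neck_shaft_angle must lie in (90, 160) degrees", call. = FALSE)
  if (!(neck_length > 0 && shaft_radius > 0 && shaft_length > 0))
    stop("neck_length, shaft_radius and shaft_length must be positive", call. = FALSE)
  if (!(neck_radius_distal >= neck_radius))
    stop("neck_radius_distal must be at least neck_radius", call. = FALSE)
  structure(list(head_radius = head_radius, head_center = as.numeric(head_center),
                 neck_radius = neck_radius,
                 neck_radius_distal = neck_radius_distal,
                 neck_length = neck_length, blend_mm = blend_mm,
                 neck_shaft_angle = neck_shaft_angle, shaft_radius = shaft_radius,
                 shaft_length = shaft_length, cortical_thickness = cortical_thickness,
                 head_shell = head_shell, side = side, seed = as.integer(seed)),
            class = "femur_params")
}

#' @export
print.femur_params <- function(x, ...) {
  cat(sprintf(paste0("femur_params (%s): head R=%.1f mm, neck r=%.1f mm x %.1f mm,",
                     " NSA=%.0f deg, shaft r=%.1f mm x %.1f mm\n"),
              x$side, x$head_radius, x$neck_radius, x$neck_length,
              x$neck_shaft_angle, x$shaft_radius, x$shaft_length))
  invisible(x)
}

# Derived frame quantities, always for the canonical (right-side) build.
femur_frame <- function(params) {
  theta <- deg2rad(params$neck_shaft_angle - 90)
  u_neck <- c(-cos(theta), 0, -sin(theta))     # head centre -> shaft, inferolateral
  junction <- params$head_center + params$neck_length * u_neck
  z_top <- junction[3L] + params$shaft_radius
  z_bot <- junction[3L] - params$shaft_length
  list(u_neck = u_neck, junction = junction, z_top = z_top, z_bot = z_bot,
       shaft_axis_xy = junction[1:2])
}

#' Generate the parametric femur surface mesh with ground truth
#'
#' Builds a triangulated surface: a head sphere with the neck-junction cap
#' removed, stitched watertight to the neck cylinder (closed with a distal
#' disk), plus a closed shaft cylinder as a second component. Head-sphere
#' vertices are tagged. Deterministic.
#'
#' @param params a [femur_params()] object.
#' @param n_lat,n_lon head-sphere tessellation (bands / segments).
#' @return a list with components `mesh` (a [surface_mesh()]) and `truth`
#'   (class `femur_ground_truth`: true head centre/radius, named 3D landmark
#'   positions, identity projection transform).
#' @export
generate_femur_surface <- function(params, n_lat = 96L, n_lon = 128L) {
  stopifnot(inherits(params, "femur_params"))
  fr <- femur_frame(params)
  R <- params$head_radius; rn <- params$neck_radius
  c0 <- params$head_center
  theta0 <- asin(rn / R)
  head <- uv_sphere_mesh(center = c0, radius = R, n_lat = n_lat, n_lon = n_lon,
                         axis = fr$u_neck, theta_range = c(theta0, pi))
  n_head_vertices <- nrow(head$vertices)
  verts <- head$vertices
  tris <- head$triangles
  # the theta0 ring is the first n_lon vertex block; it already lies on the
  # neck cylinder of radius rn about the neck axis
  ring0 <- seq_len(n_lon)
  basis <- orthonormal_basis(fr$u_neck)
  phis <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  rd <- params$neck_radius_distal
  end_ring_pts <- sweep(rd * (outer(cos(phis), basis$u) + outer(sin(phis), basis$v)),
                        2L, fr$junction, "+")
  end_ring <- nrow(verts) + seq_len(n_lon)
  verts <- rbind(verts, end_ring_pts)
  tris <- rbind(tris, cylinder_wall_triangles(ring0, end_ring))
  end_center <- nrow(verts) + 1L
  verts <- rbind(verts, fr$junction)
  tris <- rbind(tris, disk_fan_triangles(end_center, end_ring, flip = TRUE))
  # shaft: closed vertical cylinder, second component
  sx <- fr$shaft_axis_xy
  top_pts <- cbind(sx[1L] + params$shaft_radius * cos(phis),
                   sx[2L] + params$shaft_radius * sin(phis), fr$z_top)
  bot_pts <- cbind(sx[1L] + params$shaft_radius * cos(phis),
                   sx[2L] + params$shaft_radius * sin(phis), fr$z_bot)
  top_ring <- nrow(verts) + seq_len(n_lon)
  verts <- rbind(verts, top_pts)
  bot_ring <- nrow(verts) + seq_len(n_lon)
  verts <- rbind(verts, bot_pts)
  tris <- rbind(tris, cylinder_wall_triangles(top_ring, bot_ring))
  top_c <- nrow(verts) + 1L; bot_c <- nrow(verts) + 2L
  verts <- rbind(verts, c(sx[1L], sx[2L], fr$z_top), c(sx[1L], sx[2L], fr$z_bot))
  tris <- rbind(tris, disk_fan_triangles(top_c, top_ring, flip = FALSE),
                disk_fan_triangles(bot_c, bot_ring, flip = TRUE))
  landmarks <- femur_landmarks_3d(params)
  if (params$side == "left") {
    verts[, 1L] <- 2 * c0[1L] - verts[, 1L]
    tris <- tris[, c(1L, 3L, 2L)]
    landmarks[, 1L] <- 2 * c0[1L] - landmarks[, 1L]
  }
  mesh <- surface_mesh(verts, tris, head_vertices = seq_len(n_head_vertices))
  truth <- structure(list(head_center = c0, head_radius = R,
                          landmarks_3d = landmarks,
                          projection = planar_registration(rotation_deg = 0,
                                                           translation = c(0, 0),
                                                           scale = 1),
                          side = params$side, params = params),
                     class = "femur_ground_truth")
  list(mesh = mesh, truth = truth)
}

# Named 3D landmark positions on the canonical (right) femur; rows are named.
femur_landmarks_3d <- function(params) {
  fr <- femur_frame(params)
  c0 <- params$head_center; R <- params$head_radius
  lm <- rbind(
    p1  = c(fr$junction[1L] - params$shaft_radius, 0, fr$junction[3L] + 4),
    p2  = c(fr$junction[1L], 0, fr$z_top),
    p3  = c0 + c(-R, 0, 0),
    p6  = c0 + c(R, 0, 0),
    p16 = c0 + c(0, 0, R),
    p19 = c0
  )
  lm
}

#' @export
print.femur_ground_truth <- function(x, ...) {
  cat(sprintf("femur_ground_truth (%s): head centre (%.2f, %.2f, %.2f) mm, radius %.2f mm; %d landmarks\n",
              x$side, x$head_center[1L], x$head_center[2L], x$head_center[3L],
              x$head_radius, nrow(x$landmarks_3d)))
  invisible(x)
}

# Signed distance (negative inside) to the union of head sphere, neck
# cylinder and shaft cylinder. `points` is n x 3.
femur_signed_distance <- function(points, params) {
  points <- as_point_matrix(points, 3L)
  p <- points
  if (params$side == "left")
    p[, 1L] <- 2 * params$head_center[1L] - p[, 1L]
  fr <- femur_frame(params)
  d_sphere <- sqrt(rowSums(sweep(p, 2L, params$head_center)^2)) - params$head_radius
  t0 <- sqrt(params$head_radius^2 - params$neck_radius^2)
  neck_start <- params$head_center + t0 * fr$u_neck
  d_neck <- capped_cone_sdf(p, neck_start, fr$junction, params$neck_radius,
                            params$neck_radius_distal)
  a_shaft <- c(fr$shaft_axis_xy, fr$z_top)
  b_shaft <- c(fr$shaft_axis_xy, fr$z_bot)
  d_shaft <- capped_cylinder_sdf(p, a_shaft, b_shaft, params$shaft_radius)
  k <- params$blend_mm %||% 0
  smooth_min(smooth_min(d_sphere, d_neck, k), d_shaft, k)
}

# Polynomial smooth minimum: a C1 union of signed distances whose concave
# creases are rounded with radius of order k.
smooth_min <- function(a, b, k) {
  if (k <= 0) return(pmin(a, b))
  h <- pmax(k - abs(a - b), 0) / k
  pmin(a, b) - h * h * k * 0.25
}

# SDF of a capped conical frustum with axis a -> b, radius r1 at a, r2 at b.
# The wall distance is measured perpendicular to the slant (exact for the
# wall; caps combined in the usual rounded-corner manner).
capped_cone_sdf <- function(p, a, b, r1, r2) {
  axis <- b - a
  h <- vec_norm(axis)
  u <- axis / h
  rel <- sweep(p, 2L, a)
  t <- as.numeric(rel %*% u)
  radial <- sqrt(pmax(rowSums(rel^2) - t^2, 0))
  slope <- (r2 - r1) / h
  cosa <- 1 / sqrt(1 + slope^2)
  dr <- (radial - (r1 + slope * t)) * cosa
  dz <- pmax(-t, t - h)
  outside <- sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
  inside <- pmin(pmax(dr, dz), 0)
  as.numeric(outside + inside)
}

# Exact SDF of a finite capped cylinder with axis a -> b.
capped_cylinder_sdf <- function(p, a, b, radius) {
  axis <- b - a
  h <- vec_norm(axis)
  u <- axis / h
  rel <- sweep(p, 2L, a)
  t <- rel %*% u
  radial <- sqrt(pmax(rowSums(rel^2) - t^2, 0))
  dr <- radial - radius                 # signed distance to the wall
  dz <- pmax(-t, t - h)                 # signed distance to the caps
  outside <- sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
  inside <- pmin(pmax(dr, dz), 0)
  as.numeric(outside + inside)
}

#' Voxel-template tetrahedral mesh of the parametric femur
#'
#' Voxelizes the implicit solid (voxel centres inside the union of
#' primitives), splits each interior voxel with a fixed 5- or 6-tetrahedron
#' template (conforming across voxels), and labels elements cortical where
#' the centroid lies within the local cortex thickness of the outer surface
#' (head shell inside the head sphere, diaphyseal cortex elsewhere), else
#' cancellous.
#'
#' @param params a [femur_params()].
#' @param voxel_size voxel edge (mm, default 2 as is conventional for
#'   proximal-femur models); must be smaller than the neck diameter.
#' @param template `"kuhn6"` (six tets per voxel) or `"five"`
#'   (parity-alternated five-tet template).
#' @return a [tet_model()] with node sets `distal_fixed`, `head_apex`,
#'   `gt_lateral` (lateral greater-trochanter surface nodes) and
#'   `lesser_trochanter` (medial proximal metaphysis surface nodes), and an
#'   `anatomy` attribute carrying the generating parameters.
#' @export
generate_tet_mesh <- function(params, voxel_size = 2,
                              template = c("kuhn6", "five")) {
  stopifnot(inherits(params, "femur_params"))
  template <- match.arg(template)
  if (!(voxel_size > 0)) stop("voxel_size must be positive", call. = FALSE)
  if (voxel_size >= 2 * params$neck_radius)
    stop("meshing error: voxel_size is not smaller than the neck diameter",
         call. = FALSE)
  fr <- femur_frame(params)
  c0 <- params$head_center; R <- params$head_radius
  lo <- pmin(c0 - R, c(fr$shaft_axis_xy, fr$z_bot) - params$shaft_radius)
  hi <- pmax(c0 + R, c(fr$shaft_axis_xy, fr$z_top) + params$shaft_radius)
  lo <- lo - voxel_size; hi <- hi + voxel_size
  res <- voxel_tet_grid(function(pts) femur_signed_distance(pts, params) <= 0,
                        lo, hi, voxel_size, template)
  if (nrow(res$elements) == 0L)
    stop("meshing error: no interior voxels at this voxel_size", call. = FALSE)
  centroids <- (res$nodes[res$elements[, 1L], ] + res$nodes[res$elements[, 2L], ] +
                  res$nodes[res$elements[, 3L], ] + res$nodes[res$elements[, 4L], ]) / 4
  sdf <- femur_signed_distance(centroids, params)
  in_head <- sqrt(rowSums(sweep(centroids, 2L, c0)^2)) <= R
  shell <- ifelse(in_head, params$head_shell, params$cortical_thickness)
  label <- ifelse(sdf >= -shell, "cortical", "cancellous")
  # node sets: distal shaft layer (full fixation) and the head apex node
  distal_fixed <- which(res$nodes[, 3L] <= fr$z_bot + voxel_size + 1e-9)
  head_nodes <- which(sqrt(rowSums(sweep(res$nodes, 2L, c0)^2)) <= R + 1e-9)
  head_apex <- head_nodes[which.max(res$nodes[head_nodes, 3L])]
  # muscle-attachment surface bands near the trochanters (mirror-aware)
  J <- fr$junction
  if (params$side == "left") J[1L] <- 2 * c0[1L] - J[1L]
  msign <- if (params$side == "right") 1 else -1      # +x medial on the right
  model0 <- tet_model(nodes = res$nodes, elements = res$elements,
                      labels = label, node_sets = list())
  surf_nodes <- sort(unique(as.vector(boundary_faces(model0)$faces)))
  xs <- res$nodes[surf_nodes, 1L]; zs <- res$nodes[surf_nodes, 3L]
  gt_lateral <- surf_nodes[abs(zs - J[3L]) < 4 &
                             msign * (xs - J[1L]) < -0.8 * params$shaft_radius]
  lesser_troch <- surf_nodes[zs > J[3L] - 10 & zs < J[3L] - 2 &
                               msign * (xs - J[1L]) > 0.75 * params$shaft_radius]
  jc <- c0 + sqrt(R^2 - params$neck_radius^2) * fr$u_neck
  if (params$side == "left") jc[1L] <- 2 * c0[1L] - jc[1L]
  junction_node <- which.min(rowSums(sweep(res$nodes, 2L, jc)^2))
  model <- tet_model(nodes = res$nodes, elements = res$elements,
                     labels = label,
                     node_sets = list(distal_fixed = distal_fixed,
                                      head_apex = head_apex,
                                      head_neck_junction = junction_node,
                                      gt_lateral = gt_lateral,
                                      lesser_trochanter = lesser_troch))
  model$voxel_size <- voxel_size
  model$template <- template
  model$anatomy <- params
  model
}

# Voxelize an indicator function and split interior voxels into tets.
# Returns deduplicated corner nodes and an element index matrix.
voxel_tet_grid <- function(inside_fun, lo, hi, h, template) {
  nx <- max(1L, ceiling((hi[1L] - lo[1L]) / h))
  ny <- max(1L, ceiling((hi[2L] - lo[2L]) / h))
  nz <- max(1L, ceiling((hi[3L] - lo[3L]) / h))
  ijk <- as.matrix(expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz)))
  centers <- cbind(lo[1L] + (ijk[, 1L] - 0.5) * h,
                   lo[2L] + (ijk[, 2L] - 0.5) * h,
                   lo[3L] + (ijk[, 3L] - 0.5) * h)
  keep <- inside_fun(centers)
  ijk <- ijk[keep, , drop = FALSE]
  if (nrow(ijk) == 0L)
    return(list(nodes = matrix(0, 0L, 3L), elements = matrix(0L, 0L, 4L)))
  # global corner ids on the (nx+1) x (ny+1) x (nz+1) lattice
  corner_id <- function(ci, cj, ck)
    (ck - 1L) * (nx + 1L) * (ny + 1L) + (cj - 1L) * (nx + 1L) + ci
  # local corner offsets, x fastest: 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0)
  #                                  5:(0,0,1) 6:(1,0,1) 7:(0,1,1) 8:(1,1,1)
  offs <- cbind(c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
                c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
                c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  corners <- matrix(0L, nrow(ijk), 8L)
  for (c8 in 1:8)
    corners[, c8] <- corner_id(ijk[, 1L] + offs[c8, 1L],
                               ijk[, 2L] + offs[c8, 2L],
                               ijk[, 3L] + offs[c8, 3L])
  if (template == "kuhn6") {
    tpl <- rbind(c(1L, 2L, 4L, 8L), c(1L, 4L, 3L, 8L), c(1L, 3L, 7L, 8L),
                 c(1L, 7L, 5L, 8L), c(1L, 5L, 6L, 8L), c(1L, 6L, 2L, 8L))
    elements <- do.call(rbind, lapply(seq_len(nrow(tpl)), function(t)
      corners[, tpl[t, ], drop = FALSE]))
  } else {
    even_tpl <- rbind(c(1L, 4L, 6L, 7L),             # central tet
                      c(2L, 1L, 4L, 6L), c(3L, 1L, 7L, 4L),
                      c(5L, 1L, 6L, 7L), c(8L, 4L, 7L, 6L))
    odd_tpl <- rbind(c(2L, 3L, 5L, 8L),
                     c(1L, 2L, 5L, 3L), c(4L, 2L, 3L, 8L),
                     c(6L, 2L, 8L, 5L), c(7L, 3L, 5L, 8L))
    parity <- (ijk[, 1L] + ijk[, 2L] + ijk[, 3L]) %% 2L
    pick <- function(tpl, rows) do.call(rbind, lapply(seq_len(nrow(tpl)), function(t)
      corners[rows, tpl[t, ], drop = FALSE]))
    elements <- rbind(pick(even_tpl, parity == 0L), pick(odd_tpl, parity == 1L))
  }
  used <- sort(unique(as.vector(elements)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  elements <- matrix(remap[elements], ncol = 4L)
  ck <- (used - 1L) %/% ((nx + 1L) * (ny + 1L))
  rem <- (used - 1L) %% ((nx + 1L) * (ny + 1L))
  cj <- rem %/% (nx + 1L)
  ci <- rem %% (nx + 1L)
  nodes <- cbind(lo[1L] + ci * h, lo[2L] + cj * h, lo[3L] + ck * h)
  # enforce positive orientation (positive 6V) element-wise
  v1 <- nodes[elements[, 1L], , drop = FALSE]
  d2 <- nodes[elements[, 2L], , drop = FALSE] - v1
  d3 <- nodes[elements[, 3L], , drop = FALSE] - v1
  d4 <- nodes[elements[, 4L], , drop = FALSE] - v1
  vol6 <- rowSums(d2 * cross3_rows(d3, d4))
  flip <- vol6 < 0
  if (any(flip)) elements[flip, c(3L, 4L)] <- elements[flip, c(4L, 3L)]
  list(nodes = nodes, elements = elements)
}

#' Synthesize an AP-radiograph landmark set from ground truth
#'
#' Projects the femoral 3D landmarks vertically onto the coronal plane
#' (dropping the anterior-posterior coordinate), scales by the radiographic
#' magnification, adds isotropic Gaussian jitter, and places the acetabular /
#' pelvic landmarks from configurable coronal offsets so that a requested
#' center-edge (CE) angle is achieved exactly in the noise-free image. A
#' coin-like magnification marker of known true diameter is imaged at
#' `magnification` times its size.
#'
#' @param truth a `femur_ground_truth` from [generate_femur_surface()].
#' @param magnification radiographic magnification factor (> 0).
#' @param noise_sd landmark jitter standard deviation (mm, in image scale).
#' @param seed RNG seed for the jitter.
#' @param target_ce_deg requested CE angle (degrees).
#' @param marker_true_mm true marker diameter (default a 25 mm coin).
#' @param pelvis_offsets optional named list overriding the default 2D
#'   offsets (mm, in `(x, z)` relative to the projected head centre, medial
#'   positive) of the pelvic landmarks p5, p7..p15, p17, p18.
#' @return a list with `landmarks` (a [radiograph_landmarks()] set) and
#'   `truth` (the input truth extended with the pelvic 3D landmarks, the true
#'   projection transform of scale `magnification`, and the noise-free 2D
#'   positions).
#' @export
generate_radiograph <- function(truth, magnification = 1, noise_sd = 0,
                                seed = 1L, target_ce_deg = 33,
                                marker_true_mm = 25, pelvis_offsets = NULL) {
  stopifnot(inherits(truth, "femur_ground_truth"))
  if (!(magnification > 0)) stop("magnification must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  m <- if (truth$side == "right") 1 else -1    # medial direction sign in 2D x
  c2 <- truth$head_center[c(1L, 3L)]
  R <- truth$head_radius
  ce <- deg2rad(target_ce_deg)
  defaults <- list(
    p5  = c(13, 25),  p7  = c(26, -18), p8  = c(60, -15), p9  = c(85, -25),
    p10 = c(40, -70), p11 = c(-10, -23), p12 = c(-15, 70), p13 = c(25, 45),
    p14 = c(85, 95),  p15 = c(20, 65),  p17 = c(0, R + 6), p18 = c(24, -25))
  if (!is.null(pelvis_offsets)) defaults[names(pelvis_offsets)] <- pelvis_offsets
  pelvic2 <- do.call(rbind, lapply(defaults, function(o) c2 + c(m * o[1L], o[2L])))
  rownames(pelvic2) <- names(defaults)
  r4 <- R + 5
  p4 <- c2 + r4 * c(-m * sin(ce), cos(ce))
  pelvic2 <- rbind(p4 = p4, pelvic2)
  pelvic3 <- cbind(pelvic2[, 1L], 0, pelvic2[, 2L])
  rownames(pelvic3) <- rownames(pelvic2)
  landmarks_3d <- rbind(truth$landmarks_3d, pelvic3)
  landmarks_3d <- landmarks_3d[paste0("p", 1:19)[paste0("p", 1:19) %in%
                                                   rownames(landmarks_3d)], , drop = FALSE]
  clean2 <- landmarks_3d[, c(1L, 3L), drop = FALSE] * magnification
  set.seed(seed)
  noisy2 <- clean2 + matrix(stats::rnorm(length(clean2), sd = noise_sd),
                            ncol = 2L)
  lm <- radiograph_landmarks(points = noisy2, side = truth$side,
                             marker_measured = magnification * marker_true_mm,
                             marker_true = marker_true_mm)
  truth$landmarks_3d <- landmarks_3d
  truth$projection <- planar_registration(rotation_deg = 0, translation = c(0, 0),
                                          scale = magnification)
  truth$clean_2d <- clean2
  truth$target_ce_deg <- target_ce_deg
  list(landmarks = lm, truth = truth)
}
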