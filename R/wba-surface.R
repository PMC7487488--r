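# Trimming of the femoral-head surface into the weight-bearing patch
# (surface gamma): sphere fit of the head, half-space classification against
# the two extruded margin lines, the 30-degree inferior limit measured about
# the joint-reaction-force direction, area quantification and the optional
# 1 mm boundary fillet.

#' Fit the femoral-head sphere
#'
#' Algebraic (linear least-squares) sphere fit, iteratively re-selecting the
#' vertices that lie within a distance band of the current sphere so that
#' neck/shaft vertices in the hint region are rejected.
#'
#' @param mesh a [surface_mesh()].
#' @param hint either an integer vector of seed vertex indices (defaults to
#'   the mesh's `head_vertices` tag when present) or a list with elements
#'   `center` (3-vector) and `radius`, from which seed vertices within
#'   `[0.6, 1.4] * radius` of `center` are taken.
#' @param max_iter re-selection iterations.
#' @param rms_threshold fit-failure threshold as a fraction of the fitted
#'   radius (default 10 percent).
#' @return an object of class `femoral_head_model`: `center`, `radius`,
#'   `rms` (mm), `head_facets` (facets whose vertices all lie in the final
#'   band), `head_vertex_ids`, and the mesh.
#' @export
fit_head_sphere <- function(mesh, hint = NULL, max_iter = 10L,
                            rms_threshold = 0.1) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  if (is.null(hint)) hint <- mesh$head_vertices
  if (is.null(hint))
    stop("no hint given and the mesh carries no head_vertices tag", call. = FALSE)
  if (is.list(hint)) {
    d <- sqrt(rowSums(sweep(v, 2L, as.numeric(hint$center))^2))
    sel <- which(d >= 0.6 * hint$radius & d <= 1.4 * hint$radius)
  } else {
    sel <- as.integer(hint)
  }
  if (length(sel) < 10L)
    stop("sphere fit failed: hint selects fewer than 10 vertices", call. = FALSE)
  bbox_diag <- vec_norm(apply(v, 2L, max) - apply(v, 2L, min))
  fit <- NULL
  for (it in seq_len(max_iter)) {
    fit <- sphere_fit_ls(v[sel, , drop = FALSE])
    if (!is.finite(fit$radius) || fit$radius > 10 * bbox_diag)
      stop("sphere fit failed: surface is (near-)planar in the hint region",
           call. = FALSE)
    d <- sqrt(rowSums(sweep(v, 2L, fit$center)^2)) - fit$radius
    band <- max(3 * fit$rms, 0.01 * fit$radius)
    new_sel <- which(abs(d) <= band)
    if (length(new_sel) < 10L) break
    if (length(new_sel) == length(sel) && all(new_sel == sel)) break
    sel <- new_sel
  }
  if (fit$rms > rms_threshold * fit$radius)
    stop(sprintf("sphere fit failed: rms %.3g mm exceeds %.3g mm (%.0f%% of radius)",
                 fit$rms, rms_threshold * fit$radius, 100 * rms_threshold),
         call. = FALSE)
  in_band <- rep(FALSE, nrow(v)); in_band[sel] <- TRUE
  tri <- mesh$triangles
  head_facets <- which(in_band[tri[, 1L]] & in_band[tri[, 2L]] & in_band[tri[, 3L]])
  structure(list(mesh = mesh, center = fit$center, radius = fit$radius,
                 rms = fit$rms, head_facets = head_facets,
                 head_vertex_ids = sel),
            class = "femoral_head_model")
}

# One algebraic sphere fit: ||x||^2 = 2 c.x + (r^2 - c.c), linear in (c, k).
sphere_fit_ls <- function(pts) {
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e)
    stop("sphere fit failed: degenerate vertex configuration", call. = FALSE))
  center <- sol[1:3]
  r2 <- sol[4L] + sum(center^2)
  if (r2 <= 0) stop("sphere fit failed: non-positive squared radius", call. = FALSE)
  radius <- sqrt(r2)
  rms <- sqrt(mean((sqrt(rowSums(sweep(pts, 2L, center)^2)) - radius)^2))
  list(center = as.numeric(center), radius = radius, rms = rms)
}

#' @export
print.femoral_head_model <- function(x, ...) {
  cat(sprintf("femoral_head_model: centre (%.3f, %.3f, %.3f) mm, radius %.3f mm, fit rms %.4g mm\n",
              x$center[1L], x$center[2L], x$center[3L], x$radius, x$rms))
  cat(sprintf("  %d head facets of %d total\n",
              length(x$head_facets), nrow(x$mesh$triangles)))
  invisible(x)
}

# An extruded margin-line half-space: the trim plane contains the lifted
# line and the projection direction; keep_sign fixes the patch side.
margin_half_space <- function(line3, plane, reference_point) {
  n <- unitize(cross3(line3$direction, plane$normal))
  s_ref <- sum((as.numeric(reference_point) - line3$point) * n)
  if (abs(s_ref) < 1e-9)
    stop("reference point lies on the extruded margin plane; patch side undefined",
         call. = FALSE)
  list(normal = n, point = line3$point, keep_sign = sign(s_ref))
}

half_space_keep <- function(points, hs) {
  s <- sweep(as_point_matrix(points, 3L), 2L, hs$point) %*% hs$normal
  hs$keep_sign * s >= 0
}

#' Trim the head surface by the lifted margin lines (surface beta)
#'
#' Each margin line, lifted onto the datum plane, is extruded along the
#' plane normal into a trim plane; a head facet is kept when its centroid
#' lies on the patch side of both planes. The patch side of each plane is
#' the side containing `reference_point` (by default the fitted head centre,
#' mirroring the construction's head-centre-between-the-lines condition).
#'
#' @param head a [fit_head_sphere()] result.
#' @param lateral,medial [line3d()] margin lines lying in `plane`.
#' @param plane the [datum_plane()].
#' @param reference_point 3D point fixing the patch side (default: fitted
#'   head centre).
#' @return list with `facets` (facet indices into the mesh, surface beta)
#'   and `half_spaces` (the two oriented trim planes, reused downstream).
#' @export
trim_by_margin_lines <- function(head, lateral, medial, plane = datum_plane(),
                                 reference_point = NULL) {
  stopifnot(inherits(head, "femoral_head_model"))
  if (is.null(reference_point)) reference_point <- head$center
  hs_lat <- margin_half_space(lateral, plane, reference_point)
  hs_med <- margin_half_space(medial, plane, reference_point)
  cent <- triangle_centroids(head$mesh$vertices,
                             head$mesh$triangles[head$head_facets, , drop = FALSE])
  keep_lat <- half_space_keep(cent, hs_lat)
  keep_med <- half_space_keep(cent, hs_med)
  if (!any(keep_lat))
    stop("empty patch: the lateral margin line removed every facet", call. = FALSE)
  if (!any(keep_lat & keep_med))
    stop("empty patch: the medial margin line removed every facet", call. = FALSE)
  list(facets = head$head_facets[keep_lat & keep_med],
       half_spaces = list(lateral = hs_lat, medial = hs_med),
       removed = c(lateral = sum(!keep_lat),
                   medial = sum(keep_lat & !keep_med)))
}

#' Apply the inferior limit and assemble the weight-bearing patch (surface gamma)
#'
#' Keeps facets whose centroid elevation, measured toward the superior sense
#' defined by the joint reaction force (superior = `-jrf_direction`), is at
#' least `-limit_deg` below the horizontal plane through the fitted head
#' centre. The kept facets are reduced to their largest edge-connected
#' component and the boundary polyline and area are assembled.
#'
#' @param facets integer facet indices (surface beta), e.g. from
#'   [trim_by_margin_lines()]; its `half_spaces` may be passed on via
#'   `half_spaces` so the patch provenance carries all three constraints.
#' @param head a [fit_head_sphere()] result.
#' @param jrf_direction unit 3-vector of the joint reaction force acting on
#'   the head (default straight inferior).
#' @param limit_deg inferior limit in degrees below the horizontal (default
#'   30).
#' @param half_spaces optional list of oriented margin half-spaces.
#' @return an object of class `wba_patch`: facet ids, ordered boundary
#'   polyline(s) in mm, area in mm^2, and the provenance of all trimming
#'   constraints.
#' @export
apply_inferior_limit <- function(facets, head, jrf_direction = c(0, 0, -1),
                                 limit_deg = 30, half_spaces = NULL) {
  stopifnot(inherits(head, "femoral_head_model"))
  if (length(facets) == 0L) stop("empty facet set", call. = FALSE)
  superior <- -unitize(as.numeric(jrf_direction))
  tri <- head$mesh$triangles[facets, , drop = FALSE]
  cent <- triangle_centroids(head$mesh$vertices, tri)
  rel <- sweep(cent, 2L, head$center)
  elev <- asin(pmin(pmax((rel %*% superior) / sqrt(rowSums(rel^2)), -1), 1))
  keep <- as.numeric(elev) >= -deg2rad(limit_deg)
  if (!any(keep))
    stop("empty patch: the inferior limit removed every facet", call. = FALSE)
  kept <- facets[keep]
  tri_k <- head$mesh$triangles[kept, , drop = FALSE]
  comp <- facet_components(tri_k)
  n_comp <- max(comp)
  kept <- kept[comp == 1L]
  tri_k <- head$mesh$triangles[kept, , drop = FALSE]
  loops <- boundary_loops(tri_k)
  boundary <- lapply(loops, function(path) head$mesh$vertices[path, , drop = FALSE])
  provenance <- list(half_spaces = half_spaces,
                     inferior = list(center = head$center, superior = superior,
                                     limit_deg = limit_deg),
                     n_components_before_reduction = n_comp)
  structure(list(mesh = head$mesh, facets = kept, boundary = boundary,
                 area = sum(triangle_areas(head$mesh$vertices, tri_k)),
                 provenance = provenance,
                 head = list(center = head$center, radius = head$radius,
                             rms = head$rms)),
            class = "wba_patch")
}

#' @export
print.wba_patch <- function(x, ...) {
  cat(sprintf("wba_patch: %d facets, area %.2f mm^2, %d boundary loop(s)\n",
              length(x$facets), x$area, length(x$boundary)))
  if (!is.null(x$provenance$n_components_before_reduction) &&
      x$provenance$n_components_before_reduction > 1L)
    cat(sprintf("  note: reduced from %d edge-connected components\n",
                x$provenance$n_components_before_reduction))
  invisible(x)
}

#' Weight-bearing patch area
#'
#' Exact sum of the triangle areas of the patch facets.
#' @param patch a `wba_patch` (or any list with `mesh` and `facets`).
#' @return area in mm^2 (0 for an empty facet set).
#' @export
patch_area <- function(patch) {
  if (length(patch$facets) == 0L) return(0)
  sum(triangle_areas(patch$mesh$vertices,
                     patch$mesh$triangles[patch$facets, , drop = FALSE]))
}

#' Centroid of the patch surface (area-weighted)
#' @param patch a `wba_patch`.
#' @return 3-vector (mm).
#' @export
patch_centroid <- function(patch) {
  tri <- patch$mesh$triangles[patch$facets, , drop = FALSE]
  a <- triangle_areas(patch$mesh$vertices, tri)
  cent <- triangle_centroids(patch$mesh$vertices, tri)
  as.numeric(colSums(cent * a) / sum(a))
}

#' Membership test for the patch's trimming constraints
#'
#' Applies the patch's recorded half-space and inferior-limit tests to
#' arbitrary 3D points. This is the single classification rule shared by the
#' facet trim, the Monte-Carlo area oracle, and the resolution of the FE
#' loading region on the volume mesh.
#'
#' @param points `n x 3` matrix (mm).
#' @param provenance a `wba_patch$provenance` list.
#' @return logical vector.
#' @export
patch_membership <- function(points, provenance) {
  points <- as_point_matrix(points, 3L)
  keep <- rep(TRUE, nrow(points))
  for (hs in provenance$half_spaces %||% list())
    keep <- keep & as.vector(half_space_keep(points, hs))
  inf <- provenance$inferior
  rel <- sweep(points, 2L, inf$center)
  elev <- asin(pmin(pmax((rel %*% inf$superior) / sqrt(rowSums(rel^2)), -1), 1))
  keep & (as.numeric(elev) >= -deg2rad(inf$limit_deg))
}

#' Monte-Carlo surface-integral estimate of the patch area
#'
#' Samples points uniformly on the fitted head sphere and applies the same
#' half-space tests as the facet trim; the patch area estimate is the hit
#' fraction times the sphere area. Serves as the independent check on the
#' facet-based area.
#'
#' @param patch a `wba_patch`.
#' @param n number of sample points.
#' @param seed RNG seed.
#' @return list with `area` (mm^2) and `se` (standard error, mm^2).
#' @export
patch_area_mc <- function(patch, n = 1e6, seed = 1L) {
  set.seed(seed)
  z <- stats::rnorm(n); x <- stats::rnorm(n); y <- stats::rnorm(n)
  dirs <- cbind(x, y, z) / sqrt(x^2 + y^2 + z^2)
  pts <- sweep(patch$head$radius * dirs, 2L, patch$head$center, "+")
  hit <- patch_membership(pts, patch$provenance)
  p <- mean(hit)
  total <- 4 * pi * patch$head$radius^2
  list(area = p * total, se = total * sqrt(p * (1 - p) / n))
}

#' Fillet (round) the patch boundary corners
#'
#' Replaces sharp boundary corners by arcs of the given radius in the local
#' tangent plane of the fitted sphere and drops the facets whose centroids
#' fall in the removed corner wedges. Intended to ease FE post-processing;
#' the reported weight-bearing area excludes the fillet unless it is
#' requested explicitly.
#'
#' @param patch a `wba_patch`.
#' @param fillet_radius corner radius in mm (default 1); 0 returns the patch
#'   unchanged.
#' @param corner_threshold_deg only corners turning more than this are
#'   filleted (arc sampling stays below it, making the operation idempotent).
#' @return the smoothed `wba_patch`; the area change is recorded in
#'   `$fillet` (`area_before`, `area_after`, `radius`).
#' @export
smooth_patch_boundary <- function(patch, fillet_radius = 1,
                                  corner_threshold_deg = 10) {
  stopifnot(inherits(patch, "wba_patch"))
  if (fillet_radius < 0) stop("fillet_radius must be non-negative", call. = FALSE)
  if (fillet_radius == 0) return(patch)
  area0 <- patch_area(patch)
  inradius_proxy <- sqrt(area0 / pi)
  if (fillet_radius > inradius_proxy) {
    warning("fillet radius exceeds the patch inradius; returning unsmoothed patch",
            call. = FALSE)
    return(patch)
  }
  center <- patch$head$center
  tri <- patch$mesh$triangles[patch$facets, , drop = FALSE]
  cent <- triangle_centroids(patch$mesh$vertices, tri)
  drop <- rep(FALSE, length(patch$facets))
  new_boundary <- list()
  thr <- deg2rad(corner_threshold_deg)
  for (loop in patch$boundary) {
    pts <- loop
    closed <- isTRUE(all.equal(pts[1L, ], pts[nrow(pts), ], tolerance = 1e-12,
                               check.attributes = FALSE))
    if (closed) pts <- pts[-nrow(pts), , drop = FALSE]
    np <- nrow(pts)
    if (np < 3L) { new_boundary[[length(new_boundary) + 1L]] <- loop; next }
    out_pts <- list()
    for (i in seq_len(np)) {
      prev <- pts[if (i == 1L) np else i - 1L, ]
      cur <- pts[i, ]
      nxt <- pts[if (i == np) 1L else i + 1L, ]
      n_loc <- unitize(cur - center)              # sphere tangent-plane normal
      b <- orthonormal_basis(n_loc)
      to2 <- function(p) {
        rel <- p - cur
        rel <- rel - sum(rel * n_loc) * n_loc
        c(sum(rel * b$u), sum(rel * b$v))
      }
      a2 <- to2(prev); c2 <- to2(nxt)
      la <- vec_norm(a2); lc <- vec_norm(c2)
      if (la < 1e-9 || lc < 1e-9) { out_pts[[length(out_pts) + 1L]] <- cur; next }
      ua <- a2 / la; uc <- c2 / lc
      interior <- acos(pmin(pmax(sum(ua * uc), -1), 1))
      turning <- pi - interior
      if (turning < thr || interior < 1e-6) {
        out_pts[[length(out_pts) + 1L]] <- cur
        next
      }
      t_len <- fillet_radius / tan(interior / 2)
      if (t_len > 0.5 * min(la, lc)) {            # no room: keep the corner
        out_pts[[length(out_pts) + 1L]] <- cur
        next
      }
      t1 <- ua * t_len; t2 <- uc * t_len
      bis <- unitize(ua + uc)
      arc_c <- bis * fillet_radius / sin(interior / 2)
      # drop facet centroids inside the corner wedge: corner side of the
      # chord t1-t2 and outside the fillet circle
      near <- which(!drop &
                      sqrt(rowSums(sweep(cent, 2L, cur)^2)) <
                        3 * max(t_len, fillet_radius))
      if (length(near)) {
        rel <- sweep(cent[near, , drop = FALSE], 2L, cur)
        rel <- rel - (rel %*% n_loc) %*% t(n_loc)
        u2 <- cbind(rel %*% b$u, rel %*% b$v)
        chord <- t2 - t1
        side_corner <- sign((0 - t1[1L]) * chord[2L] - (0 - t1[2L]) * chord[1L])
        s_pt <- (u2[, 1L] - t1[1L]) * chord[2L] - (u2[, 2L] - t1[2L]) * chord[1L]
        outside_circle <- sqrt((u2[, 1L] - arc_c[1L])^2 +
                                 (u2[, 2L] - arc_c[2L])^2) > fillet_radius
        drop[near[side_corner * s_pt > 0 & outside_circle]] <- TRUE
      }
      # arc samples from t1 to t2 (lifted back to 3D)
      ang1 <- atan2(t1[2L] - arc_c[2L], t1[1L] - arc_c[1L])
      ang2 <- atan2(t2[2L] - arc_c[2L], t2[1L] - arc_c[1L])
      dang <- ang2 - ang1
      if (dang > pi) dang <- dang - 2 * pi
      if (dang < -pi) dang <- dang + 2 * pi
      n_arc <- max(2L, ceiling(abs(dang) / (thr * 0.8)))
      angs <- ang1 + dang * seq(0, 1, length.out = n_arc + 1L)
      arc2 <- cbind(arc_c[1L] + fillet_radius * cos(angs),
                    arc_c[2L] + fillet_radius * sin(angs))
      arc3 <- sweep(arc2[, 1L] %o% b$u + arc2[, 2L] %o% b$v, 2L, cur, "+")
      out_pts[[length(out_pts) + 1L]] <- arc3
    }
    newp <- do.call(rbind, lapply(out_pts, rbind))
    if (closed) newp <- rbind(newp, newp[1L, ])
    new_boundary[[length(new_boundary) + 1L]] <- newp
  }
  kept <- patch$facets[!drop]
  patch$facets <- kept
  patch$boundary <- new_boundary
  patch$area <- patch_area(patch)
  patch$fillet <- list(radius = fillet_radius, area_before = area0,
                       area_after = patch$area)
  patch
}
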