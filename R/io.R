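# Plain-text readers/writers for the exchange formats the pipeline uses:
# ASCII STL surface meshes, legacy ASCII VTK unstructured grids, a minimal
# Abaqus INP dialect (*NODE, *ELEMENT, *ELSET, *NSET) and the landmark
# JSON/CSV schema.

#' Write a surface mesh as ASCII STL
#' @param mesh a [surface_mesh()].
#' @param path output file.
#' @param name solid name.
#' @export
write_stl <- function(mesh, path, name = "wbafem") {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1L], , drop = FALSE]
  b <- v[tr[, 2L], , drop = FALSE]
  cc <- v[tr[, 3L], , drop = FALSE]
  n <- cross3_rows(b - a, cc - a)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  block <- sprintf(
    "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
    n[, 1L], n[, 2L], n[, 3L], a[, 1L], a[, 2L], a[, 3L],
    b[, 1L], b[, 2L], b[, 3L], cc[, 1L], cc[, 2L], cc[, 3L])
  writeLines(block, con)
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Read an ASCII STL file
#'
#' Rebuilds an indexed mesh by merging exactly coincident vertices.
#' @param path STL file path.
#' @return a [surface_mesh()].
#' @export
read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vx) == 0L || length(vx) %% 3L != 0L)
    stop("not a valid ASCII STL file: ", path, call. = FALSE)
  nums <- t(vapply(strsplit(trimws(vx), "\\s+"),
                   function(p) as.numeric(p[2:4]), numeric(3)))
  key <- paste(sprintf("%.9g", nums[, 1L]), sprintf("%.9g", nums[, 2L]),
               sprintf("%.9g", nums[, 3L]))
  uid <- match(key, unique(key))
  verts <- nums[!duplicated(key), , drop = FALSE]
  tris <- matrix(uid, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, tris)
}

#' Write a tetrahedral model (or stress field) as legacy ASCII VTK
#'
#' Unstructured grid with material labels as cell data; optionally nodal
#' displacements and element Von Mises / principal stresses from a
#' [assemble_and_solve()] result, for visualization.
#'
#' @param model a [tet_model()].
#' @param path output file.
#' @param field optional `stress_field`.
#' @export
write_vtk <- function(model, path, field = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(model$nodes); m <- nrow(model$elements)
  writeLines(c("# vtk DataFile Version 3.0", "wbafem tetrahedral model",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", model$nodes[, 1L], model$nodes[, 2L],
                     model$nodes[, 3L]), con)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(sprintf("4 %d %d %d %d", model$elements[, 1L] - 1L,
                     model$elements[, 2L] - 1L, model$elements[, 3L] - 1L,
                     model$elements[, 4L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  writeLines(c(sprintf("CELL_DATA %d", m), "SCALARS material int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(ifelse(model$labels == "cortical", 1L, 2L)), con)
  if (!is.null(field)) {
    writeLines("SCALARS von_mises double 1", con)
    writeLines("LOOKUP_TABLE default", con)
    writeLines(sprintf("%.9g", field$von_mises), con)
    writeLines(c(sprintf("POINT_DATA %d", n), "VECTORS displacement double"), con)
    writeLines(sprintf("%.9g %.9g %.9g", field$displacements[, 1L],
                       field$displacements[, 2L], field$displacements[, 3L]), con)
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured tetrahedral grid
#' @param path VTK file.
#' @return a [tet_model()] (material cell data 1 = cortical, 2 = cancellous;
#'   defaults to cortical when absent).
#' @export
read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", lines)
  if (length(ip) != 1L) stop("not a legacy VTK unstructured grid: ", path,
                             call. = FALSE)
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1L]][2L])
  pt_nums <- scan(text = paste(lines[(ip + 1L):length(lines)], collapse = "\n"),
                  n = 3L * n, quiet = TRUE)
  nodes <- matrix(pt_nums, ncol = 3L, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1L]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1L]][2L])
  cell_lines <- lines[(ic + 1L):(ic + m)]
  cells <- t(vapply(strsplit(trimws(cell_lines), "\\s+"),
                    function(p) as.integer(p), integer(5)))
  if (any(cells[, 1L] != 4L))
    stop("only 4-node tetrahedral cells are supported", call. = FALSE)
  elements <- cells[, 2:5, drop = FALSE] + 1L
  labels <- rep("cortical", m)
  im <- grep("^SCALARS material", lines)
  if (length(im) == 1L) {
    vals <- scan(text = paste(lines[(im + 2L):length(lines)], collapse = "\n"),
                 n = m, quiet = TRUE)
    labels <- ifelse(vals == 1, "cortical", "cancellous")
  }
  tet_model(nodes, elements, labels)
}

#' Write a tetrahedral model in the minimal Abaqus INP dialect
#'
#' Emits `*NODE`, one `*ELEMENT, TYPE=C3D4` block per material with a
#' matching `*ELSET`, and one `*NSET` block per named node set.
#'
#' @param model a [tet_model()].
#' @param path output file.
#' @export
write_inp <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*HEADING", con)
  writeLines("wbafem proximal femur model (N-mm-MPa)", con)
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(model$nodes)),
                     model$nodes[, 1L], model$nodes[, 2L], model$nodes[, 3L]), con)
  for (lab in c("cortical", "cancellous")) {
    ids <- which(model$labels == lab)
    if (!length(ids)) next
    writeLines(sprintf("*ELEMENT, TYPE=C3D4, ELSET=%s", toupper(lab)), con)
    writeLines(sprintf("%d, %d, %d, %d, %d", ids, model$elements[ids, 1L],
                       model$elements[ids, 2L], model$elements[ids, 3L],
                       model$elements[ids, 4L]), con)
  }
  for (nm in names(model$node_sets)) {
    writeLines(sprintf("*NSET, NSET=%s", toupper(nm)), con)
    writeLines(chunk_ids(model$node_sets[[nm]]), con)
  }
  invisible(path)
}

chunk_ids <- function(ids, per_line = 12L) {
  ids <- as.integer(ids)
  starts <- seq(1L, length(ids), by = per_line)
  vapply(starts, function(s)
    paste(ids[s:min(s + per_line - 1L, length(ids))], collapse = ", "),
    character(1))
}

#' Read the minimal Abaqus INP dialect
#'
#' Supports `*NODE`, `*ELEMENT` of `TYPE=C3D4` or `C3D10` (quadratic
#' elements contribute their four corner nodes), `*ELSET` (the set names
#' `CORTICAL`/`CANCELLOUS`, or `ELSET=` on the element block, drive the
#' material label) and `*NSET`.
#'
#' @param path INP file.
#' @return a [tet_model()].
#' @export
read_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\*\\*", lines)]
  is_kw <- grepl("^\\*", lines)
  kw_idx <- which(is_kw)
  blocks <- list()
  for (k in seq_along(kw_idx)) {
    from <- kw_idx[k] + 1L
    to <- if (k < length(kw_idx)) kw_idx[k + 1L] - 1L else length(lines)
    blocks[[k]] <- list(header = toupper(lines[kw_idx[k]]),
                        body = if (from <= to) lines[from:to] else character(0))
  }
  nodes <- NULL; node_ids <- NULL
  elem_rows <- list(); elem_ids <- list(); elem_labels <- list()
  nsets <- list(); elsets <- list()
  for (bl in blocks) {
    h <- bl$header
    if (startsWith(h, "*NODE")) {
      parts <- strsplit(gsub("\\s", "", bl$body), ",")
      dat <- t(vapply(parts, function(p) as.numeric(p[1:4]), numeric(4)))
      node_ids <- as.integer(dat[, 1L])
      nodes <- dat[, 2:4, drop = FALSE]
    } else if (startsWith(h, "*ELEMENT")) {
      type <- sub(".*TYPE=([A-Z0-9]+).*", "\\1", h)
      if (!type %in% c("C3D4", "C3D10"))
        stop("unsupported element type: ", type, call. = FALSE)
      elset <- if (grepl("ELSET=", h)) sub(".*ELSET=([A-Z0-9_]+).*", "\\1", h) else NA
      parts <- strsplit(gsub("\\s", "", bl$body), ",")
      dat <- t(vapply(parts, function(p) as.numeric(p[1:5]), numeric(5)))
      elem_ids[[length(elem_ids) + 1L]] <- as.integer(dat[, 1L])
      elem_rows[[length(elem_rows) + 1L]] <- matrix(as.integer(dat[, 2:5]),
                                                    ncol = 4L)
      elem_labels[[length(elem_labels) + 1L]] <-
        rep(tolower(if (is.na(elset)) "cortical" else elset), nrow(dat))
    } else if (startsWith(h, "*NSET")) {
      nm <- tolower(sub(".*NSET=([A-Z0-9_]+).*", "\\1", h))
      ids <- as.integer(unlist(strsplit(gsub("\\s", "", bl$body), ",")))
      nsets[[nm]] <- ids[!is.na(ids)]
    } else if (startsWith(h, "*ELSET")) {
      nm <- tolower(sub(".*ELSET=([A-Z0-9_]+).*", "\\1", h))
      ids <- as.integer(unlist(strsplit(gsub("\\s", "", bl$body), ",")))
      elsets[[nm]] <- ids[!is.na(ids)]
    }
  }
  if (is.null(nodes)) stop("no *NODE block found", call. = FALSE)
  elements <- do.call(rbind, elem_rows)
  eids <- unlist(elem_ids)
  labels <- unlist(elem_labels)
  ord <- order(eids)                      # restore the original element order
  elements <- elements[ord, , drop = FALSE]
  eids <- eids[ord]; labels <- labels[ord]
  for (nm in intersect(names(elsets), c("cortical", "cancellous")))
    labels[match(elsets[[nm]], eids)] <- nm
  labels[!labels %in% c("cortical", "cancellous")] <- "cortical"
  # remap node ids to 1..n
  remap <- integer(max(node_ids)); remap[node_ids] <- seq_along(node_ids)
  elements <- matrix(remap[elements], ncol = 4L)
  nsets <- lapply(nsets, function(ids) as.integer(remap[ids]))
  tet_model(nodes, elements, labels, node_sets = nsets)
}

#' Write a landmark set as JSON
#'
#' Schema: `{side, marker: {measured_mm, true_mm}, points: {"p1": [x, y], ...}}`.
#' @param lm a [radiograph_landmarks()] set.
#' @param path output file.
#' @export
write_landmarks_json <- function(lm, path) {
  pts <- stats::setNames(lapply(seq_len(nrow(lm$points)),
                                function(i) as.numeric(lm$points[i, ])),
                         rownames(lm$points))
  obj <- list(side = lm$side,
              marker = list(measured_mm = lm$marker_measured,
                            true_mm = lm$marker_true),
              points = pts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landmark set from JSON
#' @param path JSON file in the schema of [write_landmarks_json()].
#' @return a [radiograph_landmarks()] set.
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- do.call(rbind, lapply(obj$points, as.numeric))
  rownames(pts) <- names(obj$points)
  radiograph_landmarks(points = pts, side = obj$side,
                       marker_measured = obj$marker$measured_mm,
                       marker_true = obj$marker$true_mm)
}

#' Read a landmark set from CSV
#'
#' Expects columns `name`, `x_mm`, `y_mm`; the marker diameters are supplied
#' as arguments because the CSV carries coordinates only.
#' @param path CSV file.
#' @param side hip side.
#' @param marker_measured,marker_true marker diameters (mm).
#' @return a [radiograph_landmarks()] set.
#' @export
read_landmarks_csv <- function(path, side, marker_measured, marker_true = 25) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns name, x_mm, y_mm", call. = FALSE)
  pts <- as.matrix(df[, c("x_mm", "y_mm")])
  rownames(pts) <- df$name
  radiograph_landmarks(pts, side = side, marker_measured = marker_measured,
                       marker_true = marker_true)
}

#' Write a landmark set as CSV (columns name, x_mm, y_mm)
#' @param lm a [radiograph_landmarks()] set.
#' @param path output file.
#' @export
write_landmarks_csv <- function(lm, path) {
  df <- data.frame(name = rownames(lm$points), x_mm = lm$points[, 1L],
                   y_mm = lm$points[, 2L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a registration report as JSON
#' @param reg a [planar_registration()].
#' @param path output file.
#' @export
write_registration_json <- function(reg, path) {
  obj <- list(rotation_deg = reg$rotation_deg,
              translation_mm = reg$translation, scale = reg$scale,
              rms_error_mm = reg$rms_error,
              correspondences = reg$correspondences,
              residuals_mm = as.list(reg$residuals))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a weight-bearing patch
#'
#' Writes the patch as (a) an STL sub-mesh, (b) a JSON facet-index set with
#' the area and trimming parameters, or (c) an Abaqus `*NSET` block of the
#' volume-mesh nodes inside the patch region (for FE loading).
#'
#' @param patch a `wba_patch`.
#' @param path output file.
#' @param format `"stl"`, `"json"` or `"nset"`.
#' @param model a [tet_model()]; required for `"nset"`.
#' @param nset_name node-set name for the `*NSET` block.
#' @export
write_patch <- function(patch, path, format = c("stl", "json", "nset"),
                        model = NULL, nset_name = "PATCH_NODES") {
  format <- match.arg(format)
  if (format == "stl") {
    tr <- patch$mesh$triangles[patch$facets, , drop = FALSE]
    used <- sort(unique(as.vector(tr)))
    remap <- integer(max(used)); remap[used] <- seq_along(used)
    sub <- surface_mesh(patch$mesh$vertices[used, , drop = FALSE],
                        matrix(remap[tr], ncol = 3L))
    write_stl(sub, path, name = "weight_bearing_patch")
  } else if (format == "json") {
    obj <- list(area_mm2 = patch$area, n_facets = length(patch$facets),
                facets = patch$facets,
                head = patch$head,
                inferior_limit_deg = patch$provenance$inferior$limit_deg,
                superior_direction = patch$provenance$inferior$superior)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    if (is.null(model)) stop("format 'nset' requires a tet model", call. = FALSE)
    nodes <- patch_nodes_on_model(patch, model)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("*NSET, NSET=%s", toupper(nset_name)), con)
    writeLines(chunk_ids(nodes), con)
  }
  invisible(path)
}

# Volume-mesh nodes on the articular surface inside the patch region.
patch_nodes_on_model <- function(patch, model, tol = NULL) {
  tol <- tol %||% (if (!is.null(model$voxel_size)) 0.75 * model$voxel_size else 1.5)
  bf <- boundary_faces(model)
  on_head <- abs(sqrt(rowSums(sweep(bf$centroids, 2L, patch$head$center)^2)) -
                   patch$head$radius) <= tol
  keep <- on_head & patch_membership(bf$centroids, patch$provenance)
  sort(unique(as.vector(bf$faces[keep, , drop = FALSE])))
}
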