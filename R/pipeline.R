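# End-to-end orchestration: landmarks -> margin lines -> registration ->
# weight-bearing patch -> FE load-case comparison, with a run manifest and a
# packaged synthetic demo volunteer.

#' Default standing joint reaction force
#'
#' Single-leg-stance hip contact force used by the demo configuration:
#' magnitude about 2.4 x body weight for a 75 kg adult (1800 N), tilted 13
#' degrees laterally and about 4.6 degrees posteriorly from the vertical in
#' the `+x` medial / `+y` anterior / `+z` superior frame, following the
#' orientation ranges reported by instrumented-implant and musculoskeletal
#' studies. The force acts on the femoral head, pointing inferiorly.
#'
#' @param side hip side (the lateral tilt mirrors for the left hip).
#' @param magnitude_N force magnitude (N).
#' @return 3-vector (N).
#' @export
default_jrf <- function(side = c("right", "left"), magnitude_N = 1800) {
  side <- match.arg(side)
  d <- unitize(c(-sin(deg2rad(13)), -sin(deg2rad(4.6)), -1))
  if (side == "left") d[1L] <- -d[1L]
  magnitude_N * d
}

#' Default simplified muscle loads for the standing femur
#'
#' Two extra point-load groups completing the stance load model alongside
#' the joint reaction force: the iliotibial-band/vastus tension band acting
#' inferiorly along the lateral greater trochanter (about 1.6 body weights)
#' and the iliopsoas acting superomedially-anteriorly at the lesser
#' trochanter (about 1 body weight). A joint force applied alone to a
#' distally clamped femur exaggerates proximal bending; the tension-band
#' action of the lateral soft tissues is what keeps the physiological
#' proximal femur predominantly in compression.
#'
#' @param model a [generate_tet_mesh()] result (needs the `gt_lateral` and
#'   `lesser_trochanter` node sets and the `anatomy` parameters).
#' @param body_weight_N body weight (default 750 N, a 76 kg adult).
#' @return a list of `list(nodes, force)` entries for
#'   [build_load_case()]'s `extra` parameter, or `NULL` when the model
#'   lacks the attachment node sets.
#' @export
default_muscle_loads <- function(model, body_weight_N = 750) {
  gt <- model$node_sets$gt_lateral
  lt <- model$node_sets$lesser_trochanter
  if (is.null(gt) || is.null(lt) || !length(gt) || !length(lt)) return(NULL)
  msign <- if (!is.null(model$anatomy) && model$anatomy$side == "left") -1 else 1
  list(
    list(name = "iliotibial_band", nodes = gt,
         force = 1.6 * body_weight_N * c(0, 0, -1)),
    list(name = "iliopsoas", nodes = lt,
         force = 1.0 * body_weight_N * unitize(c(msign * 0.25, 0.2, 0.95))))
}

#' Pipeline configuration
#'
#' Collects all inputs and parameters of a run. Any entry accepting a file
#' path also accepts the corresponding in-memory object.
#'
#' @param landmarks landmark JSON/CSV path or a [radiograph_landmarks()] set.
#' @param surface_mesh STL path or a [surface_mesh()].
#' @param tet_mesh INP/VTK path or a [tet_model()]; required for FE stages.
#' @param mesh_landmarks named 3D landmark positions on the mesh (matrix with
#'   row names, or a JSON path with `{name: [x,y,z], ...}`), used for
#'   registration.
#' @param marker_true_mm true marker diameter (mm).
#' @param limit_deg inferior limit (degrees).
#' @param fillet logical: apply the 1 mm boundary fillet before reporting.
#' @param fillet_radius_mm fillet radius.
#' @param load_cases subset of `c("A", "B", "C")` to run.
#' @param total_force_N joint reaction force vector (N); defaults to
#'   [default_jrf()] for the landmark side.
#' @param materials a [material_spec()].
#' @param muscle_loads `TRUE` (default) to add [default_muscle_loads()] to
#'   every load case, `FALSE` for joint-force-only loading, or an explicit
#'   list of `list(nodes, force)` entries.
#' @param head_hint optional list(center, radius) seeding the sphere fit.
#' @param registration_names landmark names used as registration
#'   correspondences.
#' @param allow_scale allow a scale factor in the registration.
#' @param circle_diameter_mm case-B circle diameter.
#' @param stages which stages to run: subset of `c("wba", "fe")`.
#' @param output_dir output directory.
#' @param seed integer seed recorded in the manifest.
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(landmarks, surface_mesh = NULL, tet_mesh = NULL,
                            mesh_landmarks = NULL, marker_true_mm = 25,
                            limit_deg = 30, fillet = FALSE,
                            fillet_radius_mm = 1,
                            load_cases = c("A", "B", "C"),
                            total_force_N = NULL,
                            materials = material_spec(), muscle_loads = TRUE,
                            head_hint = NULL,
                            registration_names = c("p1", "p2", "p3", "p6",
                                                   "p16", "p19"),
                            allow_scale = TRUE, circle_diameter_mm = 20,
                            stages = c("wba", "fe"), output_dir = tempdir(),
                            seed = 1L, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (length(stages) == 0L) stop("config error: no stages requested", call. = FALSE)
  stages <- match.arg(stages, c("wba", "fe"), several.ok = TRUE)
  load_cases <- match.arg(load_cases, c("A", "B", "C"), several.ok = TRUE)
  for (p in list(landmarks, surface_mesh, tet_mesh, mesh_landmarks)) {
    if (is.character(p) && length(p) == 1L && !file.exists(p))
      stop("config error: input file does not exist: ", p, call. = FALSE)
  }
  if ("wba" %in% stages && is.null(surface_mesh))
    stop("config error: stage 'wba' requires a surface mesh", call. = FALSE)
  if ("fe" %in% stages && is.null(tet_mesh))
    stop("config error: stage 'fe' requires a tetrahedral mesh", call. = FALSE)
  structure(list(landmarks = landmarks, surface_mesh = surface_mesh,
                 tet_mesh = tet_mesh, mesh_landmarks = mesh_landmarks,
                 marker_true_mm = marker_true_mm, limit_deg = limit_deg,
                 fillet = fillet, fillet_radius_mm = fillet_radius_mm,
                 load_cases = load_cases, total_force_N = total_force_N,
                 materials = materials, muscle_loads = muscle_loads,
                 head_hint = head_hint,
                 registration_names = registration_names,
                 allow_scale = allow_scale,
                 circle_diameter_mm = circle_diameter_mm, stages = stages,
                 output_dir = output_dir, seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

pipeline_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) message(sprintf(fmt, ...))
  invisible(NULL)
}

resolve_landmarks <- function(x) {
  if (inherits(x, "radiograph_landmarks")) return(x)
  if (grepl("\\.json$", x, ignore.case = TRUE)) return(read_landmarks_json(x))
  stop("config error: landmark CSV input needs marker data; use read_landmarks_csv() and pass the object",
       call. = FALSE)
}

resolve_surface <- function(x) {
  if (inherits(x, "surface_mesh")) return(x)
  read_stl(x)
}

resolve_tet <- function(x) {
  if (inherits(x, "tet_model")) return(x)
  if (grepl("\\.vtk$", x, ignore.case = TRUE)) return(read_vtk(x))
  read_inp(x)
}

resolve_mesh_landmarks <- function(x) {
  if (is.matrix(x)) return(x)
  obj <- jsonlite::read_json(x, simplifyVector = TRUE)
  lm <- do.call(rbind, lapply(obj, as.numeric))
  rownames(lm) <- names(obj)
  lm
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in order: magnification correction and
#' boundary construction, sphere fit and registration, patch trimming and
#' area quantification (`wba`), then the FE load-case comparison (`fe`).
#' Writes patch exports, an area report, the FE comparison report, and a
#' manifest with parameters and output checksums.
#'
#' @param config a [pipeline_config()].
#' @return a list (the run manifest plus in-memory results `patch`,
#'   `construction`, `registration`, `comparison`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  t0 <- Sys.time()

  lm <- resolve_landmarks(config$landmarks)
  lm_corr <- correct_magnification(lm)
  pipeline_log(config, "landmarks: %d points (%s hip), magnification scale %.4f",
               nrow(lm_corr$points), lm_corr$side, attr(lm_corr, "scale"))
  construction <- build_boundary_construction(lm_corr)
  pipeline_log(config, "boundary construction: CE angle %.2f deg", construction$ce_deg)
  force <- config$total_force_N %||% default_jrf(lm$side)

  patch <- NULL; registration <- NULL; head_fit <- NULL
  if ("wba" %in% config$stages) {
    mesh <- resolve_surface(config$surface_mesh)
    head_fit <- fit_head_sphere(mesh, hint = config$head_hint %||% mesh$head_vertices)
    pipeline_log(config, "head sphere: centre (%.2f, %.2f, %.2f), radius %.2f mm, rms %.3g mm",
                 head_fit$center[1L], head_fit$center[2L], head_fit$center[3L],
                 head_fit$radius, head_fit$rms)
    plane <- datum_plane()
    if (is.null(config$mesh_landmarks))
      stop("config error: stage 'wba' requires mesh_landmarks for registration",
           call. = FALSE)
    mlm3 <- resolve_mesh_landmarks(config$mesh_landmarks)
    source2 <- project_to_plane(mlm3, plane)
    rownames(source2) <- rownames(mlm3)
    registration <- register_landmarks(source2, lm_corr$points,
                                       allow_scale = config$allow_scale,
                                       names = config$registration_names)
    pipeline_log(config, "registration: rot %.3f deg, scale %.5f, rms %.3g mm",
                 registration$rotation_deg, registration$scale,
                 registration$rms_error)
    lat3 <- lift_line(construction$lateral_line, registration, plane)
    med3 <- lift_line(construction$medial_line, registration, plane)
    beta <- trim_by_margin_lines(head_fit, lat3, med3, plane)
    pipeline_log(config, "margin trim: removed %d (lateral) + %d (medial) of %d head facets",
                 beta$removed[1L], beta$removed[2L], length(head_fit$head_facets))
    patch <- apply_inferior_limit(beta$facets, head_fit,
                                  jrf_direction = unitize(force),
                                  limit_deg = config$limit_deg,
                                  half_spaces = beta$half_spaces)
    pipeline_log(config, "inferior limit %g deg: patch %d facets, area %.2f mm^2",
                 config$limit_deg, length(patch$facets), patch$area)
    if (isTRUE(config$fillet)) {
      patch <- smooth_patch_boundary(patch, config$fillet_radius_mm)
      pipeline_log(config, "fillet %.1f mm: area %.2f -> %.2f mm^2",
                   config$fillet_radius_mm, patch$fillet$area_before, patch$area)
    }
    write_patch(patch, out("patch.stl"), "stl")
    write_patch(patch, out("patch.json"), "json")
    write_registration_json(registration, out("registration.json"))
    area_report <- list(area_mm2 = patch$area, n_facets = length(patch$facets),
                        ce_angle_deg = construction$ce_deg,
                        limit_deg = config$limit_deg,
                        fillet = isTRUE(config$fillet),
                        head_radius_mm = head_fit$radius)
    jsonlite::write_json(area_report, out("area_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  comparison <- NULL
  if ("fe" %in% config$stages) {
    model <- resolve_tet(config$tet_mesh)
    muscles <- config$muscle_loads
    if (isTRUE(muscles)) muscles <- default_muscle_loads(model)
    if (isFALSE(muscles)) muscles <- NULL
    if (!is.null(muscles))
      pipeline_log(config, "muscle loads: %s",
                   paste(vapply(muscles, function(m)
                     sprintf("%s (%.0f N over %d nodes)",
                             m$name %||% "muscle", vec_norm(m$force),
                             length(m$nodes)), character(1)), collapse = ", "))
    cases <- list()
    for (lc in config$load_cases) {
      cases[[lc]] <- switch(lc,
        A = {
          if (is.null(patch))
            stop("config error: case A requires the 'wba' stage (the patch defines the load region)",
                 call. = FALSE)
          build_load_case(model, "A_patch", force,
                          list(patch = patch, extra = muscles))
        },
        B = build_load_case(model, "B_circle", force,
                            list(diameter_mm = config$circle_diameter_mm,
                                 extra = muscles)),
        C = build_load_case(model, "C_point", force,
                            list(extra = muscles)))
      pipeline_log(config, "case %s: load over %d node(s)", lc,
                   length(cases[[lc]]$nodes))
    }
    comparison <- compare_load_cases(model, config$materials, cases)
    for (nm in names(comparison$cases)) {
      r <- comparison$cases[[nm]]
      pipeline_log(config, "case %s: max cortical Von Mises %.3f MPa -- %s",
                   nm, r$peak$von_mises, r$classifier)
    }
    report <- lapply(comparison$cases, function(r)
      list(kind = r$kind, max_cortical_von_mises_MPa = r$peak$von_mises,
           peak_location_mm = as.numeric(r$peak$location),
           classifier = r$classifier,
           distance_to_loaded_mm = r$distance_to_loaded_mm,
           distance_to_junction_mm = r$distance_to_junction_mm,
           equilibrium_residual_N = as.numeric(r$equilibrium_residual_N)))
    jsonlite::write_json(report, out("fe_report.json"), auto_unbox = TRUE,
                         digits = NA)
    if (!is.null(comparison$path_table))
      utils::write.csv(comparison$path_table, out("path_alpha.csv"),
                       row.names = FALSE)
  }

  outputs <- list.files(config$output_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    package = "wbafem",
    version = as.character(utils::packageVersion("wbafem")),
    seed = config$seed,
    stages = config$stages,
    parameters = list(marker_true_mm = config$marker_true_mm,
                      limit_deg = config$limit_deg,
                      fillet = isTRUE(config$fillet),
                      fillet_radius_mm = config$fillet_radius_mm,
                      load_cases = config$load_cases,
                      total_force_N = as.numeric(force),
                      circle_diameter_mm = config$circle_diameter_mm,
                      muscle_loads = !isFALSE(config$muscle_loads),
                      registration_names = config$registration_names,
                      allow_scale = config$allow_scale,
                      materials = unclass(config$materials)),
    checksums = as.list(tools::md5sum(sort(outputs))),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(manifest,
              list(patch = patch, construction = construction,
                   registration = registration, head_fit = head_fit,
                   comparison = comparison)))
}

#' Write the packaged synthetic demo volunteer
#'
#' Generates one complete synthetic case -- surface STL, labeled tetrahedral
#' mesh (INP and VTK), landmark JSON, mesh-landmark JSON and a ready
#' configuration -- sized to run the full pipeline in a few minutes on one
#' CPU.
#'
#' @param output_dir writable directory.
#' @param seed integer seed (drives the landmark jitter).
#' @param voxel_size_mm FE voxel size (default 2 mm).
#' @param noise_sd_mm landmark jitter (default 0.3 mm).
#' @param target_ce_deg CE angle of the synthetic hip (default 33).
#' @param magnification radiographic magnification (default 1.15).
#' @param params optional [femur_params()] override.
#' @return invisibly, a list with the file paths and the ready
#'   [pipeline_config()].
#' @export
make_demo_fixture <- function(output_dir, seed = 1L, voxel_size_mm = 2,
                              noise_sd_mm = 0.3, target_ce_deg = 33,
                              magnification = 1.15, params = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(output_dir, f)
  if (is.null(params)) params <- femur_params(seed = seed)
  fem <- generate_femur_surface(params)
  rad <- generate_radiograph(fem$truth, magnification = magnification,
                             noise_sd = noise_sd_mm, seed = seed,
                             target_ce_deg = target_ce_deg)
  model <- generate_tet_mesh(params, voxel_size = voxel_size_mm)
  write_stl(fem$mesh, out("femur.stl"))
  write_inp(model, out("femur.inp"))
  write_vtk(model, out("femur.vtk"))
  write_landmarks_json(rad$landmarks, out("landmarks.json"))
  mlm <- rad$truth$landmarks_3d
  jsonlite::write_json(stats::setNames(lapply(seq_len(nrow(mlm)),
                                              function(i) as.numeric(mlm[i, ])),
                                       rownames(mlm)),
                       out("mesh_landmarks.json"), auto_unbox = TRUE, digits = NA)
  truth_obj <- list(side = rad$truth$side,
                    head_center = as.numeric(rad$truth$head_center),
                    head_radius = rad$truth$head_radius,
                    target_ce_deg = target_ce_deg,
                    magnification = magnification,
                    noise_sd_mm = noise_sd_mm)
  jsonlite::write_json(truth_obj, out("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  config <- pipeline_config(landmarks = out("landmarks.json"),
                            surface_mesh = out("femur.stl"),
                            tet_mesh = out("femur.inp"),
                            mesh_landmarks = out("mesh_landmarks.json"),
                            head_hint = list(center = rad$truth$head_center,
                                             radius = rad$truth$head_radius),
                            output_dir = file.path(output_dir, "results"),
                            seed = seed)
  cfg_obj <- list(landmarks = "landmarks.json", surface_mesh = "femur.stl",
                  tet_mesh = "femur.inp", mesh_landmarks = "mesh_landmarks.json",
                  head_hint = list(center = as.numeric(rad$truth$head_center),
                                   radius = rad$truth$head_radius),
                  seed = seed)
  jsonlite::write_json(cfg_obj, out("config.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(dir = output_dir, config = config,
                 files = list.files(output_dir, full.names = TRUE),
                 params = params, truth = rad$truth))
}
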