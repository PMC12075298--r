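#' Run configuration for the averaging pipeline
#'
#' Collects every tunable of the end-to-end flow with validated defaults.
#' Unknown keys are rejected so typos in config files fail loudly.
#'
#' @param segment_counts named per-segment resampling counts
#'   (see [segment_counts()]).
#' @param voxel_spacing_mm voxelization / surface-extraction grid spacing.
#' @param window_mm cross-section sampling window side length.
#' @param pixel_mm cross-section in-plane sampling step.
#' @param ring_points boundary points per reconstruction ring.
#' @param blend_radius_mm junction smooth-union blend radius (the fillet
#'   analog).
#' @param wall_thickness_mm printable wall thickness.
#' @param smooth_factor Taubin smoothing strength in [0, 1].
#' @param junction_mask_radius_mm radius of the spheres masked out of Dice
#'   comparisons around bifurcation landmarks.
#' @param seed RNG seed recorded with the run.
#' @return A validated `run_config` list.
#' @export
run_config <- function(segment_counts = vesselphantom::segment_counts(),
                       voxel_spacing_mm = 0.5, window_mm = 60, pixel_mm = NULL,
                       ring_points = 32L, blend_radius_mm = 3,
                       wall_thickness_mm = 1.5, smooth_factor = 0.5,
                       junction_mask_radius_mm = 20, seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$pixel_mm)) cfg$pixel_mm <- cfg$voxel_spacing_mm / 2
  num <- c("voxel_spacing_mm", "window_mm", "pixel_mm", "ring_points",
           "blend_radius_mm", "wall_thickness_mm", "junction_mask_radius_mm")
  for (k in num) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0) {
      abort(paste0("Config field `", k, "` must be a positive scalar."))
    }
  }
  if (cfg$smooth_factor < 0 || cfg$smooth_factor > 1) {
    abort("`smooth_factor` must be in [0, 1].")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file; keys must match [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$segment_counts)) {
    raw$segment_counts <- segment_counts(as.list(raw$segment_counts))
  }
  do.call(run_config, raw)
}

pipeline_logger <- function(log_path) {
  function(stage, ...) {
    rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage), list(...))
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE)
    if (!is.null(log_path)) cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(sprintf("[%s] %s", stage, paste(names(rec[-(1:2)]), unlist(rec[-(1:2)]),
                                            sep = "=", collapse = " ")))
    invisible(NULL)
  }
}

#' Run the cohort-averaging pipeline end to end
#'
#' Executes, in order: load each patient's lumen mesh and centerlines,
#' resample centerlines at equal arc length, voxelize the mesh, register to
#' the aortic bifurcation landmark, measure perpendicular cross-sections,
#' average the cohort, reconstruct the averaged lumen surface, smooth it
#' and generate the thin-walled shell, then quality-check the model against
#' every input patient (junction-masked Dice coefficient and closest-point
#' distance map against the first patient). Every stage logs its counts
#' (patients in, sections excluded per segment, ...) as JSON lines.
#'
#' Patient inputs live in `input_dir`, one subdirectory per patient
#' containing `mesh.stl` and `centerlines.csv`.
#'
#' @param input_dir directory of patient subdirectories.
#' @param output_dir where results are written (`averaged_anatomy.csv`,
#'   `lumen.stl`, `shell.stl`, `qc.json`, `log.jsonl`, `config.json`).
#' @param config a [run_config()].
#' @return Invisibly, a list: `anatomy`, `lumen`, `shell`, `qc`.
#' @export
run_average_pipeline <- function(input_dir, output_dir, config = run_config()) {
  if (!dir.exists(input_dir)) abort(paste0("Input directory not found: ", input_dir))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- pipeline_logger(file.path(output_dir, "log.jsonl"))
  jsonlite::write_json(unclass(config), file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  patients <- list.dirs(input_dir, recursive = FALSE)
  if (length(patients) == 0L) abort("No patient subdirectories found.")
  log("load", n_patients = length(patients))

  samples <- list()
  volumes <- list()
  meshes <- list()
  for (pdir in patients) {
    pid <- basename(pdir)
    mesh_path <- file.path(pdir, "mesh.stl")
    cll_path <- file.path(pdir, "centerlines.csv")
    stage <- "load"
    res <- tryCatch({
      if (!file.exists(mesh_path)) abort(paste0("Missing mesh.stl for patient ", pid))
      if (!file.exists(cll_path)) abort(paste0("Missing centerlines.csv for patient ", pid))
      mesh <- load_mesh(mesh_path)
      cll <- load_centerlines(cll_path)
      stage <- "resample"
      rs <- resample_equal_arclength(cll, n = config$segment_counts)
      stage <- "voxelize"
      vol <- voxelize_mesh(mesh, spacing = config$voxel_spacing_mm)
      stage <- "register"
      bif <- detect_bifurcation_point(cll)
      rs <- translate_to_landmark(rs, bif)
      vol <- translate_to_landmark(vol, bif)
      mesh <- translate_to_landmark(mesh, bif)
      stage <- "measure"
      sec <- measure_sections(vol, rs, window = config$window_mm,
                              pixel = config$pixel_mm)
      excl <- dplyr::summarise(dplyr::group_by(sec, .data$label),
                               excluded = sum(!.data$valid), .groups = "drop")
      log("measure", patient = pid,
          sections = nrow(sec), excluded = sum(!sec$valid),
          excluded_by_segment = setNames(excl$excluded, excl$label))
      list(sample = dplyr::mutate(sec, patient = pid), volume = vol, mesh = mesh)
    }, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed for patient %s: %s",
                    stage, pid, conditionMessage(e)))
    })
    samples[[pid]] <- res$sample
    volumes[[pid]] <- res$volume
    meshes[[pid]] <- res$mesh
  }

  log("average", n_patients = length(samples))
  anatomy <- average_cohort(dplyr::bind_rows(samples))
  save_averaged_anatomy(anatomy, file.path(output_dir, "averaged_anatomy.csv"))
  save_averaged_anatomy(anatomy, file.path(output_dir, "averaged_anatomy.json"))

  log("reconstruct", ring_points = config$ring_points,
      blend_radius_mm = config$blend_radius_mm)
  rings <- build_rings(anatomy, m = config$ring_points)
  lumen <- blend_junctions(rings, blend_radius = config$blend_radius_mm,
                           spacing = config$voxel_spacing_mm)
  lumen <- smooth_mesh(lumen, factor = config$smooth_factor)
  save_mesh(lumen, file.path(output_dir, "lumen.stl"))

  log("thin_wall", thickness_mm = config$wall_thickness_mm)
  shell <- thin_wall_shell(lumen, thickness = config$wall_thickness_mm)
  save_mesh(shell, file.path(output_dir, "shell.stl"))

  log("qc", n_patients = length(volumes))
  model_vol <- voxelize_mesh(lumen, spacing = config$voxel_spacing_mm)
  qc_rows <- purrr::imap(volumes, function(v, pid) {
    cg <- common_grid(model_vol, v)
    masked <- lapply(cg, mask_spheres, centers = rbind(c(0, 0, 0)),
                     radius = config$junction_mask_radius_mm)
    tibble(
      patient = pid,
      sdsc = sdsc(cg[[1]], cg[[2]]),
      sdsc_junction_masked = sdsc(masked[[1]], masked[[2]])
    )
  }) |> dplyr::bind_rows()
  dmap <- mesh_distance_map(lumen, meshes[[1]])
  save_mesh(dmap$mesh, file.path(output_dir, "distance_map.ply"), with_scalars = TRUE)
  qc <- list(
    per_patient = qc_rows,
    distance_to_first_patient = as.list(dmap$summary)
  )
  jsonlite::write_json(qc, file.path(output_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log("done", mean_sdsc = mean(qc_rows$sdsc_junction_masked))
  invisible(list(anatomy = anatomy, lumen = lumen, shell = shell, qc = qc))
}

#' Write a synthetic cohort to a patient input directory
#'
#' Materializes [synth_cohort()] output in the directory layout
#' [run_average_pipeline()] consumes (`<patient>/mesh.stl` +
#' `<patient>/centerlines.csv`), with the machine-readable ground truth
#' saved alongside as `ground_truth.json`.
#'
#' @param output_dir target directory.
#' @param base,cohort generator parameter sets.
#' @param spacing mesh extraction spacing (mm).
#' @return `output_dir`, invisibly.
#' @export
write_synth_cohort <- function(output_dir, base = vessel_tree_params(),
                               cohort = cohort_params(), spacing = 0.8) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  co <- synth_cohort(base, cohort, meshes = TRUE, spacing = spacing)
  for (i in seq_along(co$patients)) {
    pdir <- file.path(output_dir, sprintf("patient_%02d", i))
    dir.create(pdir, showWarnings = FALSE)
    save_mesh(co$patients[[i]]$mesh, file.path(pdir, "mesh.stl"))
    save_centerlines(co$patients[[i]]$centerlines, file.path(pdir, "centerlines.csv"))
  }
  truth <- co$ground_truth
  jsonlite::write_json(
    list(
      params = unclass(truth$params),
      cohort = unclass(cohort),
      centerlines = truth$centerlines,
      diameters = truth$diameters
    ),
    file.path(output_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(output_dir)
}
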