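#' Average a cohort of measured patient anatomies
#'
#' Takes per-patient resampled centerline points with measured diameters
#' (long format: one row per patient, segment and point index) and averages
#' coordinates (per axis) and diameters index-wise across patients,
#' restricted at each index to the patients whose measurement there is
#' valid. All patients must share the same per-segment point counts and be
#' registered to a common landmark (see [translate_to_landmark()])
#' beforehand. Patients missing a segment entirely (partial inclusion) are
#' simply absent from that segment's averages.
#'
#' Spread is reported as the sample standard deviation (n-1 denominator)
#' per axis, combined into a single 3D value as
#' `sd_3d = sqrt(sd_x^2 + sd_y^2 + sd_z^2)`, plus the diameter SD.
#'
#' @param samples a tibble with columns `patient`, `label`, `point_index`,
#'   `x`, `y`, `z`, `diameter`, `valid`; or a list of per-patient tibbles
#'   (patient ids taken from names).
#' @return An `averaged_anatomy` tibble: `label`, `point_index`, `x`, `y`,
#'   `z`, `diameter`, `sd_x`, `sd_y`, `sd_z`, `sd_3d`, `sd_diam`,
#'   `n_contrib`, `valid`.
#' @export
average_cohort <- function(samples) {
  samples <- bind_patient_samples(samples)
  counts <- samples |>
    dplyr::distinct(.data$patient, .data$label, .data$point_index) |>
    dplyr::count(.data$patient, .data$label)
  mismatch <- counts |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$n) == 1L, .groups = "drop")
  if (any(!mismatch$ok)) {
    abort(paste0(
      "Patients disagree on resampled point counts for segment(s): ",
      paste(mismatch$label[!mismatch$ok], collapse = ", ")
    ))
  }
  sd0 <- function(v) if (length(v) < 2L) NA_real_ else sd(v)
  out <- samples |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$label, .data$point_index) |>
    dplyr::summarise(
      sd_x = sd0(.data$x), sd_y = sd0(.data$y), sd_z = sd0(.data$z),
      sd_diam = sd0(.data$diameter),
      x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
      diameter = mean(.data$diameter),
      n_contrib = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(sd_3d = sqrt(.data$sd_x^2 + .data$sd_y^2 + .data$sd_z^2), valid = TRUE)
  # carry indices where no patient was valid, flagged invalid
  all_idx <- dplyr::distinct(samples, .data$label, .data$point_index)
  out <- all_idx |>
    dplyr::left_join(out, by = c("label", "point_index")) |>
    dplyr::mutate(
      valid = !is.na(.data$valid) & .data$valid,
      n_contrib = dplyr::coalesce(.data$n_contrib, 0L)
    ) |>
    dplyr::arrange(.data$label, .data$point_index) |>
    dplyr::select(
      "label", "point_index", "x", "y", "z", "diameter",
      "sd_x", "sd_y", "sd_z", "sd_3d", "sd_diam", "n_contrib", "valid"
    )
  class(out) <- c("averaged_anatomy", class(out))
  out
}

bind_patient_samples <- function(samples) {
  if (is.data.frame(samples)) {
    df <- as_tibble(samples)
  } else if (is.list(samples)) {
    ids <- names(samples)
    if (is.null(ids)) ids <- sprintf("patient_%02d", seq_along(samples))
    df <- purrr::map2(samples, ids, ~ dplyr::mutate(.x, patient = .y)) |>
      dplyr::bind_rows()
  } else {
    abort("`samples` must be a data frame or a list of per-patient data frames.")
  }
  need <- c("patient", "label", "point_index", "x", "y", "z", "diameter", "valid")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) abort("Cohort is empty.")
  bad <- df$valid & (!is.finite(df$diameter) | df$diameter <= 0)
  if (any(bad)) abort("Valid rows must carry positive finite diameters.")
  df
}

#' Cohort spread summary
#'
#' Per-segment maxima over point indices of the 3D-combined coordinate SD
#' (`sqrt(sd_x^2 + sd_y^2 + sd_z^2)`) and of the diameter SD, describing how
#' much patient anatomies deviate around the average.
#'
#' @inheritParams average_cohort
#' @return A tibble: `label`, `max_coord_sd` (mm), `max_diam_sd` (mm).
#' @export
cohort_spread <- function(samples) {
  samples <- bind_patient_samples(samples)
  if (dplyr::n_distinct(samples$patient) < 2L) {
    abort("Cohort spread needs at least 2 patients.")
  }
  avg <- average_cohort(samples)
  avg |>
    dplyr::filter(.data$n_contrib >= 2L) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      max_coord_sd = max(.data$sd_3d),
      max_diam_sd = max(.data$sd_diam),
      .groups = "drop"
    )
}

#' Read / write an averaged anatomy
#'
#' CSV columns: `label`, `point_index`, `x`, `y`, `z`, `diameter`, `sd_x`,
#' `sd_y`, `sd_z`, `sd_3d`, `sd_diam`, `n_contrib`, `valid`.
#'
#' @param anatomy an `averaged_anatomy` tibble.
#' @param path file path (`.csv` or `.json`).
#' @return `load_averaged_anatomy()` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
save_averaged_anatomy <- function(anatomy, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(anatomy, path, dataframe = "columns", digits = NA, na = "null")
  } else {
    readr::write_csv(anatomy, path)
  }
  invisible(path)
}

#' @rdname save_averaged_anatomy
#' @export
load_averaged_anatomy <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  class(df) <- c("averaged_anatomy", class(df))
  df
}

#' @export
tidy.averaged_anatomy <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.averaged_anatomy <- function(x, ...) {
  ok <- dplyr::filter(as_tibble(unclass(x)), .data$valid)
  tibble(
    n_segments = dplyr::n_distinct(ok$label),
    n_points = nrow(ok),
    max_diameter = max(ok$diameter),
    max_coord_sd = if (all(is.na(ok$sd_3d))) NA_real_ else max(ok$sd_3d, na.rm = TRUE),
    max_diam_sd = if (all(is.na(ok$sd_diam))) NA_real_ else max(ok$sd_diam, na.rm = TRUE)
  )
}
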