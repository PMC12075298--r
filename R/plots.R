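#' Plot an attenuation spectrum
#'
#' Raw per-frequency attenuation as points with the Gaussian-smoothed curve
#' (computed on the fly if absent) as a line, mirroring how acoustic
#' characterization results are usually presented.
#'
#' @param object an [attenuation_spectrum()].
#' @param window smoothing window (data points) when no smoothed column
#'   exists yet.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.attenuation_spectrum <- function(object, window = 16L, ...) {
  if (!"alpha_smoothed" %in% names(object)) object <- smooth_spectrum(object, window)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency_MHz)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$alpha_dB_mm),
                        alpha = 0.35, size = 0.8, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$alpha_smoothed),
                       linewidth = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = "Frequency (MHz)", y = "Attenuation (dB/mm)") +
    ggplot2::theme_minimal()
}

#' Plot an averaged anatomy's diameter profiles
#'
#' Mean circular-equivalent diameter against centerline point index per
#' vessel segment, with a plus/minus one SD ribbon where the cohort has two
#' or more contributing patients.
#'
#' @param object an `averaged_anatomy` (see [average_cohort()]).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.averaged_anatomy <- function(object, ...) {
  d <- dplyr::filter(as_tibble(unclass(object)), .data$valid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$point_index, y = .data$diameter)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$diameter - .data$sd_diam,
                   ymax = .data$diameter + .data$sd_diam),
      fill = "grey75", na.rm = TRUE
    ) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$label), scales = "free_x") +
    ggplot2::labs(x = "Centerline point (proximal to distal)",
                  y = "Lumen diameter (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a mesh distance map histogram
#'
#' Distribution of the per-vertex closest-point distances with the mean and
#' 95th percentile marked.
#'
#' @param object a `distance_map` (see [mesh_distance_map()]).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.distance_map <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance_mm)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey55") +
    ggplot2::geom_vline(xintercept = object$summary$mean, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$summary$p95, linetype = 3) +
    ggplot2::labs(x = "Distance to reference surface (mm)", y = "Vertices") +
    ggplot2::theme_minimal()
}

#' Plot centerlines in a coronal projection
#'
#' Simple x-z projection of every labeled centerline, a quick anatomical
#' sanity view of a patient or an averaged model.
#'
#' @param cll a centerline tibble.
#' @return A ggplot object.
#' @export
plot_centerlines <- function(cll) {
  ggplot2::ggplot(cll, ggplot2::aes(x = .data$x, y = .data$z, color = .data$label)) +
    ggplot2::geom_path() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "z (mm)", color = "segment") +
    ggplot2::theme_minimal()
}
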