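#' Circular-equivalent diameter of a cross-sectional area
#'
#' Diameter of the circle with the same area: `2 * sqrt(area / pi)`.
#'
#' @param area cross-sectional lumen area(s), mm^2, non-negative.
#' @return Diameter(s) in mm.
#' @export
equivalent_diameter <- function(area) {
  if (any(!is.finite(area)) || any(area < 0)) abort("`area` must be non-negative and finite.")
  2 * sqrt(area / pi)
}

# Deterministic in-plane axes: first axis is the projection of global +x onto
# the plane (fallback +y when the normal is nearly parallel to x), second
# completes the right-handed frame.
plane_axes <- function(normal) {
  normal <- normal / sqrt(sum(normal^2))
  u <- c(1, 0, 0) - sum(c(1, 0, 0) * normal) * normal
  if (sqrt(sum(u^2)) < 1e-6) {
    u <- c(0, 1, 0) - sum(c(0, 1, 0) * normal) * normal
  }
  u <- u / sqrt(sum(u^2))
  v <- c(
    normal[2] * u[3] - normal[3] * u[2],
    normal[3] * u[1] - normal[1] * u[3],
    normal[1] * u[2] - normal[2] * u[1]
  )
  list(u = u, v = v / sqrt(sum(v^2)))
}

#' Measure a lumen cross-section perpendicular to the centerline
#'
#' Samples the binary volume on a square planar grid perpendicular to the
#' centerline tangent (trilinear interpolation of occupancy, thresholded at
#' 0.5), labels connected components with 8-connectivity, and takes the
#' component containing the plane center -- or the nearest component within
#' 3 mm -- as the lumen. The lumen area is the member-pixel count times the
#' pixel area; its circular-equivalent diameter is also returned.
#'
#' Sections where no component lies within 3 mm of the center, or whose
#' lumen component touches the sampling-window border (the plane has run
#' into a bifurcation or out of the field), are flagged invalid.
#'
#' @param volume a [binary_volume()].
#' @param center 3D point on the centerline (mm), inside the volume bounds.
#' @param normal unit tangent of the centerline at `center`.
#' @param window side length of the sampling window (mm); must be large
#'   enough to contain the local lumen.
#' @param pixel in-plane sampling step (mm); defaults to half the smallest
#'   voxel spacing.
#' @return A `cross_section` object: list with `center`, `normal`,
#'   `in_plane_axes`, `image` (logical matrix), `pixel`, `area` (mm^2),
#'   `diameter` (mm), `valid`, and `reason` when invalid.
#' @export
measure_cross_section <- function(volume, center, normal, window = 60,
                                  pixel = min(volume$spacing) / 2) {
  if (window <= 0) abort("`window` must be positive.")
  if (pixel <= 0) abort("`pixel` must be positive.")
  center <- as.numeric(center)
  d <- dim(volume$occupancy)
  lo <- volume$origin
  hi <- volume$origin + (d - 1L) * volume$spacing
  if (any(center < lo - volume$spacing) || any(center > hi + volume$spacing)) {
    abort("`center` lies outside the volume bounds.")
  }
  normal <- as.numeric(normal)
  normal <- normal / sqrt(sum(normal^2))
  ax <- plane_axes(normal)

  half <- window / 2
  offs <- seq(-half, half, by = pixel)
  np <- length(offs)
  pts <- vapply(1:3, function(k) {
    as.vector(center[k] + outer(offs, offs, function(a, b) a * ax$u[k] + b * ax$v[k]))
  }, numeric(np * np))
  occ <- cpp_trilinear(
    as.vector(volume$occupancy * 1.0), d, volume$origin, volume$spacing, pts
  )
  img <- matrix(occ >= 0.5, nrow = np)

  out <- list(
    center = center, normal = normal, in_plane_axes = ax,
    image = img, pixel = pixel, area = NA_real_, diameter = NA_real_,
    valid = FALSE, reason = NA_character_
  )
  class(out) <- "cross_section"
  if (!any(img)) {
    out$reason <- "empty"
    return(out)
  }
  # a plane sitting on an end face of the lumen (vessel truncated by the
  # segmentation) sees only the interpolated boundary shell; require lumen
  # occupancy one voxel fore and aft of the plane center
  axial <- cpp_trilinear(
    as.vector(volume$occupancy * 1.0), d, volume$origin, volume$spacing,
    rbind(center + min(volume$spacing) * normal, center - min(volume$spacing) * normal)
  )
  if (any(axial < 0.5)) {
    out$reason <- "plane at a lumen end face"
    return(out)
  }

  lab <- cpp_label8(img)
  ctr <- (np + 1) / 2  # fractional center pixel for even grids
  ci <- as.integer(round(ctr))
  lumen <- lab[ci, ci]
  if (lumen == 0L) {
    # nearest component within 3 mm of the plane center
    idx <- which(lab > 0L, arr.ind = TRUE)
    dist_mm <- sqrt((idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2) * pixel
    if (min(dist_mm) > 3) {
      out$reason <- "no component within 3 mm of center"
      return(out)
    }
    lumen <- lab[idx[which.min(dist_mm), , drop = FALSE]]
  }
  members <- lab == lumen
  if (any(members[1, ]) || any(members[np, ]) || any(members[, 1]) || any(members[, np])) {
    out$reason <- "lumen touches window border"
    return(out)
  }
  out$area <- sum(members) * pixel^2
  out$diameter <- equivalent_diameter(out$area)
  out$lumen_mask <- members
  out$valid <- TRUE
  out
}

#' @export
print.cross_section <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<cross_section> area %.2f mm^2, equivalent diameter %.2f mm\n",
                x$area, x$diameter))
  } else {
    cat(sprintf("<cross_section> invalid (%s)\n", x$reason))
  }
  invisible(x)
}

#' Measure lumen diameters along resampled centerlines
#'
#' Runs [measure_cross_section()] at every resampled centerline point, using
#' central-difference tangents as plane normals, and returns one row per
#' point with the measured area and circular-equivalent diameter.
#'
#' Sections are flagged invalid when no lumen is found, when the lumen
#' touches the sampling-window border, when the plane sits on a lumen end
#' face, or -- near bifurcations -- when the lumen component has merged with
#' a neighboring vessel (detected by another segment's centerline crossing
#' the plane inside the lumen component; no accurate diameter exists
#' there). Invalid rows are kept with `valid = FALSE` and `NA`
#' measurements.
#'
#' @param volume a [binary_volume()] of the lumen.
#' @param resampled a resampled centerline tibble (see
#'   [resample_equal_arclength()]).
#' @inheritParams measure_cross_section
#' @return A tibble: `label`, `point_index`, `x`, `y`, `z`, `area`,
#'   `diameter`, `valid`.
#' @export
measure_sections <- function(volume, resampled, window = 60,
                             pixel = min(volume$spacing) / 2) {
  withtan <- add_tangents(resampled)
  allp <- cbind(withtan$x, withtan$y, withtan$z)
  step_of <- if ("arc_step" %in% names(withtan)) withtan$arc_step else
    rep(min(volume$spacing), nrow(withtan))
  labels <- withtan$label
  half <- window / 2
  rows <- purrr::pmap(
    list(withtan$x, withtan$y, withtan$z, withtan$tx, withtan$ty, withtan$tz,
         withtan$label),
    function(x, y, z, tx, ty, tz, lab) {
      cs <- measure_cross_section(volume, c(x, y, z), c(tx, ty, tz),
                                  window = window, pixel = pixel)
      valid <- cs$valid
      if (valid) {
        # another vessel's centerline passing through the lumen component
        # means the section has merged with a neighboring vessel
        ctr <- c(x, y, z)
        n <- cs$normal
        rel <- sweep(allp, 2, ctr)
        d2 <- rowSums(rel^2)
        oop <- abs(rel %*% n)
        cand <- which(labels != lab & d2 < half^2 & oop < pmax(1.5 * pixel, step_of))
        if (length(cand) > 0L) {
          a <- rel[cand, , drop = FALSE] %*% cs$in_plane_axes$u
          b <- rel[cand, , drop = FALSE] %*% cs$in_plane_axes$v
          np <- nrow(cs$lumen_mask)
          i <- round((a + half) / pixel) + 1L
          j <- round((b + half) / pixel) + 1L
          ok <- i >= 1L & i <= np & j >= 1L & j <= np
          if (any(ok) && any(cs$lumen_mask[cbind(i[ok], j[ok])])) valid <- FALSE
        }
      }
      tibble(
        area = if (valid) cs$area else NA_real_,
        diameter = if (valid) cs$diameter else NA_real_,
        valid = valid
      )
    }
  )
  dplyr::bind_cols(
    dplyr::select(withtan, "label", "point_index", "x", "y", "z"),
    dplyr::bind_rows(rows)
  )
}
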