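#' Sorensen-Dice similarity coefficient of two binary volumes
#'
#' `SDSC(X, Y) = 2 |X intersect Y| / (|X| + |Y|)` counting occupied voxels.
#' 1 means the volumes are identical, 0 means they share no occupied voxel.
#' Both volumes must live on the same grid; use [common_grid()] first when
#' they do not.
#'
#' @param x,y [binary_volume()] objects on a common grid, not both empty.
#' @return Similarity in [0, 1].
#' @export
sdsc <- function(x, y) {
  same_grid <- identical(dim(x$occupancy), dim(y$occupancy)) &&
    max(abs(x$spacing - y$spacing)) < 1e-9 &&
    max(abs(x$origin - y$origin)) < 1e-9
  if (!same_grid) {
    abort("Volumes are on different grids; resample them with common_grid() first.")
  }
  nx <- sum(x$occupancy)
  ny <- sum(y$occupancy)
  if (nx + ny == 0L) abort("Both volumes are empty; SDSC is undefined.")
  2 * sum(x$occupancy & y$occupancy) / (nx + ny)
}

#' Mask spheres out of a binary volume
#'
#' Clears all voxels within `radius` of any of the given centers. Used to
#' exclude bifurcation neighborhoods (where no cross-sectional diameters
#' exist and surfaces are interpolated) from Dice comparisons.
#'
#' @param volume a [binary_volume()].
#' @param centers `k x 3` matrix of sphere centers (mm).
#' @param radius scalar or length-k radii (mm).
#' @return The masked volume.
#' @export
mask_spheres <- function(volume, centers, radius) {
  centers <- rbind(centers)
  radius <- rep(as.numeric(radius), length.out = nrow(centers))
  d <- dim(volume$occupancy)
  occ <- volume$occupancy
  for (k in seq_len(nrow(centers))) {
    # voxel index box around the sphere
    lo_i <- pmax(1L, floor(world_to_index(volume, centers[k, ] - radius[k])))
    hi_i <- pmin(d, ceiling(world_to_index(volume, centers[k, ] + radius[k])))
    if (any(lo_i > hi_i)) next
    xs <- seq.int(lo_i[1], hi_i[1])
    ys <- seq.int(lo_i[2], hi_i[2])
    zs <- seq.int(lo_i[3], hi_i[3])
    wx <- volume$origin[1] + (xs - 1) * volume$spacing[1] - centers[k, 1]
    wy <- volume$origin[2] + (ys - 1) * volume$spacing[2] - centers[k, 2]
    wz <- volume$origin[3] + (zs - 1) * volume$spacing[3] - centers[k, 3]
    d2 <- outer(outer(wx^2, wy^2, "+"), wz^2, "+")
    sub <- occ[xs, ys, zs, drop = FALSE]
    sub[d2 <= radius[k]^2] <- FALSE
    occ[xs, ys, zs] <- sub
  }
  volume$occupancy <- occ
  volume
}

#' Landmark-based translation registration
#'
#' The translation that moves `moving` landmarks onto `fixed` landmarks in
#' the least-squares sense: the mean of the paired differences. Applying it
#' minimizes the sum of squared landmark distances over all translations.
#'
#' @param moving,fixed matched `k x 3` landmark matrices (mm), same order.
#' @return A length-3 translation vector (mm).
#' @export
landmark_translation <- function(moving, fixed) {
  moving <- rbind(moving)
  fixed <- rbind(fixed)
  if (nrow(moving) != nrow(fixed)) abort("Landmark sets have different sizes.")
  if (nrow(moving) < 1L) abort("Need at least one landmark pair.")
  colMeans(fixed - moving)
}

#' Closest-point distance map from a generated mesh to a reference
#'
#' For every vertex of the generated mesh, the distance to the closest point
#' on the reference surface (point-to-triangle, not vertex-to-vertex). The
#' distances are stored as per-vertex scalars, ready for color-coded PLY
#' export, together with max / mean / 95th-percentile summaries.
#' The measure is one-directional, generated to reference; call it twice and
#' take the larger maximum for a symmetric Hausdorff distance.
#'
#' @param generated a [tri_mesh()], pre-registered to the reference.
#' @param reference a non-empty [tri_mesh()].
#' @return A `distance_map`: list with `mesh` (generated mesh carrying
#'   `vertex_scalars` in mm) and `summary` (tibble: max, mean, p95).
#' @export
mesh_distance_map <- function(generated, reference) {
  if (!inherits(generated, "tri_mesh") || !inherits(reference, "tri_mesh")) {
    abort("Both arguments must be tri_mesh objects.")
  }
  d <- cpp_point_mesh_distance(generated$vertices, reference$vertices, reference$faces - 1L)
  generated$vertex_scalars <- d
  out <- list(
    mesh = generated,
    summary = tibble(
      max = max(d), mean = mean(d),
      p95 = as.numeric(quantile(d, 0.95, names = FALSE))
    )
  )
  class(out) <- "distance_map"
  out
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf(
    "<distance_map> %d vertices: max %.3f mm, mean %.3f mm, p95 %.3f mm\n",
    nrow(x$mesh$vertices), x$summary$max, x$summary$mean, x$summary$p95
  ))
  invisible(x)
}

#' @export
tidy.distance_map <- function(x, ...) {
  tibble(vertex = seq_along(x$mesh$vertex_scalars), distance_mm = x$mesh$vertex_scalars)
}

#' @export
glance.distance_map <- function(x, ...) x$summary

#' Integrate an axisymmetric radial velocity profile to volumetric flow
#'
#' Assuming radial symmetry, the volumetric flow through a circular lumen is
#' `Q = integral_0^R v(r) 2 pi r dr`, evaluated with the trapezoidal rule.
#' Velocities in cm/s and radii in mm give flow in ml/s (the unit conversion
#' is exact: 1 cm/s x mm^2 = 0.01 ml/s).
#'
#' @param profile a data frame with columns `radius_mm` (strictly
#'   increasing, within `[0, R]`) and `velocity_cm_s`.
#' @param R lumen radius in mm; defaults to the largest tabulated radius.
#' @return Flow in ml/s.
#' @export
volumetric_flow_axisymmetric <- function(profile, R = max(profile$radius_mm)) {
  need <- c("radius_mm", "velocity_cm_s")
  if (!all(need %in% names(profile))) {
    abort("`profile` needs columns radius_mm and velocity_cm_s.")
  }
  r <- profile$radius_mm
  v <- profile$velocity_cm_s
  if (R <= 0) abort("`R` must be positive.")
  if (any(diff(r) <= 0)) abort("`radius_mm` must be strictly increasing.")
  if (any(r > R + 1e-9)) abort("Tabulated radii exceed the lumen radius R.")
  if (any(!is.finite(v))) abort("Velocities must be finite.")
  # close the integrand at 0 and R if not tabulated there
  if (r[1] > 0) {
    r <- c(0, r)
    v <- c(v[1], v)
  }
  if (r[length(r)] < R) {
    r <- c(r, R)
    v <- c(v, v[length(v)])
  }
  integrand <- v * 2 * pi * r          # cm/s * mm
  q_cm_mm2 <- sum(diff(r) * (head(integrand, -1) + tail(integrand, -1)) / 2)
  q_cm_mm2 * 0.01                      # cm/s * mm^2 -> ml/s
}

#' Fold a diametral velocity profile about the centerline
#'
#' A planar velocity profile measured across the full vessel diameter
#' (distance from the centerline in [-R, R]) is folded and averaged into a
#' single-sided radial profile for [volumetric_flow_axisymmetric()].
#'
#' @param distance_mm signed distances from the centerline (mm).
#' @param velocity_cm_s velocities at those positions.
#' @param n_bins number of radial bins.
#' @return A tibble with `radius_mm` (bin centers) and `velocity_cm_s`.
#' @export
fold_radial_profile <- function(distance_mm, velocity_cm_s, n_bins = 50L) {
  if (length(distance_mm) != length(velocity_cm_s)) {
    abort("Distance and velocity vectors differ in length.")
  }
  r <- abs(distance_mm)
  R <- max(r)
  edges <- seq(0, R, length.out = n_bins + 1L)
  bin <- pmin(findInterval(r, edges, rightmost.closed = TRUE), n_bins)
  tibble(
    radius_mm = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
    velocity_cm_s = as.numeric(tapply(velocity_cm_s, factor(bin, levels = seq_len(n_bins)), mean))
  ) |>
    tidyr::fill("velocity_cm_s", .direction = "downup")
}
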