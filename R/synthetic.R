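#' Parameters of a synthetic aortoiliac vessel tree
#'
#' Defines an analytic ground-truth anatomy: an abdominal aorta running
#' proximal-to-distal with sinusoidal tortuosity and a Gaussian aneurysmal
#' bulge in its diameter profile, two common iliac branches leaving the
#' aortic bifurcation at symmetric angles, and optional renal arteries.
#' Defaults are sized like an EVAR-candidate AAA anatomy: a 120 mm aorta of
#' 20 mm base flow-lumen diameter with a bulge peaking at 35 mm, 12 mm
#' common iliacs and 6 mm renals.
#'
#' @param aorta_length_mm aorta centerline length.
#' @param base_diameter_mm non-aneurysmal aorta diameter.
#' @param bulge_amplitude_mm added diameter at the aneurysm peak.
#' @param bulge_center fractional position of the aneurysm center along the
#'   aorta, in (0, 1).
#' @param bulge_width_mm Gaussian sigma of the bulge along the centerline.
#' @param tortuosity_amplitude_mm,tortuosity_wavelength_mm sinusoidal
#'   in-plane deviation of the aorta centerline.
#' @param iliac_angle_deg angle of each common iliac from the aorta axis.
#' @param iliac_length_mm,iliac_diameter_mm common iliac size.
#' @param renal include renal arteries.
#' @param renal_takeoff fractional takeoff position along the aorta.
#' @param renal_length_mm,renal_diameter_mm renal artery size.
#' @return A `vessel_tree_params` list.
#' @export
vessel_tree_params <- function(aorta_length_mm = 120, base_diameter_mm = 20,
                               bulge_amplitude_mm = 15, bulge_center = 0.55,
                               bulge_width_mm = 15,
                               tortuosity_amplitude_mm = 4,
                               tortuosity_wavelength_mm = 90,
                               iliac_angle_deg = 30, iliac_length_mm = 60,
                               iliac_diameter_mm = 12,
                               renal = FALSE, renal_takeoff = 0.12,
                               renal_length_mm = 35, renal_diameter_mm = 6) {
  p <- as.list(environment())
  if (p$base_diameter_mm <= 0 || p$iliac_diameter_mm <= 0 || p$renal_diameter_mm <= 0) {
    abort("Diameters must be positive.")
  }
  if (p$bulge_center <= 0 || p$bulge_center >= 1) abort("`bulge_center` must be in (0, 1).")
  if (p$bulge_amplitude_mm < 0) abort("`bulge_amplitude_mm` must be non-negative.")
  if (p$iliac_angle_deg <= 0 || p$iliac_angle_deg >= 80) {
    abort("`iliac_angle_deg` must be in (0, 80) to avoid self-intersection.")
  }
  structure(p, class = "vessel_tree_params")
}

# analytic centerline + diameter profile per segment; n_dense points each
tree_centerlines <- function(params, n_dense = 200L) {
  p <- params
  t_ao <- seq(0, 1, length.out = n_dense)
  s_ao <- t_ao * p$aorta_length_mm
  aorta <- tibble(
    label = "aorta",
    point_index = seq_len(n_dense),
    x = p$tortuosity_amplitude_mm * sin(2 * pi * s_ao / p$tortuosity_wavelength_mm),
    y = 0,
    z = -s_ao
  )
  bif <- c(aorta$x[n_dense], aorta$y[n_dense], aorta$z[n_dense])
  th <- p$iliac_angle_deg * pi / 180
  mk_iliac <- function(side) {
    sgn <- if (side == "L") -1 else 1
    u <- seq(0, 1, length.out = n_dense)
    # direction turns from straight down to the branch angle over the first
    # 30% of the branch, then runs straight
    ang <- sgn * th * pmin(u / 0.3, 1)
    dx <- sin(ang)
    dz <- -cos(ang)
    step <- p$iliac_length_mm / (n_dense - 1L)
    xs <- bif[1] + cumsum(c(0, dx[-1])) * step
    zs <- bif[3] + cumsum(c(0, dz[-1])) * step
    tibble(
      label = paste0("common_iliac_", side),
      point_index = seq_len(n_dense),
      x = xs, y = 0, z = zs
    )
  }
  out <- dplyr::bind_rows(aorta, mk_iliac("L"), mk_iliac("R"))
  if (isTRUE(p$renal)) {
    i0 <- which.min(abs(t_ao - p$renal_takeoff))
    org <- c(aorta$x[i0], aorta$y[i0], aorta$z[i0])
    mk_renal <- function(side) {
      sgn <- if (side == "L") -1 else 1
      u <- seq(0, 1, length.out = max(40L, n_dense %/% 3L))
      dirv <- c(0.2 * -sgn * 0, sgn * 1, -0.15)  # mostly lateral (y), slightly caudal
      dirv <- dirv / sqrt(sum(dirv^2))
      tibble(
        label = paste0("renal_", side),
        point_index = seq_along(u),
        x = org[1] + dirv[1] * u * p$renal_length_mm,
        y = org[2] + dirv[2] * u * p$renal_length_mm,
        z = org[3] + dirv[3] * u * p$renal_length_mm
      )
    }
    out <- dplyr::bind_rows(out, mk_renal("L"), mk_renal("R"))
  }
  out
}

# ground-truth diameter as a function of normalized position per segment
tree_diameter_fun <- function(params) {
  p <- params
  function(label, t_frac) {
    s <- t_frac * p$aorta_length_mm
    c0 <- p$bulge_center * p$aorta_length_mm
    switch(sub("_[LR]$", "", label),
      aorta = p$base_diameter_mm +
        p$bulge_amplitude_mm * exp(-(s - c0)^2 / (2 * p$bulge_width_mm^2)),
      common_iliac = rep(p$iliac_diameter_mm, length(t_frac)),
      renal = rep(p$renal_diameter_mm, length(t_frac)),
      abort(paste0("No diameter profile for segment ", label))
    )
  }
}

#' Generate a synthetic vessel tree with known ground truth
#'
#' Builds analytic centerlines and diameter profiles from
#' [vessel_tree_params()] and reconstructs the corresponding watertight
#' lumen surface through the package's own implicit tube-union machinery at
#' high ring density. The ground truth (centerlines and per-point diameters)
#' is returned alongside the mesh, so measurement and averaging stages can
#' be validated against it.
#'
#' @param params a [vessel_tree_params()].
#' @param spacing surface-extraction grid spacing in mm.
#' @param blend_radius junction blend radius in mm.
#' @param n_dense centerline points per segment used for the ground truth.
#' @param mesh build the surface mesh (set `FALSE` to get only centerlines
#'   and diameters, e.g. for large cohorts).
#' @return A list: `mesh` ([tri_mesh()] or `NULL`), `centerlines` (tibble),
#'   `diameters` (tibble: label, point_index, diameter), `params`.
#' @export
synth_vessel_tree <- function(params = vessel_tree_params(), spacing = 0.8,
                              blend_radius = 3, n_dense = 200L, mesh = TRUE) {
  cll <- tree_centerlines(params, n_dense = n_dense)
  dfun <- tree_diameter_fun(params)
  diam <- cll |>
    dplyr::group_by(.data$label) |>
    dplyr::mutate(
      t_frac = (.data$point_index - 1) / (dplyr::n() - 1),
      diameter = dfun(.data$label[1], .data$t_frac)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("label", "point_index", "diameter")
  m <- NULL
  if (isTRUE(mesh)) {
    anat <- cll |>
      dplyr::left_join(diam, by = c("label", "point_index")) |>
      dplyr::mutate(valid = TRUE)
    rings <- build_rings(anat, m = 32L)
    m <- blend_junctions(rings, blend_radius = blend_radius, spacing = spacing)
  }
  list(mesh = m, centerlines = cll, diameters = diam, params = params)
}

#' Cohort generation parameters
#'
#' @param n number of synthetic patients.
#' @param coord_sigma_mm standard deviation of the total 3D Gaussian
#'   displacement applied to each centerline control point (isotropic, so
#'   each axis receives `coord_sigma_mm / sqrt(3)`).
#' @param diam_sigma_mm standard deviation of the diameter perturbation.
#' @param jitter_frac relative jitter applied to patient size parameters
#'   (lengths, bulge amplitude), uniform in `[-jitter_frac, +jitter_frac]`.
#' @param n_control smooth-noise control points per segment; noise is
#'   interpolated between them so perturbed centerlines stay smooth and
#'   patient lengths genuinely differ.
#' @param seed RNG seed for reproducibility.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n = 30L, coord_sigma_mm = 2, diam_sigma_mm = 1,
                          jitter_frac = 0.05, n_control = 5L, seed = 1L) {
  if (n < 1L) abort("`n` must be at least 1.")
  if (coord_sigma_mm < 0 || diam_sigma_mm < 0) abort("Noise sigmas must be non-negative.")
  structure(as.list(environment()), class = "cohort_params")
}

#' Generate a synthetic patient cohort with known mean anatomy
#'
#' Each patient is the base tree with (a) uniformly jittered size
#' parameters and (b) smooth zero-mean Gaussian perturbations of the
#' centerline control points and diameters. Because all noise is zero-mean,
#' the ground-truth cohort mean is the base anatomy itself, which the
#' averaging pipeline should recover at the central-limit rate.
#'
#' @param base a [vessel_tree_params()] describing the cohort mean.
#' @param cohort a [cohort_params()].
#' @param meshes also build each patient's surface mesh (slow; only needed
#'   when the full measurement pipeline is exercised).
#' @param spacing mesh extraction spacing when `meshes = TRUE`.
#' @return A list: `patients` (list of per-patient lists as returned by
#'   [synth_vessel_tree()]), `ground_truth` (the noise-free base tree).
#' @export
synth_cohort <- function(base = vessel_tree_params(), cohort = cohort_params(),
                         meshes = FALSE, spacing = 0.8) {
  set.seed(cohort$seed)
  truth <- synth_vessel_tree(base, mesh = FALSE)
  patients <- lapply(seq_len(cohort$n), function(i) {
    p <- base
    jig <- function(val) val * (1 + runif(1, -cohort$jitter_frac, cohort$jitter_frac))
    p$aorta_length_mm <- jig(p$aorta_length_mm)
    p$iliac_length_mm <- jig(p$iliac_length_mm)
    p$bulge_amplitude_mm <- jig(p$bulge_amplitude_mm)
    pt <- synth_vessel_tree(p, mesh = FALSE)
    cll <- perturb_centerlines(pt$centerlines, cohort$coord_sigma_mm, cohort$n_control)
    diam <- perturb_diameters(pt$diameters, cohort$diam_sigma_mm, cohort$n_control)
    m <- NULL
    if (isTRUE(meshes)) {
      anat <- dplyr::mutate(
        dplyr::left_join(cll, diam, by = c("label", "point_index")),
        valid = TRUE
      )
      m <- blend_junctions(build_rings(anat, m = 32L), spacing = spacing)
    }
    list(mesh = m, centerlines = cll, diameters = diam, params = p)
  })
  list(patients = patients, ground_truth = truth)
}

# diameter noise is smooth along the vessel too: a patient is wider or
# narrower over segment-scale stretches, not voxel to voxel
perturb_diameters <- function(diam, sigma, n_control = 5L) {
  if (sigma == 0) return(diam)
  diam |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(function(d, key) {
      np <- nrow(d)
      nc <- min(n_control, np)
      ci <- seq(1, np, length.out = nc)
      noise <- approx(ci, rnorm(nc, 0, sigma), xout = seq_len(np))$y
      d$diameter <- pmax(1, d$diameter + noise)
      d
    }) |>
    dplyr::ungroup()
}

# smooth zero-mean noise: isotropic 3D Gaussian displacements (total SD =
# sigma, i.e. sigma/sqrt(3) per axis) at sparse control points, linearly
# interpolated to every centerline point
perturb_centerlines <- function(cll, sigma, n_control = 5L) {
  if (sigma == 0) return(cll)
  sig_axis <- sigma / sqrt(3)
  cll |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(function(d, key) {
      np <- nrow(d)
      nc <- min(n_control, np)
      ci <- seq(1, np, length.out = nc)
      for (col in c("x", "y", "z")) {
        noise <- approx(ci, rnorm(nc, 0, sig_axis), xout = seq_len(np))$y
        d[[col]] <- d[[col]] + noise
      }
      d
    }) |>
    dplyr::ungroup()
}

#' Build a patient sample table from synthetic ground truth
#'
#' Converts a synthetic patient (or cohort) into the long measurement table
#' [average_cohort()] consumes, by resampling the centerlines to the
#' configured per-segment counts and carrying the ground-truth diameters
#' (interpolated to the resampled arc positions) as the measurements.
#'
#' @param patient one element of `synth_cohort()$patients` or the result of
#'   [synth_vessel_tree()].
#' @param counts per-segment point counts, see [segment_counts()].
#' @return A tibble: `label`, `point_index`, `x`, `y`, `z`, `diameter`,
#'   `valid`.
#' @export
patient_sample_from_truth <- function(patient, counts = segment_counts()) {
  res <- resample_equal_arclength(patient$centerlines, n = counts)
  diam_src <- patient$diameters |>
    dplyr::group_by(.data$label) |>
    dplyr::mutate(t_frac = (.data$point_index - 1) / (dplyr::n() - 1)) |>
    dplyr::ungroup()
  res |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(function(d, key) {
      src <- dplyr::filter(diam_src, .data$label == key$label)
      tf <- (d$point_index - 1) / (nrow(d) - 1)
      d$diameter <- approx(src$t_frac, src$diameter, xout = tf, rule = 2)$y
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(valid = TRUE) |>
    dplyr::select("label", "point_index", "x", "y", "z", "diameter", "valid")
}

#' Generate a synthetic tone-burst pulse pair
#'
#' Hann-windowed tone bursts emulating through-transmission recordings: a
#' reference waveform and a copy time-shifted by exactly `delay_us`
#' (evaluated analytically, so fractional-sample delays are exact) and
#' scaled by `amplitude_ratio`, with optional additive white noise.
#' Positive `delay_us` makes the second waveform arrive later; pass a
#' negative value to emulate a faster-than-water sample (arrival advance).
#'
#' @param frequency_MHz transmit frequency.
#' @param dt_us sample interval in microseconds (default 0.004 us = 4 ns).
#' @param cycles burst length in carrier cycles (default 30).
#' @param delay_us time shift of the second recording.
#' @param amplitude_ratio amplitude scale of the second recording.
#' @param noise_sd additive white-noise standard deviation (relative to the
#'   unit burst amplitude).
#' @param record_us total record length; defaults to the burst length plus
#'   generous margins.
#' @return A list of two [pulse_recording()]s: `reference` and `delayed`.
#' @export
synth_pulse_pair <- function(frequency_MHz, dt_us = 0.004, cycles = 30L,
                             delay_us = 0, amplitude_ratio = 1, noise_sd = 0,
                             record_us = NULL) {
  if (cycles < 1L) abort("`cycles` must be at least 1.")
  if (1 / (2 * dt_us) <= frequency_MHz) abort("Nyquist violated for this dt.")
  burst_us <- cycles / frequency_MHz
  t0 <- 1.0  # burst onset margin, us
  if (is.null(record_us)) record_us <- t0 + burst_us + abs(delay_us) + 2
  if (abs(delay_us) > record_us) abort("`delay_us` exceeds the record length.")
  t <- seq(0, record_us, by = dt_us)
  burst <- function(tt) {
    ph <- tt - t0
    inside <- ph >= 0 & ph <= burst_us
    a <- numeric(length(tt))
    a[inside] <- 0.5 * (1 - cos(2 * pi * ph[inside] / burst_us)) *
      sin(2 * pi * frequency_MHz * ph[inside])
    a
  }
  ref <- burst(t)
  del <- amplitude_ratio * burst(t - delay_us)
  if (noise_sd > 0) {
    ref <- ref + rnorm(length(t), 0, noise_sd)
    del <- del + rnorm(length(t), 0, noise_sd)
  }
  list(
    reference = pulse_recording(t, ref, frequency_MHz),
    delayed = pulse_recording(t, del, frequency_MHz)
  )
}
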