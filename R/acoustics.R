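#' Speed of sound in pure water
#'
#' Fifth-order polynomial fit of the speed of sound in pure water against
#' temperature (Marczak 1997), valid on 0-95 degrees Celsius. At the 21.8
#' degrees of a typical lab water bath it evaluates to 1488 m/s.
#'
#' @param temperature_c water temperature in degrees Celsius, in [0, 95].
#' @return Speed of sound in m/s.
#' @export
water_sos <- function(temperature_c) {
  if (any(!is.finite(temperature_c)) || any(temperature_c < 0) || any(temperature_c > 95)) {
    abort("Temperature outside the 0-95 degC validity range of the relation.")
  }
  coefs <- c(
    1.402385e3, 5.038813, -5.799136e-2,
    3.287156e-4, -1.398845e-6, 2.787860e-9
  )
  tt <- outer(temperature_c, 0:5, "^")
  as.numeric(tt %*% coefs)
}

#' A received through-transmission pulse recording
#'
#' A repetition-averaged received waveform as a tibble of `time_us` /
#' `amplitude`, tagged with the transmit frequency, sample interval and
#' repetition count.
#'
#' @param time_us sample times in microseconds (uniform spacing).
#' @param amplitude received amplitudes (arbitrary units).
#' @param frequency_MHz transmit frequency in MHz; must satisfy Nyquist for
#'   the sample interval.
#' @param n_repetitions how many repetitions were averaged into this trace.
#' @return A `pulse_recording` tibble.
#' @export
pulse_recording <- function(time_us, amplitude, frequency_MHz, n_repetitions = 1L) {
  if (length(time_us) != length(amplitude)) abort("Time and amplitude lengths differ.")
  if (length(time_us) < 4L) abort("Recording too short.")
  dt <- diff(time_us)
  if (any(abs(dt - dt[1]) > 1e-9)) abort("Sample times must be uniformly spaced.")
  dt <- dt[1]
  if (dt <= 0) abort("Sample interval must be positive.")
  if (any(!is.finite(amplitude))) abort("Amplitudes must be finite.")
  if (1 / (2 * dt) <= frequency_MHz) {
    abort("Nyquist violated: 1/(2 dt) must exceed the transmit frequency.")
  }
  out <- tibble(time_us = as.numeric(time_us), amplitude = as.numeric(amplitude))
  attr(out, "frequency_MHz") <- frequency_MHz
  attr(out, "dt_us") <- dt
  attr(out, "n_repetitions") <- as.integer(n_repetitions)
  class(out) <- c("pulse_recording", class(out))
  out
}

#' Average repeated recordings
#'
#' Point-wise mean of repeated waveforms of one transmit frequency; done
#' before any further processing to reduce noise.
#'
#' @param recordings list of [pulse_recording()]s with identical time bases.
#' @return One averaged [pulse_recording()].
#' @export
average_repetitions <- function(recordings) {
  if (length(recordings) < 1L) abort("No recordings to average.")
  t0 <- recordings[[1]]$time_us
  for (r in recordings) {
    if (length(r$time_us) != length(t0) || max(abs(r$time_us - t0)) > 1e-9) {
      abort("Recordings must share one time base.")
    }
  }
  amp <- rowMeans(vapply(recordings, function(r) r$amplitude, numeric(length(t0))))
  pulse_recording(t0, amp, attr(recordings[[1]], "frequency_MHz"),
                  n_repetitions = sum(vapply(recordings, function(r) {
                    as.integer(attr(r, "n_repetitions") %||% 1L)
                  }, integer(1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Burst amplitude of a recording at its transmit frequency.
# "spectral": magnitude of the discrete Fourier component at f over a
# steady-state window (cycles 5-25 after burst onset), robust to the
# transient edges of the burst. "p2p": half the peak-to-peak amplitude in
# the same window.
burst_amplitude <- function(time_us, amplitude, frequency_MHz,
                            method = c("spectral", "p2p")) {
  method <- match.arg(method)
  peak <- max(abs(amplitude))
  if (peak == 0) return(0)
  onset <- time_us[which(abs(amplitude) > 0.05 * peak)[1]]
  w0 <- onset + 5 / frequency_MHz
  w1 <- onset + 25 / frequency_MHz
  sel <- time_us >= w0 & time_us <= w1
  if (sum(sel) < 8L) sel <- time_us >= onset  # short record: use all of the burst
  if (method == "spectral") {
    ph <- exp(-2i * pi * frequency_MHz * time_us[sel])
    Mod(sum(amplitude[sel] * ph)) * 2 / sum(sel)
  } else {
    (max(amplitude[sel]) - min(amplitude[sel])) / 2
  }
}

#' Two-thickness attenuation spectrum
#'
#' Frequency-dependent attenuation from the amplitude ratio between a thin
#' and a thick sample of the same material:
#' `alpha(f) = 20 log10(A_thin(f) / A_thick(f)) / (d_thick - d_thin)`
#' in dB/mm. Using two thicknesses cancels the (equal) front/back interface
#' reflection losses. Frequencies where the thick-sample amplitude vanishes
#' are flagged unreliable and carry `NA`.
#'
#' @param thin,thick long tibbles with columns `frequency_MHz`, `time_us`,
#'   `amplitude`: the repetition-averaged received waveform per transmit
#'   frequency, on matched frequency grids.
#' @param d_thin,d_thick sample thicknesses in mm, `d_thick > d_thin`.
#' @param method amplitude metric, `"spectral"` (default) or `"p2p"`.
#' @return An `attenuation_spectrum` tibble: `frequency_MHz`,
#'   `alpha_dB_mm`, `reliable`.
#' @export
attenuation_spectrum <- function(thin, thick, d_thin = 1, d_thick = 2,
                                 method = c("spectral", "p2p")) {
  method <- match.arg(method)
  if (d_thick <= d_thin) abort("`d_thick` must exceed `d_thin`.")
  amp_tbl <- function(df) {
    df |>
      dplyr::group_by(.data$frequency_MHz) |>
      dplyr::summarise(
        A = burst_amplitude(.data$time_us, .data$amplitude,
                            .data$frequency_MHz[1], method = method),
        .groups = "drop"
      )
  }
  a1 <- amp_tbl(thin)
  a2 <- amp_tbl(thick)
  if (nrow(a1) != nrow(a2) || max(abs(a1$frequency_MHz - a2$frequency_MHz)) > 1e-9) {
    abort("Thin and thick recordings are on different frequency grids.")
  }
  out <- tibble(
    frequency_MHz = a1$frequency_MHz,
    alpha_dB_mm = ifelse(
      a2$A > 0,
      20 * log10(a1$A / a2$A) / (d_thick - d_thin),
      NA_real_
    ),
    reliable = a2$A > 0 & a1$A > 0
  )
  class(out) <- c("attenuation_spectrum", class(out))
  out
}

#' Speed of sound from the cross-correlation delay against a water reference
#'
#' In the substitution method, replacing a water path of length `d` by the
#' sample shifts the arrival time by `dt = d/c_water - d/c_sample`
#' (advance positive: a faster-than-water sample arrives earlier), so
#' `c_sample = d / (d/c_water - dt)`. The delay is found at the
#' cross-correlation peak with parabolic sub-sample interpolation.
#'
#' @param sample,reference [pulse_recording()]s (or `time_us`/`amplitude`
#'   data frames) with identical time bases.
#' @param thickness_mm sample thickness `d` in mm.
#' @param c_water water speed of sound in m/s (see [water_sos()]).
#' @param u_thickness_mm,u_delay_us,u_c_water optional 1-sigma input
#'   uncertainties; when any is nonzero the SoS uncertainty is propagated to
#'   first order (see [propagate_sos_uncertainty()]).
#' @return A `sos_estimate`: list with `sos` (m/s), `delay_us` (advance
#'   positive), `uncertainty` (m/s).
#' @export
sos_from_delay <- function(sample, reference, thickness_mm, c_water,
                           u_thickness_mm = 0, u_delay_us = 0, u_c_water = 0) {
  if (thickness_mm <= 0) abort("`thickness_mm` must be positive.")
  if (c_water <= 0) abort("`c_water` must be positive.")
  s <- sample$amplitude
  r <- reference$amplitude
  if (length(s) != length(r)) abort("Sample and reference have different lengths.")
  dts <- diff(sample$time_us[1:2])
  dtr <- diff(reference$time_us[1:2])
  if (abs(dts - dtr) > 1e-12) abort("Sample and reference have different sample intervals.")
  n <- length(s)
  # cc[k] corresponds to lag = k - n, where positive lag means the sample
  # waveform is shifted later than the reference
  cc <- convolve(s, r, conj = TRUE, type = "open")
  lags <- seq(-(n - 1L), n - 1L)
  pk <- which.max(cc)
  if (pk == 1L || pk == length(cc)) {
    abort("Cross-correlation peak at the series boundary; delay is unreliable.")
  }
  delta <- 0.5 * (cc[pk - 1L] - cc[pk + 1L]) /
    (cc[pk - 1L] - 2 * cc[pk] + cc[pk + 1L])
  lag <- lags[pk] + delta
  delay_us <- -lag * dts  # advance positive: sample earlier than reference
  t_water_us <- 1000 * thickness_mm / c_water
  denom <- t_water_us - delay_us
  if (denom <= 0) {
    abort("Nonphysical delay: d/c_water - dt is not positive.")
  }
  sos <- 1000 * thickness_mm / denom
  unc <- propagate_sos_uncertainty(
    thickness_mm, delay_us, c_water,
    u_thickness_mm, u_delay_us, u_c_water
  )
  structure(
    list(sos = sos, delay_us = delay_us, uncertainty = unc),
    class = "sos_estimate"
  )
}

#' @export
print.sos_estimate <- function(x, ...) {
  cat(sprintf("<sos_estimate> %.1f m/s (delay %+.4f us%s)\n", x$sos, x$delay_us,
              if (x$uncertainty > 0) sprintf(", +/- %.1f m/s", x$uncertainty) else ""))
  invisible(x)
}

#' @export
tidy.sos_estimate <- function(x, ...) {
  tibble(sos_m_s = x$sos, delay_us = x$delay_us, uncertainty_m_s = x$uncertainty)
}

#' First-order uncertainty of the substitution-method speed of sound
#'
#' Gaussian propagation through `c = d / (d/c_w - dt)`:
#' `u^2 = (dc/dd)^2 u_d^2 + (dc/ddt)^2 u_dt^2 + (dc/dc_w)^2 u_cw^2`
#' with the partial derivatives evaluated analytically
#' (`dc/ddt = c^2/d`, `dc/dc_w = c^2/c_w^2`, `dc/dd = -dt c^2 / d^2`).
#'
#' @param thickness_mm sample thickness in mm.
#' @param delay_us measured arrival advance in microseconds.
#' @param c_water water speed of sound in m/s.
#' @param u_thickness_mm,u_delay_us,u_c_water 1-sigma input uncertainties
#'   (mm, us, m/s), all non-negative.
#' @return 1-sigma SoS uncertainty in m/s.
#' @export
propagate_sos_uncertainty <- function(thickness_mm, delay_us, c_water,
                                      u_thickness_mm = 0, u_delay_us = 0,
                                      u_c_water = 0) {
  if (any(c(u_thickness_mm, u_delay_us, u_c_water) < 0)) {
    abort("Uncertainties must be non-negative.")
  }
  d <- thickness_mm * 1e-3        # m
  dt <- delay_us * 1e-6           # s
  u_d <- u_thickness_mm * 1e-3
  u_t <- u_delay_us * 1e-6
  tt <- d / c_water - dt
  cs <- d / tt
  dc_dd <- -dt * cs^2 / d^2
  dc_dt <- cs^2 / d
  dc_dcw <- cs^2 / c_water^2
  sqrt((dc_dd * u_d)^2 + (dc_dt * u_t)^2 + (dc_dcw * u_c_water)^2)
}

#' Gaussian-weighted moving average
#'
#' Smooths a series with a Gaussian kernel of standard deviation
#' `window / 4`, truncated to `window` data points and renormalized at the
#' edges so endpoints stay unbiased. `window = 1` is the identity.
#'
#' @param x numeric series.
#' @param window kernel support in data points (>= 1, <= length of series).
#' @return The smoothed series, same length; `NA`s are ignored (smoothed
#'   over) and returned as smoothed values where neighbors exist.
#' @export
gaussian_moving_average <- function(x, window = 16L) {
  n <- length(x)
  if (window < 1L || window > n) abort("`window` must be in [1, length(x)].")
  if (window == 1L) return(x)
  h <- floor(window / 2)
  off <- -h:h
  w <- exp(-off^2 / (2 * (window / 4)^2))
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1L & j <= n & !is.na(x[pmax(pmin(j, n), 1L)])
    jj <- j[ok]
    ww <- w[ok]
    out[i] <- sum(ww * x[jj]) / sum(ww)
  }
  out
}

#' Smooth an attenuation or speed-of-sound spectrum
#'
#' Applies [gaussian_moving_average()] to the value column of a spectrum
#' table (default window 16 data points, i.e. 0.32 MHz at the 0.02 MHz
#' frequency step), adding a `*_smoothed` column.
#'
#' @param spectrum an `attenuation_spectrum`, or any tibble with a
#'   `frequency_MHz` column plus one value column.
#' @param window kernel support in data points.
#' @return The input with an added smoothed column.
#' @export
smooth_spectrum <- function(spectrum, window = 16L) {
  val_col <- if (inherits(spectrum, "attenuation_spectrum")) "alpha_dB_mm" else {
    cand <- setdiff(names(spectrum)[vapply(spectrum, is.numeric, logical(1))], "frequency_MHz")
    if (length(cand) == 0L) abort("No numeric value column to smooth.")
    cand[1]
  }
  spectrum[[paste0(sub("_dB_mm$|_m_s$", "", val_col), "_smoothed")]] <-
    gaussian_moving_average(spectrum[[val_col]], window)
  spectrum
}

#' Linear fit and extrapolation of an attenuation spectrum
#'
#' Ordinary least squares of attenuation against frequency restricted to a
#' fit band (default 3-7 MHz, below the band where thick-sample
#' signal-to-noise degrades), with evaluation/extrapolation at a chosen
#' frequency such as an imaging transducer's center frequency.
#'
#' @param spectrum an [attenuation_spectrum()].
#' @param fit_range length-2 frequency interval in MHz.
#' @param eval_at frequency (MHz) at which to evaluate the fitted line.
#' @return An `attenuation_fit`: list with `slope` (dB/mm/MHz), `intercept`
#'   (dB/mm), `eval_at`, `value` (dB/mm), `n` and the underlying `lm` fit.
#' @export
fit_attenuation_line <- function(spectrum, fit_range = c(3, 7), eval_at = 7.54) {
  sel <- spectrum$frequency_MHz >= fit_range[1] &
    spectrum$frequency_MHz <= fit_range[2] &
    !is.na(spectrum$alpha_dB_mm)
  if (sum(sel) < 2L) abort("Fewer than 2 usable points inside the fit range.")
  d <- spectrum[sel, ]
  fit <- lm(alpha_dB_mm ~ frequency_MHz, data = d)
  structure(
    list(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      eval_at = eval_at,
      value = unname(predict(fit, tibble(frequency_MHz = eval_at))),
      n = nrow(d), fit = fit
    ),
    class = "attenuation_fit"
  )
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf(
    "<attenuation_fit> slope %.3f dB/mm/MHz, intercept %.3f dB/mm; %.2f dB/mm at %.2f MHz (n = %d)\n",
    x$slope, x$intercept, x$value, x$eval_at, x$n
  ))
  invisible(x)
}

#' @export
tidy.attenuation_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std_error = sm[, "Std. Error"]
  )
}

#' @export
glance.attenuation_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(
    slope = x$slope, intercept = x$intercept,
    value_at_eval = x$value, eval_at = x$eval_at,
    r_squared = sm$r.squared, n = x$n
  )
}

#' Density from sample mass and volume
#'
#' Plain mass over volume; printing or curing state plays no role.
#'
#' @param mass_g sample mass in grams.
#' @param volume_mm3 sample volume in mm^3.
#' @return Density in kg/m^3.
#' @export
sample_density <- function(mass_g, volume_mm3) {
  if (any(volume_mm3 <= 0)) abort("Volume must be positive.")
  mass_g / volume_mm3 * 1e6
}

#' Read / write pulse recordings as CSV
#'
#' Long format with columns `frequency_MHz`, `time_us`, `amplitude`;
#' multiple transmit frequencies may share one file.
#'
#' @param path CSV path.
#' @param recordings a long tibble in the same format.
#' @return `load_recordings()` returns the tibble.
#' @export
load_recordings <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("frequency_MHz", "time_us", "amplitude")
  if (!all(need %in% names(df))) {
    abort(paste0("Recording CSV needs columns: ", paste(need, collapse = ", ")))
  }
  df
}

#' @rdname load_recordings
#' @export
save_recordings <- function(recordings, path) {
  readr::write_csv(recordings, path)
  invisible(path)
}
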