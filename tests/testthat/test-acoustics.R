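test_that("the water speed-of-sound relation reproduces published values", {
  expect_equal(round(water_sos(21.8)), 1488)
  expect_equal(water_sos(0), 1402.385, tolerance = 1e-6)  # the constant term
  expect_gt(water_sos(24), water_sos(20))
  # independent Horner evaluation of the same published polynomial
  horner <- function(T) {
    co <- c(1.402385e3, 5.038813, -5.799136e-2, 3.287156e-4, -1.398845e-6, 2.787860e-9)
    Reduce(function(acc, c_) acc * T + c_, rev(co), accumulate = FALSE, init = 0)
  }
  for (T in c(20, 25, 30)) expect_lt(abs(water_sos(T) - horner(T)), 0.2)
  expect_error(water_sos(-5), "validity")
  expect_error(water_sos(100), "validity")
})

test_that("two-thickness attenuation follows the log amplitude ratio", {
  freqs <- seq(3, 5, by = 0.5)
  mk <- function(ratio) {
    dplyr::bind_rows(lapply(freqs, function(f) {
      pp <- synth_pulse_pair(f, dt_us = 0.01, cycles = 30, amplitude_ratio = ratio)
      tibble::tibble(frequency_MHz = f, time_us = pp$delayed$time_us,
                     amplitude = pp$delayed$amplitude)
    }))
  }
  same <- attenuation_spectrum(mk(1), mk(1), d_thin = 1, d_thick = 2)
  expect_equal(same$alpha_dB_mm, rep(0, length(freqs)), tolerance = 1e-9)

  tenth <- attenuation_spectrum(mk(1), mk(0.1), d_thin = 1, d_thick = 2)
  expect_equal(tenth$alpha_dB_mm, rep(20, length(freqs)), tolerance = 1e-6)

  # swapping thin and thick flips the sign
  swapped <- attenuation_spectrum(mk(0.1), mk(1), d_thin = 1, d_thick = 2)
  expect_equal(swapped$alpha_dB_mm, -tenth$alpha_dB_mm, tolerance = 1e-9)
})

test_that("a synthetic frequency sweep recovers the imposed attenuation law", {
  freqs <- seq(3, 8.6, by = 0.1)
  mk <- function(ratio_fun) {
    dplyr::bind_rows(lapply(freqs, function(f) {
      pp <- synth_pulse_pair(f, dt_us = 0.008, cycles = 30,
                             amplitude_ratio = ratio_fun(f))
      tibble::tibble(frequency_MHz = f, time_us = pp$delayed$time_us,
                     amplitude = pp$delayed$amplitude)
    }))
  }
  thin <- mk(function(f) 1)
  thick <- mk(function(f) 10^(-1.0 * f / 20))  # alpha(f) = 1.0 f dB/mm over 1 mm
  spec <- attenuation_spectrum(thin, thick, d_thin = 1, d_thick = 2)
  sel <- spec$frequency_MHz >= 3 & spec$frequency_MHz <= 7
  rel_err <- abs(spec$alpha_dB_mm[sel] - spec$frequency_MHz[sel]) / spec$frequency_MHz[sel]
  expect_lt(max(rel_err), 0.02)
  fit <- fit_attenuation_line(spec, c(3, 7), eval_at = 7.54)
  expect_equal(fit$slope, 1.0, tolerance = 0.02)
})

test_that("cross-correlation delay yields the substitution-method SoS", {
  pp0 <- synth_pulse_pair(5, dt_us = 0.004, delay_us = 0)
  est0 <- sos_from_delay(pp0$delayed, pp0$reference, 2, 1488)
  expect_equal(est0$sos, 1488, tolerance = 1e-6)
  expect_equal(est0$delay_us, 0, tolerance = 1e-9)

  d <- 2; cw <- 1488; truth <- 1785
  adv <- 1000 * d / cw - 1000 * d / truth
  pp <- synth_pulse_pair(5, dt_us = 0.004, delay_us = -adv)
  est <- sos_from_delay(pp$delayed, pp$reference, d, cw)
  expect_lt(abs(est$sos - truth) / truth, 0.005)

  # reference against itself: zero lag exactly
  self <- sos_from_delay(pp$reference, pp$reference, d, cw)
  expect_identical(self$delay_us, 0)
})

test_that("imposed sample speeds are recovered across the physiologic range", {
  d <- 2; cw <- 1488
  for (truth in c(1400, 1600, 1785, 2000, 2200)) {
    adv <- 1000 * d / cw - 1000 * d / truth
    pp <- synth_pulse_pair(5, dt_us = 0.004, delay_us = -adv)
    est <- sos_from_delay(pp$delayed, pp$reference, d, cw)
    expect_lt(abs(est$sos - truth) / truth, 0.005)
  }
})

test_that("Gaussian moving average is edge-aware and mass-preserving", {
  expect_equal(gaussian_moving_average(rep(2, 100), 16), rep(2, 100))
  x <- rnorm(50)
  expect_identical(gaussian_moving_average(x, 1), x)

  spike <- c(rep(0, 40), 1, rep(0, 40))
  sm <- gaussian_moving_average(spike, 16)
  expect_lt(max(sm), 1)                      # peak reduced
  expect_equal(sum(sm), 1, tolerance = 1e-9) # interior kernel mass preserved
  expect_error(gaussian_moving_average(x, 51), "window")
})

test_that("smooth_spectrum adds a smoothed column to spectrum tables", {
  spec <- structure(
    tibble::tibble(frequency_MHz = seq(3, 5, 0.02),
                   alpha_dB_mm = sin(seq(3, 5, 0.02)) + rnorm(101, 0, 0.1),
                   reliable = TRUE),
    class = c("attenuation_spectrum", class(tibble::tibble()))
  )
  out <- smooth_spectrum(spec, 16)
  expect_true("alpha_smoothed" %in% names(out))
  expect_lt(sd(diff(out$alpha_smoothed)), sd(diff(out$alpha_dB_mm)))
})

test_that("linear attenuation fits are exact on lines and sane under noise", {
  f <- seq(3, 7, 0.1)
  spec <- structure(
    tibble::tibble(frequency_MHz = f, alpha_dB_mm = 1.0 * f + 0.5, reliable = TRUE),
    class = c("attenuation_spectrum", class(tibble::tibble()))
  )
  fit <- fit_attenuation_line(spec, c(3, 7), eval_at = 9)
  expect_equal(fit$slope, 1.0, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-12)
  expect_equal(fit$value, 9.5, tolerance = 1e-12)

  two <- structure(
    tibble::tibble(frequency_MHz = c(3, 7), alpha_dB_mm = c(3, 7), reliable = TRUE),
    class = c("attenuation_spectrum", class(tibble::tibble()))
  )
  f2 <- fit_attenuation_line(two, c(3, 7), eval_at = 7.54)
  expect_equal(f2$slope, 1)
  expect_equal(f2$value, 7.54)

  set.seed(5)
  noisy <- structure(
    tibble::tibble(frequency_MHz = f, alpha_dB_mm = 1.0 * f + 0.5 + rnorm(41, 0, 0.2),
                   reliable = TRUE),
    class = c("attenuation_spectrum", class(tibble::tibble()))
  )
  fn <- fit_attenuation_line(noisy, c(3, 7))
  se <- tidy(fn)$std_error[2]
  expect_lt(abs(fn$slope - 1.0), 3 * se)
  expect_error(fit_attenuation_line(noisy, c(10, 12)), "Fewer than 2")
})

test_that("SoS uncertainty propagation matches partials and Monte Carlo", {
  expect_equal(propagate_sos_uncertainty(2, 0.2, 1488), 0)

  # only delay uncertainty: u = (c^2/d) u_t in SI units
  d <- 2; dt <- 0.2; cw <- 1488; u_t <- 0.001
  cs <- 1000 * d / (1000 * d / cw - dt)
  expect_equal(
    propagate_sos_uncertainty(d, dt, cw, u_delay_us = u_t),
    cs^2 / (d * 1e-3) * (u_t * 1e-6),
    tolerance = 1e-9
  )

  set.seed(8)
  n <- 1e4
  draws <- 1000 * (d + rnorm(n, 0, 0.05)) / (1000 * (d + rnorm(n, 0, 0.05)) / cw - dt)
  # Monte Carlo with thickness-only uncertainty (numerator and denominator
  # share one thickness draw)
  dd <- d + rnorm(n, 0, 0.05)
  mc <- sd(1000 * dd / (1000 * dd / cw - dt))
  ana <- propagate_sos_uncertainty(d, dt, cw, u_thickness_mm = 0.05)
  expect_lt(abs(ana - mc) / mc, 0.05)

  expect_error(propagate_sos_uncertainty(2, 0.2, 1488, u_delay_us = -1), "non-negative")
})

test_that("density is plain mass over volume at the right scale", {
  # 20 x 20 x 2.06 mm slab weighing 0.9311 g -> about 1130 kg/m^3
  expect_equal(sample_density(0.9311, 20 * 20 * 2.06), 1130, tolerance = 1)
  expect_error(sample_density(1, 0), "positive")
})

test_that("pulse recordings validate Nyquist and repetition averaging", {
  t <- seq(0, 10, by = 0.004)
  expect_error(pulse_recording(t, sin(t), frequency_MHz = 200), "Nyquist")
  r1 <- pulse_recording(t, sin(t), 5)
  r2 <- pulse_recording(t, sin(t) + 1, 5)
  avg <- average_repetitions(list(r1, r2))
  expect_equal(avg$amplitude, sin(t) + 0.5)
  expect_equal(attr(avg, "n_repetitions"), 2L)
})
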