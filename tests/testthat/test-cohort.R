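toy_sample <- function(patient, diam = 20, dx = 0, n = 10) {
  tibble::tibble(
    patient = patient, label = "aorta", point_index = seq_len(n),
    x = dx, y = 0, z = -seq_len(n), diameter = diam, valid = TRUE
  )
}

test_that("averaging an identical cohort is idempotent with zero spread", {
  cohort <- dplyr::bind_rows(lapply(sprintf("p%d", 1:5), toy_sample))
  avg <- average_cohort(cohort)
  expect_equal(avg$diameter, rep(20, 10))
  expect_equal(avg$x, rep(0, 10))
  expect_equal(avg$sd_x, rep(0, 10))
  expect_equal(avg$sd_diam, rep(0, 10))
  expect_equal(avg$n_contrib, rep(5L, 10))
})

test_that("index-wise means match the arithmetic mean oracle", {
  cohort <- dplyr::bind_rows(lapply(1:10, function(i) toy_sample(paste0("p", i), diam = 20 + i)))
  avg <- average_cohort(cohort)
  expect_equal(avg$diameter, rep(mean(20 + 1:10), 10))
  expect_equal(avg$diameter, rep(25.5, 10))
})

test_that("spread follows the sample SD (n-1) convention", {
  cohort <- dplyr::bind_rows(toy_sample("a", diam = 20), toy_sample("b", diam = 22))
  sp <- cohort_spread(cohort)
  expect_equal(sp$max_diam_sd, sd(c(20, 22)))
  expect_equal(sp$max_diam_sd, sqrt(2), tolerance = 1e-12)

  # two patients offset +/-3 mm in x only: per-axis sample SD via brute force
  cohort2 <- dplyr::bind_rows(toy_sample("a", dx = -3), toy_sample("b", dx = 3))
  sp2 <- cohort_spread(cohort2)
  expect_equal(sp2$max_coord_sd, sd(c(-3, 3)))  # sd_y = sd_z = 0

  expect_error(cohort_spread(toy_sample("only")), "at least 2")
})

test_that("averaging commutes with global translation", {
  cohort <- dplyr::bind_rows(toy_sample("a", dx = -1), toy_sample("b", dx = 1),
                             toy_sample("c", dx = 0.5))
  t_vec <- c(3, -2, 7)
  moved <- dplyr::mutate(cohort, x = x + t_vec[1], y = y + t_vec[2], z = z + t_vec[3])
  a1 <- average_cohort(moved)
  a2 <- average_cohort(cohort)
  expect_equal(a1$x, a2$x + t_vec[1], tolerance = 1e-12)
  expect_equal(a1$z, a2$z + t_vec[3], tolerance = 1e-12)
  expect_equal(a1$sd_3d, a2$sd_3d, tolerance = 1e-12)
})

test_that("averages and SDs are invariant to patient ordering", {
  cohort <- dplyr::bind_rows(lapply(1:6, function(i) toy_sample(paste0("p", i), diam = 18 + i, dx = i / 2)))
  shuffled <- dplyr::arrange(cohort, dplyr::desc(patient), point_index)
  expect_equal(average_cohort(cohort), average_cohort(shuffled))
})

test_that("count mismatches and empty-index cases are handled", {
  bad <- dplyr::bind_rows(toy_sample("a", n = 10), toy_sample("b", n = 8))
  expect_error(average_cohort(bad), "disagree")

  one_invalid <- dplyr::bind_rows(toy_sample("a"), toy_sample("b"))
  one_invalid$valid[one_invalid$patient == "a" & one_invalid$point_index == 5] <- FALSE
  one_invalid$valid[one_invalid$patient == "b" & one_invalid$point_index == 5] <- FALSE
  avg <- average_cohort(one_invalid)
  expect_false(avg$valid[avg$point_index == 5])
  expect_equal(avg$n_contrib[avg$point_index == 5], 0L)
  expect_true(all(avg$valid[avg$point_index != 5]))
})

test_that("a noisy synthetic cohort recovers the base anatomy at the CLT rate", {
  co <- synth_cohort(
    vessel_tree_params(),
    cohort_params(n = 30, coord_sigma_mm = 2, diam_sigma_mm = 1,
                  jitter_frac = 0, seed = 7)
  )
  samples <- lapply(co$patients, patient_sample_from_truth)
  avg <- average_cohort(samples)
  truth <- patient_sample_from_truth(co$ground_truth)
  j <- dplyr::inner_join(avg, truth, by = c("label", "point_index"),
                         suffix = c("", ".t"))
  coord_err <- sqrt((j$x - j$x.t)^2 + (j$y - j$y.t)^2 + (j$z - j$z.t)^2)
  expect_lt(max(coord_err), 3 * 2 / sqrt(30))
  expect_lt(max(abs(j$diameter - j$diameter.t)), 3 * 1 / sqrt(30) * 2)
})

test_that("averaged anatomy serializes to CSV and JSON and back", {
  avg <- average_cohort(dplyr::bind_rows(toy_sample("a"), toy_sample("b", diam = 24)))
  for (ext in c(".csv", ".json")) {
    tf <- withr::local_tempfile(fileext = ext)
    save_averaged_anatomy(avg, tf)
    back <- load_averaged_anatomy(tf)
    expect_equal(back$diameter, avg$diameter, tolerance = 1e-12)
    expect_s3_class(back, "averaged_anatomy")
  }
  g <- glance(avg)
  expect_equal(g$n_segments, 1L)
  expect_equal(g$max_diameter, 22)
})
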