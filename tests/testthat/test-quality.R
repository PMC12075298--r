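vol_from <- function(arr, spacing = 1, origin = c(0, 0, 0)) {
  binary_volume(arr, spacing, origin)
}

test_that("Dice coefficient satisfies its defining identities", {
  occ <- array(FALSE, c(10, 10, 10))
  occ[3:7, 3:7, 3:7] <- TRUE
  x <- vol_from(occ)
  expect_identical(sdsc(x, x), 1)

  other <- array(FALSE, c(10, 10, 10))
  other[8:10, 8:10, 8:10] <- TRUE
  expect_identical(sdsc(x, vol_from(other)), 0)

  # |X| = |Y| = 100, overlap 50
  a <- array(FALSE, c(20, 20, 1)); a[1:100] <- TRUE
  b <- array(FALSE, c(20, 20, 1)); b[51:150] <- TRUE
  expect_equal(sdsc(vol_from(a), vol_from(b)), 0.5)
})

test_that("Dice is symmetric, bounded, and guards its grid preconditions", {
  set.seed(2)
  a <- vol_from(array(runif(1000) > 0.5, c(10, 10, 10)))
  b <- vol_from(array(runif(1000) > 0.5, c(10, 10, 10)))
  expect_identical(sdsc(a, b), sdsc(b, a))
  expect_gte(sdsc(a, b), 0)
  expect_lte(sdsc(a, b), 1)
  shifted <- translate_volume(b, c(1, 0, 0))
  expect_error(sdsc(a, shifted), "common_grid")
  e <- vol_from(array(FALSE, c(5, 5, 5)))
  expect_error(sdsc(e, e), "empty")
})

test_that("volumes voxelized on different grids can be Dice-compared after resampling", {
  c1 <- voxelize_mesh(fixture_cylinder(r = 5, z0 = 0, z1 = 20), spacing = 0.5)
  c2 <- voxelize_mesh(translate_mesh(fixture_cylinder(r = 5, z0 = 0, z1 = 20), c(30, 0, 0)),
                      spacing = 0.5)
  cg <- common_grid(c1, c2)
  expect_identical(sdsc(cg[[1]], cg[[2]]), 0)          # disjoint cylinders
  cg2 <- common_grid(c1, c1)
  expect_identical(sdsc(cg2[[1]], cg2[[2]]), 1)
})

test_that("landmark translation is the least-squares mean difference", {
  expect_equal(landmark_translation(rbind(c(0, 0, 0)), rbind(c(1, 1, 1))), c(1, 1, 1))
  mv <- rbind(c(0, 0, 0), c(1, 0, 2), c(-1, 3, 0))
  expect_equal(landmark_translation(mv, sweep(mv, 2, c(-2, 0, 0), "+")), c(-2, 0, 0))

  set.seed(9)
  fx <- mv + matrix(rnorm(9, 0, 0.1), 3)
  t_hat <- landmark_translation(mv, fx)
  expect_equal(t_hat, colMeans(fx - mv))
  # any other translation has larger sum of squared distances
  ssq <- function(tr) sum((sweep(mv, 2, -tr) - fx)^2)
  for (d in list(c(0.05, 0, 0), c(0, -0.05, 0), c(0, 0, 0.05))) {
    expect_gt(ssq(t_hat + d), ssq(t_hat))
  }
  expect_error(landmark_translation(mv, mv[1:2, ]), "different sizes")
})

test_that("closest-point distances match analytic and brute-force oracles", {
  s5 <- fixture_icosphere(5, 3)
  dm0 <- mesh_distance_map(s5, s5)
  expect_equal(dm0$summary$max, 0)

  s6 <- fixture_icosphere(6, 3)
  dm <- mesh_distance_map(s6, s5)
  # concentric spheres: all distances 1 up to the facet chord error
  expect_lt(max(abs(dm$mesh$vertex_scalars - 1)), 0.02)

  cube <- fixture_cube(1)
  shifted <- translate_mesh(fixture_cube(1), c(0.5, 0, 0))
  dmc <- mesh_distance_map(shifted, cube)
  expect_equal(dmc$summary$max, 0.5, tolerance = 1e-9)
  # brute-force point sampling oracle on the shifted far face
  set.seed(4)
  probe <- cbind(1.5, runif(200), runif(200))
  d_oracle <- vesselphantom:::cpp_point_mesh_distance(probe, cube$vertices, cube$faces - 1L)
  expect_equal(max(d_oracle), 0.5, tolerance = 1e-9)

  # translation invariance when both meshes move together
  dm2 <- mesh_distance_map(translate_mesh(s6, c(3, -2, 1)), translate_mesh(s5, c(3, -2, 1)))
  expect_equal(dm2$mesh$vertex_scalars, dm$mesh$vertex_scalars, tolerance = 1e-9)

  expect_equal(nrow(tidy(dm)), nrow(s6$vertices))
  expect_named(glance(dm), c("max", "mean", "p95"))
})

test_that("junction masking removes spheres from the occupancy", {
  occ <- array(TRUE, c(21, 21, 21))
  v <- binary_volume(occ, 1, origin = c(-10, -10, -10))
  masked <- mask_spheres(v, rbind(c(0, 0, 0)), 5)
  # voxel-center count inside a radius-5 sphere on the unit grid
  centers <- expand.grid(-10:10, -10:10, -10:10)
  inside <- rowSums(centers^2) <= 25
  expect_equal(sum(v$occupancy) - sum(masked$occupancy), sum(inside))
})

test_that("axisymmetric flow integration matches closed forms", {
  r <- seq(0, 10, length.out = 50)
  plug <- tibble::tibble(radius_mm = r, velocity_cm_s = 20)
  expect_equal(volumetric_flow_axisymmetric(plug), pi * 100 * 20 * 0.01,
               tolerance = 1e-9)

  pois <- tibble::tibble(radius_mm = r, velocity_cm_s = 30 * (1 - (r / 10)^2))
  expect_lt(
    abs(volumetric_flow_axisymmetric(pois) - pi * 100 * 30 / 2 * 0.01) /
      (pi * 100 * 30 / 2 * 0.01),
    0.005
  )

  # arbitrary tabulated profile vs fine-grid quadrature
  vfun <- function(rr) 10 + 5 * sin(rr / 3) + rr^2 / 20
  coarse <- tibble::tibble(radius_mm = r, velocity_cm_s = vfun(r))
  rf <- seq(0, 10, length.out = 5000)
  fine <- tibble::tibble(radius_mm = rf, velocity_cm_s = vfun(rf))
  q50 <- volumetric_flow_axisymmetric(coarse)
  qf <- volumetric_flow_axisymmetric(fine)
  expect_lt(abs(q50 - qf) / qf, 0.005)

  # linearity in the profile
  q1 <- volumetric_flow_axisymmetric(plug)
  q2 <- volumetric_flow_axisymmetric(pois)
  both <- tibble::tibble(radius_mm = r,
                         velocity_cm_s = 2 * plug$velocity_cm_s + pois$velocity_cm_s)
  expect_equal(volumetric_flow_axisymmetric(both), 2 * q1 + q2, tolerance = 1e-9)

  expect_error(
    volumetric_flow_axisymmetric(tibble::tibble(radius_mm = c(0, 12), velocity_cm_s = 1), R = 10),
    "exceed"
  )
})

test_that("diametral profiles fold into single-sided radial profiles", {
  x <- seq(-10, 10, length.out = 201)
  v <- 30 * (1 - (x / 10)^2)
  prof <- fold_radial_profile(x, v, n_bins = 40)
  expect_equal(nrow(prof), 40L)
  q <- volumetric_flow_axisymmetric(prof, R = 10)
  expect_lt(abs(q - pi * 100 * 15 * 0.01) / (pi * 100 * 15 * 0.01), 0.02)
})
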