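test_that("rings sit perpendicular to a straight centerline at the right radius", {
  rg <- build_rings(fixture_straight_anatomy(diameter = 20), m = 32)$aorta
  expect_equal(rg$radii, rep(10, 21))
  expect_equal(rg$normals, matrix(rep(c(0, 0, -1), each = 21), ncol = 3),
               ignore_attr = TRUE)
  # 32 points per ring, 11.25 degrees apart
  expect_equal(dim(rg$points)[2], 32L)
  p1 <- rg$points[1, 1, ] - rg$centers[1, ]
  p2 <- rg$points[1, 2, ] - rg$centers[1, ]
  ang <- acos(sum(p1 * p2) / (sqrt(sum(p1^2)) * sqrt(sum(p2^2)))) * 180 / pi
  expect_equal(ang, 11.25, tolerance = 1e-9)
  expect_error(build_rings(dplyr::mutate(fixture_straight_anatomy(), diameter = 0)),
               "Non-positive")
})

test_that("rotation-minimizing frames do not twist along a helix", {
  t <- seq(0, 4 * pi, length.out = 200)
  helix <- tibble::tibble(
    label = "aorta", point_index = seq_along(t),
    x = 15 * cos(t), y = 15 * sin(t), z = 4 * t, diameter = 8, valid = TRUE
  )
  rg <- build_rings(helix, m = 32)$aorta
  # oracle: transport the previous frame vector by projection onto the next
  # ring plane; RMF should agree within 2 degrees per step
  max_twist <- 0
  for (i in seq_len(nrow(rg$centers) - 1)) {
    v <- rg$u[i, ] - sum(rg$u[i, ] * rg$normals[i + 1, ]) * rg$normals[i + 1, ]
    v <- v / sqrt(sum(v^2))
    ang <- acos(pmin(1, abs(sum(v * rg$u[i + 1, ])))) * 180 / pi
    max_twist <- max(max_twist, ang)
  }
  expect_lt(max_twist, 2)
})

test_that("lofted tubes match analytic lateral areas", {
  tube <- loft_segment(build_rings(fixture_straight_anatomy(diameter = 20), m = 32)$aorta)
  expect_lt(abs(mesh_area(tube) - 2 * pi * 10 * 20) / (2 * pi * 10 * 20), 0.02)
  # every vertex at distance r from the axis (straight case exact up to chord)
  rr <- sqrt(tube$vertices[, 1]^2 + tube$vertices[, 2]^2)
  expect_lt(max(abs(rr - 10)) / 10, 0.01)

  taper <- dplyr::mutate(fixture_straight_anatomy(),
                         diameter = seq(20, 10, length.out = 21))
  cone <- loft_segment(build_rings(taper, m = 32)$aorta)
  slant <- sqrt(20^2 + 5^2)
  expect_lt(abs(mesh_area(cone) - pi * 15 * slant) / (pi * 15 * slant), 0.02)

  two <- loft_segment(build_rings(fixture_straight_anatomy(n = 2), m = 32)$aorta)
  expect_equal(nrow(two$faces), 2L * 32L)

  overlapping <- fixture_straight_anatomy(n = 3, length_mm = 1e-9)
  expect_error(loft_segment(build_rings(overlapping, m = 32)$aorta), "Coincident|overlap")
})

test_that("a Y junction blends into one watertight genus-0 surface", {
  y_anat <- dplyr::bind_rows(
    tibble::tibble(label = "aorta", point_index = 1:30, x = 0, y = 0,
                   z = seq(60, 1, length.out = 30), diameter = 10, valid = TRUE),
    tibble::tibble(label = "common_iliac_L", point_index = 1:30,
                   x = seq(-0.5, -30, length.out = 30), y = 0,
                   z = seq(-1, -50, length.out = 30), diameter = 10, valid = TRUE),
    tibble::tibble(label = "common_iliac_R", point_index = 1:30,
                   x = seq(0.5, 30, length.out = 30), y = 0,
                   z = seq(-1, -50, length.out = 30), diameter = 10, valid = TRUE)
  )
  mesh <- blend_junctions(build_rings(y_anat, m = 32), blend_radius = 3, spacing = 0.6)
  expect_true(is_watertight(mesh))
  # Euler characteristic of a genus-0 closed surface
  nE <- nrow(unique(t(apply(
    rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)]),
    1, sort
  ))))
  expect_equal(nrow(mesh$vertices) - nE + nrow(mesh$faces), 2L)
  # far from the junction the cross-section is circular at the ring radius
  far <- mesh$vertices[mesh$vertices[, 3] > 40 & mesh$vertices[, 3] < 50, ]
  rr <- sqrt(far[, 1]^2 + far[, 2]^2)
  expect_lt(max(abs(rr - 5)) / 5, 0.01)
})

test_that("zero blend radius degenerates to the plain union", {
  y <- dplyr::bind_rows(
    tibble::tibble(label = "aorta", point_index = 1:10, x = 0, y = 0,
                   z = seq(30, 0, length.out = 10), diameter = 10, valid = TRUE),
    tibble::tibble(label = "common_iliac_L", point_index = 1:10,
                   x = seq(0, -15, length.out = 10), y = 0,
                   z = seq(0, -25, length.out = 10), diameter = 10, valid = TRUE),
    tibble::tibble(label = "common_iliac_R", point_index = 1:10,
                   x = seq(0, 15, length.out = 10), y = 0,
                   z = seq(0, -25, length.out = 10), diameter = 10, valid = TRUE)
  )
  sharp <- blend_junctions(build_rings(y, m = 16), blend_radius = 0, spacing = 0.6)
  soft <- blend_junctions(build_rings(y, m = 16), blend_radius = 3, spacing = 0.6)
  expect_true(is_watertight(sharp))
  # the blend only adds material at the crotch; volumes differ by little
  expect_gt(mesh_volume(soft), mesh_volume(sharp))
  expect_lt((mesh_volume(soft) - mesh_volume(sharp)) / mesh_volume(sharp), 0.1)
})

test_that("renal chains are extended to the aortic wall at their proximal radius", {
  anat <- dplyr::bind_rows(
    tibble::tibble(label = "aorta", point_index = 1:41, x = 0, y = 0,
                   z = seq(0, -80, length.out = 41), diameter = 20, valid = TRUE),
    # renal starting 14 mm off the aorta axis (4 mm off the r=10 wall)
    tibble::tibble(label = "renal_L", point_index = 1:10,
                   x = 0, y = seq(14, 40, length.out = 10),
                   z = -20, diameter = 6, valid = TRUE)
  )
  rings <- build_rings(anat, m = 24)
  chains <- vesselphantom:::anchor_chains(rings)
  expect_equal(nrow(chains$renal_L$centers), 11L)       # anchor prepended
  expect_equal(chains$renal_L$radii[1], 3)              # most proximal radius
  expect_equal(chains$renal_L$centers[1, ], c(0, 0, -20))  # nearest aorta point
  mesh <- blend_junctions(rings, blend_radius = 3, spacing = 0.6)
  expect_true(is_watertight(mesh))
})

test_that("Taubin smoothing reduces noise while preserving volume", {
  s <- fixture_icosphere(5, 3)
  expect_identical(smooth_mesh(s, factor = 0), s)

  set.seed(3)
  noisy <- s
  noisy$vertices <- noisy$vertices + matrix(rnorm(length(noisy$vertices), 0, 0.2),
                                            ncol = 3)
  sm <- smooth_mesh(noisy, factor = 0.5)
  rms <- function(m) sqrt(mean((sqrt(rowSums(m$vertices^2)) - 5)^2))
  expect_lt(rms(sm), rms(noisy))

  cyl_anat <- fixture_straight_anatomy(n = 41, length_mm = 40, diameter = 20)
  cyl <- blend_junctions(build_rings(cyl_anat, m = 32), blend_radius = 0, spacing = 0.5)
  smc <- smooth_mesh(cyl, factor = 0.5)
  expect_lt(abs(mesh_volume(smc) - mesh_volume(cyl)) / mesh_volume(cyl), 0.02)
})

test_that("the thin wall displaces the surface by the wall thickness", {
  cyl_anat <- fixture_straight_anatomy(n = 41, length_mm = 40, diameter = 20)
  lumen <- blend_junctions(build_rings(cyl_anat, m = 32), blend_radius = 0, spacing = 0.5)
  shell <- thin_wall_shell(lumen, 1.5)
  expect_true(is_watertight(shell))
  mid <- abs(shell$vertices[, 3] + 20) < 5
  rr <- sqrt(shell$vertices[mid, 1]^2 + shell$vertices[mid, 2]^2)
  expect_lt(abs(max(rr) - 11.5) / 11.5, 0.01)
  expect_lt(abs(min(rr) - 10) / 10, 0.01)

  expect_error(thin_wall_shell(lumen, 0), "positive")

  s <- surface_from_volume(voxelize_mesh(fixture_icosphere(5, 3), spacing = 0.4))
  sh <- thin_wall_shell(s, 1.5)
  truth <- 4 / 3 * pi * (6.5^3 - 5^3)
  expect_lt(abs(mesh_volume(sh) - truth) / truth, 0.03)
})

test_that("single-patient reconstruction matches the source anatomy closely", {
  pt <- synth_vessel_tree(vessel_tree_params(renal = FALSE), spacing = 0.8)
  vol <- voxelize_mesh(pt$mesh, spacing = 0.8)
  res <- resample_equal_arclength(pt$centerlines, n = segment_counts())
  sec <- measure_sections(vol, res, window = 70, pixel = 0.4)
  avg <- average_cohort(dplyr::mutate(sec, patient = "p1"))
  rec <- blend_junctions(build_rings(avg, m = 32), blend_radius = 3, spacing = 0.8)
  expect_true(is_watertight(rec))
  cg <- common_grid(voxelize_mesh(rec, spacing = 0.8), vol)
  bif <- detect_bifurcation_point(pt$centerlines)
  masked <- lapply(cg, mask_spheres, centers = rbind(bif), radius = 20)
  expect_gte(sdsc(masked[[1]], masked[[2]]), 0.95)
})
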