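# Geometry fixtures built in code: icosphere, capped cylinder tube, and a
# grid-aligned cube. All coordinates in mm.

fixture_icosphere <- function(r = 5, subdivisions = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    mid <- new.env()
    getmid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(mid[[k]])) return(mid[[k]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    newf <- vector("list", nrow(f))
    for (q in seq_len(nrow(f))) {
      a <- f[q, 1]; b <- f[q, 2]; c_ <- f[q, 3]
      ab <- getmid(a, b); bc <- getmid(b, c_); ca <- getmid(c_, a)
      newf[[q]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- do.call(rbind, newf)
  }
  v <- v / sqrt(rowSums(v^2)) * r
  tri_mesh(v, f)
}

# closed cylinder of radius r along +z from z0 to z1, fan-capped
fixture_cylinder <- function(r = 5, z0 = 0, z1 = 40, n_theta = 64, dz = 2,
                             center_xy = c(0, 0)) {
  zs <- seq(z0, z1, by = dz)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ring <- cbind(center_xy[1] + r * cos(th), center_xy[2] + r * sin(th))
  v <- do.call(rbind, lapply(zs, function(z) cbind(ring, z)))
  nz <- length(zs)
  idx <- function(i, j) (i - 1) * n_theta + ((j - 1) %% n_theta) + 1
  f <- do.call(rbind, lapply(seq_len(nz - 1), function(i) {
    j <- seq_len(n_theta)
    rbind(
      cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
      cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    )
  }))
  v <- rbind(v, c(center_xy, z0), c(center_xy, z1))
  c1 <- nrow(v) - 1; c2 <- nrow(v)
  f <- rbind(
    f,
    t(vapply(seq_len(n_theta), function(j) c(idx(1, j + 1), idx(1, j), c1), numeric(3))),
    t(vapply(seq_len(n_theta), function(j) c(idx(nz, j), idx(nz, j + 1), c2), numeric(3)))
  )
  tri_mesh(v, f)
}

fixture_cube <- function(side = 10, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(
    origin[1] + c(0, side), origin[2] + c(0, side), origin[3] + c(0, side)
  ))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6)
  )
  tri_mesh(v, f)
}

# straight-tube anatomy table for ring/loft tests
fixture_straight_anatomy <- function(n = 21, length_mm = 20, diameter = 20) {
  tibble::tibble(
    label = "aorta",
    point_index = seq_len(n),
    x = 0, y = 0,
    z = -seq(0, length_mm, length.out = n),
    diameter = diameter,
    valid = TRUE
  )
}
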