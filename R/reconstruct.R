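#' Build cross-sectional rings along an averaged anatomy
#'
#' Places a circular ring at every valid averaged centerline point with
#' radius `diameter / 2`, oriented perpendicular to the local tangent. Ring
#' frames are propagated along each segment with the rotation-minimizing
#' double-reflection method so rings do not twist against each other in
#' tortuous segments.
#'
#' @param anatomy an `averaged_anatomy` tibble (see [average_cohort()]), or
#'   any tibble with `label`, `point_index`, `x`, `y`, `z`, `diameter` and
#'   optional `valid` columns.
#' @param m boundary points per ring (>= 8); 32 keeps the chordal radius
#'   error below 0.5 percent.
#' @return A `ring_set`: named list per segment with `centers` (n x 3),
#'   `normals` (n x 3), `radii` (n), `u`/`v` frame vectors (n x 3), and
#'   `points` (n x m x 3).
#' @export
build_rings <- function(anatomy, m = 32L) {
  if (m < 8L) abort("`m` must be at least 8 ring points.")
  df <- as_tibble(unclass(anatomy))
  if (!"valid" %in% names(df)) df$valid <- TRUE
  df <- dplyr::filter(df, .data$valid)
  if (nrow(df) == 0L) abort("No valid anatomy points to build rings from.")
  if (any(!is.finite(df$diameter) | df$diameter <= 0)) {
    abort("Non-positive diameter at a valid anatomy point.")
  }
  segs <- split(df, df$label)
  out <- lapply(segs, function(d) {
    d <- dplyr::arrange(d, .data$point_index)
    p <- cbind(d$x, d$y, d$z)
    if (nrow(p) < 2L) abort(paste0("Segment '", d$label[1], "' has fewer than 2 valid points."))
    tg <- tangents(p)
    fr <- rmf_frames(p, tg)
    r <- d$diameter / 2
    ang <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
    pts <- array(NA_real_, dim = c(nrow(p), m, 3))
    for (i in seq_len(nrow(p))) {
      circ <- outer(cos(ang), fr$u[i, ]) + outer(sin(ang), fr$v[i, ])
      pts[i, , ] <- matrix(p[i, ], m, 3, byrow = TRUE) + r[i] * circ
    }
    list(centers = p, normals = tg, radii = r, u = fr$u, v = fr$v, points = pts)
  })
  structure(out, class = "ring_set", m = m)
}

# Rotation-minimizing frames by the double-reflection method
# (Wang, Juettler, Zheng & Liu 2008).
rmf_frames <- function(points, tang) {
  n <- nrow(points)
  u <- matrix(NA_real_, n, 3)
  ax <- plane_axes(tang[1, ])
  u[1, ] <- ax$u
  for (i in seq_len(n - 1L)) {
    v1 <- points[i + 1L, ] - points[i, ]
    c1 <- sum(v1 * v1)
    rL <- u[i, ] - (2 / c1) * sum(v1 * u[i, ]) * v1
    tL <- tang[i, ] - (2 / c1) * sum(v1 * tang[i, ]) * v1
    v2 <- tang[i + 1L, ] - tL
    c2 <- sum(v2 * v2)
    u_next <- if (c2 < 1e-30) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthogonalize against the tangent to stop drift
    u_next <- u_next - sum(u_next * tang[i + 1L, ]) * tang[i + 1L, ]
    u[i + 1L, ] <- u_next / sqrt(sum(u_next^2))
  }
  v <- cbind(
    tang[, 2] * u[, 3] - tang[, 3] * u[, 2],
    tang[, 3] * u[, 1] - tang[, 1] * u[, 3],
    tang[, 1] * u[, 2] - tang[, 2] * u[, 1]
  )
  list(u = u, v = v / sqrt(rowSums(v^2)))
}

#' Loft an open tube through one segment's rings
#'
#' Connects consecutive rings with triangulated quad strips; the tube is
#' left open at both ends.
#'
#' @param rings one entry of a [build_rings()] ring set (>= 2 rings).
#' @return A [tri_mesh()] open tube with `2 * m * (n - 1)` triangles.
#' @export
loft_segment <- function(rings) {
  pts <- rings$points
  n <- dim(pts)[1]
  m <- dim(pts)[2]
  if (n < 2L) abort("Need at least 2 rings to loft.")
  gaps <- sqrt(rowSums((rings$centers[-1, , drop = FALSE] -
                          rings$centers[-n, , drop = FALSE])^2))
  if (any(gaps < 1e-6)) abort("Consecutive rings overlap (center spacing < 1e-6 mm).")
  v <- matrix(aperm(pts, c(2, 1, 3)), ncol = 3)  # ring-major vertex order
  idx <- function(i, j) (i - 1L) * m + ((j - 1L) %% m) + 1L
  f <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    j <- seq_len(m)
    f[[i]] <- rbind(
      cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
      cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    )
  }
  tri_mesh(v, do.call(rbind, f))
}

# Capsule chains (centers + radii) per segment, junction-anchored:
# iliac children are prepended with their parent's terminal center, renal
# chains are extended to the nearest aorta centerline point, both at the
# child's most proximal radius -- the same rule the averaging method needs
# because no cross-sectional diameters exist inside bifurcations.
anchor_chains <- function(rings) {
  chains <- lapply(rings, function(rg) list(centers = rg$centers, radii = rg$radii))
  labs <- names(chains)
  prepend <- function(ch, anchor) {
    list(centers = rbind(anchor, ch$centers), radii = c(ch$radii[1], ch$radii))
  }
  parent_of <- c(
    common_iliac_L = "aorta", common_iliac_R = "aorta",
    external_iliac_L = "common_iliac_L", internal_iliac_L = "common_iliac_L",
    external_iliac_R = "common_iliac_R", internal_iliac_R = "common_iliac_R"
  )
  for (lab in intersect(names(parent_of), labs)) {
    par <- parent_of[[lab]]
    if (!par %in% labs) next
    anchor <- chains[[par]]$centers[nrow(chains[[par]]$centers), ]
    gap <- sqrt(sum((chains[[lab]]$centers[1, ] - anchor)^2))
    if (gap > 1e-6) chains[[lab]] <- prepend(chains[[lab]], anchor)
  }
  for (lab in intersect(c("renal_L", "renal_R"), labs)) {
    if (!"aorta" %in% labs) next
    ao <- chains[["aorta"]]$centers
    prox <- chains[[lab]]$centers[1, ]
    d2 <- rowSums(sweep(ao, 2, prox)^2)
    anchor <- ao[which.min(d2), ]
    if (sqrt(min(d2)) > 1e-6) chains[[lab]] <- prepend(chains[[lab]], anchor)
  }
  chains
}

# Terminal (inlet/outlet) planes: segment ends that do not meet a junction.
terminal_planes <- function(rings) {
  labs <- names(rings)
  planes <- list()
  add_plane <- function(rg, at_start) {
    n <- nrow(rg$centers)
    i <- if (at_start) 1L else n
    t_out <- rg$normals[i, ] * (if (at_start) -1 else 1)
    list(center = rg$centers[i, ], normal = t_out, radius = rg$radii[i])
  }
  has <- function(l) l %in% labs
  if (has("aorta")) {
    planes <- c(planes, list(add_plane(rings$aorta, TRUE)))
    if (!has("common_iliac_L") && !has("common_iliac_R")) {
      planes <- c(planes, list(add_plane(rings$aorta, FALSE)))
    }
  }
  for (side in c("L", "R")) {
    ci <- paste0("common_iliac_", side)
    ei <- paste0("external_iliac_", side)
    ii <- paste0("internal_iliac_", side)
    if (has(ci) && !has(ei) && !has(ii)) planes <- c(planes, list(add_plane(rings[[ci]], FALSE)))
    if (has(ei)) planes <- c(planes, list(add_plane(rings[[ei]], FALSE)))
    if (has(ii)) planes <- c(planes, list(add_plane(rings[[ii]], FALSE)))
    rn <- paste0("renal_", side)
    if (has(rn)) planes <- c(planes, list(add_plane(rings[[rn]], FALSE)))
  }
  planes
}

#' Blend lofted segments into one watertight surface
#'
#' Joins all segments of a ring set into a single closed surface by implicit
#' union: each segment becomes a capsule-chain signed-distance field, the
#' fields are united with a polynomial smooth-minimum whose blend radius
#' plays the role of the manual fillet at the bifurcations, and the zero
#' level set is extracted on a regular grid. Child segments that do not
#' reach their parent (no diameters can be measured inside a bifurcation)
#' are extended to the parent at their most proximal radius; renal chains
#' are extended to the nearest aorta centerline point the same way.
#'
#' Inlet and outlet ends are cut flat at the terminal ring planes and capped
#' (closed surface); with `open_ends = TRUE` the caps are removed
#' afterwards, leaving an open tube network for printing.
#'
#' @param rings a [build_rings()] ring set.
#' @param blend_radius smooth-union blend radius in mm (0 gives a sharp
#'   plain union).
#' @param spacing extraction grid spacing in mm.
#' @param open_ends drop the flat end caps after extraction.
#' @return A [tri_mesh()], watertight when `open_ends = FALSE`.
#' @export
blend_junctions <- function(rings, blend_radius = 3, spacing = 0.5, open_ends = FALSE) {
  if (!inherits(rings, "ring_set")) abort("`rings` must be a ring_set from build_rings().")
  if (blend_radius < 0) abort("`blend_radius` must be non-negative.")
  chains <- anchor_chains(rings)
  planes <- terminal_planes(rings)

  allc <- do.call(rbind, lapply(chains, `[[`, "centers"))
  maxr <- max(unlist(lapply(chains, `[[`, "radii")))
  pad <- maxr + blend_radius + 2 * spacing
  lo <- apply(allc, 2, min) - pad
  hi <- apply(allc, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  pts <- expand_grid_centers(lo, spacing, dims)
  sdf <- cpp_tube_union_sdf(pts, unname(chains), blend_radius)
  for (pl in planes) {
    # localized flat cut: only active near the terminal so distant geometry
    # is untouched
    dplane <- (pts[, 1] - pl$center[1]) * pl$normal[1] +
      (pts[, 2] - pl$center[2]) * pl$normal[2] +
      (pts[, 3] - pl$center[3]) * pl$normal[3]
    near <- sqrt((pts[, 1] - pl$center[1])^2 + (pts[, 2] - pl$center[2])^2 +
                   (pts[, 3] - pl$center[3])^2) < 2 * pl$radius + blend_radius
    sdf[near] <- pmax(sdf[near], dplane[near])
  }
  res <- cpp_marching_tets(-sdf, dims, 0, lo, c(spacing, spacing, spacing))
  if (nrow(res$vertices) == 0L) abort("Implicit union produced no surface; check the anatomy scale against the grid spacing.")
  mesh <- merge_vertices(tri_mesh(res$vertices, res$faces + 1L), tol = 1e-9)

  comp <- mesh_components(mesh)
  if (comp$n > 1L) {
    sizes <- sort(comp$face_counts, decreasing = TRUE)
    if (sizes[2] > 0.02 * sum(sizes)) {
      gaps <- junction_gaps(chains)
      abort(sprintf(
        "Implicit union is disconnected (%d substantial components); largest junction gap %.1f mm exceeds the blend reach.",
        sum(sizes > 0.02 * sum(sizes)), max(gaps)
      ))
    }
    # tiny satellite specks are extraction artifacts at grid tangencies
    keep <- comp$face_membership == comp$largest
    mesh <- merge_vertices(tri_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE]), tol = 1e-12)
  }
  if (open_ends) mesh <- drop_end_caps(mesh, planes, spacing)
  mesh
}

junction_gaps <- function(chains) {
  ends <- do.call(rbind, lapply(chains, function(ch) {
    rbind(ch$centers[1, ], ch$centers[nrow(ch$centers), ])
  }))
  n <- length(chains)
  if (n < 2L) return(0)
  gaps <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- chains[[i]]$centers
      b <- chains[[j]]$centers
      d <- sqrt(max(0, min(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b))))
      gaps <- c(gaps, d)
    }
  }
  gaps
}

mesh_components <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (col in list(c(1, 2), c(2, 3))) {
    for (q in seq_len(nrow(f))) {
      a <- find(f[q, col[1]])
      b <- find(f[q, col[2]])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(f[, 1], find, integer(1))
  tab <- table(roots)
  list(
    n = length(tab),
    face_counts = as.integer(tab),
    face_membership = roots,
    largest = as.integer(names(tab)[which.max(tab)])
  )
}

drop_end_caps <- function(mesh, planes, spacing) {
  cent <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
             mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
             mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
  nrm <- face_normals(mesh)
  drop <- rep(FALSE, nrow(mesh$faces))
  for (pl in planes) {
    dpl <- abs(sweep(cent, 2, pl$center) %*% pl$normal)
    aligned <- abs(nrm %*% pl$normal) > 0.85
    nearby <- sqrt(rowSums(sweep(cent, 2, pl$center)^2)) < 2 * pl$radius
    drop <- drop | (dpl < 0.6 * spacing & aligned & nearby)
  }
  tri_mesh(mesh$vertices, mesh$faces[!drop, , drop = FALSE])
}

#' Taubin-smooth a mesh
#'
#' Volume-preserving two-step Laplacian smoothing: `factor` in [0, 1] maps
#' to the shrink step `lambda = 0.6 * factor` with inflate step
#' `mu = -lambda - 0.01`, run for `iterations` passes. `factor = 0` is the
#' identity.
#'
#' @param mesh a [tri_mesh()].
#' @param factor smoothing strength in [0, 1].
#' @param iterations number of lambda/mu passes.
#' @return The smoothed mesh.
#' @export
smooth_mesh <- function(mesh, factor = 0.5, iterations = 10L) {
  if (factor < 0 || factor > 1) abort("`factor` must be in [0, 1].")
  if (factor == 0) return(mesh)
  lambda <- 0.6 * factor
  mu <- -lambda - 0.01
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- unique(rbind(e, e[, c(2, 1)]))
  nv <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  v <- mesh$vertices
  for (it in seq_len(iterations)) {
    v <- v + lambda * (as.matrix(A %*% v) / deg - v)
    v <- v + mu * (as.matrix(A %*% v) / deg - v)
  }
  mesh$vertices <- v
  mesh
}

mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(
    a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  ) / 6
}

vertex_normals <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(  # area-weighted (unnormalized cross products)
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  n <- matrix(0, nrow(v), 3)
  for (c_ in 1:3) {
    for (ax in 1:3) {
      acc <- rowsum(fn[, ax], f[, c_], reorder = FALSE)
      n[as.integer(rownames(acc)), ax] <- n[as.integer(rownames(acc)), ax] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Generate the thin-walled shell of a lumen surface
#'
#' Displaces every vertex outward along its vertex normal by the wall
#' thickness to make the outer surface, reverses the lumen surface as the
#' inner wall, and stitches inner and outer boundary loops when the lumen
#' has open ends. The default 1.5 mm wall matches reported human AAA wall
#' thickness.
#'
#' A self-intersection check measures the distance from each outer vertex
#' back to the lumen surface; vertices that fold closer than 80 percent of
#' the wall thickness (local radius of curvature smaller than the wall) are
#' reported via the `folded_vertices` attribute and a warning.
#'
#' @param lumen a [tri_mesh()] with consistent outward orientation.
#' @param thickness wall thickness in mm, > 0.
#' @return A [tri_mesh()] shell (watertight when the lumen is closed).
#' @export
thin_wall_shell <- function(lumen, thickness = 1.5) {
  if (!is.finite(thickness) || thickness <= 0) abort("`thickness` must be positive.")
  if (mesh_signed_volume(lumen) < 0) lumen$faces <- lumen$faces[, c(1, 3, 2)]
  nv <- nrow(lumen$vertices)
  nrm <- vertex_normals(lumen)
  outer_v <- lumen$vertices + thickness * nrm
  inner_f <- lumen$faces[, c(1, 3, 2)]          # reversed: normals into lumen
  outer_f <- lumen$faces + nv
  verts <- rbind(lumen$vertices, outer_v)
  faces <- rbind(inner_f, outer_f)

  # stitch open boundary loops between inner and outer surfaces
  f <- lumen$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  bnd <- e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  if (nrow(bnd) > 0L) {
    quads <- rbind(
      cbind(bnd[, 1], bnd[, 2], bnd[, 2] + nv),
      cbind(bnd[, 1], bnd[, 2] + nv, bnd[, 1] + nv)
    )
    faces <- rbind(faces, quads)
  }
  shell <- tri_mesh(verts, faces)

  d_back <- cpp_point_mesh_distance(outer_v, lumen$vertices, lumen$faces - 1L)
  folded <- which(d_back < 0.8 * thickness)
  if (length(folded) > 0L) {
    warn(sprintf(
      "Thin wall self-intersects at %d vertices (wall thicker than the local radius of curvature).",
      length(folded)
    ))
  }
  attr(shell, "folded_vertices") <- folded
  shell
}
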