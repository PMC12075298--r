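#' Axis-aligned binary occupancy volume
#'
#' A 3D logical array plus the affine grid geometry: per-axis voxel size
#' `spacing` (mm) and the world coordinate of the *center* of voxel
#' `[1, 1, 1]` as `origin` (mm). Column-major with x fastest, matching R
#' array layout.
#'
#' @param occupancy 3D logical array.
#' @param spacing length-3 positive numeric, mm per voxel.
#' @param origin length-3 numeric, world position of the first voxel center.
#' @return A `binary_volume` object.
#' @export
binary_volume <- function(occupancy, spacing, origin = c(0, 0, 0)) {
  if (length(dim(occupancy)) != 3L) abort("`occupancy` must be a 3D array.")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive voxel sizes in mm.")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) abort("`origin` must be a finite 3-vector.")
  storage.mode(occupancy) <- "logical"
  structure(
    list(occupancy = occupancy, spacing = spacing, origin = origin),
    class = "binary_volume"
  )
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf(
    "<binary_volume> %d x %d x %d voxels @ (%.3g, %.3g, %.3g) mm, %d occupied (%.1f mm^3)\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    sum(x$occupancy), volume_mm3(x)
  ))
  invisible(x)
}

#' Occupied volume in mm^3
#'
#' @param volume a [binary_volume()].
#' @return Occupied voxel count times voxel volume, mm^3.
#' @export
volume_mm3 <- function(volume) sum(volume$occupancy) * prod(volume$spacing)

#' Convert between world and voxel-index coordinates
#'
#' The mapping is affine: `world = origin + (index - 1) * spacing`, with
#' 1-based voxel indices addressing voxel centers.
#'
#' @param volume a [binary_volume()].
#' @param points numeric matrix (`n x 3`).
#' @return An `n x 3` matrix in the other coordinate system (`index_to_world`
#'   returns mm; `world_to_index` returns fractional 1-based indices).
#' @export
world_to_index <- function(volume, points) {
  points <- rbind(points)
  sweep(sweep(points, 2, volume$origin, "-"), 2, volume$spacing, "/") + 1
}

#' @rdname world_to_index
#' @export
index_to_world <- function(volume, points) {
  points <- rbind(points)
  sweep(sweep(points - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

#' Voxelize a closed surface mesh
#'
#' Marks a voxel occupied iff its center lies inside the surface, decided by
#' vertical ray-crossing parity. The grid covers the mesh bounding box plus
#' `padding` voxels on every side. Non-watertight meshes are fan-filled when
#' their boundary loops are short; larger holes raise an error reporting the
#' open boundary edge count.
#'
#' @param mesh a [tri_mesh()], assumed closed.
#' @param spacing voxel size in mm (scalar or length 3). The default 0.5 mm
#'   is about half a typical abdominal CTA pixel, fine enough to resolve
#'   lumen boundaries.
#' @param padding margin in voxels around the mesh bounding box.
#' @return A [binary_volume()].
#' @export
voxelize_mesh <- function(mesh, spacing = 0.5, padding = 4L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) abort("`spacing` must be positive.")
  if (!is_watertight(mesh)) {
    mesh <- try_fill_holes(mesh)
    if (!is_watertight(mesh)) {
      abort(sprintf(
        "Mesh is not watertight: %d open boundary edges remain after hole filling.",
        n_boundary_edges(mesh)
      ))
    }
  }
  lo <- apply(mesh$vertices, 2, min) - padding * spacing
  hi <- apply(mesh$vertices, 2, max) + padding * spacing
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  occ <- cpp_voxelize(mesh$vertices, mesh$faces - 1L, lo, spacing, dims)
  binary_volume(array(occ, dim = dims), spacing = spacing, origin = lo)
}

# Fan-fill boundary loops of up to `max_loop` edges around the loop centroid.
try_fill_holes <- function(mesh, max_loop = 25L) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  boundary <- e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  if (nrow(boundary) == 0L) return(mesh)
  v <- mesh$vertices
  new_faces <- list()
  remaining <- boundary
  while (nrow(remaining) > 0L) {
    loop <- remaining[1, ]
    remaining <- remaining[-1, , drop = FALSE]
    verts <- loop
    repeat {
      nxt <- which(remaining[, 1] == verts[length(verts)])[1]
      if (is.na(nxt)) break
      verts <- c(verts, remaining[nxt, 2])
      remaining <- remaining[-nxt, , drop = FALSE]
      if (verts[length(verts)] == verts[1]) break
      if (length(verts) > max_loop + 1L) return(mesh)  # give up, report upstream
    }
    ring <- unique(verts)
    if (length(ring) < 3L) next
    centroid <- colMeans(v[ring, , drop = FALSE])
    v <- rbind(v, centroid)
    ci <- nrow(v)
    idx <- c(seq_along(ring), 1L)
    for (q in seq_along(ring)) {
      new_faces[[length(new_faces) + 1L]] <- c(ring[idx[q + 1L]], ring[idx[q]], ci)
    }
  }
  if (length(new_faces) == 0L) return(mesh)
  tri_mesh(v, rbind(mesh$faces, do.call(rbind, new_faces)))
}

#' Extract the occupancy isosurface of a binary volume
#'
#' Runs marching-tetrahedra isosurfacing at occupancy level 0.5 on the
#' zero-padded grid, so the result is a closed surface in world millimetre
#' coordinates. By default the 0/1 field is first softened with a narrow
#' separable tent filter (support one voxel per side), which removes the
#' voxel staircase while keeping the 0.5 level surface at the voxel
#' boundary; set `smooth_field = FALSE` for the raw blocky isosurface.
#'
#' @param volume a [binary_volume()] with at least one occupied voxel.
#' @param smooth_field soften the binary field before extraction.
#' @return A [tri_mesh()].
#' @export
surface_from_volume <- function(volume, smooth_field = TRUE) {
  occ <- volume$occupancy
  if (!any(occ)) abort("Empty volume: no occupied voxels to surface.")
  d <- dim(occ)
  pad <- 2L
  field <- array(0, dim = d + 2L * pad)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- occ * 1.0
  if (smooth_field) {
    smoothed <- tent_filter3(tent_filter3(field))
    # tiny features (about one voxel across) would be smoothed below the
    # extraction level entirely; keep the raw field for those volumes
    if (max(smoothed) > 0.5) field <- smoothed
  }
  res <- cpp_marching_tets(
    as.vector(field), dim(field), 0.5,
    volume$origin - pad * volume$spacing, volume$spacing
  )
  merge_vertices(tri_mesh(res$vertices, res$faces + 1L), tol = 1e-9)
}

# separable (1/4, 1/2, 1/4) filter along each axis, clamped at edges
tent_filter3 <- function(arr) {
  for (ax in 1:3) {
    n <- dim(arr)[ax]
    lo <- c(1L, seq_len(n - 1L))
    hi <- c(seq_len(n - 1L) + 1L, n)
    arr <- switch(ax,
      0.5 * arr + 0.25 * arr[lo, , , drop = FALSE] + 0.25 * arr[hi, , , drop = FALSE],
      0.5 * arr + 0.25 * arr[, lo, , drop = FALSE] + 0.25 * arr[, hi, , drop = FALSE],
      0.5 * arr + 0.25 * arr[, , lo, drop = FALSE] + 0.25 * arr[, , hi, drop = FALSE]
    )
  }
  arr
}

#' Translate a binary volume
#'
#' Shifts the grid origin; no resampling occurs.
#'
#' @param volume a [binary_volume()].
#' @param offset length-3 numeric, mm.
#' @return The translated volume.
#' @export
translate_volume <- function(volume, offset) {
  stopifnot(length(offset) == 3L, all(is.finite(offset)))
  volume$origin <- volume$origin + as.numeric(offset)
  volume
}

#' Resample binary volumes onto a shared grid
#'
#' Builds the union bounding grid of the inputs (spacing taken from the
#' first volume) and samples each volume at the new voxel centers by
#' nearest-voxel lookup. Needed before Dice comparison of volumes that were
#' voxelized on different grids.
#'
#' @param ... two or more [binary_volume()] objects.
#' @param spacing optional spacing override (mm).
#' @return A list of volumes on one common grid.
#' @export
common_grid <- function(..., spacing = NULL) {
  vols <- list(...)
  if (length(vols) == 1L && is.list(vols[[1]]) && !inherits(vols[[1]], "binary_volume")) {
    vols <- vols[[1]]
  }
  if (length(vols) < 2L) abort("Need at least two volumes.")
  spacing <- if (is.null(spacing)) vols[[1]]$spacing else rep(as.numeric(spacing), length.out = 3)
  lo <- Reduce(pmin, lapply(vols, function(v) v$origin))
  hi <- Reduce(pmax, lapply(vols, function(v) v$origin + (dim(v$occupancy) - 1L) * v$spacing))
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  idx <- expand_grid_centers(lo, spacing, dims)
  lapply(vols, function(v) {
    ijk <- round(world_to_index(v, idx))
    d <- dim(v$occupancy)
    inside <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
      ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= d[3]
    occ <- logical(nrow(ijk))
    occ[inside] <- v$occupancy[cbind(ijk[inside, 1], ijk[inside, 2], ijk[inside, 3])]
    binary_volume(array(occ, dim = dims), spacing = spacing, origin = lo)
  })
}

expand_grid_centers <- function(origin, spacing, dims) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  cbind(
    rep(xs, times = dims[2] * dims[3]),
    rep(rep(ys, each = dims[1]), times = dims[3]),
    rep(zs, each = dims[1] * dims[2])
  )
}
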