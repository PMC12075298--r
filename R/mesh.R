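#' Triangulated surface mesh
#'
#' Lightweight container for a triangle mesh in world coordinates (mm):
#' an `n x 3` vertex matrix, an `m x 3` face matrix of 1-based vertex
#' indices, and optional per-vertex scalars (e.g. distances in mm).
#' Zero-area faces are dropped at construction.
#'
#' @param vertices numeric matrix (`n x 3`), vertex coordinates in mm.
#' @param faces integer matrix (`m x 3`), 1-based vertex indices.
#' @param vertex_scalars optional numeric vector of length `n`.
#' @return A `tri_mesh` object.
#' @export
tri_mesh <- function(vertices, faces, vertex_scalars = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) abort("`vertices` must have 3 columns (x, y, z in mm).")
  if (ncol(faces) != 3L) abort("`faces` must have 3 columns of vertex indices.")
  if (nrow(vertices) == 0L || nrow(faces) == 0L) {
    abort("Mesh is empty: at least one vertex and one face are required.")
  }
  if (any(!is.finite(vertices))) abort("Non-finite vertex coordinates.")
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    abort("Face indices out of range for the vertex set.")
  }
  area <- triangle_areas(vertices, faces)
  if (any(area == 0)) faces <- faces[area > 0, , drop = FALSE]
  if (nrow(faces) == 0L) abort("All faces are degenerate (zero area).")
  if (!is.null(vertex_scalars)) {
    vertex_scalars <- as.numeric(vertex_scalars)
    if (length(vertex_scalars) != nrow(vertices)) {
      abort("`vertex_scalars` must have one value per vertex.")
    }
  }
  structure(
    list(vertices = vertices, faces = faces, vertex_scalars = vertex_scalars),
    class = "tri_mesh"
  )
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf(
    "<tri_mesh> %d vertices, %d faces%s%s\n",
    nrow(x$vertices), nrow(x$faces),
    if (is_watertight(x)) ", watertight" else
      sprintf(", %d boundary edges", n_boundary_edges(x)),
    if (!is.null(x$vertex_scalars)) ", with vertex scalars" else ""
  ))
  invisible(x)
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Mesh surface area and enclosed volume
#'
#' `mesh_area()` sums triangle areas (mm^2). `mesh_volume()` returns the
#' enclosed volume (mm^3) by the divergence theorem; it is meaningful for
#' closed, consistently oriented surfaces and is returned as an absolute
#' value.
#'
#' @param mesh a [tri_mesh()].
#' @return A scalar, mm^2 or mm^3.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh$vertices, mesh$faces))

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(det6)) / 6
}

mesh_edge_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

n_boundary_edges <- function(mesh) sum(mesh_edge_table(mesh) == 1L)

#' Is a mesh watertight?
#'
#' A mesh is considered watertight when every edge is shared by exactly two
#' faces (no boundary edges, no non-manifold fins).
#'
#' @param mesh a [tri_mesh()].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) all(mesh_edge_table(mesh) == 2L)

#' Merge coincident vertices
#'
#' Groups vertices whose coordinates agree within `tol` (mm) on every axis
#' and rewires faces; faces that collapse are dropped. STL files store each
#' facet's corners independently, so this runs on every STL load.
#'
#' @param mesh a [tri_mesh()].
#' @param tol merge tolerance in mm.
#' @return A `tri_mesh` with unique vertices.
#' @export
merge_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  grp <- match(key, unique(key))
  keep <- !duplicated(grp)
  vnew <- v[keep, , drop = FALSE]
  fnew <- matrix(grp[mesh$faces], ncol = 3)
  ok <- fnew[, 1] != fnew[, 2] & fnew[, 2] != fnew[, 3] & fnew[, 1] != fnew[, 3]
  tri_mesh(vnew, fnew[ok, , drop = FALSE],
           vertex_scalars = if (!is.null(mesh$vertex_scalars)) mesh$vertex_scalars[keep])
}

#' Translate a mesh
#'
#' @param mesh a [tri_mesh()].
#' @param offset length-3 numeric, mm.
#' @return The translated mesh.
#' @export
translate_mesh <- function(mesh, offset) {
  stopifnot(length(offset) == 3L, all(is.finite(offset)))
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(offset), "+")
  mesh
}

# ---------------------------------------------------------------------------
# STL / PLY input-output
# ---------------------------------------------------------------------------

#' Read a surface mesh from STL or PLY
#'
#' Reads binary or ASCII STL and ASCII PLY. Duplicate vertices are merged
#' with a 1e-6 mm tolerance; coordinates are taken to be millimetres.
#' PLY files may carry one extra per-vertex property (beyond x, y, z),
#' which is returned as `vertex_scalars`.
#'
#' @param path file path ending in `.stl` or `.ply`.
#' @return A [tri_mesh()].
#' @export
load_mesh <- function(path) {
  if (!file.exists(path)) abort(paste0("Mesh file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    abort(paste0("Unsupported mesh format '.", ext, "' (expected STL or PLY)."))
  )
  merge_vertices(mesh, tol = 1e-6)
}

#' Write a surface mesh to STL or PLY
#'
#' STL is written binary (set `ascii = TRUE` for ASCII STL). Per-vertex
#' scalars require PLY, where they are stored as a `distance_mm` property.
#'
#' @param mesh a [tri_mesh()].
#' @param path output path, `.stl` or `.ply`.
#' @param with_scalars write `mesh$vertex_scalars` alongside coordinates
#'   (PLY only).
#' @param ascii write ASCII STL instead of binary.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, with_scalars = FALSE, ascii = FALSE) {
  if (!inherits(mesh, "tri_mesh")) abort("`mesh` must be a tri_mesh.")
  ext <- tolower(tools::file_ext(path))
  if (with_scalars) {
    if (ext != "ply") abort("Per-vertex scalars require PLY; STL cannot carry them.")
    if (is.null(mesh$vertex_scalars)) abort("Mesh has no vertex scalars to write.")
  }
  switch(ext,
    stl = if (ascii) write_stl_ascii(mesh, path) else write_stl_binary(mesh, path),
    ply = write_ply(mesh, path, with_scalars = with_scalars),
    abort(paste0("Unsupported mesh format '.", ext, "' (expected STL or PLY)."))
  )
  invisible(path)
}

read_stl <- function(path) {
  n <- file.size(path)
  head_raw <- readBin(path, "raw", n = min(n, 512))
  printable <- head_raw >= as.raw(0x09) & head_raw <= as.raw(0x7e)
  is_ascii <- all(printable)
  if (is_ascii) {
    head_txt <- rawToChar(head_raw)
    is_ascii <- grepl("^\\s*solid", head_txt) && grepl("facet", head_txt)
  }
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L) {
    abort("Malformed ASCII STL: vertex count is not a multiple of three.")
  }
  nums <- vapply(
    strsplit(trimws(vlines), "\\s+"),
    function(x) as.numeric(x[2:4]),
    numeric(3)
  )
  v <- t(nums)
  if (any(!is.finite(v))) abort("Malformed ASCII STL: non-numeric vertex coordinates.")
  f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  tri_mesh(v, f)
}

read_stl_binary <- function(path) {
  sz <- file.size(path)
  if (sz < 84) abort("Malformed binary STL: file shorter than its header.")
  raw <- readBin(path, "raw", n = sz)
  nf <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  if (nf <= 0 || sz < 84 + 50 * nf) abort("Malformed binary STL: facet count disagrees with file size.")
  body <- matrix(raw[85:(84 + 50 * nf)], nrow = 50)
  floats <- readBin(as.raw(body[1:48, ]), "numeric", size = 4, n = 12L * nf,
                    endian = "little")
  per <- matrix(floats, nrow = 12)  # normal xyz, then three vertices
  v <- matrix(as.vector(per[4:12, ]), ncol = 3, byrow = TRUE)
  f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  tri_mesh(v, f)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  nrm <- face_normals(mesh)
  block <- t(cbind(
    nrm,
    v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE], v[f[, 3], , drop = FALSE]
  ))
  fl <- writeBin(as.vector(block), raw(), size = 4, endian = "little")
  flm <- matrix(fl, nrow = 48)
  out <- rbind(flm, matrix(as.raw(0), nrow = 2, ncol = ncol(flm)))
  writeBin(as.vector(out), con)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- face_normals(mesh)
  tri <- function(i) {
    c(
      sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g",
              v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
      "    endloop",
      "  endfacet"
    )
  }
  writeLines(
    c("solid vesselphantom", unlist(lapply(seq_len(nrow(f)), tri)), "endsolid vesselphantom"),
    path
  )
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) abort("Malformed PLY: no end_header.")
  hdr <- trimws(lines[seq_len(end)])
  if (!identical(hdr[1], "ply")) abort("Malformed PLY: missing magic line.")
  if (!any(grepl("^format ascii", hdr))) abort("Only ASCII PLY is supported.")
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", hdr, value = TRUE)))
  if (length(nv) != 1L || length(nf) != 1L) abort("Malformed PLY header.")
  vtx_start <- grep("^element vertex", hdr)[1]
  face_decl <- grep("^element face", hdr)[1]
  vprops <- grep("^property ", hdr[(vtx_start + 1):(face_decl - 1)], value = TRUE)
  nprop <- length(vprops)
  body <- lines[(end + 1):length(lines)]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  vm <- t(vapply(vrows, function(x) as.numeric(x[seq_len(nprop)]), numeric(nprop)))
  scal <- if (nprop >= 4L) vm[, 4] else NULL
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  fm <- t(vapply(frows, function(x) as.integer(x[2:4]), integer(3))) + 1L
  tri_mesh(vm[, 1:3, drop = FALSE], fm, vertex_scalars = scal)
}

write_ply <- function(mesh, path, with_scalars = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  hdr <- c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    if (with_scalars) "property double distance_mm",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  vtx <- if (with_scalars) {
    sprintf("%.9g %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3], mesh$vertex_scalars)
  } else {
    sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  }
  writeLines(c(hdr, vtx, sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])), path)
}
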