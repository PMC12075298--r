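#' Vessel segment vocabulary and per-segment resampling counts
#'
#' `vessel_segments()` lists the closed label vocabulary for aortoiliac
#' center lumen lines. `segment_counts()` gives the number of equally spaced
#' resampling points per segment, set by typical segment length: 200 for the
#' aorta, 100 for the common iliac arteries, 150 for the external iliacs and
#' 75 for the internal iliacs and renals.
#'
#' @param ... named overrides, e.g. `segment_counts(aorta = 300)`.
#' @return A character vector of labels, or a named integer vector of counts.
#' @export
vessel_segments <- function() {
  c(
    "aorta",
    "common_iliac_L", "common_iliac_R",
    "external_iliac_L", "external_iliac_R",
    "internal_iliac_L", "internal_iliac_R",
    "renal_L", "renal_R"
  )
}

#' @rdname vessel_segments
#' @export
segment_counts <- function(...) {
  counts <- c(
    aorta = 200L,
    common_iliac_L = 100L, common_iliac_R = 100L,
    external_iliac_L = 150L, external_iliac_R = 150L,
    internal_iliac_L = 75L, internal_iliac_R = 75L,
    renal_L = 75L, renal_R = 75L
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) over <- over[[1]]
  for (nm in names(over)) {
    if (!nm %in% names(counts)) abort(paste0("Unknown vessel segment: ", nm))
    counts[nm] <- as.integer(over[[nm]])
  }
  if (any(counts < 2L)) abort("Segment counts must be at least 2.")
  counts
}

#' Validate a centerline table
#'
#' A centerline table holds one or more labeled center lumen lines in long
#' form: columns `label`, `point_index`, `x`, `y`, `z` (mm), ordered
#' proximal to distal within each label.
#'
#' @param cll a data frame of centerline points.
#' @return The validated tibble, arranged by label and point index.
#' @export
validate_centerlines <- function(cll) {
  need <- c("label", "point_index", "x", "y", "z")
  missing_cols <- setdiff(need, names(cll))
  if (length(missing_cols) > 0) {
    abort(paste0("Centerline table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(cll$label), vessel_segments())
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown vessel segment label(s): ", paste(bad, collapse = ", "),
      ". Valid labels: ", paste(vessel_segments(), collapse = ", ")
    ))
  }
  cll <- dplyr::arrange(as_tibble(cll), .data$label, .data$point_index)
  for (d in split(cll, cll$label)) {
    if (nrow(d) < 2L) abort(paste0("Segment '", d$label[1], "' has fewer than 2 points."))
    if (any(diff(d$point_index) <= 0)) {
      abort(paste0("Non-monotone point_index in segment '", d$label[1], "'."))
    }
    step <- sqrt(diff(d$x)^2 + diff(d$y)^2 + diff(d$z)^2)
    if (any(step == 0)) {
      abort(paste0("Coincident consecutive points in segment '", d$label[1], "'."))
    }
  }
  dplyr::select(cll, dplyr::all_of(need))
}

#' Read / write centerlines as CSV
#'
#' The interchange format is a CSV with columns `label`, `point_index`,
#' `x`, `y`, `z` in mm, one row per centerline point.
#'
#' @param path CSV file path.
#' @param cll a centerline tibble.
#' @return `load_centerlines()` returns a validated tibble;
#'   `save_centerlines()` returns `path` invisibly.
#' @export
load_centerlines <- function(path) {
  if (!file.exists(path)) abort(paste0("Centerline file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_centerlines(df)
}

#' @rdname load_centerlines
#' @export
save_centerlines <- function(cll, path) {
  readr::write_csv(validate_centerlines(cll), path)
  invisible(path)
}

#' Resample centerlines at equal arc-length spacing
#'
#' Each labeled polyline is resampled to a fixed number of points placed at
#' equal arc length along the chordal polyline (linear interpolation between
#' input points); the first and last points are preserved exactly. This
#' normalizes anatomy-length differences between patients so point indices
#' correspond across a cohort.
#'
#' @param cll a centerline tibble (see [validate_centerlines()]).
#' @param n either a single point count applied to every segment, or a named
#'   vector/list mapping labels to counts; defaults to [segment_counts()].
#' @return A tibble with columns `label`, `point_index` (1-based), `x`, `y`,
#'   `z`, and `arc_step` (the constant spacing in mm for that segment).
#' @export
resample_equal_arclength <- function(cll, n = segment_counts()) {
  cll <- validate_centerlines(cll)
  resample_one <- function(d, label) {
    nk <- if (length(n) == 1L && is.null(names(n))) as.integer(n) else {
      if (!label %in% names(n)) abort(paste0("No resampling count given for segment '", label, "'."))
      as.integer(n[[label]])
    }
    if (nk < 2L) abort("Resampling count must be at least 2.")
    p <- cbind(d$x, d$y, d$z)
    if (sum(sqrt(rowSums(diff(p)^2))) <= 0) {
      abort(paste0("Zero-length polyline in segment '", label, "'."))
    }
    pass <- function(p) {
      s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
      len <- s[length(s)]
      targets <- seq(0, len, length.out = nk)
      out <- vapply(1:3, function(ax) approx(s, p[, ax], xout = targets, ties = "ordered")$y,
                    numeric(nk))
      out[1, ] <- p[1, ]
      out[nk, ] <- p[nrow(p), ]
      out
    }
    # iterate to the equal-chord fixed point so resampling is idempotent:
    # one pass places points at equal arc length of the *input* polyline,
    # whose chords are not yet exactly uniform where it curves
    out <- pass(p)
    for (it in seq_len(20L)) {
      nxt <- pass(out)
      delta <- max(abs(nxt - out))
      out <- nxt
      if (delta < 1e-12) break
    }
    steps <- sqrt(rowSums(diff(out)^2))
    tibble(
      point_index = seq_len(nk),
      x = out[, 1], y = out[, 2], z = out[, 3],
      arc_step = sum(steps) / (nk - 1)
    )
  }
  cll |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(~ resample_one(.x, .y$label)) |>
    dplyr::ungroup() |>
    dplyr::select("label", "point_index", "x", "y", "z", "arc_step")
}

#' Unit tangent vectors along an ordered polyline
#'
#' Central differences at interior points, one-sided differences at the two
#' ends, normalized to unit length.
#'
#' @param points an `n x 3` matrix of ordered coordinates (mm), `n >= 2`.
#' @return An `n x 3` matrix of unit tangents.
#' @export
tangents <- function(points) {
  points <- as.matrix(points)
  np <- nrow(points)
  if (np < 2L) abort("Need at least 2 points for tangents.")
  if (any(rowSums(diff(points)^2) == 0)) abort("Coincident neighboring points.")
  i_prev <- c(1L, seq_len(np - 1L))
  i_next <- c(seq_len(np - 1L) + 1L, np)
  t_ <- points[i_next, , drop = FALSE] - points[i_prev, , drop = FALSE]
  t_ / sqrt(rowSums(t_^2))
}

#' Add tangent columns to a resampled centerline table
#'
#' @param cll a (resampled) centerline tibble.
#' @return The tibble with unit tangent columns `tx`, `ty`, `tz`.
#' @export
add_tangents <- function(cll) {
  cll |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(function(d, key) {
      tg <- tangents(cbind(d$x, d$y, d$z))
      dplyr::mutate(d, tx = tg[, 1], ty = tg[, 2], tz = tg[, 3])
    }) |>
    dplyr::ungroup()
}

#' Locate the aortic bifurcation landmark
#'
#' Returns the distal endpoint of the aorta centerline. If both common iliac
#' proximal endpoints lie more than 5 mm from it, the centroid of the three
#' endpoints is returned instead, with a warning (the exported centerlines
#' then disagree about where the vessels meet).
#'
#' @param cll a centerline tibble containing `aorta`, `common_iliac_L` and
#'   `common_iliac_R` segments.
#' @return A length-3 numeric point (mm).
#' @export
detect_bifurcation_point <- function(cll) {
  cll <- validate_centerlines(cll)
  need <- c("aorta", "common_iliac_L", "common_iliac_R")
  missing_seg <- setdiff(need, unique(cll$label))
  if (length(missing_seg) > 0) {
    abort(paste0("Missing segment(s) for bifurcation detection: ",
                 paste(missing_seg, collapse = ", ")))
  }
  seg_end <- function(lab, first) {
    d <- dplyr::filter(cll, .data$label == lab)
    r <- if (first) d[1, ] else d[nrow(d), ]
    c(r$x, r$y, r$z)
  }
  distal <- seg_end("aorta", first = FALSE)
  prox_l <- seg_end("common_iliac_L", first = TRUE)
  prox_r <- seg_end("common_iliac_R", first = TRUE)
  dl <- sqrt(sum((prox_l - distal)^2))
  dr <- sqrt(sum((prox_r - distal)^2))
  if (dl > 5 && dr > 5) {
    warn(sprintf(
      "Common iliac origins are %.1f and %.1f mm from the aorta end; using the centroid of the three endpoints as the bifurcation landmark.",
      dl, dr
    ))
    return((distal + prox_l + prox_r) / 3)
  }
  distal
}

#' Translate geometry to a landmark
#'
#' Applies the rigid translation by `-landmark` so the landmark moves to the
#' origin. Works on centerline tables, meshes, binary volumes (origin shift,
#' no resampling) and plain coordinate matrices.
#'
#' @param x geometry: centerline tibble, [tri_mesh()], [binary_volume()], or
#'   an `n x 3` matrix.
#' @param landmark finite length-3 point (mm).
#' @return `x` translated.
#' @export
translate_to_landmark <- function(x, landmark) {
  if (length(landmark) != 3L || any(!is.finite(as.numeric(landmark)))) {
    abort("`landmark` must be a finite 3D point.")
  }
  UseMethod("translate_to_landmark")
}

#' @export
translate_to_landmark.data.frame <- function(x, landmark) {
  landmark <- as.numeric(landmark)
  dplyr::mutate(
    as_tibble(x),
    x = .data$x - landmark[1], y = .data$y - landmark[2], z = .data$z - landmark[3]
  )
}

#' @export
translate_to_landmark.tri_mesh <- function(x, landmark) translate_mesh(x, -landmark)

#' @export
translate_to_landmark.binary_volume <- function(x, landmark) translate_volume(x, -landmark)

#' @export
translate_to_landmark.matrix <- function(x, landmark) {
  sweep(x, 2, as.numeric(landmark), "-")
}
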