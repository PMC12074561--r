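#' Centerline paths and the sectional curvature kernel
#'
#' A `centerline_path` is an ordered polyline of 3D points (millimetres, LPS
#' patient frame) with per-point cumulative arc length. It is the substrate
#' on which all stent geometry parameters are measured: along-path
#' distances, chord directions, angles between chords, and the maximum
#' sectional curvature of the stented segment.
#'
#' @name curvepath
NULL

as_points_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- as.matrix(points)
  if (ncol(points) != 3L) {
    stop_tips3d("tips3d_bad_input", "points must be an n x 3 matrix of x, y, z (mm)")
  }
  if (!all(is.finite(points))) {
    stop_tips3d("tips3d_bad_input", "points must be finite")
  }
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  points
}

#' Construct a centerline path from ordered points
#'
#' @param points an n x 3 matrix (or data frame with columns x, y, z) of
#'   ordered 3D points in millimetres.
#' @param spacing_mm nominal station spacing the points were sampled at.
#' @param validate check the path invariants (at least two points, strictly
#'   increasing arc length, near-uniform steps).
#' @return an object of class `centerline_path` with elements `points`,
#'   `spacing_mm` and `cumlen_mm`.
#' @seealso [resample_path()] which builds a uniformly spaced path from an
#'   arbitrary polyline.
#' @export
centerline_path <- function(points, spacing_mm, validate = TRUE) {
  points <- as_points_matrix(points)
  steps <- sqrt(rowSums((points[-1, , drop = FALSE] -
                           points[-nrow(points), , drop = FALSE])^2))
  path <- structure(
    list(points = points, spacing_mm = as.numeric(spacing_mm),
         cumlen_mm = c(0, cumsum(steps))),
    class = "centerline_path"
  )
  if (validate) validate_centerline_path(path)
  path
}

validate_centerline_path <- function(path) {
  n <- nrow(path$points)
  if (n < 2L) stop_tips3d("tips3d_degenerate_path", "a path needs at least 2 points")
  steps <- diff(path$cumlen_mm)
  if (any(steps <= 0)) {
    stop_tips3d("tips3d_degenerate_path",
                "cumulative arc length must be strictly increasing (no repeated points)")
  }
  sp <- path$spacing_mm
  if (!is.finite(sp) || sp <= 0) {
    stop_tips3d("tips3d_bad_input", "spacing_mm must be a positive length")
  }
  interior <- steps[-length(steps)]
  if (length(interior) && any(abs(interior - sp) > 0.5 * sp + 1e-9)) {
    stop_tips3d("tips3d_bad_input",
                "interior steps must lie within half the nominal spacing")
  }
  invisible(path)
}

#' @export
print.centerline_path <- function(x, ...) {
  cat(sprintf("<centerline_path> %d points, %.2f mm long, %.2g mm spacing\n",
              nrow(x$points), path_length(x), x$spacing_mm))
  invisible(x)
}

#' Total arc length of a path (mm)
#' @param path a `centerline_path`.
#' @export
path_length <- function(path) {
  path$cumlen_mm[length(path$cumlen_mm)]
}

#' Resample a polyline at uniform arc-length steps
#'
#' Linearly interpolates an ordered polyline at (near-)uniform arc-length
#' stations. The first and last input points are preserved and the total
#' arc length is preserved to well within 1%. No smoothing is applied unless
#' `smooth_mm > 0`, because smoothing changes curvature and must therefore
#' be an explicit choice.
#'
#' @param raw_points ordered 3D points (n x 3 matrix or data frame).
#' @param spacing_mm target station spacing in mm (default 1).
#' @param smooth_mm optional moving-average window (mm) applied to the
#'   resampled stations; endpoints are kept fixed. 0 disables smoothing.
#' @return a [centerline_path()].
#' @export
resample_path <- function(raw_points, spacing_mm = 1, smooth_mm = 0) {
  pts <- as_points_matrix(raw_points)
  if (spacing_mm <= 0) stop_tips3d("tips3d_bad_input", "spacing_mm must be > 0")
  # drop consecutive duplicates
  if (nrow(pts) > 1) {
    keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                               pts[-nrow(pts), , drop = FALSE])^2) > 0)
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 2L) {
    stop_tips3d("tips3d_degenerate_path", "all input points coincide")
  }
  cum <- c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                                     pts[-nrow(pts), , drop = FALSE])^2))))
  total <- cum[length(cum)]
  n_out <- max(2L, as.integer(round(total / spacing_mm)) + 1L)
  s_out <- seq(0, total, length.out = n_out)
  out <- vapply(1:3, function(j) approx(cum, pts[, j], xout = s_out)$y,
                numeric(n_out))
  colnames(out) <- c("x", "y", "z")
  if (smooth_mm > 0) out <- smooth_points(out, smooth_mm, total / (n_out - 1))
  # nominal spacing from the realized chord steps: on a curved polyline the
  # chord between successive arc-length stations is slightly shorter than
  # the arc step
  path <- centerline_path(out, spacing_mm = 1, validate = FALSE)
  path$spacing_mm <- mean(diff(path$cumlen_mm))
  validate_centerline_path(path)
  path
}

# centered moving average with fixed endpoints; window in mm converted to an
# odd station count
smooth_points <- function(points, window_mm, step_mm) {
  k <- max(1L, as.integer(round(window_mm / step_mm)))
  if (k %% 2L == 0L) k <- k + 1L
  if (k < 3L || nrow(points) < k + 2L) return(points)
  half <- (k - 1L) %/% 2L
  n <- nrow(points)
  out <- points
  kernel <- rep(1 / k, k)
  for (j in 1:3) {
    sm <- stats::filter(points[, j], kernel, sides = 2)
    idx <- (half + 1L):(n - half)
    out[idx, j] <- sm[idx]
  }
  out[1, ] <- points[1, ]
  out[n, ] <- points[n, ]
  out
}

check_on_path <- function(path, s, what = "arc position") {
  total <- path_length(path)
  bad <- !is.finite(s) | s < -1e-9 | s > total + 1e-9
  if (any(bad)) {
    stop_tips3d("tips3d_out_of_range",
                sprintf("%s %.3f mm outside [0, %.3f]", what, s[bad][1], total))
  }
  pmin(pmax(s, 0), total)
}

#' Interpolate points on a path at given arc-length positions
#'
#' @param path a `centerline_path`.
#' @param s_mm arc-length positions (vectorised), 0 at the path origin.
#' @return an n x 3 matrix of points.
#' @export
point_at <- function(path, s_mm) {
  s_mm <- check_on_path(path, s_mm)
  out <- vapply(1:3, function(j) {
    approx(path$cumlen_mm, path$points[, j], xout = s_mm)$y
  }, numeric(length(s_mm)))
  if (length(s_mm) == 1L) out <- matrix(out, nrow = 1)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Along-path distance between two arc positions
#'
#' @param path a `centerline_path`.
#' @param s_a_mm,s_b_mm arc-length positions in mm within the path.
#' @return distance in mm measured along the path.
#' @export
arc_distance <- function(path, s_a_mm, s_b_mm) {
  s_a_mm <- check_on_path(path, s_a_mm)
  s_b_mm <- check_on_path(path, s_b_mm)
  abs(s_b_mm - s_a_mm)
}

#' Unit direction of a chord on a path
#'
#' A section's direction is its chord: the unit vector from the chord's
#' start point to its end point. `forward` uses the chord `[s, s + chord]`,
#' `backward` uses `[s - chord, s]` (still oriented start to end, i.e. in
#' the direction of increasing arc length).
#'
#' @param path a `centerline_path`.
#' @param s_mm chord anchor arc position (mm).
#' @param chord_mm chord length (mm).
#' @param orientation `"forward"` or `"backward"`.
#' @return a unit 3-vector.
#' @export
chord_direction <- function(path, s_mm, chord_mm,
                            orientation = c("forward", "backward")) {
  orientation <- match.arg(orientation)
  ends <- if (orientation == "forward") c(s_mm, s_mm + chord_mm)
          else c(s_mm - chord_mm, s_mm)
  total <- path_length(path)
  if (ends[1] < -1e-9 || ends[2] > total + 1e-9) {
    stop_tips3d("tips3d_out_of_range",
                sprintf("chord [%.2f, %.2f] exceeds path extent [0, %.2f]",
                        ends[1], ends[2], total))
  }
  p <- point_at(path, ends)
  v <- p[2, ] - p[1, ]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop_tips3d("tips3d_degenerate_vector", "zero-length chord")
  v / nv
}

#' Angle between two 3-vectors in degrees
#'
#' @param u,v non-zero 3-vectors (need not be unit length).
#' @return angle in degrees in \[0, 180\].
#' @export
angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) {
    stop_tips3d("tips3d_degenerate_vector", "angle of a zero vector is undefined")
  }
  acos(pmin(1, pmax(-1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Sectional curvature parameters
#'
#' Geometry of the curvature metric: two chords of `chord_mm` separated by a
#' gap of `gap_mm`. Defaults follow the measurement convention of 1 cm
#' chords ("angle measurements over 1 cm") separated by 5 mm gaps.
#'
#' @param gap_mm gap between the two chords (end of first to start of
#'   second), mm. Default 5.
#' @param chord_mm chord length per section, mm. Default 10.
#' @export
curvature_params <- function(gap_mm = 5, chord_mm = 10) {
  if (gap_mm <= 0 || chord_mm <= 0) {
    stop_tips3d("tips3d_bad_input", "gap_mm and chord_mm must be > 0")
  }
  structure(list(gap_mm = gap_mm, chord_mm = chord_mm),
            class = "curvature_params")
}

#' Arc-length interval on a path
#'
#' @param s_start_mm,s_end_mm interval bounds in mm with
#'   `0 <= s_start < s_end`.
#' @export
arc_interval <- function(s_start_mm, s_end_mm) {
  if (!is.finite(s_start_mm) || !is.finite(s_end_mm) ||
      s_start_mm < 0 || s_end_mm <= s_start_mm) {
    stop_tips3d("tips3d_bad_input", "need 0 <= s_start < s_end")
  }
  structure(list(s_start_mm = s_start_mm, s_end_mm = s_end_mm),
            class = "arc_interval")
}

#' Maximum sectional curvature of a stented path segment
#'
#' Slides a station `s` over the stent interval; at each station the
#' direction change between the chord over `[s, s + chord]` and the chord
#' over `[s + chord + gap, s + 2 chord + gap]` is evaluated, and the maximum
#' over all admissible stations is returned. A straight path scores 0; a
#' single localized planar bend whose curved part falls entirely between one
#' chord pair scores the full bend angle (the printed worked examples: 0 for
#' straight, 90 for a 90 degree bend).
#'
#' @param path a `centerline_path`.
#' @param stent an [arc_interval()]: the stent's extent on the path.
#' @param params a [curvature_params()].
#' @param station_step_mm maximisation grid step, mm (default 0.5; at most
#'   a tenth of the gap so the discrete maximum tracks the continuous one).
#' @return the maximum angle in degrees, with attributes `station_mm` (first
#'   station attaining the maximum) and `n_stations`.
#' @export
max_section_curvature <- function(path, stent, params = curvature_params(),
                                  station_step_mm = 0.5) {
  stopifnot(inherits(stent, "arc_interval"))
  window <- 2 * params$chord_mm + params$gap_mm
  total <- path_length(path)
  s0 <- max(0, stent$s_start_mm)
  s1 <- min(total, stent$s_end_mm)
  if (s1 - s0 < window - 1e-9) {
    stop_tips3d("tips3d_insufficient_length",
                sprintf("stent interval %.1f mm shorter than one chord pair (%.1f mm)",
                        s1 - s0, window))
  }
  s_max <- s1 - window
  stations <- unique(c(seq(s0, s_max, by = station_step_mm), s_max))
  c_mm <- params$chord_mm; g_mm <- params$gap_mm
  a0 <- point_at(path, stations)
  a1 <- point_at(path, stations + c_mm)
  b0 <- point_at(path, stations + c_mm + g_mm)
  b1 <- point_at(path, stations + 2 * c_mm + g_mm)
  d1 <- a1 - a0
  d2 <- b1 - b0
  n1 <- sqrt(rowSums(d1^2)); n2 <- sqrt(rowSums(d2^2))
  ok <- n1 > 1e-12 & n2 > 1e-12
  cosang <- rowSums(d1 * d2) / (n1 * n2)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ang[!ok] <- NA_real_
  i <- which.max(ang)
  structure(ang[i], station_mm = stations[i], n_stations = length(stations))
}

#' Serialize a centerline path to JSON
#'
#' Points are written as `[x, y, z]` mm triples together with the nominal
#' spacing and cumulative arc lengths, so paths round-trip exactly enough
#' for downstream measurement (all lengths mm).
#'
#' @param path a `centerline_path`.
#' @param file optional file to write to; if `NULL` the JSON string is
#'   returned.
#' @export
path_to_json <- function(path, file = NULL) {
  obj <- list(points = unname(split(path$points, row(path$points)[, 1])),
              spacing_mm = path$spacing_mm,
              cumlen_mm = path$cumlen_mm)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}

#' Read a centerline path from JSON
#' @param x a JSON string or path to a JSON file written by [path_to_json()].
#' @export
path_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  pts <- obj$points
  if (is.list(pts)) pts <- do.call(rbind, pts)
  pts <- matrix(as.numeric(pts), ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  centerline_path(pts, spacing_mm = obj$spacing_mm, validate = FALSE)
}

#' Tidy a centerline path into a tibble of stations
#'
#' @param x a `centerline_path`.
#' @param ... unused.
#' @return a tibble with columns `s_mm`, `x`, `y`, `z`.
#' @method tidy centerline_path
#' @export
tidy.centerline_path <- function(x, ...) {
  pts <- x$points
  tibble::tibble(s_mm = x$cumlen_mm,
                 x = pts[, "x"], y = pts[, "y"], z = pts[, "z"])
}
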