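#' Path landmarks
#'
#' Arc-length positions (mm) of the six landmarks that delimit every
#' distance and angle: the path origin at the portal venous confluence, the
#' beginning of the uncovered distal stent end, the two covered stent ends,
#' the cranial stent end, and the IVC junction at the path terminus.
#'
#' @param uncovered_distal_begin,covered_distal_begin,covered_cranial_end,stent_cranial_end
#'   arc-length positions in mm; must be non-decreasing in that order.
#' @param ivc_junction total path length (mm).
#' @param confluence_start always 0 (path origin).
#' @export
path_landmarks <- function(uncovered_distal_begin, covered_distal_begin,
                           covered_cranial_end,
                           stent_cranial_end = covered_cranial_end,
                           ivc_junction, confluence_start = 0) {
  lm <- list(confluence_start = confluence_start,
             uncovered_distal_begin = uncovered_distal_begin,
             covered_distal_begin = covered_distal_begin,
             covered_cranial_end = covered_cranial_end,
             stent_cranial_end = stent_cranial_end,
             ivc_junction = ivc_junction)
  vals <- unlist(lm)
  if (confluence_start != 0 || any(!is.finite(vals)) || any(diff(vals) < -1e-6)) {
    stop_tips3d("tips3d_invalid_landmarks",
                "landmarks must be finite and non-decreasing from 0")
  }
  structure(lm, class = "path_landmarks")
}

# clamp an arc position to the path (check_landmarks has already verified
# agreement within its tolerance; sub-mm chord-length bookkeeping must not
# push a landmark past the terminus)
lm_pos <- function(path, s) min(max(s, 0), path_length(path))

check_landmarks <- function(path, lm, tol_mm = 1) {
  if (!inherits(lm, "path_landmarks")) {
    stop_tips3d("tips3d_invalid_landmarks", "not a path_landmarks object")
  }
  total <- path_length(path)
  if (abs(lm$ivc_junction - total) > tol_mm) {
    stop_tips3d("tips3d_invalid_landmarks",
                sprintf("ivc_junction (%.2f) must equal the path length (%.2f)",
                        lm$ivc_junction, total))
  }
  invisible(lm)
}

#' Snap 3D landmark points onto a path
#'
#' Accepts landmarks given as 3D points (e.g. clicked in a viewer) and
#' converts each to the arc-length position of the nearest point on the
#' path (nearest station, refined by projection onto the adjacent
#' segments).
#'
#' @param path a [centerline_path()].
#' @param points named list of 3-vectors (LPS mm); names are the landmark
#'   fields of [path_landmarks()] except `confluence_start` and
#'   `ivc_junction`, which are pinned to the path ends.
#' @return a [path_landmarks()].
#' @export
snap_landmarks <- function(path, points) {
  snap1 <- function(p) {
    d2 <- rowSums(sweep(path$points, 2, p, `-`)^2)
    i <- which.min(d2)
    best_s <- path$cumlen_mm[i]
    best_d <- d2[i]
    # refine by projecting onto the two segments adjacent to the station
    for (j in c(i - 1L, i)) {
      if (j < 1L || j >= nrow(path$points)) next
      a <- path$points[j, ]; b <- path$points[j + 1L, ]
      ab <- b - a
      t <- min(max(sum((p - a) * ab) / sum(ab^2), 0), 1)
      dd <- sum((p - (a + t * ab))^2)
      if (dd < best_d) {
        best_d <- dd
        best_s <- path$cumlen_mm[j] +
          t * (path$cumlen_mm[j + 1L] - path$cumlen_mm[j])
      }
    }
    best_s
  }
  total <- path_length(path)
  path_landmarks(
    uncovered_distal_begin = snap1(as.numeric(points$uncovered_distal_begin)),
    covered_distal_begin = snap1(as.numeric(points$covered_distal_begin)),
    covered_cranial_end = snap1(as.numeric(points$covered_cranial_end)),
    stent_cranial_end = if (!is.null(points$stent_cranial_end))
      snap1(as.numeric(points$stent_cranial_end))
    else snap1(as.numeric(points$covered_cranial_end)),
    ivc_junction = total
  )
}

#' Read landmarks from JSON
#'
#' Accepts either arc-length positions (`{"arc_mm": {"uncovered_distal_begin":
#' 20, ...}}`) or 3D points (`{"points": {"uncovered_distal_begin": [x,y,z],
#' ...}}`) snapped to the nearest path station.
#'
#' @param path a [centerline_path()] (used for snapping and the terminus).
#' @param file JSON file.
#' @export
read_landmarks <- function(path, file) {
  obj <- jsonlite::fromJSON(file)
  if (!is.null(obj$arc_mm)) {
    a <- obj$arc_mm
    return(path_landmarks(
      uncovered_distal_begin = a$uncovered_distal_begin,
      covered_distal_begin = a$covered_distal_begin,
      covered_cranial_end = a$covered_cranial_end,
      stent_cranial_end = a$stent_cranial_end %||% a$covered_cranial_end,
      ivc_junction = a$ivc_junction %||% path_length(path)))
  }
  if (!is.null(obj$points)) return(snap_landmarks(path, obj$points))
  stop_tips3d("tips3d_bad_input", "landmarks JSON needs 'arc_mm' or 'points'")
}

#' Distance from the cranial stent end to the IVC (mm)
#'
#' Along-path length from the cranial TIPS stent end in the hepatic vein to
#' the IVC junction.
#'
#' @param path a [centerline_path()].
#' @param lm a [path_landmarks()].
#' @export
cranial_end_to_ivc <- function(path, lm) {
  check_landmarks(path, lm)
  arc_distance(path, lm_pos(path, lm$stent_cranial_end),
               lm_pos(path, lm$ivc_junction))
}

#' Length of the covered stent portion (mm)
#'
#' Along-path length from the beginning of the distal covered stent end to
#' the end of the cranial covered stent end.
#'
#' @inheritParams cranial_end_to_ivc
#' @export
covered_length <- function(path, lm) {
  check_landmarks(path, lm)
  arc_distance(path, lm_pos(path, lm$covered_distal_begin),
               lm_pos(path, lm$covered_cranial_end))
}

#' Length from the portal confluence to the stent (mm)
#'
#' Along-path length from the beginning of the path to the beginning of the
#' uncovered distal stent end.
#'
#' @inheritParams cranial_end_to_ivc
#' @export
confluence_to_stent <- function(path, lm) {
  check_landmarks(path, lm)
  arc_distance(path, 0, lm_pos(path, lm$uncovered_distal_begin))
}

#' Angle between the covered stent ends (degrees)
#'
#' Angle between the stent-end axes: the local tangents serve as the
#' straight lines orthogonal to the two covered end planes. Both chords are
#' oriented in the direction of increasing arc length (distal chord
#' `[covered_distal_begin, +chord]`, cranial chord
#' `[covered_cranial_end - chord, covered_cranial_end]`), so a straight
#' stent scores 0 and the angle is the direction change across the covered
#' portion, which can exceed 90 degrees.
#'
#' @inheritParams cranial_end_to_ivc
#' @param chord_mm tangent chord length (default 10 mm, the curvature
#'   section scale).
#' @export
covered_ends_angle <- function(path, lm, chord_mm = 10) {
  check_landmarks(path, lm)
  d1 <- chord_direction(path, lm_pos(path, lm$covered_distal_begin),
                        chord_mm, "forward")
  d2 <- chord_direction(path, lm_pos(path, lm$covered_cranial_end),
                        chord_mm, "backward")
  angle_deg(d1, d2)
}

#' Alpha angle at the stent entry (degrees)
#'
#' Angle between the course of the portal vein just upstream of the covered
#' stent's caudal beginning and the stent's entry direction: the chord
#' `[covered_distal_begin - chord, covered_distal_begin]` against the chord
#' `[covered_distal_begin, covered_distal_begin + chord]`.
#'
#' @inheritParams covered_ends_angle
#' @export
alpha_angle <- function(path, lm, chord_mm = 10) {
  check_landmarks(path, lm)
  up <- chord_direction(path, lm$covered_distal_begin, chord_mm, "backward")
  dn <- chord_direction(path, lm$covered_distal_begin, chord_mm, "forward")
  angle_deg(up, dn)
}

#' Minimal stent diameter (mm)
#'
#' Smallest equivalent-circle diameter over the non-empty section profiles
#' of the stent interval.
#'
#' @param profiles a tibble from [profile_stent()].
#' @export
min_stent_diameter <- function(profiles) {
  ok <- profiles[!profiles$empty, , drop = FALSE]
  if (nrow(ok) == 0L) {
    stop_tips3d("tips3d_no_lumen", "all section profiles are empty")
  }
  min(ok$equiv_diameter_mm)
}

#' Compute the seven 3D TIPS geometry parameters
#'
#' Assembles the full geometry block from a volume, a measurement path and
#' landmarks: cranial-end-to-IVC distance, minimal stent diameter, covered
#' length, maximum sectional curvature (evaluated over the entire stent,
#' uncovered distal portion included), covered-ends angle, alpha angle and
#' confluence-to-stent distance. All distances are along-path arc lengths.
#'
#' @param volume a [label_volume()] (used for the diameter profiles).
#' @param path a [centerline_path()].
#' @param lm a [path_landmarks()].
#' @param params a [curvature_params()].
#' @param chord_mm tangent chord for the two end angles (default 10 mm).
#' @param profile_step_mm station step for the diameter profile (default 1).
#' @param profile_inset_mm margin trimmed from both stent ends before
#'   profiling (default 2 mm): a section plane straddling the stent's end
#'   face cuts a partial cross-section whose area says nothing about the
#'   lumen calibre.
#' @param ... further arguments passed to [profile_stent()].
#' @return a `tips_geometry` object (named list of the seven parameters);
#'   see [tidy.tips_geometry()].
#' @export
compute_all <- function(volume, path, lm, params = curvature_params(),
                        chord_mm = 10, profile_step_mm = 1,
                        profile_inset_mm = 2, ...) {
  check_landmarks(path, lm)
  stent <- arc_interval(lm_pos(path, lm$uncovered_distal_begin),
                        lm_pos(path, lm$stent_cranial_end))
  inset <- min(profile_inset_mm,
               (stent$s_end_mm - stent$s_start_mm) / 4)
  profiles <- profile_stent(
    volume, path,
    arc_interval(stent$s_start_mm + inset, stent$s_end_mm - inset),
    step_mm = profile_step_mm, ...)
  curv <- max_section_curvature(path, stent, params)
  geom <- tips_geometry(
    cranial_end_to_ivc_mm = cranial_end_to_ivc(path, lm),
    min_stent_diameter_mm = min_stent_diameter(profiles),
    covered_length_mm = covered_length(path, lm),
    max_curvature_deg = as.numeric(curv),
    covered_ends_angle_deg = covered_ends_angle(path, lm, chord_mm),
    alpha_angle_deg = alpha_angle(path, lm, chord_mm),
    confluence_to_stent_mm = confluence_to_stent(path, lm)
  )
  attr(geom, "curvature_station_mm") <- attr(curv, "station_mm")
  attr(geom, "profiles") <- profiles
  geom
}

#' The seven-parameter geometry container
#'
#' @param cranial_end_to_ivc_mm,min_stent_diameter_mm,covered_length_mm,max_curvature_deg,covered_ends_angle_deg,alpha_angle_deg,confluence_to_stent_mm
#'   the seven parameters (lengths in mm, angles in degrees).
#' @export
tips_geometry <- function(cranial_end_to_ivc_mm, min_stent_diameter_mm,
                          covered_length_mm, max_curvature_deg,
                          covered_ends_angle_deg, alpha_angle_deg,
                          confluence_to_stent_mm) {
  g <- list(cranial_end_to_ivc_mm = cranial_end_to_ivc_mm,
            min_stent_diameter_mm = min_stent_diameter_mm,
            covered_length_mm = covered_length_mm,
            max_curvature_deg = max_curvature_deg,
            covered_ends_angle_deg = covered_ends_angle_deg,
            alpha_angle_deg = alpha_angle_deg,
            confluence_to_stent_mm = confluence_to_stent_mm)
  lengths <- unlist(g[c(1, 2, 3, 7)])
  angles <- unlist(g[c(4, 5, 6)])
  if (any(!is.finite(unlist(g))) || any(lengths < -1e-9) ||
      any(angles < -1e-9 | angles > 180 + 1e-9)) {
    stop_tips3d("tips3d_bad_input",
                "geometry parameters must be finite, lengths >= 0, angles in [0, 180]")
  }
  structure(g, class = "tips_geometry")
}

#' @export
print.tips_geometry <- function(x, ...) {
  cat("<tips_geometry>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %8.2f\n", nm, x[[nm]]))
  invisible(x)
}

#' Tidy the geometry parameters into a one-row tibble
#'
#' Column names match the per-subject CSV schema.
#'
#' @param x a `tips_geometry`.
#' @param ... unused.
#' @method tidy tips_geometry
#' @export
tidy.tips_geometry <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' Write geometry parameters as JSON
#' @param geom a `tips_geometry`.
#' @param file output file; if `NULL`, the JSON string is returned.
#' @export
geometry_to_json <- function(geom, file = NULL) {
  js <- jsonlite::toJSON(unclass(geom), auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}
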