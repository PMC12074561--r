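#' Parametric stent/vessel phantoms
#'
#' Synthetic curved-tube phantoms rendered into label volumes with analytic
#' ground truth, standing in for post-procedure CT segmentations. The
#' centerline is an exact piecewise line/arc curve (sharp bends are rounded
#' with a small fillet so the tube is renderable; the fillet is kept below
#' the curvature gap so a localized bend still scores its full angle), the
#' tube has a constant radius with an optional waist, and every geometry
#' parameter is computed in closed form on the exact curve.
#'
#' @name phantom
NULL

# ---- exact piecewise line/arc curves ------------------------------------

curve_new <- function(segments) {
  lens <- vapply(segments, function(s) s$len, numeric(1))
  structure(list(segments = segments, cum = c(0, cumsum(lens))),
            class = "phantom_curve")
}

curve_total <- function(curve) curve$cum[length(curve$cum)]

# vectorized evaluation of points and unit tangents at arc positions s
curve_eval <- function(curve, s) {
  s <- pmin(pmax(s, 0), curve_total(curve))
  seg_i <- pmax(1L, findInterval(s, curve$cum, rightmost.closed = TRUE))
  pts <- matrix(0, length(s), 3, dimnames = list(NULL, c("x", "y", "z")))
  tgs <- matrix(0, length(s), 3)
  for (i in unique(seg_i)) {
    seg <- curve$segments[[i]]
    sel <- seg_i == i
    u <- s[sel] - curve$cum[i]
    if (seg$type == "line") {
      pts[sel, ] <- matrix(seg$p0, sum(sel), 3, byrow = TRUE) + u %o% seg$dir
      tgs[sel, ] <- matrix(seg$dir, sum(sel), 3, byrow = TRUE)
    } else {
      a <- seg$a0 + sign(seg$sweep) * u / seg$radius
      pts[sel, ] <- matrix(seg$center, sum(sel), 3, byrow = TRUE) +
        seg$radius * (cos(a) %o% seg$e1 + sin(a) %o% seg$e2)
      tgs[sel, ] <- sign(seg$sweep) * ((-sin(a)) %o% seg$e1 + cos(a) %o% seg$e2)
    }
  }
  list(points = pts, tangents = tgs)
}

# filleted polyline: straight edges joined by circular fillets of radius rf
filleted_polyline <- function(vertices, fillet_mm = 2) {
  nv <- nrow(vertices)
  segs <- list()
  cursor <- vertices[1, ]
  for (i in seq_len(nv - 2L)) {
    a <- vertices[i, ]; b <- vertices[i + 1L, ]; c_ <- vertices[i + 2L, ]
    u <- (b - a) / sqrt(sum((b - a)^2))
    v <- (c_ - b) / sqrt(sum((c_ - b)^2))
    theta <- acos(min(1, max(-1, sum(u * v))))
    if (theta < 1e-9) next
    t <- fillet_mm * tan(theta / 2)
    p_in <- b - t * u
    line_len <- sqrt(sum((p_in - cursor)^2))
    if (line_len > 1e-9) {
      segs[[length(segs) + 1L]] <-
        list(type = "line", p0 = cursor, dir = u, len = line_len)
    }
    ctr <- b + (fillet_mm / cos(theta / 2)) * (v - u) / sqrt(sum((v - u)^2))
    e1 <- (p_in - ctr) / fillet_mm
    segs[[length(segs) + 1L]] <-
      list(type = "arc", center = ctr, radius = fillet_mm,
           e1 = e1, e2 = u, a0 = 0, sweep = theta, len = fillet_mm * theta)
    cursor <- b + t * v
  }
  last_dir <- vertices[nv, ] - vertices[nv - 1L, ]
  last_dir <- last_dir / sqrt(sum(last_dir^2))
  line_len <- sqrt(sum((vertices[nv, ] - cursor)^2))
  if (line_len > 1e-9) {
    segs[[length(segs) + 1L]] <-
      list(type = "line", p0 = cursor, dir = last_dir, len = line_len)
  }
  curve_new(segs)
}

# rotate direction d by theta towards the unit normal n (n perpendicular to d)
turn_dir <- function(d, theta_rad, azimuth_rad = 0) {
  ref <- c(cos(azimuth_rad), sin(azimuth_rad), 0)
  n <- ref - sum(ref * d) * d
  if (sqrt(sum(n^2)) < 1e-9) n <- c(1, 0, 0) - d[1] * d
  n <- n / sqrt(sum(n^2))
  cos(theta_rad) * d + sin(theta_rad) * n
}

# ---- phantom specification ----------------------------------------------

#' Specify a phantom
#'
#' The path layout runs portal vein -> uncovered distal stent -> covered
#' stent -> hepatic vein to the IVC, with segment lengths `pv_mm`,
#' `uncovered_mm`, `covered_mm` and `cranial_mm`. Defaults emulate the
#' measured cohort: an 8 mm-diameter tube, a 60 mm covered portion and a
#' 16.5 mm cranial offset.
#'
#' @param shape `"straight"`, `"bend"` (single planar bend), `"arc"`
#'   (circular arc over the whole path) or `"composite"` (several bends,
#'   optionally out of plane).
#' @param turns_deg bend angles (degrees) for `bend`/`composite`.
#' @param turn_at_mm intended arc positions of the bend centers (defaults
#'   to the middle of the covered portion).
#' @param azimuths_deg per-bend turning-plane azimuth (0 keeps all bends in
#'   one plane).
#' @param sweep_deg total sweep for `arc`.
#' @param radius_mm tube radius (mm); must be at least 2 voxels.
#' @param waist optional `list(s_mm, radius_mm, width_mm)`: a smooth
#'   diameter reduction centered at `s_mm`.
#' @param pv_mm,uncovered_mm,covered_mm,cranial_mm layout lengths (mm).
#' @param spacing_mm isotropic voxel size (mm).
#' @param fillet_mm bend fillet radius (default 2 mm, below the 5 mm
#'   curvature gap).
#' @param dropout fraction of stent voxels randomly cleared (strut
#'   artefacts); default 0.
#' @param seed RNG seed for the dropout.
#' @param pad_mm background margin around the tube.
#' @export
phantom_spec <- function(shape = c("straight", "bend", "arc", "composite"),
                         turns_deg = numeric(0), turn_at_mm = NULL,
                         azimuths_deg = NULL, sweep_deg = NULL,
                         radius_mm = 4, waist = NULL,
                         pv_mm = 20, uncovered_mm = 10, covered_mm = 60,
                         cranial_mm = 16.5, spacing_mm = 1, fillet_mm = 2,
                         dropout = 0, seed = 1L, pad_mm = 6) {
  shape <- match.arg(shape)
  if (shape == "bend" && length(turns_deg) != 1L) {
    stop_tips3d("tips3d_bad_input", "shape 'bend' needs exactly one turn")
  }
  if (shape == "arc" && is.null(sweep_deg)) {
    stop_tips3d("tips3d_bad_input", "shape 'arc' needs sweep_deg")
  }
  if (any(turns_deg < 0 | turns_deg > 180)) {
    stop_tips3d("tips3d_bad_input", "turns must lie in [0, 180] degrees")
  }
  total <- pv_mm + uncovered_mm + covered_mm + cranial_mm
  if (is.null(turn_at_mm) && length(turns_deg)) {
    turn_at_mm <- pv_mm + uncovered_mm + covered_mm / 2
    if (length(turns_deg) > 1L) {
      turn_at_mm <- seq(pv_mm + uncovered_mm + 15, pv_mm + uncovered_mm +
                          covered_mm - 15, length.out = length(turns_deg))
    }
  }
  if (is.null(azimuths_deg)) azimuths_deg <- rep(0, length(turns_deg))
  structure(list(shape = shape, turns_deg = turns_deg,
                 turn_at_mm = turn_at_mm, azimuths_deg = azimuths_deg,
                 sweep_deg = sweep_deg, radius_mm = radius_mm, waist = waist,
                 pv_mm = pv_mm, uncovered_mm = uncovered_mm,
                 covered_mm = covered_mm, cranial_mm = cranial_mm,
                 total_mm = total, spacing_mm = spacing_mm,
                 fillet_mm = fillet_mm, dropout = dropout,
                 seed = as.integer(seed), pad_mm = pad_mm),
            class = "phantom_spec")
}

phantom_curve <- function(spec) {
  L <- spec$total_mm
  if (spec$shape == "straight" || length(spec$turns_deg) == 0L &&
      spec$shape != "arc") {
    return(curve_new(list(list(type = "line", p0 = c(0, 0, 0),
                               dir = c(0, 0, 1), len = L))))
  }
  if (spec$shape == "arc") {
    sweep <- spec$sweep_deg * pi / 180
    R <- L / sweep
    return(curve_new(list(list(
      type = "arc", center = c(R, 0, 0), radius = R,
      e1 = c(-1, 0, 0), e2 = c(0, 0, 1), a0 = 0, sweep = sweep,
      len = L))))
  }
  # bend / composite: build polyline vertices so that, after filleting, each
  # bend center sits at its intended arc position and the curve length is L
  thetas <- spec$turns_deg * pi / 180
  rf <- spec$fillet_mm
  t_i <- rf * tan(thetas / 2)
  delta <- 2 * t_i - rf * thetas # per-bend arc-length shortening
  verts <- matrix(0, length(thetas) + 2L, 3)
  d <- c(0, 0, 1)
  pos <- c(0, 0, 0)
  prev_v <- 0
  for (i in seq_along(thetas)) {
    v_i <- spec$turn_at_mm[i] + sum(delta[seq_len(i - 1L)]) +
      (t_i[i] - rf * thetas[i] / 2)
    pos <- pos + (v_i - prev_v) * d
    verts[i + 1L, ] <- pos
    d <- turn_dir(d, thetas[i], spec$azimuths_deg[i] * pi / 180)
    prev_v <- v_i
  }
  v_last <- L + sum(delta)
  verts[length(thetas) + 2L, ] <- pos + (v_last - prev_v) * d
  filleted_polyline(verts, rf)
}

phantom_radius <- function(spec, s) {
  r <- rep(spec$radius_mm, length(s))
  w <- spec$waist
  if (!is.null(w)) {
    width <- w$width_mm %||% 10
    in_w <- abs(s - w$s_mm) <= width / 2
    r[in_w] <- spec$radius_mm - (spec$radius_mm - w$radius_mm) *
      0.5 * (1 + cos(2 * pi * (s[in_w] - w$s_mm) / width))
  }
  r
}

phantom_label <- function(spec, s) {
  lm <- phantom_landmarks(spec)
  ifelse(s < lm$uncovered_distal_begin, 1L,
         ifelse(s < lm$covered_distal_begin, 2L,
                ifelse(s <= lm$covered_cranial_end, 3L, 1L)))
}

phantom_landmarks <- function(spec) {
  path_landmarks(
    uncovered_distal_begin = spec$pv_mm,
    covered_distal_begin = spec$pv_mm + spec$uncovered_mm,
    covered_cranial_end = spec$pv_mm + spec$uncovered_mm + spec$covered_mm,
    ivc_junction = spec$total_mm
  )
}

# brute-force chord-pair maximisation on the exact curve (0.05 mm grid)
exact_max_curvature <- function(curve, s0, s1, params = curvature_params(),
                                step = 0.05) {
  window <- 2 * params$chord_mm + params$gap_mm
  stations <- seq(s0, s1 - window, by = step)
  c_mm <- params$chord_mm; g_mm <- params$gap_mm
  a0 <- curve_eval(curve, stations)$points
  a1 <- curve_eval(curve, stations + c_mm)$points
  b0 <- curve_eval(curve, stations + c_mm + g_mm)$points
  b1 <- curve_eval(curve, stations + 2 * c_mm + g_mm)$points
  d1 <- a1 - a0; d2 <- b1 - b0
  cosang <- rowSums(d1 * d2) /
    (sqrt(rowSums(d1^2)) * sqrt(rowSums(d2^2)))
  max(acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
}

exact_chord_dir <- function(curve, s_from, s_to) {
  p <- curve_eval(curve, c(s_from, s_to))$points
  v <- p[2, ] - p[1, ]
  v / sqrt(sum(v^2))
}

phantom_truth_geometry <- function(spec, curve, chord_mm = 10) {
  lm <- phantom_landmarks(spec)
  stent0 <- lm$uncovered_distal_begin
  stent1 <- lm$stent_cranial_end
  cdb <- lm$covered_distal_begin
  cce <- lm$covered_cranial_end
  min_d <- 2 * spec$radius_mm
  if (!is.null(spec$waist) &&
      spec$waist$s_mm >= stent0 && spec$waist$s_mm <= stent1) {
    min_d <- 2 * spec$waist$radius_mm
  }
  tips_geometry(
    cranial_end_to_ivc_mm = spec$cranial_mm,
    min_stent_diameter_mm = min_d,
    covered_length_mm = spec$covered_mm,
    max_curvature_deg = exact_max_curvature(curve, stent0, stent1),
    covered_ends_angle_deg = angle_deg(
      exact_chord_dir(curve, cdb, cdb + chord_mm),
      exact_chord_dir(curve, cce - chord_mm, cce)),
    alpha_angle_deg = angle_deg(
      exact_chord_dir(curve, cdb - chord_mm, cdb),
      exact_chord_dir(curve, cdb, cdb + chord_mm)),
    confluence_to_stent_mm = spec$pv_mm
  )
}

#' Render a phantom into a label volume with analytic ground truth
#'
#' Every voxel whose center lies within the (possibly waisted) radius
#' profile of the analytic centerline receives the label of its nearest
#' centerline sample (1 lumen, 2 uncovered stent, 3 covered stent); label
#' dropout, if requested, is applied reproducibly from the spec seed.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `volume` (a [label_volume()]) and `truth`
#'   (exact `path`, `landmarks`, `landmark_points`, analytic `geometry`,
#'   suggested `seeds`, and the `spec`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  r_min <- if (is.null(spec$waist)) spec$radius_mm else
    min(spec$radius_mm, spec$waist$radius_mm)
  if (r_min < 2 * spec$spacing_mm) {
    stop_tips3d("tips3d_unmeasurable",
                sprintf("tube radius %.2f mm under 2 voxels (%.2f mm)",
                        r_min, 2 * spec$spacing_mm))
  }
  curve <- phantom_curve(spec)
  L <- curve_total(curve)
  lm <- phantom_landmarks(spec)

  dense_s <- seq(0, L, by = min(0.25, spec$spacing_mm / 2))
  dense <- curve_eval(curve, dense_s)$points
  r_s <- phantom_radius(spec, dense_s)
  lab_s <- phantom_label(spec, dense_s)

  margin <- spec$radius_mm + spec$pad_mm
  bbox_min <- apply(dense, 2, min) - margin
  bbox_max <- apply(dense, 2, max) + margin
  dims <- as.integer(ceiling((bbox_max - bbox_min) / spec$spacing_mm)) + 1L
  spacing <- rep(spec$spacing_mm, 3)

  local_pts <- sweep(dense, 2, bbox_min, `-`)
  vox <- cpp_stamp_tube(dims, spacing, local_pts, r_s, as.integer(lab_s),
                        pad = spec$spacing_mm)
  if (spec$dropout > 0) {
    withr_seed <- spec$seed
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(withr_seed)
    stent_idx <- which(vox %in% c(2L, 3L))
    drop_n <- round(spec$dropout * length(stent_idx))
    if (drop_n > 0) vox[sample(stent_idx, drop_n)] <- 0L
  }
  volume <- label_volume(vox, spacing_mm = spacing, origin = bbox_min)

  truth_path <- centerline_path(curve_eval(curve, seq(0, L, by = 0.25))$points,
                                spacing_mm = 0.25, validate = FALSE)
  landmark_points <- lapply(
    lm[c("uncovered_distal_begin", "covered_distal_begin",
         "covered_cranial_end", "stent_cranial_end")],
    function(s) as.numeric(curve_eval(curve, s)$points))
  seeds <- list(
    confluence = as.numeric(curve_eval(curve, 0)$points),
    ivc = as.numeric(curve_eval(curve, L)$points),
    waypoints = list())
  list(volume = volume,
       truth = list(path = truth_path, landmarks = lm,
                    landmark_points = landmark_points,
                    geometry = phantom_truth_geometry(spec, curve),
                    seeds = seeds, curve = curve, spec = spec))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Deterministic phantom validation battery
#'
#' A fixed battery spanning straight tubes, single bends of 15-120 degrees,
#' waists of 6-8 mm, cranial offsets of 0-26.5 mm (spanning the cohort
#' group medians 6.00 and 16.49 mm), gentle arcs, entry-angle composites
#' and out-of-plane double bends, at 0.5 and 1.0 mm voxels.
#'
#' @param seed RNG seed forwarded to every spec (dropout is 0 by default,
#'   so volumes are identical across runs regardless).
#' @param spacings voxel sizes to span (default 0.5 and 1.0 mm).
#' @return a list of `make_phantom()` results; the `manifest` attribute is
#'   a tibble describing each entry.
#' @export
phantom_suite <- function(seed = 1L, spacings = c(0.5, 1.0)) {
  specs <- list()
  add <- function(name, ...) {
    specs[[length(specs) + 1L]] <<- list(name = name, args = list(...))
  }
  add("straight", shape = "straight")
  for (th in c(15, 30, 45, 60, 90, 120)) {
    add(sprintf("bend%d", th), shape = "bend", turns_deg = th)
  }
  for (wd in c(6, 7, 8)) {
    add(sprintf("waist%g", wd), shape = "straight",
        waist = list(s_mm = 60, radius_mm = wd / 2, width_mm = 10))
  }
  for (off in c(0, 6, 26.5)) {
    add(sprintf("offset%g", off), shape = "straight", cranial_mm = off)
  }
  for (sw in c(45, 60)) add(sprintf("arc%d", sw), shape = "arc", sweep_deg = sw)
  for (al in c(45, 90)) {
    add(sprintf("alpha%d", al), shape = "composite", turns_deg = al,
        turn_at_mm = 30) # at covered_distal_begin
  }
  add("double30_60", shape = "composite", turns_deg = c(30, 60))
  add("oblique45_45", shape = "composite", turns_deg = c(45, 45),
      azimuths_deg = c(0, 90))
  add("bend60_offset6", shape = "bend", turns_deg = 60, cranial_mm = 6)

  out <- list()
  manifest <- list()
  for (sp in spacings) {
    for (entry in specs) {
      args <- c(entry$args, list(spacing_mm = sp, seed = seed))
      spec <- do.call(phantom_spec, args)
      ph <- make_phantom(spec)
      out[[length(out) + 1L]] <- ph
      manifest[[length(manifest) + 1L]] <- tibble::tibble(
        name = entry$name, spacing_mm = sp,
        truth_curvature_deg = ph$truth$geometry$max_curvature_deg)
    }
  }
  attr(out, "manifest") <- dplyr::bind_rows(manifest)
  out
}

#' Write a phantom to disk (NIfTI volume + JSON truth)
#'
#' @param phantom a result of [make_phantom()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly. Files: `volume.nii.gz`, `seeds.json`,
#'   `landmarks.json` (3D points), `truth.json` (landmarks, geometry).
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_label_volume(phantom$volume, file.path(dir, "volume.nii.gz"))
  write_seeds(phantom$truth$seeds, file.path(dir, "seeds.json"))
  jsonlite::write_json(list(points = phantom$truth$landmark_points),
                       file.path(dir, "landmarks.json"), digits = NA)
  jsonlite::write_json(
    list(landmarks = unclass(phantom$truth$landmarks),
         geometry = unclass(phantom$truth$geometry),
         spec = unclass(phantom$truth$spec)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
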