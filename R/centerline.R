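#' Semiautomated centerline extraction
#'
#' Builds the venous measurement path from the portal venous confluence
#' seed, through the stent, to the IVC seed: a minimum-cost 26-connected
#' voxel path through non-background labels, with edge costs inversely
#' weighted by the interior Euclidean distance transform so the path hugs
#' the middle of the lumen (medialness), followed by sub-voxel recentering
#' on the distance-transform ridge and uniform resampling.
#'
#' @param volume a [label_volume()].
#' @param seeds a seed list as returned by [read_seeds()]: `confluence` and
#'   `ivc` points in LPS mm, optional ordered `waypoints`.
#' @param spacing_mm station spacing of the returned path (default 1 mm).
#' @param epsilon_mm medialness softening constant in the edge weight
#'   `step / (epsilon + dt(target))` (default 0.1).
#' @param recenter_passes sub-voxel recentering iterations on the distance
#'   transform ridge (default 2; 0 disables).
#' @param smooth_mm optional moving-average window applied after
#'   recentering (default 0: the ridge recentering already yields a smooth
#'   sub-voxel path, and any smoothing smears localized bends).
#' @return a [centerline_path()] from the confluence seed to the IVC seed.
#' @export
extract_centerline <- function(volume, seeds, spacing_mm = 1,
                               epsilon_mm = 0.1, recenter_passes = 2,
                               smooth_mm = 0) {
  fg <- volume$voxels > 0L
  d <- dim(volume$voxels)
  dt <- cpp_edt3(as.logical(fg), as.integer(d), as.numeric(volume$spacing_mm))
  dim(dt) <- d

  seed_idx <- function(p, name) {
    idx <- round(world_to_voxel(volume, matrix(p, ncol = 3)))
    if (any(idx < 1) || any(idx > matrix(d, ncol = 3))) {
      stop_tips3d("tips3d_bad_seed", sprintf("%s seed outside the volume", name))
    }
    if (!fg[idx[1], idx[2], idx[3]]) {
      stop_tips3d("tips3d_bad_seed",
                  sprintf("%s seed lies in a background voxel", name))
    }
    idx
  }
  stops <- c(list(seed_idx(seeds$confluence, "confluence")),
             lapply(seq_along(seeds$waypoints %||% list()), function(i) {
               seed_idx(seeds$waypoints[[i]], sprintf("waypoint %d", i))
             }),
             list(seed_idx(seeds$ivc, "ivc")))

  g <- voxel_graph(fg, volume$spacing_mm, dt, epsilon_mm)
  lin <- function(idx) (idx[3] - 1) * d[1] * d[2] + (idx[2] - 1) * d[1] + idx[1]
  vid <- g$vid # linear voxel index -> vertex id (0 if background)

  vpath <- integer(0)
  for (i in seq_len(length(stops) - 1L)) {
    from <- vid[lin(stops[[i]])]
    to <- vid[lin(stops[[i + 1L]])]
    sp <- suppressWarnings(
      igraph::shortest_paths(g$graph, from = from, to = to,
                             weights = igraph::E(g$graph)$weight,
                             mode = "out", output = "vpath")
    )
    vp <- as.integer(sp$vpath[[1]])
    if (length(vp) == 0L) {
      stop_tips3d("tips3d_no_path",
                  "seeds are not connected through non-background voxels")
    }
    vpath <- c(vpath, if (i == 1L) vp else vp[-1])
  }

  ijk <- arrayInd(g$voxel_of[vpath], d)
  pts <- voxel_to_world(volume, ijk)
  # light pre-smoothing of the voxel chain stabilizes tangents before
  # recentering; the ridge recentering below restores true axis positions
  path <- resample_path(pts, spacing_mm = spacing_mm,
                        smooth_mm = 2 * max(volume$spacing_mm))
  for (p in seq_len(recenter_passes)) {
    path <- recenter_on_ridge(path, volume, dt)
  }
  if (recenter_passes > 0) path <- refine_kinks(path, volume, dt)
  if (smooth_mm > 0) {
    path <- centerline_path(
      smooth_points(path$points, smooth_mm, path$spacing_mm),
      spacing_mm = path$spacing_mm, validate = FALSE)
  }
  path
}

# directed voxel adjacency graph over foreground voxels, 26-connectivity,
# edge weight = step length / (epsilon + dt at target)
voxel_graph <- function(fg, spacing_mm, dt, epsilon_mm) {
  d <- dim(fg)
  nfg <- sum(fg)
  vid <- integer(length(fg))
  vid[which(fg)] <- seq_len(nfg)
  voxel_of <- which(fg)

  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # half the offsets; add both edge directions explicitly (weights differ)
  keep <- offsets[, 3] > 0 | (offsets[, 3] == 0 & offsets[, 2] > 0) |
    (offsets[, 3] == 0 & offsets[, 2] == 0 & offsets[, 1] > 0)
  offsets <- offsets[keep, , drop = FALSE]

  from_all <- integer(0); to_all <- integer(0); w_ab <- numeric(0); w_ba <- numeric(0)
  idx_arr <- array(seq_along(fg), dim = d)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    step <- sqrt(sum((o * spacing_mm)^2))
    xs <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    ys <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    zs <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    a <- idx_arr[xs - o[1], ys - o[2], zs - o[3], drop = FALSE]
    b <- idx_arr[xs, ys, zs, drop = FALSE]
    ok <- fg[a] & fg[b]
    a <- a[ok]; b <- b[ok]
    from_all <- c(from_all, a)
    to_all <- c(to_all, b)
    w_ab <- c(w_ab, step / (epsilon_mm + dt[b]))
    w_ba <- c(w_ba, step / (epsilon_mm + dt[a]))
  }
  edges <- rbind(cbind(vid[from_all], vid[to_all]),
                 cbind(vid[to_all], vid[from_all]))
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  igraph::E(g)$weight <- c(w_ab, w_ba)
  if (igraph::vcount(g) < nfg) g <- igraph::add_vertices(g, nfg - igraph::vcount(g))
  list(graph = g, vid = vid, voxel_of = voxel_of)
}

# Sub-voxel recentering: in the plane orthogonal to the local tangent, the
# distance-to-background field of a tubular lumen peaks on the medial axis.
# Each station is moved to the dt-weighted centroid of in-plane samples
# whose dt exceeds a fraction of the local ridge height. The ridge height
# is capped at the path-median local maximum (the tube's nominal inscribed
# radius): at an elbow the union of the two limbs admits larger inscribed
# spheres toward the inner corner, and an uncapped threshold would chase
# them off-axis. Thresholding likewise keeps glancing sections of a
# neighbouring limb (low dt) from dragging the centroid. Endpoints are
# left untouched.
recenter_on_ridge <- function(path, volume, dt, extent_mm = 12,
                              grid_mm = 0.5, threshold = 0.85,
                              max_shift_mm = 3) {
  n <- nrow(path$points)
  if (n < 3L) return(path)
  total <- path_length(path)
  out <- path$points
  offs <- seq(-extent_mm / 2, extent_mm / 2, by = grid_mm)
  grid <- as.matrix(expand.grid(u = offs, v = offs))
  planes <- vector("list", n)
  locmax <- rep(NA_real_, n)
  for (i in 2:(n - 1L)) {
    s <- path$cumlen_mm[i]
    h <- min(2, s, total - s)
    if (h < 0.5) next
    tg <- point_at(path, s + h) - point_at(path, s - h)
    ntg <- sqrt(sum(tg^2))
    if (ntg < 1e-9) next
    tg <- as.numeric(tg) / ntg
    basis <- plane_basis(tg)
    pts <- matrix(out[i, ], nrow(grid), 3, byrow = TRUE) +
      grid[, 1] %o% basis$e1 + grid[, 2] %o% basis$e2
    vals <- interp_field(volume, dt, pts)
    planes[[i]] <- list(pts = pts, vals = vals)
    locmax[i] <- max(vals)
  }
  m_typ <- median(locmax, na.rm = TRUE)
  for (i in 2:(n - 1L)) {
    if (is.null(planes[[i]])) next
    m <- min(locmax[i], m_typ)
    if (!is.finite(m) || m <= 0) next
    vals <- planes[[i]]$vals
    pts <- planes[[i]]$pts
    keep <- vals >= threshold * m
    ctr <- colSums(pts[keep, , drop = FALSE] * vals[keep]) / sum(vals[keep])
    shift <- ctr - out[i, ]
    ns <- sqrt(sum(shift^2))
    if (ns > max_shift_mm) shift <- shift * max_shift_mm / ns
    out[i, ] <- out[i, ] + shift
  }
  centerline_path(out, spacing_mm = path$spacing_mm, validate = FALSE)
}

# orthonormal in-plane basis for a unit normal
plane_basis <- function(normal) {
  a <- c(1, 0, 0)
  if (abs(normal[1]) > 0.9) a <- c(0, 1, 0)
  e1 <- cross3(normal, a)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(normal, e1)
  list(e1 = e1, e2 = e2)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Kink refinement. At a sharp bend the voxel solid is a mitered corner
# whose medial surface runs through the straight-extension vertex, so any
# ridge-following path cuts inside the rounded spine; the local distance
# field cannot distinguish the two. A tube prior resolves it: fit straight
# lines to the limbs flanking the kink, recover the corner geometry
# (vertex, turn angle, bend plane), estimate the rounding radius from the
# inner-wall clearance at the vertex -- for a constant-radius tube,
# clearance = r - rf * (1 / cos(theta / 2) - 1) -- and rebuild the kink
# zone as the circular fillet tangent to both limbs.
refine_kinks <- function(path, volume, dt, turn_trigger_deg = 40,
                         fit_mm = 8) {
  pts <- path$points
  n <- nrow(pts)
  sp <- path$spacing_mm
  h <- max(1L, as.integer(round(2 / sp)))
  fitk <- max(3L, as.integer(round(fit_mm / sp)))
  if (n < 2L * fitk + 4L * h) return(path)
  turn <- rep(0, n)
  for (i in (h + 1L):(n - h)) {
    a <- pts[i, ] - pts[i - h, ]
    b <- pts[i + h, ] - pts[i, ]
    if (sum(a^2) < 1e-12 || sum(b^2) < 1e-12) next
    turn[i] <- angle_deg(a, b)
  }
  r_typ <- median(interp_field(volume, dt, pts))
  zones <- zone_runs(turn > turn_trigger_deg / 2)
  for (z in zones) {
    if (max(turn[z$from:z$to]) < turn_trigger_deg) next
    i0 <- z$from - 2L * h
    i1 <- z$to + 2L * h
    f0 <- (i0 - fitk):(i0 - 1L)
    f1 <- (i1 + 1L):(i1 + fitk)
    if (f0[1] < 1L || f1[length(f1)] > n) next
    l0 <- fit_line(pts[f0, , drop = FALSE])
    l1 <- fit_line(pts[f1, , drop = FALSE])
    theta <- angle_deg(l0$dir, l1$dir)
    if (theta < 20 || theta > 175) next
    V <- line_closest_point(l0, l1)
    if (is.null(V)) next
    th <- theta * pi / 180
    inner <- l1$dir - l0$dir
    inner <- inner / sqrt(sum(inner^2))
    # inner-wall clearance at the vertex -> fillet radius estimate
    ts <- seq(0, 2 * r_typ, by = 0.25)
    probe <- matrix(V, length(ts), 3, byrow = TRUE) + ts %o% inner
    dv <- interp_field(volume, dt, probe)
    out_idx <- which(dv < 0.3)
    k <- if (length(out_idx)) max(1L, out_idx[1] - 1L) else length(ts)
    w_in <- ts[k] + dv[k]
    cth <- cos(th / 2)
    rf <- (r_typ - w_in) * cth / (1 - cth)
    rf <- min(max(rf, 0.5), 6)
    t_tan <- rf * tan(th / 2)
    centre <- V + (rf / cth) * inner
    a1 <- V - t_tan * l0$dir # arc start (tangent point on limb 0)
    e1 <- (a1 - centre) / rf
    # closest point on the two limbs and the fillet arc
    for (i in max(1L, i0 - h):min(n, i1 + h)) {
      x <- pts[i, ]
      cand <- rbind(project_ray(x, V, -l0$dir, t_tan),
                    project_ray(x, V, l1$dir, t_tan),
                    project_arc(x, centre, rf, e1, l0$dir, th))
      d2 <- rowSums(sweep(cand, 2, x, `-`)^2)
      pts[i, ] <- cand[which.min(d2), ]
    }
  }
  resample_path(pts, spacing_mm = sp)
}

zone_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (j in seq_along(r$values)) {
    if (r$values[j]) out[[length(out) + 1L]] <- list(from = starts[j], to = ends[j])
  }
  out
}

# total least squares line through points, direction oriented along the
# point order
fit_line <- function(p) {
  ctr <- colMeans(p)
  d <- svd(sweep(p, 2, ctr, `-`), nu = 0, nv = 1)$v[, 1]
  if (sum(d * (p[nrow(p), ] - p[1, ])) < 0) d <- -d
  list(centre = ctr, dir = d)
}

# midpoint of the shortest segment between two fitted lines
line_closest_point <- function(l0, l1) {
  w0 <- l0$centre - l1$centre
  a <- sum(l0$dir * l0$dir); b <- sum(l0$dir * l1$dir); c <- sum(l1$dir * l1$dir)
  d <- sum(l0$dir * w0); e <- sum(l1$dir * w0)
  den <- a * c - b * b
  if (abs(den) < 1e-9) return(NULL)
  t0 <- (b * e - c * d) / den
  t1 <- (a * e - b * d) / den
  (l0$centre + t0 * l0$dir + l1$centre + t1 * l1$dir) / 2
}

# nearest point to x on the segment from `from + eps*dir` extending to
# infinity beyond the tangent length (the limb side of the corner)
project_ray <- function(x, vertex, dir, t_min) {
  t <- sum((x - vertex) * dir)
  t <- max(t, t_min)
  vertex + t * dir
}

# nearest point to x on the fillet arc: angle range [0, th] from e1 with
# in-plane tangent direction d0 at the arc start
project_arc <- function(x, centre, rf, e1, d0, th) {
  e2 <- d0 - sum(d0 * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  v <- x - centre
  a <- atan2(sum(v * e2), sum(v * e1))
  a <- min(max(a, 0), th)
  centre + rf * (cos(a) * e1 + sin(a) * e2)
}
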