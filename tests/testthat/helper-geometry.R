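# Independent geometry oracles. These deliberately avoid the package's path
# machinery: interpolation is done directly with stats::approx on a dense
# polyline, and the curvature search is an exhaustive scan on a fine grid.

interp_polyline <- function(pts, s) {
  cum <- c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                                     pts[-nrow(pts), , drop = FALSE])^2))))
  cbind(approx(cum, pts[, 1], xout = s)$y,
        approx(cum, pts[, 2], xout = s)$y,
        approx(cum, pts[, 3], xout = s)$y)
}

polyline_length <- function(pts) {
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                      pts[-nrow(pts), , drop = FALSE])^2)))
}

# exhaustive chord-pair search over a 0.1 mm station grid
oracle_max_curvature <- function(pts, s0, s1, chord = 10, gap = 5,
                                 step = 0.1) {
  stations <- seq(s0, s1 - (2 * chord + gap), by = step)
  a0 <- interp_polyline(pts, stations)
  a1 <- interp_polyline(pts, stations + chord)
  b0 <- interp_polyline(pts, stations + chord + gap)
  b1 <- interp_polyline(pts, stations + 2 * chord + gap)
  d1 <- a1 - a0
  d2 <- b1 - b0
  cosang <- rowSums(d1 * d2) /
    (sqrt(rowSums(d1^2)) * sqrt(rowSums(d2^2)))
  max(acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
}

# sharp planar bend: two straight arms meeting at a vertex (no fillet)
sharp_bend_points <- function(theta_deg, arm_mm = 25, step = 0.2) {
  th <- theta_deg * pi / 180
  s1 <- seq(0, arm_mm, by = step)
  s2 <- seq(step, arm_mm, by = step)
  vertex <- c(0, 0, arm_mm)
  arm2_dir <- c(sin(th), 0, cos(th))
  rbind(cbind(0, 0, s1),
        t(vertex + arm2_dir %o% s2))
}

# planar circular arc of radius R and given sweep, starting along +z
arc_points <- function(R, sweep_deg, step = 0.1) {
  s <- seq(0, R * sweep_deg * pi / 180, by = step)
  a <- s / R
  cbind(R - R * cos(a), 0, R * sin(a))
}

# smooth random 3D path: a sum of a few long-wavelength sinusoids as
# transverse offsets on a straight spine, giving vessel-like curvature
random_smooth_points <- function(n_mm = 100, step = 0.2, amp = 4) {
  z <- seq(0, n_mm, by = step)
  smooth1 <- function() {
    w <- runif(3, 30, 90) # wavelengths (mm)
    ph <- runif(3, 0, 2 * pi)
    a <- runif(3)
    off <- rowSums(sapply(1:3, function(j) a[j] * sin(2 * pi * z / w[j] + ph[j])))
    off / max(abs(off)) * amp
  }
  cbind(smooth1(), smooth1(), z)
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(pts, R, t) {
  sweep(pts %*% t(R), 2, t, `+`)
}
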