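test_that("resample_path reproduces straight and curved polylines", {
  # straight 60 mm segment at 1 mm spacing
  p <- resample_path(rbind(c(0, 0, 0), c(0, 0, 60)), spacing_mm = 1)
  expect_equal(nrow(p$points), 61L)
  expect_equal(p$cumlen_mm, 0:60)

  # straight 100 mm polyline with irregular input steps
  z <- c(0, 1, 3.7, 10, 11, 47.2, 63, 99, 100)
  p2 <- resample_path(cbind(0, 0, z), spacing_mm = 2)
  expect_lt(abs(path_length(p2) - 100), 1)

  # quarter circle of radius 20 sampled at 0.1 mm, resampled at 1 mm
  th <- seq(0, pi / 2, length.out = 1L + ceiling(10 * pi / 0.1))
  qc <- cbind(20 * sin(th), 0, 20 - 20 * cos(th))
  p3 <- resample_path(qc, spacing_mm = 1)
  expect_lt(abs(path_length(p3) - 10 * pi), 0.1)

  expect_error(resample_path(rbind(c(1, 2, 3), c(1, 2, 3))),
               class = "tips3d_degenerate_path")
})

test_that("arc_distance measures along the path and rejects outside stations", {
  p <- resample_path(rbind(c(0, 0, 0), c(0, 0, 60)), 1)
  expect_equal(arc_distance(p, 0, 60), 60)
  expect_equal(arc_distance(p, 23.5, 23.5), 0)
  th <- seq(0, pi / 2, length.out = 2000)
  arc <- resample_path(cbind(20 * sin(th), 0, 20 - 20 * cos(th)), 0.5)
  expect_equal(arc_distance(arc, 0, path_length(arc)), 10 * pi,
               tolerance = 1e-3)
  expect_error(arc_distance(p, -1, 10), class = "tips3d_out_of_range")
  expect_error(arc_distance(p, 0, 61), class = "tips3d_out_of_range")
})

test_that("chord_direction is the unit chord vector and respects symmetry", {
  p <- resample_path(rbind(c(0, 0, 0), c(0, 0, 60)), 1)
  expect_equal(as.numeric(chord_direction(p, 10, 10)), c(0, 0, 1))
  expect_equal(as.numeric(chord_direction(p, 20, 10, "backward")), c(0, 0, 1))

  # reflecting the path through the origin negates every chord direction
  pts <- sharp_bend_points(40)
  path <- resample_path(pts, 0.5)
  path_neg <- resample_path(-pts, 0.5)
  d <- chord_direction(path, 5, 10)
  d_neg <- chord_direction(path_neg, 5, 10)
  expect_equal(d_neg, -d, tolerance = 1e-9)

  # on a circle the chord direction equals the tangent at the chord midpoint
  R <- 40
  arc <- resample_path(arc_points(R, 80), 0.25)
  s <- 12
  chord <- 10
  d_arc <- chord_direction(arc, s, chord)
  mid <- (s + chord / 2) / R
  expect_equal(as.numeric(d_arc), c(sin(mid), 0, cos(mid)), tolerance = 1e-3)

  expect_error(chord_direction(p, 55, 10), class = "tips3d_out_of_range")
})

test_that("angle_deg clamps and covers the trivial geometries", {
  expect_equal(angle_deg(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(angle_deg(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_deg(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_error(angle_deg(c(0, 0, 0), c(1, 0, 0)),
               class = "tips3d_degenerate_vector")
})

test_that("max_section_curvature reproduces the printed worked examples", {
  # straight stent: exactly 0
  p <- resample_path(rbind(c(0, 0, 0), c(0, 0, 60)), 1)
  expect_equal(as.numeric(max_section_curvature(p, arc_interval(0, 60))), 0)

  # a sharp planar 90 degree bend contained in one chord+gap window: 90
  p90 <- resample_path(sharp_bend_points(90, arm_mm = 20), 0.5)
  expect_equal(as.numeric(max_section_curvature(p90,
                                                arc_interval(0, path_length(p90)))),
               90, tolerance = 1e-6)

  expect_error(max_section_curvature(p, arc_interval(0, 20)),
               class = "tips3d_insufficient_length")
})

test_that("max_section_curvature matches the exhaustive oracle", {
  # localized 45 degree bend
  pts45 <- sharp_bend_points(45)
  p45 <- resample_path(pts45, 0.5)
  got <- as.numeric(max_section_curvature(p45, arc_interval(0, path_length(p45))))
  want <- oracle_max_curvature(pts45, 0, polyline_length(pts45))
  expect_lt(abs(got - want), 0.5)
  expect_lt(abs(got - 45), 0.5)

  # gentle arc, total bend 60 degrees over 80 mm: far below 60, equal to
  # the closed form (chord + gap) / R
  R <- 80 / (60 * pi / 180)
  ptsarc <- arc_points(R, 60)
  parc <- resample_path(ptsarc, 0.5)
  got_arc <- as.numeric(max_section_curvature(parc,
                                              arc_interval(0, path_length(parc))))
  want_arc <- oracle_max_curvature(ptsarc, 0, polyline_length(ptsarc))
  expect_lt(got_arc, 60)
  expect_lt(abs(got_arc - want_arc), 0.5)
  expect_equal(want_arc, 15 / R * 180 / pi, tolerance = 0.01)
})

test_that("curvature metric is non-negative and monotone in the bend angle", {
  set.seed(7)
  vals <- vapply(c(0, 20, 45, 60, 90, 120, 150), function(th) {
    pts <- if (th == 0) cbind(0, 0, seq(0, 50, by = 0.2))
           else sharp_bend_points(th)
    p <- resample_path(pts, 0.5)
    as.numeric(max_section_curvature(p, arc_interval(0, path_length(p))))
  }, numeric(1))
  expect_true(all(vals >= 0))
  expect_true(all(diff(vals) >= -1e-6))
  expect_equal(vals[1], 0)
})

test_that("angles and arc distances are rigid-motion invariant, lengths scale", {
  set.seed(11)
  pts <- random_smooth_points()
  p <- resample_path(pts, 1)
  L <- path_length(p)
  base_curv <- as.numeric(max_section_curvature(p, arc_interval(5, L - 5)))
  base_dist <- arc_distance(p, 3, L - 3)
  for (k in 1:5) {
    R <- random_rotation()
    t <- rnorm(3, sd = 50)
    p2 <- resample_path(apply_rigid(pts, R, t), 1)
    expect_lt(abs(arc_distance(p2, 3, path_length(p2) - 3) - base_dist) /
                base_dist, 1e-6)
    curv2 <- as.numeric(max_section_curvature(p2,
                                              arc_interval(5, path_length(p2) - 5)))
    expect_lt(abs(curv2 - base_curv), 1e-6)
  }
  # uniform scaling multiplies distances by k and leaves angles unchanged
  k <- 2.7
  p3 <- resample_path(pts * k, 1 * k)
  expect_lt(abs(path_length(p3) - k * L) / (k * L), 1e-6)
  curv3 <- as.numeric(max_section_curvature(
    p3, arc_interval(5 * k, path_length(p3) - 5 * k),
    curvature_params(gap_mm = 5 * k, chord_mm = 10 * k),
    station_step_mm = 0.5 * k))
  expect_lt(abs(curv3 - base_curv), 1e-6)
})

test_that("centerline paths round-trip through JSON", {
  pts <- sharp_bend_points(30)
  p <- resample_path(pts, 1)
  f <- withr::local_tempfile(fileext = ".json")
  path_to_json(p, f)
  p2 <- path_from_json(f)
  expect_equal(p2$points, p$points, tolerance = 1e-12)
  expect_equal(p2$spacing_mm, p$spacing_mm)
  expect_equal(tidy(p)$s_mm, p$cumlen_mm)
})
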