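# analytic straight layout: confluence 0 .. stent 20 .. covered 30..90,
# terminus 106.49 (cranial gap 16.49, matching the dysfunction-group scale)
straight_layout <- function() {
  path <- resample_path(rbind(c(0, 0, 0), c(0, 0, 106.49)), 0.5)
  lm <- path_landmarks(uncovered_distal_begin = 20, covered_distal_begin = 30,
                       covered_cranial_end = 90, ivc_junction = 106.49)
  list(path = path, lm = lm)
}

test_that("along-path landmark distances follow the construction", {
  sl <- straight_layout()
  expect_equal(cranial_end_to_ivc(sl$path, sl$lm), 16.49)
  expect_equal(covered_length(sl$path, sl$lm), 60)
  expect_equal(confluence_to_stent(sl$path, sl$lm), 20)

  # stent ending exactly at the IVC junction
  lm0 <- path_landmarks(uncovered_distal_begin = 20, covered_distal_begin = 30,
                        covered_cranial_end = 106.49, ivc_junction = 106.49)
  expect_equal(cranial_end_to_ivc(sl$path, lm0), 0)

  # zero-length covered region
  lmz <- path_landmarks(uncovered_distal_begin = 20, covered_distal_begin = 30,
                        covered_cranial_end = 30, stent_cranial_end = 90,
                        ivc_junction = 106.49)
  expect_equal(covered_length(sl$path, lmz), 0)

  # curved path: distances are arc lengths, not straight lines
  R <- 80 / (60 * pi / 180)
  arc <- resample_path(arc_points(R, 60), 0.25)
  lm_arc <- path_landmarks(uncovered_distal_begin = 10,
                           covered_distal_begin = 15,
                           covered_cranial_end = 70,
                           ivc_junction = path_length(arc))
  expect_lt(abs(covered_length(arc, lm_arc) - 55), 0.5)
})

test_that("landmark ordering violations raise an invalid-landmarks error", {
  expect_error(path_landmarks(uncovered_distal_begin = 30,
                              covered_distal_begin = 20,
                              covered_cranial_end = 90, ivc_junction = 100),
               class = "tips3d_invalid_landmarks")
  sl <- straight_layout()
  lm_far <- path_landmarks(uncovered_distal_begin = 20,
                           covered_distal_begin = 30,
                           covered_cranial_end = 90, ivc_junction = 300)
  expect_error(cranial_end_to_ivc(sl$path, lm_far),
               class = "tips3d_invalid_landmarks")
})

test_that("end angles reproduce forced geometries", {
  sl <- straight_layout()
  expect_equal(covered_ends_angle(sl$path, sl$lm), 0)
  expect_equal(alpha_angle(sl$path, sl$lm), 0)

  # planar 90 degree elbow mid-covered: the end tangents are orthogonal
  pts <- sharp_bend_points(90, arm_mm = 60, step = 0.25)
  elbow <- resample_path(pts, 0.25)
  lm_e <- path_landmarks(uncovered_distal_begin = 20,
                         covered_distal_begin = 30,
                         covered_cranial_end = 90,
                         ivc_junction = path_length(elbow))
  expect_equal(covered_ends_angle(elbow, lm_e), 90, tolerance = 1e-6)

  # perpendicular stent entry: bend exactly at the covered begin
  lm_a <- path_landmarks(uncovered_distal_begin = 30,
                         covered_distal_begin = 60,
                         covered_cranial_end = 100,
                         ivc_junction = path_length(elbow))
  expect_equal(alpha_angle(elbow, lm_a), 90, tolerance = 1e-6)

  # smooth arc: covered-ends angle equals the turn between the chords
  R <- 80 / (60 * pi / 180)
  arc <- resample_path(arc_points(R, 60), 0.25)
  lm_arc <- path_landmarks(uncovered_distal_begin = 10,
                           covered_distal_begin = 15,
                           covered_cranial_end = 75,
                           ivc_junction = path_length(arc))
  expect_equal(covered_ends_angle(arc, lm_arc), (60 - 10) / R * 180 / pi,
               tolerance = 1)
  expect_error(covered_ends_angle(sl$path,
                                  path_landmarks(95, 100, 103,
                                                 ivc_junction = 106.49)),
               class = "tips3d_out_of_range")
})

test_that("min_stent_diameter takes the smallest non-empty profile", {
  prof <- tibble::tibble(s_mm = 1:4, area_mm2 = c(50, 40, 60, 0),
                         equiv_diameter_mm = 2 * sqrt(c(50, 40, 60, 0) / pi),
                         empty = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(min_stent_diameter(prof), 2 * sqrt(40 / pi))
  expect_equal(min_stent_diameter(prof[2, ]), 2 * sqrt(40 / pi))
  expect_error(min_stent_diameter(prof[prof$empty, ]),
               class = "tips3d_no_lumen")
})

test_that("landmarks given as 3D points snap to the right arc positions", {
  pts <- sharp_bend_points(60, arm_mm = 55, step = 0.25)
  path <- resample_path(pts, 0.5)
  truth <- c(uncovered = 20, covered_b = 30, covered_e = 95)
  p3 <- lapply(truth, function(s) as.numeric(point_at(path, s)))
  lm <- snap_landmarks(path, list(uncovered_distal_begin = p3[[1]],
                                  covered_distal_begin = p3[[2]],
                                  covered_cranial_end = p3[[3]]))
  expect_equal(lm$uncovered_distal_begin, 20, tolerance = 0.01)
  expect_equal(lm$covered_distal_begin, 30, tolerance = 0.01)
  expect_equal(lm$covered_cranial_end, 95, tolerance = 0.01)
  expect_equal(lm$ivc_junction, path_length(path))
})

test_that("the landmark partition satisfies the path-length sum rule", {
  for (th in c(0, 30, 75)) {
    pts <- if (th == 0) cbind(0, 0, seq(0, 110, by = 0.25))
           else sharp_bend_points(th, arm_mm = 55, step = 0.25)
    path <- resample_path(pts, 0.5)
    lm <- path_landmarks(uncovered_distal_begin = 20,
                         covered_distal_begin = 30,
                         covered_cranial_end = 90,
                         ivc_junction = path_length(path))
    total <- confluence_to_stent(path, lm) +
      arc_distance(path, lm$uncovered_distal_begin, lm$stent_cranial_end) +
      cranial_end_to_ivc(path, lm)
    expect_lt(abs(total - path_length(path)), 0.5)
  }
})

test_that("compute_all assembles all seven parameters on a phantom", {
  ph <- make_phantom(phantom_spec("straight", spacing_mm = 1))
  geom <- compute_all(ph$volume, ph$truth$path, ph$truth$landmarks)
  expect_s3_class(geom, "tips_geometry")
  expect_equal(geom$max_curvature_deg, 0)
  expect_equal(geom$covered_ends_angle_deg, 0)
  expect_equal(geom$alpha_angle_deg, 0)
  expect_equal(geom$covered_length_mm, 60)
  expect_equal(geom$cranial_end_to_ivc_mm, 16.5)
  expect_lt(abs(geom$min_stent_diameter_mm - 8), 1)
  td <- tidy(geom)
  expect_equal(names(td),
               c("cranial_end_to_ivc_mm", "min_stent_diameter_mm",
                 "covered_length_mm", "max_curvature_deg",
                 "covered_ends_angle_deg", "alpha_angle_deg",
                 "confluence_to_stent_mm"))
  expect_error(compute_all(ph$volume, ph$truth$path, list(a = 1)),
               class = "tips3d_invalid_landmarks")
})
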