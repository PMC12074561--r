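straight_tube_volume <- function(radius = 4, len = 40, spacing = 1) {
  make_phantom(phantom_spec("straight", pv_mm = 10, uncovered_mm = 5,
                            covered_mm = len - 20, cranial_mm = 5,
                            radius_mm = radius, spacing_mm = spacing))
}

test_that("label_volume validates its invariants", {
  arr <- array(0L, c(4, 4, 4))
  expect_s3_class(label_volume(arr, 1), "label_volume")
  arr_bad <- arr; arr_bad[1] <- 7L
  expect_error(label_volume(arr_bad, 1), class = "tips3d_bad_volume")
  expect_error(label_volume(arr, c(1, -1, 1)), class = "tips3d_bad_volume")
  expect_error(label_volume(arr, 1, direction = matrix(1, 3, 3)),
               class = "tips3d_bad_volume")
  expect_error(label_volume(array(0L, c(4, 4)), 1),
               class = "tips3d_bad_volume")
})

test_that("voxel and world coordinates are mutually inverse", {
  R <- random_rotation()
  vol <- label_volume(array(0L, c(5, 6, 7)), spacing_mm = c(0.5, 1, 2),
                      origin = c(10, -4, 3), direction = R)
  ijk <- rbind(c(1, 1, 1), c(5, 6, 7), c(2.5, 3.25, 4))
  xyz <- voxel_to_world(vol, ijk)
  expect_equal(world_to_voxel(vol, xyz), ijk, tolerance = 1e-9)
  # origin is the world position of voxel (1,1,1)
  expect_equal(as.numeric(xyz[1, ]), c(10, -4, 3))
})

test_that("NIfTI round trip preserves voxels and millimetre geometry", {
  ph <- straight_tube_volume(spacing = 1)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_label_volume(ph$volume, f)
  vol2 <- read_label_volume(f)
  expect_identical(vol2$voxels, ph$volume$voxels)
  expect_equal(vol2$spacing_mm, ph$volume$spacing_mm, tolerance = 1e-5)
  expect_equal(vol2$origin, ph$volume$origin, tolerance = 1e-4)
  expect_equal(vol2$direction, ph$volume$direction, tolerance = 1e-5)
})

test_that("seed JSON round trips and rejects incomplete files", {
  seeds <- list(confluence = c(1, 2, 3), ivc = c(4, 5, 6),
                waypoints = list(c(2, 2, 2)))
  f <- withr::local_tempfile(fileext = ".json")
  write_seeds(seeds, f)
  s2 <- read_seeds(f)
  expect_equal(s2$confluence, seeds$confluence)
  expect_equal(s2$ivc, seeds$ivc)
  expect_equal(s2$waypoints[[1]], c(2, 2, 2))
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"confluence": [1,2,3]}', f2)
  expect_error(read_seeds(f2), class = "tips3d_bad_input")
})

test_that("centerline of a straight tube stays within half a voxel diagonal", {
  ph <- straight_tube_volume(radius = 4, len = 80, spacing = 1)
  path <- extract_centerline(ph$volume, ph$truth$seeds, spacing_mm = 1)
  # true axis in this phantom frame: x = y = axis centre, z free
  axis_xy <- ph$truth$path$points[1, 1:2]
  interior <- path$cumlen_mm > 10 & path$cumlen_mm < path_length(path) - 10
  dev <- sqrt(rowSums(sweep(path$points[interior, 1:2, drop = FALSE],
                            2, axis_xy, `-`)^2))
  expect_lt(max(dev), sqrt(3) / 2)
})

test_that("an L-bend tube recovers the analytic centerline length within 5%", {
  ph <- make_phantom(phantom_spec("bend", turns_deg = 90, spacing_mm = 1))
  path <- extract_centerline(ph$volume, ph$truth$seeds, spacing_mm = 1)
  truth_len <- path_length(ph$truth$path)
  expect_lt(abs(path_length(path) - truth_len) / truth_len, 0.05)
})

test_that("disconnected tubes and background seeds raise classed errors", {
  arr <- array(0L, c(20, 20, 30))
  arr[5:8, 5:8, 2:28] <- 1L
  arr[14:17, 14:17, 2:28] <- 1L
  vol <- label_volume(arr, 1)
  seeds <- list(confluence = voxel_to_world(vol, rbind(c(6, 6, 5)))[1, ],
                ivc = voxel_to_world(vol, rbind(c(15, 15, 25)))[1, ],
                waypoints = list())
  expect_error(extract_centerline(vol, seeds), class = "tips3d_no_path")
  seeds_bad <- list(confluence = voxel_to_world(vol, rbind(c(1, 1, 1)))[1, ],
                    ivc = seeds$ivc, waypoints = list())
  expect_error(extract_centerline(vol, seeds_bad), class = "tips3d_bad_seed")
})

test_that("swapping the seeds reverses the path with near-equal length", {
  ph <- straight_tube_volume(radius = 4, len = 60, spacing = 1)
  seeds <- ph$truth$seeds
  p1 <- extract_centerline(ph$volume, seeds, spacing_mm = 1)
  p2 <- extract_centerline(ph$volume,
                           list(confluence = seeds$ivc, ivc = seeds$confluence,
                                waypoints = list()),
                           spacing_mm = 1)
  expect_lt(abs(path_length(p1) - path_length(p2)) / path_length(p1), 0.01)
  expect_equal(p2$points[1, ], p1$points[nrow(p1$points), ], tolerance = 1.5)
})
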