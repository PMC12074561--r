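#' Labelled voxel volumes
#'
#' A `label_volume` is a 3D integer voxel grid with millimetre geometry
#' (per-axis spacing, origin, orthonormal direction matrix) standing in for
#' a post-procedure CT segmentation. Label codes: 0 background, 1 vessel
#' lumen, 2 uncovered stent, 3 covered stent. All world coordinates are LPS
#' millimetres (DICOM convention); NIfTI files, which are RAS by
#' convention, are converted on load and on save.
#'
#' @name label_volume
NULL

LABEL_CODES <- c(background = 0L, lumen = 1L, uncovered_stent = 2L,
                 covered_stent = 3L)

#' Construct a label volume
#'
#' @param voxels 3D integer array with values in `{0, 1, 2, 3}`.
#' @param spacing_mm per-axis voxel size (length 3, mm).
#' @param origin world position (LPS mm) of the center of voxel `[1, 1, 1]`.
#' @param direction 3 x 3 orthonormal matrix whose columns are the world
#'   directions of the voxel axes.
#' @export
label_volume <- function(voxels, spacing_mm, origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (length(dim(voxels)) != 3L) {
    stop_tips3d("tips3d_bad_volume", "voxels must be a 3D array")
  }
  storage.mode(voxels) <- "integer"
  if (!all(voxels %in% 0:3)) {
    stop_tips3d("tips3d_bad_volume", "labels must be in {0, 1, 2, 3}")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3)
  if (any(spacing_mm <= 0)) {
    stop_tips3d("tips3d_bad_volume", "spacing must be positive on every axis")
  }
  direction <- as.matrix(direction)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6) {
    stop_tips3d("tips3d_bad_volume", "direction matrix must be orthonormal")
  }
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 origin = as.numeric(origin), direction = direction),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ %.2g x %.2g x %.2g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  tab <- table(factor(x$voxels, levels = 0:3,
                      labels = names(LABEL_CODES)))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Convert voxel indices to world coordinates (LPS mm)
#'
#' @param volume a `label_volume`.
#' @param ijk n x 3 matrix of 1-based voxel indices (may be fractional).
#' @return n x 3 matrix of LPS mm points.
#' @export
voxel_to_world <- function(volume, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  scaled <- sweep(ijk - 1, 2, volume$spacing_mm, `*`)
  out <- scaled %*% t(volume$direction)
  sweep(out, 2, volume$origin, `+`)
}

#' Convert world coordinates (LPS mm) to fractional voxel indices
#'
#' @param volume a `label_volume`.
#' @param xyz n x 3 matrix of LPS mm points.
#' @return n x 3 matrix of 1-based fractional voxel indices.
#' @export
world_to_voxel <- function(volume, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  centered <- sweep(xyz, 2, volume$origin, `-`)
  sweep(centered %*% volume$direction, 2, volume$spacing_mm, `/`) + 1
}

# Nearest-voxel label lookup for a point matrix; outside-volume points get
# 0. Ties at half-voxel positions are broken upward with a bias far above
# floating-point noise, so rigidly co-transformed volume+path assemblies
# sample identically.
lookup_labels <- function(volume, xyz) {
  idx <- floor(world_to_voxel(volume, xyz) + 0.5 + 1e-9)
  d <- dim(volume$voxels)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- integer(nrow(idx))
  if (any(ok)) {
    lin <- (idx[ok, 3] - 1) * d[1] * d[2] + (idx[ok, 2] - 1) * d[1] + idx[ok, 1]
    out[ok] <- volume$voxels[lin]
  }
  out
}

# trilinear interpolation of a numeric 3D field defined on the voxel grid
interp_field <- function(volume, field, xyz) {
  idx <- world_to_voxel(volume, xyz)
  d <- dim(volume$voxels)
  i0 <- pmin(pmax(floor(idx), 1), matrix(rep(d - 1L, each = nrow(idx)), ncol = 3))
  fr <- pmin(pmax(idx - i0, 0), 1)
  out <- numeric(nrow(idx))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    lin <- (i0[, 3] + dz - 1) * d[1] * d[2] + (i0[, 2] + dy - 1) * d[1] +
      (i0[, 1] + dx)
    out <- out + w * field[lin]
  }
  outside <- idx[, 1] < 0.5 | idx[, 1] > d[1] + 0.5 |
             idx[, 2] < 0.5 | idx[, 2] > d[2] + 0.5 |
             idx[, 3] < 0.5 | idx[, 3] > d[3] + 0.5
  out[outside] <- 0
  out
}

ras_to_lps <- diag(c(-1, -1, 1))

#' Read a label volume from NIfTI
#'
#' The NIfTI world frame (RAS) is converted to LPS on load. Only volumes
#' with orthonormal axes are supported.
#'
#' @param path a `.nii` or `.nii.gz` file with integer labels 0-3.
#' @return a [label_volume()].
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- arr[, , , 1]
  arr <- array(as.integer(round(arr)), dim(arr)) # drop NIfTI attributes
  A <- ras_to_lps %*% xf[1:3, 1:3]
  origin <- as.numeric(ras_to_lps %*% xf[1:3, 4])
  spacing <- sqrt(colSums(A^2))
  direction <- sweep(A, 2, spacing, `/`)
  label_volume(arr, spacing_mm = spacing, origin = origin,
               direction = direction)
}

#' Write a label volume to NIfTI
#'
#' The in-memory LPS geometry is converted back to the NIfTI RAS
#' convention.
#'
#' @param volume a [label_volume()].
#' @param path output `.nii` or `.nii.gz` file.
#' @export
write_label_volume <- function(volume, path) {
  A_ras <- ras_to_lps %*% (volume$direction %*% diag(volume$spacing_mm))
  origin_ras <- as.numeric(ras_to_lps %*% volume$origin)
  xf <- rbind(cbind(A_ras, origin_ras), c(0, 0, 0, 1))
  img <- RNifti::asNifti(volume$voxels, datatype = "int16")
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read seed points from JSON
#'
#' Seeds delimit the semiautomated path: the portal venous confluence seed,
#' the IVC seed, and optional ordered waypoints, all in LPS mm:
#' `{"confluence": [x,y,z], "ivc": [x,y,z], "waypoints": [[...], ...]}`.
#'
#' @param path JSON file.
#' @return a list with elements `confluence`, `ivc`, `waypoints`.
#' @export
read_seeds <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = FALSE)
  if (is.null(obj$confluence) || is.null(obj$ivc)) {
    stop_tips3d("tips3d_bad_input", "seeds JSON needs 'confluence' and 'ivc'")
  }
  wp <- obj$waypoints %||% list()
  if (!is.list(wp)) wp <- list(wp)
  list(confluence = as.numeric(obj$confluence),
       ivc = as.numeric(obj$ivc),
       waypoints = lapply(wp, as.numeric))
}

#' Write seed points to JSON
#' @param seeds a list with `confluence`, `ivc` and optional `waypoints`.
#' @param path output JSON file.
#' @export
write_seeds <- function(seeds, path) {
  obj <- list(confluence = seeds$confluence, ivc = seeds$ivc,
              waypoints = seeds$waypoints %||% list())
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
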