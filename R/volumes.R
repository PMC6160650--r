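#' Construct a gray-matter volume
#'
#' A `gm_volume` is a single subject-timepoint 3D scalar map of modulated
#' gray-matter volume together with its grid geometry: a 4x4 voxel-to-world
#' affine (mm) and the per-axis voxel edge lengths. Voxel indices are 1-based
#' in R; world coordinates are computed from 0-based indices so that reported
#' peak coordinates follow the usual neuroimaging convention.
#'
#' @param data 3D numeric array of voxel values.
#' @param affine 4x4 voxel-to-world matrix (mm). Defaults to an axis-aligned
#'   RAS affine with the given voxel size, centred on the grid.
#' @param voxel_size_mm per-axis voxel edge lengths; must equal the column
#'   norms of the affine's linear part.
#' @return An object of class `gm_volume`.
#' @export
gm_volume <- function(data, affine = NULL, voxel_size_mm = c(1.5, 1.5, 1.5)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (any(dim(data) <= 0L)) stop("non-positive grid dimensions")
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("non-positive voxel size")
  if (is.null(affine)) affine <- default_affine(dim(data), voxel_size_mm)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("'affine' must be 4x4")
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  colnorm <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(colnorm - voxel_size_mm) > 1e-3 * max(voxel_size_mm)))
    stop("voxel_size_mm does not match the affine's column norms")
  structure(list(data = data, affine = affine, voxel_size_mm = voxel_size_mm),
            class = "gm_volume")
}

#' Construct a named binary region mask
#'
#' @param data 3D array coercible to 0/1.
#' @param name label for the region (e.g. "TIS", "DSA").
#' @inheritParams gm_volume
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(data, name = "region", affine = NULL,
                        voxel_size_mm = c(1.5, 1.5, 1.5)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  storage.mode(data) <- "integer"
  if (!all(data %in% c(0L, 1L))) stop("mask values must be 0 or 1")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (is.null(affine)) affine <- default_affine(dim(data), voxel_size_mm)
  structure(list(data = data, name = as.character(name)[1],
                 affine = as.matrix(affine), voxel_size_mm = voxel_size_mm),
            class = "region_mask")
}

# Axis-aligned RAS affine with the world origin at the grid centre.
default_affine <- function(dim, voxel_size_mm) {
  voxel_size_mm <- rep_len(voxel_size_mm, 3L)
  a <- diag(c(voxel_size_mm, 1))
  a[1:3, 4] <- -voxel_size_mm * (dim - 1) / 2
  a
}

#' @export
print.gm_volume <- function(x, ...) {
  cat("gm_volume:", paste(dim(x$data), collapse = " x "),
      "voxels @", paste(signif(x$voxel_size_mm, 4), collapse = "x"), "mm\n")
  cat("  range:", paste(signif(range(x$data), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
print.region_mask <- function(x, ...) {
  cat("region_mask '", x$name, "': ", sum(x$data), " of ",
      length(x$data), " voxels\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-4) {
  all(dim(a$data) == dim(b$data)) && max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes/masks are not on the same grid")
  invisible(TRUE)
}

#' Convert voxel indices to world (mm) coordinates
#'
#' @param ijk matrix (or vector) of 1-based voxel indices, one row per voxel.
#' @param affine 4x4 voxel-to-world matrix; indices are shifted to 0-based
#'   before applying it.
#' @return Matrix of world coordinates (mm), one row per input voxel.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  xyz1 <- cbind(ijk - 1, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

#' Convert a voxel count to a physical volume in ml
#'
#' Cluster sizes in voxel-based morphometry tables are reported both as voxel
#' counts and as millilitres; at 1.5 mm isotropic resolution one voxel is
#' 3.375 mm^3, so e.g. 3,382 voxels correspond to 11.4 ml.
#'
#' @param n_voxels non-negative voxel count.
#' @param voxel_size_mm per-axis voxel edge lengths (mm).
#' @return Volume in ml (not rounded; round to one decimal for table display).
#' @export
voxels_to_ml <- function(n_voxels, voxel_size_mm = c(1.5, 1.5, 1.5)) {
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("non-positive voxel size")
  if (any(n_voxels < 0)) stop("negative voxel count")
  n_voxels * prod(voxel_size_mm) / 1000
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b `region_mask` objects (or 0/1 arrays) on the same grid.
#' @return 2|A&B| / (|A|+|B|); NA when both masks are empty.
#' @export
dice <- function(a, b) {
  da <- if (inherits(a, "region_mask")) a$data else a
  db <- if (inherits(b, "region_mask")) b$data else b
  if (!all(dim(da) == dim(db))) stop("masks are not on the same grid")
  s <- sum(da) + sum(db)
  if (s == 0) return(NA_real_)
  2 * sum(da & db) / s
}

#' Read a single-volume NIfTI-1 image
#'
#' The affine is taken from the stored transform (sform preferred); when the
#' header's pixdim disagrees with the affine's column norms by more than
#' 1e-3 mm a warning is issued and the affine wins.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return A `gm_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a single 3D volume, got ", length(d), "D")
  affine <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(affine) <- list(dim = c(4L, 4L))
  if (abs(det(affine)) < 1e-12) stop("non-invertible affine in ", path)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  hdr_pixdim <- RNifti::pixdim(img)[1:3]
  if (any(hdr_pixdim > 0) && any(abs(hdr_pixdim - vox) > 1e-3))
    warning("header voxel size disagrees with affine; using the affine")
  gm_volume(array(as.numeric(img), d), affine = affine, voxel_size_mm = vox)
}

#' Write a volume or mask as NIfTI-1
#'
#' Volumes are stored as float32, masks as uint8; the affine goes in the
#' sform (code 2, aligned/standard space).
#'
#' @param volume a `gm_volume` or `region_mask`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  is_mask <- inherits(volume, "region_mask")
  if (!is_mask && !inherits(volume, "gm_volume"))
    stop("'volume' must be a gm_volume or region_mask")
  dt <- if (is_mask) "uint8" else "float"
  d <- dim(volume$data)
  aff <- volume$affine
  hdr <- RNifti::niftiHeader(list(
    dim = c(3L, d, 1L, 1L, 1L, 1L),
    pixdim = c(1, volume$voxel_size_mm, 0, 0, 0, 0),
    srow_x = aff[1, ], srow_y = aff[2, ], srow_z = aff[3, ],
    sform_code = 2L))
  img <- RNifti::asNifti(volume$data, reference = hdr, datatype = dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}
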