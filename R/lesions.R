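# White-matter lesions depress the apparent GM value locally; before
# statistics they are filled in ("in-painted") from the intensity
# distribution of normal-appearing tissue so they do not drag the voxelwise
# model. The implant step exists so the in-painting can be exercised against
# a known ground truth.


# Binary sphere on a voxel grid (centre-within-radius membership), scanning
# only the bounding box.
sphere_mask_array <- function(dim, center, radius_mm, voxel_size_mm) {
  m <- array(0L, dim)
  rv <- ceiling(radius_mm / voxel_size_mm)
  rng <- lapply(1:3, function(a)
    max(1L, center[a] - rv[a]):min(dim[a], center[a] + rv[a]))
  if (any(lengths(rng) == 0L)) return(m)
  g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  d2 <- ((g$i - center[1]) * voxel_size_mm[1])^2 +
        ((g$j - center[2]) * voxel_size_mm[2])^2 +
        ((g$k - center[3]) * voxel_size_mm[3])^2
  inside <- d2 <= radius_mm^2
  m[cbind(g$i, g$j, g$k)[inside, , drop = FALSE]] <- 1L
  m
}

#' Implant synthetic lesions into a volume
#'
#' Places spherical lesion blobs (constant intensity offset) at random
#' locations inside a brain mask, returning the modified volume and the
#' lesion mask. Placement is deterministic under the seed.
#'
#' @param volume a `gm_volume`.
#' @param lesion_spec list with `n_lesions`, `radius_mm`, `offset`
#'   (intensity shift applied to lesion voxels, typically negative).
#' @param brain_mask `region_mask` restricting allowed lesion centres.
#' @param seed integer seed for blob placement.
#' @return list(volume = lesioned `gm_volume`, lesion_mask = `region_mask`).
#' @export
implant_lesions <- function(volume, lesion_spec, brain_mask, seed = 1L) {
  stopifnot(inherits(volume, "gm_volume"), inherits(brain_mask, "region_mask"))
  stop_if_grid_mismatch(volume, brain_mask)
  n <- lesion_spec$n_lesions %||% 0L
  mask_arr <- array(0L, dim(volume$data))
  if (n == 0L)
    return(list(volume = volume,
                lesion_mask = region_mask(mask_arr, "lesions", volume$affine,
                                          volume$voxel_size_mm)))
  radius <- lesion_spec$radius_mm %||% 3
  offset <- lesion_spec$offset %||% -0.3
  inside <- which(brain_mask$data == 1L)
  if (length(inside) == 0L) stop("brain mask is empty")
  # candidate centres: voxels whose whole blob fits inside the mask
  # (erosion of the mask by the blob's voxel offsets)
  d <- dim(volume$data)
  rv <- ceiling(radius / volume$voxel_size_mm)
  box <- 2L * rv + 3L
  ctr0 <- rv + 2L
  offs <- arrayInd(which(sphere_mask_array(box, ctr0, radius,
                                           volume$voxel_size_mm) == 1L), box)
  offs <- sweep(offs, 2L, ctr0, "-")
  fits <- array(TRUE, d)
  for (r in seq_len(nrow(offs))) {
    sh <- shift_logical(brain_mask$data == 1L, offs[r, ])
    fits <- fits & sh
  }
  candidates <- which(fits)
  if (length(candidates) < n)
    stop("lesion blob extends outside the brain mask (no fitting placement)")
  withr::with_seed(seed, {
    centers <- arrayInd(sample(candidates, n), d)
  })
  for (b in seq_len(n)) {
    blob <- sphere_mask_array(d, centers[b, ], radius, volume$voxel_size_mm)
    if (any(blob == 1L & brain_mask$data == 0L))
      stop("lesion blob extends outside the brain mask")
    mask_arr[blob == 1L] <- 1L
  }
  volume$data[mask_arr == 1L] <- volume$data[mask_arr == 1L] + offset
  list(volume = volume,
       lesion_mask = region_mask(mask_arr, "lesions", volume$affine,
                                 volume$voxel_size_mm))
}

#' In-paint lesions from the normal-appearing tissue distribution
#'
#' Each lesion voxel is replaced by an independent draw from a Gaussian
#' fitted (mean, SD) to the intensities of a reference mask of
#' normal-appearing tissue; voxels outside the lesion mask are untouched.
#'
#' @param volume a `gm_volume`.
#' @param lesion_mask `region_mask` of voxels to fill.
#' @param reference_mask non-empty `region_mask` of normal-appearing tissue,
#'   disjoint from the lesions.
#' @param seed integer seed for the fill draws.
#' @return The in-painted `gm_volume`.
#' @export
inpaint_lesions <- function(volume, lesion_mask, reference_mask, seed = 1L) {
  stopifnot(inherits(volume, "gm_volume"),
            inherits(lesion_mask, "region_mask"),
            inherits(reference_mask, "region_mask"))
  stop_if_grid_mismatch(volume, lesion_mask)
  stop_if_grid_mismatch(volume, reference_mask)
  ref_idx <- which(reference_mask$data == 1L)
  if (length(ref_idx) == 0L) stop("reference mask is empty")
  les_idx <- which(lesion_mask$data == 1L)
  if (any(reference_mask$data[les_idx] == 1L))
    stop("reference mask overlaps the lesion mask")
  if (length(les_idx) == 0L) return(volume)
  ref <- volume$data[ref_idx]
  mu <- mean(ref)
  sd_ref <- if (length(ref) > 1L) stats::sd(ref) else 0
  withr::with_seed(seed, {
    volume$data[les_idx] <- stats::rnorm(length(les_idx), mu, sd_ref)
  })
  volume
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Logical array shifted by an integer voxel offset; out-of-range is FALSE.
# shift_logical(x, o)[i] == x[i + o] where defined.
shift_logical <- function(x, off) {
  d <- dim(x)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    dst[[a]] <- max(1L, 1L - off[a]):min(d[a], d[a] - off[a])
    src[[a]] <- dst[[a]] + off[a]
    if (length(dst[[a]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}
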