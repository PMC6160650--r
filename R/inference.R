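# Multiple-testing control on voxelwise p-maps and cluster reporting.

#' Benjamini-Hochberg step-up FDR control
#'
#' Over the m in-mask p-values, finds the largest k with
#' p_(k) <= k q / m and declares every voxel with p <= p_(k) significant
#' (none when no such k exists). Implemented directly as the step-up scan;
#' the package's tests cross-check it against `stats::p.adjust`.
#'
#' @param p_values vector of one-sided p-values in (0, 1].
#' @param q target false discovery rate (default 0.05).
#' @return list: `significant` (logical vector), `threshold` (the adaptive
#'   p cutoff, 0 when nothing is declared), `n_significant`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  m <- length(p_values)
  ps <- sort(p_values)
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0L) {
    return(list(significant = rep(FALSE, m), threshold = 0,
                n_significant = 0L))
  }
  thr <- ps[max(ok)]
  sig <- p_values <= thr
  list(significant = sig, threshold = thr, n_significant = sum(sig))
}

# Neighbour offsets for 6 (faces), 18 (faces+edges), 26 (faces+edges+
# corners) connectivity.
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

# Connected-component labelling over the nonzero voxels of a 3D mask,
# breadth-first with vectorized frontier expansion.
label_components <- function(mask_arr, connectivity = 26L) {
  d <- dim(mask_arr)
  idx <- which(mask_arr != 0)
  labels <- array(0L, d)
  if (length(idx) == 0L) return(labels)
  offs <- connectivity_offsets(connectivity)
  coords <- arrayInd(idx, d)
  inside <- array(FALSE, d); inside[idx] <- TRUE
  lab_of <- stats::setNames(rep(0L, length(idx)), idx)
  next_lab <- 0L
  unvisited <- array(FALSE, d); unvisited[idx] <- TRUE
  for (start in idx) {
    if (!unvisited[start]) next
    next_lab <- next_lab + 1L
    frontier <- start
    unvisited[start] <- FALSE
    labels[start] <- next_lab
    while (length(frontier) > 0L) {
      fc <- arrayInd(frontier, d)
      nb <- matrix(0L, nrow = nrow(fc) * nrow(offs), ncol = 3L)
      for (a in 1:3) nb[, a] <- rep(fc[, a], each = nrow(offs)) + offs[, a]
      valid <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
               nb[, 2] >= 1L & nb[, 2] <= d[2] &
               nb[, 3] >= 1L & nb[, 3] <= d[3]
      nb <- nb[valid, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * d[1] +
                    (nb[, 3] - 1L) * d[1] * d[2])
      lin <- lin[unvisited[lin]]
      unvisited[lin] <- FALSE
      labels[lin] <- next_lab
      frontier <- lin
    }
  }
  labels
}

#' Extract suprathreshold clusters into a report table
#'
#' Connected components of the significance mask under the chosen
#' connectivity; each cluster is reported with its voxel count, volume in ml,
#' the world (mm) coordinate of its peak (maximum Z; ties broken at the
#' smallest linear index), and the peak Z, sorted by size descending --
#' mirroring the conventional VBM cluster table.
#'
#' @param sig_mask `region_mask` of significant voxels.
#' @param z_map `stat_map` (its `z` array locates peaks) on the same grid.
#' @param connectivity 6, 18 or 26 (default 26, the SPM-like convention).
#' @return list of class `cluster_table`: `table` (data.frame with columns
#'   label, x_mm, y_mm, z_mm, size_voxels, size_ml, peak_z) and `labels`
#'   (3D integer array of cluster ids).
#' @export
extract_clusters <- function(sig_mask, z_map, connectivity = 26L) {
  stopifnot(inherits(sig_mask, "region_mask"))
  if (!all(dim(sig_mask$data) == z_map$grid) ||
      max(abs(sig_mask$affine - z_map$affine)) > 1e-4)
    stop("significance mask and z-map are not on the same grid")
  labels <- label_components(sig_mask$data, connectivity)
  n_clust <- max(labels)
  if (n_clust == 0L) {
    tab <- data.frame(label = character(0), x_mm = numeric(0),
                      y_mm = numeric(0), z_mm = numeric(0),
                      size_voxels = integer(0), size_ml = numeric(0),
                      peak_z = numeric(0))
    return(structure(list(table = tab, labels = labels),
                     class = "cluster_table"))
  }
  rows <- lapply(seq_len(n_clust), function(k) {
    vox <- which(labels == k)  # ascending linear index
    zv <- z_map$z[vox]
    zv[is.na(zv)] <- -Inf
    peak <- vox[which.max(zv)]  # which.max takes the first maximum
    xyz <- voxel_to_world(arrayInd(peak, dim(labels)), sig_mask$affine)
    data.frame(label = "", x_mm = xyz[1], y_mm = xyz[2], z_mm = xyz[3],
               size_voxels = length(vox),
               size_ml = voxels_to_ml(length(vox), sig_mask$voxel_size_mm),
               peak_z = max(zv))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$size_voxels), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, labels = labels), class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat("cluster_table:", nrow(x$table), "clusters,",
      sum(x$table$size_voxels), "voxels total\n")
  if (nrow(x$table)) print(format(x$table, digits = 3), ...)
  invisible(x)
}

#' Intersection of two region masks
#'
#' @param mask_a,mask_b `region_mask` objects on the same grid.
#' @return `region_mask` of the voxelwise logical AND, named
#'   "<a> & <b>".
#' @export
region_overlap <- function(mask_a, mask_b) {
  stopifnot(inherits(mask_a, "region_mask"), inherits(mask_b, "region_mask"))
  stop_if_grid_mismatch(mask_a, mask_b)
  region_mask(array(as.integer(mask_a$data & mask_b$data), dim(mask_a$data)),
              paste(mask_a$name, "&", mask_b$name),
              mask_a$affine, mask_a$voxel_size_mm)
}
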