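#' Threshold segmentation into connected components
#'
#' Voxels with intensity in `[threshold_low, threshold_high]` are grouped
#' into 26-connected components.  Components are labelled `1, 2, ...` in
#' descending size order (ties broken by the lexicographically smallest
#' member voxel index) and components smaller than `min_size` voxels are
#' discarded.  26-connectivity is used deliberately: square fiducials
#' voxelized on tilted surfaces can become corner-connected, and the
#' permissive connectivity keeps them single components.
#'
#' @param volume a [voxel_volume()].
#' @param threshold_low,threshold_high inclusive intensity band;
#'   `threshold_low < threshold_high` required.
#' @param min_size minimum component size in voxels (default 4; use 1 when
#'   segmenting few-voxel implanted markers).
#' @return A `label_map`: list with `labels` (3-D integer array, 0 =
#'   background), `sizes` (voxel counts per kept label), `spacing`,
#'   `origin`.  An empty band yields a `label_map` with zero components.
#' @export
segment <- function(volume, threshold_low, threshold_high, min_size = 4) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!(threshold_low < threshold_high))
    stop("threshold_low must be < threshold_high")
  dims <- dim(volume$data)
  raw <- .label_components_26(as.numeric(volume$data), as.integer(dims),
                              threshold_low, threshold_high)
  n_raw <- attr(raw, "n_components")
  if (n_raw == 0) {
    labels <- array(0L, dims)
  } else {
    sizes <- tabulate(raw, nbins = n_raw)
    first_idx <- rep(NA_integer_, n_raw)
    nz <- which(raw > 0L)
    # first (lexicographically smallest) member index per raw label
    first_idx[raw[nz[!duplicated(raw[nz])]]] <-
      nz[!duplicated(raw[nz])]
    keep <- which(sizes >= min_size)
    ord <- keep[order(-sizes[keep], first_idx[keep])]
    remap <- integer(n_raw)
    remap[ord] <- seq_along(ord)
    labels <- array(0L, dims)
    labels[nz] <- remap[raw[nz]]
    sizes <- sizes[ord]
  }
  structure(list(labels = labels,
                 sizes = if (n_raw > 0) sizes else integer(0),
                 spacing = volume$spacing, origin = volume$origin),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map>", length(x$sizes), "components;",
      if (length(x$sizes)) paste("sizes", paste(utils::head(x$sizes, 8),
                                                collapse = ", ")) else "",
      "\n")
  invisible(x)
}

#' Number of components in a label map
#' @param labelmap a `label_map`.
#' @return Integer count.
#' @export
n_components <- function(labelmap) length(labelmap$sizes)

label_world_coords <- function(labelmap, label) {
  idx_flat <- which(labelmap$labels == label)
  if (!length(idx_flat)) stop("label ", label, " absent from label map")
  d <- dim(labelmap$labels)
  i <- (idx_flat - 1L) %% d[1]
  j <- ((idx_flat - 1L) %/% d[1]) %% d[2]
  k <- (idx_flat - 1L) %/% (d[1] * d[2])
  index_to_world(labelmap, cbind(i, j, k))
}

#' Geometric centre of a segmented component
#'
#' The unweighted centroid of the member voxels' world coordinates — the
#' accuracy reference point for targets.  (Intensity weighting would be a
#' no-op here because synthetic classes are homogeneous.)
#'
#' @param labelmap a `label_map`.
#' @param label positive component label.
#' @return length-3 world coordinate (mm).
#' @export
target_centre <- function(labelmap, label) {
  colMeans(label_world_coords(labelmap, label))
}

#' Marker frame by principal component analysis
#'
#' Centroid and principal axes of a segmented marker's voxel cloud.  Axes
#' are the eigenvectors of the 3x3 covariance of member-voxel world
#' coordinates, ordered by descending eigenvalue; for a thin slab fiducial
#' the third (smallest-variance) axis is the surface normal.  Signs are
#' fixed to make frames reproducible: the normal points away from
#' `interior_point` (the body centroid), the first axis has positive dot
#' product with world +x (tie-break +y), and the frame is right-handed.
#'
#' @param labelmap a `label_map`.
#' @param label component label; must have >= 4 voxels.
#' @param interior_point reference point the normal must face away from
#'   (default the origin-side centroid of all labelled voxels' volume — pass
#'   the envelope centre for scene work).
#' @return A `marker_frame`: list with `centroid` (mm), `axes` (3x3, columns
#'   = axes), `eigenvalues` (mm^2, descending).
#' @export
extract_marker_frame <- function(labelmap, label, interior_point = c(0, 0, 0)) {
  W <- label_world_coords(labelmap, label)
  if (nrow(W) < 4)
    stop("degeneracy error: label ", label, " has fewer than 4 voxels")
  ctr <- colMeans(W)
  e <- eigen(stats::cov(W), symmetric = TRUE)
  axes <- e$vectors          # columns, descending eigenvalue
  evals <- pmax(e$values, 0)
  # sign conventions
  outward <- ctr - interior_point
  if (sum(axes[, 3] * outward) < 0) axes[, 3] <- -axes[, 3]
  a1 <- axes[, 1]
  if (abs(a1[1]) > 1e-12) {
    if (a1[1] < 0) axes[, 1] <- -axes[, 1]
  } else if (a1[2] < 0) axes[, 1] <- -axes[, 1]
  axes[, 2] <- cross3(axes[, 3], axes[, 1])  # right-handed completion
  structure(list(centroid = ctr, axes = axes, eigenvalues = evals,
                 n_voxels = nrow(W)),
            class = "marker_frame")
}

#' @export
print.marker_frame <- function(x, ...) {
  cat("<marker_frame> centroid", paste(round(x$centroid, 2), collapse = ", "),
      "mm; eigenvalues", paste(signif(x$eigenvalues, 3), collapse = ", "),
      "mm^2\n")
  invisible(x)
}

#' Export a label map in NIfTI-1
#' @param labelmap a `label_map`.
#' @param path output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labelmap, path) {
  write_nifti(labelmap, path, datatype = "int32")
}

#' Tabulate marker frames of every component
#'
#' Convenience wrapper running [extract_marker_frame()] (falling back to the
#' bare centroid for components of fewer than 4 voxels) over all labels.
#'
#' @param labelmap a `label_map`.
#' @param interior_point see [extract_marker_frame()].
#' @return data.frame with label, size, centroid, axes and eigenvalues.
#' @export
marker_frame_table <- function(labelmap, interior_point = c(0, 0, 0)) {
  n <- n_components(labelmap)
  rows <- lapply(seq_len(n), function(l) {
    if (labelmap$sizes[l] >= 4) {
      mf <- extract_marker_frame(labelmap, l, interior_point)
      data.frame(label = l, n_voxels = mf$n_voxels,
                 cx = mf$centroid[1], cy = mf$centroid[2], cz = mf$centroid[3],
                 nx = mf$axes[1, 3], ny = mf$axes[2, 3], nz = mf$axes[3, 3],
                 ev1 = mf$eigenvalues[1], ev2 = mf$eigenvalues[2],
                 ev3 = mf$eigenvalues[3])
    } else {
      ctr <- target_centre(labelmap, l)
      data.frame(label = l, n_voxels = labelmap$sizes[l],
                 cx = ctr[1], cy = ctr[2], cz = ctr[3],
                 nx = NA_real_, ny = NA_real_, nz = NA_real_,
                 ev1 = NA_real_, ev2 = NA_real_, ev3 = NA_real_)
    }
  })
  do.call(rbind, rows)
}
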