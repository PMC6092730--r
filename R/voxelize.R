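#' CT-like voxel volumes
#'
#' A `voxel_volume` is a 3-D scalar grid with isotropic-or-not spacing and a
#' world origin, under the voxel-centre convention: the world coordinate of
#' 0-based index `(i, j, k)` is `origin + (i, j, k) * spacing`.  Intensities
#' are HU-like class values; no acquisition physics is modelled.
#'
#' @param data 3-D numeric array.
#' @param spacing length-3 positive voxel spacing (mm/voxel).
#' @param origin length-3 world position of the first voxel centre (mm).
#' @return A `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, all(spacing > 0),
            length(origin) == 3L)
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume>", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(x$spacing, collapse = "/"), "mm, origin",
      paste(round(x$origin, 2), collapse = ", "), "mm\n")
  invisible(x)
}

#' Convert between voxel indices and world coordinates
#'
#' Indices are 0-based, per the voxel-centre convention.
#'
#' @param volume a `voxel_volume` (or `label_map`).
#' @param idx N x 3 matrix of 0-based indices.
#' @param pts N x 3 matrix of world points (mm).
#' @return The mapped N x 3 matrix.
#' @export
index_to_world <- function(volume, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx, 2, volume$spacing, `*`), 2, volume$origin, `+`)
}

#' @rdname index_to_world
#' @export
world_to_index <- function(volume, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  sweep(sweep(pts, 2, volume$origin, `-`), 2, volume$spacing, `/`)
}

#' Default HU-like intensities per voxel class
#'
#' Air -1000, soft tissue 40, target 300, radiopaque fiducial 3000 — spaced
#' so single-threshold bands are unambiguous.
#' @return Named numeric vector.
#' @export
default_intensity_map <- function() {
  c(air = -1000, tissue = 40, target = 300, fiducial = 3000)
}

#' Intensity bands for segmentation
#'
#' Half-way cut points between the class intensities of
#' [default_intensity_map()].
#' @param class `"fiducial"`, `"target"` or `"tissue"`.
#' @param intensity_map named vector as from [default_intensity_map()].
#' @return length-2 `c(low, high)` band.
#' @export
intensity_band <- function(class = c("fiducial", "target", "tissue"),
                           intensity_map = default_intensity_map()) {
  class <- match.arg(class)
  im <- sort(intensity_map)
  i <- match(class, names(im))
  lo <- if (i == 1) -Inf else mean(im[c(i - 1, i)])
  hi <- if (i == length(im)) Inf else mean(im[c(i, i + 1)])
  c(lo, hi)
}

# encode scene targets as rasterizer shape lists
target_shape <- function(tg) {
  if (inherits(tg, "sphere_lesion")) {
    list(type = "sphere", centre = tg$centre, radius = tg$diameter / 2)
  } else if (inherits(tg, "point_target")) {
    list(type = "ellipsoid", centre = tg$centre,
         semi_axes = tg$extent / 2,
         axis1 = c(1, 0, 0), axis2 = c(0, 1, 0), axis3 = c(0, 0, 1))
  } else if (inherits(tg, "bar_target")) {
    ax <- tg$endpoint_b - tg$endpoint_a
    len <- sqrt(sum(ax^2))
    list(type = "cylinder", centre = tg$centre, axis = ax / len,
         half_length = len / 2, radius = tg$radius)
  } else stop("unknown target type")
}

#' Voxelize a scene into a CT-like volume
#'
#' Rasterises the body envelope (soft-tissue class), the targets (target
#' class) and the square fiducials (radiopaque class) over an air background
#' by a voxel-centre-inside-solid test.  Where solids overlap, the
#' precedence is fiducial > target > tissue > air (enforced by class-code
#' ordering; not an error).  The grid covers the envelope plus a margin and
#' its origin lies on the integer-mm lattice, so integer-mm scene
#' coordinates coincide with voxel centres at 1 mm (and 0.5 mm) spacing.
#'
#' @param scene a `scene_spec` (an empty scene yields an all-air volume).
#' @param spacing isotropic voxel spacing in mm, in `[0.5, 3]`.
#' @param intensity_map named class intensities, see
#'   [default_intensity_map()].
#' @param margin_mm world margin added around the envelope (default 10).
#' @return A `voxel_volume` of intensities.
#' @export
voxelize <- function(scene, spacing = 1,
                     intensity_map = default_intensity_map(),
                     margin_mm = 10) {
  stopifnot(spacing >= 0.5, spacing <= 3)
  env <- scene$envelope
  lo <- floor(env$centre - env$semi_axes - margin_mm)
  hi <- ceiling(env$centre + env$semi_axes + margin_mm)
  dims <- as.integer(floor((hi - lo) / spacing)) + 1L
  origin <- lo
  cls <- .rasterize_envelope(dims, origin, rep(spacing, 3), env$centre,
                             env$semi_axes, env$exponent)
  if (length(scene$targets))
    .rasterize_solids(cls, dims, origin, rep(spacing, 3),
                      lapply(scene$targets, target_shape), 2L)
  if (length(scene$fiducials))
    .rasterize_solids(cls, dims, origin, rep(spacing, 3),
                      lapply(scene$fiducials, function(f)
                        list(type = "slab", centre = f$centre,
                             axis1 = f$axis1, axis2 = f$axis2,
                             normal = f$normal, edge = f$edge,
                             thickness = f$thickness)), 3L)
  lut <- unname(intensity_map[c("air", "tissue", "target", "fiducial")])
  arr <- lut[cls + 1L]
  dim(arr) <- dims
  voxel_volume(arr, rep(spacing, 3), origin)
}

#' Make an empty (all-air) scene for testing
#'
#' @param envelope_mm full widths of a nominal bounding envelope (mm); the
#'   scene has no fiducials and no targets and rasterises to tissue-only or,
#'   with `tissue = FALSE`, to pure air.
#' @param tissue include the body envelope?
#' @return A `scene_spec`.
#' @export
empty_scene <- function(envelope_mm = c(100, 80, 60), tissue = TRUE) {
  env <- superellipsoid(envelope_mm / 2, exponent = 3)
  if (!tissue) env$semi_axes <- env$semi_axes * 1e-6
  new_scene("empty", env, list(), list(), needle_assembly(),
            rigid_identity(), matrix(0, 0, 3), 0L)
}
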