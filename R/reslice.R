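#' Region of interest around the labelled foreground
#'
#' The tight bounding box of the label's foreground voxels, expanded by a
#' margin on each side of every axis and clamped to the volume bounds. The
#' default margin of 15 voxels reproduces the boundary the raters placed
#' around the CMC1 joint when cropping clinical volumes.
#'
#' @param label A [label_volume()] with at least one foreground voxel.
#' @param margin Non-negative integer margin in voxels, recycled to the three
#'   axes `(z, y, x)`.
#' @return A [us_roi()] (1-based inclusive bounds).
#' @export
roi_from_label <- function(label, margin = 15L) {
  stopifnot(inherits(label, "label_volume"))
  margin <- as.integer(rep_len(margin, 3L))
  if (any(margin < 0L)) stop("margin must be >= 0", call. = FALSE)
  idx <- which(label$voxels != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("cannot build an ROI from an empty label", call. = FALSE)
  d <- dim(label$voxels)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  us_roi(lo, hi)
}

#' Crop a volume or label to a region of interest
#'
#' Returns the sub-grid over the (inclusive) ROI bounds; the physical origin
#' is shifted so cropped voxels keep their world coordinates.
#'
#' @param volume A [us_volume()] or [label_volume()].
#' @param roi A [us_roi()] lying within the volume bounds.
#' @return The same class as `volume`.
#' @export
crop_volume <- function(volume, roi) {
  stopifnot(inherits(volume, "us_volume"), inherits(roi, "us_roi"))
  d <- dim(volume$voxels)
  if (any(roi$hi > d))
    stop("roi exceeds the volume bounds", call. = FALSE)
  sub <- volume$voxels[roi$lo[1]:roi$hi[1],
                       roi$lo[2]:roi$hi[2],
                       roi$lo[3]:roi$hi[3], drop = FALSE]
  # origin is (x0, y0, z0) while indices are (z, y, x)
  shift <- (roi$lo - 1L) * volume$spacing[c(3, 2, 1)]
  origin <- volume$origin + shift[c(3, 2, 1)]
  if (inherits(volume, "label_volume")) label_volume(sub, volume$spacing, origin)
  else us_volume(sub, volume$spacing, origin)
}

#' Evenly spaced slice indices spanning a depth
#'
#' `n` integer z-indices spanning `[1, depth]`, endpoints included, spaced
#' evenly and rounded half-up; `n = 1` degenerates to the first slice.
#'
#' @param depth Volume depth (number of transverse planes).
#' @param n Number of slices, `1 <= n <= depth`.
#' @return Strictly increasing integer vector of length `n`.
#' @export
even_slice_indices <- function(depth, n) {
  depth <- as.integer(depth); n <- as.integer(n)
  if (n < 1L || n > depth)
    stop(sprintf("n_slices must be between 1 and the volume depth (%d)", depth),
         call. = FALSE)
  if (n == 1L) return(1L)
  as.integer(floor((seq_len(n) - 1) * (depth - 1) / (n - 1) + 0.5)) + 1L
}

#' Reslice a volume into transverse 2D planes
#'
#' Extracts `n_slices` native transverse planes at evenly spaced integer
#' z-indices spanning the full depth (first and last plane included). No
#' interpolation is performed, so resliced label planes stay binary.
#'
#' @param volume A [us_volume()] or [label_volume()].
#' @param n_slices Number of planes to extract; the clinical protocol used
#'   8-15 per volume.
#' @return A [slice_stack()].
#' @export
reslice <- function(volume, n_slices) {
  stopifnot(inherits(volume, "us_volume"))
  d <- dim(volume$voxels)
  idx <- even_slice_indices(d[1], n_slices)
  images <- lapply(idx, function(i) volume$voxels[i, , ])
  slice_stack(images, idx,
              in_plane_spacing = volume$spacing[c(1, 2)],
              slice_spacing = volume$spacing[3],
              parent_depth = d[1], origin = volume$origin)
}

#' Re-stack 2D masks into a 3D label volume
#'
#' Places one binary mask per stack slice back at its known z-index in the
#' parent grid; all other planes are zero.
#'
#' @param stack The [slice_stack()] the masks correspond to.
#' @param masks List of binary matrices, one per stack slice, same shape as
#'   the stack images.
#' @param parent_shape Optional `(nz, ny, nx)`; defaults to the stack's
#'   parent geometry.
#' @return A [label_volume()].
#' @export
restack <- function(stack, masks, parent_shape = NULL) {
  stopifnot(inherits(stack, "slice_stack"))
  if (length(masks) != length(stack$images))
    stop(sprintf("expected %d masks, got %d", length(stack$images), length(masks)),
         call. = FALSE)
  shp <- dim(stack$images[[1]])
  ok <- vapply(masks, function(m) is.matrix(m) && identical(dim(m), shp), logical(1))
  if (!all(ok)) stop("mask shapes must match the stack images", call. = FALSE)
  if (is.null(parent_shape)) parent_shape <- c(stack$parent_depth, shp)
  parent_shape <- as.integer(parent_shape)
  vox <- array(0, parent_shape)
  for (k in seq_along(masks)) {
    vox[stack$slice_indices[k], , ] <- as.numeric(masks[[k]] != 0)
  }
  label_volume(vox,
               spacing = c(stack$in_plane_spacing, stack$slice_spacing),
               origin = stack$origin)
}

#' Seeded train/test split at the 3D-volume level
#'
#' Partitions volume identifiers into training and testing sets. The split is
#' made per 3D volume, never per slice, so no slice of one volume can appear
#' in both sets. `round(train_fraction * n)` ids go to training.
#'
#' @param volume_ids Vector of at least two unique identifiers.
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return List with elements `train` and `test`.
#' @export
split_by_volume <- function(volume_ids, train_fraction = 0.8, seed = 1L) {
  if (length(volume_ids) < 2L)
    stop("need at least 2 volume ids to split", call. = FALSE)
  if (anyDuplicated(volume_ids)) stop("volume ids must be unique", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  n <- length(volume_ids)
  n_train <- as.integer(floor(train_fraction * n + 0.5))
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- with_seed(seed, sample.int(n))
  list(train = volume_ids[sort(perm[seq_len(n_train)])],
       test = volume_ids[sort(perm[(n_train + 1L):n])])
}

# Run code under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
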