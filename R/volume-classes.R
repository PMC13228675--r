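#' Construct an ultrasound volume
#'
#' A 3D greyscale ultrasound volume with anisotropic voxel spacing. Voxels are
#' stored as a 3D array in `(z, y, x)` index order: the first index walks the
#' transverse slices along the probe sweep, the second the image rows (depth
#' within a slice), the third the image columns. Intensities are expected in
#' `[0, 1]`; [load_volume()] min-max normalizes at load time.
#'
#' @param voxels 3D numeric array, dimensions `(nz, ny, nx)`.
#' @param spacing Numeric length 3, voxel size in mm as `(dx, dy, dz)`:
#'   in-plane column spacing, in-plane row spacing, inter-slice spacing.
#'   Defaults to the 0.114 x 0.114 x 0.333 mm grid of the mechanically swept
#'   linear-transducer system the package targets.
#' @param origin Numeric length 3, physical position in mm of voxel
#'   `[1, 1, 1]`, as `(x0, y0, z0)`.
#' @return An object of class `us_volume`.
#' @export
us_volume <- function(voxels, spacing = c(0.114, 0.114, 0.333),
                      origin = c(0, 0, 0)) {
  voxels <- as_voxel_array(voxels)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, length(origin) == 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be strictly positive", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "us_volume")
}

#' Construct a binary label volume
#'
#' Voxel-wise membership of the synovial region (ground truth or prediction),
#' sharing the grid, spacing and origin of its paired [us_volume()].
#'
#' @param voxels 3D array coercible to 0/1.
#' @inheritParams us_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing = c(0.114, 0.114, 0.333),
                         origin = c(0, 0, 0)) {
  voxels <- as_voxel_array(voxels)
  u <- unique(as.vector(voxels))
  if (!all(u %in% c(0, 1)))
    stop("label voxels must be 0/1", call. = FALSE)
  v <- us_volume(voxels, spacing, origin)
  class(v) <- c("label_volume", "us_volume")
  v
}

as_voxel_array <- function(voxels) {
  if (is.logical(voxels)) voxels <- array(as.numeric(voxels), dim(voxels))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array (z, y, x)", call. = FALSE)
  if (any(dim(voxels) < 1L)) stop("each dimension must be >= 1", call. = FALSE)
  voxels
}

#' @export
print.us_volume <- function(x, ...) {
  d <- dim(x$voxels)
  kind <- if (inherits(x, "label_volume")) "label_volume" else "us_volume"
  cat(sprintf("<%s> %d x %d x %d (z,y,x), spacing %.3f x %.3f x %.3f mm (dx,dy,dz)\n",
              kind, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  if (inherits(x, "label_volume")) {
    cat(sprintf("  foreground voxels: %d (%.2f mm^3)\n",
                sum(x$voxels), label_voxel_volume_mm3(x)))
  }
  invisible(x)
}

#' @export
dim.us_volume <- function(x) dim(x$voxels)

#' Voxel-count volume of a label in mm^3
#'
#' Foreground voxel count times the voxel volume `dx * dy * dz`; the
#' voxel-counting estimate of synovial tissue volume, used as the independent
#' cross-check for mesh enclosed volumes.
#'
#' @param label A `label_volume`.
#' @return Volume in mm^3.
#' @export
label_voxel_volume_mm3 <- function(label) {
  stopifnot(inherits(label, "label_volume"))
  sum(label$voxels) * prod(label$spacing)
}

#' Construct a region of interest
#'
#' Axis-aligned voxel-index box, 1-based inclusive bounds per axis in
#' `(z, y, x)` order.
#'
#' @param lo,hi Integer length 3, lower/upper bounds (inclusive) per axis.
#' @return An object of class `us_roi`.
#' @export
us_roi <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(length(lo) == 3, length(hi) == 3)
  if (any(lo < 1L) || any(hi < lo))
    stop("roi bounds must satisfy 1 <= lo <= hi on each axis", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "us_roi")
}

#' Construct a transverse slice stack
#'
#' An ordered set of 2D transverse planes extracted from a parent volume.
#' Each image is a `(ny, nx)` matrix; `slice_indices` are the (strictly
#' increasing, 1-based) z indices of the planes in the parent volume.
#'
#' @param images List of 2D matrices, all the same shape.
#' @param slice_indices Integer vector, one per image.
#' @param in_plane_spacing Numeric length 2, `(dx, dy)` in mm.
#' @param slice_spacing Inter-slice spacing `dz` in mm of the parent grid.
#' @param parent_depth Number of slices of the parent volume.
#' @param origin Physical origin of the parent volume.
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(images, slice_indices, in_plane_spacing,
                        slice_spacing, parent_depth,
                        origin = c(0, 0, 0)) {
  slice_indices <- as.integer(slice_indices)
  stopifnot(is.list(images), length(images) == length(slice_indices))
  if (length(images) < 1L) stop("stack must contain at least one slice", call. = FALSE)
  if (any(diff(slice_indices) <= 0L))
    stop("slice_indices must be strictly increasing", call. = FALSE)
  if (min(slice_indices) < 1L || max(slice_indices) > parent_depth)
    stop("slice_indices must lie within the parent volume depth", call. = FALSE)
  shp <- dim(images[[1]])
  ok <- vapply(images, function(im) is.matrix(im) && identical(dim(im), shp), logical(1))
  if (!all(ok)) stop("all slice images must share the same 2D shape", call. = FALSE)
  structure(list(images = images, slice_indices = slice_indices,
                 in_plane_spacing = as.numeric(in_plane_spacing),
                 slice_spacing = as.numeric(slice_spacing),
                 parent_depth = as.integer(parent_depth),
                 origin = as.numeric(origin)),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  shp <- dim(x$images[[1]])
  cat(sprintf("<slice_stack> %d transverse slices of %d x %d (y,x), z-indices %s\n",
              length(x$images), shp[1], shp[2],
              paste(range(x$slice_indices), collapse = "..")))
  invisible(x)
}

#' @export
length.slice_stack <- function(x) length(x$images)

#' Physical z position (mm) of each slice in a stack
#' @param stack A `slice_stack`.
#' @return Numeric vector of z positions in mm.
#' @export
slice_z_mm <- function(stack) {
  stack$origin[3] + (stack$slice_indices - 1) * stack$slice_spacing
}
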