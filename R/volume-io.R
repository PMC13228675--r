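#' Load a 3D ultrasound volume from NIfTI or MetaImage
#'
#' Reads a volumetric image, takes spacing from the header, and min-max
#' normalizes intensities to `[0, 1]` (a constant volume is clamped, not
#' rescaled). The on-disk `(x, y, z)` axis order of both formats is permuted
#' to the package's `(z, y, x)` array convention.
#'
#' @param path Path to a `.nii`, `.nii.gz`, `.mha` or `.mhd` file.
#' @param normalize Min-max normalize intensities (default `TRUE`). Use
#'   `FALSE` for images already on a fixed scale.
#' @return A [us_volume()].
#' @seealso [load_label()], [save_volume()]
#' @export
load_volume <- function(path, normalize = TRUE) {
  raw <- read_volume_raw(path)
  v <- raw$voxels
  if (normalize) {
    rng <- range(v)
    if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1])
    else v <- pmin(pmax(v, 0), 1)
    dim(v) <- dim(raw$voxels)
  }
  us_volume(v, spacing = raw$spacing, origin = raw$origin)
}

#' Load a binary label volume
#'
#' As [load_volume()] but without intensity normalization; voxels are
#' binarized at 0.5 (manual segmentations are commonly stored as 0/255).
#'
#' @inheritParams load_volume
#' @return A [label_volume()].
#' @export
load_label <- function(path) {
  raw <- read_volume_raw(path)
  v <- raw$voxels
  thr <- if (max(v) > 1) max(v) / 2 else 0.5
  b <- array(as.numeric(v >= thr & v > 0), dim(v))
  label_volume(b, spacing = raw$spacing, origin = raw$origin)
}

#' Save a volume as NIfTI or MetaImage
#'
#' Format is chosen from the file extension (`.nii`/`.nii.gz`, `.mha`/`.mhd`).
#'
#' @param volume A [us_volume()] or [label_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "us_volume"))
  vx <- aperm(volume$voxels, c(3, 2, 1))  # back to on-disk (x, y, z)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vx)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mh[ad]$", path)) {
    write_metaimage(vx, volume$spacing, volume$origin, path)
  } else {
    stop(sprintf("unsupported volume format for '%s' (use .nii, .nii.gz, .mha or .mhd)",
                 path), call. = FALSE)
  }
  invisible(path)
}

read_volume_raw <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read volume '%s': file does not exist", path), call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop(sprintf(
                      "cannot read volume '%s': %s", path, conditionMessage(e)),
                      call. = FALSE))
    d <- dim(img)
    if (length(d) != 3L)
      stop(sprintf("cannot read volume '%s': expected a 3D image, got %dD",
                   path, length(d)), call. = FALSE)
    spacing <- RNifti::pixdim(img)[seq_len(3)]
    vox <- array(as.numeric(img), d)
  } else if (grepl("\\.mh[ad]$", path)) {
    m <- read_metaimage(path)
    vox <- m$voxels; spacing <- m$spacing
    return(list(voxels = aperm(vox, c(3, 2, 1)), spacing = spacing,
                origin = m$origin))
  } else {
    stop(sprintf("cannot read volume '%s': unsupported format", path), call. = FALSE)
  }
  list(voxels = aperm(vox, c(3, 2, 1)), spacing = spacing, origin = c(0, 0, 0))
}

# Minimal uncompressed MetaImage (.mha/.mhd) support. Header is plain
# key = value text; payload is raw little-endian voxel data, inline for .mha
# (ElementDataFile = LOCAL) or in a sidecar file for .mhd.
mha_types <- c(MET_UCHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
               MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop(sprintf("cannot read volume '%s': truncated MetaImage header", path),
           call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) next
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr[["NDims"]] %||% "0")
  if (ndims != 3L)
    stop(sprintf("cannot read volume '%s': expected a 3D image, got %dD",
                 path, ndims), call. = FALSE)
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  etype <- hdr[["ElementType"]] %||% "MET_FLOAT"
  if (!etype %in% names(mha_types))
    stop(sprintf("cannot read volume '%s': unsupported ElementType %s", path, etype),
         call. = FALSE)
  n <- prod(dims)
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    payload <- con
  } else {
    payload <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(payload), add = TRUE)
  }
  sz <- mha_types[[etype]]
  what <- if (etype %in% c("MET_FLOAT", "MET_DOUBLE")) "numeric" else "integer"
  signed <- !etype %in% c("MET_UCHAR", "MET_USHORT")
  v <- readBin(payload, what = what, n = n, size = sz, signed = signed,
               endian = "little")
  if (length(v) != n)
    stop(sprintf("cannot read volume '%s': payload shorter than DimSize", path),
         call. = FALSE)
  list(voxels = array(as.numeric(v), dims), spacing = spacing, origin = origin)
}

write_metaimage <- function(vox_xyz, spacing, origin, path) {
  dims <- dim(vox_xyz)
  mhd <- grepl("\\.mhd$", path)
  datafile <- if (mhd) sub("\\.mhd$", ".raw", basename(path)) else "LOCAL"
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", dims[1], dims[2], dims[3]),
           sprintf("ElementSpacing = %.9g %.9g %.9g",
                   spacing[1], spacing[2], spacing[3]),
           sprintf("Offset = %.9g %.9g %.9g", origin[1], origin[2], origin[3]),
           "ElementType = MET_FLOAT",
           sprintf("ElementDataFile = %s", datafile))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  payload <- if (mhd) {
    pc <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(pc), add = TRUE)
    pc
  } else con
  writeBin(as.numeric(vox_xyz), payload, size = 4L, endian = "little")
  invisible(path)
}

#' Export a 2D slice or mask as 8-bit PNG
#'
#' Intensities in `[0, 1]` map to grey levels 0-255; mask foreground is
#' written as 255.
#'
#' @param image 2D matrix `(ny, nx)`, values in `[0, 1]`.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
save_slice_png <- function(image, path) {
  stopifnot(is.matrix(image))
  img <- pmin(pmax(image, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
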