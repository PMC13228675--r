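#' Construct a stitched triangle surface
#'
#' @param vertices Numeric matrix `V x 3` of `(x, y, z)` in mm.
#' @param faces Integer matrix `F x 3` of vertex indices (1-based),
#'   consistently oriented with outward normals.
#' @return An object of class `stitched_surface`.
#' @export
stitched_surface <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces),
            class = "stitched_surface")
}

#' @export
print.stitched_surface <- function(x, ...) {
  cat(sprintf("<stitched_surface> %d vertices, %d faces, watertight: %s\n",
              nrow(x$vertices), nrow(x$faces), mesh_is_watertight(x)))
  invisible(x)
}

mesh_edges <- function(surface) {
  f <- surface$faces
  rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
}

#' Is a surface watertight?
#'
#' A surface is watertight (closed and consistently oriented) when every
#' undirected edge is shared by exactly two faces and every directed edge
#' appears exactly once.
#'
#' @param surface A [stitched_surface()].
#' @return Logical scalar.
#' @export
mesh_is_watertight <- function(surface) {
  e <- mesh_edges(surface)
  directed <- paste(e[, 1], e[, 2])
  if (anyDuplicated(directed)) return(FALSE)
  und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(und) == 2L)
}

#' Euler characteristic V - E + F of a surface
#'
#' Equals 2 for a single closed genus-0 surface.
#'
#' @param surface A [stitched_surface()].
#' @return Integer.
#' @export
mesh_euler_characteristic <- function(surface) {
  e <- mesh_edges(surface)
  und <- unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(surface$vertices) - length(und) + nrow(surface$faces)
}

#' Stitch a stack of aligned contours into a closed surface
#'
#' Adjacent contour pairs are joined as quad strips (split into triangles)
#' after cyclic correspondence by [align_contours()]; the first and last
#' contours are capped by triangle fans to their centroids, closing the
#' ends of the volume. The output is watertight with consistent outward
#' face orientation.
#'
#' @param contours List of at least two [us_contour()] objects with strictly
#'   increasing `z` and a uniform point count (use [resample_contour()]).
#' @return A [stitched_surface()].
#' @export
stitch <- function(contours) {
  m <- length(contours)
  if (m < 2) stop("need at least 2 contours to stitch", call. = FALSE)
  ns <- vapply(contours, function(cc) nrow(cc$points), integer(1))
  if (length(unique(ns)) != 1)
    stop("all contours must share one point count; resample first", call. = FALSE)
  zs <- vapply(contours, function(cc) cc$z, numeric(1))
  if (any(diff(zs) <= 0))
    stop("contour z positions must be strictly increasing", call. = FALSE)
  n <- ns[1]
  # cumulative cyclic alignment so consecutive rings correspond point-wise
  aligned <- contours
  for (j in 2:m) {
    k <- align_contours(aligned[[j - 1]], aligned[[j]])
    aligned[[j]] <- rotate_contour(aligned[[j]], k)
  }
  verts <- do.call(rbind, lapply(aligned, function(cc)
    cbind(cc$points, cc$z)))
  c_bot <- c(colMeans(aligned[[1]]$points), aligned[[1]]$z)
  c_top <- c(colMeans(aligned[[m]]$points), aligned[[m]]$z)
  verts <- rbind(verts, c_bot, c_top)
  i_bot <- m * n + 1L
  i_top <- m * n + 2L
  faces <- vector("list", m + 1)
  nxt <- c(2:n, 1)
  for (j in seq_len(m - 1)) {
    a <- (j - 1) * n + seq_len(n)       # ring j
    b <- j * n + seq_len(n)             # ring j + 1
    faces[[j]] <- rbind(cbind(a, a[nxt], b[nxt]),
                        cbind(a, b[nxt], b))
  }
  a <- seq_len(n)
  faces[[m]] <- cbind(i_bot, a[nxt], a)                 # bottom cap (faces -z)
  b <- (m - 1) * n + seq_len(n)
  faces[[m + 1]] <- cbind(i_top, b, b[nxt])             # top cap (faces +z)
  dimnames(verts) <- NULL
  stitched_surface(verts, do.call(rbind, faces))
}

#' Enclosed volume of a watertight surface (mm^3)
#'
#' Signed sum of origin-tetrahedron volumes over the faces (divergence
#' theorem), returned as an absolute value; invariant to rigid motion.
#'
#' @param surface A [stitched_surface()]; must be watertight.
#' @return Volume in mm^3.
#' @export
enclosed_volume <- function(surface) {
  stopifnot(inherits(surface, "stitched_surface"))
  if (!mesh_is_watertight(surface))
    stop("surface is not watertight; enclosed volume is undefined", call. = FALSE)
  v <- surface$vertices
  f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(det6)) / 6
}

#' Reconstruct a surface and its enclosed volume from slice masks
#'
#' The full reconstruction pipeline: per-slice sub-pixel contour extraction,
#' largest-component selection, arc-length resampling, cyclic alignment,
#' quad-strip stitching and end capping, then enclosed-volume computation.
#' Leading/trailing empty slices are dropped. Interior empty slices are
#' bridged by stitching the two flanking contours directly across the gap
#' (a linear interpolation of the surface) when `interpolate_gaps = TRUE`;
#' otherwise the stack is split at gaps and the largest sub-surface is
#' reported.
#'
#' @param stack A [slice_stack()] providing slice geometry.
#' @param masks List of binary matrices, one per stack slice.
#' @param interpolate_gaps Bridge interior empty slices (default `TRUE`).
#' @param n_points Resampled points per contour (default 64).
#' @return List with `surface` (a [stitched_surface()]), `volume_mm3`,
#'   `warnings` (character vector describing dropped slices/components).
#' @export
masks_to_surface <- function(stack, masks, interpolate_gaps = TRUE,
                             n_points = 64L) {
  stopifnot(inherits(stack, "slice_stack"))
  if (length(masks) != length(stack$images))
    stop("one mask per stack slice is required", call. = FALSE)
  zmm <- slice_z_mm(stack)
  warnings <- character(0)
  contours <- vector("list", length(masks))
  for (k in seq_along(masks)) {
    cs <- extract_contours(masks[[k]], z = zmm[k],
                           spacing = stack$in_plane_spacing,
                           origin = stack$origin[c(1, 2)])
    if (length(cs) == 0) next
    if (length(cs) > 1)
      warnings <- c(warnings, sprintf(
        "slice %d: %d smaller component(s) dropped", stack$slice_indices[k],
        length(cs) - 1L))
    contours[[k]] <- resample_contour(largest_contour(cs), n_points)
  }
  nonempty <- which(!vapply(contours, is.null, logical(1)))
  if (length(nonempty) < 2)
    stop("fewer than 2 slices contain a segmentable region; cannot reconstruct",
         call. = FALSE)
  rng <- range(nonempty)
  dropped_ends <- setdiff(seq_along(masks), seq(rng[1], rng[2]))
  if (length(dropped_ends))
    warnings <- c(warnings, sprintf("empty end slice(s) dropped: %s",
                                    paste(stack$slice_indices[dropped_ends],
                                          collapse = ", ")))
  interior <- seq(rng[1], rng[2])
  gaps <- interior[vapply(contours[interior], is.null, logical(1))]
  if (length(gaps))
    warnings <- c(warnings, sprintf("interior empty slice(s) %s: %s",
                                    paste(stack$slice_indices[gaps], collapse = ", "),
                                    if (interpolate_gaps) "bridged" else "split"))
  if (interpolate_gaps || length(gaps) == 0) {
    surf <- stitch(contours[nonempty])
    vol <- enclosed_volume(surf)
  } else {
    runs <- split(nonempty, cumsum(c(0, diff(nonempty) > 1)))
    runs <- Filter(function(r) length(r) >= 2, runs)
    if (length(runs) == 0)
      stop("no contiguous run of 2+ segmented slices; cannot reconstruct",
           call. = FALSE)
    surfs <- lapply(runs, function(r) stitch(contours[r]))
    vols <- vapply(surfs, enclosed_volume, numeric(1))
    surf <- surfs[[which.max(vols)]]
    vol <- max(vols)
  }
  list(surface = surf, volume_mm3 = vol, warnings = warnings)
}

#' Reconstruct directly from a label volume
#'
#' Convenience wrapper: reslices a [label_volume()] densely (every plane)
#' and runs [masks_to_surface()].
#'
#' @param label A [label_volume()].
#' @inheritParams masks_to_surface
#' @return As [masks_to_surface()].
#' @export
label_to_surface <- function(label, interpolate_gaps = TRUE, n_points = 64L) {
  stopifnot(inherits(label, "label_volume"))
  stack <- reslice(label, dim(label$voxels)[1])
  masks_to_surface(stack, stack$images, interpolate_gaps, n_points)
}

#' Export a surface as ASCII OBJ or PLY
#'
#' @param surface A [stitched_surface()].
#' @param path Output path ending in `.obj` or `.ply`.
#' @return `path`, invisibly.
#' @export
save_surface <- function(surface, path) {
  stopifnot(inherits(surface, "stitched_surface"))
  v <- surface$vertices; f <- surface$faces
  if (grepl("\\.obj$", path)) {
    lines <- c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  } else if (grepl("\\.ply$", path)) {
    lines <- c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header",
               sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  } else {
    stop("unsupported mesh format (use .obj or .ply)", call. = FALSE)
  }
  writeLines(lines, path)
  invisible(path)
}
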