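#' Construct a slice contour
#'
#' A closed boundary polyline in physical in-plane coordinates. Points are
#' stored without repeating the first point; orientation is normalized to
#' counter-clockwise (positive shoelace area).
#'
#' @param points Numeric matrix `n x 2` of `(x, y)` in mm, `n >= 3`.
#' @param z Physical z position of the slice plane in mm.
#' @return An object of class `us_contour`.
#' @export
us_contour <- function(points, z) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  # drop consecutive duplicates (and a repeated closing point)
  if (nrow(points) > 1) {
    d <- rowSums((points - points[c(nrow(points), seq_len(nrow(points) - 1)), ,
                                  drop = FALSE])^2)
    points <- points[c(TRUE, d[-1] > 1e-18), , drop = FALSE]
    if (nrow(points) > 1 && sum((points[1, ] - points[nrow(points), ])^2) <= 1e-18)
      points <- points[-nrow(points), , drop = FALSE]
  }
  if (nrow(points) < 3) stop("a contour needs at least 3 points", call. = FALSE)
  if (shoelace_area(points) < 0) points <- points[nrow(points):1, , drop = FALSE]
  structure(list(points = points, z = as.numeric(z)), class = "us_contour")
}

#' @export
print.us_contour <- function(x, ...) {
  cat(sprintf("<us_contour> %d points at z = %.3f mm, area %.4f mm^2\n",
              nrow(x$points), x$z, contour_area(x)))
  invisible(x)
}

shoelace_area <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1)
  sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2]) / 2
}

#' Enclosed polygon area of a contour (mm^2)
#' @param contour A [us_contour()].
#' @return Area in mm^2 (positive; contours are CCW).
#' @export
contour_area <- function(contour) shoelace_area(contour$points)

#' Perimeter of a contour (mm)
#' @param contour A [us_contour()].
#' @return Perimeter in mm.
#' @export
contour_perimeter <- function(contour) {
  pts <- contour$points
  n <- nrow(pts)
  sum(sqrt(rowSums((pts[c(2:n, 1), , drop = FALSE] - pts)^2)))
}

#' Extract sub-pixel boundary contours from a binary mask
#'
#' Traces the 0.5 iso-level of the mask (marching-squares style, via linear
#' interpolation between pixel centres), yielding smooth sub-pixel
#' boundaries rather than pixel-edge staircases. Coordinates are converted
#' to physical mm; components with fewer than 3 points are discarded.
#'
#' @param mask Binary matrix `(ny, nx)`.
#' @param z Physical z position in mm of the slice (default 0).
#' @param spacing In-plane spacing `(dx, dy)` in mm.
#' @param origin In-plane physical position `(x0, y0)` of pixel `[1, 1]`.
#' @return List of [us_contour()] (empty list for an empty mask).
#' @export
extract_contours <- function(mask, z = 0, spacing = c(0.114, 0.114),
                             origin = c(0, 0)) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(list())
  # zero padding closes contours that touch the image border
  mp <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  mp[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  ycoords <- origin[2] + (seq_len(nrow(mp)) - 2) * spacing[2]  # rows
  xcoords <- origin[1] + (seq_len(ncol(mp)) - 2) * spacing[1]  # cols
  cls <- grDevices::contourLines(x = ycoords, y = xcoords, z = mp, levels = 0.5)
  out <- list()
  for (cl in cls) {
    pts <- cbind(x = cl$y, y = cl$x)   # contourLines' x runs over rows (our y)
    ok <- tryCatch(us_contour(pts, z), error = function(e) NULL)
    if (!is.null(ok)) out[[length(out) + 1L]] <- ok
  }
  out
}

#' Largest contour by enclosed area
#'
#' The synovial region is treated as a single structure per slice; when a
#' mask yields several boundary components the largest is kept. Ties break
#' to the first in scan order.
#'
#' @param contours List of [us_contour()].
#' @return The largest contour, or `NULL` for an empty list (the empty-slice
#'   signal, distinct from an error).
#' @export
largest_contour <- function(contours) {
  if (length(contours) == 0) return(NULL)
  areas <- vapply(contours, contour_area, numeric(1))
  contours[[which.max(areas)]]
}

#' Resample a contour to equally spaced points
#'
#' `n_points` points equally spaced by arc length along the closed polyline,
#' starting at the original start point. The perimeter is preserved to well
#' under 1% for smooth contours at the default 64 points.
#'
#' @param contour A [us_contour()].
#' @param n_points Number of points (`>= 3`).
#' @return A [us_contour()] with `n_points` points.
#' @export
resample_contour <- function(contour, n_points = 64L) {
  stopifnot(inherits(contour, "us_contour"), n_points >= 3)
  pts <- contour$points
  n <- nrow(pts)
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[n + 1]
  if (total <= 0) stop("degenerate contour with zero perimeter", call. = FALSE)
  s <- (seq_len(n_points) - 1) * total / n_points
  xs <- stats::approx(cum, closed[, 1], xout = s)$y
  ys <- stats::approx(cum, closed[, 2], xout = s)$y
  us_contour(cbind(xs, ys), contour$z)
}

#' Cyclic correspondence offset between two contours
#'
#' Exhaustively searches all cyclic index offsets (same orientation) for the
#' one minimizing the sum of squared distances between corresponding points.
#' For uniformly resampled contours this is the twist-minimizing
#' correspondence used before stitching.
#'
#' @param c1,c2 [us_contour()] objects with equal point counts.
#' @return Integer offset `k` in `0..n-1`: point `i` of `c1` corresponds to
#'   point `1 + ((i - 1 + k) %% n)` of `c2`.
#' @export
align_contours <- function(c1, c2) {
  p1 <- c1$points; p2 <- c2$points
  n <- nrow(p1)
  if (nrow(p2) != n)
    stop("contours must have equal point counts", call. = FALSE)
  costs <- vapply(0:(n - 1), function(k) {
    idx <- 1 + ((seq_len(n) - 1 + k) %% n)
    sum((p1 - p2[idx, , drop = FALSE])^2)
  }, numeric(1))
  which.min(costs) - 1L
}

# Reindex a contour so its point 1 becomes point 1 + k (cyclically).
rotate_contour <- function(contour, k) {
  n <- nrow(contour$points)
  idx <- 1 + ((seq_len(n) - 1 + k) %% n)
  out <- contour
  out$points <- contour$points[idx, , drop = FALSE]
  out
}

#' Export a list of contours as JSON
#'
#' @param contours List of [us_contour()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_contours_json <- function(contours, path) {
  payload <- lapply(contours, function(cc)
    list(z = cc$z, x = cc$points[, 1], y = cc$points[, 2]))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
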