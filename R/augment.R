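#' Data-augmentation configuration
#'
#' Random combinations of vertical and horizontal flips, rotations up to
#' 20 degrees, translations up to 20% of the image size and zooms up to
#' 20% — the recipe used to artificially expand the 2D training dataset.
#'
#' @param horizontal_flip,vertical_flip Enable the respective flip (drawn
#'   with probability 0.5 when enabled).
#' @param max_rotation_deg Rotation bound in degrees (`>= 0`).
#' @param max_translation_frac Translation bound as a fraction of each image
#'   dimension (`0 <= f < 1`).
#' @param max_zoom_frac Zoom bound: scale drawn in `[1 - f, 1 + f]`
#'   (`0 <= f < 1`).
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(horizontal_flip = TRUE, vertical_flip = TRUE,
                                max_rotation_deg = 20,
                                max_translation_frac = 0.20,
                                max_zoom_frac = 0.20) {
  if (max_rotation_deg < 0 || max_translation_frac < 0 || max_zoom_frac < 0)
    stop("augmentation bounds must be non-negative", call. = FALSE)
  if (max_translation_frac >= 1 || max_zoom_frac >= 1)
    stop("fractional bounds must be < 1", call. = FALSE)
  structure(list(horizontal_flip = horizontal_flip,
                 vertical_flip = vertical_flip,
                 max_rotation_deg = max_rotation_deg,
                 max_translation_frac = max_translation_frac,
                 max_zoom_frac = max_zoom_frac),
            class = "augmentation_config")
}

# Bilinear sampling of `img` at back-transformed output coordinates.
# theta in radians; zoom > 0; shift in pixels; rotation/zoom about the centre.
affine_sample <- function(img, theta, zoom, shift_r, shift_c) {
  H <- nrow(img); W <- ncol(img)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  rr <- rep(seq_len(H), times = W) - cr - shift_r
  cc_ <- rep(seq_len(W), each = H) - cc - shift_c
  ct <- cos(theta); st <- sin(theta)
  # inverse map: un-rotate, un-zoom
  src_r <- (ct * rr + st * cc_) / zoom + cr
  src_c <- (-st * rr + ct * cc_) / zoom + cc
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- numeric(length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * fc * val(r0 + 1, c0 + 1)
  matrix(out, H, W)
}

#' Randomly augment an image/mask pair
#'
#' Draws one random geometric transform (flips, rotation, translation, zoom)
#' bounded by the configuration and applies the identical transform to the
#' image (bilinear interpolation) and the mask (bilinear then re-binarized
#' at 0.5). Randomness comes from the current RNG stream, so a seeded caller
#' (e.g. [train_model()]) is fully reproducible. With every augmentation
#' disabled the pair is returned unchanged.
#'
#' @param image,mask 2D matrices of identical shape.
#' @param cfg An [augmentation_config()].
#' @return List with elements `image` and `mask`.
#' @export
augment <- function(image, mask, cfg) {
  stopifnot(inherits(cfg, "augmentation_config"))
  if (!identical(dim(image), dim(mask)))
    stop("image and mask must have identical shape", call. = FALSE)
  if (!cfg$horizontal_flip && !cfg$vertical_flip &&
      cfg$max_rotation_deg == 0 && cfg$max_translation_frac == 0 &&
      cfg$max_zoom_frac == 0)
    return(list(image = image, mask = mask))
  if (cfg$horizontal_flip && stats::runif(1) < 0.5) {
    image <- image[, ncol(image):1]
    mask <- mask[, ncol(mask):1]
  }
  if (cfg$vertical_flip && stats::runif(1) < 0.5) {
    image <- image[nrow(image):1, ]
    mask <- mask[nrow(mask):1, ]
  }
  theta <- if (cfg$max_rotation_deg > 0)
    stats::runif(1, -cfg$max_rotation_deg, cfg$max_rotation_deg) * pi / 180 else 0
  zoom <- if (cfg$max_zoom_frac > 0)
    stats::runif(1, 1 - cfg$max_zoom_frac, 1 + cfg$max_zoom_frac) else 1
  shift_r <- if (cfg$max_translation_frac > 0)
    stats::runif(1, -1, 1) * cfg$max_translation_frac * nrow(image) else 0
  shift_c <- if (cfg$max_translation_frac > 0)
    stats::runif(1, -1, 1) * cfg$max_translation_frac * ncol(image) else 0
  if (theta != 0 || zoom != 1 || shift_r != 0 || shift_c != 0) {
    image <- affine_sample(image, theta, zoom, shift_r, shift_c)
    m <- affine_sample(mask, theta, zoom, shift_r, shift_c)
    mask <- matrix(as.numeric(m >= 0.5), nrow(m), ncol(m))
  }
  list(image = image, mask = mask)
}
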