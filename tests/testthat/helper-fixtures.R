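# Shared fixtures, built in code at test time.

# filled disc mask centred in an n x n grid
disc_mask <- function(n = 64, radius = 10, centre = c((n + 1) / 2, (n + 1) / 2)) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  matrix(as.numeric((rr - centre[1])^2 + (cc - centre[2])^2 <= radius^2), n, n)
}

# analytic circle contour with n points
circle_contour <- function(r = 5, n = 64, z = 0, centre = c(0, 0)) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  us_contour(cbind(centre[1] + r * cos(ang), centre[2] + r * sin(ang)), z)
}

# small crescent phantom for fast tests
small_phantom_params <- function(seed = 1, ...) {
  phantom_params(shape = c(24L, 48L, 48L),
                 crescent = list(t_peak_vox = 7, half_width_frac = 0.32,
                                 z_extent_frac = 0.8, clearance_vox = 3),
                 seed = seed, ...)
}

# 3x3 box dilation / erosion of a binary matrix
dilate3 <- function(m)
  as.matrix(EBImage::dilate(EBImage::Image(m), EBImage::makeBrush(3, "box")))
erode3 <- function(m)
  as.matrix(EBImage::erode(EBImage::Image(m), EBImage::makeBrush(3, "box")))
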