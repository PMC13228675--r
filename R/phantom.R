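#' Parameters of the synthetic ultrasound phantom
#'
#' Describes a speckled 3D volume emulating a transverse sweep over a small
#' joint: two bright curved bands (bone surrogates for the trapezium and
#' first-metacarpal surfaces) with optional attenuation shadows beneath them,
#' and a hypoechoic target region between the bands standing in for synovial
#' hypertrophy. The target is either a crescent hugging the upper band
#' (thickness varying smoothly across slices) or an ellipsoid with known
#' analytic volume.
#'
#' @param shape Integer `(nz, ny, nx)` grid size. Default `c(40, 64, 64)`.
#' @param spacing Voxel size `(dx, dy, dz)` in mm; default the clinical
#'   0.114 x 0.114 x 0.333 mm grid.
#' @param target_kind `"crescent"` or `"ellipsoid"`.
#' @param semi_axes_mm Ellipsoid semi-axes `(a, b, c)` in mm along `(x, y, z)`.
#' @param center_frac Target centre as a fraction of the grid `(z, y, x)`;
#'   ellipsoid mode only (the crescent is tied to the band geometry).
#' @param crescent List of crescent controls: `t_peak_vox` peak thickness in
#'   voxels, `half_width_frac` lateral half-extent as a fraction of the image
#'   width, `z_extent_frac` fraction of the slices carrying the target,
#'   `clearance_vox` minimum gap kept to the bands.
#' @param speckle_sd Relative standard deviation of the multiplicative
#'   gamma-distributed speckle (`0` disables noise).
#' @param shadow_prob Probability that a lateral beam position under a band
#'   casts an attenuation shadow.
#' @param shadow_width Shadow width in voxels along x.
#' @param echogenicity Named mean intensities `target`, `background`, `bone`;
#'   must be ordered `target < background < bone` (the target is hypoechoic).
#' @param seed Integer seed; identical parameters give bit-identical phantoms.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(40L, 64L, 64L),
                           spacing = c(0.114, 0.114, 0.333),
                           target_kind = c("crescent", "ellipsoid"),
                           semi_axes_mm = c(2, 2, 2),
                           center_frac = c(0.5, 0.5, 0.5),
                           crescent = list(t_peak_vox = 9, half_width_frac = 0.32,
                                           z_extent_frac = 0.8, clearance_vox = 3),
                           speckle_sd = 0.5,
                           shadow_prob = 0.15,
                           shadow_width = 3L,
                           echogenicity = c(target = 0.12, background = 0.35,
                                            bone = 0.85),
                           seed = 1L) {
  target_kind <- match.arg(target_kind)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 8))
  if (any(spacing <= 0)) stop("spacing must be strictly positive", call. = FALSE)
  if (any(semi_axes_mm <= 0)) stop("semi-axes must be strictly positive", call. = FALSE)
  if (crescent$t_peak_vox <= 0) stop("crescent thickness must be positive", call. = FALSE)
  e <- echogenicity
  if (!(e[["target"]] < e[["background"]] && e[["background"]] < e[["bone"]]))
    stop("echogenicities must be ordered target < background < bone", call. = FALSE)
  if (speckle_sd < 0 || shadow_prob < 0 || shadow_prob > 1)
    stop("invalid noise parameters", call. = FALSE)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 target_kind = target_kind,
                 semi_axes_mm = as.numeric(semi_axes_mm),
                 center_frac = as.numeric(center_frac),
                 crescent = crescent,
                 speckle_sd = speckle_sd, shadow_prob = shadow_prob,
                 shadow_width = as.integer(shadow_width),
                 echogenicity = e, seed = as.integer(seed)),
            class = "phantom_params")
}

# Band centre lines (row index as a function of column u in [-1, 1]); the
# upper band is convex downward, the lower concave. In ellipsoid mode the
# bands sit nearer the image edges so a centred target of known analytic
# volume has room between them.
phantom_bands <- function(p) {
  ny <- p$shape[2]; nx <- p$shape[3]
  u <- ((seq_len(nx) - (nx + 1) / 2) / (nx / 2))
  if (p$target_kind == "ellipsoid") {
    top <- ny * 0.12 + ny * 0.05 * u^2
    bot <- ny * 0.90 - ny * 0.03 * u^2
  } else {
    top <- ny * 0.25 + ny * 0.10 * u^2
    bot <- ny * 0.78 - ny * 0.06 * u^2
  }
  list(top = top, bot = bot, halfwidth = max(1.5, ny / 40), u = u)
}

#' Generate a synthetic phantom volume with its ground-truth label
#'
#' Builds the piecewise-constant echogenicity field described by
#' [phantom_params()], applies per-beam attenuation shadows below the bands,
#' then multiplies by gamma-distributed speckle and clips to `[0, 1]`.
#' The label marks the hypoechoic target and never touches band voxels.
#'
#' @param params A [phantom_params()].
#' @return List with elements `volume` (a [us_volume()]) and `label`
#'   (a [label_volume()]).
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  nz <- p$shape[1]; ny <- p$shape[2]; nx <- p$shape[3]
  e <- p$echogenicity
  bands <- phantom_bands(p)
  with_seed(p$seed, {
    img <- array(e[["background"]], c(nz, ny, nx))
    lab <- array(0, c(nz, ny, nx))
    yy <- seq_len(ny)
    band_mask_slice <- matrix(FALSE, ny, nx)
    for (x in seq_len(nx)) {
      band_mask_slice[abs(yy - bands$top[x]) <= bands$halfwidth, x] <- TRUE
      band_mask_slice[abs(yy - bands$bot[x]) <= bands$halfwidth, x] <- TRUE
    }
    tgt <- phantom_target_mask(p, bands)   # (nz, ny, nx) logical
    for (z in seq_len(nz)) {
      sl <- img[z, , ]
      sl[band_mask_slice] <- e[["bone"]]
      tz <- tgt[z, , ]
      sl[tz] <- e[["target"]]
      img[z, , ] <- sl
      lab[z, , ] <- as.numeric(tz)
    }
    if (any(lab == 1 & array(rep(band_mask_slice, each = nz), c(nz, ny, nx))))
      stop("phantom geometry error: target intersects a band", call. = FALSE)
    # attenuation shadows: random beam positions under the upper band
    if (p$shadow_prob > 0) {
      for (z in seq_len(nz)) {
        hit <- which(stats::runif(nx) < p$shadow_prob)
        for (x0 in hit) {
          xs <- intersect(x0 + seq_len(p$shadow_width) - 1L, seq_len(nx))
          for (x in xs) {
            below <- yy > bands$top[x] + bands$halfwidth
            img[z, below, x] <- img[z, below, x] * 0.45
          }
        }
      }
    }
    if (p$speckle_sd > 0) {
      k <- 1 / p$speckle_sd^2
      noise <- array(stats::rgamma(nz * ny * nx, shape = k, rate = k),
                     c(nz, ny, nx))
      img <- img * noise
    }
    img <- pmin(pmax(img, 0), 1)
    dim(img) <- c(nz, ny, nx)
  })
  list(volume = us_volume(img, p$spacing),
       label = label_volume(lab, p$spacing))
}

# Logical (nz, ny, nx) target mask for either target kind.
phantom_target_mask <- function(p, bands) {
  nz <- p$shape[1]; ny <- p$shape[2]; nx <- p$shape[3]
  tgt <- array(FALSE, c(nz, ny, nx))
  yy <- seq_len(ny)
  if (p$target_kind == "ellipsoid") {
    ax <- p$semi_axes_mm  # (a, b, c) along (x, y, z)
    ctr <- p$center_frac * p$shape  # (z, y, x) in voxels
    dx <- p$spacing[1]; dy <- p$spacing[2]; dz <- p$spacing[3]
    # clearance check: target must fit with >= 2 voxels to spare
    half_vox <- c(ax[3] / dz, ax[2] / dy, ax[1] / dx)
    if (any(ctr - half_vox < 2) || any(ctr + half_vox > p$shape - 1))
      stop("phantom geometry error: ellipsoid does not fit in the volume",
           call. = FALSE)
    zs <- (seq_len(nz) - ctr[1]) * dz / ax[3]
    ys <- (yy - ctr[2]) * dy / ax[2]
    xs <- (seq_len(nx) - ctr[3]) * dx / ax[1]
    for (z in seq_len(nz)) {
      r2 <- outer(ys^2, xs^2, `+`) + zs[z]^2
      tgt[z, , ] <- r2 <= 1
    }
  } else {
    cr <- p$crescent
    u <- bands$u
    z_half <- cr$z_extent_frac * nz / 2
    zc <- (nz + 1) / 2
    for (z in seq_len(nz)) {
      zt <- 1 - ((z - zc) / z_half)^2      # smooth thickness profile over z
      if (zt <= 0) next
      lat <- 1 - (u / cr$half_width_frac / 2)^2  # lateral taper
      t_here <- cr$t_peak_vox * sqrt(max(zt, 0)) * pmax(lat, 0)
      top_edge <- bands$top + bands$halfwidth + cr$clearance_vox
      for (x in seq_len(nx)) {
        if (t_here[x] < 1) next
        y0 <- top_edge[x]
        y1 <- y0 + t_here[x]
        if (y1 > bands$bot[x] - bands$halfwidth - cr$clearance_vox)
          y1 <- bands$bot[x] - bands$halfwidth - cr$clearance_vox
        if (y1 <= y0) next
        tgt[z, yy >= y0 & yy <= y1, x] <- TRUE
      }
    }
    if (!any(tgt))
      stop("phantom geometry error: crescent target is empty", call. = FALSE)
  }
  tgt
}

#' Second-rater perturbation parameters
#'
#' Controls the simulated inter-rater disagreement applied by
#' [simulate_second_rater()]: a smooth (spatially correlated) random boundary
#' jitter plus a uniform dilation (positive radius) or erosion (negative).
#'
#' @param jitter_amplitude Standard deviation of the boundary displacement in
#'   voxels (`>= 0`).
#' @param radius Systematic dilation (`> 0`) or erosion (`< 0`) in voxels.
#' @param jitter_cell Correlation length of the jitter field in voxels.
#' @param seed Integer seed.
#' @return An object of class `rater_perturbation`.
#' @export
rater_perturbation <- function(jitter_amplitude = 1.5, radius = 0,
                               jitter_cell = 16L, seed = 1L) {
  if (jitter_amplitude < 0) stop("jitter_amplitude must be >= 0", call. = FALSE)
  structure(list(jitter_amplitude = jitter_amplitude, radius = radius,
                 jitter_cell = as.integer(jitter_cell),
                 seed = as.integer(seed)),
            class = "rater_perturbation")
}

#' Simulate a second rater by perturbing a label volume
#'
#' Each slice boundary is displaced by a smooth low-frequency random field
#' (so disagreement is spatially correlated, as human inter-rater
#' disagreement is) plus a uniform dilation/erosion, implemented as a
#' threshold shift of the slice's signed Euclidean distance transform. Per
#' originally connected slice component, only the best-overlapping perturbed
#' component is kept, so connectivity is preserved. Slices eroded to empty
#' are left empty and listed in the `empty_slices` attribute.
#'
#' @param label A non-empty [label_volume()].
#' @param pert A [rater_perturbation()].
#' @return A [label_volume()] with attribute `empty_slices` (integer vector
#'   of originally non-empty slices that came back empty; a warning is also
#'   raised when any exist).
#' @export
simulate_second_rater <- function(label, pert) {
  stopifnot(inherits(label, "label_volume"), inherits(pert, "rater_perturbation"))
  if (sum(label$voxels) == 0) stop("label is empty", call. = FALSE)
  d <- dim(label$voxels)
  out <- array(0, d)
  empty_slices <- integer(0)
  with_seed(pert$seed, {
    for (z in seq_len(d[1])) {
      m <- label$voxels[z, , ]
      if (!any(m != 0)) next
      if (pert$jitter_amplitude == 0 && pert$radius == 0) {
        out[z, , ] <- m
        next
      }
      s <- signed_distance_2d(m)
      jit <- if (pert$jitter_amplitude > 0)
        smooth_noise_field(d[2], d[3], pert$jitter_cell, pert$jitter_amplitude)
      else matrix(0, d[2], d[3])
      m2 <- (s + jit + pert$radius) > 0
      m2 <- keep_matched_components(m, m2)
      if (!any(m2)) {
        empty_slices <- c(empty_slices, z)
      } else {
        out[z, , ] <- as.numeric(m2)
      }
    }
  })
  if (length(empty_slices))
    warning(sprintf("perturbation emptied %d slice(s): %s",
                    length(empty_slices), paste(empty_slices, collapse = ", ")))
  res <- label_volume(out, label$spacing, label$origin)
  attr(res, "empty_slices") <- empty_slices
  res
}

# Signed distance to the mask boundary (positive inside), with the half-pixel
# offset that places the 0-level on the 0.5 iso-contour between pixels.
signed_distance_2d <- function(m) {
  m <- m != 0
  din <- as.matrix(EBImage::distmap(EBImage::Image(m * 1)))
  dout <- as.matrix(EBImage::distmap(EBImage::Image((!m) * 1)))
  s <- matrix(0, nrow(m), ncol(m))
  s[m] <- din[m] - 0.5
  s[!m] <- -(dout[!m] - 0.5)
  s
}

# Low-frequency Gaussian field: coarse iid normal grid, bilinear upsampling.
smooth_noise_field <- function(ny, nx, cell, sd) {
  gy <- max(2L, ceiling(ny / cell) + 1L)
  gx <- max(2L, ceiling(nx / cell) + 1L)
  coarse <- matrix(stats::rnorm(gy * gx, sd = sd), gy, gx)
  fy <- (seq_len(ny) - 1) / (ny - 1) * (gy - 1) + 1
  fx <- (seq_len(nx) - 1) / (nx - 1) * (gx - 1) + 1
  iy <- pmin(floor(fy), gy - 1L); ty <- fy - iy
  ix <- pmin(floor(fx), gx - 1L); tx <- fx - ix
  a <- coarse[cbind(rep(iy, nx), rep(ix, each = ny))]
  b <- coarse[cbind(rep(iy + 1, nx), rep(ix, each = ny))]
  cc <- coarse[cbind(rep(iy, nx), rep(ix + 1, each = ny))]
  dd <- coarse[cbind(rep(iy + 1, nx), rep(ix + 1, each = ny))]
  w <- (1 - rep(ty, nx)) * (1 - rep(tx, each = ny)) * a +
    rep(ty, nx) * (1 - rep(tx, each = ny)) * b +
    (1 - rep(ty, nx)) * rep(tx, each = ny) * cc +
    rep(ty, nx) * rep(tx, each = ny) * dd
  matrix(w, ny, nx)
}

# For each connected component of the original mask, keep the perturbed
# component with the largest overlap; unmatched perturbed components drop.
keep_matched_components <- function(orig, pert) {
  if (!any(pert)) return(pert)
  lab_o <- as.matrix(EBImage::bwlabel(EBImage::Image(orig * 1)))
  lab_p <- as.matrix(EBImage::bwlabel(EBImage::Image(pert * 1)))
  keep <- integer(0)
  for (o in setdiff(unique(as.vector(lab_o)), 0)) {
    overlap <- lab_p[lab_o == o]
    overlap <- overlap[overlap > 0]
    if (length(overlap)) {
      tab <- table(overlap)
      keep <- c(keep, as.integer(names(tab)[which.max(tab)]))
    }
  }
  matrix(lab_p %in% keep, nrow(pert), ncol(pert))
}

#' Generate a seeded dataset of phantom volumes
#'
#' Draws per-volume target geometry (size, position, thickness and extent)
#' from seeded distributions around a template, then generates each phantom
#' with its own derived seed. Deterministic for a given master seed.
#'
#' @param n_volumes Number of phantoms (`>= 1`).
#' @param template A [phantom_params()] serving as the centre of the draws.
#' @param seed Master integer seed.
#' @return List of `n_volumes` elements, each a list with `id`, `params`,
#'   `volume`, `label`.
#' @export
generate_dataset <- function(n_volumes, template = phantom_params(), seed = 1L) {
  stopifnot(n_volumes >= 1)
  draws <- with_seed(seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, n_volumes),
         scale = stats::runif(n_volumes, 0.75, 1.15),
         shift = stats::runif(n_volumes, -0.06, 0.06),
         zext = stats::runif(n_volumes, 0.85, 1.1))
  })
  lapply(seq_len(n_volumes), function(i) {
    p <- template
    p$seed <- draws$seeds[i]
    if (p$target_kind == "ellipsoid") {
      p$semi_axes_mm <- p$semi_axes_mm * min(draws$scale[i], 1.05)
      # shift along x and z only; the y extent is bounded by the bands
      p$center_frac <- p$center_frac +
        c(draws$shift[i], 0, -draws$shift[i])
      p$center_frac <- pmin(pmax(p$center_frac, 0.3), 0.7)
    } else {
      p$crescent$t_peak_vox <- p$crescent$t_peak_vox * draws$scale[i]
      p$crescent$half_width_frac <-
        min(0.45, p$crescent$half_width_frac * draws$zext[i])
      p$crescent$z_extent_frac <-
        min(0.95, p$crescent$z_extent_frac * draws$zext[i])
    }
    ph <- generate_phantom(p)
    list(id = sprintf("phantom_%03d", i), params = p,
         volume = ph$volume, label = ph$label)
  })
}

#' Write a phantom dataset to disk
#'
#' Saves each volume/label pair as NIfTI and a manifest CSV
#' (`id, seed, target_kind, true_volume_mm3`).
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset, function(d) {
    save_volume(d$volume, file.path(dir, paste0(d$id, "_image.nii.gz")))
    save_volume(d$label, file.path(dir, paste0(d$id, "_label.nii.gz")))
    data.frame(id = d$id, seed = d$params$seed,
               target_kind = d$params$target_kind,
               true_volume_mm3 = label_voxel_volume_mm3(d$label))
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
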