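test_that("ellipsoid phantom label volume matches the analytic ellipsoid", {
  p <- phantom_params(target_kind = "ellipsoid", semi_axes_mm = c(2, 2, 2),
                      shape = c(40L, 64L, 64L), seed = 3)
  ph <- generate_phantom(p)
  analytic <- 4 / 3 * pi * prod(p$semi_axes_mm)
  expect_lt(abs(label_voxel_volume_mm3(ph$label) - analytic) / analytic, 0.05)
})

test_that("ellipsoid voxelization error shrinks at least 2x at half spacing", {
  va <- 4 / 3 * pi * 2^3
  err <- vapply(1:2, function(k) {
    f <- c(2, 1)[k]   # coarse grid vs the default clinical grid
    p <- phantom_params(target_kind = "ellipsoid", semi_axes_mm = c(2, 2, 2),
                        shape = as.integer(c(40, 64, 64) / f),
                        spacing = c(0.114, 0.114, 0.333) * f,
                        speckle_sd = 0, shadow_prob = 0, seed = 3)
    abs(label_voxel_volume_mm3(generate_phantom(p)$label) - va) / va
  }, numeric(1))
  expect_lt(err[2], err[1] / 2 + 1e-12)
})

test_that("identical seeds give bit-identical phantoms", {
  p <- small_phantom_params(seed = 11)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$label$voxels, b$label$voxels)
})

test_that("noiseless phantom is piecewise constant at the three echogenicities", {
  p <- small_phantom_params(seed = 2, speckle_sd = 0, shadow_prob = 0)
  ph <- generate_phantom(p)
  expect_setequal(unique(as.vector(ph$volume$voxels)),
                  unname(p$echogenicity[c("target", "background", "bone")]))
  # hypoechoic target: label voxels carry the lowest level
  expect_true(all(ph$volume$voxels[ph$label$voxels == 1] ==
                    p$echogenicity[["target"]]))
})

test_that("target stays hypoechoic and clear of the bone bands across seeds", {
  for (seed in c(1, 9, 23)) {
    p <- small_phantom_params(seed = seed)
    ph <- generate_phantom(p)
    inside <- mean(ph$volume$voxels[ph$label$voxels == 1])
    outside <- mean(ph$volume$voxels[ph$label$voxels == 0])
    expect_lt(inside, outside)
    # bands are the brightest structures; the label must not touch them
    p0 <- p; p0$speckle_sd <- 0; p0$shadow_prob <- 0
    ph0 <- generate_phantom(p0)
    expect_true(all(ph0$volume$voxels[ph0$label$voxels == 1] <
                      p$echogenicity[["bone"]]))
  }
})

test_that("an oversized ellipsoid raises a geometry error", {
  p <- phantom_params(target_kind = "ellipsoid", semi_axes_mm = c(20, 20, 20),
                      shape = c(24L, 48L, 48L), seed = 1)
  expect_error(generate_phantom(p), "geometry")
})

test_that("zero perturbation reproduces the label exactly", {
  ph <- generate_phantom(small_phantom_params(seed = 4))
  r <- simulate_second_rater(ph$label, rater_perturbation(0, 0, seed = 1))
  expect_identical(r$voxels, ph$label$voxels)
})

test_that("pure dilation strictly grows and pure erosion shrinks the label", {
  ph <- generate_phantom(small_phantom_params(seed = 4))
  grown <- simulate_second_rater(ph$label, rater_perturbation(0, 1, seed = 1))
  expect_gt(sum(grown$voxels), sum(ph$label$voxels))
  shrunk <- suppressWarnings(
    simulate_second_rater(ph$label, rater_perturbation(0, -1, seed = 1)))
  expect_lt(sum(shrunk$voxels), sum(ph$label$voxels))
})

test_that("jitter-only perturbation is volume-symmetric on a smooth target", {
  # low-curvature ellipsoid isolates the operator's symmetry from the
  # curvature bias intrinsic to thin crescents
  p <- phantom_params(target_kind = "ellipsoid", semi_axes_mm = c(2, 2, 2),
                      shape = c(40L, 64L, 64L), seed = 3)
  lab <- generate_phantom(p)$label
  tv <- sum(lab$voxels)
  diffs <- vapply(1:50, function(s) {
    r <- suppressWarnings(
      simulate_second_rater(lab, rater_perturbation(1, 0, seed = s)))
    sum(r$voxels) - tv
  }, numeric(1))
  expect_lt(abs(mean(diffs)) / tv, 0.02)
})

test_that("a perturbation eroding slices to empty flags them and warns", {
  lab <- array(0, c(6, 32, 32))
  lab[2, 15:17, 15:17] <- 1     # tiny 3x3 island
  lab[4, 5:25, 5:25] <- 1
  L <- label_volume(lab)
  expect_warning(
    r <- simulate_second_rater(L, rater_perturbation(0, -4, seed = 1)),
    "emptied")
  expect_equal(attr(r, "empty_slices"), 2L)
  expect_equal(sum(r$voxels[2, , ]), 0)
  expect_gt(sum(r$voxels[4, , ]), 0)
})

test_that("perturbed slices keep one component per original component", {
  ph <- generate_phantom(small_phantom_params(seed = 6))
  r <- suppressWarnings(
    simulate_second_rater(ph$label, rater_perturbation(2, 0, seed = 9)))
  for (z in seq_len(dim(r$voxels)[1])) {
    m <- r$voxels[z, , ]
    if (!any(m != 0)) next
    orig <- ph$label$voxels[z, , ]
    n_orig <- max(EBImage::bwlabel(EBImage::Image(orig)))
    n_pert <- max(EBImage::bwlabel(EBImage::Image(m)))
    expect_lte(n_pert, n_orig)
  }
})

test_that("dataset generation is seeded, varied and self-consistent", {
  tpl <- small_phantom_params()
  ds <- generate_dataset(5, tpl, seed = 21)
  ds2 <- generate_dataset(5, tpl, seed = 21)
  for (i in 1:5)
    expect_identical(ds[[i]]$label$voxels, ds2[[i]]$label$voxels)
  # pairwise labels are distinct (DSC < 1)
  for (i in 1:4) for (j in (i + 1):5) {
    d <- derive_metrics(confusion(ds[[i]]$label$voxels,
                                  ds[[j]]$label$voxels))$dsc
    expect_lt(d, 100)
  }
  # n = 1 equals a direct generate_phantom with the drawn params
  d1 <- generate_dataset(1, tpl, seed = 21)
  direct <- generate_phantom(d1[[1]]$params)
  expect_identical(d1[[1]]$volume$voxels, direct$volume$voxels)
})

test_that("a saved dataset round-trips through its manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(2, small_phantom_params(), seed = 8)
  manifest_path <- save_dataset(ds, dir)
  man <- read.csv(manifest_path)
  expect_equal(nrow(man), 2)
  expect_equal(man$true_volume_mm3,
               vapply(ds, function(d) label_voxel_volume_mm3(d$label),
                      numeric(1)))
  lab <- load_label(file.path(dir, paste0(man$id[1], "_label.nii.gz")))
  expect_equal(lab$voxels, ds[[1]]$label$voxels)
})
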