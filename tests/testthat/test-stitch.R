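test_that("two stacked squares stitch into a prism of exact volume", {
  s <- 2; dz <- 0.5
  sq <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  surf <- stitch(list(us_contour(sq, 0), us_contour(sq, dz)))
  expect_true(mesh_is_watertight(surf))
  expect_equal(mesh_euler_characteristic(surf), 2)
  expect_equal(enclosed_volume(surf), s^2 * dz, tolerance = 1e-12)
})

test_that("stitched circle stack matches the polygonal-prism closed form", {
  n <- 64; r <- 5; dz <- 0.333; m <- 40
  circs <- lapply(seq_len(m), function(j) circle_contour(r, n, (j - 1) * dz))
  surf <- stitch(circs)
  h <- (m - 1) * dz
  poly <- 0.5 * n * r^2 * sin(2 * pi / n) * h
  v <- enclosed_volume(surf)
  expect_lt(abs(v - poly) / poly, 0.005)
  expect_lt(abs(v - pi * r^2 * h) / (pi * r^2 * h), 0.01)
  expect_true(mesh_is_watertight(surf))
  expect_equal(mesh_euler_characteristic(surf), 2)
})

test_that("stitching aligns twisted contours before joining", {
  n <- 32
  c1 <- circle_contour(4, n, 0)
  c2 <- rotate_contour(circle_contour(4, n, 0.4), 11)
  c2$z <- 0.4
  surf <- stitch(list(c1, c2))
  v <- enclosed_volume(surf)
  poly <- 0.5 * n * 16 * sin(2 * pi / n) * 0.4
  expect_lt(abs(v - poly) / poly, 0.005)
  expect_error(stitch(list(c1)), "at least 2")
})

test_that("enclosed volume is exact on a unit cube and rigid-motion invariant", {
  verts <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                 c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  faces <- rbind(c(1,3,2), c(1,4,3), c(5,6,7), c(5,7,8),
                 c(1,2,6), c(1,6,5), c(2,3,7), c(2,7,6),
                 c(3,4,8), c(3,8,7), c(4,1,5), c(4,5,8))
  cube <- stitched_surface(verts, faces)
  expect_true(mesh_is_watertight(cube))
  expect_equal(enclosed_volume(cube), 1)
  # rotate + translate
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- stitched_surface(t(R %*% t(verts)) +
                              matrix(c(10, -4, 3), 8, 3, byrow = TRUE), faces)
  expect_lt(abs(enclosed_volume(moved) - 1), 1e-9)
  # removing a face opens the surface
  open_surf <- stitched_surface(verts, faces[-1, ])
  expect_false(mesh_is_watertight(open_surf))
  expect_error(enclosed_volume(open_surf), "watertight")
})

test_that("mask-stack reconstruction recovers a cylinder and bridges gaps", {
  n_slices <- 12; radius <- 14
  masks <- replicate(n_slices, disc_mask(64, radius), simplify = FALSE)
  st <- slice_stack(masks, seq_len(n_slices), c(0.114, 0.114), 0.333, n_slices)
  rec <- masks_to_surface(st, masks, n_points = 64)
  expect_true(mesh_is_watertight(rec$surface))
  r_mm <- radius * 0.114
  expect_lt(abs(rec$volume_mm3 - pi * r_mm^2 * (n_slices - 1) * 0.333) /
              (pi * r_mm^2 * (n_slices - 1) * 0.333), 0.03)
  # interior empty slice, bridged
  gappy <- masks
  gappy[[6]] <- masks[[6]] * 0
  rec2 <- masks_to_surface(st, gappy, interpolate_gaps = TRUE, n_points = 64)
  expect_lt(abs(rec2$volume_mm3 - rec$volume_mm3) / rec$volume_mm3, 0.02)
  expect_match(paste(rec2$warnings, collapse = " "), "bridged")
  # without interpolation the largest contiguous run is reported
  rec3 <- masks_to_surface(st, gappy, interpolate_gaps = FALSE, n_points = 64)
  expect_lt(rec3$volume_mm3, rec$volume_mm3)
  expect_match(paste(rec3$warnings, collapse = " "), "split")
  # fewer than 2 usable slices is an error
  lone <- lapply(masks, function(m) m * 0)
  lone[[3]] <- masks[[3]]
  expect_error(masks_to_surface(st, lone), "fewer than 2")
})

test_that("dilating every mask strictly increases the reconstructed volume", {
  masks <- replicate(8, disc_mask(48, 10), simplify = FALSE)
  st <- slice_stack(masks, 1:8, c(0.114, 0.114), 0.333, 8)
  v0 <- masks_to_surface(st, masks)$volume_mm3
  v1 <- masks_to_surface(st, lapply(masks, dilate3))$volume_mm3
  expect_gt(v1, v0)
})

test_that("mesh volume agrees with voxel counting on phantom labels", {
  ph <- generate_phantom(small_phantom_params(seed = 5))
  rec <- label_to_surface(ph$label)
  vox <- label_voxel_volume_mm3(ph$label)
  expect_lt(abs(rec$volume_mm3 - vox) / vox, 0.05)
  expect_true(mesh_is_watertight(rec$surface))
  expect_equal(mesh_euler_characteristic(rec$surface), 2)
})

test_that("mesh export writes valid ASCII OBJ and PLY", {
  surf <- stitch(list(circle_contour(2, 16, 0), circle_contour(2, 16, 1)))
  fo <- withr::local_tempfile(fileext = ".obj")
  fp <- withr::local_tempfile(fileext = ".ply")
  save_surface(surf, fo)
  save_surface(surf, fp)
  obj <- readLines(fo)
  expect_equal(sum(startsWith(obj, "v ")), nrow(surf$vertices))
  expect_equal(sum(startsWith(obj, "f ")), nrow(surf$faces))
  ply <- readLines(fp)
  expect_equal(ply[1], "ply")
  expect_match(ply[3], sprintf("element vertex %d", nrow(surf$vertices)))
})
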