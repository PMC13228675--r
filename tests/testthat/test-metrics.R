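test_that("confusion counts match hand-counted grids", {
  gt <- matrix(0, 2, 2); gt[1, 1] <- 1; gt[1, 2] <- 1
  pred <- matrix(0, 2, 2); pred[1, 2] <- 1; pred[2, 2] <- 1
  cts <- confusion(pred, gt)
  expect_equal(unclass(cts)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  # identity: k foreground of N
  m <- disc_mask(16, 4)
  cid <- confusion(m, m)
  expect_equal(cid$tp, sum(m))
  expect_equal(cid$tn, length(m) - sum(m))
  expect_equal(cid$fp + cid$fn, 0)
  # empty prediction
  ce <- confusion(m * 0, m)
  expect_equal(ce$fn, sum(m))
  expect_equal(ce$tp + ce$fp, 0)
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("derived metrics follow the standard formulas and conventions", {
  m <- derive_metrics(list(tp = 1, fp = 1, fn = 1, tn = 0))
  expect_equal(m$precision, 50)
  expect_equal(m$recall, 50)
  expect_equal(m$dsc, 50)
  perfect <- derive_metrics(confusion(disc_mask(8, 2), disc_mask(8, 2)))
  expect_equal(unlist(perfect[c("precision", "recall", "accuracy", "dsc")]),
               c(precision = 100, recall = 100, accuracy = 100, dsc = 100))
  both_empty <- derive_metrics(list(tp = 0, fp = 0, fn = 0, tn = 9))
  expect_equal(both_empty$dsc, 100)
  expect_true(both_empty$degenerate)
  empty_pred <- derive_metrics(list(tp = 0, fp = 0, fn = 5, tn = 4))
  expect_equal(empty_pred$precision, 0)
  expect_true(empty_pred$degenerate)
})

test_that("averaging and summing slice counts give identical pooled metrics", {
  set.seed(13)
  sl <- lapply(1:8, function(i)
    confusion(matrix(rbinom(64, 1, 0.4), 8), matrix(rbinom(64, 1, 0.4), 8)))
  a <- aggregate_3d(sl, "mean"); b <- aggregate_3d(sl, "sum")
  for (f in c("precision", "recall", "accuracy", "dsc"))
    expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
  # identical counts on every slice equal a single slice
  one <- aggregate_3d(sl[c(1, 1, 1)])
  single <- derive_metrics(sl[[1]])
  expect_equal(one$dsc, single$dsc, tolerance = 1e-12)
  # pooled counts equal the concatenated grid
  g1 <- matrix(rbinom(64, 1, .5), 8); g2 <- matrix(rbinom(64, 1, .5), 8)
  p1 <- g1; p2 <- matrix(0, 8, 8)
  pooled <- aggregate_3d(list(confusion(p1, g1), confusion(p2, g2)))
  concat <- derive_metrics(confusion(rbind(p1, p2), rbind(g1, g2)))
  expect_equal(pooled$dsc, concat$dsc, tolerance = 1e-12)
  expect_error(aggregate_3d(list()), "at least one")
})

test_that("Dice is symmetric, precision/recall swap, and Dice >= Jaccard", {
  set.seed(17)
  for (i in 1:20) {
    a <- matrix(rbinom(256, 1, runif(1, .1, .6)), 16)
    b <- matrix(rbinom(256, 1, runif(1, .1, .6)), 16)
    mab <- derive_metrics(confusion(a, b))
    mba <- derive_metrics(confusion(b, a))
    expect_equal(mab$dsc, mba$dsc, tolerance = 1e-12)
    expect_equal(mab$precision, mba$recall, tolerance = 1e-12)
    cts <- confusion(a, b)
    jacc <- 100 * cts$tp / (cts$tp + cts$fp + cts$fn)
    expect_gte(mab$dsc, jacc)
  }
})

test_that("percent difference uses the manual reference as denominator", {
  pd <- percent_difference(0.30, 0.26)
  expect_equal(pd$signed, (0.30 - 0.26) / 0.26 * 100, tolerance = 1e-12)
  expect_equal(pd$absolute, pd$signed)
  expect_equal(percent_difference(5, 5)$absolute, 0)
  half <- percent_difference(2.5, 5)
  expect_equal(half$signed, -50)
  expect_equal(half$absolute, 50)
  expect_error(percent_difference(1, 0), "> 0")
})

test_that("surface distances match a brute-force all-pairs oracle", {
  brute <- function(a, b) {
    dab <- apply(a, 1, function(p) min(sqrt(colSums((t(b) - p)^2))))
    dba <- apply(b, 1, function(p) min(sqrt(colSums((t(a) - p)^2))))
    list(msd = (mean(dab) + mean(dba)) / 2, hd = max(dab, dba))
  }
  set.seed(23)
  for (i in 1:10) {
    a <- matrix(rnorm(2 * sample(5:200, 1)), ncol = 2)
    b <- matrix(rnorm(2 * sample(5:200, 1)), ncol = 2)
    got <- surface_distances(a, b)
    want <- brute(a, b)
    expect_lt(abs(got$msd - want$msd), 1e-9)
    expect_lt(abs(got$hd - want$hd), 1e-9)
    expect_gte(got$hd, got$msd)
  }
  # closed forms
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  off <- surface_distances(sq, sq + matrix(c(3, 0), 4, 2, byrow = TRUE))
  expect_equal(off$hd, 3)
  expect_equal(surface_distances(rbind(c(0, 0)), rbind(c(3, 4))),
               list(msd = 5, hd = 5))
  expect_equal(surface_distances(sq, sq), list(msd = 0, hd = 0))
  expect_error(surface_distances(sq[0, ], sq), "non-empty")
})

test_that("signed distances are positive outside and negative inside the reference", {
  m0 <- disc_mask(40, 8)
  pts <- function(m) do.call(rbind, lapply(
    extract_contours(m, 0, c(0.114, 0.114)), function(cc) cc$points))
  dil <- signed_surface_distances(pts(dilate3(m0)), m0, c(0.114, 0.114))
  expect_gt(dil$signed_msd, 0)
  expect_lt(abs(dil$signed_msd - 0.114) / 0.114, 0.30)
  ero <- signed_surface_distances(pts(erode3(m0)), m0, c(0.114, 0.114))
  expect_lt(ero$signed_msd, 0)
  same <- signed_surface_distances(pts(m0), m0, c(0.114, 0.114))
  expect_lt(abs(same$signed_msd), 1e-6)   # float cancellation floor, in mm
  # configurable convention flips the sign
  flipped <- signed_surface_distances(pts(dilate3(m0)), m0, c(0.114, 0.114),
                                      outside_positive = FALSE)
  expect_equal(flipped$signed_msd, -dil$signed_msd)
})

test_that("2D pair evaluation composes its constituents", {
  m0 <- disc_mask(48, 10)
  perfect <- evaluate_pair_2d(m0, m0)
  expect_equal(unlist(perfect[1, c("precision", "recall", "accuracy", "dsc",
                                   "avpd")]),
               c(precision = 100, recall = 100, accuracy = 100, dsc = 100,
                 avpd = 0))
  for (f in c("msd", "hd", "smsd", "shd"))
    expect_lt(abs(perfect[[f]]), 1e-6)   # mm; float cancellation floor
  dil <- evaluate_pair_2d(dilate3(m0), m0)
  expect_gt(dil$smsd, 0)
  expect_gt(dil$signed_avpd, 0)
  expect_equal(dil$avpd, abs(dil$signed_avpd))
  # crafted 2x2 case
  gt <- matrix(c(1, 0, 1, 0), 2, 2); pred <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(evaluate_pair_2d(pred, gt)$dsc, 50)
  degen <- evaluate_pair_2d(m0 * 0, m0)
  expect_true(degen$degenerate)
})

test_that("3D pair evaluation is perfect on identity and responds to perturbation", {
  ph <- generate_phantom(small_phantom_params(seed = 12))
  id_rec <- evaluate_pair_3d(ph$label, ph$label)
  expect_equal(id_rec$dsc, 100)
  expect_equal(id_rec$avpd, 0, tolerance = 1e-9)
  expect_lt(abs(id_rec$msd), 1e-6)
  pert <- suppressWarnings(simulate_second_rater(
    ph$label, rater_perturbation(1, 1, seed = 2)))
  rec <- evaluate_pair_3d(pert, ph$label)
  expect_lt(rec$dsc, 100)
  expect_gt(rec$dsc, 50)
  expect_gt(rec$smsd, 0)    # net dilation lies outside the reference
  expect_gt(rec$msd, 0)
  expect_lt(rec$msd, 1)     # sub-mm disagreement for a 1-voxel perturbation
  expect_error(evaluate_pair_3d(ph$label, label_volume(array(0:1, c(2, 2, 2)))),
               "grid")
})

test_that("metric CSV uses the conventional report headers", {
  rec <- evaluate_pair_2d(disc_mask(16, 4), disc_mask(16, 4))
  f <- withr::local_tempfile(fileext = ".csv")
  save_metrics_csv(rec, f)
  hdr <- names(read.csv(f, check.names = FALSE))
  expect_true(all(c("Precision (%)", "DSC (%)", "MSD (mm)", "sMSD (mm)",
                    "A/VPD (%)") %in% hdr))
})
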