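#' Confusion counts between a predicted and a gold-standard mask
#'
#' Counts pixels (2D) or voxels (3D): true positive — overlapping foreground;
#' false positive — foreground in the prediction only; false negative —
#' foreground in the gold standard only; true negative — background in both.
#'
#' @param pred,gt Binary arrays of identical shape.
#' @return Object of class `confusion_counts` with fields `tp, fp, fn, tn`.
#' @export
confusion <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("pred and gt must have identical shape", call. = FALSE)
  p <- pred != 0; g <- gt != 0
  tp <- sum(p & g)
  fp <- sum(p & !g)
  fn <- sum(!p & g)
  tn <- sum(!p & !g)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' Precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, accuracy `(tp+tn)/total`,
#' Dice `2tp/(2tp+fp+fn)`, each as a percentage. Degenerate 0/0 cases follow
#' a fixed convention and set the `degenerate` flag: when both masks are
#' empty, precision/recall/Dice are 100%; an empty prediction against a
#' non-empty gold standard gives precision 0%.
#'
#' @param counts A [confusion()] result (or list with `tp, fp, fn, tn`).
#' @return List with `precision`, `recall`, `accuracy`, `dsc` (percent) and
#'   logical `degenerate`.
#' @export
derive_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  degenerate <- FALSE
  ratio <- function(num, den, empty_value) {
    if (den == 0) { degenerate <<- TRUE; empty_value } else num / den
  }
  both_empty <- (tp + fp + fn) == 0
  precision <- ratio(tp, tp + fp, if (both_empty) 1 else 0)
  recall <- ratio(tp, tp + fn, if (both_empty) 1 else 0)
  dsc <- ratio(2 * tp, 2 * tp + fp + fn, 1)
  accuracy <- ratio(tp + tn, total, 1)
  list(precision = 100 * precision, recall = 100 * recall,
       accuracy = 100 * accuracy, dsc = 100 * dsc, degenerate = degenerate)
}

#' Pool per-slice confusion counts into 3D overlap metrics
#'
#' Per-slice counts are averaged (equivalently summed — the derived ratios
#' are scale-invariant) and the overlap metrics are derived from the pooled
#' counts, mirroring how per-slice confusion values are combined into the
#' 3D reconstruction's recall, precision and accuracy.
#'
#' @param per_slice List of [confusion()] results, one per slice.
#' @param reduce `"mean"` or `"sum"` (identical derived metrics).
#' @return As [derive_metrics()].
#' @export
aggregate_3d <- function(per_slice, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  if (length(per_slice) < 1) stop("need at least one slice", call. = FALSE)
  acc <- list(tp = 0, fp = 0, fn = 0, tn = 0)
  for (cts in per_slice) for (f in names(acc)) acc[[f]] <- acc[[f]] + cts[[f]]
  if (reduce == "mean") for (f in names(acc)) acc[[f]] <- acc[[f]] / length(per_slice)
  derive_metrics(acc)
}

#' Area or volume percent difference
#'
#' Signed: `(measured - reference) / reference * 100`, the reference being
#' the manual gold-standard measurement; absolute: its magnitude.
#'
#' @param measured Measured area (mm^2) or volume (mm^3).
#' @param reference Gold-standard value, `> 0`.
#' @return List with `absolute` and `signed` percent differences.
#' @export
percent_difference <- function(measured, reference) {
  if (!is.finite(reference) || reference <= 0)
    stop("reference must be > 0", call. = FALSE)
  s <- (measured - reference) / reference * 100
  list(absolute = abs(s), signed = s)
}

# Chunked exhaustive nearest-neighbour distances from each row of `a` to the
# point set `b` (both n x d matrices, physical mm).
nn_dist <- function(a, b, chunk = 512L) {
  a <- as.matrix(a); b <- as.matrix(b)
  nb2 <- rowSums(b^2)
  out <- numeric(nrow(a))
  for (s in seq(1, nrow(a), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(a))
    d2 <- outer(rowSums(a[idx, , drop = FALSE]^2), nb2, `+`) -
      2 * a[idx, , drop = FALSE] %*% t(b)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Symmetric mean surface distance and Hausdorff distance
#'
#' `msd` is the mean of the two directed mean nearest-neighbour distances;
#' `hd` is the larger of the two directed maxima. Distances are exhaustive
#' nearest-neighbour in physical mm.
#'
#' @param pred_pts,gt_pts Point sets (`n x 2` or `n x 3` matrices, mm).
#' @return List with `msd` and `hd` in mm.
#' @export
surface_distances <- function(pred_pts, gt_pts) {
  pred_pts <- as.matrix(pred_pts); gt_pts <- as.matrix(gt_pts)
  if (nrow(pred_pts) == 0 || nrow(gt_pts) == 0)
    stop("point sets must be non-empty", call. = FALSE)
  d_pg <- nn_dist(pred_pts, gt_pts)
  d_gp <- nn_dist(gt_pts, pred_pts)
  list(msd = (mean(d_pg) + mean(d_gp)) / 2,
       hd = max(max(d_pg), max(d_gp)))
}

#' Signed surface distances against a gold-standard mask
#'
#' Each predicted boundary point's nearest distance to the gold-standard
#' boundary is signed positive when the point lies outside the gold-standard
#' interior and negative inside (convention configurable). `signed_msd` is
#' the mean signed distance; `signed_hd` the signed distance of maximal
#' magnitude.
#'
#' @param pred_pts Predicted boundary points: `n x 2` (mm, one slice) or
#'   `n x 3` (mm, surface vertices).
#' @param gt A binary matrix (2D) or [label_volume()] / 3D binary array
#'   defining the gold-standard interior.
#' @param spacing `(dx, dy)` for a 2D mask; taken from the object for a
#'   `label_volume`.
#' @param origin Physical position of the first pixel/voxel.
#' @param outside_positive Sign convention (default: outside positive).
#' @return List with `signed_msd` and `signed_hd` in mm.
#' @export
signed_surface_distances <- function(pred_pts, gt, spacing = c(0.114, 0.114),
                                     origin = NULL, outside_positive = TRUE) {
  pred_pts <- as.matrix(pred_pts)
  if (inherits(gt, "label_volume")) {
    spacing3 <- gt$spacing
    origin <- origin %||% gt$origin
    gt_arr <- gt$voxels
  } else if (is.matrix(gt)) {
    origin <- origin %||% c(0, 0)
    gt_arr <- gt
  } else if (is.array(gt) && length(dim(gt)) == 3) {
    spacing3 <- c(spacing, 0.333)[seq_len(3)]
    origin <- origin %||% c(0, 0, 0)
    gt_arr <- gt
  } else stop("gt must be a 2D mask, 3D array or label_volume", call. = FALSE)

  if (is.matrix(gt_arr)) {
    if (ncol(pred_pts) != 2) stop("pred points must be n x 2 for a 2D mask",
                                  call. = FALSE)
    cs <- extract_contours(gt_arr, z = 0, spacing = spacing, origin = origin)
    if (length(cs) == 0) stop("gold-standard mask is empty", call. = FALSE)
    gt_pts <- do.call(rbind, lapply(cs, function(cc) cc$points))
    col_idx <- round((pred_pts[, 1] - origin[1]) / spacing[1]) + 1
    row_idx <- round((pred_pts[, 2] - origin[2]) / spacing[2]) + 1
    inside <- lookup_binary(gt_arr, cbind(row_idx, col_idx))
  } else {
    if (ncol(pred_pts) != 3) stop("pred points must be n x 3 for a 3D mask",
                                  call. = FALSE)
    dx <- spacing3[1]; dy <- spacing3[2]; dz <- spacing3[3]
    gt_pts_list <- list()
    for (z in seq_len(dim(gt_arr)[1])) {
      m <- gt_arr[z, , ]
      if (!any(m != 0)) next
      cs <- extract_contours(m, z = origin[3] + (z - 1) * dz,
                             spacing = c(dx, dy), origin = origin[c(1, 2)])
      for (cc in cs)
        gt_pts_list[[length(gt_pts_list) + 1L]] <- cbind(cc$points, cc$z)
    }
    if (length(gt_pts_list) == 0)
      stop("gold-standard label is empty", call. = FALSE)
    gt_pts <- do.call(rbind, gt_pts_list)
    col_idx <- round((pred_pts[, 1] - origin[1]) / dx) + 1
    row_idx <- round((pred_pts[, 2] - origin[2]) / dy) + 1
    z_idx <- round((pred_pts[, 3] - origin[3]) / dz) + 1
    inside <- lookup_binary_3d(gt_arr, cbind(z_idx, row_idx, col_idx))
  }
  d <- nn_dist(pred_pts, gt_pts)
  sgn <- ifelse(inside, -1, 1)
  if (!outside_positive) sgn <- -sgn
  sd_vals <- sgn * d
  list(signed_msd = mean(sd_vals),
       signed_hd = sd_vals[which.max(abs(sd_vals))])
}

lookup_binary <- function(m, idx) {
  idx[, 1] <- pmin(pmax(idx[, 1], 1), nrow(m))
  idx[, 2] <- pmin(pmax(idx[, 2], 1), ncol(m))
  m[idx] != 0
}

lookup_binary_3d <- function(a, idx) {
  d <- dim(a)
  for (k in 1:3) idx[, k] <- pmin(pmax(idx[, k], 1), d[k])
  a[idx] != 0
}

#' Full 2D metric record for one slice pair
#'
#' Overlap metrics from the confusion matrix, boundary distance metrics
#' (mm) from extracted sub-pixel contours, signed distances against the
#' gold-standard interior, and area percent difference from foreground
#' areas.
#'
#' @param pred,gt Binary matrices of identical shape.
#' @param spacing In-plane spacing `(dx, dy)` in mm.
#' @param outside_positive Sign convention for signed distances.
#' @return A one-row `data.frame` (class `metrics_record`) with columns
#'   `precision, recall, accuracy, dsc` (percent), `msd, hd, smsd, shd`
#'   (mm), `avpd, signed_avpd` (percent), `degenerate` (logical).
#' @export
evaluate_pair_2d <- function(pred, gt, spacing = c(0.114, 0.114),
                             outside_positive = TRUE) {
  ov <- derive_metrics(confusion(pred, gt))
  px_area <- prod(spacing)
  has_pred <- any(pred != 0); has_gt <- any(gt != 0)
  if (has_pred && has_gt) {
    pc <- do.call(rbind, lapply(extract_contours(pred, 0, spacing),
                                function(cc) cc$points))
    gc_ <- do.call(rbind, lapply(extract_contours(gt, 0, spacing),
                                 function(cc) cc$points))
    dd <- surface_distances(pc, gc_)
    sd_ <- signed_surface_distances(pc, gt, spacing,
                                    outside_positive = outside_positive)
    pd <- percent_difference(sum(pred != 0) * px_area, sum(gt != 0) * px_area)
    rec <- data.frame(precision = ov$precision, recall = ov$recall,
                      accuracy = ov$accuracy, dsc = ov$dsc,
                      msd = dd$msd, hd = dd$hd,
                      smsd = sd_$signed_msd, shd = sd_$signed_hd,
                      avpd = pd$absolute, signed_avpd = pd$signed,
                      degenerate = ov$degenerate)
  } else {
    rec <- data.frame(precision = ov$precision, recall = ov$recall,
                      accuracy = ov$accuracy, dsc = ov$dsc,
                      msd = NA_real_, hd = NA_real_,
                      smsd = NA_real_, shd = NA_real_,
                      avpd = if (has_gt) 100 else NA_real_,
                      signed_avpd = if (has_gt) -100 else NA_real_,
                      degenerate = TRUE)
  }
  class(rec) <- c("metrics_record", class(rec))
  rec
}

#' Full 3D metric record for one volume pair
#'
#' Overlap metrics from pooled per-slice confusion counts; boundary distance
#' metrics between the stitched surfaces' vertex sets; signed distances of
#' the predicted surface against the gold-standard label interior; volume
#' percent difference between enclosed mesh volumes.
#'
#' @param pred,gt [label_volume()] objects on the same grid.
#' @param pred_surface,gt_surface Optional precomputed reconstructions (the
#'   `list(surface, volume_mm3, ...)` returned by [masks_to_surface()]);
#'   reconstructed from the labels when omitted.
#' @param outside_positive Sign convention for signed distances.
#' @return A one-row `data.frame` as [evaluate_pair_2d()], plus columns
#'   `volume_pred_mm3`, `volume_gt_mm3`.
#' @export
evaluate_pair_3d <- function(pred, gt, pred_surface = NULL, gt_surface = NULL,
                             outside_positive = TRUE) {
  stopifnot(inherits(pred, "label_volume"), inherits(gt, "label_volume"))
  if (!identical(dim(pred$voxels), dim(gt$voxels)))
    stop("pred and gt labels must share one grid", call. = FALSE)
  nz <- dim(gt$voxels)[1]
  per_slice <- lapply(seq_len(nz), function(z)
    confusion(pred$voxels[z, , ], gt$voxels[z, , ]))
  ov <- aggregate_3d(per_slice)
  if (is.null(pred_surface)) pred_surface <- label_to_surface(pred)
  if (is.null(gt_surface)) gt_surface <- label_to_surface(gt)
  dd <- surface_distances(pred_surface$surface$vertices,
                          gt_surface$surface$vertices)
  sd_ <- signed_surface_distances(pred_surface$surface$vertices, gt,
                                  outside_positive = outside_positive)
  pd <- percent_difference(pred_surface$volume_mm3, gt_surface$volume_mm3)
  rec <- data.frame(precision = ov$precision, recall = ov$recall,
                    accuracy = ov$accuracy, dsc = ov$dsc,
                    msd = dd$msd, hd = dd$hd,
                    smsd = sd_$signed_msd, shd = sd_$signed_hd,
                    avpd = pd$absolute, signed_avpd = pd$signed,
                    degenerate = ov$degenerate,
                    volume_pred_mm3 = pred_surface$volume_mm3,
                    volume_gt_mm3 = gt_surface$volume_mm3)
  class(rec) <- c("metrics_record", class(rec))
  rec
}

#' Write metric records as CSV with the standard report headers
#'
#' Columns are renamed to the conventional table headers
#' (`Precision (%) ... A/VPD (%)`).
#'
#' @param records A `data.frame` of stacked metric records.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
save_metrics_csv <- function(records, path) {
  hdr <- c(precision = "Precision (%)", recall = "Recall (%)",
           accuracy = "Accuracy (%)", dsc = "DSC (%)", msd = "MSD (mm)",
           hd = "HD (mm)", smsd = "sMSD (mm)", shd = "sHD (mm)",
           avpd = "A/VPD (%)", signed_avpd = "sA/VPD (%)")
  nm <- names(records)
  names(records) <- ifelse(nm %in% names(hdr), hdr[nm], nm)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
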