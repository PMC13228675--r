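#' End-to-end experiment configuration
#'
#' Bundles every stage of the phantom study: data generation, volume-level
#' split, model/training/augmentation configs, reconstruction and evaluation
#' options. Defaults give the desk-scale study: 40 phantoms split 30/10,
#' 10 transverse slices per volume (300 training slices), a depth-2
#' 8-filter U-Net and 64-point contour stitching.
#'
#' @param n_volumes Number of phantoms.
#' @param train_fraction Fraction of volumes used for training.
#' @param slices_per_volume Transverse slices resliced per volume (the
#'   clinical protocol used 8-15, averaging about 10).
#' @param phantom A [phantom_params()] template.
#' @param architectures Character vector of architectures to train and
#'   compare (`"unet"`, `"unetpp"`).
#' @param model A [model_config()] (architecture field is overridden per
#'   entry of `architectures`).
#' @param train A [train_config()].
#' @param augment An [augmentation_config()] or `NULL`.
#' @param n_points Resampled contour points for stitching.
#' @param interpolate_gaps Bridge interior empty prediction slices.
#' @param outside_positive Signed-distance sign convention.
#' @param threshold Probability threshold for binary masks.
#' @param seed Master seed for the whole experiment.
#' @param out_dir Run directory (created; must be writable).
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_volumes = 40L, train_fraction = 0.75,
                       slices_per_volume = 10L,
                       phantom = phantom_params(),
                       architectures = "unet",
                       model = model_config("unet", depth = 2L,
                                            base_filters = 8L),
                       train = train_config(learning_rate = 1e-3, epochs = 10L,
                                            steps_per_epoch = NULL,
                                            batch_size = 10L),
                       augment = augmentation_config(),
                       n_points = 64L, interpolate_gaps = TRUE,
                       outside_positive = TRUE, threshold = 0.5,
                       seed = 1L, out_dir = tempfile("synovol_run_")) {
  stopifnot(inherits(phantom, "phantom_params"),
            inherits(model, "model_config"),
            inherits(train, "train_config"))
  if (!is.null(augment)) stopifnot(inherits(augment, "augmentation_config"))
  if (n_volumes < 4) stop("need at least 4 volumes", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  architectures <- match.arg(architectures, c("unet", "unetpp"),
                             several.ok = TRUE)
  structure(list(n_volumes = as.integer(n_volumes),
                 train_fraction = train_fraction,
                 slices_per_volume = as.integer(slices_per_volume),
                 phantom = phantom, architectures = architectures,
                 model = model, train = train, augment = augment,
                 n_points = as.integer(n_points),
                 interpolate_gaps = interpolate_gaps,
                 outside_positive = outside_positive, threshold = threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full phantom experiment
#'
#' Generate phantoms, split at the volume level, reslice, train each
#' configured architecture, predict held-out slices, restack and
#' reconstruct 3D surfaces, and evaluate 2D and 3D performance. Artifacts
#' (config, manifest, checkpoints, per-slice and per-volume metric CSVs,
#' meshes, comparison report, Bland-Altman data) are written under the run
#' directory. Deterministic for a given seed.
#'
#' @param cfg A [run_config()].
#' @param verbose Print stage progress.
#' @return List with `per_volume` (named by architecture: metric
#'   `data.frame`s), `per_slice`, `history`, `comparison` (when two
#'   architectures were run), `bland_altman` (method vs manual STV), and
#'   `dirs` (artifact paths).
#' @export
run_experiment <- function(cfg, verbose = interactive()) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  dirs <- list(root = cfg$out_dir,
               checkpoints = file.path(cfg$out_dir, "checkpoints"),
               masks = file.path(cfg$out_dir, "masks"),
               meshes = file.path(cfg$out_dir, "meshes"),
               reports = file.path(cfg$out_dir, "reports"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- cfg
  cfg_json$phantom <- unclass(cfg_json$phantom)
  jsonlite::write_json(lapply(unclass(cfg_json), unclass),
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  say("stage phantom: generating %d volumes", cfg$n_volumes)
  dataset <- generate_dataset(cfg$n_volumes, cfg$phantom, seed = cfg$seed)
  ids <- vapply(dataset, `[[`, character(1), "id")
  manifest <- data.frame(id = ids,
                         seed = vapply(dataset, function(d) d$params$seed,
                                       numeric(1)),
                         target_kind = cfg$phantom$target_kind,
                         true_volume_mm3 = vapply(dataset, function(d)
                           label_voxel_volume_mm3(d$label), numeric(1)))

  say("stage split: %0.f%% of volumes to training", 100 * cfg$train_fraction)
  sp <- split_by_volume(ids, cfg$train_fraction, seed = cfg$seed)
  manifest$split <- ifelse(manifest$id %in% sp$train, "train", "test")
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)

  slice_pairs <- function(entry) {
    vs <- reslice(entry$volume, cfg$slices_per_volume)
    ls <- reslice(entry$label, cfg$slices_per_volume)
    lapply(seq_along(vs$images), function(k)
      list(image = vs$images[[k]], mask = ls$images[[k]]))
  }
  train_entries <- dataset[ids %in% sp$train]
  test_entries <- dataset[ids %in% sp$test]
  train_pairs <- unlist(lapply(train_entries, slice_pairs), recursive = FALSE)
  say("stage reslice: %d training slices from %d volumes",
      length(train_pairs), length(train_entries))

  per_volume <- list(); per_slice <- list(); history <- list()
  for (arch in cfg$architectures) {
    mcfg <- cfg$model
    mcfg$architecture <- arch
    mcfg$encoder <- if (arch == "unetpp") "resnet" else "plain"
    say("stage train [%s]: %d epochs", arch, cfg$train$epochs)
    model <- build_model(mcfg, seed = cfg$seed)
    fit <- train_model(model, train_pairs, val_pairs = list(),
                       tcfg = cfg$train, acfg = cfg$augment)
    save_model(fit$model, file.path(dirs$checkpoints, arch))
    save_history_csv(fit$history,
                     file.path(dirs$reports, paste0(arch, "_history.csv")))
    history[[arch]] <- fit$history

    say("stage predict/reconstruct/evaluate [%s]: %d test volumes",
        arch, length(test_entries))
    vol_rows <- list(); slice_rows <- list()
    for (entry in test_entries) {
      vs <- reslice(entry$volume, cfg$slices_per_volume)
      ls <- reslice(entry$label, cfg$slices_per_volume)
      pred_masks <- predict_stack(fit$model, vs, threshold = cfg$threshold)
      for (k in seq_along(pred_masks)) {
        r2 <- evaluate_pair_2d(pred_masks[[k]], ls$images[[k]],
                               spacing = vs$in_plane_spacing,
                               outside_positive = cfg$outside_positive)
        r2$id <- entry$id; r2$slice <- vs$slice_indices[k]
        slice_rows[[length(slice_rows) + 1L]] <- r2
      }
      pred_label <- restack(vs, pred_masks)
      save_volume(pred_label, file.path(
        dirs$masks, sprintf("%s_%s_pred.nii.gz", entry$id, arch)))
      gt_rec <- masks_to_surface(ls, ls$images,
                                 interpolate_gaps = cfg$interpolate_gaps,
                                 n_points = cfg$n_points)
      pred_rec <- tryCatch(
        masks_to_surface(vs, pred_masks,
                         interpolate_gaps = cfg$interpolate_gaps,
                         n_points = cfg$n_points),
        error = function(e) NULL)
      if (is.null(pred_rec)) {
        warning(sprintf("%s [%s]: reconstruction failed; volume skipped",
                        entry$id, arch))
        next
      }
      save_surface(pred_rec$surface, file.path(
        dirs$meshes, sprintf("%s_%s_pred.obj", entry$id, arch)))
      r3 <- evaluate_pair_3d(pred_label, restack(ls, ls$images),
                             pred_surface = pred_rec, gt_surface = gt_rec,
                             outside_positive = cfg$outside_positive)
      r3$id <- entry$id
      vol_rows[[length(vol_rows) + 1L]] <- r3
    }
    per_volume[[arch]] <- do.call(rbind, vol_rows)
    per_slice[[arch]] <- do.call(rbind, slice_rows)
    save_metrics_csv(per_volume[[arch]], file.path(
      dirs$reports, paste0(arch, "_per_volume.csv")))
    save_metrics_csv(per_slice[[arch]], file.path(
      dirs$reports, paste0(arch, "_per_slice.csv")))
  }

  comparison <- NULL
  if (length(cfg$architectures) == 2) {
    a <- cfg$architectures[1]; b <- cfg$architectures[2]
    comparison <- compare_methods_report(per_volume[[a]], per_volume[[b]])
    utils::write.csv(comparison,
                     file.path(dirs$reports, "method_comparison.csv"),
                     row.names = FALSE)
  }

  ba <- lapply(per_volume, function(tab) {
    if (is.null(tab) || nrow(tab) < 3) return(NULL)
    bland_altman(tab$volume_pred_mm3 / 1000, tab$volume_gt_mm3 / 1000,
                 label = "STV (cm^3), method - manual")
  })
  for (arch in names(ba))
    if (!is.null(ba[[arch]]))
      save_bland_altman_csv(ba[[arch]], file.path(
        dirs$reports, paste0(arch, "_bland_altman.csv")))

  list(per_volume = per_volume, per_slice = per_slice, history = history,
       comparison = comparison, bland_altman = ba, dirs = dirs,
       manifest = manifest)
}

#' Evaluate prediction labels against gold-standard labels
#'
#' The rater-comparison mode: no training, just the full 3D metric record
#' per matched volume plus paired statistics and Bland-Altman agreement on
#' the enclosed volumes.
#'
#' @param pred_labels,gt_labels Named lists of [label_volume()] objects with
#'   matching names (volume ids).
#' @param interpolate_gaps,n_points,outside_positive Reconstruction and
#'   evaluation options as in [run_config()].
#' @return List with `per_volume` (metric `data.frame`), `bland_altman`,
#'   and `volume_comparison` (paired test on STV).
#' @export
evaluate_only <- function(pred_labels, gt_labels, interpolate_gaps = TRUE,
                          n_points = 64L, outside_positive = TRUE) {
  ids <- names(gt_labels)
  if (is.null(ids) || is.null(names(pred_labels)))
    stop("labels must be named by volume id", call. = FALSE)
  missing_ids <- setdiff(ids, names(pred_labels))
  if (length(missing_ids))
    stop(sprintf("missing prediction(s) for: %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  rows <- lapply(ids, function(id) {
    r <- evaluate_pair_3d(pred_labels[[id]], gt_labels[[id]],
                          outside_positive = outside_positive)
    r$id <- id
    r
  })
  per_volume <- do.call(rbind, rows)
  ba <- NULL; cmp <- NULL
  if (nrow(per_volume) >= 3) {
    ba <- bland_altman(per_volume$volume_pred_mm3 / 1000,
                       per_volume$volume_gt_mm3 / 1000,
                       label = "STV (cm^3), method - manual")
    cmp <- paired_compare(per_volume$volume_pred_mm3,
                          per_volume$volume_gt_mm3, label = "STV (mm^3)")
  }
  list(per_volume = per_volume, bland_altman = ba, volume_comparison = cmp)
}
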