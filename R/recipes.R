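# Reference desk-scale study conditions: the synthetic scene sets and
# training recipes the package's own validation runs on. Fixing them in one
# place makes the test suite and the acceptance script exercise identical
# conditions.

#' Reference synthetic scene sets
#'
#' The package's standing study conditions for self-validation:
#' \describe{
#'   \item{tissue}{384 x 384 scenes at 5x-equivalent resolution (mpp 2),
#'     two tissue fragments covering about half the frame — the
#'     tissue-contour stage is evaluated on these.}
#'   \item{seg}{96 x 96 training scenes at mpp 2, one fragment, tumor
#'     fraction 0.4 — segmenter training patches are cropped from these.}
#'   \item{seg_holdout}{128 x 128 held-out scenes with the seg geometry.}
#'   \item{det}{128 x 128 scenes at 20x-equivalent resolution (mpp 0.5,
#'     lymphocyte diameter 12-20 px), two thirds dense aggregates
#'     (5000 cells/mm^2) and one third moderate density (1200/mm^2) —
#'     detector training data.}
#'   \item{det_sparse}{sparse held-out scenes (density as given, default
#'     800/mm^2) for detection recall evaluation.}
#' }
#'
#' @param kind which set to generate.
#' @param n number of scenes.
#' @param seed master seed; scene seeds are derived from it.
#' @param density density override for `det_sparse` (cells per mm^2).
#' @return List of `synthetic_scene` objects.
#' @export
reference_scenes <- function(kind = c("tissue", "seg", "seg_holdout",
                                      "det", "det_sparse"),
                             n = 10, seed = 1, density = 800) {
  kind <- match.arg(kind)
  mk <- function(i, ...) generate_scene(scene_spec(...,
    seed = derive_seed(seed, 7000L + i)))
  switch(kind,
    tissue = lapply(seq_len(n), function(i)
      mk(i, width = 384, height = 384, n_tissue_blobs = 2,
         tissue_fraction = 0.5, tumor_fraction = 0.35,
         lymphocyte_density = 300, mpp = 2.0)),
    seg = lapply(seq_len(n), function(i)
      mk(1000L + i, width = 96, height = 96, n_tissue_blobs = 1,
         tissue_fraction = 0.6, tumor_fraction = 0.4,
         lymphocyte_density = 200, mpp = 2.0)),
    seg_holdout = lapply(seq_len(n), function(i)
      mk(2000L + i, width = 128, height = 128, n_tissue_blobs = 1,
         tissue_fraction = 0.6, tumor_fraction = 0.4,
         lymphocyte_density = 200, mpp = 2.0)),
    det = c(lapply(seq_len(ceiling(2 * n / 3)), function(i)
      mk(3000L + i, width = 128, height = 128, n_tissue_blobs = 1,
         tissue_fraction = 0.75, tumor_fraction = 0.15,
         lymphocyte_density = 5000, mpp = 0.5)),
      lapply(seq_len(n - ceiling(2 * n / 3)), function(i)
        mk(3500L + i, width = 128, height = 128, n_tissue_blobs = 1,
           tissue_fraction = 0.75, tumor_fraction = 0.15,
           lymphocyte_density = 1200, mpp = 0.5))),
    det_sparse = lapply(seq_len(n), function(i)
      mk(4000L + i, width = 128, height = 128, n_tissue_blobs = 1,
         tissue_fraction = 0.75, tumor_fraction = 0.15,
         lymphocyte_density = density, mpp = 0.5))
  )
}

#' Reference desk-scale segmenter training
#'
#' Trains the small nested-U variant (3 encoder stages, mid width 4, stage
#' width 8) on 64-pixel patches from the `seg` reference scenes: AdamW,
#' initial rate 1e-3, cosine annealing, up to 25 epochs with patience 10.
#'
#' @param seed master seed for data and training.
#' @param n_scenes number of training scenes.
#' @param max_epochs epoch budget.
#' @return `list(model, history)` from [train_segmenter].
#' @export
train_reference_segmenter <- function(seed = 1, n_scenes = 14,
                                      max_epochs = 25) {
  scenes <- reference_scenes("seg", n = n_scenes, seed = seed)
  cfg <- seg_train_config(patch_size = 64, batch_size = 4, lr0 = 1e-3,
                          max_epochs = max_epochs, patience = 10,
                          depth = 3, mid_ch = 4, base_ch = 8,
                          seed = derive_seed(seed, 81))
  train_segmenter(scenes, cfg)
}

#' Reference desk-scale detector training
#'
#' Trains the light detector (width 4, one conv per backbone stage) on the
#' `det` reference scenes at 20x-equivalent resolution: SGD at 2e-2,
#' momentum 0.9, cosine-annealed per-sample steps, balanced objectness with
#' hard-negative mining, flip augmentation.
#'
#' At this schedule length the optimization is bimodal: most runs collapse
#' the objectness loss into a discriminative regime, an occasional
#' initialization stays on the high-loss plateau. The recipe therefore
#' measures recall on a selection set of sparse scenes (distinct from any
#' held-out evaluation set) after each run, restarts with a derived seed (up
#' to `max_attempts` runs), accepts the first run reaching selection recall
#' 0.85, and otherwise returns the attempt with the best selection recall.
#'
#' @param seed master seed for data and training.
#' @param n_scenes number of training scenes.
#' @param max_epochs epoch budget per attempt.
#' @param max_attempts restart budget.
#' @return `list(model, history, attempts, selection_recall)` from
#'   [train_detector].
#' @export
train_reference_detector <- function(seed = 1, n_scenes = 24,
                                     max_epochs = 60, max_attempts = 3) {
  scenes <- reference_scenes("det", n = n_scenes, seed = seed)
  best <- NULL
  for (attempt in seq_len(max_attempts)) {
    cfg <- det_train_config(input_size = 128, batch_size = 1,
                            optimizer = "sgd", max_epochs = max_epochs,
                            mpp = 0.5, width = 4,
                            stage_convs = 1, lr0 = 2e-2, momentum = 0.9,
                            gains = c(cls = 1, obj = 6, box = 3),
                            seed = derive_seed(seed, 82L + 100L * attempt))
    tr <- train_detector(scenes, cfg)
    tr$attempts <- attempt
    sel <- evaluate_reference_detection(tr$model, n_scenes = 12,
                                        seed = derive_seed(seed, 84L))
    tr$selection_recall <- if (is.finite(sel$recall)) sel$recall else 0
    if (is.null(best) || tr$selection_recall > best$selection_recall)
      best <- tr
    if (tr$selection_recall >= 0.85) break
  }
  best
}

#' Detection recall on sparse reference scenes
#'
#' Pooled recall at IoU 0.5 of a trained detector over sparse held-out
#' scenes (truth boxes are the drawn disc extents).
#'
#' @param model a trained detector.
#' @param cfg its [det_train_config].
#' @param n_scenes held-out scene count.
#' @param seed scene seed.
#' @param density scene density (cells per mm^2).
#' @return `list(recall, precision, n_gt, n_det)`.
#' @export
evaluate_reference_detection <- function(model, cfg = model$config,
                                         n_scenes = 40, seed = 99,
                                         density = 800) {
  held <- reference_scenes("det_sparse", n = n_scenes, seed = seed,
                           density = density)
  tp <- fp <- fn <- nd <- 0
  for (sc in held) {
    gt <- scene_gt_boxes(sc)
    det <- detect_tils(model, sc$image, stroma_mask = NULL, cfg = cfg)
    m <- match_detections(det, gt, iou_min = 0.5)
    tp <- tp + sum(m$labels == "TP")
    fp <- fp + sum(m$labels == "FP")
    fn <- fn + m$fn
    nd <- nd + nrow(det)
  }
  list(recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       n_gt = tp + fn, n_det = nd)
}

#' Segmentation Dice on held-out reference scenes
#'
#' @param model a trained segmenter.
#' @param n_scenes held-out scene count.
#' @param seed scene seed.
#' @return Vector of per-scene Dice coefficients against parenchyma truth.
#' @export
evaluate_reference_segmentation <- function(model, n_scenes = 5, seed = 99) {
  held <- reference_scenes("seg_holdout", n = n_scenes, seed = seed)
  vapply(held, function(sc) {
    pr <- predict_parenchyma(model, sc$image, tile = 64, overlap = 16)
    dice_coefficient(pr$mask, sc$parenchyma_truth)
  }, 0)
}

#' Tissue-contour Dice over reference scenes
#'
#' @param n_scenes scene count.
#' @param seed scene seed.
#' @return Vector of per-scene Dice coefficients at thumbnail scale.
#' @export
evaluate_reference_tissue <- function(n_scenes = 50, seed = 1) {
  scenes <- reference_scenes("tissue", n = n_scenes, seed = seed)
  vapply(scenes, function(sc) {
    seg <- suppressWarnings(segment_tissue(sc$image))
    truth <- round(resize_matrix(sc$tissue_truth$grid,
                                 nrow(seg$mask$grid), ncol(seg$mask$grid),
                                 "nearest"))
    dice_coefficient(seg$mask$grid, truth)
  }, 0)
}

#' Ground-truth boxes of a synthetic scene
#'
#' Lymphocyte truth points dilated to the drawn disc extents.
#'
#' @param scene a `synthetic_scene`.
#' @return A [detection_boxes] data frame (confidence 0.999).
#' @export
scene_gt_boxes <- function(scene) {
  lt <- scene$lymphocyte_truth
  if (nrow(lt) == 0)
    return(detection_boxes())
  detection_boxes(x0 = lt$x - lt$r, y0 = lt$y - lt$r,
                  x1 = lt$x + lt$r, y1 = lt$y + lt$r,
                  confidence = rep(0.999, nrow(lt)))
}
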