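# End-to-end orchestration: tissue -> parenchyma -> detection ->
# quantification, with config validation, stage short-circuiting and a
# reproducibility manifest.

#' Stub segmentation model emitting a constant probability
#'
#' For plumbing tests and dry runs of the pipeline without trained weights.
#'
#' @param prob constant probability in (0, 1).
#' @return An object of class `til_stub_segmenter`.
#' @export
stub_segmenter <- function(prob = 0.8) {
  stopifnot(prob > 0, prob < 1)
  structure(list(prob = prob), class = "til_stub_segmenter")
}

#' Stub detector emitting a fixed list of boxes
#'
#' @param boxes a [detection_boxes] data frame returned verbatim (before NMS
#'   and stroma gating).
#' @param cfg a [det_train_config] supplying thresholds.
#' @return An object of class `til_stub_detector`.
#' @export
stub_detector <- function(boxes = detection_boxes(),
                          cfg = det_train_config(input_size = 64)) {
  structure(list(boxes = boxes, config = cfg), class = "til_stub_detector")
}

#' Save / load a trained model
#'
#' Models are plain R lists of arrays; they serialize with `saveRDS`. The
#' checkpoint carries the full config and seed for reproducibility.
#'
#' @param model a model object.
#' @param path destination file.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Pipeline configuration
#'
#' @param seg_model parenchyma model (trained `u2netp_model`, a
#'   [stub_segmenter], or a checkpoint path).
#' @param det_model lymphocyte detector (trained, [stub_detector], or path).
#' @param contour a [contour_config].
#' @param det_cfg a [det_train_config] used at inference (thresholds, tile
#'   size, anchors); defaults to the detector's own config.
#' @param hpf an [hpf_spec].
#' @param thresholds a [grade_thresholds].
#' @param n_fields high-power fields counted per image.
#' @param seg_tile,seg_overlap tiled-inference geometry for the segmenter.
#' @param seed master seed, recorded in all outputs.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seg_model = stub_segmenter(),
                            det_model = stub_detector(),
                            contour = contour_config(),
                            det_cfg = NULL,
                            hpf = hpf_spec(),
                            thresholds = grade_thresholds(),
                            n_fields = 5,
                            seg_tile = 640, seg_overlap = 64,
                            seed = 1) {
  structure(list(seg_model = seg_model, det_model = det_model,
                 contour = contour, det_cfg = det_cfg, hpf = hpf,
                 thresholds = thresholds, n_fields = as.integer(n_fields),
                 seg_tile = as.integer(seg_tile),
                 seg_overlap = as.integer(seg_overlap),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param cfg a [pipeline_config].
#' @return Character vector of problems; empty iff every invariant of every
#'   sub-configuration holds.
#' @export
validate_config <- function(cfg) {
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)
  if (!inherits(cfg, "pipeline_config")) return("not a pipeline_config")
  for (slot in c("seg_model", "det_model")) {
    m <- cfg[[slot]]
    if (is.character(m) && !file.exists(m))
      note(sprintf("%s: checkpoint path '%s' does not exist", slot, m))
    if (is.null(m)) note(sprintf("%s: missing model", slot))
  }
  if (!inherits(cfg$contour, "contour_config")) note("contour: not a contour_config")
  else {
    if (any(cfg$contour$hsv_low > cfg$contour$hsv_high))
      note("contour: hsv_low exceeds hsv_high")
    if (cfg$contour$close_iterations < 1) note("contour: close_iterations < 1")
    if (cfg$contour$median_radius < 1) note("contour: median_radius < 1")
  }
  dc <- cfg$det_cfg
  if (is.null(dc) && inherits(cfg$det_model, c("til_detector_model", "til_stub_detector")))
    dc <- cfg$det_model$config
  if (!is.null(dc)) {
    if (dc$nms_iou <= 0 || dc$nms_iou >= 1)
      note(sprintf("det_cfg: nms_iou = %g outside (0, 1)", dc$nms_iou))
    if (dc$conf_threshold <= 0 || dc$conf_threshold >= 1)
      note(sprintf("det_cfg: conf_threshold = %g outside (0, 1)", dc$conf_threshold))
  }
  if (!inherits(cfg$hpf, "hpf_spec")) note("hpf: not an hpf_spec")
  else if (cfg$hpf$field_area_mm2 <= 0) note("hpf: field_area_mm2 <= 0")
  if (!inherits(cfg$thresholds, "grade_thresholds")) note("thresholds: invalid")
  if (cfg$n_fields < 1) note("n_fields < 1")
  problems
}

resolve_model <- function(m) if (is.character(m)) load_model(m) else m

#' Run the full annotation pipeline on one image
#'
#' Three sequential stages: deterministic tissue-contour segmentation, tumor
#' parenchyma segmentation, lymphocyte detection inside the stromal mask
#' (`tissue AND NOT parenchyma`), followed by per-HPF counting and grading.
#' An empty tissue mask short-circuits the remaining stages. Mask subset
#' relations (`stroma <= tissue`, `parenchyma <= tissue` on tissue support,
#' box centers inside stroma) are asserted on every run, and all artifacts
#' are described in a manifest carrying input hash, config and seed.
#'
#' @param image a [raster_image] with scale metadata, or a path readable by
#'   [read_image] (then `mpp` / `magnification` must be supplied).
#' @param cfg a [pipeline_config]; must validate cleanly.
#' @param out_dir optional directory; when given, writes tissue.png,
#'   parenchyma.png, stroma.png, boxes.geojson, counts.csv, report.json and
#'   manifest.json.
#' @param mpp,magnification metadata when `image` is a path.
#' @return `list(tissue, parenchyma, stroma, boxes, counts, grades, report,
#'   manifest)`.
#' @export
run_pipeline <- function(image, cfg = pipeline_config(), out_dir = NULL,
                         mpp = NULL, magnification = NULL) {
  problems <- validate_config(cfg)
  if (length(problems))
    stop(paste(c("invalid pipeline config:", problems), collapse = "\n  "))
  if (is.character(image)) image <- read_image(image, mpp = mpp,
                                               magnification = magnification)
  # complete scale metadata through the magnification * mpp = 10 relation
  if (is.null(image$magnification) && !is.null(image$mpp))
    image$magnification <- 10 / image$mpp
  if (is.null(image$mpp) && !is.null(image$magnification))
    image$mpp <- 10 / image$magnification
  stage <- "tissue_contour"
  result <- tryCatch({
    ts <- suppressWarnings(segment_tissue(image, cfg$contour))
    H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
    tissue_full <- binary_mask(
      round(resize_matrix(ts$mask$grid, H, W, "nearest")) != 0, scale = 1)
    empty_tissue <- sum(tissue_full$grid) == 0

    stage <- "parenchyma_segmentation"
    if (empty_tissue) {
      par_full <- binary_mask(matrix(0L, H, W))
    } else {
      seg_model <- resolve_model(cfg$seg_model)
      pred <- predict_parenchyma(seg_model, image, tile = cfg$seg_tile,
                                 overlap = cfg$seg_overlap)
      par_full <- binary_mask(pred$mask$grid * tissue_full$grid)
    }
    stroma <- stromal_mask(tissue_full, par_full)

    stage <- "lymphocyte_detection"
    boxes <- if (empty_tissue || sum(stroma$grid) == 0) detection_boxes()
    else {
      det_model <- resolve_model(cfg$det_model)
      dc <- if (is.null(cfg$det_cfg)) det_model$config else cfg$det_cfg
      detect_tils(det_model, image, stroma_mask = stroma, cfg = dc)
    }

    stage <- "quantification"
    counts <- if (nrow(boxes) == 0 && sum(stroma$grid) == 0)
      rep(0L, cfg$n_fields)
    else tryCatch(
      count_in_fields(boxes, stroma, cfg$hpf, n_fields = cfg$n_fields,
                      seed = cfg$seed),
      error = function(e) rep(0L, cfg$n_fields))
    grades <- grade(as.integer(counts), cfg$thresholds)

    # pipeline-level invariants, asserted on every run
    stopifnot(all(stroma$grid <= tissue_full$grid),
              all(stroma$grid + par_full$grid <= 1 + 0 * stroma$grid))
    if (nrow(boxes) > 0) {
      cx <- pmin(pmax(floor((boxes$x0 + boxes$x1) / 2) + 1L, 1L), W)
      cy <- pmin(pmax(floor((boxes$y0 + boxes$y1) / 2) + 1L, 1L), H)
      stopifnot(all(stroma$grid[cbind(cy, cx)] == 1L))
    }
    list(tissue = tissue_full, tissue_thumb = ts$mask,
         tissue_polygons = ts$polygons, parenchyma = par_full,
         stroma = stroma, boxes = boxes,
         counts = as.integer(counts), grades = grades)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })

  report <- list(
    n_boxes = nrow(result$boxes),
    counts_per_hpf = result$counts,
    grades = as.character(result$grades),
    tissue_fraction = mean(result$tissue$grid),
    parenchyma_fraction = mean(result$parenchyma$grid),
    seed = cfg$seed)

  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("tilscope")),
                   image_dim = dim(image$pixels),
                   n_fields = cfg$n_fields,
                   artifacts = character())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(tissue = file.path(out_dir, "tissue.png"),
               parenchyma = file.path(out_dir, "parenchyma.png"),
               stroma = file.path(out_dir, "stroma.png"),
               boxes = file.path(out_dir, "boxes.geojson"),
               counts = file.path(out_dir, "counts.csv"),
               report = file.path(out_dir, "report.json"))
    write_mask(result$tissue, paths["tissue"])
    write_mask(result$parenchyma, paths["parenchyma"])
    write_mask(result$stroma, paths["stroma"])
    b <- result$boxes
    ann <- annotation_set(
      polygons = if (nrow(b)) lapply(seq_len(nrow(b)), function(i)
        list(class = "lymphocyte",
             coords = rbind(c(b$x0[i], b$y0[i]), c(b$x1[i], b$y0[i]),
                            c(b$x1[i], b$y1[i]), c(b$x0[i], b$y1[i]))))
        else list(),
      points = if (nrow(b)) data.frame(class = "lymphocyte",
                                       x = (b$x0 + b$x1) / 2,
                                       y = (b$y0 + b$y1) / 2) else NULL)
    write_annotation_file(ann, paths["boxes"])
    utils::write.csv(data.frame(field = seq_along(result$counts),
                                count = result$counts,
                                grade = as.character(result$grades)),
                     paths["counts"], row.names = FALSE)
    jsonlite::write_json(report, paths["report"], auto_unbox = TRUE, digits = NA)
    manifest$artifacts <- as.list(tools::md5sum(unname(paths)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  c(result, list(report = report, manifest = manifest))
}
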