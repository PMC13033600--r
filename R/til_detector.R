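# Compact single-stage anchor-based lymphocyte detector: small convolutional
# backbone, top-down (FPN) + bottom-up (PAN) feature aggregation, decoupled
# heads at strides 8/16/32 (P3-P5), BCE classification + BCE objectness +
# CIoU box regression, greedy NMS post-processing.

#' Construct a table of detection boxes
#'
#' Boxes are axis-aligned in half-open pixel coordinates (`x1 > x0`,
#' `y1 > y0`) with a confidence in (0, 1) and class `"lymphocyte"`.
#'
#' @param x0,y0,x1,y1 numeric vectors of box corners.
#' @param confidence numeric vector in (0, 1).
#' @param class class label, recycled.
#' @return A data frame of class `detection_boxes`.
#' @export
detection_boxes <- function(x0 = double(), y0 = double(), x1 = double(),
                            y1 = double(), confidence = double(),
                            class = "lymphocyte") {
  if (length(x0) && (any(x1 <= x0) || any(y1 <= y0)))
    stop("degenerate box: need x1 > x0 and y1 > y0")
  if (length(confidence) && (any(confidence <= 0) || any(confidence >= 1)))
    stop("confidence must lie in (0, 1)")
  df <- data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                   confidence = if (length(confidence)) confidence
                                else rep(0.5, length(x0)),
                   class = if (length(x0)) rep_len(class, length(x0)) else character())
  class(df) <- c("detection_boxes", "data.frame")
  df
}

box_iou_pair <- function(a, b) {
  iw <- pmax(0, pmin(a[3], b[3]) - pmax(a[1], b[1]))
  ih <- pmax(0, pmin(a[4], b[4]) - pmax(a[2], b[2]))
  inter <- iw * ih
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) 0 else inter / ua
}

# IoU of one box (x0,y0,x1,y1) against rows of a matrix of boxes
box_iou_vec <- function(box, M) {
  if (nrow(M) == 0) return(double())
  iw <- pmax(0, pmin(box[3], M[, 3]) - pmax(box[1], M[, 1]))
  ih <- pmax(0, pmin(box[4], M[, 4]) - pmax(box[2], M[, 2]))
  inter <- iw * ih
  ua <- (box[3] - box[1]) * (box[4] - box[2]) +
    (M[, 3] - M[, 1]) * (M[, 4] - M[, 2]) - inter
  ifelse(ua <= 0, 0, inter / ua)
}

#' Complete-IoU loss between two boxes
#'
#' `1 - IoU + rho^2 / c^2 + alpha * v`: overlap, normalized squared
#' center distance (`rho^2` over the squared enclosing-box diagonal `c^2`),
#' and an aspect-consistency penalty `v = (4 / pi^2) (atan(w_gt / h_gt) -
#' atan(w / h))^2` weighted by `alpha = v / ((1 - IoU) + v)`.
#'
#' @param pred,gt single boxes: numeric `c(x0, y0, x1, y1)` or one-row
#'   [detection_boxes].
#' @return `list(loss, terms)` where `terms` holds `iou`, `rho2`, `c2`, `v`
#'   and `alpha_ciou` for audit.
#' @export
ciou_loss <- function(pred, gt) {
  as_xyxy <- function(b) {
    if (is.data.frame(b)) b <- as.numeric(b[1, c("x0", "y0", "x1", "y1")])
    as.numeric(b[1:4])
  }
  p <- as_xyxy(pred); g <- as_xyxy(gt)
  if (p[3] <= p[1] || p[4] <= p[2] || g[3] <= g[1] || g[4] <= g[2])
    stop("degenerate (zero-area) box")
  iou <- box_iou_pair(p, g)
  pc <- c((p[1] + p[3]) / 2, (p[2] + p[4]) / 2)
  gc <- c((g[1] + g[3]) / 2, (g[2] + g[4]) / 2)
  rho2 <- sum((pc - gc)^2)
  cw <- max(p[3], g[3]) - min(p[1], g[1])
  ch <- max(p[4], g[4]) - min(p[2], g[2])
  c2 <- cw^2 + ch^2
  w <- p[3] - p[1]; h <- p[4] - p[2]
  gw <- g[3] - g[1]; gh <- g[4] - g[2]
  v <- (4 / pi^2) * (atan(gw / gh) - atan(w / h))^2
  alpha <- if (v > 0) v / ((1 - iou) + v) else 0
  loss <- 1 - iou + rho2 / c2 + alpha * v
  list(loss = loss,
       terms = list(iou = iou, rho2 = rho2, c2 = c2, v = v,
                    alpha_ciou = alpha))
}

# CIoU and its gradient in center/size parameterization, vectorized over n
# boxes. alpha and the 1/(w^2+h^2) factor of the v-chain are treated as
# constants, the standard practice for this loss.
ciou_grad <- function(cx, cy, w, h, gcx, gcy, gw, gh) {
  x0 <- cx - w / 2; x1 <- cx + w / 2; y0 <- cy - h / 2; y1 <- cy + h / 2
  gx0 <- gcx - gw / 2; gx1 <- gcx + gw / 2; gy0 <- gcy - gh / 2; gy1 <- gcy + gh / 2
  iw <- pmax(0, pmin(x1, gx1) - pmax(x0, gx0))
  ih <- pmax(0, pmin(y1, gy1) - pmax(y0, gy0))
  I <- iw * ih
  U <- w * h + gw * gh - I
  iou <- ifelse(U > 0, I / U, 0)
  pos <- I > 0
  # d(inter)/d corners (zero when no overlap)
  dI_dx1 <- ifelse(pos & (x1 <= gx1), ih, 0)
  dI_dx0 <- ifelse(pos & (x0 >= gx0), -ih, 0)
  dI_dy1 <- ifelse(pos & (y1 <= gy1), iw, 0)
  dI_dy0 <- ifelse(pos & (y0 >= gy0), -iw, 0)
  dI_dcx <- dI_dx0 + dI_dx1
  dI_dcy <- dI_dy0 + dI_dy1
  dI_dw <- (dI_dx1 - dI_dx0) / 2
  dI_dh <- (dI_dy1 - dI_dy0) / 2
  dU_dcx <- -dI_dcx; dU_dcy <- -dI_dcy
  dU_dw <- h - dI_dw; dU_dh <- w - dI_dh
  dIoU <- function(dI, dU) ifelse(U > 0, (dI * U - I * dU) / U^2, 0)
  diou_dcx <- dIoU(dI_dcx, dU_dcx); diou_dcy <- dIoU(dI_dcy, dU_dcy)
  diou_dw <- dIoU(dI_dw, dU_dw); diou_dh <- dIoU(dI_dh, dU_dh)
  # center-distance term
  cw <- pmax(x1, gx1) - pmin(x0, gx0)
  chh <- pmax(y1, gy1) - pmin(y0, gy0)
  c2 <- cw^2 + chh^2
  rho2 <- (cx - gcx)^2 + (cy - gcy)^2
  dcw_dx1 <- as.numeric(x1 >= gx1); dcw_dx0 <- -as.numeric(x0 <= gx0)
  dch_dy1 <- as.numeric(y1 >= gy1); dch_dy0 <- -as.numeric(y0 <= gy0)
  dc2_dcx <- 2 * cw * (dcw_dx0 + dcw_dx1)
  dc2_dcy <- 2 * chh * (dch_dy0 + dch_dy1)
  dc2_dw <- 2 * cw * (dcw_dx1 - dcw_dx0) / 2
  dc2_dh <- 2 * chh * (dch_dy1 - dch_dy0) / 2
  dr_dcx <- 2 * (cx - gcx); dr_dcy <- 2 * (cy - gcy)
  dterm <- function(dr, dc2) (dr * c2 - rho2 * dc2) / c2^2
  # aspect term
  dlt <- atan(gw / gh) - atan(w / h)
  v <- (4 / pi^2) * dlt^2
  alpha <- ifelse(v > 0, v / ((1 - iou) + v), 0)
  wh2 <- w^2 + h^2
  dv_dw <- -(8 / pi^2) * dlt * h / wh2
  dv_dh <- (8 / pi^2) * dlt * w / wh2
  loss <- 1 - iou + rho2 / c2 + alpha * v
  list(loss = loss, iou = iou,
       dcx = -diou_dcx + dterm(dr_dcx, dc2_dcx),
       dcy = -diou_dcy + dterm(dr_dcy, dc2_dcy),
       dw = -diou_dw + dterm(dc2 = dc2_dw, dr = 0) + alpha * dv_dw,
       dh = -diou_dh + dterm(dc2 = dc2_dh, dr = 0) + alpha * dv_dh)
}

#' Greedy non-maximum suppression
#'
#' Boxes are visited in order of decreasing confidence (ties broken by earlier
#' index); each kept box suppresses all remaining boxes with IoU at or above
#' the threshold.
#'
#' @param boxes a [detection_boxes] data frame.
#' @param iou_threshold suppression threshold in (0, 1).
#' @return The kept subset, ordered by decreasing confidence.
#' @export
nms <- function(boxes, iou_threshold = 0.45) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  if (nrow(boxes) == 0) return(boxes)
  ord <- order(-boxes$confidence, seq_len(nrow(boxes)))
  M <- as.matrix(boxes[ord, c("x0", "y0", "x1", "y1")])
  keep <- logical(length(ord))
  alive <- rep(TRUE, length(ord))
  for (i in seq_along(ord)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < length(ord)) {
      later <- which(alive & seq_along(ord) > i)
      if (length(later)) {
        ious <- box_iou_vec(M[i, ], M[later, , drop = FALSE])
        alive[later[ious >= iou_threshold]] <- FALSE
      }
    }
  }
  out <- boxes[ord[keep], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- configuration ---------------------------------------------------------

#' Detector training configuration
#'
#' Canonical recipe: 640-pixel inputs, batch 8, SGD with initial learning
#' rate 1e-2, weight decay 5e-4 and momentum 0.937, cosine-annealed, up to
#' 250 epochs. Anchors default to size bands: lymphocyte diameters 6-12
#' microns (at the configured `mpp`) on the stride-8 head, small and large
#' aggregate scales on the coarser heads, three anchors per scale.
#'
#' @param input_size inference/training tile side (multiple of 32 advised).
#' @param batch_size gradient-accumulation batch.
#' @param optimizer `"sgd"` (canonical recipe) or `"adamw"` (useful for very
#'   short desk-scale schedules, where per-parameter step scaling replaces
#'   the tuning a long SGD run provides).
#' @param lr0,weight_decay,momentum optimizer hyperparameters.
#' @param t_max cosine annealing period (defaults to `max_epochs`).
#' @param max_epochs epoch budget.
#' @param anchors list of three 2-column matrices (w, h in pixels) for
#'   strides 8, 16, 32; `NULL` derives them from `mpp`.
#' @param mpp microns per pixel used for the default anchors.
#' @param conf_threshold detection confidence cut (default 0.25).
#' @param nms_iou NMS IoU threshold (default 0.45).
#' @param width backbone base width (channels).
#' @param stage_convs 2 (canonical: two 3x3 convs per backbone stage) or 1
#'   (light desk-scale backbone).
#' @param balance_obj logical; reweight the objectness BCE gradient so
#'   positive and negative anchors contribute equally (helps short training
#'   schedules; default TRUE).
#' @param gains named gradient gains for the three loss terms (default
#'   cls 1, obj 1, box 3).
#' @param seed master seed.
#' @return An object of class `det_train_config`.
#' @export
det_train_config <- function(input_size = 640, batch_size = 8,
                             optimizer = c("sgd", "adamw"),
                             lr0 = 1e-2, weight_decay = 5e-4, momentum = 0.937,
                             t_max = NULL, max_epochs = 250, anchors = NULL,
                             mpp = 1.0, conf_threshold = 0.25, nms_iou = 0.45,
                             width = 8, stage_convs = 2, balance_obj = TRUE,
                             gains = c(cls = 1, obj = 1, box = 3), seed = 1) {
  stopifnot(input_size >= 32, conf_threshold > 0, conf_threshold < 1,
            nms_iou > 0, nms_iou < 1, lr0 > 0, max_epochs >= 1)
  if (is.null(t_max)) t_max <- max_epochs
  if (is.null(anchors)) {
    # size bands per scale: single cells (6-12 um) on the stride-8 head,
    # small and large lymphoid aggregates on the coarser heads. Single-cell
    # boxes then assign to the fine head only (size-ratio rule).
    d3 <- c(6, 9, 12) / mpp
    d4 <- c(48, 64, 96) / mpp
    d5 <- c(128, 176, 224) / mpp
    anchors <- list(cbind(d3, d3), cbind(d4, d4), cbind(d5, d5))
  }
  stopifnot(length(anchors) == 3,
            all(vapply(anchors, function(a) all(a > 0), TRUE)))
  optimizer <- match.arg(optimizer)
  structure(list(input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 lr0 = lr0, weight_decay = weight_decay, momentum = momentum,
                 t_max = t_max, max_epochs = as.integer(max_epochs),
                 anchors = anchors, mpp = mpp,
                 conf_threshold = conf_threshold, nms_iou = nms_iou,
                 width = as.integer(width),
                 stage_convs = as.integer(stage_convs),
                 balance_obj = balance_obj,
                 gains = gains, seed = as.integer(seed)),
            class = "det_train_config")
}

# ---- model -----------------------------------------------------------------

STRIDES <- c(8L, 16L, 32L)

#' Build the compact lymphocyte detector
#'
#' A small convolutional backbone downsampling to strides 8/16/32, a top-down
#' pathway merging coarse semantics into fine maps and a bottom-up pathway
#' re-aggregating them, and a decoupled head per scale (separate
#' classification and box-regression/objectness branches). Each cell predicts
#' 3 anchors; anchor offsets use the bounded sigmoid decode.
#'
#' @param cfg a [det_train_config].
#' @return An object of class `til_detector_model` with `params`, `config`
#'   and `n_params`.
#' @export
build_detector <- function(cfg = det_train_config()) {
  c1 <- cfg$width
  P <- new.env(parent = emptyenv())
  P$params <- list(); P$stats <- list()
  A <- nrow(cfg$anchors[[1]])
  two <- cfg$stage_convs >= 2
  with_seed(derive_seed(cfg$seed, 41), {
    init_conv(P, "stem", 3, 3, c1, bn = FALSE)
    init_conv(P, "d1a", 3, c1, 2 * c1, bn = FALSE)
    if (two) init_conv(P, "d1b", 3, 2 * c1, 2 * c1, bn = FALSE)
    init_conv(P, "d2a", 3, 2 * c1, 4 * c1, bn = FALSE)
    if (two) init_conv(P, "d2b", 3, 4 * c1, 4 * c1, bn = FALSE)
    init_conv(P, "d3a", 3, 4 * c1, 4 * c1, bn = FALSE)
    if (two) init_conv(P, "d3b", 3, 4 * c1, 4 * c1, bn = FALSE)
    init_conv(P, "d4a", 3, 4 * c1, 8 * c1, bn = FALSE)
    if (two) init_conv(P, "d4b", 3, 8 * c1, 8 * c1, bn = FALSE)
    init_conv(P, "d5a", 3, 8 * c1, 8 * c1, bn = FALSE)
    if (two) init_conv(P, "d5b", 3, 8 * c1, 8 * c1, bn = FALSE)
    init_conv(P, "lat5", 1, 8 * c1, 4 * c1, bn = FALSE)
    init_conv(P, "lat4", 1, 8 * c1, 4 * c1, bn = FALSE)
    init_conv(P, "lat3", 1, 4 * c1, 4 * c1, bn = FALSE)
    init_conv(P, "fpn4", 3, 4 * c1, 4 * c1, bn = FALSE)
    init_conv(P, "fpn3", 3, 4 * c1, 4 * c1, bn = FALSE)
    init_conv(P, "pan34", 3, 4 * c1, 4 * c1, bn = FALSE)  # stride-2 down
    init_conv(P, "pan4", 3, 4 * c1, 4 * c1, bn = FALSE)
    init_conv(P, "pan45", 3, 4 * c1, 4 * c1, bn = FALSE)  # stride-2 down
    init_conv(P, "pan5", 3, 4 * c1, 4 * c1, bn = FALSE)
    for (s in 1:3) {
      init_conv(P, paste0("h", s, ".stem"), 3, 4 * c1, 4 * c1, bn = FALSE)
      init_conv(P, paste0("h", s, ".cls"), 1, 4 * c1, A, bn = FALSE)
      init_conv(P, paste0("h", s, ".regstem"), 3, 4 * c1, 4 * c1, bn = FALSE)
      init_conv(P, paste0("h", s, ".box"), 1, 4 * c1, 4 * A, bn = FALSE)
      init_conv(P, paste0("h", s, ".obj"), 1, 4 * c1, A, bn = FALSE)
    }
  })
  structure(list(params = P$params, stats = P$stats,
                 config = cfg,
                 n_params = n_trainable(P$params)),
            class = "til_detector_model")
}

# conv + ReLU blocks (no normalization: the compact detector works on [0,1]
# inputs and normalization-free scores stay calibrated across tiles)
cbr <- function(tp, P, name, x, stride = 1L) {
  h <- nn_conv2d(tp, x, P$params[[paste0(name, ".W")]],
                 P$params[[paste0(name, ".b")]], k = 3L,
                 stride = stride, name = name)
  nn_leaky_relu(tp, h)
}

cbr1 <- function(tp, P, name, x) {
  h <- nn_conv2d(tp, x, P$params[[paste0(name, ".W")]],
                 P$params[[paste0(name, ".b")]], k = 1L, name = name)
  nn_leaky_relu(tp, h)
}

conv_plain <- function(tp, P, name, x, k = 1L) {
  nn_conv2d(tp, x, P$params[[paste0(name, ".W")]],
            P$params[[paste0(name, ".b")]], k = k, name = name)
}

# Forward pass; returns per-scale head output nodes (logits).
detector_fwd <- function(model, x_array, tp = tape_new(), training = TRUE) {
  P <- list(params = model$params, stats = model$stats, training = training)
  x <- tp_leaf(tp, x_array)
  two <- !is.null(model$config$stage_convs) && model$config$stage_convs >= 2
  blk <- function(nm_a, nm_b, inp) {
    h <- cbr(tp, P, nm_a, inp, 2L)
    if (two) h <- cbr(tp, P, nm_b, h)
    h
  }
  h <- cbr(tp, P, "stem", x)
  h <- blk("d1a", "d1b", h)
  h <- blk("d2a", "d2b", h)
  c3 <- blk("d3a", "d3b", h)     # stride 8
  c4 <- blk("d4a", "d4b", c3)    # stride 16
  c5 <- blk("d5a", "d5b", c4)    # stride 32
  # top-down
  p5 <- cbr1(tp, P, "lat5", c5)
  up5 <- nn_resize(tp, p5, dim(c4$value)[1], dim(c4$value)[2], "nearest")
  p4 <- cbr(tp, P, "fpn4", nn_add(tp, up5, cbr1(tp, P, "lat4", c4)))
  up4 <- nn_resize(tp, p4, dim(c3$value)[1], dim(c3$value)[2], "nearest")
  p3 <- cbr(tp, P, "fpn3", nn_add(tp, up4, cbr1(tp, P, "lat3", c3)))
  # bottom-up
  n3 <- p3
  d34 <- cbr(tp, P, "pan34", n3, 2L)
  d34 <- nn_resize(tp, d34, dim(p4$value)[1], dim(p4$value)[2], "nearest")
  n4 <- cbr(tp, P, "pan4", nn_add(tp, d34, p4))
  d45 <- cbr(tp, P, "pan45", n4, 2L)
  d45 <- nn_resize(tp, d45, dim(p5$value)[1], dim(p5$value)[2], "nearest")
  n5 <- cbr(tp, P, "pan5", nn_add(tp, d45, p5))
  feats <- list(n3, n4, n5)
  heads <- vector("list", 3)
  for (s in 1:3) {
    hs <- cbr(tp, P, paste0("h", s, ".stem"), feats[[s]])
    rs <- cbr(tp, P, paste0("h", s, ".regstem"), feats[[s]])
    heads[[s]] <- list(
      cls = conv_plain(tp, P, paste0("h", s, ".cls"), hs),
      box = conv_plain(tp, P, paste0("h", s, ".box"), rs),
      obj = conv_plain(tp, P, paste0("h", s, ".obj"), rs))
  }
  list(tape = tp, heads = heads,
       grids = lapply(feats, function(f) dim(f$value)[1:2]))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Decode one scale's logits into boxes (bounded sigmoid decode).
decode_scale <- function(cls, box, obj, anchors, stride) {
  d <- dim(obj)
  A <- nrow(anchors)
  out <- vector("list", A)
  Hg <- d[1]; Wg <- d[2]
  cellx <- matrix(rep(0:(Wg - 1), each = Hg), Hg, Wg)
  celly <- matrix(rep(0:(Hg - 1), times = Wg), Hg, Wg)
  for (a in seq_len(A)) {
    tx <- box[, , (a - 1) * 4 + 1]; ty <- box[, , (a - 1) * 4 + 2]
    tw <- box[, , (a - 1) * 4 + 3]; th <- box[, , (a - 1) * 4 + 4]
    cx <- (2 * sigmoid(tx) - 0.5 + cellx) * stride
    cy <- (2 * sigmoid(ty) - 0.5 + celly) * stride
    w <- (2 * sigmoid(tw))^2 * anchors[a, 1]
    h <- (2 * sigmoid(th))^2 * anchors[a, 2]
    conf <- sigmoid(obj[, , a]) * sigmoid(cls[, , a])
    out[[a]] <- data.frame(x0 = as.vector(cx - w / 2), y0 = as.vector(cy - h / 2),
                           x1 = as.vector(cx + w / 2), y1 = as.vector(cy + h / 2),
                           confidence = as.vector(conf))
  }
  do.call(rbind, out)
}

#' Assign ground-truth boxes to anchors
#'
#' Each in-frame ground-truth box is assigned, at the cell containing its
#' center (half-open convention), to every anchor whose width and height
#' ratios to the box are within [1/4, 4]. A box matching no anchor that way
#' falls back to its best-ratio anchor, so every in-frame box gets at least
#' one anchor. Boxes outside the frame are skipped with a warning.
#'
#' @param gt_boxes [detection_boxes] or matrix with x0, y0, x1, y1.
#' @param anchors list of three anchor matrices (w, h) for strides 8/16/32.
#' @param grids list of three `c(H, W)` grid sizes.
#' @param frame `c(H, W)` of the input frame in pixels.
#' @param neighbor_cells if `TRUE`, additionally assign the two grid cells
#'   nearest to the box center (the bounded decode can still reach the true
#'   center from them); used during training to densify supervision. The
#'   default `FALSE` assigns the center cell only.
#' @return `list(obj_targets = <list of H x W x A 0/1 arrays>, assignments =
#'   <data frame scale, gy, gx, a, gt>)`.
#' @export
assign_targets <- function(gt_boxes, anchors, grids, frame,
                           neighbor_cells = FALSE) {
  A <- nrow(anchors[[1]])
  obj <- lapply(grids, function(g) array(0, c(g[1], g[2], A)))
  asg <- list()
  if (is.data.frame(gt_boxes)) gt_boxes <- as.matrix(gt_boxes[, c("x0", "y0", "x1", "y1")])
  n <- if (is.null(gt_boxes)) 0 else nrow(gt_boxes)
  for (i in seq_len(n)) {
    b <- gt_boxes[i, ]
    cx <- (b[1] + b[3]) / 2; cy <- (b[2] + b[4]) / 2
    w <- b[3] - b[1]; h <- b[4] - b[2]
    if (cx < 0 || cy < 0 || cx >= frame[2] || cy >= frame[1]) {
      warning(sprintf("ground-truth box %d outside frame; skipped", i))
      next
    }
    best <- c(Inf, NA, NA, NA, NA)   # ratio, scale, gy, gx, a
    for (s in 1:3) {
      stride <- STRIDES[s]
      gx <- floor(cx / stride) + 1L
      gy <- floor(cy / stride) + 1L
      if (gx > grids[[s]][2] || gy > grids[[s]][1]) next
      # cells to supervise at this scale: center, plus optionally the two
      # nearest neighbors along x and y
      cells <- list(c(gy, gx))
      if (neighbor_cells) {
        fx <- cx / stride - (gx - 1L)
        fy <- cy / stride - (gy - 1L)
        nx <- gx + if (fx < 0.5) -1L else 1L
        ny <- gy + if (fy < 0.5) -1L else 1L
        if (nx >= 1L && nx <= grids[[s]][2]) cells <- c(cells, list(c(gy, nx)))
        if (ny >= 1L && ny <= grids[[s]][1]) cells <- c(cells, list(c(ny, gx)))
      }
      for (a in seq_len(A)) {
        rw <- max(w / anchors[[s]][a, 1], anchors[[s]][a, 1] / w)
        rh <- max(h / anchors[[s]][a, 2], anchors[[s]][a, 2] / h)
        r <- max(rw, rh)
        if (r <= 4) {
          for (ce in cells) {
            obj[[s]][ce[1], ce[2], a] <- 1
            asg[[length(asg) + 1L]] <- data.frame(scale = s, gy = ce[1],
                                                  gx = ce[2], a = a, gt = i)
          }
        }
        if (r < best[1]) best <- c(r, s, gy, gx, a)
      }
    }
    hit <- any(vapply(asg, function(z) z$gt == i, TRUE))
    if (!hit && is.finite(best[1])) {
      s <- best[2]; gy <- best[3]; gx <- best[4]; a <- best[5]
      obj[[s]][gy, gx, a] <- 1
      asg[[length(asg) + 1L]] <- data.frame(scale = s, gy = gy, gx = gx,
                                            a = a, gt = i)
    }
  }
  list(obj_targets = obj,
       assignments = if (length(asg)) do.call(rbind, asg)
                     else data.frame(scale = integer(), gy = integer(),
                                     gx = integer(), a = integer(), gt = integer()))
}

bce_logit <- function(z, y) {
  # numerically stable BCE on logits
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

#' Detection loss components
#'
#' `total = cls_bce + obj_bce + box_ciou` (unit weights): binary
#' cross-entropy on the classification branch (assigned anchors, single
#' class), binary cross-entropy on objectness over all anchors, and CIoU
#' averaged over assigned anchors only.
#'
#' @param heads list of per-scale head values (`cls`, `box`, `obj` logits) as
#'   produced by the forward pass.
#' @param targets output of [assign_targets].
#' @param gt_boxes the ground-truth boxes the assignment refers to.
#' @param anchors,input_frame anchors and `c(H, W)` frame for decoding.
#' @return `list(total, cls_bce, obj_bce, box_ciou)`.
#' @export
detection_loss <- function(heads, targets, gt_boxes, anchors, input_frame) {
  comp <- detection_loss_grad(heads, targets, gt_boxes, anchors,
                              want_grad = FALSE)
  comp[c("total", "cls_bce", "obj_bce", "box_ciou")]
}

# Loss with analytic gradients for the head logits; grads feed the tape.
# balance_obj reweights the objectness BCE so positive and negative anchors
# contribute equally (desk-scale training aid; with no positives it reduces
# to the plain mean). gains scale the three terms for the gradient only.
detection_loss_grad <- function(heads, targets, gt_boxes, anchors,
                                want_grad = TRUE, balance_obj = FALSE,
                                gains = c(cls = 1, obj = 1, box = 1)) {
  if (is.data.frame(gt_boxes) && nrow(gt_boxes))
    gt_boxes <- as.matrix(gt_boxes[, c("x0", "y0", "x1", "y1")])
  asg <- targets$assignments
  n_obj_total <- 0
  n_pos <- sum(vapply(targets$obj_targets, sum, 0))
  obj_sum <- 0
  grads <- if (want_grad) vector("list", 3) else NULL
  use_balance <- balance_obj && n_pos > 0
  # objectness BCE over all anchors, all scales
  for (s in 1:3) {
    z <- heads[[s]]$obj
    y <- targets$obj_targets[[s]]
    n_obj_total <- n_obj_total + length(z)
    obj_sum <- obj_sum + sum(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
    if (want_grad)
      grads[[s]] <- list(cls = array(0, dim(heads[[s]]$cls)),
                         box = array(0, dim(heads[[s]]$box)),
                         obj = (sigmoid(z) - y) * (if (use_balance) y else 0))
  }
  obj_bce <- obj_sum / n_obj_total
  if (want_grad) {
    n_neg <- n_obj_total - n_pos
    if (use_balance) {
      # balanced positives + online hard-negative mining: the 3*n_pos
      # highest-scoring negatives carry most of the negative mass, so false
      # alarms are suppressed within a short training schedule
      negz <- unlist(lapply(1:3, function(s)
        heads[[s]]$obj[targets$obj_targets[[s]] == 0]))
      k <- min(max(3L * n_pos, 1L), length(negz))
      zcut <- sort(negz, decreasing = TRUE)[k]
      n_hard <- sum(negz >= zcut)
      for (s in 1:3) {
        z <- heads[[s]]$obj
        y <- targets$obj_targets[[s]]
        g0 <- sigmoid(z) - y
        hard <- (y == 0) & (z >= zcut)
        w <- y * (0.5 / n_pos) + hard * (0.4 / n_hard) +
          ((y == 0) & !hard) * (0.1 / max(n_neg - n_hard, 1))
        grads[[s]]$obj <- gains[["obj"]] * g0 * w
      }
    } else {
      for (s in 1:3) {
        g0 <- sigmoid(heads[[s]]$obj) - targets$obj_targets[[s]]
        grads[[s]]$obj <- gains[["obj"]] * g0 / n_obj_total
      }
    }
  }
  cls_bce <- 0; box_ciou <- 0
  n_as <- nrow(asg)
  if (n_as > 0) {
    cls_terms <- double(n_as); box_terms <- double(n_as)
    for (k in seq_len(n_as)) {
      s <- asg$scale[k]; gy <- asg$gy[k]; gx <- asg$gx[k]; a <- asg$a[k]
      stride <- STRIDES[s]
      zc <- heads[[s]]$cls[gy, gx, a]
      cls_terms[k] <- max(zc, 0) - zc + log1p(exp(-abs(zc)))
      if (want_grad)
        grads[[s]]$cls[gy, gx, a] <- grads[[s]]$cls[gy, gx, a] +
          gains[["cls"]] * (sigmoid(zc) - 1) / n_as
      b <- gt_boxes[asg$gt[k], ]
      tx <- heads[[s]]$box[gy, gx, (a - 1) * 4 + 1]
      ty <- heads[[s]]$box[gy, gx, (a - 1) * 4 + 2]
      tw <- heads[[s]]$box[gy, gx, (a - 1) * 4 + 3]
      th <- heads[[s]]$box[gy, gx, (a - 1) * 4 + 4]
      sx <- sigmoid(tx); sy <- sigmoid(ty); sw <- sigmoid(tw); sh <- sigmoid(th)
      cx <- (2 * sx - 0.5 + (gx - 1)) * stride
      cy <- (2 * sy - 0.5 + (gy - 1)) * stride
      w <- (2 * sw)^2 * anchors[[s]][a, 1]
      h <- (2 * sh)^2 * anchors[[s]][a, 2]
      cg <- ciou_grad(cx, cy, w, h,
                      (b[1] + b[3]) / 2, (b[2] + b[4]) / 2,
                      b[3] - b[1], b[4] - b[2])
      box_terms[k] <- cg$loss
      if (want_grad) {
        gb <- gains[["box"]]
        dtx <- gb * cg$dcx * 2 * stride * sx * (1 - sx)
        dty <- gb * cg$dcy * 2 * stride * sy * (1 - sy)
        dtw <- gb * cg$dw * 8 * sw * anchors[[s]][a, 1] * sw * (1 - sw)
        dth <- gb * cg$dh * 8 * sh * anchors[[s]][a, 2] * sh * (1 - sh)
        ix <- (a - 1) * 4
        grads[[s]]$box[gy, gx, ix + 1] <- grads[[s]]$box[gy, gx, ix + 1] + dtx / n_as
        grads[[s]]$box[gy, gx, ix + 2] <- grads[[s]]$box[gy, gx, ix + 2] + dty / n_as
        grads[[s]]$box[gy, gx, ix + 3] <- grads[[s]]$box[gy, gx, ix + 3] + dtw / n_as
        grads[[s]]$box[gy, gx, ix + 4] <- grads[[s]]$box[gy, gx, ix + 4] + dth / n_as
      }
    }
    cls_bce <- mean(cls_terms)
    box_ciou <- mean(box_terms)
  }
  list(total = cls_bce + obj_bce + box_ciou, cls_bce = cls_bce,
       obj_bce = obj_bce, box_ciou = box_ciou, grads = grads)
}

# ---- training --------------------------------------------------------------

det_val_metrics <- function(model, scenes, cfg) {
  tp_n <- fp_n <- fn_n <- 0
  for (sc in scenes) {
    gt <- scene_gt_boxes(sc)
    det <- detect_tils(model, sc$image, stroma_mask = NULL, cfg = cfg)
    m <- match_detections(det, gt, iou_min = 0.5)
    tp_n <- tp_n + sum(m$labels == "TP")
    fp_n <- fp_n + sum(m$labels == "FP")
    fn_n <- fn_n + m$fn
  }
  prec <- if (tp_n + fp_n > 0) tp_n / (tp_n + fp_n) else NA
  rec <- if (tp_n + fn_n > 0) tp_n / (tp_n + fn_n) else NA
  f1 <- if (is.finite(prec) && is.finite(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1)
}

#' Train the lymphocyte detector
#'
#' SGD (momentum, weight decay) with cosine-annealed learning rate on the
#' composite detection loss; per-epoch validation precision / recall / F1 at
#' IoU 0.5; the checkpoint with the best validation F1 is returned. Fully
#' deterministic given the config seed.
#'
#' @param scenes list of `synthetic_scene` objects; lymphocyte truth points
#'   are dilated to boxes of the drawn disc extent.
#' @param cfg a [det_train_config].
#' @param val_scenes optional explicit validation set (default: slide-level
#'   70/15/15 split of `scenes`).
#' @return `list(model, history)`.
#' @export
train_detector <- function(scenes, cfg = det_train_config(), val_scenes = NULL) {
  if (length(scenes) == 0) stop("empty training dataset")
  if (is.null(val_scenes)) {
    if (length(scenes) >= 5) {
      sp <- split_slides(seq_along(scenes), seed = cfg$seed)
      val_scenes <- scenes[sp$val]
      scenes <- scenes[sp$train]
    } else val_scenes <- scenes
  }
  model <- build_detector(cfg)
  opt <- optimizer_new(cfg$optimizer, lr = cfg$lr0,
                       weight_decay = cfg$weight_decay,
                       momentum = cfg$momentum)
  prep <- lapply(scenes, function(sc) {
    list(x = sc$image$pixels / 255, gt = scene_gt_boxes(sc))
  })
  history <- list()
  best <- list(f1 = -Inf, params = model$params, epoch = 0L)
  for (epoch in seq_len(cfg$max_epochs) - 1L) {
    lr <- cosine_lr(epoch, cfg$lr0, cfg$t_max)
    ord <- with_seed(derive_seed(cfg$seed, 200L + epoch), sample(seq_along(prep)))
    losses <- double(0)
    acc <- NULL; acc_n <- 0L
    for (ii in ord) {
      d <- prep[[ii]]
      # random horizontal / vertical flips (image and boxes together)
      fl <- with_seed(derive_seed(cfg$seed, 4000L + epoch * 131L + ii),
                      stats::runif(2) < 0.5)
      if (fl[1]) {
        W <- dim(d$x)[2]
        d$x <- d$x[, W:1, , drop = FALSE]
        if (nrow(d$gt)) {
          x0 <- W - d$gt$x1; x1 <- W - d$gt$x0
          d$gt$x0 <- x0; d$gt$x1 <- x1
        }
      }
      if (fl[2]) {
        H <- dim(d$x)[1]
        d$x <- d$x[H:1, , , drop = FALSE]
        if (nrow(d$gt)) {
          y0 <- H - d$gt$y1; y1 <- H - d$gt$y0
          d$gt$y0 <- y0; d$gt$y1 <- y1
        }
      }
      fw <- detector_fwd(model, d$x)
      heads_val <- lapply(fw$heads, function(h)
        list(cls = h$cls$value, box = h$box$value, obj = h$obj$value))
      tg <- suppressWarnings(
        assign_targets(d$gt, cfg$anchors, fw$grids, frame = dim(d$x)[1:2],
                       neighbor_cells = TRUE))
      lg <- detection_loss_grad(heads_val, tg, d$gt, cfg$anchors,
                                balance_obj = isTRUE(cfg$balance_obj),
                                gains = cfg$gains)
      losses <- c(losses, lg$total)
      outs <- list(); seeds <- list()
      for (s in 1:3) for (part in c("cls", "box", "obj")) {
        outs[[length(outs) + 1L]] <- fw$heads[[s]][[part]]
        seeds[[length(seeds) + 1L]] <- lg$grads[[s]][[part]]
      }
      gsum <- tape_backward(fw$tape, outs, seeds)
      if (is.null(acc)) acc <- gsum
      else for (nm in names(gsum))
        acc[[nm]] <- if (is.null(acc[[nm]])) gsum[[nm]] else acc[[nm]] + gsum[[nm]]
      acc_n <- acc_n + 1L
      if (acc_n >= cfg$batch_size || ii == ord[length(ord)]) {
        acc <- lapply(acc, function(g) g / acc_n)
        st <- optimizer_step(opt, model$params, acc, lr = lr)
        opt <- st$opt; model$params <- st$params
        acc <- NULL; acc_n <- 0L
      }
    }
    vm <- det_val_metrics(model, val_scenes, cfg)
    history[[length(history) + 1L]] <-
      data.frame(epoch = epoch, lr = lr, train_loss = mean(losses),
                 val_precision = vm$precision, val_recall = vm$recall,
                 val_f1 = vm$f1)
    # ties (and near-ties) go to the later epoch: the longer-trained model
    if (vm$f1 >= best$f1 - 1e-9) best <- list(f1 = max(vm$f1, best$f1),
                                              params = model$params,
                                              epoch = epoch)
  }
  model$params <- best$params
  model$best_epoch <- best$epoch
  list(model = model, history = do.call(rbind, history))
}

# ---- inference -------------------------------------------------------------

#' Detect lymphocytes in an image, gated to stromal regions
#'
#' Runs tiled inference at the configured input size, applies the confidence
#' threshold per tile, merges tile detections, applies NMS globally, and
#' finally discards boxes whose center lies outside the stroma mask.
#'
#' @param model a trained `til_detector_model` (or a stub with class
#'   `til_stub_detector` for plumbing tests).
#' @param image a [raster_image].
#' @param stroma_mask a [binary_mask] registered to the image (any scale), or
#'   `NULL` to skip gating.
#' @param cfg a [det_train_config] (thresholds, anchors, tile size).
#' @return A [detection_boxes] data frame.
#' @export
detect_tils <- function(model, image, stroma_mask = NULL,
                        cfg = NULL) {
  stopifnot(inherits(image, "raster_image"))
  if (is.null(cfg)) cfg <- model$config
  x <- image$pixels / 255
  H <- dim(x)[1]; W <- dim(x)[2]
  tile <- cfg$input_size
  overlap <- min(64L, tile %/% 4L)
  dets <- list()
  if (inherits(model, "til_stub_detector")) {
    dets[[1]] <- model$boxes
  } else {
    for (sy in tile_starts(H, tile, overlap)) {
      for (sx in tile_starts(W, tile, overlap)) {
        ty <- sy:min(sy + tile - 1L, H)
        tx <- sx:min(sx + tile - 1L, W)
        fw <- detector_fwd(model, x[ty, tx, , drop = FALSE], training = TRUE)
        tile_dets <- list()
        for (s in 1:3) {
          dec <- decode_scale(fw$heads[[s]]$cls$value, fw$heads[[s]]$box$value,
                              fw$heads[[s]]$obj$value, cfg$anchors[[s]],
                              STRIDES[s])
          tile_dets[[s]] <- dec[dec$confidence >= cfg$conf_threshold, , drop = FALSE]
        }
        td <- do.call(rbind, tile_dets)
        if (nrow(td)) {
          td$x0 <- td$x0 + (sx - 1L); td$x1 <- td$x1 + (sx - 1L)
          td$y0 <- td$y0 + (sy - 1L); td$y1 <- td$y1 + (sy - 1L)
          dets[[length(dets) + 1L]] <- td
        }
      }
    }
  }
  if (!length(dets)) return(detection_boxes())
  all_d <- do.call(rbind, dets)
  ok <- is.finite(all_d$x0) & is.finite(all_d$y0) & is.finite(all_d$x1) &
    is.finite(all_d$y1) & is.finite(all_d$confidence) &
    all_d$x1 > all_d$x0 & all_d$y1 > all_d$y0
  all_d <- all_d[ok, , drop = FALSE]
  if (!nrow(all_d)) return(detection_boxes())
  all_d$confidence <- pmin(pmax(all_d$confidence, 1e-6), 1 - 1e-6)
  boxes <- detection_boxes(all_d$x0, all_d$y0, all_d$x1, all_d$y1,
                           all_d$confidence)
  kept <- nms(boxes, cfg$nms_iou)
  if (!is.null(stroma_mask)) {
    sc <- stroma_mask$scale
    cx <- (kept$x0 + kept$x1) / 2
    cy <- (kept$y0 + kept$y1) / 2
    gy <- pmin(pmax(floor(cy / sc) + 1L, 1L), nrow(stroma_mask$grid))
    gx <- pmin(pmax(floor(cx / sc) + 1L, 1L), ncol(stroma_mask$grid))
    inside <- stroma_mask$grid[cbind(gy, gx)] == 1L
    kept <- kept[inside, , drop = FALSE]
    rownames(kept) <- NULL
  }
  kept
}
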