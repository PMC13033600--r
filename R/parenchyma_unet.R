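# Lightweight nested-U segmentation network for tumor parenchyma, its
# composite loss (weighted BCE + Dice), the training loop and tiled inference
# at 5x-equivalent resolution.

MPP_5X <- 2.0  # microns per pixel at 5x-equivalent (magnification * mpp = 10)

# ---- loss configuration and losses ----------------------------------------

#' Composite segmentation loss configuration
#'
#' The training objective is `alpha * L_WBCE + beta * L_Dice`: weighted binary
#' cross-entropy addresses class imbalance (positive pixels weighted by `w`),
#' the Dice term rewards boundary overlap. The weights are not dictated by the
#' method; defaults are `alpha = beta = 1`, `w = 1`.
#'
#' @param alpha weight of the WBCE term (>= 0).
#' @param beta weight of the Dice term (>= 0; not both zero).
#' @param w positive-class weight inside the WBCE (> 0).
#' @param eps_dice smoothing constant of the Dice term (default 1e-6).
#' @return An object of class `seg_loss_config`.
#' @export
seg_loss_config <- function(alpha = 1, beta = 1, w = 1, eps_dice = 1e-6) {
  stopifnot(alpha >= 0, beta >= 0, alpha + beta > 0, w > 0, eps_dice > 0)
  structure(list(alpha = alpha, beta = beta, w = w, eps_dice = eps_dice),
            class = "seg_loss_config")
}

as_prob_array <- function(pred) {
  if (inherits(pred, "seg_prediction")) pred <- pred$prob
  if (is.list(pred) && !is.null(pred$prob)) pred <- pred$prob
  as.array(pred)
}

as_target_array <- function(target) {
  if (inherits(target, "binary_mask")) target <- target$grid
  as.array(target)
}

CLIP_P <- 1e-7

#' Weighted binary cross-entropy loss
#'
#' `-(1/N) * sum_i [ w * y_i * log(p_i) + (1 - y_i) * log(1 - p_i) ]`, the
#' mean over all N pixels, with predictions clipped to
#' `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param pred predicted probabilities (array / matrix, or a `seg_prediction`).
#' @param target ground-truth labels in \{0,1\} ([binary_mask] or array).
#' @param w positive-class weight.
#' @param grad if `TRUE`, also return the gradient with respect to `pred`.
#' @return The scalar loss, or `list(loss, grad)` when `grad = TRUE`.
#' @export
wbce_loss <- function(pred, target, w = 1, grad = FALSE) {
  p <- as_prob_array(pred)
  y <- as_target_array(target)
  if (!all(dim(p) == dim(y)) && length(p) != length(y))
    stop("prediction / target shape mismatch")
  pc <- pmin(pmax(p, CLIP_P), 1 - CLIP_P)
  n <- length(pc)
  loss <- -sum(w * y * log(pc) + (1 - y) * log(1 - pc)) / n
  if (!grad) return(loss)
  g <- -(w * y / pc - (1 - y) / (1 - pc)) / n
  g[p < CLIP_P | p > 1 - CLIP_P] <- 0
  list(loss = loss, grad = array(g, dim(p)))
}

#' Dice loss
#'
#' `1 - (2 * sum(y * p) + eps) / (sum(y) + sum(p) + eps)` with the smoothing
#' constant in both numerator and denominator.
#'
#' @inheritParams wbce_loss
#' @param eps_dice smoothing constant.
#' @return The scalar loss in [0, 1], or `list(loss, grad)`.
#' @export
dice_loss <- function(pred, target, eps_dice = 1e-6, grad = FALSE) {
  p <- as_prob_array(pred)
  y <- as_target_array(target)
  if (length(p) != length(y)) stop("prediction / target shape mismatch")
  num <- 2 * sum(y * p) + eps_dice
  den <- sum(y) + sum(p) + eps_dice
  loss <- 1 - num / den
  if (!grad) return(loss)
  g <- -(2 * y * den - num) / den^2
  list(loss = loss, grad = array(g, dim(p)))
}

#' Composite total loss `alpha * WBCE + beta * Dice`
#'
#' @inheritParams wbce_loss
#' @param cfg a [seg_loss_config].
#' @return The scalar loss, or `list(loss, grad, wbce, dice)` when
#'   `grad = TRUE`.
#' @export
total_loss <- function(pred, target, cfg = seg_loss_config(), grad = FALSE) {
  if (!grad) {
    return(cfg$alpha * wbce_loss(pred, target, cfg$w) +
           cfg$beta * dice_loss(pred, target, cfg$eps_dice))
  }
  a <- wbce_loss(pred, target, cfg$w, grad = TRUE)
  b <- dice_loss(pred, target, cfg$eps_dice, grad = TRUE)
  list(loss = cfg$alpha * a$loss + cfg$beta * b$loss,
       grad = cfg$alpha * a$grad + cfg$beta * b$grad,
       wbce = a$loss, dice = b$loss)
}

#' Segmentation prediction container
#'
#' @param prob H x W probability matrix in (0, 1).
#' @param threshold binarization threshold (default 0.5; the mask is
#'   `prob >= threshold`).
#' @param scale downsample factor of `prob` relative to the source image.
#' @return An object of class `seg_prediction` with fields `prob` and `mask`.
#' @export
seg_prediction <- function(prob, threshold = 0.5, scale = 1) {
  stopifnot(all(is.finite(prob)))
  structure(list(prob = prob, mask = binary_mask(prob >= threshold, scale = scale),
                 threshold = threshold),
            class = "seg_prediction")
}

# ---- architecture ----------------------------------------------------------

rsu_heights <- function(depth) {
  full <- c("7", "6", "5", "4", "F", "F")
  stopifnot(depth >= 2, depth <= 6)
  full[(6 - depth + 1):6]
}

init_rsu <- function(P, name, h, c_in, mid, out) {
  init_conv(P, paste0(name, ".in"), 3, c_in, out)
  if (h == "F") {
    init_conv(P, paste0(name, ".c1"), 3, out, mid)
    for (i in 2:4) init_conv(P, paste0(name, ".c", i), 3, mid, mid)
    for (i in 3:2) init_conv(P, paste0(name, ".d", i), 3, 2 * mid, mid)
    init_conv(P, paste0(name, ".d1"), 3, 2 * mid, out)
  } else {
    L <- as.integer(h)
    init_conv(P, paste0(name, ".c1"), 3, out, mid)
    for (i in 2:L) init_conv(P, paste0(name, ".c", i), 3, mid, mid)
    if (L >= 3) for (i in (L - 1):2) init_conv(P, paste0(name, ".d", i), 3, 2 * mid, mid)
    init_conv(P, paste0(name, ".d1"), 3, 2 * mid, out)
  }
}

rebnconv_fwd <- function(tp, P, name, x, dil = 1L) {
  h <- nn_conv2d(tp, x, P$params[[paste0(name, ".W")]],
                 P$params[[paste0(name, ".b")]], k = 3L,
                 dilation = as.integer(dil), name = name)
  h <- nn_batchnorm(tp, h, P$params[[paste0(name, ".g")]],
                    P$params[[paste0(name, ".be")]], name = name,
                    training = isTRUE(P$training), run = P$stats[[name]])
  nn_relu(tp, h)
}

rsu_fwd <- function(tp, P, name, x, h) {
  hxin <- rebnconv_fwd(tp, P, paste0(name, ".in"), x)
  if (h == "F") {
    h1 <- rebnconv_fwd(tp, P, paste0(name, ".c1"), hxin, 1)
    h2 <- rebnconv_fwd(tp, P, paste0(name, ".c2"), h1, 2)
    h3 <- rebnconv_fwd(tp, P, paste0(name, ".c3"), h2, 4)
    h4 <- rebnconv_fwd(tp, P, paste0(name, ".c4"), h3, 8)
    d3 <- rebnconv_fwd(tp, P, paste0(name, ".d3"), nn_concat(tp, h4, h3), 4)
    d2 <- rebnconv_fwd(tp, P, paste0(name, ".d2"), nn_concat(tp, d3, h2), 2)
    d1 <- rebnconv_fwd(tp, P, paste0(name, ".d1"), nn_concat(tp, d2, h1), 1)
    return(nn_add(tp, d1, hxin))
  }
  L <- as.integer(h)
  enc <- vector("list", L)
  enc[[1]] <- rebnconv_fwd(tp, P, paste0(name, ".c1"), hxin)
  cur <- enc[[1]]
  for (i in 2:(L - 1)) {
    cur <- nn_maxpool2(tp, cur)
    enc[[i]] <- rebnconv_fwd(tp, P, paste0(name, ".c", i), cur)
    cur <- enc[[i]]
  }
  enc[[L]] <- rebnconv_fwd(tp, P, paste0(name, ".c", L), cur, 2)
  d <- enc[[L]]
  for (i in (L - 1):2) {
    d <- rebnconv_fwd(tp, P, paste0(name, ".d", i), nn_concat(tp, d, enc[[i]]))
    # rise to the resolution of the next shallower encoder level
    tgt <- dim(enc[[i - 1]]$value)
    d <- nn_resize(tp, d, tgt[1], tgt[2], "bilinear")
  }
  d <- rebnconv_fwd(tp, P, paste0(name, ".d1"), nn_concat(tp, d, enc[[1]]))
  nn_add(tp, d, hxin)
}

#' Build the small nested-U segmentation network
#'
#' The default configuration is the canonical small nested-U: six
#' encoder/decoder stages of residual U-blocks (heights 7/6/5/4 plus two
#' dilation-only blocks) mixing standard and dilated 3 x 3 convolutions,
#' mid-channel width 16 and stage width 64, one 3 x 3 side output per decoder
#' level fused by a 1 x 1 convolution into a single sigmoid map. The default
#' build has 1.13 M trainable parameters (two decimals, in millions).
#'
#' Smaller desk-scale variants are available through `depth`, `mid_ch` and
#' `base_ch`. Side-output fusion can be modulated by a parameter-free
#' attention gate (normalized per-map confidence weighting); it adds no
#' parameters and is on by default.
#'
#' @param in_channels,out_channels input / output channel counts.
#' @param mid_ch RSU bottleneck width (canonical 16).
#' @param base_ch stage width (canonical 64).
#' @param depth number of encoder stages, 2..6 (canonical 6).
#' @param seed seed for the (He normal) weight initialization.
#' @param attention_fusion logical; apply the parameter-free gate when fusing
#'   side outputs.
#' @return An object of class `u2netp_model` with elements `params` (named
#'   flat list of trainable arrays), `config`, and `n_params`.
#' @export
build_u2netp <- function(in_channels = 3, out_channels = 1, mid_ch = 16,
                         base_ch = 64, depth = 6, seed = 1,
                         attention_fusion = TRUE) {
  heights <- rsu_heights(depth)
  P <- new.env(parent = emptyenv())
  P$params <- list()
  P$stats <- list()
  with_seed(derive_seed(seed, 31), {
    for (i in seq_len(depth)) {
      c_in <- if (i == 1) in_channels else base_ch
      init_rsu(P, paste0("s", i), heights[i], c_in, mid_ch, base_ch)
    }
    for (i in (depth - 1):1)
      init_rsu(P, paste0("s", i, "d"), heights[i], 2 * base_ch, mid_ch, base_ch)
    for (i in seq_len(depth))
      init_conv(P, paste0("side", i), 3, base_ch, out_channels, bn = FALSE)
    init_conv(P, "fuse", 1, depth * out_channels, out_channels, bn = FALSE)
  })
  structure(list(params = P$params, stats = P$stats,
                 config = list(in_channels = in_channels,
                               out_channels = out_channels,
                               mid_ch = mid_ch, base_ch = base_ch,
                               depth = depth, heights = heights, seed = seed,
                               attention_fusion = attention_fusion),
                 n_params = n_trainable(P$params)),
            class = "u2netp_model")
}

#' Trainable parameter count of a model, in millions
#'
#' @param model a `u2netp_model` or `til_detector_model`.
#' @param digits decimals to round to (default 2).
#' @return Parameter count in millions.
#' @export
param_count_millions <- function(model, digits = 2) {
  round(model$n_params / 1e6, digits)
}

# Forward pass; returns the fused sigmoid node plus side sigmoid nodes.
# training = TRUE normalizes with per-sample batch statistics (updating the
# running averages); training = FALSE uses the stored running statistics.
u2netp_fwd <- function(model, x_array, tp = tape_new(), training = TRUE) {
  cfg <- model$config
  P <- list(params = model$params, stats = model$stats, training = training)
  depth <- cfg$depth
  x <- tp_leaf(tp, x_array)
  enc <- vector("list", depth)
  cur <- x
  for (i in seq_len(depth)) {
    enc[[i]] <- rsu_fwd(tp, P, paste0("s", i), cur, cfg$heights[i])
    if (i < depth) cur <- nn_maxpool2(tp, enc[[i]])
  }
  dec <- vector("list", depth)
  dec[[depth]] <- enc[[depth]]
  d <- enc[[depth]]
  for (i in (depth - 1):1) {
    tgt <- dim(enc[[i]]$value)
    dup <- nn_resize(tp, d, tgt[1], tgt[2], "bilinear")
    d <- rsu_fwd(tp, P, paste0("s", i, "d"), nn_concat(tp, dup, enc[[i]]),
                 cfg$heights[i])
    dec[[i]] <- d
  }
  H <- dim(x_array)[1]; W <- dim(x_array)[2]
  sides <- vector("list", depth)
  for (i in seq_len(depth)) {
    s <- nn_conv2d(tp, dec[[i]], model$params[[paste0("side", i, ".W")]],
                   model$params[[paste0("side", i, ".b")]], k = 3L,
                   name = paste0("side", i))
    sides[[i]] <- nn_resize(tp, s, H, W, "bilinear")
  }
  gated <- sides
  if (isTRUE(cfg$attention_fusion)) {
    conf <- vapply(sides, function(s) mean(abs(1 / (1 + exp(-s$value)) - 0.5)), 0)
    wgt <- depth * exp(conf) / sum(exp(conf))   # detached, parameter-free
    gated <- lapply(seq_len(depth), function(i) nn_scale(tp, sides[[i]], wgt[i]))
  }
  cat_sides <- Reduce(function(a, b) nn_concat(tp, a, b), gated)
  fused_logit <- nn_conv2d(tp, cat_sides, model$params[["fuse.W"]],
                           model$params[["fuse.b"]], k = 1L, name = "fuse")
  fused <- nn_sigmoid(tp, fused_logit)
  list(tape = tp, fused = fused,
       sides = lapply(sides, function(s) nn_sigmoid(tp, s)))
}

# ---- training --------------------------------------------------------------

#' Segmenter training configuration
#'
#' Canonical recipe: 640-pixel patches, batch 16, AdamW (beta1 0.9, beta2
#' 0.999, eps 1e-8), initial learning rate 1e-4 with cosine annealing
#' (T_max = 50), up to 300 epochs with early stopping at patience 20. Model
#' geometry arguments select desk-scale variants.
#'
#' @param patch_size square patch side in pixels.
#' @param batch_size gradient-accumulation batch.
#' @param lr0,beta1,beta2,eps_opt AdamW hyperparameters.
#' @param t_max cosine annealing period.
#' @param max_epochs,patience epoch budget and early-stopping patience
#'   (`patience < max_epochs`).
#' @param depth,mid_ch,base_ch model geometry (see [build_u2netp]).
#' @param seed master seed.
#' @return An object of class `seg_train_config`.
#' @export
seg_train_config <- function(patch_size = 640, batch_size = 16,
                             lr0 = 1e-4, beta1 = 0.9, beta2 = 0.999,
                             eps_opt = 1e-8, t_max = 50,
                             max_epochs = 300, patience = 20,
                             depth = 6, mid_ch = 16, base_ch = 64, seed = 1) {
  stopifnot(patch_size >= 16, batch_size >= 1, lr0 > 0, t_max >= 1,
            max_epochs >= 1, patience >= 1, patience < max_epochs)
  structure(list(patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 beta1 = beta1, beta2 = beta2, eps_opt = eps_opt,
                 t_max = t_max, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), depth = depth,
                 mid_ch = mid_ch, base_ch = base_ch, seed = as.integer(seed)),
            class = "seg_train_config")
}

# scene -> list(x = patch x patch x 3 in [0,1] at 5x-equivalent, y = {0,1}).
# The scene is resampled to 5x-equivalent by its mpp, then a patch is cropped
# at native resolution (seeded) — never squeezed — so training and tiled
# inference see the same spatial statistics.
scene_to_patch <- function(scene, patch_size, crop_seed = 1) {
  img <- scene$image
  mpp <- if (!is.null(img$mpp)) img$mpp else MPP_5X
  f <- MPP_5X / mpp
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  h5 <- max(8L, as.integer(round(H / f))); w5 <- max(8L, as.integer(round(W / f)))
  x <- if (f != 1) resize_array(img$pixels, h5, w5, if (f > 1) "area" else "bilinear")
       else img$pixels
  y <- if (f != 1) resize_matrix(scene$parenchyma_truth$grid, h5, w5, "nearest")
       else scene$parenchyma_truth$grid
  if (h5 >= patch_size && w5 >= patch_size) {
    off <- with_seed(crop_seed, c(sample.int(h5 - patch_size + 1L, 1),
                                  sample.int(w5 - patch_size + 1L, 1)))
    x <- x[off[1]:(off[1] + patch_size - 1L),
           off[2]:(off[2] + patch_size - 1L), , drop = FALSE]
    y <- y[off[1]:(off[1] + patch_size - 1L),
           off[2]:(off[2] + patch_size - 1L), drop = FALSE]
  } else {
    x <- resize_array(x, patch_size, patch_size, "bilinear")
    y <- resize_matrix(y, patch_size, patch_size, "nearest")
  }
  list(x = x / 255, y = round(y))
}

seg_val_metrics <- function(model, patches) {
  dices <- prec <- rec <- double(length(patches))
  for (i in seq_along(patches)) {
    out <- u2netp_fwd(model, patches[[i]]$x, training = FALSE)
    prob <- out$fused$value[, , 1]
    pred <- prob >= 0.5
    y <- patches[[i]]$y != 0
    tp_ <- sum(pred & y); fp_ <- sum(pred & !y); fn_ <- sum(!pred & y)
    dices[i] <- if (tp_ + fp_ + fn_ == 0) 1 else 2 * tp_ / (2 * tp_ + fp_ + fn_)
    prec[i] <- if (tp_ + fp_ == 0) NA else tp_ / (tp_ + fp_)
    rec[i] <- if (tp_ + fn_ == 0) NA else tp_ / (tp_ + fn_)
  }
  p <- mean(prec, na.rm = TRUE); r <- mean(rec, na.rm = TRUE)
  f1 <- if (is.finite(p) && is.finite(r) && p + r > 0) 2 * p * r / (p + r) else 0
  list(dice = mean(dices), precision = p, recall = r, f1 = f1)
}

#' Train the parenchyma segmenter
#'
#' AdamW with cosine-annealed learning rate on the composite WBCE + Dice
#' loss; per-epoch validation Dice / precision / recall / F1; early stopping
#' when validation Dice fails to improve for `patience` epochs; the returned
#' checkpoint is the one with the best validation Dice (F1 breaks ties).
#' Fully deterministic given the config seed.
#'
#' @param scenes list of `synthetic_scene` objects (or prepared
#'   `list(x, y)` patches); images are resampled to 5x-equivalent resolution
#'   by their `mpp` and scaled to `patch_size`.
#' @param train_cfg a [seg_train_config].
#' @param loss_cfg a [seg_loss_config].
#' @param val_scenes optional explicit validation set; by default a 70/15/15
#'   slide-level split of `scenes` supplies it.
#' @return `list(model, history)`; `history` has one row per epoch with train
#'   loss, learning rate and validation metrics.
#' @export
train_segmenter <- function(scenes, train_cfg = seg_train_config(),
                            loss_cfg = seg_loss_config(), val_scenes = NULL) {
  if (length(scenes) == 0) stop("empty training dataset")
  prep <- function(s, i) if (inherits(s, "synthetic_scene"))
    scene_to_patch(s, train_cfg$patch_size,
                   crop_seed = derive_seed(train_cfg$seed, 300L + i)) else s
  if (is.null(val_scenes)) {
    if (length(scenes) >= 5) {
      sp <- split_slides(seq_along(scenes), seed = train_cfg$seed)
      val_scenes <- scenes[sp$val]
      scenes <- scenes[sp$train]
    } else val_scenes <- scenes
  }
  train <- Map(prep, scenes, seq_along(scenes))
  val <- Map(prep, val_scenes, 1000L + seq_along(val_scenes))
  model <- build_u2netp(depth = train_cfg$depth, mid_ch = train_cfg$mid_ch,
                        base_ch = train_cfg$base_ch, seed = train_cfg$seed)
  opt <- optimizer_new("adamw", lr = train_cfg$lr0, beta1 = train_cfg$beta1,
                       beta2 = train_cfg$beta2, eps = train_cfg$eps_opt)
  history <- list()
  best <- list(dice = -Inf, f1 = -Inf, params = model$params, epoch = 0L)
  since_best <- 0L
  for (epoch in seq_len(train_cfg$max_epochs) - 1L) {
    lr <- cosine_lr(epoch, train_cfg$lr0, train_cfg$t_max)
    ord <- with_seed(derive_seed(train_cfg$seed, 100L + epoch),
                     sample(seq_along(train)))
    losses <- double(0)
    acc <- NULL; acc_n <- 0L
    for (ii in ord) {
      pt <- train[[ii]]
      fw <- u2netp_fwd(model, pt$x)
      lg <- total_loss(fw$fused$value[, , 1], pt$y, loss_cfg, grad = TRUE)
      losses <- c(losses, lg$loss)
      grads <- tape_backward(fw$tape, fw$fused,
                             array(lg$grad, c(dim(pt$y), 1)))
      if (is.null(acc)) acc <- grads
      else for (nm in names(grads))
        acc[[nm]] <- if (is.null(acc[[nm]])) grads[[nm]] else acc[[nm]] + grads[[nm]]
      acc_n <- acc_n + 1L
      if (acc_n >= train_cfg$batch_size || ii == ord[length(ord)]) {
        acc <- lapply(acc, function(g) g / acc_n)
        st <- optimizer_step(opt, model$params, acc, lr = lr)
        opt <- st$opt; model$params <- st$params
        acc <- NULL; acc_n <- 0L
      }
    }
    vm <- seg_val_metrics(model, val)
    history[[length(history) + 1L]] <-
      data.frame(epoch = epoch, lr = lr, train_loss = mean(losses),
                 val_dice = vm$dice, val_precision = vm$precision,
                 val_recall = vm$recall, val_f1 = vm$f1)
    improved <- vm$dice > best$dice + 1e-6 ||
      (abs(vm$dice - best$dice) <= 1e-6 && vm$f1 > best$f1 + 1e-6)
    if (improved) {
      best <- list(dice = vm$dice, f1 = vm$f1, params = model$params,
                   epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= train_cfg$patience) break
    }
  }
  model$params <- best$params
  model$best_epoch <- best$epoch
  list(model = model, history = do.call(rbind, history))
}

# ---- inference -------------------------------------------------------------

tile_starts <- function(n, tile, overlap) {
  if (n <= tile) return(1L)
  step <- tile - overlap
  st <- seq(1L, n - tile + 1L, by = step)
  if (st[length(st)] != n - tile + 1L) st <- c(st, n - tile + 1L)
  st
}

#' Predict a parenchyma mask for an image
#'
#' The image is resampled to 5x-equivalent resolution (using `mpp`, or
#' `magnification` via the `magnification * mpp = 10` relation), processed in
#' overlapping tiles whose per-pixel probabilities are averaged, thresholded
#' at 0.5, and the mask is brought back to source resolution with
#' nearest-neighbor upsampling.
#'
#' @param model a trained `u2netp_model`.
#' @param image a [raster_image] with known `mpp` or `magnification`.
#' @param tile tile side in pixels (default 640).
#' @param overlap tile overlap in pixels (default 64).
#' @param threshold probability cut for the mask.
#' @return A `seg_prediction`; `prob` is at 5x-equivalent scale, `mask` at
#'   source resolution (scale 1).
#' @export
predict_parenchyma <- function(model, image, tile = 640, overlap = 64,
                               threshold = 0.5) {
  stopifnot(inherits(image, "raster_image"))
  mpp <- image$mpp
  if (is.null(mpp) && !is.null(image$magnification)) mpp <- 10 / image$magnification
  if (is.null(mpp)) stop("image scale unknown: need mpp or magnification")
  f <- MPP_5X / mpp
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  h5 <- max(8L, as.integer(round(H / f)))
  w5 <- max(8L, as.integer(round(W / f)))
  x <- if (f != 1) resize_array(image$pixels, h5, w5, if (f > 1) "area" else "bilinear")
       else image$pixels
  x <- x / 255
  accum <- matrix(0, h5, w5); wsum <- matrix(0, h5, w5)
  tile_prob <- function(xt) {
    if (inherits(model, "til_stub_segmenter"))
      matrix(model$prob, dim(xt)[1], dim(xt)[2])
    else u2netp_fwd(model, xt, training = FALSE)$fused$value[, , 1]
  }
  for (sy in tile_starts(h5, tile, overlap)) {
    for (sx in tile_starts(w5, tile, overlap)) {
      ty <- sy:min(sy + tile - 1L, h5)
      tx <- sx:min(sx + tile - 1L, w5)
      accum[ty, tx] <- accum[ty, tx] + tile_prob(x[ty, tx, , drop = FALSE])
      wsum[ty, tx] <- wsum[ty, tx] + 1
    }
  }
  prob <- accum / wsum
  mask5 <- prob >= threshold
  mask_src <- round(resize_matrix(mask5 * 1, H, W, "nearest")) != 0
  out <- seg_prediction(prob, threshold = threshold, scale = f)
  out$mask <- binary_mask(mask_src, scale = 1)
  out
}
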