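test_that("segmentation losses evaluate to their closed-form values", {
  # WBCE: y = 1, p = 0.5 -> ln 2; perfect prediction -> ~0
  expect_equal(wbce_loss(0.5, 1), log(2), tolerance = 1e-9)
  expect_lt(wbce_loss(c(1, 0), c(1, 0)), 1e-6)
  # y = [1,0], p = [0.9,0.2], w = 2 -> (-2 ln .9 - ln .8)/2
  expect_equal(wbce_loss(c(0.9, 0.2), c(1, 0), w = 2),
               (-2 * log(0.9) - log(0.8)) / 2, tolerance = 1e-9)

  # Dice: y = [1,1,0,0], p = [1,0,0,0] -> 1/3
  expect_equal(dice_loss(c(1, 0, 0, 0), c(1, 1, 0, 0)), 1 / 3, tolerance = 1e-6)
  expect_lt(dice_loss(c(1, 1, 0), c(1, 1, 0)), 1e-5)
  expect_gt(dice_loss(c(0, 0, 1), c(1, 0, 0)), 0.999)

  # composite: alpha/beta recover the parts and combine linearly
  p <- c(0.9, 0.2); y <- c(1, 0)
  expect_equal(total_loss(p, y, seg_loss_config(alpha = 1, beta = 0, w = 2)),
               wbce_loss(p, y, w = 2))
  expect_equal(total_loss(p, y, seg_loss_config(alpha = 0, beta = 1)),
               dice_loss(p, y))
  expect_equal(total_loss(p, y, seg_loss_config(alpha = 0.5, beta = 2, w = 2)),
               0.5 * wbce_loss(p, y, w = 2) + 2 * dice_loss(p, y))

  expect_error(wbce_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "mismatch")
})

test_that("total loss is non-negative, vanishes only at the target, and the
           Dice term is symmetric for binary arguments", {
  set.seed(12)
  for (i in 1:20) {
    y <- rbinom(16, 1, 0.5)
    p <- runif(16)
    expect_gte(total_loss(p, y), 0)
  }
  y <- rbinom(16, 1, 0.5)
  expect_lt(total_loss(pmin(pmax(y, 1e-7), 1 - 1e-7), y), 1e-5)
  a <- rbinom(12, 1, 0.4); b <- rbinom(12, 1, 0.4)
  expect_equal(dice_loss(a, b), dice_loss(b, a))
})

test_that("the default nested-U build carries 1.13 M parameters and side
           structure intact", {
  m <- build_u2netp()
  expect_equal(param_count_millions(m), 1.13)
  expect_equal(m$config$depth, 6)
  expect_equal(m$config$heights, c("7", "6", "5", "4", "F", "F"))
  # six side convs plus the 1x1 fusion
  expect_true(all(paste0("side", 1:6, ".W") %in% names(m$params)))
  expect_equal(dim(m$params[["fuse.W"]]), c(6L, 1L))

  m2 <- build_u2netp(seed = 1)
  expect_identical(m$params, m2$params)       # same seed, same init
  m3 <- build_u2netp(seed = 2)
  expect_false(identical(m$params, m3$params))
})

test_that("forward pass maps 64x64x3 to 64x64 probabilities", {
  m <- build_u2netp()
  set.seed(3)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- tilscope:::u2netp_fwd(m, x, training = FALSE)
  expect_equal(dim(out$fused$value), c(64L, 64L, 1L))
  expect_true(all(out$fused$value > 0 & out$fused$value < 1))
  expect_length(out$sides, 6)
})

test_that("autodiff gradients of the composite loss match finite differences", {
  m <- build_u2netp(depth = 2, mid_ch = 2, base_ch = 3, seed = 3,
                    attention_fusion = FALSE)
  set.seed(42)
  x <- array(runif(4 * 4 * 3), c(4, 4, 3))
  y <- matrix(rbinom(16, 1, 0.5), 4, 4)
  lcfg <- seg_loss_config(alpha = 0.7, beta = 1.3, w = 2)
  fw <- tilscope:::u2netp_fwd(m, x)
  lg <- total_loss(fw$fused$value[, , 1], y, lcfg, grad = TRUE)
  g <- tilscope:::tape_backward(fw$tape, fw$fused, array(lg$grad, c(4, 4, 1)))
  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    total_loss(tilscope:::u2netp_fwd(m2, x)$fused$value[, , 1], y, lcfg)
  }
  for (nm in c("fuse.W", "s1.in.W", "s1d.d1.g", "side1.b", "s2.c2.W")) {
    p <- m$params
    i <- ((utils::head(which(abs(g[[nm]]) == max(abs(g[[nm]]))), 1)))
    h <- 1e-5
    p[[nm]][i] <- p[[nm]][i] + h; lp <- loss_at(p)
    p[[nm]][i] <- p[[nm]][i] - 2 * h; lm <- loss_at(p)
    fd <- (lp - lm) / (2 * h)
    expect_equal(g[[nm]][i], fd, tolerance = 1e-4)
  }
})

test_that("cosine schedule starts at lr0 and bottoms out at T_max", {
  expect_equal(cosine_lr(0, 1e-4, 50), 1e-4)
  expect_equal(cosine_lr(50, 1e-4, 50), 0)
  expect_equal(cosine_lr(25, 1e-4, 50), 5e-5)
  expect_true(all(diff(vapply(0:50, cosine_lr, 0, lr0 = 1e-4, t_max = 50)) < 0))
})

test_that("a short seeded training run reduces the loss and early stopping
           fires after the configured patience", {
  scenes <- lapply(1:6, function(s)
    generate_scene(scene_spec(width = 48, height = 48, n_tissue_blobs = 1,
                              tissue_fraction = 0.6, tumor_fraction = 0.4,
                              lymphocyte_density = 0, seed = 600 + s)))
  cfg <- seg_train_config(patch_size = 32, batch_size = 2, lr0 = 1e-3,
                          max_epochs = 6, patience = 5, depth = 2,
                          mid_ch = 2, base_ch = 4, seed = 2)
  tr <- train_segmenter(scenes, cfg)
  expect_lt(tail(tr$history$train_loss, 1), tr$history$train_loss[1])
  expect_true(all(c("val_dice", "val_precision", "val_recall", "val_f1")
                  %in% names(tr$history)))

  # early-stopping contract: training halts exactly `patience` epochs after
  # the best validation Dice (vanishing learning rate keeps improvements
  # small so the run stops well before max_epochs)
  cfg0 <- seg_train_config(patch_size = 32, batch_size = 2, lr0 = 1e-30,
                           max_epochs = 30, patience = 3, depth = 2,
                           mid_ch = 2, base_ch = 4, seed = 2)
  tr0 <- train_segmenter(scenes, cfg0)
  expect_lt(nrow(tr0$history), 30)
  expect_equal(nrow(tr0$history), which.max(tr0$history$val_dice) + 3)
  expect_equal(tr0$model$best_epoch, which.max(tr0$history$val_dice) - 1)
  expect_error(train_segmenter(list(), cfg), "empty")
})

test_that("tiled inference covers every pixel, creates no seams with a
           constant-probability stub, and respects mask conventions", {
  img <- raster_image(array(sample(0:255, 96 * 96 * 3, TRUE), c(96, 96, 3)),
                      mpp = 2)
  pred <- predict_parenchyma(stub_segmenter(0.8), img, tile = 48, overlap = 16)
  expect_true(all(pred$prob == 0.8))                 # overlap averaging: no seams
  expect_true(all(pred$mask$grid == 1L))             # 0.8 >= 0.5 -> full frame
  expect_equal(dim(pred$mask$grid), c(96L, 96L))

  low <- predict_parenchyma(stub_segmenter(0.3), img, tile = 48, overlap = 16)
  expect_true(all(low$mask$grid == 0L))

  no_scale <- raster_image(array(0, c(16, 16, 3)))
  expect_error(predict_parenchyma(stub_segmenter(), no_scale), "scale unknown")
})
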