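test_that("CIoU evaluates the printed decomposition exactly", {
  b <- c(0, 0, 1, 1)
  same <- ciou_loss(b, b)
  expect_equal(same$loss, 0)
  expect_equal(same$terms$iou, 1)
  expect_equal(same$terms$rho2, 0)
  expect_equal(same$terms$v, 0)

  # unit squares 10 apart: 1 - 0 + 100/122 + 0
  far <- ciou_loss(c(-0.5, -0.5, 0.5, 0.5), c(9.5, -0.5, 10.5, 0.5))
  expect_equal(far$loss, 1 + 100 / 122, tolerance = 1e-6)
  expect_equal(far$terms$iou, 0)
  expect_equal(far$terms$c2, 122)

  # concentric 2x2 vs 2x4: centers coincide, aspects differ
  conc <- ciou_loss(c(-1, -1, 1, 1), c(-1, -2, 1, 2))
  expect_equal(conc$terms$rho2, 0)
  v_hand <- (4 / pi^2) * (atan(2 / 4) - atan(2 / 2))^2
  expect_equal(conc$terms$v, v_hand, tolerance = 1e-12)
  iou_hand <- 4 / 8
  alpha_hand <- v_hand / ((1 - iou_hand) + v_hand)
  expect_equal(conc$loss, 1 - iou_hand + 0 + alpha_hand * v_hand,
               tolerance = 1e-12)
  expect_equal(conc$terms$alpha_ciou, alpha_hand)

  expect_error(ciou_loss(c(0, 0, 0, 1), b), "degenerate")
})

test_that("CIoU is non-negative and reduces to 1 - IoU for matched aspect
           and center, and its gradient matches finite differences", {
  set.seed(8)
  for (i in 1:30) {
    p <- sort(runif(2, 0, 20)); q <- sort(runif(2, 0, 20))
    g <- sort(runif(2, 0, 20)); h <- sort(runif(2, 0, 20))
    if (diff(p) < 0.1 || diff(q) < 0.1 || diff(g) < 0.1 || diff(h) < 0.1) next
    l <- ciou_loss(c(p[1], q[1], p[2], q[2]), c(g[1], h[1], g[2], h[2]))
    expect_gte(l$loss, 0)
  }
  # same center and aspect: loss = 1 - IoU exactly
  l <- ciou_loss(c(-1, -1, 1, 1), c(-2, -2, 2, 2))
  expect_equal(l$loss, 1 - l$terms$iou)

  # analytic gradient vs finite differences (equal aspects, so the detached
  # alpha term vanishes)
  fd <- vapply(1:4, function(j) {
    h <- 1e-6; a <- c(5, 5, 4, 6)
    a1 <- a; a1[j] <- a1[j] + h; a2 <- a; a2[j] <- a2[j] - h
    (tilscope:::ciou_grad(a1[1], a1[2], a1[3], a1[4], 7, 4.5, 4, 6)$loss -
     tilscope:::ciou_grad(a2[1], a2[2], a2[3], a2[4], 7, 4.5, 4, 6)$loss) /
      (2 * h)
  }, 0)
  an <- unlist(tilscope:::ciou_grad(5, 5, 4, 6, 7, 4.5, 4, 6)[
    c("dcx", "dcy", "dw", "dh")])
  expect_equal(unname(an), fd, tolerance = 1e-5)
})

test_that("greedy NMS agrees with the quadratic reference on 1,000 seeded
           instances and satisfies its invariants", {
  # the two stated examples first
  two <- detection_boxes(c(0, 1), c(0, 0), c(10, 11), c(10, 10),
                         confidence = c(0.9, 0.8))
  kept <- nms(two, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)

  disj <- detection_boxes(c(0, 20, 40), c(0, 0, 0), c(5, 25, 45), c(5, 5, 5),
                          confidence = c(0.3, 0.9, 0.6))
  expect_equal(nms(disj, 0.5)$confidence, c(0.9, 0.6, 0.3))

  for (case in 1:1000) {
    n <- sample(2:20, 1)
    thr <- runif(1, 0.2, 0.8)
    boxes <- random_boxes(n, seed = 10000 + case)
    kept <- nms(boxes, thr)
    ref <- oracle_nms(boxes, thr)
    # same set of boxes kept
    expect_equal(sort(paste(kept$x0, kept$y0, kept$x1, kept$y1)),
                 sort(paste(boxes$x0[ref], boxes$y0[ref],
                            boxes$x1[ref], boxes$y1[ref])))
    # invariants: subset, pairwise IoU below threshold, idempotent
    if (case <= 50) {
      M <- as.matrix(kept[, 1:4])
      if (nrow(M) > 1) {
        for (i in 1:(nrow(M) - 1)) {
          ious <- tilscope:::box_iou_vec(M[i, ], M[(i + 1):nrow(M), , drop = FALSE])
          expect_true(all(ious < thr))
        }
      }
      expect_equal(nms(kept, thr), kept)
    }
  }
  expect_equal(nrow(nms(detection_boxes(), 0.5)), 0)
})

test_that("the detector builds P3-P5 grids at strides 8/16/32 with decoupled
           heads and seeded initialization", {
  cfg <- det_train_config(input_size = 64, width = 4, stage_convs = 1, seed = 5)
  m <- build_detector(cfg)
  set.seed(1)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  fw <- tilscope:::detector_fwd(m, x)
  expect_equal(fw$grids, list(c(8L, 8L), c(4L, 4L), c(2L, 2L)))
  for (s in 1:3) {
    expect_equal(dim(fw$heads[[s]]$cls$value)[3], 3L)      # A anchors
    expect_equal(dim(fw$heads[[s]]$box$value)[3], 12L)     # 4A
    dec <- tilscope:::decode_scale(fw$heads[[s]]$cls$value,
                                   fw$heads[[s]]$box$value,
                                   fw$heads[[s]]$obj$value,
                                   cfg$anchors[[s]], c(8L, 16L, 32L)[s])
    expect_true(all(dec$confidence > 0 & dec$confidence < 1))
    expect_true(all(dec$x1 > dec$x0 & dec$y1 > dec$y0))
  }
  m2 <- build_detector(cfg)
  expect_identical(m$params, m2$params)
})

test_that("target assignment follows the center-cell half-open rule and the
           size-ratio gate, and every in-frame box gets an anchor", {
  anchors <- list(cbind(c(16, 16, 16), c(16, 16, 16)),
                  cbind(c(128, 128, 128), c(128, 128, 128)),
                  cbind(c(256, 256, 256), c(256, 256, 256)))
  grids <- list(c(8L, 8L), c(4L, 4L), c(2L, 2L))
  center <- detection_boxes(24, 24, 40, 40, confidence = 0.9)  # 16x16 at (32,32)
  tg <- assign_targets(center, anchors, grids, frame = c(64, 64))
  a3 <- tg$assignments[tg$assignments$scale == 1, ]
  expect_true(all(a3$gy == 5 & a3$gx == 5))  # cell containing (32,32), half-open
  expect_true(all(tg$assignments$scale == 1))  # coarse anchors ratio-excluded
  expect_equal(sum(tg$obj_targets[[2]]), 0)

  # border center at exactly a cell boundary goes to the right/lower cell
  border <- detection_boxes(8, 8, 24, 24, confidence = 0.9)   # center (16,16)
  tgb <- assign_targets(border, anchors, grids, frame = c(64, 64))
  ab <- tgb$assignments[tgb$assignments$scale == 1, ][1, ]
  expect_equal(c(ab$gy, ab$gx), c(3, 3))

  none <- assign_targets(detection_boxes(), anchors, grids, frame = c(64, 64))
  expect_equal(sum(vapply(none$obj_targets, sum, 0)), 0)

  out <- detection_boxes(100, 100, 120, 120, confidence = 0.9)
  expect_warning(assign_targets(out, anchors, grids, frame = c(64, 64)),
                 "outside frame")

  # property: any in-frame box is assigned at least one anchor (fallback rule)
  set.seed(77)
  for (i in 1:25) {
    b <- random_boxes(1, seed = 600 + i, frame = 64)
    tgi <- assign_targets(b, anchors, grids, frame = c(64, 64))
    expect_gte(nrow(tgi$assignments), 1)
  }
})

test_that("detection loss composes BCE + BCE + CIoU with the stated
           degenerate behavior", {
  anchors <- list(cbind(c(16, 16, 16), c(16, 16, 16)),
                  cbind(c(128, 128, 128), c(128, 128, 128)),
                  cbind(c(256, 256, 256), c(256, 256, 256)))
  grids <- list(c(8L, 8L), c(4L, 4L), c(2L, 2L))
  mk_heads <- function(const = 0) lapply(grids, function(g) list(
    cls = array(const, c(g, 3)), box = array(0, c(g, 3 * 4)),
    obj = array(const, c(g, 3))))

  # no ground truth: box term zero, obj term = BCE of logits against zeros
  tg0 <- assign_targets(detection_boxes(), anchors, grids, frame = c(64, 64))
  l0 <- detection_loss(mk_heads(0), tg0, detection_boxes(), anchors, c(64, 64))
  expect_equal(l0$box_ciou, 0)
  expect_equal(l0$cls_bce, 0)
  expect_equal(l0$obj_bce, log(2), tolerance = 1e-9)  # sigmoid(0) vs 0

  # single box: total equals the hand-assembled sum of the three parts
  gt <- detection_boxes(24, 24, 40, 40, confidence = 0.9)
  tg <- assign_targets(gt, anchors, grids, frame = c(64, 64))
  heads <- mk_heads(0.3)
  l <- detection_loss(heads, tg, gt, anchors, c(64, 64))
  sig <- function(z) 1 / (1 + exp(-z))
  # objness BCE by hand over all anchors
  n_tot <- sum(vapply(grids, function(g) prod(g) * 3, 0))
  y <- unlist(lapply(tg$obj_targets, as.vector))
  z <- rep(0.3, n_tot)
  obj_hand <- mean(-y * log(sig(z)) - (1 - y) * log(1 - sig(z)))
  expect_equal(l$obj_bce, obj_hand, tolerance = 1e-9)
  # cls BCE by hand: all assigned anchors have logit 0.3, target 1
  expect_equal(l$cls_bce, -log(sig(0.3)), tolerance = 1e-9)
  # box: decode anchor at the assigned cell and evaluate CIoU directly
  a1 <- tg$assignments[1, ]
  stride <- 8
  cx <- (2 * sig(0) - 0.5 + (a1$gx - 1)) * stride
  cy <- (2 * sig(0) - 0.5 + (a1$gy - 1)) * stride
  w <- (2 * sig(0))^2 * 16
  box_hand <- ciou_loss(c(cx - w / 2, cy - w / 2, cx + w / 2, cy + w / 2),
                        c(24, 24, 40, 40))$loss
  expect_equal(l$box_ciou, box_hand, tolerance = 1e-9)
  expect_equal(l$total, l$cls_bce + l$obj_bce + l$box_ciou)

  # perfect box prediction at the assigned anchors: box term ~ 0
  heads2 <- mk_heads(0.3)
  for (k in seq_len(nrow(tg$assignments))) {
    aa <- tg$assignments[k, ]
    st <- c(8, 16, 32)[aa$scale]
    # invert the decode for the true center/size
    txy <- function(c_img, cell) {
      u <- (c_img / st - (cell - 1) + 0.5) / 2
      log(u / (1 - u))
    }
    tw <- function(w_img, aw) {
      u <- sqrt(w_img / aw) / 2
      log(u / (1 - u))
    }
    ix <- (aa$a - 1) * 4
    heads2[[aa$scale]]$box[aa$gy, aa$gx, ix + 1] <- txy(32, aa$gx)
    heads2[[aa$scale]]$box[aa$gy, aa$gx, ix + 2] <- txy(32, aa$gy)
    heads2[[aa$scale]]$box[aa$gy, aa$gx, ix + 3] <- tw(16, anchors[[aa$scale]][aa$a, 1])
    heads2[[aa$scale]]$box[aa$gy, aa$gx, ix + 4] <- tw(16, anchors[[aa$scale]][aa$a, 2])
  }
  l2 <- detection_loss(heads2, tg, gt, anchors, c(64, 64))
  expect_lt(l2$box_ciou, 1e-9)
})

test_that("stub-based detection gates to stroma and deduplicates across tiles", {
  boxes <- detection_boxes(c(10, 40), c(10, 40), c(20, 50), c(20, 50),
                           confidence = c(0.9, 0.8))
  cfg <- det_train_config(input_size = 64, width = 4, stage_convs = 1)
  stub <- stub_detector(boxes, cfg)
  img <- raster_image(array(200, c(64, 64, 3)), mpp = 0.5)

  # all-zero stroma: nothing survives
  none <- detect_tils(stub, img, binary_mask(matrix(0L, 64, 64)), cfg)
  expect_equal(nrow(none), 0)

  # stroma covering only the first box's center
  g <- matrix(0L, 64, 64); g[1:32, 1:32] <- 1L
  one <- detect_tils(stub, img, binary_mask(g), cfg)
  expect_equal(nrow(one), 1)
  expect_equal(one$confidence, 0.9)

  # duplicated stub boxes collapse to one detection after NMS
  dup <- stub_detector(rbind(boxes, boxes), cfg)
  both <- detect_tils(dup, img, binary_mask(matrix(1L, 64, 64)), cfg)
  expect_equal(nrow(both), 2)
})

test_that("a tiny seeded training run decreases the loss deterministically", {
  scenes <- lapply(1:4, function(s)
    generate_scene(scene_spec(width = 64, height = 64, n_tissue_blobs = 1,
                              tissue_fraction = 0.8, tumor_fraction = 0.1,
                              lymphocyte_density = 4000, mpp = 0.5,
                              seed = 700 + s)))
  cfg <- det_train_config(input_size = 64, batch_size = 1, max_epochs = 4,
                          mpp = 0.5, width = 4, stage_convs = 1, seed = 5,
                          lr0 = 1e-2, momentum = 0.9)
  tr1 <- train_detector(scenes, cfg, val_scenes = scenes[1])
  expect_lt(tail(tr1$history$train_loss, 1), tr1$history$train_loss[1])
  tr2 <- train_detector(scenes, cfg, val_scenes = scenes[1])
  expect_identical(tr1$history, tr2$history)
  expect_identical(tr1$model$params, tr2$model$params)
  expect_error(train_detector(list(), cfg), "empty")
})
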