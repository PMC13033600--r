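test_that("scene generation is deterministic and honors its invariants", {
  s1 <- generate_scene(scene_spec(width = 96, height = 96, seed = 7))
  s2 <- generate_scene(scene_spec(width = 96, height = 96, seed = 7))
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$lymphocyte_truth, s2$lymphocyte_truth)

  s3 <- generate_scene(scene_spec(width = 96, height = 96, seed = 8))
  expect_false(identical(s1$image$pixels, s3$image$pixels))

  # parenchyma inside tissue; lymphocyte centers in stroma
  for (sc in list(s1, s3)) {
    expect_true(all(sc$parenchyma_truth$grid <= sc$tissue_truth$grid))
    lt <- sc$lymphocyte_truth
    if (nrow(lt)) {
      ix <- cbind(floor(lt$y) + 1, floor(lt$x) + 1)
      expect_true(all(sc$tissue_truth$grid[ix] == 1))
      expect_true(all(sc$parenchyma_truth$grid[ix] == 0))
    }
  }

  none <- generate_scene(scene_spec(width = 64, height = 64,
                                    lymphocyte_density = 0, seed = 3))
  expect_equal(nrow(none$lymphocyte_truth), 0)

  expect_error(scene_spec(tumor_fraction = 0.96), "no stroma")
})

test_that("realized lymphocyte counts follow the Poisson placement law", {
  # pooled over seeds: total count within 3 SE of density x stromal area
  dens <- 1500
  total <- 0; expected <- 0
  for (s in 1:60) {
    sc <- generate_scene(scene_spec(width = 72, height = 72, n_tissue_blobs = 1,
                                    tissue_fraction = 0.7, tumor_fraction = 0.2,
                                    lymphocyte_density = dens, mpp = 2,
                                    seed = 500 + s))
    stroma_mm2 <- sum(sc$tissue_truth$grid * (1 - sc$parenchyma_truth$grid)) *
      (2 / 1000)^2
    total <- total + nrow(sc$lymphocyte_truth)
    expected <- expected + dens * stroma_mm2
  }
  expect_lt(abs(total - expected), 3 * sqrt(expected))
})

test_that("realized tissue fraction tracks the requested target", {
  fr <- vapply(1:50, function(s)
    mean(generate_scene(scene_spec(width = 96, height = 96,
                                   tissue_fraction = 0.5,
                                   seed = 900 + s))$tissue_truth$grid), 0)
  expect_lt(mean(abs(fr - 0.5)), 0.05)
})

test_that("median denoising equals the brute-force sliding-window oracle", {
  set.seed(21)
  img <- raster_image(array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3)))
  for (radius in c(1, 2)) {
    out <- denoise(img, "median", radius = radius)
    # replicate-padded brute force on channel 1
    ch <- img$pixels[, , 1]
    oracle <- matrix(0, 32, 32)
    for (y in 1:32) for (x in 1:32) {
      ys <- pmin(pmax((y - radius):(y + radius), 1), 32)
      xs <- pmin(pmax((x - radius):(x + radius), 1), 32)
      oracle[y, x] <- stats::median(ch[ys, xs])
    }
    expect_equal(out$pixels[, , 1], matrix(as.integer(round(oracle)), 32, 32))
  }
  # a single salt pixel is replaced by its neighborhood median
  flat <- array(100, c(8, 8, 3))
  flat[4, 4, ] <- 255
  cleaned <- denoise(raster_image(flat), "median", 1)
  expect_equal(cleaned$pixels[4, 4, 1], 100L)

  # constant images are unchanged by both filters
  const <- raster_image(array(77, c(8, 8, 3)))
  expect_equal(denoise(const, "gaussian", 2)$pixels, const$pixels)
  expect_equal(denoise(const, "median", 1)$pixels, const$pixels)
  expect_error(denoise(const, "boxcar"), "arg")
})

test_that("augmentation applies geometry jointly and is seeded", {
  sc <- generate_scene(scene_spec(width = 48, height = 48, seed = 5))
  masks <- list(sc$tissue_truth, sc$parenchyma_truth)
  pts <- sc$lymphocyte_truth

  # identity configuration changes nothing
  ident <- augment(sc$image, masks, pts,
                   augment_config(p_hflip = 0, p_vflip = 0, p_rot90 = 0,
                                  crop_range = c(1, 1), hue_jitter = 0,
                                  sat_jitter = 0, val_jitter = 0, seed = 1))
  expect_identical(ident$image$pixels, sc$image$pixels)
  expect_identical(ident$masks[[1]]$grid, sc$tissue_truth$grid)
  expect_equal(ident$points$x, pts$x)

  # horizontal flip is an involution (same geometry draw both times)
  cfgf <- augment_config(p_hflip = 1, p_vflip = 0, p_rot90 = 0,
                         crop_range = c(1, 1), hue_jitter = 0,
                         sat_jitter = 0, val_jitter = 0, seed = 2)
  once <- augment(sc$image, masks, pts, cfgf)
  twice <- augment(once$image, once$masks, once$points, cfgf)
  expect_identical(twice$image$pixels, sc$image$pixels)
  expect_identical(twice$masks[[2]]$grid, sc$parenchyma_truth$grid)
  expect_equal(sort(twice$points$x), sort(pts$x), tolerance = 1e-9)

  # same seed, same result; different seed, different draws
  a <- augment(sc$image, masks, pts, augment_config(seed = 9))
  b <- augment(sc$image, masks, pts, augment_config(seed = 9))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$draws, b$draws)
})

test_that("crop-area draws stay inside the configured range and points are
           dropped exactly when their centers leave the window", {
  sc <- generate_scene(scene_spec(width = 40, height = 40, seed = 6,
                                  lymphocyte_density = 800))
  areas <- vapply(1:200, function(s)
    augment(sc$image, list(), NULL,
            augment_config(p_hflip = 0, p_vflip = 0, p_rot90 = 0,
                           hue_jitter = 0, sat_jitter = 0, val_jitter = 0,
                           seed = s))$draws$area, 0)
  expect_true(all(areas >= 0.85 & areas <= 1.00))

  pts <- sc$lymphocyte_truth
  out <- augment(sc$image, list(), pts,
                 augment_config(p_hflip = 0, p_vflip = 0, p_rot90 = 0,
                                crop_range = c(0.85, 0.86), hue_jitter = 0,
                                sat_jitter = 0, val_jitter = 0, seed = 4))
  w <- out$draws$window  # c(ox, oy, cw, ch)
  keep <- pts$x >= w[1] & pts$x < w[1] + w[3] &
          pts$y >= w[2] & pts$y < w[2] + w[4]
  expect_equal(nrow(out$points), sum(keep))
})

test_that("slide-level split has the documented sizes and is a partition", {
  sp <- split_slides(sprintf("s%02d", 1:20), seed = 1)
  expect_equal(lengths(sp), c(train = 14L, val = 3L, test = 3L))

  sp3 <- split_slides(c("a", "b", "c"), seed = 1)
  expect_equal(lengths(sp3), c(train = 1L, val = 1L, test = 1L))

  ids <- sprintf("w%03d", 1:37)
  for (seed in 1:100) {
    sp <- split_slides(ids, seed = seed)
    all_out <- c(sp$train, sp$val, sp$test)
    expect_setequal(all_out, ids)
    expect_equal(anyDuplicated(all_out), 0L)
  }
  expect_error(split_slides(c("a", "a", "b")), "duplicate")
  expect_error(split_slides(c("a", "b")), "at least 3")
})

test_that("nearest-neighbor inpainting fills holes from surrounding pixels", {
  img <- raster_image(array(rep(c(10, 200), each = 16 * 8), c(16, 16, 3)))
  miss <- matrix(0L, 16, 16); miss[8, 8] <- 1L
  out <- inpaint_nearest(img, binary_mask(miss))
  expect_true(out$pixels[8, 8, 1] %in% c(10L, 200L))
  untouched <- img$pixels; untouched[8, 8, ] <- out$pixels[8, 8, ]
  expect_identical(out$pixels, untouched)
})
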