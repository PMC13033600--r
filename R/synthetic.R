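# Seeded synthetic H&E-like scenes with exact ground truth, the augmentation
# recipe, slide-level splitting, and denoising utilities.

#' Specification of a synthetic H&E scene
#'
#' @param width,height scene size in pixels.
#' @param n_tissue_blobs number of tissue fragments.
#' @param tissue_fraction target fraction of the frame covered by tissue.
#' @param tumor_fraction target fraction of tissue covered by tumor
#'   parenchyma (must be <= 0.95 so stroma remains to host lymphocytes).
#' @param lymphocyte_density expected lymphocytes per mm^2 of stroma.
#' @param mpp microns per pixel (nominal magnification is taken as `10 / mpp`,
#'   the usual scanner relation: 1 micron per pixel at 10x).
#' @param stain_fade 0 (normal staining) to 1 (maximally faded toward white).
#' @param seed integer seed; all randomness of the scene flows from it through
#'   per-phase derived streams.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 384, height = 384, n_tissue_blobs = 2,
                       tissue_fraction = 0.5, tumor_fraction = 0.35,
                       lymphocyte_density = 300, mpp = 2.0,
                       stain_fade = 0, seed = 1) {
  stopifnot(width >= 16, height >= 16, n_tissue_blobs >= 0,
            tissue_fraction >= 0, tissue_fraction <= 1,
            tumor_fraction >= 0, tumor_fraction <= 1,
            lymphocyte_density >= 0, mpp > 0,
            stain_fade >= 0, stain_fade <= 1)
  if (tumor_fraction > 0.95)
    stop("tumor_fraction > 0.95 leaves no stroma to host lymphocytes")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_tissue_blobs = as.integer(n_tissue_blobs),
                 tissue_fraction = tissue_fraction,
                 tumor_fraction = tumor_fraction,
                 lymphocyte_density = lymphocyte_density,
                 mpp = mpp, stain_fade = stain_fade, seed = as.integer(seed)),
            class = "scene_spec")
}

# random star-convex blob polygon around (cx, cy) with base radius r
random_blob_polygon <- function(cx, cy, r, n_vertices = 72, roughness = 0.25) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  amp <- stats::runif(4, 0, roughness / (1:4))
  phase <- stats::runif(4, 0, 2 * pi)
  rr <- r * (1 + Reduce(`+`, lapply(1:4, function(k)
    amp[k] * cos((k + 1) * theta + phase[k]))))
  rr <- pmax(rr, 0.2 * r)
  cbind(cx + rr * cos(theta), cy + rr * sin(theta))
}

# rasterize one polygon into a logical H x W grid, bounding-box restricted
fill_polygon_grid <- function(H, W, coords) {
  x0 <- max(1L, floor(min(coords[, 1])) ); x1 <- min(W, ceiling(max(coords[, 1])) + 1L)
  y0 <- max(1L, floor(min(coords[, 2])) ); y1 <- min(H, ceiling(max(coords[, 2])) + 1L)
  g <- matrix(FALSE, H, W)
  if (x0 > x1 || y0 > y1) return(g)
  xs <- rep(x0:x1, each = y1 - y0 + 1) - 0.5
  ys <- rep(y0:y1, times = x1 - x0 + 1) - 0.5
  inside <- points_in_polygon(xs, ys, coords)
  g[cbind(rep(y0:y1, times = x1 - x0 + 1), rep(x0:x1, each = y1 - y0 + 1))] <- inside
  g
}

# grow a union of random blobs until it covers target_px of the allowed area
grow_blobs <- function(H, W, n_blobs, target_px, allowed = NULL, r0 = NULL) {
  g <- matrix(FALSE, H, W)
  polys <- list()
  if (n_blobs < 1 || target_px <= 0) return(list(grid = g, polygons = polys))
  if (is.null(r0)) r0 <- sqrt(target_px / n_blobs / pi)
  allowed_idx <- if (is.null(allowed)) NULL else which(allowed)
  for (b in seq_len(n_blobs)) {
    if (is.null(allowed_idx)) {
      cx <- stats::runif(1, 0.25 * W, 0.75 * W)
      cy <- stats::runif(1, 0.25 * H, 0.75 * H)
    } else {
      i <- allowed_idx[sample.int(length(allowed_idx), 1)]
      cy <- (i - 1) %% H + 1 - 0.5
      cx <- (i - 1) %/% H + 1 - 0.5
    }
    r <- r0 * stats::runif(1, 0.75, 1.25)
    poly <- random_blob_polygon(cx, cy, r)
    polys[[b]] <- poly
    g <- g | fill_polygon_grid(H, W, poly)
  }
  # rescale blob radii about their centers to approach the target coverage
  for (iter in 1:3) {
    cov <- sum(if (is.null(allowed)) g else (g & allowed))
    if (cov <= 0) break
    s <- sqrt(target_px / cov)
    if (abs(s - 1) < 0.03) break
    g <- matrix(FALSE, H, W)
    for (b in seq_along(polys)) {
      p <- polys[[b]]
      c0 <- colMeans(p)
      p <- sweep(sweep(p, 2, c0), 2, c(s, s), `*`)
      p <- sweep(p, 2, c0, `+`)
      polys[[b]] <- p
      g <- g | fill_polygon_grid(H, W, p)
    }
  }
  list(grid = g, polygons = polys)
}

# Spatially correlated noise: i.i.d. normal values on a coarse block grid,
# expanded to pixel resolution. Emulates the cellular/staining mottle that
# makes real tissue strongly textured even on low-power thumbnails.
block_noise <- function(H, W, block, sd) {
  hb <- ceiling(H / block); wb <- ceiling(W / block)
  N <- matrix(stats::rnorm(hb * wb, 0, sd), hb, wb)
  N[rep(seq_len(hb), each = block)[seq_len(H)],
    rep(seq_len(wb), each = block)[seq_len(W)]]
}

draw_disc <- function(img, cx, cy, r, rgb_col) {
  H <- dim(img)[1]; W <- dim(img)[2]
  x0 <- max(1L, floor(cx - r)); x1 <- min(W, ceiling(cx + r) + 1L)
  y0 <- max(1L, floor(cy - r)); y1 <- min(H, ceiling(cy + r) + 1L)
  if (x0 > x1 || y0 > y1) return(img)
  xs <- (x0:x1) - 0.5; ys <- (y0:y1) - 0.5
  dx2 <- outer(rep(1, length(ys)), (xs - cx)^2)
  dy2 <- outer((ys - cy)^2, rep(1, length(xs)))
  hit <- (dx2 + dy2) <= r^2
  for (k in 1:3) {
    ch <- img[y0:y1, x0:x1, k]
    ch[hit] <- rgb_col[k]
    img[y0:y1, x0:x1, k] <- ch
  }
  img
}

#' Generate a synthetic H&E-like scene with exact ground truth
#'
#' Renders a white glass background, pink stroma-textured tissue fragments
#' that pass the HSV stain gate, darker purple tumor-parenchyma blobs with
#' nuclear speckle texture, and lymphocytes as near-circular dark-blue discs
#' of diameter 6-10 microns (converted through `mpp`). The realized
#' lymphocyte count is Poisson with mean `lymphocyte_density x stromal area`.
#' Fully deterministic given `spec$seed`.
#'
#' @param spec a [scene_spec].
#' @return An object of class `synthetic_scene`: `image` ([raster_image]),
#'   `tissue_truth` / `parenchyma_truth` ([binary_mask], scale 1),
#'   `lymphocyte_truth` (data frame of centers x, y and radii),
#'   `density_realized` (cells per mm^2 of stroma), `annotations`
#'   ([annotation_set] of truth polygons and points), and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$height; W <- spec$width
  # phase 1: geometry
  geo <- with_seed(derive_seed(spec$seed, 1), {
    tis <- grow_blobs(H, W, spec$n_tissue_blobs,
                      target_px = spec$tissue_fraction * H * W)
    par_target <- spec$tumor_fraction * sum(tis$grid)
    n_par <- max(1L, spec$n_tissue_blobs)
    par <- if (par_target > 0 && sum(tis$grid) > 0)
      grow_blobs(H, W, n_par, target_px = par_target, allowed = tis$grid)
    else list(grid = matrix(FALSE, H, W), polygons = list())
    par$grid <- par$grid & tis$grid   # parenchyma is a subset of tissue
    list(tissue = tis, parenchyma = par)
  })
  tissue <- geo$tissue$grid
  parench <- geo$parenchyma$grid
  stroma <- tissue & !parench

  # phase 2: lymphocyte placement (Poisson in stroma area)
  mm2_per_px <- (spec$mpp / 1000)^2
  stroma_mm2 <- sum(stroma) * mm2_per_px
  lym <- with_seed(derive_seed(spec$seed, 2), {
    n <- if (spec$lymphocyte_density > 0 && stroma_mm2 > 0)
      stats::rpois(1, spec$lymphocyte_density * stroma_mm2) else 0L
    idx <- which(stroma)
    n <- min(n, length(idx))
    if (n > 0) {
      pick <- idx[sample.int(length(idx), n, replace = FALSE)]
      y <- (pick - 1) %% H + 1 - 0.5 + stats::runif(n, -0.45, 0.45)
      x <- (pick - 1) %/% H + 1 - 0.5 + stats::runif(n, -0.45, 0.45)
      d_um <- stats::runif(n, 6, 10)
      data.frame(x = x, y = y, r = d_um / 2 / spec$mpp)
    } else data.frame(x = double(), y = double(), r = double())
  })

  # phase 3: rendering
  img <- with_seed(derive_seed(spec$seed, 3), {
    base <- stats::runif(H * W, 245, 255)
    img <- array(0, c(H, W, 3))
    for (k in 1:3) img[, , k] <- matrix(base + stats::runif(H * W, -1, 1), H, W)
    # stroma: pink with dense cellular mottle. The correlated texture is what
    # keeps real tissue strongly non-uniform on low-power thumbnails (nuclei,
    # fibers), and it is what the edge channel of the contour stage keys on.
    stroma_col <- c(234, 168, 205)
    n_t <- sum(tissue)
    if (n_t > 0) {
      tex <- block_noise(H, W, 2, 26) + block_noise(H, W, 8, 10) +
        matrix(stats::rnorm(H * W, 0, 5), H, W)
      for (k in 1:3) {
        ch <- img[, , k]
        ch[tissue] <- stroma_col[k] + tex[tissue]
        img[, , k] <- ch
      }
    }
    # parenchyma: darker purple, stronger nuclear texture
    par_col <- c(150, 95, 170)
    n_p <- sum(parench)
    if (n_p > 0) {
      texp <- block_noise(H, W, 2, 30) + block_noise(H, W, 8, 10) +
        matrix(stats::rnorm(H * W, 0, 6), H, W)
      for (k in 1:3) {
        ch <- img[, , k]
        ch[parench] <- par_col[k] + texp[parench]
        img[, , k] <- ch
      }
      # nuclear speckles
      pidx <- which(parench)
      n_spk <- max(1L, as.integer(length(pidx) / 40))
      spk <- pidx[sample.int(length(pidx), min(n_spk, length(pidx)))]
      for (k in 1:3) {
        ch <- img[, , k]
        ch[spk] <- ch[spk] - 55
        img[, , k] <- ch
      }
    }
    # lymphocytes: dark blue discs
    if (nrow(lym) > 0) {
      lcol <- c(62, 54, 120)
      for (i in seq_len(nrow(lym)))
        img <- draw_disc(img, lym$x[i], lym$y[i], lym$r[i], lcol)
    }
    if (spec$stain_fade > 0)
      img <- img * (1 - spec$stain_fade) + 255 * spec$stain_fade
    pmin(pmax(round(img), 0), 255)
  })

  tissue_mask <- binary_mask(tissue)
  par_mask <- binary_mask(parench)
  # internal invariant checks before returning
  stopifnot(all(par_mask$grid <= tissue_mask$grid))
  if (nrow(lym) > 0) {
    ix <- cbind(pmin(pmax(floor(lym$y) + 1L, 1L), H),
                pmin(pmax(floor(lym$x) + 1L, 1L), W))
    stopifnot(all(tissue_mask$grid[ix] == 1L), all(par_mask$grid[ix] == 0L))
  }
  polys <- c(lapply(geo$tissue$polygons, function(p)
               list(class = "tissue", coords = pmax(p, 0))),
             lapply(geo$parenchyma$polygons, function(p)
               list(class = "tumor", coords = pmax(p, 0))))
  ann <- suppressWarnings(annotation_set(
    polys,
    if (nrow(lym) > 0) data.frame(class = "lymphocyte", x = lym$x, y = lym$y)
    else NULL))
  structure(list(
    image = raster_image(img, mpp = spec$mpp, magnification = 10 / spec$mpp),
    tissue_truth = tissue_mask,
    parenchyma_truth = par_mask,
    lymphocyte_truth = lym,
    density_realized = if (stroma_mm2 > 0) nrow(lym) / stroma_mm2 else 0,
    annotations = ann,
    spec = spec
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene %d x %d px, tissue %.1f%%, parenchyma %.1f%%, %d lymphocytes>\n",
    dim(x$image$pixels)[2], dim(x$image$pixels)[1],
    100 * mean(x$tissue_truth$grid), 100 * mean(x$parenchyma_truth$grid),
    nrow(x$lymphocyte_truth)))
  invisible(x)
}

# ---- denoising -------------------------------------------------------------

# 1-D replicate-padded filter as a dense operator (images here are small)
gauss_operator <- function(n, radius) {
  sigma <- radius / 2
  off <- -radius:radius
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + off, 1), n)   # replicate padding
    for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + w[t]
  }
  K
}

median_filter_channel <- function(X, radius) {
  H <- nrow(X); W <- ncol(X)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  stack <- matrix(0, H * W, nrow(offs))
  for (t in seq_len(nrow(offs))) {
    ys <- pmin(pmax(seq_len(H) + offs$dy[t], 1), H)
    xs <- pmin(pmax(seq_len(W) + offs$dx[t], 1), W)
    stack[, t] <- as.vector(X[ys, xs])
  }
  matrix(apply(stack, 1, stats::median), H, W)
}

#' Denoise an image with Gaussian or median filtering
#'
#' Channelwise filtering with replicate padding at the borders. The Gaussian
#' kernel has `sigma = radius / 2`, truncated at `radius`; the median filter
#' uses the full `(2 radius + 1)^2` window.
#'
#' @param image a [raster_image].
#' @param method `"gaussian"` or `"median"`.
#' @param radius window radius in pixels, >= 1.
#' @return A [raster_image] of the same shape.
#' @export
denoise <- function(image, method = c("gaussian", "median"), radius = 1) {
  stopifnot(inherits(image, "raster_image"), radius >= 1)
  method <- match.arg(method)
  p <- image$pixels
  out <- array(0, dim(p))
  if (method == "gaussian") {
    Ky <- gauss_operator(dim(p)[1], radius)
    Kx <- gauss_operator(dim(p)[2], radius)
    for (k in 1:3) out[, , k] <- Ky %*% p[, , k] %*% t(Kx)
  } else {
    for (k in 1:3) out[, , k] <- median_filter_channel(p[, , k], radius)
  }
  raster_image(pmin(pmax(round(out), 0), 255),
               mpp = image$mpp, magnification = image$magnification)
}

#' Mask-guided nearest-neighbor inpainting
#'
#' Replaces pixels flagged missing by the value of their nearest (4-connected
#' breadth-first) non-missing pixel. Exposed for reconstructing small dropout
#' regions; not applied anywhere by default.
#'
#' @param image a [raster_image].
#' @param missing a [binary_mask] (1 = missing) at image resolution.
#' @return A [raster_image].
#' @export
inpaint_nearest <- function(image, missing) {
  stopifnot(inherits(image, "raster_image"), inherits(missing, "binary_mask"))
  p <- image$pixels
  H <- dim(p)[1]; W <- dim(p)[2]
  if (!all(dim(missing$grid) == c(H, W))) stop("mask shape mismatch")
  src <- matrix(seq_len(H * W), H, W)     # index of the filling source pixel
  known <- missing$grid == 0L
  if (all(known) || !any(known)) return(image)
  frontier <- which(known)
  filled <- known
  while (length(frontier)) {
    nxt <- integer()
    y <- (frontier - 1L) %% H + 1L
    x <- (frontier - 1L) %/% H + 1L
    for (k in 1:4) {
      ny <- y + c(-1L, 1L, 0L, 0L)[k]
      nx <- x + c(0L, 0L, -1L, 1L)[k]
      ok <- ny >= 1 & ny <= H & nx >= 1 & nx <= W
      ni <- (nx[ok] - 1L) * H + ny[ok]
      new <- !filled[ni]
      ni <- ni[new]; from <- frontier[ok][new]
      if (length(ni)) {
        keep <- !duplicated(ni)
        ni <- ni[keep]; from <- from[keep]
        src[ni] <- src[from]
        filled[ni] <- TRUE
        nxt <- c(nxt, ni)
      }
    }
    frontier <- nxt
  }
  for (k in 1:3) {
    ch <- p[, , k]
    p[, , k] <- matrix(ch[as.vector(src)], H, W)
  }
  raster_image(p, mpp = image$mpp, magnification = image$magnification)
}

# ---- augmentation ----------------------------------------------------------

#' Augmentation configuration
#'
#' Defaults follow the recipe used for training: random horizontal/vertical
#' flips and 90-degree rotations, random cropping to 85-100% of the original
#' area (resized back), and HSV perturbation of hue +/-10% (of the 0-180
#' half-degree hue scale, i.e. +/-18), saturation +/-15% and value +/-10%
#' (multiplicative).
#'
#' @param p_hflip,p_vflip,p_rot90 probabilities of each geometric op.
#' @param crop_range length-2 area-fraction range, within (0, 1].
#' @param hue_jitter half-range of the additive hue shift as a fraction of the
#'   hue scale (0.10 = +/-18 half-degrees).
#' @param sat_jitter,val_jitter half-ranges of the multiplicative S / V
#'   factors (0.15 = factors in 0.85..1.15).
#' @param seed integer seed.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(p_hflip = 0.5, p_vflip = 0.5, p_rot90 = 0.5,
                           crop_range = c(0.85, 1.00),
                           hue_jitter = 0.10, sat_jitter = 0.15,
                           val_jitter = 0.10, seed = 1) {
  stopifnot(p_hflip >= 0, p_hflip <= 1, p_vflip >= 0, p_vflip <= 1,
            p_rot90 >= 0, p_rot90 <= 1,
            length(crop_range) == 2, crop_range[1] > 0, crop_range[2] <= 1,
            crop_range[1] <= crop_range[2],
            hue_jitter >= 0, sat_jitter >= 0, val_jitter >= 0)
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip, p_rot90 = p_rot90,
                 crop_range = crop_range, hue_jitter = hue_jitter,
                 sat_jitter = sat_jitter, val_jitter = val_jitter,
                 seed = as.integer(seed)),
            class = "augment_config")
}

rot90_cw_mat <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Apply the augmentation recipe to an image with registered truth
#'
#' Geometric operations (flips, 90-degree rotations, crop + resize back) are
#' applied identically to the image, every mask, and the point list; color
#' jitter touches the image only. Images are resized bilinearly, masks with
#' nearest neighbor (so they stay binary), points analytically. Points whose
#' centers leave the crop window are dropped; no other operation changes the
#' point count.
#'
#' @param image a [raster_image].
#' @param masks list of [binary_mask] registered to the image (may be empty).
#' @param points data frame with columns `x`, `y` (other columns carried
#'   through), or `NULL`.
#' @param cfg an [augment_config]; all draws derive from `cfg$seed`.
#' @return `list(image, masks, points, draws)` where `draws` records the
#'   sampled decisions (flips, rotation count, crop area fraction, window,
#'   HSV factors).
#' @export
augment <- function(image, masks = list(), points = NULL, cfg = augment_config()) {
  stopifnot(inherits(image, "raster_image"))
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  draws <- with_seed(derive_seed(cfg$seed, 11), {
    list(hflip = stats::runif(1) < cfg$p_hflip,
         vflip = stats::runif(1) < cfg$p_vflip,
         rot = if (stats::runif(1) < cfg$p_rot90) sample(1:3, 1) else 0L,
         area = stats::runif(1, cfg$crop_range[1], cfg$crop_range[2]),
         u = stats::runif(2),
         dh = stats::runif(1, -cfg$hue_jitter, cfg$hue_jitter) * 180,
         fs = 1 + stats::runif(1, -cfg$sat_jitter, cfg$sat_jitter),
         fv = 1 + stats::runif(1, -cfg$val_jitter, cfg$val_jitter))
  })
  img <- image$pixels
  grids <- lapply(masks, function(m) m$grid)
  px <- if (!is.null(points) && nrow(points) > 0) points$x else double()
  py <- if (!is.null(points) && nrow(points) > 0) points$y else double()

  if (draws$hflip) {
    img <- img[, dim(img)[2]:1, , drop = FALSE]
    grids <- lapply(grids, function(g) g[, ncol(g):1, drop = FALSE])
    px <- (W - 1) - px
  }
  if (draws$vflip) {
    img <- img[dim(img)[1]:1, , , drop = FALSE]
    grids <- lapply(grids, function(g) g[nrow(g):1, , drop = FALSE])
    py <- (H - 1) - py
  }
  if (draws$rot > 0) {
    for (r in seq_len(draws$rot)) {
      h <- dim(img)[1]
      img <- array(apply(img, 3, rot90_cw_mat), c(dim(img)[2], dim(img)[1], 3))
      grids <- lapply(grids, rot90_cw_mat)
      # clockwise: (x, y) -> (h - 1 - y, x)
      tmp <- px
      px <- (h - 1) - py
      py <- tmp
    }
    H <- dim(img)[1]; W <- dim(img)[2]
  }
  if (draws$area < 1) {
    s <- sqrt(draws$area)
    ch <- max(2L, as.integer(round(H * s)))
    cw <- max(2L, as.integer(round(W * s)))
    if (ch < 2 || cw < 2) stop("crop would drop below 2 x 2 pixels")
    oy <- as.integer(floor(draws$u[1] * (H - ch + 1)))
    ox <- as.integer(floor(draws$u[2] * (W - cw + 1)))
    img <- img[(oy + 1):(oy + ch), (ox + 1):(ox + cw), , drop = FALSE]
    grids <- lapply(grids, function(g)
      g[(oy + 1):(oy + ch), (ox + 1):(ox + cw), drop = FALSE])
    keep <- px >= ox & px < ox + cw & py >= oy & py < oy + ch
    px <- (px[keep] - ox) * (W / cw)
    py <- (py[keep] - oy) * (H / ch)
    img <- resize_array(img, H, W, method = "bilinear")
    grids <- lapply(grids, function(g) resize_matrix(g, H, W, method = "nearest"))
    draws$window <- c(ox, oy, cw, ch)
  } else keep <- rep(TRUE, length(px))

  # HSV jitter (image only)
  if (draws$dh != 0 || draws$fs != 1 || draws$fv != 1) {
    hsv <- rgb_to_hsv_halfdeg(pmin(pmax(round(img), 0), 255))
    h2 <- (hsv$h + draws$dh) %% 180
    s2 <- pmin(pmax(hsv$s * draws$fs, 0), 255)
    v2 <- pmin(pmax(hsv$v * draws$fv, 0), 255)
    img <- hsv_halfdeg_to_rgb(h2, s2, v2)
  }

  out_points <- NULL
  if (!is.null(points)) {
    out_points <- points[keep, , drop = FALSE]
    out_points$x <- px
    out_points$y <- py
    rownames(out_points) <- NULL
  }
  list(image = raster_image(pmin(pmax(round(img), 0), 255),
                            mpp = image$mpp, magnification = image$magnification),
       masks = lapply(grids, function(g) binary_mask(round(g) != 0)),
       points = out_points,
       draws = draws)
}

# ---- dataset splitting -----------------------------------------------------

#' Slide-level train / validation / test split
#'
#' Partitions slide identifiers (never patches) so no slide contributes to two
#' sets. Validation and test sizes are the rounded targets (each at least 1);
#' the remainder goes to train.
#'
#' @param slide_ids character or integer vector of >= 3 unique ids.
#' @param fractions length-3 vector summing to 1 (train, val, test).
#' @param seed integer seed controlling the shuffle.
#' @return `list(train, val, test)` of id vectors.
#' @export
split_slides <- function(slide_ids, fractions = c(0.70, 0.15, 0.15), seed = 1) {
  if (anyDuplicated(slide_ids)) stop("duplicate slide ids")
  n <- length(slide_ids)
  if (n < 3) stop("need at least 3 slide ids")
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3)
    stop("fractions must be length 3 and sum to 1")
  n_val <- max(1L, as.integer(round(n * fractions[2])))
  n_test <- max(1L, as.integer(round(n * fractions[3])))
  n_train <- n - n_val - n_test
  if (n_train < 1) stop("fractions leave no training slides")
  perm <- with_seed(derive_seed(seed, 21), sample(slide_ids))
  list(train = perm[seq_len(n_train)],
       val = perm[n_train + seq_len(n_val)],
       test = perm[n_train + n_val + seq_len(n_test)])
}
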