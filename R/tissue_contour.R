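# Deterministic tissue-contour segmentation of low-resolution thumbnails:
# an edge channel (Roberts -> Otsu -> iterated closing) ANDed with a stain
# color channel (HSV gate -> binary median filter).

#' Configuration of the tissue-contour stage
#'
#' @param target_magnification objective power the thumbnail is computed at
#'   (default 2.5).
#' @param close_iterations number of dilation passes (and then erosion passes)
#'   of the morphological closing, default 3.
#' @param hsv_low,hsv_high inclusive componentwise HSV bounds of the stain
#'   gate; hue on the 0-180 half-degree scale, S and V on 0-255. Defaults
#'   H 18-180, S 9-255, V 0-255 select H&E pink/purple and reject glass
#'   (white has S = 0).
#' @param median_radius radius (pixels) of the binary median filter applied to
#'   the color gate, default 4 (a 9 x 9 window).
#' @param min_area minimum connected-component area (thumbnail pixels) kept in
#'   the final mask; 0 (default) keeps everything, including scattered small
#'   tissue fragments.
#' @return An object of class `contour_config`.
#' @export
contour_config <- function(target_magnification = 2.5,
                           close_iterations = 3,
                           hsv_low = c(18, 9, 0),
                           hsv_high = c(180, 255, 255),
                           median_radius = 4,
                           min_area = 0) {
  stopifnot(target_magnification > 0, close_iterations >= 1, median_radius >= 1,
            length(hsv_low) == 3, length(hsv_high) == 3, all(hsv_low <= hsv_high),
            min_area >= 0)
  structure(list(target_magnification = target_magnification,
                 close_iterations = as.integer(close_iterations),
                 hsv_low = hsv_low, hsv_high = hsv_high,
                 median_radius = as.integer(median_radius),
                 min_area = min_area),
            class = "contour_config")
}

#' Downsample an image to the working thumbnail resolution
#'
#' Downsampling uses exact area averaging (each thumbnail pixel is the mean of
#' the source area it covers), the appropriate resampling for decimation.
#'
#' @param image a [raster_image] whose `magnification` is known, unless
#'   `factor` is given explicitly.
#' @param cfg a [contour_config] (supplies the target magnification).
#' @param factor explicit downsample factor overriding
#'   `magnification / target_magnification`.
#' @return A [raster_image] with attribute `scale` = downsample factor; `mpp`
#'   and `magnification` metadata are rescaled accordingly.
#' @export
make_thumbnail <- function(image, cfg = contour_config(), factor = NULL) {
  stopifnot(inherits(image, "raster_image"))
  if (is.null(factor)) {
    if (is.null(image$magnification))
      stop("image magnification unknown and no explicit factor given")
    factor <- image$magnification / cfg$target_magnification
  }
  if (factor <= 1) factor <- 1
  d <- dim(image$pixels)
  if (factor == 1) {
    out <- image
    attr(out, "scale") <- 1
    return(out)
  }
  h <- max(2L, as.integer(round(d[1] / factor)))
  w <- max(2L, as.integer(round(d[2] / factor)))
  a <- resize_array(image$pixels, h, w, method = "area")
  out <- raster_image(pmin(pmax(round(a), 0), 255),
                      mpp = if (is.null(image$mpp)) NULL else image$mpp * factor,
                      magnification = if (is.null(image$magnification)) NULL
                                      else image$magnification / factor)
  attr(out, "scale") <- factor
  out
}

#' Roberts cross edge magnitude
#'
#' Applies the two 2 x 2 Roberts kernels (diagonal differences) and combines
#' them with the L2 norm, clipped to the 8-bit range.
#'
#' @param gray H x W numeric matrix (8-bit grayscale).
#' @return H x W integer matrix of edge magnitudes in 0..255. The last row and
#'   column, where the 2 x 2 window leaves the frame, are 0.
#' @export
roberts_edges <- function(gray) {
  stopifnot(is.matrix(gray))
  H <- nrow(gray); W <- ncol(gray)
  g <- matrix(as.double(gray), H, W)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[-H, -W] <- g[-H, -W] - g[-1, -1]    # [[1,0],[0,-1]]
  gy[-H, -W] <- g[-H, -1] - g[-1, -W]    # [[0,1],[-1,0]]
  mag <- sqrt(gx^2 + gy^2)
  matrix(as.integer(pmin(round(mag), 255)), H, W)
}

#' Otsu threshold of an 8-bit grayscale image
#'
#' Finds the threshold maximizing between-class variance over the 256-bin
#' histogram; ties are broken toward the lowest threshold.
#'
#' @param gray H x W matrix of values in 0..255 with at least two distinct
#'   values.
#' @return `list(threshold = <int>, mask = <binary_mask>)` where the mask is
#'   `gray > threshold`.
#' @export
otsu_threshold <- function(gray) {
  v <- as.integer(round(as.vector(gray)))
  if (min(v) == max(v)) stop("Otsu threshold undefined for a constant image")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                       # P(class0) for t = 0..255
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  # between-class variance for threshold t (class0 = values <= t)
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t <- which.max(sigma_b) - 1L
  list(threshold = t, mask = binary_mask(matrix(v, nrow(gray)) > t))
}

# Shift-based morphology with the 5-pixel cross (the discrete 3 x 3 disc).
# Dilation pads the outside with background; erosion pads with foreground so
# that closing is extensive on the finite frame.
shift_pad <- function(g, dy, dx, fill) {
  H <- nrow(g); W <- ncol(g)
  out <- matrix(fill, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys, xs] <- g[ys - dy, xs - dx]
  out
}

dilate_cross <- function(g) {
  pmax(g, shift_pad(g, 1, 0, 0L), shift_pad(g, -1, 0, 0L),
       shift_pad(g, 0, 1, 0L), shift_pad(g, 0, -1, 0L))
}

erode_cross <- function(g) {
  pmin(g, shift_pad(g, 1, 0, 1L), shift_pad(g, -1, 0, 1L),
       shift_pad(g, 0, 1, 1L), shift_pad(g, 0, -1, 1L))
}

#' Iterated morphological closing with the 3 x 3 cross element
#'
#' "Closing performed n times" is implemented as n dilation passes followed by
#' n erosion passes (a literal repeat of a closing would be a no-op after the
#' first pass, closing being idempotent). The 3 x 3 "circular" element at this
#' size is the 5-pixel cross. The operation is extensive: output contains the
#' input.
#'
#' @param mask a [binary_mask].
#' @param cfg a [contour_config] (supplies `close_iterations`).
#' @return A [binary_mask] of the same shape and scale.
#' @export
close_mask <- function(mask, cfg = contour_config()) {
  stopifnot(inherits(mask, "binary_mask"))
  g <- mask$grid
  for (i in seq_len(cfg$close_iterations)) g <- dilate_cross(g)
  for (i in seq_len(cfg$close_iterations)) g <- erode_cross(g)
  binary_mask(g, scale = mask$scale)
}

# Binary majority (median) filter via integral image; windows are clipped at
# the frame border, foreground iff strictly more than half the in-frame
# window is foreground.
binary_median <- function(g, radius) {
  H <- nrow(g); W <- ncol(g)
  # S[i+1, j+1] = sum g[1..i, 1..j]
  cs <- apply(g, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  S <- matrix(0, H + 1, W + 1)
  S[2:(H + 1), 2:(W + 1)] <- cs
  y0 <- pmax(rep(1:H, times = W) - radius, 1)
  y1 <- pmin(rep(1:H, times = W) + radius, H)
  x0 <- pmax(rep(1:W, each = H) - radius, 1)
  x1 <- pmin(rep(1:W, each = H) + radius, W)
  cnt <- S[cbind(y1 + 1, x1 + 1)] - S[cbind(y0, x1 + 1)] -
    S[cbind(y1 + 1, x0)] + S[cbind(y0, x0)]
  npix <- (y1 - y0 + 1) * (x1 - x0 + 1)
  matrix(as.integer(cnt * 2 > npix), H, W)
}

#' HSV stain gate for H&E pink/purple tissue
#'
#' Converts to HSV (hue 0-180 half-degrees, S and V 0-255), passes pixels
#' falling inside the configured box componentwise (inclusive), then cleans
#' the binary gate with a median filter of the configured radius.
#'
#' @param image a [raster_image] (typically a thumbnail).
#' @param cfg a [contour_config].
#' @return A [binary_mask] at the image's resolution.
#' @export
hsv_tissue_gate <- function(image, cfg = contour_config()) {
  stopifnot(inherits(image, "raster_image"))
  hsv <- rgb_to_hsv_halfdeg(image$pixels)
  lo <- cfg$hsv_low; hi <- cfg$hsv_high
  g <- (hsv$h >= lo[1] & hsv$h <= hi[1] &
        hsv$s >= lo[2] & hsv$s <= hi[2] &
        hsv$v >= lo[3] & hsv$v <= hi[3])
  binary_mask(binary_median(matrix(as.integer(g), nrow(g)), cfg$median_radius))
}

# 4-connected component labeling (BFS flood fill).
label_components <- function(g) {
  H <- nrow(g); W <- ncol(g)
  lab <- matrix(0L, H, W)
  nextlab <- 0L
  idx <- which(g != 0)
  for (start in idx) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue
      queue <- integer()
      y <- (cur - 1L) %% H + 1L
      x <- (cur - 1L) %/% H + 1L
      for (k in 1:4) {
        ny <- y + c(-1L, 1L, 0L, 0L)[k]
        nx <- x + c(0L, 0L, -1L, 1L)[k]
        ok <- ny >= 1 & ny <= H & nx >= 1 & nx <= W
        ni <- (nx[ok] - 1L) * H + ny[ok]
        ni <- ni[g[ni] != 0 & lab[ni] == 0L]
        if (length(ni)) {
          lab[ni] <- nextlab
          queue <- c(queue, ni)
        }
      }
      queue <- unique(queue)
    }
  }
  list(labels = lab, n = nextlab)
}

# Outer contours of mask components as polygons in mask pixel coordinates,
# scaled to the parent frame.
mask_to_polygons <- function(mask, class_label = "tissue") {
  g <- mask$grid
  H <- nrow(g); W <- ncol(g)
  z <- matrix(0, H + 2, W + 2)
  z[2:(H + 1), 2:(W + 1)] <- g
  # contourLines indexes z as [x, y]; pixel (x, y) center sits at (x+0.5, y+0.5)
  cl <- grDevices::contourLines(x = seq_len(H + 2) - 1.5, y = seq_len(W + 2) - 1.5,
                                z = z, levels = 0.5)
  polys <- lapply(cl, function(co) {
    coords <- cbind(co$y, co$x) * mask$scale  # back to (x, y) order
    coords <- pmax(coords, 0)
    list(class = class_label, coords = coords)
  })
  polys <- Filter(function(p) nrow(p$coords) >= 3, polys)
  annotation_set(polys)
}

#' Segment tissue regions of a slide image
#'
#' Runs the full deterministic stage on a thumbnail at the target
#' magnification: edge channel (grayscale, Roberts magnitude, Otsu
#' binarization, iterated closing) ANDed with the HSV stain gate, optional
#' small-component suppression, and polygonization of the result.
#'
#' @param image a [raster_image] carrying `magnification`, or pass `factor`.
#' @param cfg a [contour_config].
#' @param factor explicit thumbnail downsample factor (overrides
#'   magnification).
#' @return `list(mask = <binary_mask at thumbnail scale>, polygons =
#'   <annotation_set with class "tissue", coordinates in source pixels>,
#'   thumbnail = <raster_image>, otsu_threshold = <int or NA>)`. An empty
#'   mask is returned with a warning, not an error.
#' @export
segment_tissue <- function(image, cfg = contour_config(), factor = NULL) {
  thumb <- make_thumbnail(image, cfg, factor = factor)
  scale <- attr(thumb, "scale")
  gray <- to_gray(thumb)
  edges <- roberts_edges(gray)
  if (min(edges) == max(edges)) {
    # blank frame: no edge structure anywhere
    empty <- binary_mask(matrix(0L, nrow(gray), ncol(gray)), scale = scale)
    warning("tissue segmentation produced an empty mask (no edge structure)")
    return(list(mask = empty, polygons = annotation_set(),
                thumbnail = thumb, otsu_threshold = NA_integer_))
  }
  ot <- otsu_threshold(edges)
  edge_mask <- close_mask(binary_mask(ot$mask$grid, scale = scale), cfg)
  color_mask <- hsv_tissue_gate(thumb, cfg)
  g <- edge_mask$grid * color_mask$grid
  if (cfg$min_area > 0 && any(g != 0)) {
    lab <- label_components(g)
    if (lab$n > 0) {
      sizes <- tabulate(lab$labels[lab$labels > 0], nbins = lab$n)
      keep <- which(sizes >= cfg$min_area)
      g <- matrix(as.integer(lab$labels %in% keep), nrow(g))
    }
  }
  mask <- binary_mask(g, scale = scale)
  if (!any(g != 0)) warning("tissue segmentation produced an empty mask")
  list(mask = mask, polygons = mask_to_polygons(mask),
       thumbnail = thumb, otsu_threshold = ot$threshold)
}
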