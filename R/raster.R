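#' @keywords internal
"_PACKAGE"

# ---- core containers -------------------------------------------------------

#' Create a raster image
#'
#' The universal input container of the pipeline: an 8-bit RGB pixel grid with
#' optional physical metadata. Pixel coordinates are 0-based, x rightward,
#' y downward; array element `pixels[y + 1, x + 1, ]` is the pixel at (x, y).
#'
#' @param pixels numeric or integer H x W x 3 array with values in 0..255.
#' @param mpp microns per pixel, or `NULL` when unknown.
#' @param magnification nominal objective power (e.g. 20 for a 20x scan), or
#'   `NULL` when unknown.
#' @return An object of class `raster_image` with fields `pixels`, `mpp`,
#'   `magnification`.
#' @export
raster_image <- function(pixels, mpp = NULL, magnification = NULL) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 2L || d[2] < 2L) stop("image must be at least 2 x 2")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  if (!is.null(mpp) && (!is.finite(mpp) || mpp <= 0)) stop("mpp must be > 0")
  if (!is.null(magnification) && (!is.finite(magnification) || magnification <= 0))
    stop("magnification must be > 0")
  structure(
    list(pixels = array(as.integer(round(pixels)), dim = d),
         mpp = mpp, magnification = magnification),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image %d x %d px, mpp=%s, magnification=%s>\n",
              d[2], d[1],
              if (is.null(x$mpp)) "NA" else format(x$mpp),
              if (is.null(x$magnification)) "NA" else format(x$magnification)))
  invisible(x)
}

#' Create a binary mask
#'
#' Single-channel \{0,1\} grid tied to a downsample factor relative to its
#' source image (`scale = 2` means one mask pixel spans 2 x 2 source pixels).
#'
#' @param grid matrix with values in \{0, 1\} (logical accepted).
#' @param scale downsample factor relative to the parent image, >= 1.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, scale = 1) {
  if (!is.matrix(grid)) grid <- as.matrix(grid)
  g <- matrix(as.integer(grid != 0), nrow(grid), ncol(grid))
  if (!all(grid %in% c(0, 1, TRUE, FALSE))) stop("mask values must be 0/1")
  if (!is.finite(scale) || scale < 1) stop("scale must be >= 1")
  structure(list(grid = g, scale = scale), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, scale=%g, foreground=%d px>\n",
              ncol(x$grid), nrow(x$grid), x$scale, sum(x$grid)))
  invisible(x)
}

mask_like <- function(grid, scale = 1) binary_mask(grid, scale)

# ---- seeded randomness -----------------------------------------------------

# Evaluate expr under a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive an operation-specific seed from a master seed
#'
#' Counter-based stream derivation: one master seed plus an operation index
#' give an independent, reproducible sub-seed, so each phase of a pipeline
#' can be reseeded without coupling its draws to the others.
#'
#' @param seed master integer seed.
#' @param op_id integer operation counter.
#' @return An integer seed in 1..2^31-1.
#' @export
derive_seed <- function(seed, op_id) {
  as.integer((as.double(seed) * 48271 + op_id * 7919) %% 2147483563) + 1L
}

# ---- separable resize operators -------------------------------------------

# Linear resampling along one axis expressed as an n_out x n_in matrix, so a
# 2-D resize is R_y %*% X %*% t(R_x). "area" is exact box averaging over the
# source interval covered by each target pixel (fractional overlap weights);
# "bilinear" samples at target pixel centers with edge clamping; "nearest"
# picks the source pixel containing the target pixel center.
resize_operator <- function(n_in, n_out, method = c("area", "bilinear", "nearest")) {
  method <- match.arg(method)
  R <- matrix(0, n_out, n_in)
  f <- n_in / n_out
  if (method == "area") {
    for (j in seq_len(n_out)) {
      a <- (j - 1) * f
      b <- j * f
      lo <- floor(a)
      hi <- ceiling(b) - 1
      for (s in lo:hi) {
        w <- min(b, s + 1) - max(a, s)
        if (w > 0) R[j, s + 1] <- w / (b - a)
      }
    }
  } else if (method == "bilinear") {
    for (j in seq_len(n_out)) {
      # target center in source coordinates
      c_src <- (j - 0.5) * f - 0.5
      c_src <- min(max(c_src, 0), n_in - 1)
      s0 <- floor(c_src)
      t <- c_src - s0
      R[j, s0 + 1] <- 1 - t
      if (t > 0) R[j, s0 + 2] <- t
    }
  } else {
    for (j in seq_len(n_out)) {
      s <- min(floor((j - 0.5) * f), n_in - 1)
      R[j, s + 1] <- 1
    }
  }
  R
}

# Resize a matrix (one channel) to h_out x w_out.
resize_matrix <- function(X, h_out, w_out, method = "bilinear") {
  Ry <- resize_operator(nrow(X), h_out, method)
  Rx <- resize_operator(ncol(X), w_out, method)
  Ry %*% X %*% t(Rx)
}

# Resize an H x W x C array channelwise.
resize_array <- function(A, h_out, w_out, method = "bilinear") {
  C <- dim(A)[3]
  out <- array(0, c(h_out, w_out, C))
  Ry <- resize_operator(dim(A)[1], h_out, method)
  Rx <- resize_operator(dim(A)[2], w_out, method)
  for (k in seq_len(C)) out[, , k] <- Ry %*% A[, , k] %*% t(Rx)
  out
}

# ---- color -----------------------------------------------------------------

# RGB (0..255) -> HSV with hue on the 0-180 half-degree scale and S, V on
# 0-255 (the convention implied by an H 18-180 stain gate).
rgb_to_hsv_halfdeg <- function(pixels) {
  d <- dim(pixels)
  # grDevices::rgb2hsv takes a 3 x n matrix of R,G,B rows
  m <- rbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
             as.vector(pixels[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  H <- matrix(hsv[1, ] * 180, d[1], d[2])
  S <- matrix(hsv[2, ] * 255, d[1], d[2])
  V <- matrix(hsv[3, ] * 255, d[1], d[2])
  list(h = H, s = S, v = V)
}

# HSV (same scales as above) -> RGB 0..255 array
hsv_halfdeg_to_rgb <- function(h, s, v) {
  hex <- grDevices::hsv(pmin(pmax(h / 180, 0), 1),
                        pmin(pmax(s / 255, 0), 1),
                        pmin(pmax(v / 255, 0), 1))
  col <- grDevices::col2rgb(hex)
  out <- array(0, c(nrow(h), ncol(h), 3))
  out[, , 1] <- matrix(col[1, ], nrow(h), ncol(h))
  out[, , 2] <- matrix(col[2, ], nrow(h), ncol(h))
  out[, , 3] <- matrix(col[3, ], nrow(h), ncol(h))
  out
}

# Luminosity grayscale, rounded to 8-bit.
to_gray <- function(image) {
  p <- image$pixels
  g <- 0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
  matrix(as.integer(round(g)), nrow(g), ncol(g))
}

# ---- image / mask file I/O -------------------------------------------------

#' Read an 8-bit PNG or TIFF image
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`, `.tiff`).
#' @param mpp,magnification optional metadata attached to the result (raster
#'   formats carry none).
#' @return A [raster_image]. Grayscale files are expanded to three identical
#'   channels.
#' @export
read_image <- function(path, mpp = NULL, magnification = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8)
      stop(sprintf("unsupported bit depth %d (only 8-bit supported)", info$bit.depth))
    arr <- img
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    info <- attributes(arr)
    bps <- info$bits.per.sample
    if (!is.null(bps) && any(bps != 8))
      stop(sprintf("unsupported bit depth %d (only 8-bit supported)", bps[1]))
    # heuristic fallback: 16-bit data read as [0,1] has sub-1/255 quantization
    vals <- round(arr * 65535)
    if (is.null(bps) && any(vals %% 257 != 0))
      stop("unsupported bit depth 16 (only 8-bit supported)")
  } else stop(sprintf("unsupported image format '%s'", ext))
  a <- as.array(arr)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  raster_image(round(a * 255), mpp = mpp, magnification = magnification)
}

#' Write a raster image as 8-bit PNG or TIFF
#'
#' @param image a [raster_image].
#' @param path destination; extension selects the format.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  a <- image$pixels / 255
  if (ext == "png") png::writePNG(a, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(a, path, bits.per.sample = 8L)
  else stop(sprintf("unsupported image format '%s'", ext))
  invisible(path)
}

#' Write a binary mask as a single-channel PNG (values 0/255)
#'
#' @param mask a [binary_mask].
#' @param path destination `.png` path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  if (tolower(tools::file_ext(path)) != "png") stop("masks are written as PNG")
  png::writePNG(mask$grid * 1.0, path)
  invisible(path)
}

#' Read a mask written by [write_mask]
#'
#' @param path `.png` path; any pixel > 127 becomes foreground.
#' @param scale downsample factor to record on the mask.
#' @return A [binary_mask].
#' @export
read_mask <- function(path, scale = 1) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  binary_mask(a > 0.5, scale = scale)
}
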