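# Shared fixtures and independent oracles, built in code at test time.

# ---- trained-model cache (one training per test run, reused across files) --

.desk_cache <- new.env(parent = emptyenv())

desk_segmenter <- function() {
  if (is.null(.desk_cache$seg))
    .desk_cache$seg <- train_reference_segmenter(seed = 11)
  .desk_cache$seg
}

desk_detector <- function() {
  if (is.null(.desk_cache$det))
    .desk_cache$det <- train_reference_detector(seed = 11)
  .desk_cache$det
}

# ---- random inputs ---------------------------------------------------------

random_annotation_set <- function(seed) {
  set.seed(seed)
  n_poly <- sample(0:4, 1)
  polys <- lapply(seq_len(n_poly), function(i) {
    k <- sample(3:8, 1)
    list(class = sample(c("tissue", "tumor", "necrosis", "hemorrhage"), 1),
         coords = cbind(round(runif(k, 0, 500), 2), round(runif(k, 0, 500), 2)))
  })
  n_pts <- sample(0:6, 1)
  pts <- if (n_pts > 0)
    data.frame(class = "lymphocyte",
               x = round(runif(n_pts, 0, 500), 2),
               y = round(runif(n_pts, 0, 500), 2))
  else NULL
  annotation_set(polys, pts)
}

random_mask <- function(h, w, p = 0.4, seed = 1) {
  set.seed(seed)
  binary_mask(matrix(rbinom(h * w, 1, p), h, w))
}

# ---- independent oracles ---------------------------------------------------

# even-odd point-in-polygon, scalar loop (independent of the vectorized one)
oracle_point_in_polygon <- function(px, py, coords) {
  n <- nrow(coords)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- coords[i, 1]; yi <- coords[i, 2]
    xj <- coords[j, 1]; yj <- coords[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# exhaustive-search Otsu: maximize between-class variance over all 256 cuts
oracle_otsu <- function(v) {
  v <- as.integer(round(v))
  best_t <- NA; best_s <- -Inf
  n <- length(v)
  for (t in 0:255) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    if (!length(g0) || !length(g1)) next
    w0 <- length(g0) / n; w1 <- length(g1) / n
    s <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# per-pixel set-morphology with the 5-pixel cross; dilation pads background,
# erosion pads foreground (matching the closing's extensivity convention)
oracle_dilate <- function(g) {
  H <- nrow(g); W <- ncol(g)
  out <- matrix(0L, H, W)
  for (y in 1:H) for (x in 1:W) {
    v <- g[y, x]
    if (y > 1) v <- max(v, g[y - 1, x])
    if (y < H) v <- max(v, g[y + 1, x])
    if (x > 1) v <- max(v, g[y, x - 1])
    if (x < W) v <- max(v, g[y, x + 1])
    out[y, x] <- v
  }
  out
}

oracle_erode <- function(g) {
  H <- nrow(g); W <- ncol(g)
  out <- matrix(1L, H, W)
  for (y in 1:H) for (x in 1:W) {
    v <- g[y, x]
    if (y > 1) v <- min(v, g[y - 1, x])
    if (y < H) v <- min(v, g[y + 1, x])
    if (x > 1) v <- min(v, g[y, x - 1])
    if (x < W) v <- min(v, g[y, x + 1])
    out[y, x] <- v
  }
  out
}

oracle_close <- function(g, iterations = 3) {
  for (i in seq_len(iterations)) g <- oracle_dilate(g)
  for (i in seq_len(iterations)) g <- oracle_erode(g)
  g
}

oracle_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  u <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (u <= 0) 0 else inter / u
}

# O(n^2) reference NMS: repeatedly take the most confident remaining box
# (ties by original index) and delete everything overlapping it
oracle_nms <- function(boxes, thr) {
  idx <- seq_len(nrow(boxes))
  kept <- integer()
  while (length(idx)) {
    conf <- boxes$confidence[idx]
    i <- idx[which.max(conf)]   # which.max takes first maximum = lowest index
    kept <- c(kept, i)
    rest <- setdiff(idx, i)
    drop <- rest[vapply(rest, function(j)
      oracle_iou(as.numeric(boxes[i, 1:4]), as.numeric(boxes[j, 1:4])) >= thr,
      TRUE)]
    idx <- setdiff(rest, drop)
  }
  kept
}

# rectangle-sum AP oracle: evaluate the interpolated precision envelope on a
# dense recall grid and integrate numerically
oracle_ap <- function(labels, n_gt, grid = 4000) {
  if (n_gt == 0) return(if (length(labels) == 0) 1 else 0)
  if (length(labels) == 0) return(0)
  tp <- cumsum(labels == "TP"); fp <- cumsum(labels == "FP")
  rec <- tp / n_gt; prec <- tp / (tp + fp)
  p_at <- function(r) {
    ok <- rec >= r
    if (any(ok)) max(prec[ok]) else 0
  }
  rs <- seq(1 / grid / 2, 1 - 1 / grid / 2, length.out = grid)
  mean(vapply(rs, p_at, 0))
}

random_boxes <- function(n, seed, frame = 100) {
  set.seed(seed)
  cx <- runif(n, 5, frame - 5); cy <- runif(n, 5, frame - 5)
  w <- runif(n, 3, 20); h <- runif(n, 3, 20)
  detection_boxes(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2,
                  confidence = round(runif(n, 0.05, 0.95), 3))
}
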