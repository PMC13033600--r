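# Stromal TILs counting, per-HPF grading, and the inter-rater agreement
# battery: ICC(A,1), Cohen's kappa, Fleiss' kappa, Bland-Altman.

#' Grading thresholds for TILs counts per high-power field
#'
#' Counts below `low_max` are "low", counts above `high_min` are "high", and
#' the closed interval `[low_max, high_min]` is "moderate" (so 100 and 300
#' both grade as moderate under the defaults `<100 / 100-300 / >300`).
#'
#' @param low_max exclusive upper bound of the low grade (default 100).
#' @param high_min inclusive upper bound of the moderate grade (default 300).
#' @return An object of class `grade_thresholds`.
#' @export
grade_thresholds <- function(low_max = 100, high_min = 300) {
  stopifnot(low_max > 0, low_max <= high_min)
  structure(list(low_max = low_max, high_min = high_min),
            class = "grade_thresholds")
}

#' High-power-field specification
#'
#' A 400x high-power field; the default area of 0.237 mm^2 corresponds to a
#' standard 22 mm field-number eyepiece.
#'
#' @param field_area_mm2 field area in mm^2.
#' @param mpp microns per pixel of the image the fields are placed on.
#' @return An object of class `hpf_spec`.
#' @export
hpf_spec <- function(field_area_mm2 = 0.237, mpp = 2.0) {
  stopifnot(field_area_mm2 > 0, mpp > 0)
  structure(list(field_area_mm2 = field_area_mm2, mpp = mpp),
            class = "hpf_spec")
}

#' Stromal mask: tissue minus tumor parenchyma
#'
#' @param tissue,parenchyma [binary_mask] objects of the same shape and scale.
#' @return A [binary_mask]: `tissue AND NOT parenchyma`.
#' @export
stromal_mask <- function(tissue, parenchyma) {
  stopifnot(inherits(tissue, "binary_mask"), inherits(parenchyma, "binary_mask"))
  if (!all(dim(tissue$grid) == dim(parenchyma$grid)))
    stop("mask shape mismatch")
  binary_mask(tissue$grid * (1L - parenchyma$grid), scale = tissue$scale)
}

#' Count detections in randomly placed high-power fields
#'
#' Places `n_fields` square windows of the configured physical area at seeded
#' random stroma-covered locations (window centers are drawn uniformly from
#' stroma pixels such that the window fits the frame) and counts the boxes
#' whose center lies inside the window and on stroma; window boundaries are
#' inclusive.
#'
#' @param boxes a [detection_boxes] data frame (image pixel coordinates).
#' @param stroma a [binary_mask] (any scale) over the same image.
#' @param hpf an [hpf_spec]; the window side in pixels is
#'   `sqrt(field_area_mm2) * 1000 / mpp`.
#' @param n_fields number of fields (default 5).
#' @param seed placement seed.
#' @return Integer vector of per-field counts, with attribute `windows`
#'   (x0, y0, x1, y1 of each field in image pixels).
#' @export
count_in_fields <- function(boxes, stroma, hpf, n_fields = 5, seed = 1) {
  stopifnot(inherits(stroma, "binary_mask"), inherits(hpf, "hpf_spec"))
  side_px <- sqrt(hpf$field_area_mm2) * 1000 / hpf$mpp
  sc <- stroma$scale
  Hm <- nrow(stroma$grid); Wm <- ncol(stroma$grid)
  H <- Hm * sc; W <- Wm * sc                 # frame extent in image pixels
  side_m <- side_px / sc                     # window side in mask pixels
  if (side_m > Hm || side_m > Wm)
    stop(sprintf(
      "stroma frame too small for an HPF: need %.0f x %.0f mask px, have %d x %d",
      side_m, side_m, Hm, Wm))
  # admissible centers: stroma pixels whose window fits in the frame
  half <- side_m / 2
  ys <- (seq_len(Hm) - 0.5); xs <- (seq_len(Wm) - 0.5)
  ok_y <- ys >= half & ys <= Hm - half
  ok_x <- xs >= half & xs <= Wm - half
  adm <- stroma$grid == 1L & outer(ok_y, ok_x, `&`)
  idx <- which(adm)
  if (!length(idx))
    stop(sprintf(
      "stroma too small to host a field: required %.2f mm^2 per field, available stroma %.2f mm^2",
      hpf$field_area_mm2, sum(stroma$grid) * (sc * hpf$mpp / 1000)^2))
  pick <- with_seed(derive_seed(seed, 51),
                    idx[sample.int(length(idx), n_fields, replace = TRUE)])
  cy <- ((pick - 1) %% Hm + 0.5) * sc
  cx <- ((pick - 1) %/% Hm + 0.5) * sc
  x0 <- cx - side_px / 2; x1 <- cx + side_px / 2
  y0 <- cy - side_px / 2; y1 <- cy + side_px / 2
  counts <- integer(n_fields)
  if (nrow(boxes) > 0) {
    bx <- (boxes$x0 + boxes$x1) / 2
    by <- (boxes$y0 + boxes$y1) / 2
    gy <- pmin(pmax(floor(by / sc) + 1L, 1L), Hm)
    gx <- pmin(pmax(floor(bx / sc) + 1L, 1L), Wm)
    on_stroma <- stroma$grid[cbind(gy, gx)] == 1L
    for (f in seq_len(n_fields))
      counts[f] <- sum(on_stroma & bx >= x0[f] & bx <= x1[f] &
                         by >= y0[f] & by <= y1[f])
  }
  attr(counts, "windows") <- data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  counts
}

#' Grade a per-HPF TILs count
#'
#' @param count_per_hpf non-negative count (vectorized).
#' @param thr a [grade_thresholds].
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
grade <- function(count_per_hpf, thr = grade_thresholds()) {
  if (any(count_per_hpf < 0)) stop("counts must be non-negative")
  g <- ifelse(count_per_hpf < thr$low_max, "low",
              ifelse(count_per_hpf <= thr$high_min, "moderate", "high"))
  factor(g, levels = c("low", "moderate", "high"))
}

# ---- agreement statistics --------------------------------------------------

#' Intraclass correlation, two-way random effects, absolute agreement,
#' single measures — ICC(A,1)
#'
#' Computed from the two-way ANOVA mean squares (subjects x raters), with the
#' 95% confidence interval by the F-distribution method of McGraw & Wong
#' (1996).
#'
#' @param ratings n_subjects x k_raters numeric matrix, no missing cells.
#' @param conf_level confidence level (default 0.95).
#' @return `list(estimate, ci_lower, ci_upper, ms = <mean squares>)`.
#' @export
icc_absolute <- function(ratings, conf_level = 0.95) {
  R <- as.matrix(ratings)
  if (anyNA(R)) stop("ratings must have no missing cells")
  n <- nrow(R); k <- ncol(R)
  stopifnot(n >= 2, k >= 2)
  grand <- mean(R)
  row_m <- rowMeans(R); col_m <- colMeans(R)
  if (stats::var(as.vector(R)) == 0) stop("undefined ICC: zero total variance")
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SSE <- sum((R - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (denom == 0) stop("undefined ICC: zero denominator")
  icc <- (MSR - MSE) / denom
  alpha <- 1 - conf_level
  if (MSE == 0) {
    # zero residual variance: the interval is degenerate at the estimate
    lo <- hi <- icc
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  }
  list(estimate = icc, ci_lower = min(lo, icc), ci_upper = max(hi, icc),
       ms = list(MSR = MSR, MSC = MSC, MSE = MSE))
}

kappa_point <- function(a, b, levels_all) {
  ta <- factor(a, levels = levels_all)
  tb <- factor(b, levels = levels_all)
  ct <- table(ta, tb)
  n <- sum(ct)
  po <- sum(diag(ct)) / n
  pe <- sum(rowSums(ct) * colSums(ct)) / n^2
  if (pe >= 1) return(list(kappa = 1, degenerate = TRUE))
  list(kappa = (po - pe) / (1 - pe), degenerate = FALSE)
}

#' Cohen's kappa with bootstrap confidence interval
#'
#' `kappa = (p_o - p_e) / (1 - p_e)`; the 95% CI is a seeded percentile
#' bootstrap over subjects (2,000 resamples). When both raters are constant
#' and identical (`p_e = 1`), kappa is defined as 1 with a degenerate flag.
#'
#' @param a,b equal-length label vectors (>= 2 observations).
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @param conf_level confidence level.
#' @return `list(estimate, ci_lower, ci_upper, degenerate)`.
#' @export
cohens_kappa <- function(a, b, n_boot = 2000, seed = 1, conf_level = 0.95) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a)
  if (n != length(b) || n < 2) stop("need two equal-length vectors, n >= 2")
  lev <- sort(unique(c(a, b)))
  pt <- kappa_point(a, b, lev)
  if (pt$degenerate)
    return(list(estimate = 1, ci_lower = 1, ci_upper = 1, degenerate = TRUE))
  ks <- with_seed(derive_seed(seed, 61), {
    vapply(seq_len(n_boot), function(i) {
      ix <- sample.int(n, n, replace = TRUE)
      kappa_point(a[ix], b[ix], lev)$kappa
    }, 0)
  })
  qs <- stats::quantile(ks, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(estimate = pt$kappa, ci_lower = min(qs[1], pt$kappa),
       ci_upper = max(qs[2], pt$kappa), degenerate = FALSE)
}

fleiss_point <- function(M) {
  # M: n_subjects x n_categories count matrix, constant row sum r (raters)
  n <- nrow(M); r <- sum(M[1, ])
  p_j <- colSums(M) / (n * r)
  P_i <- (rowSums(M^2) - r) / (r * (r - 1))
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (Pe >= 1) return(list(kappa = 1, degenerate = TRUE))
  list(kappa = (Pbar - Pe) / (1 - Pe), degenerate = FALSE)
}

#' Fleiss' kappa with bootstrap confidence interval
#'
#' The standard multi-rater chance-corrected agreement statistic (Fleiss
#' 1971); the 95% CI is a seeded percentile bootstrap over subjects.
#'
#' @param grades n_subjects x k_raters matrix (or data frame) of categorical
#'   labels.
#' @param n_boot,seed,conf_level bootstrap parameters.
#' @return `list(estimate, ci_lower, ci_upper, degenerate)`.
#' @export
fleiss_kappa <- function(grades, n_boot = 2000, seed = 1, conf_level = 0.95) {
  G <- as.matrix(grades)
  n <- nrow(G); k <- ncol(G)
  stopifnot(n >= 2, k >= 2)
  lev <- sort(unique(as.vector(G)))
  counts <- t(apply(G, 1, function(row) table(factor(row, levels = lev))))
  if (length(lev) == 1)
    return(list(estimate = 1, ci_lower = 1, ci_upper = 1, degenerate = TRUE))
  pt <- fleiss_point(counts)
  if (pt$degenerate)
    return(list(estimate = 1, ci_lower = 1, ci_upper = 1, degenerate = TRUE))
  ks <- with_seed(derive_seed(seed, 62), {
    vapply(seq_len(n_boot), function(i) {
      ix <- sample.int(n, n, replace = TRUE)
      sub <- counts[ix, , drop = FALSE]
      f <- fleiss_point(sub)
      if (f$degenerate) 1 else f$kappa
    }, 0)
  })
  qs <- stats::quantile(ks, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(estimate = pt$kappa, ci_lower = min(qs[1], pt$kappa),
       ci_upper = max(qs[2], pt$kappa), degenerate = FALSE)
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias is `mean(a - b)`; the 95% limits of agreement are
#' `bias +/- 1.96 * SD(a - b)` with the sample (n-1) standard deviation.
#'
#' @param a,b equal-length numeric vectors, n >= 2.
#' @return `list(bias, loa_low, loa_high, differences, means)`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("need two equal-length vectors with n >= 2")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       differences = d, means = (a + b) / 2)
}

icc_strength <- function(icc) {
  # Cicchetti (1994) bands
  if (icc >= 0.75) "excellent" else if (icc >= 0.60) "good"
  else if (icc >= 0.40) "fair" else "poor"
}

kappa_strength <- function(k) {
  # Landis & Koch (1977) bands
  if (k < 0) "poor" else if (k <= 0.20) "slight" else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate" else if (k <= 0.80) "substantial"
  else "almost perfect"
}

#' Full inter-rater agreement report
#'
#' Runs ICC(A,1) on the raw counts, grades each rater's counts, computes
#' pairwise Cohen's kappa and overall Fleiss' kappa on the grades, and
#' Bland-Altman statistics per rater pair. Agreement-strength labels follow
#' the Cicchetti (1994) bands for ICC and the Landis & Koch (1977) bands for
#' kappa.
#'
#' @param counts_by_rater n_subjects x k_raters matrix of counts; column
#'   names identify raters.
#' @param thr a [grade_thresholds].
#' @param seed seed for the bootstrap CIs.
#' @return An object of class `agreement_report`: `icc` (with strength),
#'   `kappa_pairwise` (per pair, with strengths), `fleiss` (with strength),
#'   `bland_altman` (per pair), and `grades`.
#' @export
agreement_report <- function(counts_by_rater, thr = grade_thresholds(),
                             seed = 1) {
  M <- as.matrix(counts_by_rater)
  if (is.null(colnames(M))) colnames(M) <- paste0("rater", seq_len(ncol(M)))
  stopifnot(ncol(M) >= 2)
  icc <- icc_absolute(M)
  icc$strength <- icc_strength(icc$estimate)
  grades <- apply(M, 2, function(col) as.character(grade(col, thr)))
  pairs <- utils::combn(ncol(M), 2)
  kp <- list(); ba <- list()
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    nm <- paste(colnames(M)[i1], "vs", colnames(M)[i2])
    k <- cohens_kappa(grades[, i1], grades[, i2], seed = seed + j)
    k$strength <- kappa_strength(k$estimate)
    kp[[nm]] <- k
    ba[[nm]] <- bland_altman(M[, i1], M[, i2])
  }
  fl <- fleiss_kappa(grades, seed = seed)
  fl$strength <- kappa_strength(fl$estimate)
  structure(list(icc = icc, kappa_pairwise = kp, fleiss = fl,
                 bland_altman = ba, grades = grades),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (95%% CI %.3f-%.3f), %s\n",
              x$icc$estimate, x$icc$ci_lower, x$icc$ci_upper, x$icc$strength))
  for (nm in names(x$kappa_pairwise)) {
    k <- x$kappa_pairwise[[nm]]
    cat(sprintf("Cohen's kappa %s = %.3f (95%% CI %.3f-%.3f), %s\n",
                nm, k$estimate, k$ci_lower, k$ci_upper, k$strength))
  }
  cat(sprintf("Fleiss' kappa = %.3f (95%% CI %.3f-%.3f), %s\n",
              x$fleiss$estimate, x$fleiss$ci_lower, x$fleiss$ci_upper,
              x$fleiss$strength))
  invisible(x)
}
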