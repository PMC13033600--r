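test_that("stromal mask is the pixelwise set difference tissue minus tumor", {
  tis <- random_mask(10, 10, p = 0.7, seed = 1)
  par <- binary_mask(tis$grid * random_mask(10, 10, p = 0.5, seed = 2)$grid)
  str <- stromal_mask(tis, par)
  for (i in 1:10) for (j in 1:10)
    expect_equal(str$grid[i, j], as.integer(tis$grid[i, j] == 1 && par$grid[i, j] == 0))

  expect_equal(stromal_mask(tis, binary_mask(matrix(0L, 10, 10)))$grid, tis$grid)
  expect_equal(sum(stromal_mask(tis, tis)$grid), 0L)
  expect_error(stromal_mask(tis, binary_mask(matrix(0L, 5, 5))), "mismatch")
})

test_that("high-power-field counting is seeded, windowed, and Poisson-consistent", {
  # stroma fills the frame; field side = sqrt(0.237) mm = 243.4 px at mpp 2
  stroma <- binary_mask(matrix(1L, 300, 300))
  hpf <- hpf_spec(field_area_mm2 = 0.237, mpp = 2)

  expect_equal(as.integer(count_in_fields(detection_boxes(), stroma, hpf,
                                          n_fields = 5, seed = 1)),
               rep(0L, 5))

  # 10 boxes clustered at the frame center are counted by any window
  # containing them
  ctr <- detection_boxes(rep(148, 10), 139:148, rep(152, 10), 143:152,
                         confidence = rep(0.9, 10))
  cnt <- count_in_fields(ctr, stroma, hpf, n_fields = 5, seed = 2)
  win <- attr(cnt, "windows")
  inside <- vapply(seq_len(5), function(f)
    sum(150 >= win$x0[f] & 150 <= win$x1[f] &
        139:148 + 2 >= win$y0[f] & 139:148 + 2 <= win$y1[f]), 0)
  expect_equal(as.integer(cnt), as.integer(inside))

  # same seed, same fields
  expect_identical(count_in_fields(ctr, stroma, hpf, seed = 7),
                   count_in_fields(ctr, stroma, hpf, seed = 7))

  # a frame smaller than one field errors with the areas named
  small <- binary_mask(matrix(1L, 50, 50))
  expect_error(count_in_fields(detection_boxes(), small, hpf), "too small")

  # Poisson oracle: uniform boxes at density d, mean count ~ d x field area
  d_mm2 <- 2000
  mpp <- 4
  hpf2 <- hpf_spec(0.237, mpp = mpp)
  frame <- 200  # 0.64 mm^2 at mpp 4
  total <- 0; draws <- 0
  set.seed(5)
  for (rep in 1:60) {
    n <- rpois(1, d_mm2 * (frame * mpp / 1000)^2)
    x <- runif(n, 0, frame); y <- runif(n, 0, frame)
    b <- detection_boxes(x - 1, y - 1, x + 1, y + 1, confidence = rep(0.9, n))
    cnt <- count_in_fields(b, binary_mask(matrix(1L, frame, frame)), hpf2,
                           n_fields = 2, seed = 100 + rep)
    total <- total + sum(cnt); draws <- draws + 2
  }
  expected <- draws * d_mm2 * 0.237
  expect_lt(abs(total - expected), 3 * sqrt(expected))
})

test_that("grading maps the count boundaries exactly", {
  thr <- grade_thresholds()
  expect_equal(as.character(grade(c(0, 99, 100, 300, 301), thr)),
               c("low", "low", "moderate", "moderate", "high"))
  expect_error(grade(-1), "non-negative")
})

test_that("ICC(A,1) reproduces the two-way ANOVA decomposition and its
           F-based interval", {
  # identical columns: perfect agreement
  r <- cbind(1:6, 1:6)
  icc <- icc_absolute(r)
  expect_equal(icc$estimate, 1)
  expect_equal(icc$ci_upper, 1)

  # fixed 6x2 matrix: mean squares from aov() as the independent oracle
  R <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  icc2 <- icc_absolute(R)
  long <- data.frame(y = as.vector(R),
                     subj = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]]$`Mean Sq`
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  n <- 6; k <- 2
  oracle <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  expect_equal(icc2$estimate, oracle, tolerance = 1e-12)
  expect_true(icc2$ci_lower <= icc2$estimate && icc2$estimate <= icc2$ci_upper)

  # one rater plus heavy independent noise: ICC near zero
  set.seed(31)
  a <- rnorm(200, 50, 1)
  b <- a + rnorm(200, 0, 25)
  icc3 <- icc_absolute(cbind(a, b))
  expect_lt(abs(icc3$estimate), 0.2)

  expect_error(icc_absolute(matrix(3, 4, 2)), "zero total variance")
})

test_that("ICC is invariant to common shifts and positive rescaling", {
  set.seed(4)
  base <- rnorm(30, 100, 10)
  R <- cbind(base + rnorm(30, 0, 3), base + rnorm(30, 0, 3))
  i0 <- icc_absolute(R)$estimate
  expect_equal(icc_absolute(R + 17)$estimate, i0, tolerance = 1e-12)
  expect_equal(icc_absolute(R * 3.5)$estimate, i0, tolerance = 1e-12)
})

test_that("Cohen's kappa matches hand-computed contingency values", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a"))$estimate, 1)

  # balanced binary complete disagreement
  a <- rep(c("x", "y"), 10)
  b <- rep(c("y", "x"), 10)
  expect_equal(cohens_kappa(a, b)$estimate, -1)

  # contingency [[20,5],[10,15]]: po = 0.7, pe = 0.5 -> kappa 0.4
  a2 <- c(rep("p", 25), rep("q", 25))
  b2 <- c(rep("p", 20), rep("q", 5), rep("p", 10), rep("q", 15))
  k <- cohens_kappa(a2, b2, seed = 3)
  expect_equal(k$estimate, 0.4, tolerance = 1e-12)
  expect_true(k$ci_lower <= 0.4 && 0.4 <= k$ci_upper)

  # degenerate: both raters constant and identical
  kd <- cohens_kappa(rep("z", 5), rep("z", 5))
  expect_equal(kd$estimate, 1)
  expect_true(kd$degenerate)

  # relabeling invariance
  relab <- c(p = "AA", q = "BB")
  k2 <- cohens_kappa(relab[a2], relab[b2], seed = 3)
  expect_equal(k2$estimate, k$estimate)
})

test_that("Fleiss' kappa matches the direct formula and is near zero for
           independent uniform raters", {
  allsame <- matrix("m", 5, 3)
  expect_equal(fleiss_kappa(allsame)$estimate, 1)

  # fixed 4x3 toy matrix: direct evaluation of P-bar and Pe-bar
  G <- rbind(c("a", "a", "b"), c("b", "b", "b"),
             c("a", "c", "c"), c("c", "c", "c"))
  f <- fleiss_kappa(G, seed = 2)
  counts <- t(apply(G, 1, function(r) table(factor(r, levels = c("a", "b", "c")))))
  rr <- 3
  P_i <- (rowSums(counts^2) - rr) / (rr * (rr - 1))
  p_j <- colSums(counts) / (4 * rr)
  oracle <- (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
  expect_equal(f$estimate, oracle, tolerance = 1e-12)

  set.seed(11)
  unif <- matrix(sample(c("low", "moderate", "high"), 500 * 3, TRUE), 500, 3)
  f2 <- fleiss_kappa(unif, seed = 4)
  expect_lt(abs(f2$estimate), 0.1)

  # relabeling invariance
  relab <- c(a = "z1", b = "z2", c = "z3")
  G2 <- matrix(relab[G], 4, 3)
  expect_equal(fleiss_kappa(G2, seed = 2)$estimate, f$estimate)
})

test_that("Bland-Altman bias and limits follow the sample-SD formula", {
  a <- c(3, 5, 9, 4)
  same <- bland_altman(a, a)
  expect_equal(same$bias, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)

  shift <- bland_altman(a, a + 5)
  expect_equal(shift$bias, -5)
  expect_equal(shift$loa_low, -5)

  d <- c(1, -1, 3, -3)
  ba <- bland_altman(d, rep(0, 4))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_high, 5.0607, tolerance = 1e-4)

  # swapping arguments flips the bias and keeps the interval width
  x <- rnorm(10); y <- rnorm(10)
  b1 <- bland_altman(x, y); b2 <- bland_altman(y, x)
  expect_equal(b1$bias, -b2$bias)
  expect_equal(b1$loa_high - b1$loa_low, b2$loa_high - b2$loa_low)
  expect_error(bland_altman(1, 2), "n >= 2")
})

test_that("the agreement report assembles ICC, kappas, Bland-Altman and the
           published strength bands", {
  # pipeline identical to both experts: everything is perfect agreement
  counts <- cbind(expert1 = c(50, 150, 400, 90, 220),
                  expert2 = c(50, 150, 400, 90, 220),
                  pipeline = c(50, 150, 400, 90, 220))
  rep1 <- agreement_report(counts, seed = 5)
  expect_equal(rep1$icc$estimate, 1)
  expect_equal(rep1$icc$strength, "excellent")
  expect_true(all(vapply(rep1$kappa_pairwise, function(k) k$estimate, 0) == 1))
  expect_equal(rep1$fleiss$estimate, 1)
  expect_equal(rep1$fleiss$strength, "almost perfect")
  expect_true(all(vapply(rep1$bland_altman, function(b) b$bias, 0) == 0))

  # strength bands at the published cut points
  expect_equal(tilscope:::icc_strength(0.75), "excellent")
  expect_equal(tilscope:::icc_strength(0.74), "good")
  expect_equal(tilscope:::icc_strength(0.40), "fair")
  expect_equal(tilscope:::icc_strength(0.39), "poor")
  expect_equal(tilscope:::kappa_strength(0.45), "moderate")
  expect_equal(tilscope:::kappa_strength(0.61), "substantial")
  expect_equal(tilscope:::kappa_strength(0.81), "almost perfect")
  expect_equal(tilscope:::kappa_strength(-0.1), "poor")
})

test_that("simulated rater study recovers the theoretical ICC", {
  # two-way random model: sigma_s^2 / (sigma_s^2 + sigma_e^2)
  set.seed(202)
  sigma_s <- 40; sigma_e <- 20
  subj <- rnorm(200, 150, sigma_s)
  R <- cbind(subj + rnorm(200, 0, sigma_e), subj + rnorm(200, 0, sigma_e))
  truth <- sigma_s^2 / (sigma_s^2 + sigma_e^2)
  est <- icc_absolute(R)$estimate
  expect_lt(abs(est - truth), 0.05)
})
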