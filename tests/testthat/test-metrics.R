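# Image-quality metrics are checked against hand arithmetic and
# independent brute-force oracles written in this file.

test_that("MTF matches hand arithmetic", {
  expect_equal(mtf(c(1, 0)), 1)
  expect_equal(mtf(c(0.5, 0.5, 0.5)), 0)
  expect_equal(mtf(c(0.8, 0.4)), (0.8 - 0.4) / (0.8 + 0.4))  # = 1/3
  expect_error(mtf(c(0, 0)), "all-zero")
  expect_error(mtf(numeric(0)), "empty")
})

test_that("RMSE matches the definition and a brute-force loop", {
  x <- matrix(runif(100), 10)
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  y <- x + matrix(rnorm(100), 10)
  expect_equal(rmse(2 * x, 2 * y), 2 * rmse(x, y))
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - y[i])^2
  expect_equal(rmse(x, y), sqrt(acc / length(x)), tolerance = 1e-10)
})

test_that("SSIM is 1 at identity, bounded, and matches a sliding-window oracle", {
  set.seed(61)
  x <- matrix(runif(24 * 20, 0, 1), 24)
  expect_equal(ssim(x, x), 1)
  y <- x + matrix(rnorm(24 * 20, sd = 0.2), 24)
  v <- ssim(x, y)
  expect_true(v >= -1 && v <= 1)
  # brute-force oracle: explicit symmetric padding + per-pixel window sums
  k1 <- exp(-((-5:5)^2) / (2 * 1.5^2)); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  pad <- function(m, r = 5L) {
    idx_r <- c(rev(seq_len(r)), seq_len(nrow(m)), nrow(m) + 1 - seq_len(r))
    idx_c <- c(rev(seq_len(r)), seq_len(ncol(m)), ncol(m) + 1 - seq_len(r))
    m[idx_r, idx_c]
  }
  xp <- pad(x); yp <- pad(y)
  L <- max(x); c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  sm <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    wx <- xp[i:(i + 10), j:(j + 10)]; wy <- yp[i:(i + 10), j:(j + 10)]
    mx <- sum(K * wx); my <- sum(K * wy)
    vx <- sum(K * wx^2) - mx^2; vy <- sum(K * wy^2) - my^2
    vxy <- sum(K * wx * wy) - mx * my
    sm <- sm + ((2 * mx * my + c1) * (2 * vxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  expect_equal(v, sm / length(x), tolerance = 1e-4)
  # 3D volumes take the 11x11x11 window path
  xv <- array(runif(14^3), c(14, 14, 14))
  expect_equal(ssim(xv, xv), 1)
})

test_that("PSNR and SNR follow their decibel definitions", {
  x <- matrix(c(10, 5, 2, 1), 2)
  y <- x; y[1] <- 9  # MSE = 1/4
  expect_equal(psnr(x, y), 10 * log10(100 / 0.25))
  expect_equal(psnr(x, x), Inf)
  # doubling the MSE lowers PSNR by 10*log10(2)
  y2 <- x; y2[1] <- 10 - sqrt(2)
  expect_equal(psnr(x, y) - psnr(x, y2), 10 * log10(2), tolerance = 1e-10)
  expect_equal(snr(1, 2), 10 * log10(1 / 1))   # = 0 dB
  expect_equal(snr(x, x), Inf)
  a <- matrix(runif(25), 5); b <- a + matrix(rnorm(25), 5)
  expect_equal(snr(3 * a, 3 * b), snr(a, b), tolerance = 1e-10)
})

test_that("Pearson correlation matches its covariance definition", {
  x <- runif(50)
  expect_equal(pearson_r(x, 2 * x + 3), 1)
  expect_equal(pearson_r(x, -x), -1)
  y <- runif(50)
  oracle <- mean((x - mean(x)) * (y - mean(y))) /
    (stats::sd(x) * stats::sd(y)) * (50 / 49)   # population vs sample n
  expect_equal(pearson_r(x, y), stats::cor(x, y), tolerance = 1e-12)
  expect_equal(pearson_r(x, y), oracle, tolerance = 1e-10)
})

test_that("dF/F0 normalizes against the time-averaged baseline", {
  f <- rep(5, 20)
  expect_true(all(dff(f) == 0))
  f2 <- c(rep(10, 9), 20, rep(10, 10))   # F0 = 10.5
  d <- dff(f2, baseline = 1:9)           # F0 = 10 on the stated window
  expect_equal(as.numeric(d[10]), 1.0)
  expect_equal(attr(d, "f0"), 10)
  # linearity in (F - F0)
  expect_equal(as.numeric(dff(f2, 1:9)) * 2,
               as.numeric((f2 - 10) * 2 / 10))
  expect_error(dff(rep(0, 10)), "positive")
})

test_that("peak detection applies the rise, window-maximum and prominence rules", {
  # a single constructed transient satisfying all three rules
  x <- rep(0, 40)
  x[8:11] <- c(0.01, 0.02, 0.035, 0.05)    # rise to apex at 11
  x[12:16] <- c(0.04, 0.03, 0.02, 0.01, 0.005)
  pk <- detect_peaks(x)
  expect_equal(pk$frame, 11L)
  # brute-force re-check of each rule at the apex
  expect_gt(x[11] - x[8], 0.01)
  expect_equal(which.max(x[8:21]), 4L)
  # sub-threshold noise yields nothing
  set.seed(62)
  expect_equal(nrow(detect_peaks(rnorm(50, sd = 3e-4))), 0L)
  # two apexes 5 frames apart: the lower, earlier one is suppressed by the
  # window-maximum rule (the higher apex falls inside its +10 window)
  y <- rep(0, 40)
  y[7:10] <- c(0.01, 0.02, 0.03, 0.04)     # lower apex at 10
  y[11:12] <- c(0.02, 0.025)
  y[13:15] <- c(0.04, 0.05, 0.06)          # higher apex at 15
  y[16:20] <- c(0.04, 0.03, 0.02, 0.01, 0)
  pk2 <- detect_peaks(y)
  expect_equal(pk2$frame, 15L)
  # short traces warn and return empty
  expect_warning(out <- detect_peaks(rep(0, 10)), "14")
  expect_equal(nrow(out), 0L)
  # invariance to a constant baseline shift of the raw trace
  f <- 100 + 100 * x
  f_shift <- f + 50
  p1 <- detect_peaks(as.numeric(dff(f)))
  p2 <- detect_peaks(as.numeric(dff(f_shift)))
  expect_equal(p1$frame, p2$frame)
})

test_that("75% width interpolates a symmetric triangle exactly", {
  x <- rep(0, 30)
  x[10:18] <- c(0, 0.25, 0.5, 0.75, 1, 0.75, 0.5, 0.25, 0)
  w <- peak_width_75(x, 14L)
  expect_equal(w$rise, 13)
  expect_equal(w$fall, 15)
  expect_equal(w$width, 2)    # analytic: 2 * (1 - 0.75) * half-width 4
  # plateau at the maximum is spanned
  xp <- rep(0, 30); xp[10:20] <- c(0.5, rep(1, 9), 0.5)
  # crossings interpolate on the flanks: 10.5 and 19.5, spanning the plateau
  wp <- peak_width_75(xp, 15L)
  expect_equal(wp$width, 9)
  expect_gt(w$width, 0)
})

test_that("aligned peak averaging normalizes each window to minimum zero", {
  x <- rep(0, 40)
  x[10:18] <- c(0, 0.25, 0.5, 0.75, 1, 0.75, 0.5, 0.25, 0)
  avg <- average_aligned_peaks(x, 14L, pre = 3L, post = 10L)
  expect_equal(length(avg), 14L)
  expect_equal(min(avg), 0)
  expect_equal(avg, x[11:24] - min(x[11:24]))   # single peak: equals itself
  # two known triangles, hand-averaged
  y <- rep(0, 40)
  y[20:24] <- c(0, 0.5, 1, 0.5, 0)
  avg2 <- average_aligned_peaks(list(x, y), list(14L, 22L), pre = 2L, post = 2L)
  # each window is min-subtracted before averaging
  expect_equal(avg2, (c(0, 0.25, 0.5, 0.25, 0) + c(0, 0.5, 1, 0.5, 0)) / 2)
})
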