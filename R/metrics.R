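# ------------------------------------------------------------------------
# Image-quality metrics (MTF, RMSE, SSIM, PSNR, SNR, Pearson correlation)
# and calcium-trace analysis (dF/F0, transient peak detection, 75% widths,
# aligned peak averaging).
# ------------------------------------------------------------------------

as_plain_array <- function(x) {
  if (inherits(x, "lightfield")) return(x$data)
  if (inherits(x, "ad_node")) return(x$v)
  unclass(x)
}

check_pair <- function(x, y) {
  x <- as_plain_array(x); y <- as_plain_array(y)
  if (length(x) != length(y))
    stop("reference and estimate must share one shape")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("metric inputs must be finite")
  list(x = as.numeric(x) * 1, y = as.numeric(y) * 1,
       dx = dim(as_plain_array(x)))
}

#' Modulation transfer function of an intensity profile
#'
#' `MTF = (max(L) - min(L)) / (max(L) + min(L))` for a 1D intensity profile
#' across adjacent structures; 1 for full contrast, 0 for a flat profile.
#'
#' @param L non-negative, non-empty numeric profile.
#' @return A single number in `[0, 1]`.
#' @export
mtf <- function(L) {
  if (length(L) == 0L) stop("empty profile")
  if (any(L < 0)) stop("profile must be non-negative")
  mx <- max(L); mn <- min(L)
  if (mx + mn == 0) stop("MTF undefined for an all-zero profile")
  (mx - mn) / (mx + mn)
}

#' Root-mean-square error
#'
#' `sqrt(sum((X_i - Y_i)^2) / n)` over all `n` pixels.
#'
#' @param x reference image/volume; `y` estimate (same shape).
#' @param y estimate.
#' @return A single number.
#' @export
rmse <- function(x, y) {
  p <- check_pair(x, y)
  sqrt(mean((p$x - p$y)^2))
}

gauss_kernel_1d <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1L) / 2
  k <- exp(-((seq_len(size) - 1 - r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian filtering along every axis with symmetric
# (reflection) padding at the edges.
gauss_filter <- function(arr, size = 11L, sigma = 1.5) {
  d <- dim(arr) %||% length(arr)
  if (is.null(dim(arr))) dim(arr) <- d
  k <- gauss_kernel_1d(size, sigma)
  r <- (size - 1L) %/% 2L
  nd <- length(d)
  for (ax in seq_len(nd)) {
    n <- d[ax]
    pad_idx <- c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
    pad_idx <- pmin(pmax(pad_idx, 1L), n)
    K <- matrix(0, n, n + 2L * r)
    for (i in seq_len(n)) K[i, i + seq_len(size) - 1L] <- k
    perm <- c(ax, setdiff(seq_len(nd), ax))
    m <- aperm(arr, perm)
    dim(m) <- c(n, prod(d[-ax]))
    m <- K %*% m[pad_idx, , drop = FALSE]
    dim(m) <- c(n, d[-ax])
    arr <- aperm(m, order(perm))
  }
  arr
}

#' Structural similarity index
#'
#' Local SSIM maps are computed with sliding Gaussian windows (11 x 11,
#' standard deviation 1.5, for 2D images; 11 x 11 x 11 for 3D volumes) and
#' averaged. The stabilizing constants are `C1 = (0.01 * max(X))^2` and
#' `C2 = (0.03 * max(X))^2`, taken from the reference image. Edges use
#' symmetric padding.
#'
#' @param x reference; `y` estimate (2D or 3D, same shape).
#' @param y estimate.
#' @param size,sigma Gaussian window size and standard deviation.
#' @return A single number in `[-1, 1]`; 1 iff the images are identical.
#' @export
ssim <- function(x, y, size = 11L, sigma = 1.5) {
  xa <- as_plain_array(x); ya <- as_plain_array(y)
  if (is.null(dim(xa))) dim(xa) <- length(xa)
  if (is.null(dim(ya))) dim(ya) <- length(ya)
  if (!all(dim(xa) == dim(ya))) stop("SSIM inputs must share one shape")
  L <- max(xa)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  mx <- gauss_filter(xa, size, sigma)
  my <- gauss_filter(ya, size, sigma)
  sxx <- gauss_filter(xa * xa, size, sigma) - mx * mx
  syy <- gauss_filter(ya * ya, size, sigma) - my * my
  sxy <- gauss_filter(xa * ya, size, sigma) - mx * my
  num <- (2 * mx * my + c1) * (2 * sxy + c2)
  den <- (mx * mx + my * my + c1) * (sxx + syy + c2)
  mean(num / den)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max(X)^2 / MSE(X, Y))` in decibels; `Inf` for identical
#' images.
#'
#' @inheritParams rmse
#' @return A single number (dB), possibly `Inf`.
#' @export
psnr <- function(x, y) {
  p <- check_pair(x, y)
  mse <- mean((p$x - p$y)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(p$x)^2 / mse)
}

#' Signal-to-noise ratio
#'
#' `10 * log10(sum(X^2) / sum((X - Y)^2))` in decibels; `Inf` for identical
#' images. Invariant to jointly rescaling the signal and the error.
#'
#' @inheritParams rmse
#' @return A single number (dB), possibly `Inf`.
#' @export
snr <- function(x, y) {
  p <- check_pair(x, y)
  err <- sum((p$x - p$y)^2)
  if (err == 0) return(Inf)
  10 * log10(sum(p$x^2) / err)
}

#' Pearson correlation between two images
#'
#' `E[(X - mu_X)(Y - mu_Y)] / (sigma_X * sigma_Y)`.
#'
#' @inheritParams rmse
#' @return A single number in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  p <- check_pair(x, y)
  stats::cor(p$x, p$y)
}

#' Evaluate all image metrics at once
#'
#' @inheritParams rmse
#' @return A one-row data.frame with columns rmse, ssim, psnr, snr, pearson.
#' @export
evaluate_pair <- function(x, y) {
  data.frame(rmse = rmse(x, y), ssim = ssim(as_plain_array(x), as_plain_array(y)),
             psnr = psnr(x, y), snr = snr(x, y), pearson = pearson_r(x, y))
}

# ---- calcium-trace analysis ----------------------------------------------

#' Fractional fluorescence change
#'
#' `dF/F0 = (F - F0) / F0` with the baseline `F0` the time-average of `F`
#' over `baseline` (default: the whole trace).
#'
#' @param f fluorescence time series.
#' @param baseline optional index vector of baseline frames.
#' @return Numeric dF/F0 series with attribute `"f0"`.
#' @export
dff <- function(f, baseline = NULL) {
  if (is.null(baseline)) baseline <- seq_along(f)
  f0 <- mean(f[baseline])
  if (!is.finite(f0) || f0 <= 0) stop("baseline F0 must be positive")
  structure((f - f0) / f0, f0 = f0)
}

# Topographic prominence of a local maximum (standard definition: height
# above the higher of the two key saddles toward higher terrain).
peak_prominence <- function(x, t) {
  n <- length(x)
  left_min <- x[t]; i <- t
  while (i > 1L) {
    i <- i - 1L
    if (x[i] > x[t]) break
    left_min <- min(left_min, x[i])
    if (i == 1L) break
  }
  if (i >= 1L && x[i] <= x[t]) left_min <- min(left_min, x[i])
  lm <- min(x[t], left_min)
  right_min <- x[t]; j <- t
  while (j < n) {
    j <- j + 1L
    if (x[j] > x[t]) break
    right_min <- min(right_min, x[j])
    if (j == n) break
  }
  rm_ <- min(x[t], right_min)
  x[t] - max(lm, rm_)
}

#' Detect calcium transient peaks
#'
#' A frame `t` of a dF/F0 trace is a transient peak iff (a) the signal rose
#' by more than `rise_thresh` over the 3 preceding frames, (b) it is the
#' highest value within the window from 3 frames before to 10 frames after,
#' and (c) its topographic prominence exceeds `prom_thresh`. Thresholds are
#' in dF/F0 units (1% = 0.01, 2.5% = 0.025). Traces shorter than 14 frames
#' return no peaks with a warning.
#'
#' @param x dF/F0 trace (from [dff()]).
#' @param rise_thresh minimum rise over the 3 preceding frames (default 0.01).
#' @param prom_thresh minimum prominence (default 0.025).
#' @param pre,post local-maximum window extents (defaults 3 and 10).
#' @return data.frame with columns `frame`, `value`, `prominence`, `rise`,
#'   `fall`, `width` (the last three from [peak_width_75()]).
#' @export
detect_peaks <- function(x, rise_thresh = 0.01, prom_thresh = 0.025,
                         pre = 3L, post = 10L) {
  empty <- data.frame(frame = integer(), value = numeric(),
                      prominence = numeric(), rise = numeric(),
                      fall = numeric(), width = numeric())
  n <- length(x)
  if (n < 14L) {
    warning(sprintf("trace has %d frames (< 14); no peaks detected", n))
    return(empty)
  }
  hits <- integer(0)
  for (t in (pre + 1L):n) {
    if (!(x[t] - x[t - 3L] > rise_thresh)) next
    win <- max(1L, t - pre):min(n, t + post)
    if (x[t] < max(x[win])) next
    if (which.max(x[win]) != match(t, win)) next  # earliest frame on ties
    if (!(peak_prominence(x, t) > prom_thresh)) next
    hits <- c(hits, t)
  }
  if (length(hits) == 0L) return(empty)
  w <- t(vapply(hits, function(t) unlist(peak_width_75(x, t)), numeric(3)))
  data.frame(frame = hits, value = x[hits],
             prominence = vapply(hits, function(t) peak_prominence(x, t), numeric(1)),
             rise = w[, "rise"], fall = w[, "fall"], width = w[, "width"])
}

#' Transient width at 75% of the peak value
#'
#' Finds the linearly interpolated frames at which the trace crosses 75% of
#' the peak value on the rising and falling flanks; the width is their
#' difference. A plateau at the maximum is spanned; a flank that never
#' crosses (trace boundary) is clipped to the boundary frame.
#'
#' @param x dF/F0 trace.
#' @param peak peak frame index.
#' @return `list(rise, fall, width)` in (fractional) frames.
#' @export
peak_width_75 <- function(x, peak) {
  level <- 0.75 * x[peak]
  n <- length(x)
  rise <- 1
  t <- peak
  while (t > 1L && x[t - 1L] >= level) t <- t - 1L
  if (t > 1L) {
    # crossing between t-1 and t
    rise <- (t - 1L) + (level - x[t - 1L]) / (x[t] - x[t - 1L])
  } else rise <- 1
  fall <- n
  t <- peak
  while (t < n && x[t + 1L] >= level) t <- t + 1L
  if (t < n) {
    fall <- t + (x[t] - level) / (x[t] - x[t + 1L])
  } else fall <- n
  list(rise = rise, fall = fall, width = fall - rise)
}

#' Average temporally aligned transients
#'
#' Each detected peak window (`pre` frames before to `post` frames after the
#' apex) is aligned at its apex, shifted so its minimum is 0, and the
#' windows are averaged per frame.
#'
#' @param traces a dF/F0 trace or list of traces.
#' @param peaks peak frame indices (vector, or list matching `traces`).
#' @param pre,post window extents around the apex.
#' @return Numeric vector of length `pre + post + 1` (the mean normalized
#'   transient), or NULL if no complete window exists.
#' @export
average_aligned_peaks <- function(traces, peaks, pre = 3L, post = 10L) {
  if (!is.list(traces)) { traces <- list(traces); peaks <- list(peaks) }
  wins <- list()
  for (i in seq_along(traces)) {
    x <- traces[[i]]
    for (t in peaks[[i]]) {
      if (t - pre < 1L || t + post > length(x)) next
      w <- x[(t - pre):(t + post)]
      wins[[length(wins) + 1L]] <- w - min(w)
    }
  }
  if (length(wins) == 0L) return(NULL)
  colMeans(do.call(rbind, wins))
}
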