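# Single-window EEG feature estimators (reference R implementations; the
# bulk extraction path in C++ computes the same quantities and is tested
# for agreement against these).

#' Statistical features of a 1-second window
#'
#' @param window numeric vector of samples.
#' @param run_mean,run_sd run-level mean and SD of the channel, used to
#'   z-score the window for `mean_norm` (window-level z-scoring would make
#'   the feature identically zero).
#' @return named list: `mean`, `mean_norm`, `sd` (sample SD), `skewness`
#'   and `kurtosis` (standardized central moments; kurtosis is non-excess,
#'   3 for a Gaussian). Skewness/kurtosis are `NA` for a constant window.
#' @export
stat_features <- function(window, run_mean = mean(window),
                          run_sd = stats::sd(window)) {
  if (length(window) < 3) stop("window must have at least 3 samples")
  m <- mean(window)
  s <- stats::sd(window)
  d <- window - m
  m2 <- mean(d^2)
  if (m2 > 0) {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  } else skew <- kurt <- NA_real_
  list(mean = m,
       mean_norm = if (run_sd > 0) (m - run_mean) / run_sd else NA_real_,
       sd = s, skewness = skew, kurtosis = kurt)
}

#' Hjorth parameters of a window
#'
#' Activity is the sample variance; mobility the SD ratio of the scaled
#' first difference to the signal; complexity the mobility ratio of the
#' first difference to the signal. First differences are scaled by `fs`,
#' so mobility of a sinusoid of frequency `f` approaches `2*pi*f` (rad/s).
#'
#' @param window numeric vector of samples.
#' @param fs sampling rate, Hz.
#' @return named list `activity`, `mobility`, `complexity` (the latter two
#'   `NA` for a constant window).
#' @export
hjorth <- function(window, fs = 1000) {
  if (length(window) < 3) stop("window must have at least 3 samples")
  v <- stats::var(window)
  if (v == 0)
    return(list(activity = 0, mobility = NA_real_, complexity = NA_real_))
  d1 <- diff(window) * fs
  v1 <- stats::var(d1)
  mob <- sqrt(v1 / v)
  comp <- if (v1 > 0) {
    d2 <- diff(d1) * fs
    sqrt(stats::var(d2) / v1) / mob
  } else NA_real_
  list(activity = v, mobility = mob, complexity = comp)
}

#' Welch power spectral density of a 1-second window
#'
#' Hamming-windowed 0.5-second segments with 50% overlap, averaged
#' periodograms, one-sided, on a 2 Hz frequency grid from 0 to `fs/2`.
#'
#' @param window numeric vector of exactly `fs` samples.
#' @param fs sampling rate, Hz.
#' @return list with `freq` (Hz) and `psd` (microvolt^2/Hz).
#' @export
psd_welch <- function(window, fs = 1000) {
  n <- length(window)
  if (n != fs) stop("window length must equal fs samples")
  L <- fs / 2
  hop <- L / 2
  starts <- seq(0, n - L, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  U <- sum(w^2)
  segs <- vapply(starts, function(s0) window[(s0 + 1):(s0 + L)] * w,
                 numeric(L))
  X <- stats::mvfft(segs)
  nb <- L / 2 + 1
  p <- rowMeans(Mod(X[seq_len(nb), , drop = FALSE])^2) / (fs * U)
  p[2:(nb - 1)] <- 2 * p[2:(nb - 1)]
  list(freq = (seq_len(nb) - 1) * fs / L, psd = p)
}

#' Band powers from a PSD
#'
#' Absolute power is the integral of the PSD over each half-open band
#' `[lo, hi)` (delta 0-4, theta 4-8, alpha 8-13, beta 13-30 Hz), with gamma
#' closed at 45 Hz so the five bands exactly partition `[0, 45]`. Relative
#' powers divide by the total over `[0, 45]`.
#'
#' @param psd a [psd_welch()] result (or any list with `freq`, `psd`).
#' @return list with `total`, `abs` (named by band) and `rel` (all-`NA`
#'   when the total power is zero).
#' @export
band_powers <- function(psd) {
  df <- psd$freq[2] - psd$freq[1]
  ab <- vapply(seq_along(.BANDS), function(b) {
    lo <- .BAND_EDGES[b]; hi <- .BAND_EDGES[b + 1]
    sel <- if (b == length(.BANDS)) psd$freq >= lo & psd$freq <= hi
           else psd$freq >= lo & psd$freq < hi
    sum(psd$psd[sel]) * df
  }, numeric(1))
  names(ab) <- .BANDS
  tot <- sum(ab)
  rel <- if (tot > 0) ab / tot else setNames(rep(NA_real_, 5), .BANDS)
  list(total = tot, abs = ab, rel = rel)
}

#' Pairwise band-power ratios
#'
#' All 10 unordered band pairs, numerator the lower-frequency band
#' (`"Theta/Alpha"` style orientation).
#'
#' @param abs_powers named numeric vector of absolute band powers
#'   (names `delta`, `theta`, `alpha`, `beta`, `gamma`).
#' @return named numeric vector of 10 ratios (`NA` where the denominator
#'   is zero).
#' @export
band_ratios <- function(abs_powers) {
  lo <- abs_powers[.RATIO_PAIRS$lo]
  hi <- abs_powers[.RATIO_PAIRS$hi]
  out <- ifelse(hi > 0, lo / hi, NA_real_)
  names(out) <- paste0("ratio_", .RATIO_PAIRS$lo, "_", .RATIO_PAIRS$hi)
  out
}

#' Spectral mean frequency and alpha peak frequency
#'
#' Mean frequency is the power-weighted spectral centroid over `[0, 45]` Hz;
#' the alpha peak is the grid argmax of the PSD within `[8, 13)` Hz.
#'
#' @param psd a [psd_welch()] result.
#' @return list `mean_freq`, `alpha_peak_freq` (both `NA` if the respective
#'   power mass is zero).
#' @export
spectral_descriptors <- function(psd) {
  sel <- psd$freq <= 45
  f <- psd$freq[sel]; p <- psd$psd[sel]
  tot <- sum(p)
  mf <- if (tot > 0) sum(f * p) / tot else NA_real_
  asel <- which(f >= 8 & f < 13)
  apk <- if (length(asel) && any(p[asel] > 0))
    f[asel[which.max(p[asel])]] else NA_real_
  list(mean_freq = mf, alpha_peak_freq = apk)
}

#' Task engagement indexes
#'
#' @param abs_powers named absolute band powers.
#' @return list `beta_over_theta_alpha`, `theta_over_alpha_beta` (`NA`
#'   where the denominator is zero).
#' @export
engagement <- function(abs_powers) {
  ta <- abs_powers[["theta"]] + abs_powers[["alpha"]]
  ab <- abs_powers[["alpha"]] + abs_powers[["beta"]]
  list(beta_over_theta_alpha = if (ta > 0) abs_powers[["beta"]] / ta else NA_real_,
       theta_over_alpha_beta = if (ab > 0) abs_powers[["theta"]] / ab else NA_real_)
}

#' Higuchi fractal dimension
#'
#' Curve-length estimate: for lags `k = 1..kmax` and all offsets, the
#' normalized curve length `L(k)` is computed and the fractal dimension is
#' minus the least-squares slope of `log L(k)` versus `log k`. Around 1 for
#' smooth signals, 2 for white noise.
#'
#' @param window numeric vector.
#' @param kmax maximum lag (window length should be at least `10 * kmax`).
#' @return fractal dimension (`NA` for a constant window).
#' @export
higuchi_fd <- function(window, kmax = 10) {
  n <- length(window)
  if (stats::var(window) == 0) return(NA_real_)
  lk <- ll <- numeric(0)
  for (k in seq_len(kmax)) {
    Lm <- numeric(0)
    for (m in 0:(k - 1)) {
      np <- (n - 1 - m) %/% k
      if (np < 1) next
      i <- m + 1 + (0:np) * k
      Lm <- c(Lm, sum(abs(diff(window[i]))) * (n - 1) / (np * k) / k)
    }
    if (!length(Lm) || mean(Lm) <= 0) next
    lk <- c(lk, log(k)); ll <- c(ll, log(mean(Lm)))
  }
  if (length(lk) < 2) return(NA_real_)
  -as.numeric(stats::coef(stats::lm.fit(cbind(1, lk), ll))[2])
}

#' Hurst exponent by rescaled-range analysis
#'
#' For dyadic sub-series lengths `s = 16, 32, ...` up to half the window,
#' the window is cut into `floor(n/s)` blocks; each block's rescaled range
#' R/S (range of the cumulative mean deviation over the block SD) is
#' averaged, and H is the log-log slope of mean R/S versus `s`. About 0.5
#' for white noise, near 1 for strongly persistent series.
#'
#' @param window numeric vector (length at least 64; the estimator needs
#'   two dyadic scales).
#' @return Hurst exponent (`NA` for a constant window).
#' @export
hurst_rs <- function(window) {
  n <- length(window)
  if (stats::var(window) == 0) return(NA_real_)
  s <- 16
  ls <- lrs <- numeric(0)
  while (s <= n / 2) {
    nblk <- n %/% s
    rs <- numeric(0)
    for (b in seq_len(nblk)) {
      y <- window[((b - 1) * s + 1):(b * s)]
      d <- y - mean(y)
      S <- sqrt(mean(d^2))
      if (S > 0) {
        cum <- cumsum(d)
        rs <- c(rs, (max(cum, 0) - min(cum, 0)) / S)
      }
    }
    if (length(rs)) {
      ls <- c(ls, log(s)); lrs <- c(lrs, log(mean(rs)))
    }
    s <- s * 2
  }
  if (length(ls) < 2) return(NA_real_)
  as.numeric(stats::coef(stats::lm.fit(cbind(1, ls), lrs))[2])
}
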