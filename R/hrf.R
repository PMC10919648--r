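# Canonical HRF construction and regressor conditioning.

#' Canonical double-gamma HRF with selectable hemodynamic delay
#'
#' The kernel is a difference of two gamma densities: a positive lobe whose
#' mode sits at `delay_s` and an undershoot lobe with mode at
#' `delay_s + undershoot_lag` scaled by `undershoot_ratio`. Both use unit
#' time scale, so shape `delay + 1` puts the mode exactly at `delay`.
#' Weights are sampled at `dt_s` over `[0, span_s]` and scaled to unit peak
#' (correlation downstream is scale invariant; unit peak eases plotting).
#'
#' @param delay_s hemodynamic delay (positive-lobe mode), seconds.
#' @param dt_s sampling interval, seconds (3 = the fMRI TR grid).
#' @param span_s kernel support, seconds.
#' @param undershoot_lag undershoot mode lag after the peak, seconds.
#' @param undershoot_ratio undershoot amplitude ratio.
#' @return An `hrf_kernel`: list with `delay_s`, `dt_s`, `span_s`,
#'   `times` and `weights` (unit peak).
#' @examples
#' h <- canonical_hrf(5, dt_s = 0.1)
#' h$times[which.max(h$weights)]  # 5
#' @export
canonical_hrf <- function(delay_s, dt_s = 3, span_s = 32,
                          undershoot_lag = 10, undershoot_ratio = 1 / 6) {
  if (!is.finite(delay_s) || delay_s <= 0) stop("delay_s must be positive")
  if (dt_s <= 0) stop("dt_s must be positive")
  if (delay_s >= span_s) stop("delay_s must be smaller than span_s")
  t <- seq(0, span_s, by = dt_s)
  a1 <- delay_s + 1
  a2 <- delay_s + undershoot_lag + 1
  w <- stats::dgamma(t, shape = a1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = a2, rate = 1)
  w <- w / max(w)
  structure(list(delay_s = delay_s, dt_s = dt_s, span_s = span_s,
                 times = t, weights = w),
            class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("Canonical HRF: delay %g s, dt %g s, span %g s (%d taps)\n",
              x$delay_s, x$dt_s, x$span_s, length(x$weights)))
  invisible(x)
}

#' @export
plot.hrf_kernel <- function(x, ...) {
  plot(x$times, x$weights, type = "l", xlab = "time (s)",
       ylab = "HRF weight", ...)
  abline(v = x$delay_s, lty = 3)
  invisible(x)
}

#' Causal convolution of a feature time course with an HRF kernel
#'
#' Discrete causal convolution with zero pre-padding, truncated to the
#' input length, so output sample `t` depends only on input samples
#' `<= t` (the BOLD regressor at acquisition time must not use future EEG).
#'
#' @param x numeric series sampled at the kernel's `dt_s`.
#' @param kernel an [canonical_hrf()] kernel.
#' @param dt_s sampling interval of `x`; must equal `kernel$dt_s`.
#' @return numeric series, same length as `x`.
#' @export
convolve_align <- function(x, kernel, dt_s = kernel$dt_s) {
  if (!isTRUE(all.equal(dt_s, kernel$dt_s)))
    stop("sampling interval mismatch: series dt ", dt_s,
         " vs kernel dt ", kernel$dt_s)
  h <- kernel$weights
  n <- length(x)
  y <- stats::convolve(x, rev(h), type = "open")[seq_len(n)]
  as.numeric(y)
}

# causal convolution of each matrix row with kernel weights (vectorized)
convolve_rows <- function(m, kernel) {
  h <- kernel$weights
  n <- ncol(m)
  out <- matrix(0, nrow(m), n)
  for (j in seq_along(h)) {
    if (h[j] == 0) next
    cols <- seq_len(n - j + 1)
    out[, cols + j - 1] <- out[, cols + j - 1] + h[j] * m[, cols, drop = FALSE]
  }
  out
}

#' Standardize a series to zero mean and unit SD
#'
#' @param x numeric vector with positive SD.
#' @param id identifier used in the error message for degenerate input.
#' @return standardized numeric vector.
#' @export
standardize <- function(x, id = deparse(substitute(x))) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize constant series: ", id)
  (x - mean(x)) / s
}

# row-standardize a matrix; returns list(values, ok) where !ok rows were
# constant and are left at zero
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  ctr <- m - mu
  s <- sqrt(rowSums(ctr^2) / (ncol(m) - 1))
  ok <- is.finite(s) & s > 0
  ctr[ok, ] <- ctr[ok, , drop = FALSE] / s[ok]
  ctr[!ok, ] <- 0
  list(values = ctr, ok = ok)
}
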