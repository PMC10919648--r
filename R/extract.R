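# Feature-bank extraction and feature-level repair.

#' Zero-phase band-pass filter for an EEG recording
#'
#' Windowed-sinc (Hamming) FIR filters applied sequentially: first the
#' high-pass, then the low-pass. The symmetric kernels are applied centered
#' (zero phase) with zero-padded edges, preserving length. Kernel lengths
#' follow the usual heuristic: transition bandwidth 25% of the passband
#' edge, but no narrower than 2 Hz.
#'
#' @param recording an [eeg_recording()].
#' @param hp_hz,lp_hz high-pass and low-pass cut-off frequencies, Hz.
#' @return the filtered [eeg_recording()].
#' @export
bandpass <- function(recording, hp_hz = 1, lp_hz = 45) {
  fs <- recording$fs
  if (lp_hz >= fs / 2) stop("lp_hz must be below the Nyquist frequency")
  if (hp_hz >= lp_hz) stop("hp_hz must be below lp_hz")
  kh <- .sinc_kernel(hp_hz, fs, type = "high")
  kl <- .sinc_kernel(lp_hz, fs, type = "low")
  x <- recording$data
  n <- nrow(x)
  for (k in list(kh, kl)) {
    half <- (length(k) - 1) / 2
    N <- n + length(k) - 1
    K <- fft(c(k, rep(0, N - length(k))))
    y <- apply(x, 2, function(col) {
      Re(fft(fft(c(col, rep(0, N - n))) * K, inverse = TRUE)) / N
    })
    x <- y[(half + 1):(half + n), , drop = FALSE]
  }
  recording$data <- x
  recording
}

# symmetric windowed-sinc kernel (Hamming); transition 25% of edge, >= 2 Hz
.sinc_kernel <- function(cut_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  trans <- max(0.25 * cut_hz, 2)
  ntap <- ceiling(3.3 * fs / trans)
  if (ntap %% 2 == 0) ntap <- ntap + 1
  m <- (ntap - 1) / 2
  t <- -m:m
  fc <- cut_hz / fs
  h <- 2 * fc * ifelse(t == 0, 1, sin(2 * pi * fc * t) / (2 * pi * fc * t))
  w <- 0.54 + 0.46 * cos(pi * t / m)
  h <- h * w
  h <- h / sum(h)
  if (type == "high") {
    h <- -h
    h[m + 1] <- h[m + 1] + 1
  }
  h
}

#' Cut a recording into contiguous 1-second windows
#'
#' @param recording an [eeg_recording()].
#' @return list, one element per channel, each an `fs x n_windows` matrix
#'   of non-overlapping 1-second windows (window `k` starts at sample
#'   `(k-1)*fs + 1`; a trailing partial second is dropped).
#' @export
window_segment <- function(recording) {
  fs <- recording$fs
  nwin <- nrow(recording$data) %/% fs
  if (nwin < 1) stop("recording must be at least 1 second long")
  lapply(seq_len(ncol(recording$data)), function(c) {
    matrix(recording$data[seq_len(nwin * fs), c], nrow = fs)
  }) |> setNames(recording$channel_labels)
}

#' Construct a feature matrix object
#'
#' @param values descriptors x time numeric matrix.
#' @param descriptors inventory data frame ([build_inventory()] layout).
#' @param dt_s sampling interval of the columns, seconds.
#' @param missing_mask,outlier_mask logical matrices aligned to `values`.
#' @param run_id,subject_id identifiers.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, descriptors, dt_s = 1,
                           missing_mask = NULL, outlier_mask = NULL,
                           run_id = "run1", subject_id = "sub1") {
  if (nrow(values) != nrow(descriptors))
    stop("values rows must match descriptor count")
  if (is.null(missing_mask))
    missing_mask <- matrix(FALSE, nrow(values), ncol(values))
  rownames(values) <- descriptors$id
  structure(list(values = values, descriptors = descriptors, dt_s = dt_s,
                 missing_mask = missing_mask, outlier_mask = outlier_mask,
                 run_id = run_id, subject_id = subject_id),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d descriptors x %d samples (dt = %g s)\n",
              nrow(x$values), ncol(x$values), x$dt_s))
  cat(sprintf("  missing: %d values flagged\n", sum(x$missing_mask)))
  invisible(x)
}

#' Extract the full feature bank from a recording
#'
#' Evaluates every inventory descriptor on each contiguous 1-second window
#' of every channel. Windows listed in `rejected_epochs` (e.g. from an
#' upstream epoch-rejection step) are flagged missing for all descriptors.
#'
#' @param recording a band-limited [eeg_recording()].
#' @param kmax Higuchi lag bound.
#' @param rejected_epochs integer indices of 1-second windows to flag
#'   missing (1-based), or `NULL`.
#' @param engine `"cpp"` (fast path) or `"R"` (reference path composed of
#'   the exported single-window estimators); both produce the same values.
#' @return A [feature_matrix()] with `dt_s = 1`.
#' @export
extract_all <- function(recording, kmax = 10, rejected_epochs = NULL,
                        engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  fs <- recording$fs
  if (nrow(recording$data) < 3 * fs)
    stop("recording must be at least 3 seconds long")
  inv <- build_inventory(recording$channel_labels)
  nwin <- nrow(recording$data) %/% fs
  if (engine == "cpp") {
    res <- .extract_features_cpp(recording$data, as.integer(fs),
                                 as.integer(kmax))
    vals <- res$values
    miss <- res$missing
    vals[miss] <- NA_real_
  } else {
    vals <- matrix(NA_real_, nrow(inv), nwin)
    for (c in seq_along(recording$channel_labels)) {
      ch <- recording$data[seq_len(nwin * fs), c]
      rm_ <- mean(ch); rs_ <- stats::sd(ch)
      for (t in seq_len(nwin)) {
        x <- ch[((t - 1) * fs + 1):(t * fs)]
        st <- stat_features(x, rm_, rs_)
        hj <- hjorth(x, fs)
        ps <- psd_welch(x, fs)
        bp <- band_powers(ps)
        rt <- band_ratios(bp$abs)
        sdp <- spectral_descriptors(ps)
        en <- engagement(bp$abs)
        row0 <- (c - 1) * nrow(.FEATURE_TABLE)
        vals[row0 + 1:35, t] <- c(
          st$mean, st$mean_norm, st$sd, st$skewness, st$kurtosis,
          hj$activity, hj$mobility, hj$complexity,
          bp$total, bp$abs, bp$rel, rt, sdp$mean_freq, sdp$alpha_peak_freq,
          en$beta_over_theta_alpha, en$theta_over_alpha_beta,
          higuchi_fd(x, kmax), hurst_rs(x))
      }
    }
    miss <- is.na(vals)
  }
  if (!is.null(rejected_epochs)) {
    vals[, rejected_epochs] <- NA_real_
    miss[, rejected_epochs] <- TRUE
  }
  feature_matrix(vals, inv, dt_s = 1, missing_mask = miss,
                 run_id = recording$run_id, subject_id = recording$subject_id)
}

#' Linear interpolation of missing feature samples
#'
#' Per-descriptor linear interpolation over time at missing positions;
#' leading/trailing gaps take the nearest observed value. The missing mask
#' is retained for provenance.
#'
#' @param fm a [feature_matrix()].
#' @return the repaired [feature_matrix()] (no remaining `NA`).
#' @export
interp_missing <- function(fm) {
  vals <- fm$values
  bad_rows <- which(rowSums(!is.na(vals)) < 2)
  if (length(bad_rows))
    stop("descriptor(s) with fewer than 2 observed samples: ",
         paste(utils::head(fm$descriptors$id[bad_rows], 5), collapse = ", "))
  rows <- which(rowSums(is.na(vals)) > 0)
  tt <- seq_len(ncol(vals))
  for (r in rows) {
    y <- vals[r, ]
    ok <- !is.na(y)
    vals[r, !ok] <- stats::approx(tt[ok], y[ok], xout = tt[!ok],
                                  rule = 2)$y
  }
  fm$values <- vals
  fm
}

#' Interpolate time points that are outliers across the feature bank
#'
#' Flags per-descriptor outliers (beyond the descriptor's median plus or
#' minus 3 IQR) and linearly interpolates, in every descriptor, the time
#' points where the flagged fraction across all descriptors exceeds
#' `fraction_threshold`.
#'
#' @param fm a [feature_matrix()] with no missing values
#'   (run [interp_missing()] first).
#' @param fraction_threshold fraction of descriptors that must flag a time
#'   point before it is repaired (0.25 = the conventional choice).
#' @return the repaired [feature_matrix()]; `outlier_mask` records the
#'   per-value flags.
#' @export
interp_outliers <- function(fm, fraction_threshold = 0.25) {
  vals <- fm$values
  if (anyNA(vals)) stop("run interp_missing() before interp_outliers()")
  qs <- .row_quartiles_cpp(vals)
  iqr <- qs[, 3] - qs[, 1]
  lo <- qs[, 2] - 3 * iqr
  hi <- qs[, 2] + 3 * iqr
  flags <- vals < lo | vals > hi
  frac <- colMeans(flags)
  cols <- which(frac > fraction_threshold)
  if (length(cols)) {
    tt <- seq_len(ncol(vals))
    keep <- setdiff(tt, cols)
    if (length(keep) >= 2) {
      for (r in seq_len(nrow(vals)))
        vals[r, cols] <- stats::approx(keep, vals[r, keep], xout = cols,
                                       rule = 2)$y
    }
  }
  fm$values <- vals
  fm$outlier_mask <- flags
  fm
}

#' Second-order features on the TR grid
#'
#' Aggregates non-overlapping triples of consecutive 1-second feature
#' samples into their mean, maximum and minimum, tripling the descriptor
#' count and aligning the time base to the 3-second fMRI repetition time.
#' A trailing remainder of fewer than 3 samples is dropped.
#'
#' @param fm a [feature_matrix()] with `dt_s = 1`.
#' @return A [feature_matrix()] with `dt_s = 3` and descriptors carrying
#'   transforms `mean3`, `max3`, `min3`.
#' @export
second_order <- function(fm) {
  if (fm$dt_s != 1) stop("second_order() expects a 1-second feature grid")
  nt <- ncol(fm$values) %/% 3
  if (nt < 1) stop("need at least 3 feature samples")
  i1 <- 3 * seq_len(nt) - 2
  v1 <- fm$values[, i1, drop = FALSE]
  v2 <- fm$values[, i1 + 1, drop = FALSE]
  v3 <- fm$values[, i1 + 2, drop = FALSE]
  vals <- rbind((v1 + v2 + v3) / 3, pmax(v1, v2, v3), pmin(v1, v2, v3))
  m1 <- fm$missing_mask[, i1, drop = FALSE] |
    fm$missing_mask[, i1 + 1, drop = FALSE] |
    fm$missing_mask[, i1 + 2, drop = FALSE]
  miss <- rbind(m1, m1, m1)
  desc <- do.call(rbind, lapply(c("mean3", "max3", "min3"), function(tr) {
    d <- fm$descriptors
    d$transform <- tr
    d$id <- paste(d$feature, d$channel, d$transform, sep = "|")
    d
  }))
  feature_matrix(vals, desc, dt_s = 3, missing_mask = miss,
                 run_id = fm$run_id, subject_id = fm$subject_id)
}
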