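test_that("the inventory enumerates the Table-style bank per channel", {
  inv <- build_inventory(c("F3", "F4"))
  expect_equal(nrow(inv), 70)
  expect_equal(as.integer(table(inv$group)[c("linear_time", "linear_freq",
                                             "nonlinear")]),
               c(16L, 50L, 4L))
  expect_true(all(inv$transform == "none"))
  expect_error(build_inventory(c("F3", "F3")), "duplicate")
  expect_error(build_inventory(character(0)), "non-empty")
})

test_that("band-pass filtering attenuates stop bands and passes the mid band", {
  fs <- 500
  t <- seq(0, 6, by = 1 / fs)[-1]
  mk <- function(f) eeg_recording(matrix(sin(2 * pi * f * t)), fs, "Cz")
  rms <- function(r) sqrt(mean(r$data[, 1]^2))
  mid <- function(r) {  # interior samples, away from filter edges
    n <- nrow(r$data)
    sqrt(mean(r$data[(n %/% 4):(3 * n %/% 4), 1]^2))
  }
  expect_lt(mid(bandpass(mk(0.2))) / rms(mk(0.2)), 0.05)
  expect_lt(abs(mid(bandpass(mk(10))) / rms(mk(10)) - 1), 0.02)
  expect_lt(mid(bandpass(mk(60))) / rms(mk(60)), 0.05)
  expect_equal(nrow(bandpass(mk(10))$data), length(t))
  expect_error(bandpass(mk(10), lp_hz = 300), "Nyquist")
})

test_that("windowing is contiguous, non-overlapping, floor-truncated", {
  fs <- 100
  x <- seq_len(1070)  # 10.7 s
  w <- window_segment(eeg_recording(matrix(x), fs, "Cz"))
  expect_equal(ncol(w$Cz), 10)
  expect_equal(nrow(w$Cz), fs)
  expect_equal(w$Cz[, 3], x[201:300])  # window k starts at sample k*fs
})

test_that("statistical features match hand-computed values", {
  st <- stat_features(c(1, 2, 3, 4, 5), run_mean = 0, run_sd = 1)
  expect_equal(st$mean, 3)
  expect_equal(st$sd, 1.5811388, tolerance = 1e-6)
  expect_equal(st$skewness, 0)
  expect_equal(st$mean_norm, 3)

  z <- draw_normal(1000, 21)
  z <- (z - mean(z)) / sd(z)
  expect_lt(abs(stat_features(z, 0, 1)$mean_norm), 0.2)
  expect_lt(abs(stat_features(z)$kurtosis - 3), 0.5)
  expect_true(is.na(stat_features(rep(1, 10))$skewness))
})

test_that("Hjorth parameters match the sinusoid closed form and the oracle", {
  fs <- 1000
  t <- (0:(fs - 1)) / fs
  x <- 2 * sin(2 * pi * 10 * t)
  h <- hjorth(x, fs)
  expect_equal(h$activity, 2, tolerance = 0.02)
  expect_equal(h$mobility, 2 * pi * 10, tolerance = 0.02)

  for (i in 1:20) {
    w <- draw_normal(500, 100 + i)
    got <- hjorth(w, 250)
    ref <- hjorth_oracle(w, 250)
    expect_equal(got$activity, ref$activity, tolerance = 1e-9)
    expect_equal(got$mobility, ref$mobility, tolerance = 1e-9)
    expect_equal(got$complexity, ref$complexity, tolerance = 1e-9)
    expect_gt(got$complexity, 1)  # white noise
  }
  hc <- hjorth(rep(2, 100), 100)
  expect_equal(hc$activity, 0)
  expect_true(is.na(hc$mobility) && is.na(hc$complexity))
})

test_that("Welch PSD localizes tones and preserves variance", {
  fs <- 1000
  x <- sin(2 * pi * 10 * (0:(fs - 1)) / fs)
  p <- psd_welch(x, fs)
  expect_equal(p$freq[which.max(p$psd)], 10)
  expect_equal(p$freq[2] - p$freq[1], 2)

  wn <- draw_normal(fs, 31)
  pw <- psd_welch(wn, fs)
  expect_equal(sum(pw$psd) * 2, var(wn), tolerance = 0.05)  # Parseval
  # flatness: band-averaged levels within a factor 3 over 2-45 Hz
  lev <- vapply(seq(2, 42, by = 8), function(lo) {
    mean(pw$psd[pw$freq >= lo & pw$freq < lo + 8])
  }, numeric(1))
  expect_lt(max(lev) / min(lev), 3)
})

test_that("band powers partition total power; ratios and indexes follow", {
  p <- psd_welch(draw_normal(500, 41), 500)
  bp <- band_powers(p)
  expect_equal(sum(bp$abs), bp$total)
  expect_equal(sum(bp$rel), 1, tolerance = 1e-9)

  eq <- setNames(rep(2, 5), c("delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(unname(band_ratios(eq)), rep(1, 10))
  expect_length(band_ratios(eq), 10)
  th <- eq; th[["theta"]] <- 4; th[["alpha"]] <- 2
  expect_equal(band_ratios(th)[["ratio_theta_alpha"]], 2)
  expect_true(is.na(band_ratios(c(delta = 1, theta = 1, alpha = 1,
                                  beta = 1, gamma = 0))[["ratio_beta_gamma"]]))

  en <- engagement(eq)
  expect_equal(en$beta_over_theta_alpha, 0.5)
  expect_equal(en$theta_over_alpha_beta, 0.5)
  expect_equal(engagement(c(delta = 0, theta = 1, alpha = 1, beta = 4,
                            gamma = 0))$beta_over_theta_alpha, 2)
})

test_that("spectral descriptors recover tone mixtures and flat spectra", {
  fs <- 1000
  tt <- (0:(fs - 1)) / fs
  tone <- sin(2 * pi * 10 * tt)
  sp <- spectral_descriptors(psd_welch(tone, fs))
  expect_equal(sp$alpha_peak_freq, 10)
  expect_equal(sp$mean_freq, 10, tolerance = 0.05)

  two <- sin(2 * pi * 6 * tt) + sin(2 * pi * 14 * tt)
  expect_equal(spectral_descriptors(psd_welch(two, fs))$mean_freq, 10,
               tolerance = 0.3)

  # flat-spectrum centroid ~ 22 on the 0-44 Hz grid (averaged over windows)
  cents <- vapply(1:50, function(i) {
    spectral_descriptors(psd_welch(draw_normal(fs, 200 + i), fs))$mean_freq
  }, numeric(1))
  expect_equal(mean(cents), 22.5, tolerance = 2)
})

test_that("Higuchi FD hits known limits and matches the brute-force oracle", {
  expect_equal(higuchi_fd(seq(0, 1, length.out = 1000)), 1, tolerance = 0.05)
  fds <- vapply(1:5, function(i) higuchi_fd(draw_normal(1000, 300 + i), 10),
                numeric(1))
  expect_true(all(abs(fds - 2) < 0.1))

  for (i in 1:20) {
    w <- draw_normal(400, 400 + i)
    expect_equal(higuchi_fd(w, 8), higuchi_oracle(w, 8), tolerance = 1e-6)
  }

  # FD decreases with increasing AR(1) smoothness
  ar1 <- function(phi, n, seed) {
    e <- draw_normal(n, seed)
    x <- numeric(n)
    for (t in 2:n) x[t] <- phi * x[t - 1] + e[t]
    x
  }
  fd_by_phi <- vapply(c(0.95, 0.6, 0), function(phi)
    mean(vapply(1:3, function(i) higuchi_fd(ar1(phi, 1000, 500 + i), 10),
                numeric(1))), numeric(1))
  expect_true(all(diff(fd_by_phi) > 0))
})

test_that("Hurst R/S hits known limits, is affine invariant, matches oracle", {
  # plain R/S carries a known small-sample upward bias (~+0.06 at n=1000)
  hs <- vapply(1:20, function(i) hurst_rs(draw_normal(1000, 600 + i)),
               numeric(1))
  expect_lt(abs(mean(hs) - 0.5), 0.08)
  expect_true(all(hs > 0.35 & hs < 0.7))
  expect_gt(hurst_rs(cumsum(draw_normal(1000, 611))), 0.85)

  w <- draw_normal(512, 620)
  expect_equal(hurst_rs(w), hurst_rs(3.7 * w - 11), tolerance = 1e-9)
  for (i in 1:20) {
    x <- draw_normal(512, 630 + i)
    expect_equal(hurst_rs(x), hurst_oracle(x), tolerance = 1e-6)
  }
})

test_that("extract_all fills the full bank deterministically on both engines", {
  ds <- tiny_dataset(seed = 3)
  eeg <- ds$eeg[[1]]
  fm <- extract_all(eeg)
  dur <- attr(ds$timelines[[1]], "total_duration_s")
  expect_equal(dim(fm$values), c(35 * 4, dur))
  expect_identical(fm$values, extract_all(eeg)$values)

  fmr <- extract_all(eeg, engine = "R")
  expect_equal(fm$values, fmr$values, tolerance = 1e-9)
  expect_identical(fm$missing_mask, fmr$missing_mask)

  # rejected epochs flag whole columns
  fm2 <- extract_all(eeg, rejected_epochs = c(2, 5))
  expect_true(all(is.na(fm2$values[, c(2, 5)])))
  expect_true(all(fm2$missing_mask[, c(2, 5)]))
  expect_identical(fm2$values[, -c(2, 5)], fm$values[, -c(2, 5)])
})

test_that("missing-value interpolation is linear with nearest-edge fill", {
  inv <- build_inventory("Cz")[1:2, ]
  v <- rbind(c(1, NA, 3, 4), c(NA, 2, 4, NA))
  fm <- feature_matrix(v, inv, missing_mask = is.na(v))
  out <- interp_missing(fm)
  expect_equal(unname(out$values[1, ]), c(1, 2, 3, 4))
  expect_equal(unname(out$values[2, ]), c(2, 2, 4, 4))
  expect_true(all(out$missing_mask == is.na(v)))  # provenance retained

  # identity on complete data
  v2 <- matrix(rnorm2 <- draw_normal(8, 1), 2)
  fm2 <- feature_matrix(v2, inv)
  expect_identical(interp_missing(fm2)$values, fm2$values)

  bad <- feature_matrix(rbind(c(1, NA, NA), c(1, 2, 3)),
                        inv, missing_mask = NULL)
  bad$values[1, 2:3] <- NA
  expect_error(interp_missing(bad), "mean\\|Cz\\|none")
})

test_that("outlier repair only fires above the cross-bank fraction", {
  inv <- build_inventory(c("F3", "F4", "C3", "C4"))  # 140 descriptors
  nt <- 40
  v <- matrix(draw_normal(nrow(inv) * nt, 2), nrow(inv), nt)
  # a wild value in a single descriptor: below threshold, unchanged
  v1 <- v; v1[7, 20] <- 1000
  fm1 <- interp_outliers(feature_matrix(v1, inv))
  expect_identical(unname(fm1$values), v1)
  expect_true(fm1$outlier_mask[7, 20])

  # a time point wild in 30% of descriptors: whole column repaired
  v2 <- v
  hit <- seq_len(ceiling(0.3 * nrow(v)))
  v2[hit, 20] <- 1000
  fm2 <- interp_outliers(feature_matrix(v2, inv))
  expect_equal(unname(fm2$values[1, 20]), (v2[1, 19] + v2[1, 21]) / 2)
  expect_false(any(fm2$values[, 20] == 1000))

  # a disabled run (threshold 1) equals threshold 0 when nothing exceeds
  fm3a <- interp_outliers(feature_matrix(v, inv), fraction_threshold = 1)
  expect_identical(unname(fm3a$values), v)
})

test_that("second-order transform aggregates non-overlapping triples", {
  inv <- build_inventory("Cz")[1, , drop = FALSE]
  fm <- feature_matrix(matrix(c(1, 2, 3, 4, 5, 6, 7), 1), inv)
  so <- second_order(fm)
  expect_equal(so$dt_s, 3)
  expect_equal(dim(so$values), c(3, 2))  # remainder dropped
  expect_equal(unname(so$values[, 1]), c(2, 3, 1))  # mean3, max3, min3
  expect_equal(unname(so$values[, 2]), c(5, 6, 4))
  expect_equal(so$descriptors$transform, c("mean3", "max3", "min3"))

  ds <- tiny_dataset(seed = 5)
  f1 <- extract_all(ds$eeg[[1]])
  f1 <- interp_missing(f1)
  so1 <- second_order(f1)
  expect_equal(nrow(so1$values), 3 * nrow(f1$values))
  n <- nrow(f1$values)
  expect_true(all(so1$values[(2 * n + 1):(3 * n), ] <=
                    so1$values[1:n, ] + 1e-12))
  expect_true(all(so1$values[1:n, ] <=
                    so1$values[(n + 1):(2 * n), ] + 1e-12))
  expect_error(second_order(feature_matrix(matrix(1:2, 1), inv)), "at least 3")
})
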