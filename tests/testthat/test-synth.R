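test_that("generated EEG has the contracted shape and is deterministic", {
  lat <- rep(0.5, 12)
  e1 <- make_eeg(lat, montage = default_montage()[1:6], fs = 250,
                 responsive_channels = "Fp1", seed = 3)
  expect_equal(dim(e1$data), c(12 * 250, 6))
  e2 <- make_eeg(lat, montage = default_montage()[1:6], fs = 250,
                 responsive_channels = "Fp1", seed = 3)
  expect_identical(e1$data, e2$data)
  e3 <- make_eeg(lat, montage = default_montage()[1:6], fs = 250,
                 responsive_channels = "Fp1", seed = 4)
  expect_false(identical(e1$data, e3$data))
  expect_error(make_eeg(lat, montage = c("F3", "F4"),
                        responsive_channels = "XX"), "unknown montage")
})

test_that("generated EEG is spectrally contained in 1-45 Hz", {
  e <- make_eeg(rep(0, 30), montage = c("Cz"), fs = 1000,
                responsive_channels = "Cz", gain = 0, seed = 1)
  x <- e$data[, 1]
  spec <- Mod(fft(x))^2
  n <- length(x)
  freq <- (seq_len(n) - 1) / n * 1000
  half <- freq <= 500
  inband <- half & freq >= 1 & freq <= 45
  expect_lt(sum(spec[half & !inband]) / sum(spec[half]), 0.01)
})

test_that("zero gain leaves responsive channels indistinguishable", {
  # two-sample test on 1-second band powers, responsive vs not
  lat <- make_latent_load(make_timeline(seed = 1), seed = 1)[1:300]
  e <- make_eeg(lat, montage = c("F3", "F4"), fs = 200,
                responsive_channels = "F4", responsive_band = "theta",
                gain = 0, seed = 6)
  bp <- function(ch) {
    m <- matrix(e$data[, ch], nrow = 200)
    apply(m, 2, function(w) band_powers(psd_welch(w, 200))$abs[["theta"]])
  }
  expect_gt(t.test(bp(1), bp(2))$p.value, 0.01)
})

test_that("theta power of a responsive channel tracks the latent load", {
  tl <- make_timeline(seed = 2)
  lat <- make_latent_load(tl, seed = 2)
  e <- make_eeg(lat, montage = c("C3", "C4"), fs = 250,
                responsive_channels = "C4", responsive_band = "theta",
                gain = 1, seed = 7)
  theta <- function(ch) {
    m <- matrix(e$data[, ch], nrow = 250)
    apply(m, 2, function(w) band_powers(psd_welch(w, 250))$abs[["theta"]])
  }
  expect_gt(cor(theta(2), lat), 0.5)      # responsive
  expect_lt(abs(cor(theta(1), lat)), 0.2) # non-responsive
})

test_that("noiseless BOLD equals the delay-matched convolved latent", {
  tl <- make_timeline(tiny_run_spec, seed = 1)
  lat <- make_latent_load(tl, seed = 1)
  voi <- make_voi(c(6, 6, 4), n_voi = 8, seed = 1)
  b <- make_bold(lat, c(6, 6, 4), voi, true_delay_s = 6, snr = 1e9,
                 seed = 1)
  expect_equal(dim(b$data)[4], ceiling(length(lat) / 3))
  h <- canonical_hrf(6, dt_s = 1)
  sig <- convolve_align(lat, h)
  idx <- pmin(3 * (seq_len(dim(b$data)[4]) - 1) + 2, length(lat))
  ref <- standardize(sig[idx])
  vox <- which(voi$mask, arr.ind = TRUE)[1, ]
  series <- b$data[vox[1], vox[2], vox[3], ]
  expect_gt(cor(series, ref), 1 - 1e-9)
  expect_error(make_bold(lat, c(6, 6, 4), voi, snr = 0), "snr")
})

test_that("non-VOI voxels are null at the nominal 5% level", {
  tl <- make_timeline(seed = 4)
  lat <- make_latent_load(tl, seed = 4)
  grid <- c(16, 16, 8)
  voi <- make_voi(grid, n_voi = 64, seed = 4)
  b <- make_bold(lat, grid, voi, true_delay_s = 5, snr = 2, seed = 4)
  h <- canonical_hrf(5, dt_s = 1)
  idx <- pmin(3 * (seq_len(dim(b$data)[4]) - 1) + 2, length(lat))
  reg <- standardize(convolve_align(lat, h)[idx])
  out <- which(!voi$mask)[1:1000]
  Tn <- dim(b$data)[4]
  Z <- matrix(b$data, prod(grid), Tn)
  r <- as.numeric(cor(reg, t(Z[out, ])))
  tcrit <- qt(0.975, Tn - 2)
  rcrit <- tcrit / sqrt(Tn - 2 + tcrit^2)
  hits <- sum(abs(r) > rcrit)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.05)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})

test_that("toy masks realize the requested overlap by construction", {
  tm <- make_toy_masks(c(6, 6, 4), n_voi = 10, n_overlap = 5, n_extra = 3,
                       seed = 1)
  expect_equal(sum(tm$voi$mask), 10)
  expect_equal(overlap_portion(tm$sig, tm$voi), 0.5)
  tm0 <- make_toy_masks(c(6, 6, 4), 10, 0, 4, seed = 2)
  expect_equal(overlap_portion(tm0$sig, tm0$voi), 0)
  tm1 <- make_toy_masks(c(6, 6, 4), 10, 10, 7, seed = 3)
  expect_equal(overlap_portion(tm1$sig, tm1$voi), 1)
  expect_error(make_toy_masks(c(2, 2, 2), 10, 5, 3, seed = 1), "capacity")
  expect_error(make_toy_masks(c(6, 6, 4), 4, 5, 0, seed = 1), "n_overlap")
})

test_that("datasets are reproducible from their seed", {
  d1 <- tiny_dataset(seed = 11)
  d2 <- tiny_dataset(seed = 11)
  expect_identical(d1$eeg[[1]]$data, d2$eeg[[1]]$data)
  expect_identical(d1$bold[[1]]$data, d2$bold[[1]]$data)
  expect_identical(d1$truth, d2$truth)
  expect_true(d1$truth$true_delay_s %in% c(4, 5, 6, 7))
})
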