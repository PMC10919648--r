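# Subject- and cohort-level analysis objects on miniature datasets.

fit_small <- local({
  ds <- tiny_dataset(seed = 42, runs = 2, snr = 5)
  list(ds = ds, fit = eegfmri_similarity(ds))
})

test_that("the fit object carries consistent statistics and methods work", {
  fit <- fit_small$fit
  expect_s3_class(fit, "eegfmri_sim")
  expect_equal(nrow(fit$stats), 3 * 35 * 4)
  expect_true(all(fit$stats$best_delay %in% c(4, 5, 6, 7)))
  expect_true(all(fit$stats$mean_abs_r >= 0 & fit$stats$mean_abs_r <= 1))
  expect_true(all(fit$stats$overlap_d >= 0 & fit$stats$overlap_d <= 1))
  # zero significant VOI voxels forces zero scores (empty-set rule)
  zero <- fit$stats$n_sig_in_voi == 0
  expect_true(all(fit$stats$mean_abs_r[zero] == 0))
  expect_true(all(fit$stats$max_abs_r[zero] == 0))

  expect_output(print(fit), "similarity fit")
  expect_output(summary(fit), "Occurrence")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("the bulk scan agrees with the single-feature delay optimizer", {
  fit <- fit_small$fit
  ds <- fit_small$ds
  fms <- lapply(ds$eeg, function(e)
    second_order(interp_missing(extract_all(e))))
  for (idx in c(1, 57, 140)) {
    rows <- lapply(fms, function(f) f$values[idx, ])
    od <- optimize_delay(rows, ds$bold, ds$voi)
    expect_equal(od$best_delay, fit$stats$best_delay[idx])
    sc <- vapply(1:4, function(di) mean(fit$scan[idx, di, , "mean_abs_r"]),
                 numeric(1))
    expect_equal(od$per_delay$mean_abs_r, sc, tolerance = 1e-9)
  }
})

test_that("the high-resolution convolution path mirrors the default bank", {
  ds <- fit_small$ds
  fit_hr <- eegfmri_similarity(ds, hrf_highres = TRUE)
  fit <- fit_small$fit
  expect_identical(fit_hr$stats$id, fit$stats$id)
  expect_true(all(fit_hr$stats$mean_abs_r >= 0 & fit_hr$stats$mean_abs_r <= 1))
  expect_true(all(fit_hr$stats$best_delay %in% c(4, 5, 6, 7)))
  # both paths agree on where the signal is: top channels overlap
  top_ch <- function(f) unique(as.data.frame(f$ranking)$channel[1:5])
  expect_true(length(intersect(top_ch(fit_hr), top_ch(fit))) >= 1)
})

test_that("two identical subjects give a group ranking equal to the individual", {
  fit <- fit_small$fit
  gr <- group_rank(list(fit, fit), cap = 100)
  expect_equal(gr$id, fit$ranking$id)
  expect_equal(gr$mean_abs_r, fit$ranking$mean_abs_r, tolerance = 1e-12)
  expect_error(group_rank(list(fit)), "at least 2")

  fit2 <- fit
  fit2$stats <- fit2$stats[-1, ]
  expect_error(group_rank(list(fit, fit2)), "different descriptor sets")
})

test_that("literature feature evaluation resolves pairs through the fits", {
  fit <- fit_small$fit
  feats <- data.frame(channel = c("AF3", "Fp2"),
                      feature = c("Theta / (Alpha + Beta)", "Theta/Gamma"),
                      stringsAsFactors = FALSE)
  out <- evaluate_literature_features(feats, list(fit, fit))
  expect_equal(nrow(out), 2)
  expect_equal(out$descriptor,
               c("theta_over_alpha_beta", "ratio_theta_gamma"))
  expect_true(all(out$mean_r >= 0 & out$mean_r <= 1))
  expect_true(all(out$max_r >= out$mean_r - 1e-12))

  bad <- data.frame(channel = "C3", feature = "Alpha")  # not in tiny montage
  expect_error(evaluate_literature_features(bad, list(fit)), "not found")
})

test_that("recovery_check demands ground truth and scores group rankings", {
  fit <- fit_small$fit
  rc <- recovery_check(fit)
  expect_true(rc$best_rank >= 1)
  expect_true(rc$recovered_delay %in% c(4, 5, 6, 7))
  fit_no_truth <- fit
  fit_no_truth$truth <- NULL
  expect_error(recovery_check(fit_no_truth), "ground truth")

  gr <- group_rank(list(fit, fit))
  grc <- recovery_check(fit, ranking = gr)
  expect_true(is.na(grc$recovered_delay))
  expect_true(grc$best_rank >= 1)
})
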