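make_bold_from <- function(Z, grid, tr = 3) {
  bold_volume(array(t(Z), c(grid, nrow(Z))), tr_s = tr)
}

test_that("pearson_map matches self-correlation limits and a direct oracle", {
  Tn <- 30
  reg <- standardize(draw_normal(Tn, 1))
  grid <- c(3, 2, 2)
  Z <- matrix(draw_normal(Tn * 12, 2), Tn, 12)
  Z[, 1] <- reg
  Z[, 2] <- -reg
  b <- make_bold_from(Z, grid)
  mp <- pearson_map(reg, b)
  expect_equal(as.vector(mp$r)[1], 1, tolerance = 1e-12)
  expect_equal(as.vector(mp$r)[2], -1, tolerance = 1e-12)
  expect_lt(mp$p[1], 1e-12)

  # direct covariance/SD oracle on seeded pairs
  for (i in 1:20) {
    x <- draw_normal(25, 10 + i)
    y <- draw_normal(25, 40 + i)
    b1 <- make_bold_from(cbind(y), c(1, 1, 1))
    r <- as.vector(pearson_map(x, b1)$r)
    oracle <- mean((x - mean(x)) * (y - mean(y))) /
      (sd(x) * sd(y)) * length(x) / (length(x) - 1)
    expect_equal(r, oracle, tolerance = 1e-12)
  }

  # constant voxel convention
  Zc <- Z; Zc[, 3] <- 5
  mpc <- pearson_map(reg, make_bold_from(Zc, grid))
  expect_equal(as.vector(mpc$r)[3], 0)
  expect_equal(as.vector(mpc$p)[3], 1)
  expect_error(pearson_map(reg[-1], b), "does not match")
})

test_that("BH step-up matches hand computation and the exhaustive oracle", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.5, 0.9), 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(fdr_bh(rep(1, 20))))
  for (i in 1:50) {
    p <- draw_unif(30 + (i %% 5), 100 + i)
    expect_identical(fdr_bh(p, 0.05), bh_oracle(p, 0.05))
    expect_identical(fdr_bh(p, 0.2), bh_oracle(p, 0.2))
  }
  expect_error(fdr_bh(numeric(0)), "empty")
})

test_that("the bulk scan agrees exactly with the per-map reference path", {
  Tn <- 24
  grid <- c(4, 3, 2)
  nv <- prod(grid)
  for (i in 1:10) {
    Z <- matrix(draw_normal(Tn * nv, 300 + i), Tn, nv)
    F1 <- matrix(draw_normal(Tn * 7, 400 + i), Tn, 7)
    F1 <- scale(F1)
    voi <- array(FALSE, grid); voi[draw_unif(nv, i) < 0.3] <- TRUE
    if (!any(voi)) voi[1] <- TRUE
    vm <- voi_mask(voi)
    Zs <- cogsim:::.bold_matrix(make_bold_from(Z, grid))
    st <- cogsim:::.simil_scan_cpp(F1, Zs, which(as.vector(voi)) - 1L, 0.05)
    for (f in 1:7) {
      mp <- pearson_map(F1[, f], make_bold_from(Z, grid))
      sig <- fdr_bh(mp$p, 0.05)
      vs <- voi_stats(list(r = mp$r, p = mp$p, sig = sig), vm)
      expect_equal(st[f, 1], vs$n_sig_total)
      expect_equal(st[f, 2], vs$n_sig_in_voi)
      expect_equal(st[f, 3], vs$mean_abs_r, tolerance = 1e-9)
      expect_equal(st[f, 4], vs$max_abs_r, tolerance = 1e-9)
      expect_equal(st[f, 5], vs$overlap_d, tolerance = 1e-9)
    }
  }
})

test_that("overlap portion counts VOI coverage", {
  tm <- make_toy_masks(c(5, 5, 4), n_voi = 10, n_overlap = 5, n_extra = 7,
                       seed = 2)
  expect_equal(overlap_portion(tm$sig, tm$voi), 0.5)
  expect_equal(overlap_portion(tm$voi$mask, tm$voi), 1)
  expect_equal(overlap_portion(array(FALSE, c(5, 5, 4)), tm$voi), 0)
  expect_error(overlap_portion(array(FALSE, c(2, 2, 2)), tm$voi), "shapes")
})

test_that("voi_stats uses absolute r over significant VOI voxels only", {
  grid <- c(2, 2, 1)
  voi <- voi_mask(array(c(TRUE, TRUE, FALSE, FALSE), grid))
  r <- array(c(-0.6, 0.2, 0.9, 0), grid)
  sig <- array(c(TRUE, FALSE, TRUE, FALSE), grid)
  vs <- voi_stats(list(r = r, sig = sig), voi)
  expect_equal(vs$mean_abs_r, 0.6)
  expect_equal(vs$max_abs_r, 0.6)
  expect_equal(vs$n_sig_in_voi, 1)
  expect_equal(vs$overlap_d, 0.5)

  vs0 <- voi_stats(list(r = r, sig = array(FALSE, grid)), voi)
  expect_equal(vs0$mean_abs_r, 0)
  expect_equal(vs0$max_abs_r, 0)
  expect_equal(vs0$overlap_d, 0)

  sig2 <- array(c(TRUE, TRUE, FALSE, FALSE), grid)
  r2 <- array(c(0.2, 0.8, 0, 0), grid)
  vs2 <- voi_stats(list(r = r2, sig = sig2), voi)
  expect_equal(vs2$mean_abs_r, 0.5)
  expect_equal(vs2$max_abs_r, 0.8)
})

test_that("optimize_delay recovers the planted delay and ties to 4", {
  ds <- tiny_dataset(seed = 21, runs = 2, true_delay_s = 6, snr = 1e6)
  lat3 <- lapply(ds$truth$latent_load, function(l) {
    nt <- length(l) %/% 3
    colMeans(matrix(l[1:(3 * nt)], 3))
  })
  od <- optimize_delay(lat3, ds$bold, ds$voi)
  expect_equal(od$best_delay, 6)
  expect_equal(od$per_delay$delay_s, c(4, 5, 6, 7))

  # pure-noise BOLD: all delay scores ~0, tie broken toward 4
  noise <- bold_volume(array(draw_normal(6 * 6 * 4 * 15, 5), c(6, 6, 4, 15)))
  odn <- optimize_delay(list(draw_normal(15, 6)), list(noise),
                        make_voi(c(6, 6, 4), 8, seed = 1))
  expect_equal(odn$best_delay, 4)
  expect_true(all(odn$per_delay$mean_abs_r < 0.2))
})

test_that("elbow cutoff matches a direct scan and its degenerate limits", {
  elbow_oracle <- function(s, w, eps) {
    d <- -diff(s)
    for (k in seq_len(length(d) - w + 1))
      if (all(d[k:(k + w - 1)] < eps)) return(k)
    length(s)
  }
  s1 <- 1 / (1:200)
  expect_equal(elbow_cutoff(s1, w = 10, eps = 0.002),
               elbow_oracle(s1, 10, 0.002))
  for (i in 1:10) {
    s <- sort(draw_unif(60, 700 + i), decreasing = TRUE)
    expect_equal(elbow_cutoff(s, w = 5, eps = 0.01),
                 elbow_oracle(s, 5, 0.01))
  }
  expect_equal(elbow_cutoff(rep(0.5, 50)), 1)
  expect_equal(elbow_cutoff(seq(100, 1, by = -1)), 100)
})

test_that("ranking sorts by score with deterministic tie-breaking and caps", {
  st <- data.frame(id = c("b", "a", "d", "c"),
                   mean_abs_r = c(0.5, 0.9, 0.5, 0.48),
                   max_abs_r = c(0.7, 0.9, 0.6, 0.6),
                   stringsAsFactors = FALSE)
  rk <- rank_features(st, cap = 100)
  expect_equal(rk$id, c("a", "b", "d", "c"))  # score, then max, then id
  expect_true(all(diff(rk$mean_abs_r) <= 0))

  st2 <- data.frame(id = sprintf("f%03d", 1:300),
                    mean_abs_r = c(seq(0.9, 0.5, length.out = 150),
                                   rep(0.5, 150)),
                    max_abs_r = 0.9, stringsAsFactors = FALSE)
  rk2 <- rank_features(st2, cap = 100)
  expect_equal(attr(rk2, "cutoff_index"), 100)  # cap dominates the elbow

  st3 <- data.frame(id = c("x", "y"), mean_abs_r = c(0.4, 0.4),
                    max_abs_r = c(0.4, 0.4), stringsAsFactors = FALSE)
  expect_equal(rank_features(st3)$id, c("x", "y"))
  expect_error(rank_features(st3[0, ]), "empty")
})

test_that("occurrence summaries are percentage histograms by construction", {
  st <- data.frame(id = 1:4, feature = c("abs_theta", "sd", "sd", "mean"),
                   channel = c("C4", "C4", "C4", "C4"),
                   best_delay = c(4, 4, 7, 7),
                   mean_abs_r = c(0.9, 0.8, 0.7, 0.6), max_abs_r = 0.9,
                   stringsAsFactors = FALSE)
  rk <- rank_features(st, cap = 4, w = 2, eps = 1e-9)
  occ <- occurrence_summary(rk)
  expect_equal(unname(occ$by_region[["Central"]]), 100)
  expect_equal(sum(occ$by_feature_type), 100, tolerance = 1e-9)
  expect_equal(unname(occ$by_delay[c("4", "7")]), c(50, 50))

  st$channel <- c("F4", "P4", "F4", "P4")
  rk2 <- rank_features(st, cap = 4, w = 2, eps = 1e-9)
  occ2 <- occurrence_summary(rk2)
  expect_equal(unname(occ2$by_region[c("Frontal", "Parietal")]), c(50, 50))

  st$channel <- "QQ9"
  expect_error(occurrence_summary(rank_features(st, cap = 4, w = 2,
                                                eps = 1e-9)), "QQ9")
})

test_that("region table follows 10-10 prefixes", {
  expect_equal(channel_region(c("Fp1", "AF3", "F4", "FC4", "C4", "CP1",
                                "FT7", "T8", "TP8", "P3", "PO7", "O1",
                                "Fz", "Cz", "Pz", "Oz")),
               c("Frontal", "Frontal", "Frontal", "Central", "Central",
                 "Central", "Temporal", "Temporal", "Temporal", "Parietal",
                 "Parietal", "Occipital", "Frontal", "Central", "Parietal",
                 "Occipital"))
  expect_error(channel_region("X1"), "X1")
})

test_that("literature feature names resolve to inventory descriptors", {
  expect_equal(cogsim:::resolve_feature_name("Theta / (Alpha + Beta)"),
               "theta_over_alpha_beta")
  expect_equal(cogsim:::resolve_feature_name("Theta/Gamma"),
               "ratio_theta_gamma")
  expect_equal(cogsim:::resolve_feature_name("Theta / Beta"),
               "ratio_theta_beta")
  expect_equal(cogsim:::resolve_feature_name("Alpha"), "rel_alpha")
  expect_equal(cogsim:::resolve_feature_name("Activity"), "hjorth_activity")
  expect_error(cogsim:::resolve_feature_name("Banana Index"), "resolve")
})
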