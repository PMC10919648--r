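# Voxelwise EEG-feature / BOLD similarity.

#' Voxelwise Pearson correlation map
#'
#' Correlates one (convolved, standardized) feature regressor with every
#' voxel time series. Two-sided p-values come from the exact t transform
#' with `T - 2` degrees of freedom; constant voxels get r = 0 and p = 1.
#'
#' @param regressor numeric series on the TR grid, length `T`.
#' @param bold a [bold_volume()].
#' @return list with 3D arrays `r` and `p` on the BOLD grid.
#' @export
pearson_map <- function(regressor, bold) {
  d <- dim(bold$data)
  T_ <- d[4]
  if (length(regressor) != T_)
    stop("regressor length ", length(regressor),
         " does not match number of volumes ", T_)
  if (T_ < 4) stop("need at least 4 volumes")
  Z <- matrix(bold$data, prod(d[1:3]), T_)
  r <- as.numeric(.pearson_cols_cpp(as.numeric(regressor), t(Z)))
  tt <- r * sqrt((T_ - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = T_ - 2)
  p[r == 0] <- 1
  list(r = array(r, d[1:3]), p = array(p, d[1:3]))
}

#' Benjamini-Hochberg significance mask
#'
#' Step-up FDR control over all p-values of one map: reject the `k`
#' smallest with `p_(k) <= k * alpha / m` for the largest such `k`.
#'
#' @param p numeric vector or array of p-values.
#' @param alpha FDR level.
#' @return logical significance mask, same shape as `p`.
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (!length(p)) stop("empty p-value input")
  sig <- stats::p.adjust(as.vector(p), method = "BH") <= alpha
  if (!is.null(dim(p))) sig <- array(sig, dim(p))
  sig
}

#' Overlap portion of a significance map with the VOI
#'
#' The fraction of VOI voxels that are also significant:
#' `d = |sig & voi| / |voi|`.
#'
#' @param sig logical significance mask.
#' @param voi a [voi_mask()] (or logical array).
#' @return overlap portion in `[0, 1]`.
#' @export
overlap_portion <- function(sig, voi) {
  m <- if (inherits(voi, "voi_mask")) voi$mask else voi
  if (!all(dim(sig) == dim(m))) stop("mask shapes do not match")
  nv <- sum(m)
  if (nv == 0) stop("empty VOI")
  sum(sig & m) / nv
}

#' Correlation-map statistics over the VOI
#'
#' Computes the mean and maximum absolute correlation over voxels that are
#' both FDR-significant and inside the VOI, plus the overlap portion. When
#' no significant voxel falls inside the VOI all statistics are zero.
#'
#' @param map list with arrays `r` and `p` (see [pearson_map()]), or with a
#'   precomputed logical `sig`.
#' @param voi a [voi_mask()].
#' @param alpha FDR level used if `sig` is absent.
#' @return list: `n_sig_in_voi`, `mean_abs_r`, `max_abs_r`, `overlap_d`,
#'   `n_sig_total`.
#' @export
voi_stats <- function(map, voi, alpha = 0.05) {
  sig <- map$sig
  if (is.null(sig)) sig <- fdr_bh(map$p, alpha)
  if (!all(dim(sig) == dim(voi$mask))) stop("map and VOI grids differ")
  inside <- sig & voi$mask
  n <- sum(inside)
  list(n_sig_in_voi = n,
       mean_abs_r = if (n > 0) mean(abs(map$r[inside])) else 0,
       max_abs_r = if (n > 0) max(abs(map$r[inside])) else 0,
       overlap_d = overlap_portion(sig, voi),
       n_sig_total = sum(sig))
}

# ---- bulk scan -----------------------------------------------------------

# Standardized TR-grid regressors for every descriptor at one delay.
# fm3: feature_matrix at dt 3. Returns list(values = T x nF, ok).
.regressors_for_delay <- function(fm3, delay_s, span_s = 32,
                                  undershoot_lag = 10,
                                  undershoot_ratio = 1 / 6) {
  h <- canonical_hrf(delay_s, dt_s = fm3$dt_s, span_s = span_s,
                     undershoot_lag = undershoot_lag,
                     undershoot_ratio = undershoot_ratio)
  .prep_regressors_cpp(t(fm3$values), h$weights)
}

# High-resolution alternative: convolve the 1-second features with the HRF
# sampled at 1 s, then apply the second-order (mean/max/min of triples)
# aggregation to the convolved series. Descriptor order matches the
# default path (mean3 block, then max3, then min3).
.regressors_for_delay_hr <- function(fm1, delay_s, span_s = 32,
                                     undershoot_lag = 10,
                                     undershoot_ratio = 1 / 6) {
  h <- canonical_hrf(delay_s, dt_s = 1, span_s = span_s,
                     undershoot_lag = undershoot_lag,
                     undershoot_ratio = undershoot_ratio)
  st <- standardize_rows(fm1$values)
  conv <- convolve_rows(st$values, h)
  nt <- ncol(conv) %/% 3
  i1 <- 3 * seq_len(nt) - 2
  v1 <- conv[, i1, drop = FALSE]
  v2 <- conv[, i1 + 1, drop = FALSE]
  v3 <- conv[, i1 + 2, drop = FALSE]
  vals <- rbind((v1 + v2 + v3) / 3, pmax(v1, v2, v3), pmin(v1, v2, v3))
  st2 <- standardize_rows(vals)
  list(values = t(st2$values), ok = rep(st$ok, 3) & st2$ok)
}

# standardized voxel matrix (T x V); constant voxels become zero columns
.bold_matrix <- function(bold) {
  d <- dim(bold$data)
  Z <- t(matrix(bold$data, prod(d[1:3]), d[4]))
  mu <- colMeans(Z)
  Z <- Z - rep(mu, each = nrow(Z))
  s <- sqrt(colSums(Z^2) / (nrow(Z) - 1))
  ok <- is.finite(s) & s > 0
  Z[, ok] <- Z[, ok, drop = FALSE] / rep(s[ok], each = nrow(Z))
  Z[, !ok] <- 0
  Z
}

# Per-(descriptor, delay, run) VOI statistics for one subject.
# fms: list of dt-3 feature matrices (one per run, same descriptor order)
# bolds: list of bold_volume; voi: voi_mask
# Returns array [nF, ndelay, nrun, 4] with slices n_sig_in_voi, mean_abs_r,
# max_abs_r, overlap_d.
similarity_scan <- function(fms, bolds, voi, delays = c(4, 5, 6, 7),
                            alpha = 0.05, hrf_args = list(),
                            fms_1s = NULL) {
  stopifnot(length(fms) == length(bolds))
  nrun <- length(fms)
  nF <- if (is.null(fms_1s)) nrow(fms[[1]]$values)
        else 3 * nrow(fms_1s[[1]]$values)
  voi_idx <- which(as.vector(voi$mask)) - 1L
  out <- array(0, c(nF, length(delays), nrun, 4),
               dimnames = list(NULL, paste0("d", delays), NULL,
                               c("n_sig_in_voi", "mean_abs_r",
                                 "max_abs_r", "overlap_d")))
  for (r in seq_len(nrun)) {
    Treg <- if (is.null(fms_1s)) ncol(fms[[r]]$values)
            else ncol(fms_1s[[r]]$values) %/% 3
    b <- bolds[[r]]
    if (dim(b$data)[4] < Treg)
      stop("run ", r, ": fewer BOLD volumes (", dim(b$data)[4],
           ") than feature samples (", Treg, ")")
    if (dim(b$data)[4] > Treg)   # trailing volume beyond the feature grid
      b$data <- b$data[, , , seq_len(Treg), drop = FALSE]
    Z <- .bold_matrix(b)
    for (di in seq_along(delays)) {
      reg <- if (is.null(fms_1s))
        do.call(.regressors_for_delay,
                c(list(fms[[r]], delays[di]), hrf_args))
      else
        do.call(.regressors_for_delay_hr,
                c(list(fms_1s[[r]], delays[di]), hrf_args))
      st <- .simil_scan_cpp(reg$values, Z, voi_idx, alpha)
      st[!reg$ok, ] <- 0     # constant regressors carry no information
      out[, di, r, 1] <- st[, 2]
      out[, di, r, 2] <- st[, 3]
      out[, di, r, 3] <- st[, 4]
      out[, di, r, 4] <- st[, 5]
    }
  }
  out
}

#' Optimize the hemodynamic delay for one feature
#'
#' For each candidate delay the feature's second-order time course is
#' convolved with the HRF at that delay, correlated voxelwise with each
#' run's BOLD data, and the mean absolute correlation over significant VOI
#' voxels is averaged across runs; the delay maximizing that average wins
#' (ties to the smaller delay).
#'
#' @param feature_rows list with one numeric TR-grid series per run.
#' @param bolds list of [bold_volume()], one per run.
#' @param voi a [voi_mask()].
#' @param delays candidate delays, seconds.
#' @param alpha FDR level.
#' @return list `best_delay` and `per_delay` (data frame of per-delay
#'   run-averaged statistics).
#' @export
optimize_delay <- function(feature_rows, bolds, voi,
                           delays = c(4, 5, 6, 7), alpha = 0.05) {
  if (!length(feature_rows)) stop("need at least one run")
  stats_mat <- vapply(delays, function(d) {
    h <- canonical_hrf(d, dt_s = bolds[[1]]$tr_s)
    per_run <- vapply(seq_along(feature_rows), function(r) {
      x <- feature_rows[[r]]
      if (stats::sd(x) == 0) return(c(0, 0, 0))
      reg <- standardize(convolve_align(standardize(x), h))
      mp <- pearson_map(reg, bolds[[r]])
      vs <- voi_stats(list(r = mp$r, p = mp$p), voi, alpha)
      c(vs$mean_abs_r, vs$max_abs_r, vs$overlap_d)
    }, numeric(3))
    rowMeans(per_run)
  }, numeric(3))
  scores <- stats_mat[1, ]
  best <- delays[which.max(scores)]   # which.max ties -> first = smaller
  list(best_delay = best,
       per_delay = data.frame(delay_s = delays, mean_abs_r = stats_mat[1, ],
                              max_abs_r = stats_mat[2, ],
                              overlap_d = stats_mat[3, ]))
}
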