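# Synthetic EEG + BOLD generator with planted ground truth.

#' Construct an EEG recording object
#'
#' @param data numeric matrix, one column per channel (samples x channels),
#'   in microvolts.
#' @param fs sampling rate, Hz.
#' @param channel_labels montage labels, one per column.
#' @param timeline optional [make_timeline()] result.
#' @param run_id,subject_id identifiers.
#' @param check validate the data for NaN/NA (skipped by the generator,
#'   whose output cannot contain them)?
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, channel_labels, timeline = NULL,
                          run_id = "run1", subject_id = "sub1",
                          check = TRUE) {
  data <- as.matrix(data)
  if (length(channel_labels) != ncol(data))
    stop("channel_labels length must equal the number of channels")
  if (check && anyNA(data)) stop("EEG data must not contain NaN/NA")
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 timeline = timeline, run_id = run_id,
                 subject_id = subject_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples (%.1f s at %g Hz)\n",
              ncol(x$data), nrow(x$data), nrow(x$data) / x$fs, x$fs))
  cat(" subject:", x$subject_id, " run:", x$run_id, "\n")
  invisible(x)
}

# Butterworth coefficient helpers (designed with `signal`, applied in C++)
.broadband_coefs <- function(fs, hp_hz = 1, lp_hz = 45) {
  # Butterworth edges sit inside the nominal band (1.4x / 0.89x) because the
  # soft corners would otherwise leak >1% of the 1/f background's power past
  # the band limits; containment is tested by periodogram
  hp <- signal::butter(4, 1.4 * hp_hz / (fs / 2), type = "high")
  lp <- signal::butter(6, 0.89 * lp_hz / (fs / 2), type = "low")
  list(b_hp = hp$b, a_hp = hp$a, b_lp = lp$b, a_lp = lp$a)
}

# rhythm carrier frequency: center of the (1 Hz-clamped) band
.band_center <- function(band) {
  i <- match(band, .BANDS)
  if (is.na(i)) stop("responsive_band must be one of: ",
                     paste(.BANDS, collapse = ", "))
  (max(.BAND_EDGES[i], 1) + .BAND_EDGES[i + 1]) / 2
}

#' Synthesize multichannel EEG modulated by a latent load
#'
#' Every channel carries a 1/f-shaped Gaussian background band-limited to
#' 1-45 Hz plus a sinusoidal rhythm at the center frequency of
#' `responsive_band` (random phase per channel). On the channels named in
#' `responsive_channels` the rhythm's amplitude envelope is
#' `1 + gain * latent` (held per 1-second block); elsewhere the envelope
#' is 1, so at `gain = 0` responsive and non-responsive channels are
#' statistically indistinguishable.
#'
#' @param latent latent load series at 1 Hz (one value per second).
#' @param montage channel labels (default 60-channel 10-10 montage).
#' @param fs sampling rate, Hz (1000 for the emulated recordings).
#' @param responsive_channels labels of load-responsive channels.
#' @param responsive_band band carrying the modulation (`"delta"`,
#'   `"theta"`, `"alpha"`, `"beta"` or `"gamma"`).
#' @param gain modulation gain (unitless).
#' @param seed integer seed.
#' @param amp_uv background RMS amplitude, microvolts.
#' @param osc_rel rhythm RMS relative to the background RMS.
#' @param timeline,run_id,subject_id passed to [eeg_recording()].
#' @param run_key integer namespacing the random stream across runs.
#' @return An [eeg_recording()].
#' @export
make_eeg <- function(latent, montage = default_montage(), fs = 1000,
                     responsive_channels = c("F4", "FC4", "C4"),
                     responsive_band = "theta", gain = 1, seed = 1L,
                     amp_uv = 10, osc_rel = 1, timeline = NULL,
                     run_id = "run1", subject_id = "sub1", run_key = 0L) {
  unknown <- setdiff(responsive_channels, montage)
  if (length(unknown))
    stop("unknown montage label(s): ", paste(unknown, collapse = ", "))
  dur <- length(latent)
  nsamp <- dur * fs
  bb <- .broadband_coefs(fs)
  env <- 1 + gain * latent
  X <- .synth_eeg_cpp(length(montage), nsamp, as.integer(fs),
                      as.double(seed), as.double(1000L + run_key),
                      montage %in% responsive_channels, env,
                      bb$b_hp, bb$a_hp, bb$b_lp, bb$a_lp,
                      .band_center(responsive_band), amp_uv, osc_rel)
  eeg_recording(X, fs, montage, timeline = timeline,
                run_id = run_id, subject_id = subject_id, check = FALSE)
}

#' Construct a BOLD volume object
#'
#' @param data 4D numeric array (X x Y x Z x T).
#' @param tr_s repetition time, seconds.
#' @param affine 4x4 voxel-to-world transform.
#' @param run_id,subject_id identifiers.
#' @return A `bold_volume` object.
#' @export
bold_volume <- function(data, tr_s = 3, affine = diag(c(3, 3, 3, 1)),
                        run_id = "run1", subject_id = "sub1") {
  if (length(dim(data)) != 4) stop("BOLD data must be a 4D array")
  if (dim(data)[4] < 2) stop("BOLD data must have at least 2 volumes")
  structure(list(data = data, tr_s = tr_s, affine = affine,
                 run_id = run_id, subject_id = subject_id),
            class = "bold_volume")
}

#' @export
print.bold_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD volume: %dx%dx%d grid, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' Construct a volume-of-interest mask
#'
#' @param mask logical 3D array.
#' @param affine 4x4 voxel-to-world transform (must match the paired BOLD).
#' @param label region label.
#' @return A `voi_mask` object.
#' @export
voi_mask <- function(mask, affine = diag(c(3, 3, 3, 1)), label = "VOI") {
  if (length(dim(mask)) != 3) stop("VOI mask must be a 3D array")
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("VOI mask must contain at least one voxel")
  structure(list(mask = mask, affine = affine, label = label),
            class = "voi_mask")
}

#' Place a compact VOI block in a grid
#'
#' @param grid_shape 3D grid dimensions.
#' @param n_voi number of VOI voxels (a near-cubic block, seeded location).
#' @param seed integer seed.
#' @param label region label.
#' @return A [voi_mask()].
#' @export
make_voi <- function(grid_shape, n_voi = 64, seed = 1L, label = "Insula") {
  side <- ceiling(n_voi^(1 / 3))
  dims <- pmin(rep(side, 3), grid_shape)
  while (prod(dims) < n_voi) {
    i <- which.min(dims / grid_shape)
    if (dims[i] >= grid_shape[i]) i <- which(dims < grid_shape)[1]
    if (is.na(i)) stop("n_voi exceeds grid capacity")
    dims[i] <- dims[i] + 1
  }
  u <- rng_unif(3, seed, "voi")
  corner <- 1 + floor(u * (grid_shape - dims + 1))
  mask <- array(FALSE, grid_shape)
  block <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                                 seq_len(dims[3])))
  block <- block[seq_len(n_voi), , drop = FALSE]
  mask[cbind(block[, 1] + corner[1] - 1, block[, 2] + corner[2] - 1,
             block[, 3] + corner[3] - 1)] <- TRUE
  voi_mask(mask, label = label)
}

#' Synthesize a BOLD run following a latent load
#'
#' VOI voxels follow the latent load convolved with the canonical HRF at the
#' planted delay (standardized), plus Gaussian noise of SD `1/snr`;
#' non-VOI voxels are pure unit-SD noise. One volume per TR,
#' `ceiling(duration / tr_s)` volumes in total.
#'
#' @param latent latent load series at 1 Hz.
#' @param grid_shape 3D grid dimensions.
#' @param voi a [voi_mask()] fitting `grid_shape`.
#' @param true_delay_s planted hemodynamic delay, seconds.
#' @param tr_s repetition time, seconds.
#' @param snr signal-to-noise ratio, SD(signal) / SD(noise).
#' @param seed integer seed.
#' @param run_id,subject_id identifiers.
#' @param run_key integer namespacing the random stream across runs.
#' @return A [bold_volume()].
#' @export
make_bold <- function(latent, grid_shape = c(16, 16, 8), voi,
                      true_delay_s = 5, tr_s = 3, snr = 2, seed = 1L,
                      run_id = "run1", subject_id = "sub1", run_key = 0L) {
  if (!is.finite(snr) || snr <= 0) stop("snr must be positive")
  if (!all(dim(voi$mask) == grid_shape))
    stop("VOI mask does not fit grid_shape")
  dur <- length(latent)
  nvol <- ceiling(dur / tr_s)
  # truth simulated on the 1 Hz grid, sampled at the TR window centers
  h <- canonical_hrf(true_delay_s, dt_s = 1)
  sig <- convolve_align(latent, h)
  idx <- pmin(3 * (seq_len(nvol) - 1) + 2, dur)
  s <- standardize(sig[idx])
  nvox <- prod(grid_shape)
  noise <- matrix(rng_normal(nvox * nvol, seed, "bold", run_key), nvox, nvol)
  vidx <- which(as.vector(voi$mask))
  noise[vidx, ] <- noise[vidx, ] / snr +
    matrix(s, length(vidx), nvol, byrow = TRUE)
  bold_volume(array(noise, c(grid_shape, nvol)), tr_s = tr_s,
              affine = voi$affine, run_id = run_id, subject_id = subject_id)
}

#' Toy significance/VOI mask pair with known overlap
#'
#' Builds a VOI of exactly `n_voi` voxels and a significance mask sharing
#' exactly `n_overlap` of them plus `n_extra` voxels outside the VOI, so the
#' overlap portion is `n_overlap / n_voi` by construction.
#'
#' @param grid_shape 3D grid dimensions.
#' @param n_voi,n_overlap,n_extra voxel counts (`n_overlap <= n_voi`).
#' @param seed integer seed.
#' @return list with elements `sig` (logical 3D array) and `voi`
#'   (a [voi_mask()]).
#' @export
make_toy_masks <- function(grid_shape, n_voi, n_overlap, n_extra,
                           seed = 1L) {
  nvox <- prod(grid_shape)
  if (n_overlap > n_voi) stop("n_overlap must not exceed n_voi")
  if (n_voi + n_extra > nvox) stop("counts exceed grid capacity")
  perm <- rng_perm(nvox, seed, "masks")
  voi_idx <- perm[seq_len(n_voi)]
  extra_idx <- perm[n_voi + seq_len(n_extra)]
  voi <- array(FALSE, grid_shape); voi[voi_idx] <- TRUE
  sig <- array(FALSE, grid_shape)
  sig[voi_idx[seq_len(n_overlap)]] <- TRUE
  sig[extra_idx] <- TRUE
  list(sig = sig, voi = voi_mask(voi))
}

#' Simulate a complete synthetic EEG-fMRI dataset
#'
#' Generates `runs` runs of paired EEG and BOLD data for one synthetic
#' subject, with a planted latent cognitive load following the task
#' protocol, a planted responsive (band, channel) set, and a planted
#' hemodynamic delay shared by all runs. The ground truth is returned so
#' the analysis pipeline can be scored by parameter recovery.
#'
#' @param seed integer master seed; all randomness derives from it.
#' @param runs number of runs.
#' @param run_spec main-condition durations (see [make_timeline()]).
#' @param grid_shape,n_voi BOLD grid and VOI size.
#' @param snr BOLD signal-to-noise ratio in VOI voxels.
#' @param gain EEG modulation gain.
#' @param responsive_channels,responsive_band planted EEG modulation target.
#' @param true_delay_s planted delay; `NULL` draws one from `delay_grid`.
#' @param delay_grid candidate delays, seconds.
#' @param fs EEG sampling rate, Hz.
#' @param montage channel labels.
#' @param subject_id identifier.
#' @return A `cogsim_dataset`: list with `eeg` (list of runs), `bold`
#'   (list of runs), `voi`, `timelines`, and `truth` (planted ground truth).
#' @examples
#' ds <- simulate_dataset(seed = 1, runs = 1,
#'                        run_spec = c(text = 20, code_comprehension = 30,
#'                                     bug_inspection = 40))
#' ds$truth$true_delay_s
#' @export
simulate_dataset <- function(seed = 1L, runs = 4,
                             run_spec = c(text = 60, code_comprehension = 120,
                                          bug_inspection = 240),
                             grid_shape = c(16, 16, 8), n_voi = 64,
                             snr = 2, gain = 1,
                             responsive_channels = c("F4", "FC4", "C4"),
                             responsive_band = "theta",
                             true_delay_s = NULL, delay_grid = c(4, 5, 6, 7),
                             fs = 1000, montage = default_montage(),
                             subject_id = "sub1") {
  if (is.null(true_delay_s)) {
    u <- rng_unif(1, seed, "delay")
    true_delay_s <- delay_grid[1 + floor(u * length(delay_grid))]
  }
  if (!true_delay_s %in% delay_grid)
    stop("true_delay_s must lie on the delay grid")
  voi <- make_voi(grid_shape, n_voi = n_voi, seed = seed)
  eeg <- vector("list", runs); bold <- vector("list", runs)
  tls <- vector("list", runs); latents <- vector("list", runs)
  for (r in seq_len(runs)) {
    tl <- make_timeline(run_spec, randomize_order = TRUE,
                        seed = seed + 7919L * r)
    lat <- make_latent_load(tl, seed = seed + 104729L * r)
    rid <- paste0("run", r)
    eeg[[r]] <- make_eeg(lat, montage = montage, fs = fs,
                         responsive_channels = responsive_channels,
                         responsive_band = responsive_band, gain = gain,
                         seed = seed, timeline = tl, run_id = rid,
                         subject_id = subject_id, run_key = r)
    bold[[r]] <- make_bold(lat, grid_shape = grid_shape, voi = voi,
                           true_delay_s = true_delay_s, snr = snr,
                           seed = seed, run_id = rid,
                           subject_id = subject_id, run_key = r)
    tls[[r]] <- tl; latents[[r]] <- lat
  }
  truth <- list(latent_load = latents,
                responsive_channels = responsive_channels,
                responsive_band = responsive_band,
                true_delay_s = true_delay_s,
                voi_voxel_count = sum(voi$mask), seed = seed,
                gain = gain, snr = snr)
  structure(list(eeg = eeg, bold = bold, voi = voi, timelines = tls,
                 truth = truth, subject_id = subject_id),
            class = "cogsim_dataset")
}

#' @export
print.cogsim_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic EEG-fMRI dataset '%s': %d run(s), planted delay %g s,\n",
    x$subject_id, length(x$eeg), x$truth$true_delay_s))
  cat(sprintf("  responsive band %s on %s; gain %g, snr %g, VOI %d voxels\n",
              x$truth$responsive_band,
              paste(x$truth$responsive_channels, collapse = "/"),
              x$truth$gain, x$truth$snr, x$truth$voi_voxel_count))
  invisible(x)
}

#' Plan a cohort of synthetic subjects
#'
#' Derives per-subject seeds and planted hemodynamic delays from one
#' cohort seed, so subjects can be generated (and discarded) one at a
#' time at desk scale.
#'
#' @param seed integer cohort seed.
#' @param n_subjects number of subjects.
#' @param delay_grid candidate delays; each subject's planted delay is
#'   drawn from it.
#' @return data frame with columns `subject_id`, `seed`, `true_delay_s`.
#' @export
cohort_plan <- function(seed = 1L, n_subjects = 5,
                        delay_grid = c(4, 5, 6, 7)) {
  u <- rng_unif(n_subjects, seed, "delay", 1L)
  data.frame(subject_id = sprintf("sub%02d", seq_len(n_subjects)),
             seed = vapply(seq_len(n_subjects), function(s)
               derive_seed(seed, s), integer(1)),
             true_delay_s = delay_grid[1 + floor(u * length(delay_grid))],
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of synthetic subjects
#'
#' Subjects share the planted responsive band and channels (the group-level
#' effect) but receive independent noise and subject-specific planted
#' hemodynamic delays, emulating inter-subject hemodynamic variability.
#' At the default desk scale each dataset holds about 1 GB of EEG; prefer
#' [cohort_plan()] plus per-subject [simulate_dataset()] calls (as
#' [cohort_similarity()] does) when datasets are only needed transiently.
#'
#' @param seed integer cohort seed.
#' @param n_subjects number of subjects.
#' @param ... passed to [simulate_dataset()] (except `seed`, `subject_id`,
#'   `true_delay_s`).
#' @param delay_grid candidate delays; each subject's planted delay is drawn
#'   from it.
#' @return list of `cogsim_dataset`, one per subject.
#' @export
simulate_cohort <- function(seed = 1L, n_subjects = 5,
                            delay_grid = c(4, 5, 6, 7), ...) {
  plan <- cohort_plan(seed, n_subjects, delay_grid)
  lapply(seq_len(n_subjects), function(s) {
    simulate_dataset(seed = plan$seed[s], true_delay_s = plan$true_delay_s[s],
                     subject_id = plan$subject_id[s], ...)
  })
}
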