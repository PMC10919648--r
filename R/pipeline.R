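# End-to-end pipeline driver: simulate/read -> extract -> similarity ->
# rank -> report, with a run manifest for reproducibility.

#' Build and validate a pipeline configuration
#'
#' A flat list of parameters driving [run_pipeline()]. Paths may be `NULL`
#' for synthetic mode (then a dataset is simulated from `seed`).
#'
#' @param out output directory.
#' @param eeg character vector of EDF paths (one per run), or `NULL`.
#' @param bold character vector of 4D NIfTI paths, or `NULL`.
#' @param voi VOI mask NIfTI path, or `NULL`.
#' @param seed integer seed (drives simulation in synthetic mode).
#' @param runs number of synthetic runs.
#' @param delays hemodynamic delay grid, seconds.
#' @param alpha FDR level.
#' @param cap,elbow_w,elbow_eps ranking parameters.
#' @param kmax,outlier_threshold extraction parameters.
#' @param snr,gain,responsive_band,responsive_channels synthetic-mode
#'   generator parameters.
#' @param run_spec,fs,montage,grid_shape,n_voi synthetic-mode scale
#'   parameters (see [simulate_dataset()]); `NULL` keeps the generator's
#'   desk-scale defaults.
#' @param apply_bandpass band-pass filter EEG before extraction?
#' @return validated config list (class `cogsim_config`).
#' @export
pipeline_config <- function(out, eeg = NULL, bold = NULL, voi = NULL,
                            seed = 1L, runs = 4, delays = c(4, 5, 6, 7),
                            alpha = 0.05, cap = 100, elbow_w = 10,
                            elbow_eps = 0.002, kmax = 10,
                            outlier_threshold = 0.25, snr = 2, gain = 1,
                            responsive_band = "theta",
                            responsive_channels = NULL,
                            run_spec = NULL, fs = NULL, montage = NULL,
                            grid_shape = NULL, n_voi = NULL,
                            apply_bandpass = FALSE) {
  if (!length(delays)) stop("delays must be non-empty")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  for (p in c(eeg, bold, voi))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  if (xor(is.null(eeg), is.null(bold)))
    stop("real mode needs both eeg and bold inputs")
  cfg <- list(out = out, eeg = eeg, bold = bold, voi = voi, seed = seed,
              runs = runs, delays = delays, alpha = alpha, cap = cap,
              elbow_w = elbow_w, elbow_eps = elbow_eps, kmax = kmax,
              outlier_threshold = outlier_threshold, snr = snr,
              gain = gain, responsive_band = responsive_band,
              responsive_channels = responsive_channels,
              run_spec = run_spec, fs = fs, montage = montage,
              grid_shape = grid_shape, n_voi = n_voi,
              apply_bandpass = apply_bandpass)
  class(cfg) <- "cogsim_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes extraction, similarity mapping, delay optimization and ranking
#' for one subject and writes all artifacts to the output directory:
#' per-run feature TSVs, similarity statistics TSV, ranking and occurrence
#' JSON, and a manifest with input checksums and the configuration
#' snapshot. In synthetic mode the simulated EEG/BOLD/VOI are also written
#' (EDF / NIfTI) together with the ground truth.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  if (is.null(config$eeg)) {
    sim_args <- list(seed = config$seed, runs = config$runs,
                     snr = config$snr, gain = config$gain,
                     responsive_band = config$responsive_band)
    for (k in c("run_spec", "fs", "montage", "grid_shape", "n_voi",
                "responsive_channels"))
      if (!is.null(config[[k]])) sim_args[[k]] <- config[[k]]
    ds <- do.call(simulate_dataset, sim_args)
    eeg_runs <- ds$eeg; bold_runs <- ds$bold; voi <- ds$voi
    for (r in seq_along(eeg_runs)) {
      write_eeg_edf(eeg_runs[[r]],
                    file.path(config$out, sprintf("eeg_run%d.edf", r)))
      write_nifti(bold_runs[[r]],
                  file.path(config$out, sprintf("bold_run%d.nii.gz", r)))
      tl <- ds$timelines[[r]]
      jsonlite::write_json(
        list(entries = as.data.frame(tl),
             total_duration_s = attr(tl, "total_duration_s")),
        file.path(config$out, sprintf("timeline_run%d.json", r)),
        auto_unbox = TRUE, pretty = TRUE)
    }
    write_nifti(voi, file.path(config$out, "voi.nii.gz"))
    jsonlite::write_json(ds$truth, file.path(config$out, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    inputs <- character(0)
  } else {
    eeg_runs <- lapply(seq_along(config$eeg), function(r)
      read_eeg_edf(config$eeg[r], run_id = paste0("run", r)))
    bold_runs <- lapply(seq_along(config$bold), function(r)
      read_bold_nifti(config$bold[r], run_id = paste0("run", r)))
    voi <- read_mask_nifti(config$voi)
    ds <- NULL
    inputs <- c(config$eeg, config$bold, config$voi)
  }

  fms <- vector("list", length(eeg_runs))
  for (r in seq_along(eeg_runs)) {
    er <- if (config$apply_bandpass) bandpass(eeg_runs[[r]]) else eeg_runs[[r]]
    fm <- extract_all(er, kmax = config$kmax)
    fm <- interp_missing(fm)
    fm <- interp_outliers(fm, config$outlier_threshold)
    write_features_tsv(fm,
                       file.path(config$out, sprintf("features_run%d.tsv", r)),
                       params = list(kmax = config$kmax,
                                     outlier_threshold = config$outlier_threshold))
    fms[[r]] <- second_order(fm)
  }
  fit <- eegfmri_similarity(fms, bold = bold_runs, voi = voi,
                            delays = config$delays, alpha = config$alpha,
                            cap = config$cap, elbow_w = config$elbow_w,
                            elbow_eps = config$elbow_eps)
  if (!is.null(ds)) fit$truth <- ds$truth

  utils::write.table(fit$stats, file.path(config$out, "similarity_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rk <- as.data.frame(fit$ranking)
  jsonlite::write_json(
    list(cutoff_index = attr(fit$ranking, "cutoff_index"),
         scope = attr(fit$ranking, "scope"),
         top = utils::head(rk, attr(fit$ranking, "cutoff_index"))),
    file.path(config$out, "ranking.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(lapply(fit$occurrence, as.list),
                       file.path(config$out, "occurrence.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    subject_id = fit$subject_id,
    run_ids = vapply(eeg_runs, function(e)
      if (inherits(e, "eeg_recording")) e$run_id else "run", ""),
    software_version = as.character(utils::packageVersion("cogsim")),
    config = unclass(config),
    input_checksums = as.list(tools::md5sum(inputs)),
    artifacts = list.files(config$out),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  fit$manifest <- manifest
  invisible(fit)
}
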