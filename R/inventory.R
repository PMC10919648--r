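# Feature inventory and montage tables.

# canonical per-channel feature bank (35 descriptors), in extraction order
.BANDS <- c("delta", "theta", "alpha", "beta", "gamma")
.BAND_EDGES <- c(0, 4, 8, 13, 30, 45)   # half-open [lo, hi); gamma closed at 45

.RATIO_PAIRS <- {
  p <- t(utils::combn(5, 2))
  data.frame(lo = .BANDS[p[, 1]], hi = .BANDS[p[, 2]], stringsAsFactors = FALSE)
}

.FEATURE_TABLE <- local({
  lt <- c("mean", "mean_norm", "sd", "skewness", "kurtosis",
          "hjorth_activity", "hjorth_mobility", "hjorth_complexity")
  lf <- c("total_power",
          paste0("abs_", .BANDS), paste0("rel_", .BANDS),
          paste0("ratio_", .RATIO_PAIRS$lo, "_", .RATIO_PAIRS$hi),
          "mean_freq", "alpha_peak_freq",
          "beta_over_theta_alpha", "theta_over_alpha_beta")
  nl <- c("higuchi_fd", "hurst_rs")
  data.frame(feature = c(lt, lf, nl),
             group = rep(c("linear_time", "linear_freq", "nonlinear"),
                         c(length(lt), length(lf), length(nl))),
             stringsAsFactors = FALSE)
})

#' Default 60-channel 10-10 scalp montage
#'
#' Sixty scalp electrode labels of the international 10-10 system, the
#' channel set retained after upstream preprocessing of a 64-channel cap.
#'
#' @return character vector of 60 montage labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2")
}

#' Map 10-10 channel labels to scalp regions
#'
#' Prefix-based assignment to the five scalp regions used for occurrence
#' summaries: `FT`/`TP`/`T` are Temporal, `FC`/`CP`/`C` Central,
#' `AF`/`Fp`/`F` Frontal, `PO`/`P` Parietal and `O` Occipital. Midline
#' `z` channels follow their prefix.
#'
#' @param labels character vector of montage labels.
#' @param table optional named vector overriding the prefix table
#'   (names = prefixes, values = regions), matched longest-prefix-first.
#' @return character vector of regions.
#' @export
channel_region <- function(labels, table = NULL) {
  if (is.null(table))
    table <- c(FT = "Temporal", TP = "Temporal", FC = "Central",
               CP = "Central", PO = "Parietal", AF = "Frontal",
               Fp = "Frontal", F = "Frontal", C = "Central",
               T = "Temporal", P = "Parietal", O = "Occipital")
  table <- table[order(-nchar(names(table)))]
  out <- rep(NA_character_, length(labels))
  for (i in seq_along(table)) {
    hit <- is.na(out) & startsWith(labels, names(table)[i])
    out[hit] <- table[[i]]
  }
  if (anyNA(out))
    stop("channel label(s) not in the region table: ",
         paste(unique(labels[is.na(out)]), collapse = ", "))
  out
}

#' Build the EEG feature inventory for a montage
#'
#' Enumerates the per-channel descriptor bank: 8 linear time-domain
#' descriptors (mean of the raw and run-normalized signal, SD, skewness,
#' kurtosis, and the three Hjorth parameters), 25 linear frequency-domain
#' descriptors (total power, absolute and relative power in the delta,
#' theta, alpha, beta and gamma bands, the 10 unordered band-power ratios,
#' spectral mean frequency, alpha peak frequency, and the two task
#' engagement indexes), and 2 nonlinear descriptors (Higuchi fractal
#' dimension, Hurst exponent). For a 60-channel montage this yields
#' 480 + 1500 + 120 = 2100 descriptors.
#'
#' @param channel_labels montage labels (default 60-channel 10-10 set).
#' @return data frame with columns `id`, `feature`, `channel`, `group`,
#'   `transform` (all `"none"` before the second-order transform).
#' @examples
#' inv <- build_inventory()
#' table(inv$group)
#' @export
build_inventory <- function(channel_labels = default_montage()) {
  if (!length(channel_labels)) stop("channel_labels must be non-empty")
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]),
               collapse = ", "))
  nf <- nrow(.FEATURE_TABLE)
  inv <- data.frame(
    feature = rep(.FEATURE_TABLE$feature, times = length(channel_labels)),
    channel = rep(channel_labels, each = nf),
    group = rep(.FEATURE_TABLE$group, times = length(channel_labels)),
    transform = "none",
    stringsAsFactors = FALSE)
  inv$id <- paste(inv$feature, inv$channel, inv$transform, sep = "|")
  inv[, c("id", "feature", "channel", "group", "transform")]
}

# resolve a literature-style feature label ("Theta / (Alpha + Beta)",
# "Theta/Gamma", "Alpha", "Activity", ...) to a canonical feature name
resolve_feature_name <- function(name) {
  key <- tolower(gsub("[[:space:]()]", "", name))
  lut <- c(
    "theta/(alpha+beta)" = "theta_over_alpha_beta",
    "theta/alpha+beta"   = "theta_over_alpha_beta",
    "beta/(theta+alpha)" = "beta_over_theta_alpha",
    "beta/theta+alpha"   = "beta_over_theta_alpha",
    "activity" = "hjorth_activity", "mobility" = "hjorth_mobility",
    "complexity" = "hjorth_complexity", "totalpower" = "total_power",
    "fractaldimension" = "higuchi_fd", "hurstexponent" = "hurst_rs")
  if (key %in% names(lut)) return(unname(lut[key]))
  m <- regmatches(key, regexec("^([a-z]+)/([a-z]+)$", key))[[1]]
  if (length(m) == 3 && all(m[2:3] %in% .BANDS))
    return(paste0("ratio_", m[2], "_", m[3]))
  if (key %in% .BANDS) return(paste0("rel_", key))
  if (key %in% .FEATURE_TABLE$feature) return(key)
  stop("cannot resolve feature name: ", name)
}
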