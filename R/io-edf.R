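# Minimal EDF (European Data Format) reader/writer: 16-bit integer storage,
# one-second data records, all channels at a common sampling rate (the only
# layout this package produces or consumes).

.edf_pad <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  formatC(x, width = n, flag = "-")
}

#' Write an EEG recording to an EDF file
#'
#' Stores the recording as standard 16-bit EDF with 1-second data records
#' and per-channel physical scaling covering the data range (microvolts).
#' A trailing partial second is dropped (EDF stores whole records).
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_edf <- function(recording, path) {
  fs <- recording$fs
  nrec <- nrow(recording$data) %/% fs
  ns <- ncol(recording$data)
  x <- recording$data[seq_len(nrec * fs), , drop = FALSE]
  pmin_ <- apply(x, 2, min); pmax_ <- apply(x, 2, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(.edf_pad("0", 8), .edf_pad(recording$subject_id, 80),
                .edf_pad(recording$run_id, 80),
                .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
                .edf_pad(256 * (1 + ns), 8), .edf_pad("", 44),
                .edf_pad(nrec, 8), .edf_pad(1, 8), .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(c(recording$channel_labels, 16), c(rep("", ns), 80),
                 c(rep("uV", ns), 8),
                 c(formatC(pmin_, format = "g", digits = 7), 8),
                 c(formatC(pmax_, format = "g", digits = 7), 8),
                 c(rep(dmin, ns), 8), c(rep(dmax, ns), 8),
                 c(rep("", ns), 80), c(rep(fs, ns), 8), c(rep("", ns), 32))
  for (f in fields) {
    n <- as.integer(f[length(f)])
    vals <- f[-length(f)]
    writeChar(paste0(vapply(vals, .edf_pad, "", n = n), collapse = ""),
              con, eos = NULL)
  }
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (rec in seq_len(nrec)) {
    idx <- ((rec - 1) * fs + 1):(rec * fs)
    dig <- round((t(x[idx, , drop = FALSE]) - pmin_) * scale + dmin)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EEG recording from an EDF file
#'
#' Channel labels are taken verbatim from the header; values are converted
#' to physical units (microvolts) using the per-channel scaling. All
#' channels must share one sampling rate.
#'
#' @param path EDF file path.
#' @param run_id,subject_id identifiers (default from the header).
#' @return An [eeg_recording()].
#' @export
read_eeg_edf <- function(path, run_id = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (nchar(s, type = "bytes") < n)
      stop("truncated EDF header in ", path, " (at byte ",
           seek(con, NA), ")")
    trimws(s)
  }
  rd(8)                        # version
  pid <- rd(80); rid <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  rd(80 * ns)                  # transducer
  rd(8 * ns)                   # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)                  # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  if (length(unique(spr)) != 1)
    stop("mixed per-channel sampling rates are not supported: ",
         paste(unique(spr), collapse = ", "))
  fs <- spr[1] / recdur
  total <- nrec * ns * spr[1]
  raw <- readBin(con, "integer", n = total, size = 2, endian = "little")
  if (length(raw) < total)
    stop("truncated EDF data in ", path, " (got ", length(raw) * 2,
         " of ", total * 2, " payload bytes)")
  # records x (channel-blocks of spr samples) -> samples x channels
  dim(raw) <- c(spr[1], ns, nrec)
  x <- matrix(aperm(raw, c(1, 3, 2)), nrow = spr[1] * nrec, ncol = ns)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  x <- sweep(sweep(x, 2, dmin), 2, scale, `*`)
  x <- sweep(x, 2, pmin_, `+`)
  eeg_recording(x, fs = fs, channel_labels = labels,
                run_id = if (is.null(run_id)) rid else run_id,
                subject_id = if (is.null(subject_id)) pid else subject_id)
}
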