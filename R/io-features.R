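# Feature-matrix TSV I/O.

#' Write a feature matrix to TSV (with JSON sidecar)
#'
#' The TSV has one row per descriptor: an `id` column
#' (`feature|channel|transform`) followed by one column per time point.
#' A `<path>.json` sidecar records `dt_s`, mask summaries and extraction
#' parameters.
#'
#' @param fm a [feature_matrix()].
#' @param path output TSV path.
#' @param params optional named list of extraction parameters to record.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(fm, path, params = list()) {
  df <- data.frame(id = fm$descriptors$id, fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", paste0("t", seq_len(ncol(fm$values))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- list(dt_s = fm$dt_s,
                  n_descriptors = nrow(fm$values),
                  n_samples = ncol(fm$values),
                  n_missing = sum(fm$missing_mask),
                  n_outliers = if (is.null(fm$outlier_mask)) 0
                               else sum(fm$outlier_mask),
                  run_id = fm$run_id, subject_id = fm$subject_id,
                  params = params)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a feature matrix from TSV
#'
#' @param path TSV path written by [write_features_tsv()].
#' @return A [feature_matrix()].
#' @export
read_features_tsv <- function(path) {
  if (!file.exists(path)) stop("feature TSV not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df$id
  vals <- as.matrix(df[, -1, drop = FALSE])
  parts <- strsplit(ids, "|", fixed = TRUE)
  desc <- data.frame(id = ids,
                     feature = vapply(parts, `[`, "", 1),
                     channel = vapply(parts, `[`, "", 2),
                     transform = vapply(parts, `[`, "", 3),
                     stringsAsFactors = FALSE)
  ft <- .FEATURE_TABLE
  desc$group <- ft$group[match(desc$feature, ft$feature)]
  dt_s <- 1
  run_id <- "run1"; subject_id <- "sub1"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    dt_s <- meta$dt_s
    run_id <- meta$run_id %||% run_id
    subject_id <- meta$subject_id %||% subject_id
  }
  feature_matrix(vals, desc, dt_s = dt_s, missing_mask = is.na(vals),
                 run_id = run_id, subject_id = subject_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
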