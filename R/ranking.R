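# Feature ranking, elbow threshold and occurrence summaries.

#' Elbow cutoff on a sorted score curve
#'
#' The smallest index `k` from which the score curve stays locally flat:
#' all successive differences within the window `[k, k + w)` are below
#' `eps`. Falls back to the full length when the curve never settles.
#'
#' @param sorted_scores non-increasing numeric vector.
#' @param w window width (number of consecutive differences inspected).
#' @param eps flatness threshold on successive score differences.
#' @return integer cutoff index.
#' @export
elbow_cutoff <- function(sorted_scores, w = 10, eps = 0.002) {
  n <- length(sorted_scores)
  if (n < 2) return(n)
  d <- -diff(sorted_scores)
  if (any(d < -1e-12)) stop("scores must be non-increasing")
  nk <- length(d) - w + 1
  if (nk >= 1) {
    flat <- d < eps
    run <- cumsum(flat)
    # window [k, k+w) all flat  <=>  run[k+w-1] - run[k-1] == w
    ok <- (run[seq_len(nk) + w - 1] - c(0, run)[seq_len(nk)]) == w
    if (any(ok)) return(which(ok)[1])
  }
  n
}

#' Rank descriptors by their similarity score
#'
#' Sorts descriptors by run-averaged mean absolute correlation over
#' significant VOI voxels (descending), breaking ties by maximum absolute
#' correlation and then descriptor id, and applies the elbow threshold
#' capped at `cap`.
#'
#' @param stats data frame with one row per (descriptor, chosen delay):
#'   columns `id`, `mean_abs_r`, `max_abs_r` at least; typically the
#'   `$stats` element of an [eegfmri_similarity()] fit.
#' @param cap hard upper bound on the cutoff (100 for individual rankings,
#'   200 for group rankings).
#' @param w,eps elbow parameters, see [elbow_cutoff()].
#' @param scope `"run"`, `"subject"` or `"group"` (metadata only).
#' @return A `ranking_result`: the sorted data frame with attributes
#'   `cutoff_index` and `scope`.
#' @export
rank_features <- function(stats, cap = 100, w = 10, eps = 0.002,
                          scope = "subject") {
  if (!nrow(stats)) stop("empty similarity statistics")
  ord <- order(-stats$mean_abs_r, -stats$max_abs_r, stats$id)
  out <- stats[ord, , drop = FALSE]
  rownames(out) <- NULL
  cut <- min(cap, elbow_cutoff(out$mean_abs_r, w = w, eps = eps))
  attr(out, "cutoff_index") <- cut
  attr(out, "scope") <- scope
  class(out) <- c("ranking_result", "data.frame")
  out
}

#' @export
print.ranking_result <- function(x, n = 10, ...) {
  cat(sprintf("Feature ranking (%s scope): %d descriptors, cutoff at %d\n",
              attr(x, "scope"), nrow(x), attr(x, "cutoff_index")))
  cols <- intersect(c("id", "best_delay", "mean_abs_r", "max_abs_r",
                      "overlap_d"), names(x))
  print.data.frame(utils::head(as.data.frame(x)[, cols], n),
                   row.names = FALSE, digits = 3)
  invisible(x)
}

#' Occurrence summary of a top-feature list
#'
#' Percentage histograms of the selected (above-cutoff) descriptors by
#' feature type, scalp region and optimized hemodynamic delay.
#'
#' @param ranking a [rank_features()] result with columns `feature`,
#'   `channel` and `best_delay`.
#' @param region_table optional prefix table for [channel_region()].
#' @return list of named numeric vectors (`by_feature_type`, `by_region`,
#'   `by_delay`), each summing to 100.
#' @export
occurrence_summary <- function(ranking, region_table = NULL) {
  top <- as.data.frame(ranking)[seq_len(attr(ranking, "cutoff_index")), ]
  pct <- function(x) 100 * table(x) / length(x)
  list(by_feature_type = c(pct(top$feature)),
       by_region = c(pct(channel_region(top$channel, region_table))),
       by_delay = c(pct(top$best_delay)))
}

#' Group-level descriptor ranking across subjects
#'
#' For each descriptor, the group score is the mean over all subjects'
#' runs of the mean absolute VOI correlation, each subject contributing at
#' its own optimized delay; descriptors are then ranked as in
#' [rank_features()] with a default cap of 200.
#'
#' @param fits list of [eegfmri_similarity()] fits (>= 2 subjects).
#' @param cap,w,eps ranking parameters.
#' @return A `ranking_result` with scope `"group"`.
#' @export
group_rank <- function(fits, cap = 200, w = 10, eps = 0.002) {
  if (length(fits) < 2) stop("group ranking needs at least 2 subjects")
  ids <- fits[[1]]$stats$id
  for (f in fits[-1])
    if (!identical(f$stats$id, ids))
      stop("subjects have different descriptor sets")
  per_subj <- lapply(fits, function(f) {
    di <- match(f$stats$best_delay, f$delays)
    idx <- cbind(seq_along(di), di)
    nrun <- dim(f$scan)[3]
    means <- vapply(seq_len(nrun),
                    function(r) f$scan[, , r, "mean_abs_r"][idx],
                    numeric(length(di)))
    maxs <- vapply(seq_len(nrun),
                   function(r) f$scan[, , r, "max_abs_r"][idx],
                   numeric(length(di)))
    list(means = means, maxs = maxs)
  })
  score <- rowMeans(do.call(cbind, lapply(per_subj, `[[`, "means")))
  gmax <- do.call(pmax, lapply(per_subj, function(s) apply(s$maxs, 1, max)))
  stats <- fits[[1]]$stats
  gs <- data.frame(id = ids, feature = stats$feature,
                   channel = stats$channel, transform = stats$transform,
                   mean_abs_r = score, max_abs_r = gmax,
                   stringsAsFactors = FALSE)
  rank_features(gs, cap = cap, w = w, eps = eps, scope = "group")
}

#' Evaluate literature-proposed EEG features
#'
#' Runs the named (feature, channel) descriptors through the standard
#' per-subject machinery (delay optimization already performed by the
#' fits) and reports, per pair, the across-subject average and maximum of
#' the mean absolute VOI correlation and of the overlap portion. Each
#' subject contributes its best second-order transform of the pair.
#'
#' @param features data frame with columns `channel` and `feature`
#'   (literature-style names such as `"Theta / (Alpha + Beta)"` or
#'   `"Theta/Gamma"` are resolved to inventory descriptors).
#' @param fits list of [eegfmri_similarity()] fits.
#' @return data frame with one row per (channel, feature) pair.
#' @export
evaluate_literature_features <- function(features, fits) {
  if (!is.list(fits) || inherits(fits, "eegfmri_sim")) fits <- list(fits)
  st1 <- fits[[1]]$stats
  out <- lapply(seq_len(nrow(features)), function(i) {
    fname <- resolve_feature_name(features$feature[i])
    chan <- features$channel[i]
    sel <- which(st1$feature == fname & st1$channel == chan)
    if (!length(sel))
      stop("descriptor not found in the inventory/montage: ",
           features$feature[i], " at ", chan)
    per_subj <- vapply(fits, function(f) {
      s <- f$stats[sel, ]
      b <- which.max(s$mean_abs_r)
      c(s$mean_abs_r[b], s$max_abs_r[b], s$overlap_d[b])
    }, numeric(3))
    data.frame(channel = chan, feature = features$feature[i],
               descriptor = fname,
               mean_r = mean(per_subj[1, ]), max_r = max(per_subj[2, ]),
               mean_d = mean(per_subj[3, ]), max_d = max(per_subj[3, ]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
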