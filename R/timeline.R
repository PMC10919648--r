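#' Build a run timeline of task conditions
#'
#' A run interleaves 30-second fixation-cross baselines with three main
#' conditions (natural-language text reading, code comprehension, bug
#' inspection): baseline, condition, baseline, condition, baseline,
#' condition, baseline. The order of the three main conditions can be
#' randomized per run, as in the acquisition protocol.
#'
#' @param run_spec named numeric vector of main-condition durations in
#'   seconds; names must be `text`, `code_comprehension`, `bug_inspection`.
#'   The default is the desk-scale run (540 s total); the full protocol uses
#'   `c(text = 60, code_comprehension = 300, bug_inspection = 600)`.
#' @param randomize_order randomize the order of the three main conditions?
#' @param seed integer seed driving the order permutation.
#' @param baseline_s baseline (fixation cross) duration, seconds.
#' @return A `condition_timeline`: data frame with columns `condition`,
#'   `onset_s`, `duration_s`, plus attribute `total_duration_s`.
#' @examples
#' tl <- make_timeline(seed = 1)
#' attr(tl, "total_duration_s")  # 540
#' @export
make_timeline <- function(run_spec = c(text = 60, code_comprehension = 120,
                                       bug_inspection = 240),
                          randomize_order = TRUE, seed = 1L,
                          baseline_s = 30) {
  main <- c("text", "code_comprehension", "bug_inspection")
  if (!all(main %in% names(run_spec)))
    stop("run_spec must name durations for: ", paste(main, collapse = ", "))
  run_spec <- run_spec[main]
  bad <- names(run_spec)[!is.finite(run_spec) | run_spec <= 0]
  if (length(bad))
    stop("non-positive duration for condition: ", paste(bad, collapse = ", "))
  ord <- if (randomize_order) rng_perm(3L, seed, "timeline") else 1:3
  conds <- character(0); durs <- numeric(0)
  for (i in 1:3) {
    conds <- c(conds, "baseline", names(run_spec)[ord[i]])
    durs <- c(durs, baseline_s, unname(run_spec[ord[i]]))
  }
  conds <- c(conds, "baseline"); durs <- c(durs, baseline_s)
  onset <- cumsum(c(0, durs[-length(durs)]))
  tl <- data.frame(condition = conds, onset_s = onset, duration_s = durs,
                   stringsAsFactors = FALSE)
  attr(tl, "total_duration_s") <- sum(durs)
  class(tl) <- c("condition_timeline", "data.frame")
  tl
}

#' @export
print.condition_timeline <- function(x, ...) {
  cat("Condition timeline:", attr(x, "total_duration_s"), "s total\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# condition label at each 1 Hz sample (sample t covers [t, t+1))
timeline_labels_1hz <- function(timeline) {
  total <- attr(timeline, "total_duration_s")
  labs <- character(total)
  for (i in seq_len(nrow(timeline))) {
    idx <- seq(timeline$onset_s[i] + 1,
               timeline$onset_s[i] + timeline$duration_s[i])
    labs[idx] <- timeline$condition[i]
  }
  labs
}

#' Latent cognitive-load time course for a timeline
#'
#' Piecewise-constant load levels per condition, optionally smoothed with a
#' Gaussian kernel (emulating the sluggishness of state changes) and
#' perturbed by white noise. Sampled at 1 Hz to match the 1-second feature
#' windows.
#'
#' @param timeline a [make_timeline()] result.
#' @param level_map named vector mapping each condition label occurring in
#'   the timeline to a load level.
#' @param smooth_sd_s Gaussian smoothing SD in seconds (0 = none).
#' @param noise_sd SD of additive white noise.
#' @param seed integer seed for the noise.
#' @return numeric vector, one value per second.
#' @export
make_latent_load <- function(timeline,
                             level_map = c(baseline = 0, text = 0.3,
                                           code_comprehension = 0.6,
                                           bug_inspection = 1),
                             smooth_sd_s = 3, noise_sd = 0.05, seed = 1L) {
  if (smooth_sd_s < 0) stop("smooth_sd_s must be >= 0")
  if (!all(is.finite(level_map))) stop("load levels must be finite")
  labs <- timeline_labels_1hz(timeline)
  missing_conds <- setdiff(unique(labs), names(level_map))
  if (length(missing_conds))
    stop("condition missing from level_map: ",
         paste(missing_conds, collapse = ", "))
  x <- unname(level_map[labs])
  if (smooth_sd_s > 0) {
    half <- ceiling(4 * smooth_sd_s)
    k <- exp(-0.5 * ((-half:half) / smooth_sd_s)^2)
    # renormalizing at the edges keeps levels unbiased near boundaries
    n <- length(x)
    num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
    den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
    x <- as.numeric(num[(half + 1):(half + n)] / den[(half + 1):(half + n)])
  }
  if (noise_sd > 0)
    x <- x + noise_sd * rng_normal(length(x), seed, "latent")
  x
}
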