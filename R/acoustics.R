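# Acoustic characterization of detected calls: RMS level in dBFS, per-call
# signal-to-noise ratio against the nearest clean 4-s noise window, the
# clipping exclusion, per-individual-day subsampling, and distribution
# summaries. No denoising is applied anywhere in this module.

#' SNR analysis configuration
#'
#' @param det_prob_min Minimum detection probability (strict `>`).
#' @param class_prob_min Minimum class probability (strict `>`).
#' @param noise_window_s Length of the noise window in seconds.
#' @param clip_snr_db Calls with SNR strictly above this are flagged as
#'   clipping artifacts and excluded.
#' @param chick_sample_n Per-individual-per-day sample size for chick calls.
#' @param search_step_s Granularity of the noise-window search.
#' @return A list of class `snr_config`.
#' @export
snr_config <- function(det_prob_min = 0.5, class_prob_min = 0.5,
                       noise_window_s = 4.0, clip_snr_db = 60.0,
                       chick_sample_n = 100, search_step_s = 0.1) {
  if (det_prob_min < 0 || det_prob_min > 1 || class_prob_min < 0 || class_prob_min > 1) {
    abort("probability thresholds must be in [0, 1]")
  }
  if (noise_window_s <= 0) abort("noise_window_s must be > 0")
  structure(list(det_prob_min = det_prob_min, class_prob_min = class_prob_min,
                 noise_window_s = noise_window_s, clip_snr_db = clip_snr_db,
                 chick_sample_n = chick_sample_n, search_step_s = search_step_s),
            class = "snr_config")
}

#' Select confidently detected calls of one class
#'
#' Keeps detections with `detection_prob` strictly above `det_prob_min` and
#' the target class probability strictly above `class_prob_min`; a call at
#' exactly the threshold is excluded.
#'
#' @param predictions Selection table with `detection_prob` and the class
#'   probability column for `target_class` (e.g. `p_focal`).
#' @param target_class One of [scored_classes()].
#' @param cfg An [snr_config()].
#' @return The filtered selection table.
#' @export
select_confident <- function(predictions, target_class = "Focal",
                             cfg = snr_config()) {
  predictions <- validate_selection_table(predictions, "predictions")
  col <- CLASS_PROB_COLS[[target_class]]
  if (is.null(col)) abort(sprintf("unknown target class '%s'", target_class))
  if (!"detection_prob" %in% names(predictions) || !col %in% names(predictions)) {
    abort(sprintf("predictions must carry detection_prob and %s", col))
  }
  if (anyNA(predictions$detection_prob) || anyNA(predictions[[col]])) {
    abort("missing detection or class probabilities")
  }
  dplyr::filter(predictions,
                .data$detection_prob > cfg$det_prob_min,
                .data[[col]] > cfg$class_prob_min)
}

rms <- function(x) sqrt(mean(x^2))

span_samples <- function(start_s, stop_s, fs, n) {
  # 0-based half-open [start, stop) mapped to 1-based sample indices
  i0 <- floor(start_s * fs) + 1
  i1 <- ceiling(stop_s * fs)
  i0 <- max(1, i0); i1 <- min(n, i1)
  if (i1 - i0 + 1 < 2) abort("box span shorter than 2 samples")
  i0:i1
}

#' Measure call level in dBFS
#'
#' RMS amplitude of the waveform over each box's `[start, stop)` span,
#' expressed in decibels relative to digital full scale (amplitude 1.0, so
#' a full-scale sine measures -3.01 dBFS).
#'
#' @param samples Waveform in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @param boxes Selection table of call boxes.
#' @return `boxes` with added columns `rms` and `level_dbfs`.
#' @export
measure_level_dbfs <- function(samples, sample_rate, boxes) {
  boxes <- validate_selection_table(boxes, "boxes")
  vals <- vapply(seq_len(nrow(boxes)), function(k) {
    idx <- span_samples(boxes$start_s[k], boxes$stop_s[k], sample_rate,
                        length(samples))
    rms(samples[idx])
  }, numeric(1))
  if (any(vals == 0)) abort("all-zero span: level undefined")
  boxes$rms <- vals
  boxes$level_dbfs <- 20 * log10(vals)
  boxes
}

#' Find the nearest clean noise window
#'
#' Searches for a contiguous window of `noise_window_s` seconds that
#' intersects no focal box (including the target call itself), minimizing
#' the gap between window and target box. Candidates slide outward from the
#' target at `search_step_s` steps and additionally anchor at every focal
#' box edge; ties in gap are broken toward earlier time, so with free space
#' on both sides the window abutting the call's start wins.
#'
#' @param box One-row selection table (or list with `start_s`, `stop_s`):
#'   the target call.
#' @param focal_boxes Selection table of all focal calls in the file.
#' @param file_duration_s Duration of the audio file in seconds.
#' @param cfg An [snr_config()].
#' @return Numeric vector `c(start_s, stop_s)` of the chosen window.
#' @export
select_noise_window <- function(box, focal_boxes, file_duration_s,
                                cfg = snr_config()) {
  w <- cfg$noise_window_s
  if (file_duration_s < w) abort("file shorter than the noise window")
  fb_start <- focal_boxes$start_s
  fb_stop <- focal_boxes$stop_s
  feasible <- function(s) {
    e <- s + w
    s >= 0 && e <= file_duration_s && !any(fb_start < e & fb_stop > s)
  }
  gap_of <- function(s) {
    e <- s + w
    if (e <= box$start_s) box$start_s - e
    else if (s >= box$stop_s) s - box$stop_s
    else 0 # overlapping the (non-focal) target span itself cannot happen:
           # the target is focal, so such windows are infeasible anyway
  }
  # candidate starts: sliding outward from the box plus every edge-anchored
  # window and the file boundaries, visited in increasing-gap order with
  # ties toward earlier time
  gaps <- seq(0, file_duration_s, by = cfg$search_step_s)
  cand <- c(box$start_s - w - gaps, box$stop_s + gaps,
            fb_stop, fb_start - w, 0, file_duration_s - w)
  cand <- unique(cand[cand >= 0 & cand + w <= file_duration_s])
  gaps_c <- vapply(cand, gap_of, numeric(1))
  ord <- order(gaps_c, cand)
  for (i in ord) {
    if (feasible(cand[i])) {
      return(c(start_s = cand[i], stop_s = cand[i] + w))
    }
  }
  abort("no clean noise window in file")
}

#' Estimate per-call signal-to-noise ratio
#'
#' SNR in dB of each call: `20*log10(rms(call span) / rms(noise window))`,
#' with the noise window chosen by [select_noise_window()]. Everything that
#' is not a focal call (other callers, ambient sound) counts as noise; only
#' focal boxes exclude a window. Calls with SNR above `clip_snr_db` are
#' flagged (`excluded_clipping`) as containing clipping artifacts. Calls
#' for which no clean window exists are skipped with a warning.
#'
#' @param samples Waveform in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @param boxes Selection table of target (focal) calls to measure.
#' @param focal_boxes Selection table of all focal calls in the file used
#'   for window exclusion; defaults to `boxes`.
#' @param cfg An [snr_config()].
#' @return A tibble with one row per measured call: box columns plus
#'   `signal_rms`, `noise_rms`, `snr_db`, `noise_start_s`, `noise_stop_s`,
#'   `excluded_clipping`.
#' @export
estimate_snr <- function(samples, sample_rate, boxes, focal_boxes = boxes,
                         cfg = snr_config()) {
  boxes <- validate_selection_table(boxes, "boxes")
  dur <- length(samples) / sample_rate
  rows <- purrr::map(seq_len(nrow(boxes)), function(k) {
    b <- boxes[k, ]
    win <- tryCatch(select_noise_window(b, focal_boxes, dur, cfg),
                    error = function(e) NULL)
    if (is.null(win)) return(NULL)
    sig <- rms(samples[span_samples(b$start_s, b$stop_s, sample_rate, length(samples))])
    noi <- rms(samples[span_samples(win[1], win[2], sample_rate, length(samples))])
    snr <- 20 * log10(sig / noi)
    dplyr::mutate(b, signal_rms = sig, noise_rms = noi, snr_db = snr,
                  noise_start_s = win[1], noise_stop_s = win[2],
                  excluded_clipping = snr > cfg$clip_snr_db)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) {
    rlang::warn(sprintf("%d call(s) skipped: no clean noise window", skipped))
  }
  dplyr::bind_rows(rows)
}

#' Split SNR records at the clipping threshold
#'
#' Records with `snr_db` strictly above `clip_snr_db` are treated as
#' clipping artifacts; a record at exactly the threshold is kept.
#'
#' @param records Tibble from [estimate_snr()].
#' @param cfg An [snr_config()].
#' @return A list with `kept` and `excluded` tibbles.
#' @export
filter_clipping <- function(records, cfg = snr_config()) {
  ex <- records$snr_db > cfg$clip_snr_db
  list(kept = records[!ex, , drop = FALSE],
       excluded = records[ex, , drop = FALSE])
}

#' Subsample chick calls per individual and day
#'
#' For every `(individual_id, day)` group with at least `per_day_n`
#' detections, samples exactly `per_day_n` of them without replacement
#' under the seed; smaller groups contribute nothing.
#'
#' @param detections Selection table with `individual_id` and `day` columns
#'   (`day` is the calendar day of the enclosing file's start time).
#' @param per_day_n Sample size per group (default 100).
#' @param seed Integer seed; the draw is reproducible and leaves the
#'   caller's RNG state untouched.
#' @return The sampled selection table.
#' @export
sample_chick_calls <- function(detections, per_day_n = 100, seed = 1L) {
  if (!all(c("individual_id", "day") %in% names(detections))) {
    abort("detections must carry individual_id and day columns")
  }
  withr::with_seed(as.integer(seed), {
    out <- detections |>
      dplyr::group_by(.data$individual_id, .data$day) |>
      dplyr::group_modify(function(g, key) {
        if (nrow(g) < per_day_n) g[0, ] else g[sample.int(nrow(g), per_day_n), ]
      }) |>
      dplyr::ungroup()
  })
  dplyr::arrange(out, .data$start_s)
}

#' Five-number distribution summary
#'
#' Quartiles by linear interpolation (type 7) and Tukey whisker bounds at
#' 1.5 times the interquartile range, matching the boxplot convention used
#' for per-individual SNR distributions.
#'
#' @param values Numeric vector, at least one value.
#' @return A one-row tibble: `median`, `q1`, `q3`, `iqr`, `whisker_lo`,
#'   `whisker_hi`, `n`.
#' @export
summarize_distribution <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("no values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  tibble(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
         whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[3] + 1.5 * iqr,
         n = length(values))
}

#' Normalized amplitude density curves
#'
#' Gaussian-kernel density of two sets of call levels on a shared dBFS
#' grid, each curve normalized to integrate to 1 so groups of different
#' sizes are comparable.
#'
#' @param levels_a,levels_b Numeric vectors of call levels in dBFS.
#' @param n_grid Number of grid points.
#' @param group_names Length-2 character vector naming the groups.
#' @return A tibble with columns `level_dbfs`, `density`, `group`.
#' @export
amplitude_density <- function(levels_a, levels_b, n_grid = 512,
                              group_names = c("a", "b")) {
  if (length(levels_a) == 0 || length(levels_b) == 0) {
    abort("both level sets must be nonempty")
  }
  lo <- min(levels_a, levels_b)
  hi <- max(levels_a, levels_b)
  pad <- 0.1 * (hi - lo) + 1
  grid <- seq(lo - pad, hi + pad, length.out = n_grid)
  one <- function(x, nm) {
    d <- stats::density(x, from = min(grid), to = max(grid), n = n_grid)
    y <- d$y / trapz(grid, d$y)
    tibble(level_dbfs = grid, density = y, group = nm)
  }
  dplyr::bind_rows(one(levels_a, group_names[1]), one(levels_b, group_names[2]))
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
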