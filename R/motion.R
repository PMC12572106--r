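# Tri-axial acceleration processing: normalization, decimation, zero-delay
# static/dynamic decomposition, dive clip extraction, low-amplitude
# segmentation, banking-peak detection, segment classification and the
# exact two-sided Fisher test.

#' Motion analysis configuration
#'
#' @param decim_factor Decimation factor from tag-native to working rate
#'   (200 Hz / 4 = 50 Hz).
#' @param hp_cutoff_hz High-pass cutoff separating dynamic from static
#'   acceleration (3 Hz, chosen by visual inspection in the source study's
#'   regime of wingbeat vs posture frequencies).
#' @param fir_taps Odd FIR length for the linear-phase Hamming-window
#'   high-pass; group delay `(fir_taps-1)/2` samples is corrected exactly.
#' @param peak_height_g Minimum static-z value (in normalized g) for a
#'   banking peak.
#' @param peak_min_sep_samples Minimum spacing between retained peaks in
#'   samples (50 samples = 1 s at 50 Hz).
#' @param clip_half_width_s Half-width of dive clips around annotated dive
#'   timepoints (60 s).
#' @param quiet_span_s,quiet_mag_g A separator is at least `quiet_span_s`
#'   seconds with dynamic vector magnitude below `quiet_mag_g` throughout.
#' @param min_segment_s Active segments longer than this are retained.
#' @param spec_nfft,spec_hop,spec_win STFT parameters for the z-axis
#'   spectrogram.
#' @return A list of class `motion_config`.
#' @export
motion_config <- function(decim_factor = 4, hp_cutoff_hz = 3.0, fir_taps = 67,
                          peak_height_g = 1.8, peak_min_sep_samples = 50,
                          clip_half_width_s = 60, quiet_span_s = 5.0,
                          quiet_mag_g = 0.2, min_segment_s = 20.0,
                          spec_nfft = 128, spec_hop = 12, spec_win = 128) {
  if (fir_taps %% 2 == 0) abort("fir_taps must be odd")
  if (peak_min_sep_samples < 1) abort("peak_min_sep_samples must be >= 1")
  vals <- c(decim_factor, hp_cutoff_hz, peak_height_g, clip_half_width_s,
            quiet_span_s, quiet_mag_g, min_segment_s, spec_nfft, spec_hop,
            spec_win)
  if (any(vals <= 0)) abort("all motion_config values must be positive")
  structure(list(decim_factor = decim_factor, hp_cutoff_hz = hp_cutoff_hz,
                 fir_taps = fir_taps, peak_height_g = peak_height_g,
                 peak_min_sep_samples = peak_min_sep_samples,
                 clip_half_width_s = clip_half_width_s,
                 quiet_span_s = quiet_span_s, quiet_mag_g = quiet_mag_g,
                 min_segment_s = min_segment_s, spec_nfft = spec_nfft,
                 spec_hop = spec_hop, spec_win = spec_win),
            class = "motion_config")
}

accel_magnitude <- function(accel) {
  sqrt(accel$ax^2 + accel$ay^2 + accel$az^2)
}

#' Normalize an acceleration table
#'
#' Scales all three axes by one common factor so the average magnitude of
#' the acceleration vector equals 1 (field strength 1 g); a minimal
#' calibration standing in for per-axis offset/gain correction.
#'
#' @param accel An [accel_table()].
#' @return The normalized table (mean vector magnitude 1 within 1e-9).
#' @export
normalize_accel <- function(accel) {
  m <- mean(accel_magnitude(accel))
  if (!is.finite(m) || m == 0) abort("cannot normalize an all-zero trace")
  out <- accel
  out$ax <- accel$ax / m
  out$ay <- accel$ay / m
  out$az <- accel$az / m
  out
}

fir_zero_phase <- function(x, h) {
  # linear-phase FIR with reflect padding and exact group-delay correction,
  # so the output is time-aligned with the input and of equal length
  L <- length(h)
  n <- length(x)
  if (n <= L) abort("trace too short for the FIR filter")
  pad <- L - 1
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  y <- stats::filter(xp, h, method = "convolution", sides = 1)
  y <- as.numeric(y)
  delay <- (L - 1) / 2
  start <- pad + 1 + delay
  y[start:(start + n - 1)]
}

#' Decimate an acceleration table
#'
#' Anti-alias low-pass (zero-phase Hamming FIR, cutoff 0.8 times the target
#' Nyquist) followed by keeping every `factor`-th sample.
#'
#' @param accel An [accel_table()].
#' @param factor Integer decimation factor (default from `cfg`).
#' @param cfg A [motion_config()].
#' @return The decimated table with updated sampling rate.
#' @export
decimate_accel <- function(accel, factor = NULL, cfg = motion_config()) {
  factor <- factor %||% cfg$decim_factor
  if (factor < 1) abort("decimation factor must be >= 1")
  if (factor == 1) return(accel)
  fs <- accel_fs(accel)
  cutoff <- 0.8 * (fs / factor / 2)
  h <- signal::fir1(cfg$fir_taps - 1, cutoff / (fs / 2), type = "low",
                    window = signal::hamming(cfg$fir_taps))
  h <- h / sum(h) # exact unity DC gain: constants pass through untouched
  keep <- seq(1, nrow(accel), by = factor)
  accel_table(fir_zero_phase(accel$ax, h)[keep],
              fir_zero_phase(accel$ay, h)[keep],
              fir_zero_phase(accel$az, h)[keep],
              fs = fs / factor, t0 = accel$t[1])
}

#' Split acceleration into static and dynamic components
#'
#' The dynamic component is the output of a delay-free high-pass: a
#' linear-phase symmetric FIR (Hamming window, cutoff `hp_cutoff_hz`)
#' followed by exact group-delay correction, with reflect-padded edges so
#' output length equals input length. The static component is the raw
#' signal minus the dynamic component, so `static + dynamic = raw` holds
#' sample-exactly.
#'
#' @param accel An [accel_table()].
#' @param cfg A [motion_config()].
#' @return A list with `static` and `dynamic` acceleration tables.
#' @export
decompose_static_dynamic <- function(accel, cfg = motion_config()) {
  fs <- accel_fs(accel)
  if (nrow(accel) <= cfg$fir_taps) abort("trace too short to decompose")
  h <- signal::fir1(cfg$fir_taps - 1, cfg$hp_cutoff_hz / (fs / 2),
                    type = "high", window = signal::hamming(cfg$fir_taps))
  h <- h - sum(h) / length(h) # exact zero DC gain, symmetry preserved
  dyn <- accel_table(fir_zero_phase(accel$ax, h), fir_zero_phase(accel$ay, h),
                     fir_zero_phase(accel$az, h), fs = fs, t0 = accel$t[1])
  sta <- accel_table(accel$ax - dyn$ax, accel$ay - dyn$ay, accel$az - dyn$az,
                     fs = fs, t0 = accel$t[1])
  list(static = sta, dynamic = dyn)
}

#' Extract dive clips around annotated timepoints
#'
#' Cuts a clip of `[time - 60 s, time + 60 s]` (per `clip_half_width_s`)
#' around each annotated dive timepoint, clamped to the trace bounds;
#' overlapping clips are merged into one longer clip.
#'
#' @param accel An [accel_table()].
#' @param dive_times_s Numeric vector of annotated dive timepoints.
#' @param cfg A [motion_config()].
#' @return A list of acceleration tables, one per (merged) clip.
#' @export
extract_dive_clips <- function(accel, dive_times_s, cfg = motion_config()) {
  if (length(dive_times_s) == 0) return(list())
  t0 <- accel$t[1]
  t1 <- accel$t[nrow(accel)]
  if (any(dive_times_s < t0 | dive_times_s > t1)) {
    abort("dive times must lie within the trace")
  }
  iv <- tibble(start = pmax(t0, sort(dive_times_s) - cfg$clip_half_width_s),
               stop = pmin(t1, sort(dive_times_s) + cfg$clip_half_width_s))
  merged <- iv[1, ]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv$start[k] <= merged$stop[last]) {
      merged$stop[last] <- max(merged$stop[last], iv$stop[k])
    } else {
      merged <- dplyr::bind_rows(merged, iv[k, ])
    }
  }
  purrr::map(seq_len(nrow(merged)), function(k) {
    sub <- accel[accel$t >= merged$start[k] & accel$t <= merged$stop[k], ]
    attr(sub, "fs") <- accel_fs(accel)
    class(sub) <- c("accel_tbl", setdiff(class(sub), "accel_tbl"))
    sub
  })
}

#' Segment a clip at sustained low dynamic amplitude
#'
#' Separators are maximal runs of at least `quiet_span_s` seconds during
#' which the dynamic-component vector magnitude stays below `quiet_mag_g`
#' throughout (the dynamic component is used because gravity keeps the raw
#' magnitude near 1 g). The remaining active spans are retained if longer
#' than `min_segment_s`.
#'
#' @param clip An [accel_table()] (raw; decomposed internally).
#' @param cfg A [motion_config()].
#' @param category Segment category attached to every returned row.
#' @return A tibble of segments: `start_s`, `stop_s`, `category`.
#' @export
split_low_amplitude <- function(clip, cfg = motion_config(),
                                category = "dive") {
  fs <- accel_fs(clip)
  dyn <- decompose_static_dynamic(clip, cfg)$dynamic
  quiet <- accel_magnitude(dyn) < cfg$quiet_mag_g
  min_run <- ceiling(cfg$quiet_span_s * fs)
  runs <- run_lengths_true(quiet)
  seps <- runs[runs$end - runs$start + 1 >= min_run, , drop = FALSE]
  n <- nrow(clip)
  active_start <- c(1, seps$end + 1)
  active_end <- c(seps$start - 1, n)
  keep <- active_end >= active_start
  out <- tibble(
    start_s = clip$t[active_start[keep]],
    stop_s = clip$t[active_end[keep]] + 1 / fs,
    category = category
  )
  out[out$stop_s - out$start_s > cfg$min_segment_s, , drop = FALSE]
}

#' Detect banking peaks in static z-acceleration
#'
#' Local maxima of the series with value at least `peak_height_g`; among
#' maxima closer than `peak_min_sep_samples` samples the higher one wins
#' (ties: the earlier). This mirrors the height/distance peak-picking
#' parameterization standard in signal-processing toolkits.
#'
#' @param z Numeric series (static z-acceleration in normalized g).
#' @param cfg A [motion_config()].
#' @param fs Sampling rate used to convert peak indices to times; if `NULL`
#'   indices are returned.
#' @param t0 Time of the first sample.
#' @return Peak times in seconds (or 1-based indices if `fs` is `NULL`),
#'   in time order.
#' @export
detect_static_peaks <- function(z, cfg = motion_config(), fs = NULL, t0 = 0) {
  n <- length(z)
  if (n < 3) return(if (is.null(fs)) integer() else numeric())
  # local maxima with plateau handling: a flat top peaks at its midpoint
  idx <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (z[i] > z[i - 1L]) {
      j <- i
      while (j < n && z[j + 1L] == z[i]) j <- j + 1L
      if (j < n && z[j + 1L] < z[i]) {
        idx <- c(idx, (i + j) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  idx <- idx[z[idx] >= cfg$peak_height_g]
  if (length(idx) > 1) {
    # greedy suppression: highest first, earlier wins ties
    ord <- order(-z[idx], idx)
    keep <- logical(length(idx))
    suppressed <- logical(length(idx))
    for (k in ord) {
      if (suppressed[k]) next
      keep[k] <- TRUE
      suppressed[abs(idx - idx[k]) < cfg$peak_min_sep_samples] <- TRUE
    }
    idx <- sort(idx[keep])
  }
  if (is.null(fs)) idx else t0 + (idx - 1) / fs
}

#' Tally segments into a 2x2 contingency table
#'
#' Rows are the segment category (dive / non-dive), columns whether the
#' segment contains at least one static-z banking peak.
#'
#' @param segments Tibble with columns `category` (values `"dive"` or
#'   `"non_dive"`) and `has_peak` (logical), e.g. from [analyze_dives()].
#' @return A 2x2 integer matrix with dimnames, class `contingency_2x2`.
#' @export
classify_segments <- function(segments) {
  if (nrow(segments) > 0 && !all(segments$category %in% c("dive", "non_dive"))) {
    abort("segment category must be 'dive' or 'non_dive'")
  }
  tab <- matrix(0L, 2, 2,
                dimnames = list(c("dive", "non_dive"), c("peak", "no_peak")))
  for (k in seq_len(nrow(segments))) {
    row <- segments$category[k]
    col <- if (isTRUE(segments$has_peak[k])) "peak" else "no_peak"
    tab[row, col] <- tab[row, col] + 1L
  }
  class(tab) <- c("contingency_2x2", class(tab))
  tab
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of
#' every table whose probability does not exceed that of the observed table
#' (with 1e-12 relative slack for floating-point ties). Probabilities are
#' computed in log space via `lchoose` for stability.
#'
#' @param tbl A 2x2 matrix of counts `rbind(c(a, b), c(c, d))`, or a
#'   `contingency_2x2`.
#' @return The exact two-sided p-value.
#' @export
fisher_exact_two_sided <- function(tbl) {
  tbl <- unclass(tbl)
  if (!is.matrix(tbl) || any(dim(tbl) != 2) || any(tbl < 0)) {
    abort("`tbl` must be a nonnegative 2x2 matrix")
  }
  a <- tbl[1, 1]; b <- tbl[1, 2]; cc <- tbl[2, 1]; d <- tbl[2, 2]
  m <- a + b       # row 1 total
  n2 <- cc + d     # row 2 total
  k <- a + cc      # column 1 total
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) {
    abort("degenerate table: a margin is zero")
  }
  support <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, support) + lchoose(n2, k - support) - lchoose(m + n2, k)
  logp_obs <- lchoose(m, a) + lchoose(n2, cc) - lchoose(m + n2, k)
  min(1, sum(exp(logp[logp <= logp_obs + 1e-12 * abs(logp_obs)])))
}

#' Spectrogram of an acceleration series
#'
#' Centered short-time Fourier transform magnitude with a periodic Hann
#' window (`spec_win` samples, hop `spec_hop`, `spec_nfft`-point FFT) and
#' reflect padding, returning frequency rows from 0 to the Nyquist rate.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param cfg A [motion_config()].
#' @return A list with `magnitude` (matrix, frequencies by frames),
#'   `freq_hz`, `time_s`.
#' @export
accel_spectrogram <- function(x, fs, cfg = motion_config()) {
  win <- cfg$spec_win
  hop <- cfg$spec_hop
  nfft <- cfg$spec_nfft
  n <- length(x)
  if (n < win) abort("series shorter than the analysis window")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / win) # periodic Hann
  pad <- win %/% 2
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  starts <- seq(1, length(xp) - win + 1, by = hop)
  mag <- vapply(starts, function(s) {
    frame <- xp[s:(s + win - 1)] * w
    if (nfft > win) frame <- c(frame, rep(0, nfft - win))
    abs(stats::fft(frame))[1:(nfft %/% 2 + 1)]
  }, numeric(nfft %/% 2 + 1))
  list(magnitude = mag,
       freq_hz = (0:(nfft %/% 2)) * fs / nfft,
       time_s = (starts - 1) / fs)
}

#' Dive versus non-dive flight analysis
#'
#' End-to-end comparison of annotated dive events against non-dive flight
#' intervals: extracts 2-minute clips around dive timepoints, normalizes
#' each clip, splits static from dynamic acceleration, segments clips at
#' sustained low dynamic amplitude, detects banking peaks in static z
#' within every segment, tallies the 2x2 contingency table of segment
#' category by peak presence, and tests the association with the exact
#' two-sided Fisher test.
#'
#' @param accel An [accel_table()] at the working rate (50 Hz).
#' @param dive_times_s Annotated dive timepoints in seconds.
#' @param flight_spans Tibble with `start_s`, `stop_s`: manually identified
#'   non-dive flight intervals, used as segments directly.
#' @param cfg A [motion_config()].
#' @return A list of class `dive_test`: `segments` (tibble with category,
#'   bounds, `peak_times_s`, `has_peak`), `table` (2x2), `p_value`.
#' @export
analyze_dives <- function(accel, dive_times_s, flight_spans = NULL,
                          cfg = motion_config()) {
  fs <- accel_fs(accel)
  clips <- extract_dive_clips(accel, dive_times_s, cfg)
  if (!is.null(flight_spans) && nrow(flight_spans) > 0) {
    # each non-dive flight interval is its own clip and its own segment
    flight_clips <- purrr::map(seq_len(nrow(flight_spans)), function(k) {
      sub <- accel[accel$t >= flight_spans$start_s[k] &
                     accel$t < flight_spans$stop_s[k], ]
      attr(sub, "fs") <- fs
      class(sub) <- c("accel_tbl", setdiff(class(sub), "accel_tbl"))
      sub
    })
  } else {
    flight_clips <- list()
  }
  one_clip <- function(clip, category, presegmented) {
    clip <- normalize_accel(clip)
    parts <- decompose_static_dynamic(clip, cfg)
    if (presegmented) {
      segs <- tibble(start_s = clip$t[1], stop_s = clip$t[nrow(clip)] + 1 / fs,
                     category = category)
    } else {
      segs <- split_low_amplitude(clip, cfg, category = category)
    }
    segs$peak_times_s <- purrr::map(seq_len(nrow(segs)), function(k) {
      in_seg <- clip$t >= segs$start_s[k] & clip$t < segs$stop_s[k]
      # peaks over the whole clip's static z, restricted to the segment
      pk <- detect_static_peaks(parts$static$az, cfg, fs = fs, t0 = clip$t[1])
      pk[pk >= segs$start_s[k] & pk < segs$stop_s[k]]
    })
    segs
  }
  segs <- dplyr::bind_rows(
    purrr::map(clips, one_clip, category = "dive", presegmented = FALSE),
    purrr::map(flight_clips, one_clip, category = "non_dive",
               presegmented = TRUE)
  )
  segs$has_peak <- vapply(segs$peak_times_s, function(p) length(p) > 0, logical(1))
  tab <- classify_segments(segs)
  p <- tryCatch(fisher_exact_two_sided(tab), error = function(e) NA_real_)
  structure(list(segments = segs, table = tab, p_value = p, cfg = cfg),
            class = "dive_test")
}

#' @export
print.dive_test <- function(x, ...) {
  cat("Dive vs non-dive flight comparison (static-z banking peaks)\n")
  print(unclass(x$table))
  cat(sprintf("Fisher exact two-sided p = %.4g\n", x$p_value))
  invisible(x)
}
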