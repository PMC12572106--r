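# Seeded synthetic-data generators: soundscapes with known call boxes,
# detection scenarios with known confusion counts, and tri-axial
# acceleration traces with known dive peaks and segment boundaries.
# Every generator is deterministic given its spec and seed.
#
# Level convention: all generator levels (call peak_dbfs, noise_dbfs) are
# peak-equivalent dBFS, i.e. the level of a full-scale sine is 0 dBFS and a
# signal quoted at L dBFS has RMS 10^((L - 3.01)/20). Measured RMS levels
# therefore sit ~3 dB below the quoted peak level, and the SNR of a call at
# Lc over noise at Ln is Lc - Ln.

#' Soundscape specification
#'
#' Describes a synthetic tag soundscape: Gaussian background noise at a
#' fixed level plus harmonic call bursts with known onsets, durations,
#' peak levels and labels, optionally passed through a single-pole
#' high-pass emulating the tag's analogue front end.
#'
#' @param duration_s Total duration in seconds.
#' @param sample_rate_hz Sampling rate (tag native rate is 46875 Hz; the
#'   default 8000 Hz keeps desk-scale runs fast).
#' @param noise_dbfs Background noise level, peak-equivalent dBFS.
#' @param calls Tibble with columns `onset_s`, `duration_s`, `peak_dbfs`,
#'   `label` and optionally `f0_hz` (fundamental, default 1200 Hz).
#' @param front_end_hp_hz Corner (-3 dB) frequency of the single-pole
#'   front-end high-pass, or `NULL` to disable. Default 500 Hz.
#' @param seed Integer seed.
#' @return A list of class `soundscape_spec`.
#' @export
soundscape_spec <- function(duration_s, sample_rate_hz = 8000,
                            noise_dbfs = -60,
                            calls = tibble(onset_s = numeric(),
                                           duration_s = numeric(),
                                           peak_dbfs = numeric(),
                                           label = character()),
                            front_end_hp_hz = 500, seed = 1L) {
  calls <- as_tibble(calls)
  if (nrow(calls) > 0) {
    if (any(calls$duration_s <= 0)) abort("call durations must be > 0")
    if (any(calls$onset_s < 0 | calls$onset_s + calls$duration_s > duration_s)) {
      abort("call spans must lie within [0, duration_s)")
    }
    if (any(calls$peak_dbfs < -80 | calls$peak_dbfs > 0)) {
      abort("peak_dbfs must be in [-80, 0]")
    }
  }
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 noise_dbfs = noise_dbfs, calls = calls,
                 front_end_hp_hz = front_end_hp_hz, seed = as.integer(seed)),
            class = "soundscape_spec")
}

tukey_window <- function(n, alpha = 0.25) {
  # flat-topped cosine-tapered amplitude envelope
  if (n == 1) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (x[hi] - 1) / alpha + 1)))
  w
}

single_pole_highpass <- function(x, fc, fs) {
  # first-order recursive high-pass, -3 dB near fc:
  # y[n] = a*(y[n-1] + x[n] - x[n-1])
  a <- single_pole_coef(fc, fs)
  dx <- c(x[1], diff(x))
  as.numeric(stats::filter(a * dx, a, method = "recursive"))
}

single_pole_coef <- function(fc, fs) {
  rc <- 1 / (2 * pi * fc)
  rc / (rc + 1 / fs)
}

single_pole_gain <- function(f, fc, fs) {
  # magnitude response of the discrete one-pole high-pass at frequency f
  a <- single_pole_coef(fc, fs)
  w <- 2 * pi * f / fs
  a * abs(1 - exp(-1i * w)) / Mod(1 - a * exp(-1i * w))
}

#' Generate a synthetic soundscape
#'
#' Synthesizes Gaussian background noise plus one harmonic burst per
#' specified call (three harmonics of the fundamental under a Tukey
#' envelope, scaled so the measured RMS level over the call span sits close
#' to `peak_dbfs - 3`), then optionally applies the single-pole front-end
#' high-pass. Identical spec and seed give bit-identical samples.
#'
#' @param spec A [soundscape_spec()].
#' @return A list with `samples`, `sample_rate`, and `annotations` (the
#'   exact ground-truth selection table).
#' @export
generate_soundscape <- function(spec) {
  stopifnot(inherits(spec, "soundscape_spec"))
  fs <- spec$sample_rate_hz
  n <- round(spec$duration_s * fs)
  withr::with_seed(spec$seed, {
    sigma <- 10^(spec$noise_dbfs / 20) / sqrt(2)
    if (!is.null(spec$front_end_hp_hz)) {
      # pre-compensate the broadband loss of the front-end high-pass so the
      # measured background level matches the spec after filtering
      fgrid <- seq(1, fs / 2, length.out = 512)
      sigma <- sigma / sqrt(mean(single_pole_gain(fgrid, spec$front_end_hp_hz, fs)^2))
    }
    x <- stats::rnorm(n, sd = sigma)
    calls <- spec$calls
    if (nrow(calls) > 0) {
      f0 <- if ("f0_hz" %in% names(calls)) calls$f0_hz else rep(1200, nrow(calls))
      for (k in seq_len(nrow(calls))) {
        i0 <- round(calls$onset_s[k] * fs) + 1
        len <- max(2, round(calls$duration_s[k] * fs))
        tt <- (seq_len(len) - 1) / fs
        # harmonic mix with unit sum-of-squares, scaled so the flat-envelope
        # RMS equals the peak-equivalent target amplitude / sqrt(2); each
        # harmonic is pre-compensated for the front-end response so the
        # measured level after filtering hits the target
        amps <- c(0.7, 0.2, 0.1)
        amps <- amps / sqrt(sum(amps^2)) * 10^(calls$peak_dbfs[k] / 20)
        if (!is.null(spec$front_end_hp_hz)) {
          gains <- single_pole_gain((1:3) * f0[k], spec$front_end_hp_hz, fs)
          amps <- amps / gains
        }
        burst <- amps[1] * sin(2 * pi * f0[k] * tt) +
          amps[2] * sin(2 * pi * 2 * f0[k] * tt) +
          amps[3] * sin(2 * pi * 3 * f0[k] * tt)
        burst <- burst * tukey_window(len)
        idx <- i0:(i0 + len - 1)
        x[idx] <- x[idx] + burst
      }
    }
  })
  if (!is.null(spec$front_end_hp_hz)) {
    x <- single_pole_highpass(x, spec$front_end_hp_hz, fs)
  }
  if (length(x) > 0 && max(abs(x)) > 1) {
    abort("generated soundscape exceeds full scale; lower call or noise levels")
  }
  ann <- tibble(
    start_s = spec$calls$onset_s,
    stop_s = spec$calls$onset_s + spec$calls$duration_s,
    label = if (nrow(spec$calls)) spec$calls$label else character(),
    detection_prob = rep(1, nrow(spec$calls)),
    file_id = rep("synthetic", nrow(spec$calls))
  )
  list(samples = x, sample_rate = fs,
       annotations = validate_selection_table(ann))
}

#' Detection scenario specification
#'
#' Describes a synthetic evaluation scenario: ground-truth annotations for
#' the four scored classes, and predictions derived from them by boundary
#' jitter, misses, spurious insertions and label flips.
#'
#' @param n_events Events per scored class.
#' @param mean_duration_s Mean call duration (median call duration in the
#'   annotated tag data is 0.33 s).
#' @param jitter_frac Boundary perturbation as a fraction of call duration.
#' @param miss_rate,spurious_rate,label_flip_rate Probabilities of a missed
#'   annotation, a spurious insertion (per true event), and a label flip.
#' @param duration_s Scene length over which events are placed.
#' @param seed Integer seed.
#' @return A list of class `detection_scenario_spec`.
#' @export
detection_scenario_spec <- function(n_events = 20, mean_duration_s = 0.33,
                                    jitter_frac = 0, miss_rate = 0,
                                    spurious_rate = 0, label_flip_rate = 0,
                                    duration_s = NULL, seed = 1L) {
  rates <- c(miss_rate, spurious_rate, label_flip_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must be in [0, 1]")
  if (n_events < 0) abort("n_events must be >= 0")
  total <- n_events * 4
  duration_s <- duration_s %||% max(10, total * mean_duration_s * 6)
  structure(list(n_events = n_events, mean_duration_s = mean_duration_s,
                 jitter_frac = jitter_frac, miss_rate = miss_rate,
                 spurious_rate = spurious_rate,
                 label_flip_rate = label_flip_rate,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "detection_scenario_spec")
}

#' Generate a detection scenario with known confusion counts
#'
#' Places `n_events` non-overlapping annotations per scored class, then
#' derives predictions by seeded boundary jitter, deletions (`miss_rate`),
#' label flips (`label_flip_rate`, flipped uniformly to another scored
#' class) and spurious insertions (`spurious_rate` per true event, placed
#' clear of all annotations). The expected per-class confusion counts are
#' computed internally with the exhaustive matcher
#' ([match_boxes_exhaustive()]) and returned as ground truth.
#'
#' @param spec A [detection_scenario_spec()].
#' @param cfg An [eval_config()] used for the internal exhaustive matching.
#' @return A list with `annotations`, `predictions` (selection tables) and
#'   `expected_counts` (tibble `class`, `tp`, `fp`, `fn`).
#' @export
generate_detection_scenario <- function(spec, cfg = eval_config()) {
  stopifnot(inherits(spec, "detection_scenario_spec"))
  total <- spec$n_events * 4
  withr::with_seed(spec$seed, {
    # non-overlapping slots with at least one call-length of clearance
    slot <- spec$duration_s / max(1, total)
    onsets <- (seq_len(total) - 1) * slot +
      stats::runif(total, 0, max(0, slot - 2.5 * spec$mean_duration_s))
    durs <- stats::runif(total, 0.6, 1.4) * spec$mean_duration_s
    labels <- rep(scored_classes(), each = spec$n_events)
    ord <- if (total > 0) sample.int(total) else integer()
    ann <- tibble(start_s = onsets, stop_s = onsets + durs,
                  label = labels[ord], detection_prob = 1,
                  file_id = "scenario")
    kept <- if (total > 0) stats::runif(total) >= spec$miss_rate else logical()
    pred <- ann[kept, , drop = FALSE]
    if (nrow(pred) > 0) {
      d <- pred$stop_s - pred$start_s
      pred$start_s <- pred$start_s + stats::runif(nrow(pred), -1, 1) * spec$jitter_frac * d
      pred$stop_s <- pred$stop_s + stats::runif(nrow(pred), -1, 1) * spec$jitter_frac * d
      pred$start_s <- pmax(0, pred$start_s)
      flip <- stats::runif(nrow(pred)) < spec$label_flip_rate
      if (any(flip)) {
        pred$label[flip] <- vapply(pred$label[flip], function(l) {
          sample(setdiff(scored_classes(), l), 1)
        }, character(1))
      }
    }
    n_spur <- stats::rbinom(1, max(0, total), spec$spurious_rate)
    if (n_spur > 0) {
      # spurious boxes sit inside the clearance zone after each slot's call,
      # so they never reach IoU > 0 with any annotation
      host <- sample.int(max(1, total), n_spur, replace = TRUE)
      s0 <- (host - 1) * slot + slot - 1.1 * spec$mean_duration_s
      spur <- tibble(start_s = s0,
                     stop_s = s0 + spec$mean_duration_s,
                     label = sample(scored_classes(), n_spur, replace = TRUE),
                     detection_prob = 1, file_id = "scenario")
      pred <- dplyr::bind_rows(pred, spur)
    }
    pred$detection_prob <- 1
  })
  ann <- validate_selection_table(ann)
  pred <- validate_selection_table(pred)
  ref <- match_boxes_exhaustive(ann, pred, cfg)
  list(annotations = ann, predictions = pred,
       expected_counts = confusion_counts(ref, cfg))
}

#' Acceleration scenario specification
#'
#' Describes a synthetic tri-axial acceleration trace in g: gravity along a
#' fixed axis, a wingbeat sinusoid on the dorsoventral (z) axis, slow
#' banking excursions during dives (sub-3-Hz Gaussian bumps on the static z
#' channel), brief landing impulses, quiescent gaps with the wingbeat
#' suppressed, and white sensor noise.
#'
#' @param duration_s Trace length in seconds.
#' @param fs Sampling rate in Hz (working rate 50 Hz).
#' @param wingbeat_hz Wingbeat frequency (free parameter; default 5 Hz).
#' @param wingbeat_amp_g Wingbeat amplitude in g.
#' @param dive_events Tibble with columns `time_s`, `bank_peak_g`,
#'   `bank_width_s`: the static-z excursion reaches `bank_peak_g` at
#'   `time_s` with Gaussian half-width `bank_width_s`.
#' @param quiet_gaps Tibble with columns `start_s`, `stop_s`: spans where
#'   the wingbeat is suppressed (dynamic magnitude falls to the noise floor).
#' @param landing_impulses Numeric vector of impulse times in seconds.
#' @param gravity_axis Unit 3-vector, default `c(0, 0, 1)` (z up).
#' @param noise_sd_g Sensor noise s.d. per axis (default 0.02 g).
#' @param seed Integer seed.
#' @return A list of class `accel_scenario_spec`.
#' @export
accel_scenario_spec <- function(duration_s, fs = 50, wingbeat_hz = 5,
                                wingbeat_amp_g = 0.4,
                                dive_events = tibble(time_s = numeric(),
                                                     bank_peak_g = numeric(),
                                                     bank_width_s = numeric()),
                                quiet_gaps = tibble(start_s = numeric(),
                                                    stop_s = numeric()),
                                landing_impulses = numeric(),
                                gravity_axis = c(0, 0, 1),
                                noise_sd_g = 0.02, seed = 1L) {
  dive_events <- as_tibble(dive_events)
  quiet_gaps <- as_tibble(quiet_gaps)
  if (fs <= 2 * wingbeat_hz) abort("fs must exceed twice the wingbeat frequency")
  if (nrow(dive_events) > 0) {
    if (any(dive_events$time_s < 0 | dive_events$time_s > duration_s)) {
      abort("dive event times must lie within the trace")
    }
    if (any(dive_events$bank_width_s <= 0)) abort("bank_width_s must be > 0")
  }
  if (any(landing_impulses < 0 | landing_impulses > duration_s)) {
    abort("landing impulse times must lie within the trace")
  }
  gravity_axis <- gravity_axis / sqrt(sum(gravity_axis^2))
  structure(list(duration_s = duration_s, fs = fs, wingbeat_hz = wingbeat_hz,
                 wingbeat_amp_g = wingbeat_amp_g, dive_events = dive_events,
                 quiet_gaps = quiet_gaps, landing_impulses = landing_impulses,
                 gravity_axis = gravity_axis, noise_sd_g = noise_sd_g,
                 seed = as.integer(seed)),
            class = "accel_scenario_spec")
}

#' Generate a synthetic acceleration trace
#'
#' Builds the trace as gravity + wingbeat sinusoid + banking excursions +
#' landing impulses + white noise, and returns it together with its ground
#' truth: the dive bump centres (where the static-z peak detector should
#' fire) and the active-segment boundaries implied by the quiet gaps.
#'
#' @param spec An [accel_scenario_spec()].
#' @return A list with `accel` (an [accel_table()]), `dive_peak_times_s`,
#'   and `active_spans` (tibble `start_s`, `stop_s` of spans between quiet
#'   gaps, unfiltered by any minimum length).
#' @export
generate_accel_trace <- function(spec) {
  stopifnot(inherits(spec, "accel_scenario_spec"))
  n <- round(spec$duration_s * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  withr::with_seed(spec$seed, {
    noise <- matrix(stats::rnorm(3 * n, sd = spec$noise_sd_g), ncol = 3)
  })
  g <- spec$gravity_axis
  ax <- g[1] + noise[, 1]
  ay <- g[2] + noise[, 2]
  az <- g[3] + noise[, 3]
  # wingbeat on the dorsoventral axis, suppressed inside quiet gaps
  env <- rep(1, n)
  if (nrow(spec$quiet_gaps) > 0) {
    for (k in seq_len(nrow(spec$quiet_gaps))) {
      env[t >= spec$quiet_gaps$start_s[k] & t < spec$quiet_gaps$stop_s[k]] <- 0
    }
  }
  az <- az + spec$wingbeat_amp_g * env * sin(2 * pi * spec$wingbeat_hz * t)
  # slow banking excursions: static-z reaches bank_peak_g at the bump centre
  if (nrow(spec$dive_events) > 0) {
    for (k in seq_len(nrow(spec$dive_events))) {
      ev <- spec$dive_events[k, ]
      bump <- (ev$bank_peak_g - g[3]) *
        exp(-(t - ev$time_s)^2 / (2 * ev$bank_width_s^2))
      az <- az + bump
    }
  }
  # landing impulses: short half-sine spikes (high-frequency, land in the
  # dynamic component)
  for (ti in spec$landing_impulses) {
    idx <- which(t >= ti & t < ti + 0.06)
    if (length(idx) > 0) {
      az[idx] <- az[idx] + 2.0 * sin(pi * seq_along(idx) / (length(idx) + 1))
    }
  }
  acc <- accel_table(ax, ay, az, fs = spec$fs)
  # active spans between quiet gaps
  gaps <- spec$quiet_gaps
  if (nrow(gaps) > 0) {
    gaps <- dplyr::arrange(gaps, .data$start_s)
    edges_start <- c(0, gaps$stop_s)
    edges_stop <- c(gaps$start_s, spec$duration_s)
    active <- tibble(start_s = edges_start, stop_s = edges_stop)
    active <- active[active$stop_s - active$start_s > 0, ]
  } else {
    active <- tibble(start_s = 0, stop_s = spec$duration_s)
  }
  list(accel = acc,
       dive_peak_times_s = if (nrow(spec$dive_events)) spec$dive_events$time_s else numeric(),
       active_spans = active)
}
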