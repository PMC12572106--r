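test_that("normalization fixes mean vector magnitude at 1 and is idempotent", {
  acc <- accel_table(rep(0, 100), rep(0, 100), rep(9.81, 100), fs = 50)
  n1 <- normalize_accel(acc)
  expect_equal(n1$az, rep(1, 100), tolerance = 1e-12)

  withr::with_seed(2, acc <- accel_table(rnorm(500, 0, 0.3), rnorm(500, 0, 0.3),
                                         rnorm(500, 1, 0.3), fs = 50))
  n1 <- normalize_accel(acc)
  expect_equal(mean(sqrt(n1$ax^2 + n1$ay^2 + n1$az^2)), 1, tolerance = 1e-9)
  expect_equal(normalize_accel(n1), n1, tolerance = 1e-12)
  expect_error(normalize_accel(accel_table(rep(0, 10), rep(0, 10),
                                           rep(0, 10), fs = 50)), "all-zero")
})

test_that("decimation preserves the passband and rejects the stopband", {
  fs <- 200
  t <- (0:3999) / fs
  cst <- accel_table(rep(0.5, 4000), rep(0.5, 4000), rep(1, 4000), fs = fs)
  d <- decimate_accel(cst, 4)
  expect_equal(accel_fs(d), 50)
  expect_equal(nrow(d), 1000)
  expect_equal(d$az, rep(1, 1000), tolerance = 1e-6)

  slow <- accel_table(sin(2 * pi * 1 * t), rep(0, 4000), rep(0, 4000), fs = fs)
  d <- decimate_accel(slow, 4)
  mid <- d$ax[100:900]
  expect_equal(max(abs(mid)), 1, tolerance = 0.01) # 1 Hz amplitude kept

  fast <- accel_table(sin(2 * pi * 40 * t), rep(0, 4000), rep(0, 4000), fs = fs)
  d <- decimate_accel(fast, 4)
  atten_db <- 20 * log10(max(abs(d$ax[100:900])))
  expect_lt(atten_db, -20) # 40 Hz attenuated by > 20 dB

  expect_error(decimate_accel(cst, 0), "factor")
})

test_that("static/dynamic decomposition is an exact additive, linear split", {
  fs <- 50
  t <- (0:999) / fs
  cst <- accel_table(rep(0.2, 1000), rep(-0.1, 1000), rep(1, 1000), fs = fs)
  p <- decompose_static_dynamic(cst)
  expect_equal(p$static$az, cst$az, tolerance = 1e-9)
  expect_lt(max(abs(p$dynamic$az)), 1e-9)

  # 10 Hz >> 3 Hz cutoff: dynamic captures >= 95% of power
  hi <- accel_table(sin(2 * pi * 10 * t), rep(0, 1000), rep(0, 1000), fs = fs)
  p <- decompose_static_dynamic(hi)
  expect_gt(sum(p$dynamic$ax^2) / sum(hi$ax^2), 0.95)
  expect_lt(sum(p$static$ax^2) / sum(hi$ax^2), 0.05)

  # 0.2 Hz << cutoff: static captures >= 95%
  lo <- accel_table(sin(2 * pi * 0.2 * t), rep(0, 1000), rep(0, 1000), fs = fs)
  p <- decompose_static_dynamic(lo)
  expect_gt(sum(p$static$ax^2) / sum(lo$ax^2), 0.95)

  # additive identity and linearity on random traces
  withr::with_seed(17, {
    for (i in 1:10) {
      x <- accel_table(rnorm(400), rnorm(400), rnorm(400), fs = fs)
      y <- accel_table(rnorm(400), rnorm(400), rnorm(400), fs = fs)
      px <- decompose_static_dynamic(x)
      py <- decompose_static_dynamic(y)
      expect_equal(px$static$ax + px$dynamic$ax, x$ax, tolerance = 1e-9)
      xy <- accel_table(x$ax + y$ax, x$ay + y$ay, x$az + y$az, fs = fs)
      pxy <- decompose_static_dynamic(xy)
      expect_equal(pxy$dynamic$az, px$dynamic$az + py$dynamic$az,
                   tolerance = 1e-9)
    }
  })
  expect_error(decompose_static_dynamic(cst[1:50, ]), "short")
})

test_that("dive clips are clamped and merged", {
  acc <- accel_table(rep(0, 30000), rep(0, 30000), rep(1, 30000), fs = 50)
  clips <- extract_dive_clips(acc, 300)
  expect_length(clips, 1)
  expect_equal(range(clips[[1]]$t), c(240, 360), tolerance = 0.05)

  clips <- extract_dive_clips(acc, c(300, 350))
  expect_length(clips, 1)
  expect_equal(range(clips[[1]]$t), c(240, 410), tolerance = 0.05)

  clips <- extract_dive_clips(acc, c(300, 500))
  expect_length(clips, 2)

  clips <- extract_dive_clips(acc, 30) # clamped at trace start
  expect_equal(clips[[1]]$t[1], 0)
  expect_length(extract_dive_clips(acc, numeric()), 0)
})

test_that("low-amplitude segmentation separates and length-filters", {
  # fully active 120-s clip
  tr <- generate_accel_trace(accel_scenario_spec(120, seed = 3))
  segs <- split_low_amplitude(normalize_accel(tr$accel))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$stop_s - segs$start_s, 120, tolerance = 0.1)

  # active 30 / quiet 6 / active 15: the 15-s tail is dropped
  tr <- generate_accel_trace(accel_scenario_spec(
    51, quiet_gaps = tibble::tibble(start_s = 30, stop_s = 36), seed = 4
  ))
  segs <- split_low_amplitude(normalize_accel(tr$accel))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$stop_s[1], 30, tolerance = 0.5)

  # a quiet spell shorter than 5 s does not split
  tr <- generate_accel_trace(accel_scenario_spec(
    60, quiet_gaps = tibble::tibble(start_s = 30, stop_s = 34), seed = 5
  ))
  segs <- split_low_amplitude(normalize_accel(tr$accel))
  expect_equal(nrow(segs), 1)
})

test_that("peak detection implements height + distance pruning", {
  cfg <- motion_config()
  expect_length(detect_static_peaks(rep(1, 500), cfg), 0)

  # two 2-g bumps 0.5 s apart at 50 Hz: only the higher survives
  z <- rep(1, 500)
  z[200] <- 2.0
  z[225] <- 2.2
  pk <- detect_static_peaks(z, cfg)
  expect_equal(pk, 225)

  # equal heights closer than the separation: the earlier wins
  z <- rep(1, 500)
  z[200] <- 2.0
  z[230] <- 2.0
  expect_equal(detect_static_peaks(z, cfg), 200)

  # brute-force oracle: all maxima >= height, greedily pruned
  withr::with_seed(19, {
    for (i in 1:20) {
      z <- 1 + 0.2 * sin(2 * pi * (1:600) / 40) + rnorm(600, sd = 0.05)
      spikes <- sample(50:550, 5)
      z[spikes] <- z[spikes] + runif(5, 0.8, 1.5)
      pk <- detect_static_peaks(z, cfg)
      expect_true(all(z[pk] >= cfg$peak_height_g))
      if (length(pk) > 1) {
        expect_true(all(diff(pk) >= cfg$peak_min_sep_samples))
      }
      # every surviving spike location is a local max above threshold
      expect_true(all(z[pk] >= z[pmax(1, pk - 1)] & z[pk] >= z[pmin(600, pk + 1)]))
    }
  })

  # planted peaks >= 2 s apart at 1.9 g are all recovered
  z <- rep(1, 1000)
  at <- c(100, 250, 400, 700)
  z[at] <- 1.9
  expect_equal(detect_static_peaks(z, cfg), at)
})

test_that("segment tallies and the Fisher test follow the exact definitions", {
  segs <- tibble::tibble(
    category = c("dive", "dive", "dive", "non_dive"),
    has_peak = c(TRUE, TRUE, FALSE, FALSE)
  )
  tab <- classify_segments(segs)
  expect_equal(unclass(tab),
               matrix(c(2L, 0L, 1L, 1L), 2,
                      dimnames = list(c("dive", "non_dive"),
                                      c("peak", "no_peak"))))
  expect_true(all(classify_segments(segs[0, ]) == 0))
  expect_error(classify_segments(tibble::tibble(category = "swim",
                                                has_peak = TRUE)),
               "category")

  expect_equal(fisher_exact_two_sided(rbind(c(5, 5), c(5, 5))), 1.0)
  expect_error(fisher_exact_two_sided(rbind(c(0, 0), c(3, 17))), "margin")

  # equals stats::fisher.test and is invariant under row+column swap
  withr::with_seed(23, {
    for (i in 1:50) {
      tab <- matrix(rpois(4, 5) + 1, 2)
      p <- fisher_exact_two_sided(tab)
      expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
      expect_gt(p, 0)
      expect_lte(p, 1)
      swapped <- tab[2:1, 2:1]
      expect_equal(fisher_exact_two_sided(swapped), p, tolerance = 1e-12)
    }
  })
})

test_that("spectrogram localizes a pure tone and conserves frame energy", {
  fs <- 50
  cfg <- motion_config()
  x <- sin(2 * pi * 10 * (0:999) / fs)
  sp <- accel_spectrogram(x, fs, cfg)
  peak_freq <- sp$freq_hz[apply(sp$magnitude, 2, which.max)]
  inner <- 6:(length(sp$time_s) - 6) # away from reflect-padded edges
  expect_true(all(abs(peak_freq[inner] - 10) <= fs / cfg$spec_nfft))

  z <- accel_spectrogram(rep(0, 500), fs, cfg)
  expect_true(all(z$magnitude == 0))

  # Parseval on an interior frame
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(cfg$spec_win - 1)) / cfg$spec_win)
  k <- 20
  s0 <- (k - 1) * cfg$spec_hop + 1 - cfg$spec_win %/% 2 # frame start in x
  frame <- x[s0:(s0 + cfg$spec_win - 1)] * w
  mag <- sp$magnitude[, k]
  full <- mag[1]^2 + mag[length(mag)]^2 + 2 * sum(mag[2:(length(mag) - 1)]^2)
  expect_equal(full, cfg$spec_nfft * sum(frame^2), tolerance = 0.01 * full)

  expect_error(accel_spectrogram(rep(0, 10), fs, cfg), "shorter")
})

test_that("end-to-end dive analysis recovers the constructed contingency table", {
  spec <- accel_scenario_spec(
    600,
    dive_events = tibble::tibble(time_s = c(150, 420),
                                 bank_peak_g = c(2.2, 2.0),
                                 bank_width_s = c(0.8, 0.6)),
    seed = 27
  )
  tr <- generate_accel_trace(spec)
  flights <- tibble::tibble(start_s = c(10, 550), stop_s = c(50, 590))
  res <- analyze_dives(tr$accel, tr$dive_peak_times_s, flights)
  expect_s3_class(res, "dive_test")
  tab <- unclass(res$table)
  expect_equal(tab["dive", "peak"], 2L)
  expect_equal(tab["non_dive", "no_peak"], 2L)
  expect_equal(tab["non_dive", "peak"], 0L)
  gl <- glance(res)
  expect_equal(gl$p_value, res$p_value)
  td <- tidy(res)
  expect_equal(nrow(td), nrow(res$segments))
  expect_s3_class(plot_accel_decomposition(tr$accel[1:2000, ],
                                           dive_test = res), "ggplot")
})
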