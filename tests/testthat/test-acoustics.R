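test_that("confidence filtering uses strict thresholds", {
  det <- boxes_tbl(c(1, 3, 5, 7), c(1.4, 3.4, 5.4, 7.4), "Focal",
                   detection_prob = c(1, 0.5, 0.9, 0.4),
                   p_focal = c(1, 0.9, 0.5, 0.9),
                   p_nonfocal = 0, p_chick = 0, p_cuckoo = 0)
  kept <- select_confident(det, "Focal")
  expect_equal(nrow(kept), 1) # 0.5 exactly is excluded on either criterion
  expect_equal(kept$start_s, 1)

  all_sure <- dplyr::mutate(det, detection_prob = 1, p_focal = 1)
  expect_equal(nrow(select_confident(all_sure, "Focal")), 4)

  # row-wise predicate oracle on random tables
  withr::with_seed(8, {
    rt <- random_boxes(50)
    rt$detection_prob <- runif(50)
    rt$p_focal <- runif(50)
    rt$p_nonfocal <- rt$p_chick <- rt$p_cuckoo <- 0
    kept <- select_confident(rt, "Focal")
    ref <- rt[rt$detection_prob > 0.5 & rt$p_focal > 0.5, ]
    expect_equal(nrow(kept), nrow(ref))
  })

  expect_error(select_confident(boxes_tbl(1, 2), "Focal"), "detection_prob")
})

test_that("dBFS levels use full-scale amplitude 1 as reference", {
  fs <- 8000
  box <- boxes_tbl(0, 1)
  expect_equal(measure_level_dbfs(rep(1, fs), fs, box)$level_dbfs, 0)
  expect_equal(measure_level_dbfs(rep(0.1, fs), fs, box)$level_dbfs, -20)
  sine <- sin(2 * pi * 440 * (0:(fs - 1)) / fs)
  expect_equal(measure_level_dbfs(sine, fs, box)$level_dbfs, -3.0103,
               tolerance = 0.01)
  expect_error(measure_level_dbfs(rep(0, fs), fs, box), "all-zero")
})

test_that("noise window choice minimizes gap with earlier-side tie-break", {
  cfg <- snr_config()
  # lone box mid-file: both abutting windows feasible, earlier one wins
  box <- boxes_tbl(50, 50.4)
  win <- select_noise_window(box[1, ], box, 100, cfg)
  expect_equal(unname(win), c(46, 50))

  # focal boxes tile the file except one snug 4-s hole
  focal <- boxes_tbl(c(0, 27.3), c(23.3, 100), "Focal")
  target <- focal[2, ]
  win <- select_noise_window(target, focal, 100, cfg)
  expect_equal(unname(win), c(23.3, 27.3), tolerance = 1e-9)

  # no feasible window
  dense <- boxes_tbl(seq(0, 97, by = 3), seq(2, 99, by = 3), "Focal")
  expect_error(select_noise_window(dense[10, ], dense, 99.5, cfg),
               "no clean noise window")
})

test_that("SNR follows the amplitude-ratio definition and flags clipping", {
  fs <- 8000
  # constant-amplitude signal 10x the noise amplitude -> 20 dB
  x <- c(rep(0.01, 5 * fs), rep(0.1, fs), rep(0.01, 5 * fs))
  box <- boxes_tbl(5, 6)
  rec <- estimate_snr(x, fs, box)
  expect_equal(rec$snr_db, 20, tolerance = 0.05)
  expect_false(rec$excluded_clipping)

  # equal amplitudes -> 0 dB
  rec0 <- estimate_snr(rep(0.05, 11 * fs), fs, box)
  expect_equal(rec0$snr_db, 0, tolerance = 1e-6)

  recs <- tibble::tibble(snr_db = c(59, 60, 60.0001, 61, -3))
  split <- filter_clipping(recs)
  expect_equal(split$kept$snr_db, c(59, 60, -3)) # 60.0 exactly is kept
  expect_equal(split$excluded$snr_db, c(60.0001, 61))
})

test_that("gain invariance: scaling shifts levels, leaves SNR unchanged", {
  sp <- soundscape_spec(12, calls = tibble::tibble(
    onset_s = 5, duration_s = 0.4, peak_dbfs = -15, label = "Focal"
  ), noise_dbfs = -55, seed = 31)
  sc <- generate_soundscape(sp)
  g <- 0.25
  lv1 <- measure_level_dbfs(sc$samples, sc$sample_rate, sc$annotations)
  lv2 <- measure_level_dbfs(g * sc$samples, sc$sample_rate, sc$annotations)
  expect_equal(lv2$level_dbfs - lv1$level_dbfs, 20 * log10(g), tolerance = 1e-9)
  s1 <- estimate_snr(sc$samples, sc$sample_rate, sc$annotations)
  s2 <- estimate_snr(g * sc$samples, sc$sample_rate, sc$annotations)
  expect_equal(s1$snr_db, s2$snr_db, tolerance = 1e-9)
})

test_that("chick-call sampling is exact per individual-day group and seeded", {
  withr::with_seed(3, {
    det <- random_boxes(99 + 100 + 250, duration = 5000)
    det$individual_id <- rep(c("A", "B", "C"), c(99, 100, 250))
    det$day <- "2019-05-01"
  })
  s1 <- sample_chick_calls(det, per_day_n = 100, seed = 10)
  expect_equal(sum(s1$individual_id == "A"), 0) # 99 < 100: nothing
  expect_equal(sum(s1$individual_id == "B"), 100) # exactly 100: all
  expect_equal(sum(s1$individual_id == "C"), 100) # sampled down
  s2 <- sample_chick_calls(det, per_day_n = 100, seed = 10)
  expect_equal(s1, s2)
  s3 <- sample_chick_calls(det, per_day_n = 100, seed = 11)
  expect_false(identical(s1$start_s, s3$start_s))
})

test_that("distribution summary matches order-statistics oracle", {
  s <- summarize_distribution(1:5)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$whisker_lo, 2 - 3)

  cst <- summarize_distribution(rep(7.5, 10))
  expect_equal(cst$iqr, 0)
  expect_equal(cst$whisker_lo, 7.5)
  expect_equal(cst$whisker_hi, 7.5)

  withr::with_seed(6, x <- rnorm(101))
  s <- summarize_distribution(x)
  expect_equal(s$median, sort(x)[51])
  expect_equal(s$q1, unname(quantile(x, 0.25)))
  expect_error(summarize_distribution(numeric()), "no values")
})

test_that("amplitude densities are area-normalized with mode near sample mode", {
  withr::with_seed(13, {
    a <- rnorm(400, -30, 4)
    b <- rnorm(150, -45, 5)
  })
  d <- amplitude_density(a, b, group_names = c("adult", "chick"))
  for (g in c("adult", "chick")) {
    sub <- d[d$group == g, ]
    area <- sum(diff(sub$level_dbfs) *
                  (head(sub$density, -1) + tail(sub$density, -1)) / 2)
    expect_equal(area, 1, tolerance = 1e-3)
  }
  adult <- d[d$group == "adult", ]
  expect_lt(abs(adult$level_dbfs[which.max(adult$density)] - (-30)), 4)

  ident <- amplitude_density(a, a)
  expect_equal(ident$density[ident$group == "a"],
               ident$density[ident$group == "b"])
  expect_s3_class(plot_amplitude_density(d), "ggplot")
})

test_that("quieter chick calls yield a lower median level than adult calls", {
  calls <- tibble::tibble(
    onset_s = seq(2, 38, by = 4),
    duration_s = 0.33,
    peak_dbfs = rep(c(-12, -35), 5), # adults loud, chicks quiet
    label = rep(c("Focal", "Crow chick"), 5)
  )
  sc <- generate_soundscape(soundscape_spec(40, calls = calls,
                                            noise_dbfs = -65, seed = 9))
  lv <- measure_level_dbfs(sc$samples, sc$sample_rate, sc$annotations)
  expect_lt(median(lv$level_dbfs[lv$label == "Crow chick"]),
            median(lv$level_dbfs[lv$label == "Focal"]))
})
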