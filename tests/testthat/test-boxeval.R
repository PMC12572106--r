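test_that("interval IoU matches hand arithmetic and basic identities", {
  expect_equal(interval_iou(0, 1, 0, 1), 1.0)
  expect_equal(interval_iou(0, 1, 2, 3), 0.0)
  expect_equal(interval_iou(0, 2, 1, 3), 1 / 3)
  expect_equal(interval_iou(0, 2, 1, 3), interval_iou(1, 3, 0, 2)) # symmetric
  expect_equal(interval_iou(0, 1, 1, 2), 0.0) # touching endpoints
  expect_error(interval_iou(1, 1, 0, 2), "zero-length")
})

test_that("matching pairs perfect copies and rejects sub-threshold overlap", {
  ann <- boxes_tbl(0:4, 0:4 + 0.5)
  m <- match_boxes(ann, ann)
  expect_equal(nrow(m$pairs), 5)
  expect_length(m$unmatched_annotations, 0)
  expect_length(m$unmatched_predictions, 0)
  expect_true(all(m$pairs$iou == 1))

  # shifted so IoU = 0.4: intersection 0.4/union 1.0 with unit boxes
  a <- boxes_tbl(0, 1)
  p <- boxes_tbl(0.6, 1.6) # iou = 0.4/1.6 = 0.25 < 0.5
  m <- match_boxes(a, p)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$unmatched_annotations, 1L)
  expect_equal(m$unmatched_predictions, 1L)

  # exactly at threshold is excluded (strict >)
  a2 <- boxes_tbl(0, 2)
  p2 <- boxes_tbl(0, 1) # nested: iou = 1/2 exactly
  expect_equal(interval_iou(0, 2, 0, 1), 0.5)
  expect_equal(nrow(match_boxes(a2, p2)$pairs), 0)
})

test_that("matching equals exhaustive search on ambiguous instances", {
  withr::with_seed(21, {
    for (i in 1:40) {
      ann <- random_boxes(sample(1:6, 1))
      pred <- random_boxes(sample(1:6, 1))
      fast <- match_boxes(ann, pred)
      ref <- match_boxes_exhaustive(ann, pred)
      expect_equal(nrow(fast$pairs), nrow(ref$pairs))
      expect_equal(sum(fast$pairs$iou), sum(ref$pairs$iou), tolerance = 1e-9)
      expect_true(all(fast$pairs$iou > 0.5))
    }
  })
})

test_that("matching is independent of input row order", {
  withr::with_seed(33, {
    ann <- random_boxes(6)
    pred <- dplyr::mutate(ann, start_s = start_s + 0.05, stop_s = stop_s + 0.02)
    m1 <- match_boxes(ann, pred)
    m2 <- match_boxes(ann[sample(6), ], pred[sample(6), ])
    expect_equal(m1$pairs, m2$pairs) # tables are canonically sorted inside
  })
})

test_that("mismatched file_id sets raise", {
  a <- boxes_tbl(0, 1, file_id = "f1")
  p <- boxes_tbl(0, 1, file_id = "f2")
  expect_error(match_boxes(a, p), "file_id")
})

test_that("confusion counts implement the Unknown neutrality rules", {
  cfg <- eval_config()
  # perfect scenario
  ann <- boxes_tbl(0:3 * 2, 0:3 * 2 + 0.5, scored_classes())
  ev <- evaluate_detections(ann, ann)
  expect_equal(ev$counts$tp, rep(1L, 4))
  expect_equal(ev$counts$fp, rep(0L, 4))
  expect_equal(ev$counts$fn, rep(0L, 4))

  # one Focal annotation missed entirely
  m <- match_boxes(boxes_tbl(0, 1, "Focal"), boxes_tbl(5, 6, "Focal")[0, ])
  cts <- confusion_counts(m, cfg)
  expect_equal(cts$fn[cts$class == "Focal"], 1L)
  expect_equal(sum(cts$fp), 0L)

  # unmatched Unknown annotation contributes nothing
  m <- match_boxes(boxes_tbl(0, 1, "Unknown"), boxes_tbl(5, 6)[0, ])
  expect_true(all(confusion_counts(m, cfg)[, c("tp", "fp", "fn")] == 0))

  # pair with Unknown annotation is fully neutral
  m <- match_boxes(boxes_tbl(0, 1, "Unknown"), boxes_tbl(0, 1, "Focal"))
  expect_equal(nrow(m$pairs), 1)
  expect_true(all(confusion_counts(m, cfg)[, c("tp", "fp", "fn")] == 0))

  # Unknown prediction matched to a Focal annotation: FN only, no FP
  m <- match_boxes(boxes_tbl(0, 1, "Focal"), boxes_tbl(0, 1, "Unknown"))
  cts <- confusion_counts(m, cfg)
  expect_equal(cts$fn[cts$class == "Focal"], 1L)
  expect_equal(sum(cts$fp), 0L)

  # cross-class pair: FN for true class + FP for predicted class
  m <- match_boxes(boxes_tbl(0, 1, "Focal"), boxes_tbl(0, 1, "Cuckoo"))
  cts <- confusion_counts(m, cfg)
  expect_equal(cts$fn[cts$class == "Focal"], 1L)
  expect_equal(cts$fp[cts$class == "Cuckoo"], 1L)
  expect_equal(sum(cts$tp), 0L)
})

test_that("metrics follow the P/R/F1 definitions with zero-denominator convention", {
  mt <- compute_metrics(published_counts())
  focal <- mt[mt$class == "Focal", ]
  expect_equal(focal$precision, 0.830243, tolerance = 1e-5)
  expect_equal(focal$recall, 0.791275, tolerance = 1e-5)
  expect_equal(focal$f1, 0.810291, tolerance = 1e-5)
  expect_equal(mt$f1[mt$class == "macro"], 0.780108, tolerance = 1e-5)

  z <- compute_metrics(tibble::tibble(class = scored_classes(),
                                      tp = 0L, fp = 0L, fn = 0L))
  expect_true(all(z$precision == 0))
  expect_true(all(z$zero_denominator))

  # invariants on random counts
  withr::with_seed(5, {
    for (i in 1:20) {
      cts <- tibble::tibble(class = scored_classes(),
                            tp = rpois(4, 20), fp = rpois(4, 8), fn = rpois(4, 8))
      m <- compute_metrics(cts)
      per <- m[m$class != "macro", ]
      expect_true(all(per$f1 <= pmax(per$precision, per$recall) + 1e-12))
      expect_true(all(per$precision >= 0 & per$precision <= 1))
      expect_equal(m$f1[m$class == "macro"], mean(per$f1))
    }
  })
})

test_that("spurious predictions never raise recall; deletions never raise precision numerator", {
  withr::with_seed(9, {
    scen <- generate_detection_scenario(
      detection_scenario_spec(n_events = 8, jitter_frac = 0.1, seed = 14)
    )
    base <- evaluate_detections(scen$annotations, scen$predictions)
    spur <- dplyr::bind_rows(scen$predictions,
                             boxes_tbl(990, 990.4, "Focal",
                                       detection_prob = 1, file_id = "scenario"))
    with_spur <- evaluate_detections(scen$annotations, spur)
    expect_true(all(with_spur$counts$tp + 0 >=
                      base$counts$tp - 1e-9)) # tp unchanged
    expect_true(all(tidy(with_spur)$recall <= tidy(base)$recall + 1e-12))

    fewer <- scen$predictions[-1, ]
    with_fewer <- evaluate_detections(scen$annotations, fewer)
    expect_true(all(with_fewer$counts$tp <= base$counts$tp))
  })
})

test_that("tidy/glance/autoplot expose the evaluation", {
  scen <- generate_detection_scenario(detection_scenario_spec(n_events = 5, seed = 3))
  ev <- evaluate_detections(scen$annotations, scen$predictions)
  td <- tidy(ev)
  expect_equal(nrow(td), 4)
  gl <- glance(ev)
  expect_equal(gl$macro_f1, 1.0) # clean scenario: perfect score
  expect_s3_class(plot_metrics(ev), "ggplot")
})
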