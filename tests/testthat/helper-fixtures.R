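# shared fixtures: tiny selection tables, random boxes, and the published
# confusion counts used to sanity-check the metric arithmetic

boxes_tbl <- function(start, stop, label = "Focal", ...) {
  tibble::tibble(start_s = start, stop_s = stop,
                 label = rep_len(label, length(start)), ...)
}

# counts reproduced from the final evaluation of the trained detector
# (per-class false negatives / false positives / true positives)
published_counts <- function() {
  tibble::tibble(
    class = scored_classes(),
    tp = c(1433L, 867L, 4818L, 2432L),
    fp = c(293L, 182L, 1395L, 937L),
    fn = c(378L, 251L, 1834L, 591L)
  )
}

published_metrics <- function() {
  tibble::tibble(
    class = c(scored_classes(), "macro"),
    precision = c(0.830243, 0.826501, 0.775470, 0.721875, 0.788522),
    recall = c(0.791275, 0.775491, 0.724293, 0.804498, 0.773889),
    f1 = c(0.810291, 0.800184, 0.749008, 0.760951, 0.780108)
  )
}

random_boxes <- function(n, duration = 10, label_pool = scored_classes()) {
  start <- stats::runif(n, 0, duration)
  tibble::tibble(
    start_s = start,
    stop_s = start + stats::runif(n, 0.1, 1.5),
    label = sample(label_pool, n, replace = TRUE),
    detection_prob = 1
  )
}

# independent enumeration oracle for the exact two-sided Fisher p-value
fisher_enum_oracle <- function(tbl) {
  m <- tbl[1, 1] + tbl[1, 2]
  n2 <- tbl[2, 1] + tbl[2, 2]
  k <- tbl[1, 1] + tbl[2, 1]
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(tbl[1, 1], m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}
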