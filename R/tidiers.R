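# broom-style tidiers for the fitted/evaluated objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a detection evaluation
#'
#' @param x A `box_eval` from [evaluate_detections()].
#' @param ... Unused.
#' @return Per-class rows of counts and metrics (the macro row is in
#'   [glance.box_eval()]).
#' @method tidy box_eval
#' @export
tidy.box_eval <- function(x, ...) {
  dplyr::filter(as_tibble(x$metrics), .data$class != "macro")
}

#' One-row summary of a detection evaluation
#'
#' @param x A `box_eval`.
#' @param ... Unused.
#' @return A one-row tibble with macro-averaged precision/recall/F1 and the
#'   matching tallies.
#' @method glance box_eval
#' @export
glance.box_eval <- function(x, ...) {
  macro <- dplyr::filter(as_tibble(x$metrics), .data$class == "macro")
  tibble(
    macro_precision = macro$precision, macro_recall = macro$recall,
    macro_f1 = macro$f1,
    n_annotations = nrow(x$match$annotations),
    n_predictions = nrow(x$match$predictions),
    n_matched = nrow(x$match$pairs),
    iou_threshold = x$cfg$iou_threshold
  )
}

#' Tidy a dive analysis
#'
#' @param x A `dive_test` from [analyze_dives()].
#' @param ... Unused.
#' @return One row per segment: category, bounds, peak count, `has_peak`.
#' @method tidy dive_test
#' @export
tidy.dive_test <- function(x, ...) {
  segs <- x$segments
  tibble(
    category = segs$category, start_s = segs$start_s, stop_s = segs$stop_s,
    n_peaks = vapply(segs$peak_times_s, length, integer(1)),
    has_peak = segs$has_peak
  )
}

#' One-row summary of a dive analysis
#'
#' @param x A `dive_test`.
#' @param ... Unused.
#' @return A one-row tibble with the 2x2 counts and the Fisher p-value.
#' @method glance dive_test
#' @export
glance.dive_test <- function(x, ...) {
  tab <- unclass(x$table)
  tibble(
    dive_with_peak = tab[1, 1], dive_without_peak = tab[1, 2],
    nondive_with_peak = tab[2, 1], nondive_without_peak = tab[2, 2],
    p_value = x$p_value
  )
}
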