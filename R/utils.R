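#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# The four scored caller classes, in reporting order, plus the Unknown label
# used when a call cannot be attributed.
SCORED_CLASSES <- c("Focal", "Non-focal", "Crow chick", "Cuckoo")
UNKNOWN_LABEL <- "Unknown"
ALLOWED_LABELS <- c(SCORED_CLASSES, UNKNOWN_LABEL)

# Column holding the class probability for each scored class.
CLASS_PROB_COLS <- c(
  "Focal" = "p_focal", "Non-focal" = "p_nonfocal",
  "Crow chick" = "p_chick", "Cuckoo" = "p_cuckoo"
)

#' Scored caller classes
#'
#' The four caller categories that enter per-class and macro-averaged
#' detection metrics: `Focal` (the tagged bird), `Non-focal` (another adult),
#' `Crow chick` and `Cuckoo` (nestling begging calls). Calls that cannot be
#' attributed carry the label `Unknown` and are handled by the evaluation
#' rules, never scored as a fifth class.
#'
#' @return Character vector of the four scored class labels.
#' @export
scored_classes <- function() SCORED_CLASSES

check_labels <- function(labels, where = "selection table") {
  bad <- setdiff(unique(labels), ALLOWED_LABELS)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s contains labels outside {%s}: %s",
      where, paste(ALLOWED_LABELS, collapse = ", "), paste(bad, collapse = ", ")
    ))
  }
  invisible(labels)
}

check_intervals <- function(start_s, stop_s, where = "selection table") {
  bad <- which(!(start_s < stop_s))
  if (length(bad) > 0) {
    abort(sprintf("%s: stop_s <= start_s on row %s", where, bad[1]))
  }
  if (any(start_s < 0)) {
    abort(sprintf("%s: negative start time", where))
  }
  invisible(NULL)
}

#' Validate a selection table
#'
#' A selection table is a tibble with one row per vocalization event (an
#' annotated or predicted bounding box on the time axis). Required columns:
#' `start_s`, `stop_s` (seconds from file start, half-open `[start, stop)`),
#' `label` (one of `scored_classes()` or `"Unknown"`). Optional columns:
#' `detection_prob`, `p_focal`, `p_nonfocal`, `p_chick`, `p_cuckoo`,
#' `individual_id`, `file_id`.
#'
#' @param x A data frame to validate.
#' @param where Label used in error messages.
#' @return `x` as a tibble, sorted by `start_s`, invisibly checkable.
#' @export
validate_selection_table <- function(x, where = "selection table") {
  x <- as_tibble(x)
  need <- c("start_s", "stop_s", "label")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing required column(s): %s", where, paste(miss, collapse = ", ")))
  }
  if (!is.numeric(x$start_s) || !is.numeric(x$stop_s)) {
    abort(sprintf("%s: start_s/stop_s must be numeric", where))
  }
  if (anyNA(x$start_s) || anyNA(x$stop_s)) {
    abort(sprintf("%s: missing begin/end time on row %s", where,
                  which(is.na(x$start_s) | is.na(x$stop_s))[1]))
  }
  check_intervals(x$start_s, x$stop_s, where)
  check_labels(x$label, where)
  if ("detection_prob" %in% names(x)) {
    if (any(x$detection_prob < 0 | x$detection_prob > 1, na.rm = TRUE)) {
      abort(sprintf("%s: detection_prob outside [0, 1]", where))
    }
  }
  dplyr::arrange(x, .data$start_s, .data$stop_s)
}

run_lengths_true <- function(mask) {
  # start/end indices of maximal TRUE runs in a logical vector
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(start = starts[r$values], end = ends[r$values])
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}
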