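# Evaluation of predicted vocalization boxes against human annotations:
# one-to-one interval IoU matching and per-class / macro-averaged
# precision, recall, F1, with special handling of Unknown-labelled calls.

#' Evaluation configuration
#'
#' @param iou_threshold Minimum intersection-over-union for a predicted box
#'   to be matched with an annotated box. The comparison is strict
#'   (`iou > threshold`), so at the default 0.5 a pair must exceed 0.5.
#' @param classes The scored caller classes, in reporting order.
#' @param unknown_label Label of unattributable calls; detections of such
#'   annotations are never penalized or rewarded.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(iou_threshold = 0.5, classes = scored_classes(),
                        unknown_label = "Unknown") {
  if (!(iou_threshold > 0 && iou_threshold <= 1)) {
    abort("`iou_threshold` must be in (0, 1]")
  }
  if (length(classes) != 4) abort("exactly 4 scored classes are required")
  structure(list(iou_threshold = iou_threshold, classes = classes,
                 unknown_label = unknown_label),
            class = "eval_config")
}

#' Intersection-over-union of time intervals
#'
#' IoU of half-open intervals `[start, stop)` on the time axis: length of
#' the intersection divided by length of the union. Symmetric, zero for
#' disjoint intervals, and intervals that merely touch at an endpoint have
#' IoU 0. Vectorized over its arguments.
#'
#' @param start_a,stop_a,start_b,stop_b Interval endpoints in seconds.
#' @return IoU values in `[0, 1]`.
#' @export
interval_iou <- function(start_a, stop_a, start_b, stop_b) {
  if (any(stop_a <= start_a) || any(stop_b <= start_b)) {
    abort("zero-length or inverted interval")
  }
  inter <- pmax(0, pmin(stop_a, stop_b) - pmax(start_a, start_b))
  union <- (stop_a - start_a) + (stop_b - start_b) - inter
  inter / union
}

iou_edges <- function(ann, pred, threshold) {
  # candidate (annotation, prediction) pairs with IoU strictly above threshold
  if (nrow(ann) == 0 || nrow(pred) == 0) {
    return(tibble(a = integer(), p = integer(), iou = numeric()))
  }
  grid <- expand.grid(a = seq_len(nrow(ann)), p = seq_len(nrow(pred)))
  iou <- interval_iou(ann$start_s[grid$a], ann$stop_s[grid$a],
                      pred$start_s[grid$p], pred$stop_s[grid$p])
  keep <- iou > threshold
  tibble(a = grid$a[keep], p = grid$p[keep], iou = iou[keep])
}

#' Match predicted to annotated boxes
#'
#' Finds a one-to-one, class-agnostic pairing between annotated and
#' predicted boxes among all pairs whose interval IoU strictly exceeds the
#' threshold. Among all such pairings the one maximizing the number of
#' pairs is chosen, with ties broken by maximum total IoU; this optimum is
#' computed exactly as a maximum-weight bipartite matching, so the result
#' is deterministic and independent of input row order. When both tables
#' carry a `file_id` column, matching is performed per file.
#'
#' @param annotations,predictions Selection table tibbles on the same
#'   timebase.
#' @param cfg An [eval_config()].
#' @return A list of class `box_match` with elements `pairs` (tibble of
#'   `annotation`, `prediction`, `iou` row indices into the sorted input
#'   tables), `unmatched_annotations`, `unmatched_predictions`, and the
#'   sorted `annotations` and `predictions` tables themselves.
#' @export
match_boxes <- function(annotations, predictions, cfg = eval_config()) {
  ann <- validate_selection_table(annotations, "annotations")
  pred <- validate_selection_table(predictions, "predictions")
  has_file <- "file_id" %in% names(ann) && "file_id" %in% names(pred)
  if (has_file && nrow(ann) > 0 && nrow(pred) > 0 &&
      !setequal(unique(ann$file_id), unique(pred$file_id))) {
    abort("annotations and predictions cover different file_id sets")
  }
  files <- if (has_file) unique(ann$file_id) else NA
  pairs <- tibble(annotation = integer(), prediction = integer(), iou = numeric())
  for (f in files) {
    ia <- if (has_file) which(ann$file_id == f) else seq_len(nrow(ann))
    ip <- if (has_file) which(pred$file_id == f) else seq_len(nrow(pred))
    edges <- iou_edges(ann[ia, ], pred[ip, ], cfg$iou_threshold)
    m <- solve_matching(edges, length(ia), length(ip))
    if (nrow(m) > 0) {
      pairs <- dplyr::bind_rows(pairs, tibble(
        annotation = ia[m$a], prediction = ip[m$p], iou = m$iou
      ))
    }
  }
  pairs <- dplyr::arrange(pairs, .data$annotation)
  structure(list(
    pairs = pairs,
    unmatched_annotations = setdiff(seq_len(nrow(ann)), pairs$annotation),
    unmatched_predictions = setdiff(seq_len(nrow(pred)), pairs$prediction),
    annotations = ann, predictions = pred,
    iou_threshold = cfg$iou_threshold
  ), class = "box_match")
}

solve_matching <- function(edges, n_ann, n_pred) {
  # Maximum-weight bipartite matching with weight iou + (n+1): the constant
  # dominates, so pair count is maximized first and total IoU breaks ties.
  if (nrow(edges) == 0) return(tibble(a = integer(), p = integer(), iou = numeric()))
  big <- n_ann + n_pred + 1
  g <- igraph::make_empty_graph(n = n_ann + n_pred, directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges$a, n_ann + edges$p))
  igraph::V(g)$type <- c(rep(FALSE, n_ann), rep(TRUE, n_pred))
  m <- igraph::max_bipartite_match(g, weights = edges$iou + big)$matching
  a_idx <- seq_len(n_ann)
  matched <- !is.na(m[a_idx])
  out <- tibble(a = a_idx[matched], p = as.integer(m[a_idx][matched]) - n_ann)
  out$iou <- edges$iou[match(paste(out$a, out$p), paste(edges$a, edges$p))]
  out
}

#' Exhaustive reference matching
#'
#' Brute-force search over all one-to-one assignments between annotations
#' and predictions (restricted to pairs with IoU above the threshold),
#' returning the pairing that maximizes pair count and then total IoU.
#' Exponential in the worst case; intended as an independent reference for
#' small problems and as the ground-truth matcher inside the scenario
#' generator. The search runs per connected component of the candidate-pair
#' graph, so moderately sized sparse problems are fine.
#'
#' @inheritParams match_boxes
#' @return Same structure as [match_boxes()].
#' @export
match_boxes_exhaustive <- function(annotations, predictions, cfg = eval_config()) {
  ann <- validate_selection_table(annotations, "annotations")
  pred <- validate_selection_table(predictions, "predictions")
  edges <- iou_edges(ann, pred, cfg$iou_threshold)
  pairs <- tibble(annotation = integer(), prediction = integer(), iou = numeric())
  if (nrow(edges) > 0) {
    # connected components of the bipartite candidate graph
    g <- igraph::make_empty_graph(n = nrow(ann) + nrow(pred), directed = FALSE)
    g <- igraph::add_edges(g, rbind(edges$a, nrow(ann) + edges$p))
    comp <- igraph::components(g)$membership
    for (cid in unique(comp[edges$a])) {
      sub <- edges[comp[edges$a] == cid, , drop = FALSE]
      best <- search_assignment(sub)
      if (nrow(best) > 0) {
        pairs <- dplyr::bind_rows(pairs, tibble(
          annotation = best$a, prediction = best$p, iou = best$iou
        ))
      }
    }
  }
  pairs <- dplyr::arrange(pairs, .data$annotation)
  structure(list(
    pairs = pairs,
    unmatched_annotations = setdiff(seq_len(nrow(ann)), pairs$annotation),
    unmatched_predictions = setdiff(seq_len(nrow(pred)), pairs$prediction),
    annotations = ann, predictions = pred,
    iou_threshold = cfg$iou_threshold
  ), class = "box_match")
}

search_assignment <- function(edges) {
  # depth-first enumeration over annotations in this component
  anns <- sort(unique(edges$a))
  best_count <- -1L
  best_iou <- -Inf
  best <- edges[0, ]
  recurse <- function(i, used_p, chosen) {
    if (i > length(anns)) {
      cnt <- nrow(chosen)
      tot <- sum(chosen$iou)
      if (cnt > best_count || (cnt == best_count && tot > best_iou + 1e-12)) {
        best_count <<- cnt; best_iou <<- tot; best <<- chosen
      }
      return(invisible(NULL))
    }
    opts <- edges[edges$a == anns[i] & !(edges$p %in% used_p), , drop = FALSE]
    recurse(i + 1L, used_p, chosen) # leave this annotation unmatched
    for (j in seq_len(nrow(opts))) {
      recurse(i + 1L, c(used_p, opts$p[j]), dplyr::bind_rows(chosen, opts[j, ]))
    }
  }
  recurse(1L, integer(), edges[0, ])
  best
}

#' Per-class confusion counts from a matching
#'
#' Tallies true positives, false positives and false negatives for each of
#' the four scored classes. A matched pair with equal scored labels is a TP
#' for that class; a pair with differing scored labels counts as a FN for
#' the annotated class and a FP for the predicted class. Unmatched scored
#' annotations are FNs; unmatched scored predictions are FPs. Unknown-
#' labelled calls are neutral: unmatched Unknown annotations contribute
#' nothing, pairs involving an Unknown annotation contribute nothing, and
#' Unknown-labelled predictions never contribute a FP (an annotation
#' matched to one still counts as a FN for its own class).
#'
#' @param match A `box_match` from [match_boxes()].
#' @param cfg An [eval_config()].
#' @return A tibble with columns `class`, `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(match, cfg = eval_config()) {
  ann <- match$annotations
  pred <- match$predictions
  check_labels(ann$label, "annotations")
  check_labels(pred$label, "predictions")
  unk <- cfg$unknown_label
  tp <- fp <- fn <- stats::setNames(rep(0L, length(cfg$classes)), cfg$classes)
  for (k in seq_len(nrow(match$pairs))) {
    la <- ann$label[match$pairs$annotation[k]]
    lp <- pred$label[match$pairs$prediction[k]]
    if (la == unk) next
    if (lp == la) {
      tp[la] <- tp[la] + 1L
    } else {
      fn[la] <- fn[la] + 1L
      if (lp != unk) fp[lp] <- fp[lp] + 1L
    }
  }
  for (i in match$unmatched_annotations) {
    la <- ann$label[i]
    if (la != unk) fn[la] <- fn[la] + 1L
  }
  for (i in match$unmatched_predictions) {
    lp <- pred$label[i]
    if (lp != unk) fp[lp] <- fp[lp] + 1L
  }
  tibble(class = cfg$classes, tp = as.integer(tp), fp = as.integer(fp),
         fn = as.integer(fn))
}

#' Precision, recall and F1 from confusion counts
#'
#' Computes per-class precision `tp/(tp+fp)`, recall `tp/(tp+fn)` and
#' `f1 = 2PR/(P+R)`, plus an unweighted macro average across the four
#' classes. Zero denominators yield 0 and are flagged in the
#' `zero_denominator` column.
#'
#' @param counts Tibble with columns `class`, `tp`, `fp`, `fn` (one row per
#'   scored class), as from [confusion_counts()].
#' @return A tibble of class `metrics_tbl`: one row per class plus a final
#'   `macro` row holding the unweighted means.
#' @export
compute_metrics <- function(counts) {
  need <- c("class", "tp", "fp", "fn")
  if (!all(need %in% names(counts))) {
    abort("`counts` must have columns class, tp, fp, fn")
  }
  if (any(counts$tp < 0 | counts$fp < 0 | counts$fn < 0)) {
    abort("counts must be nonnegative")
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  per <- counts |>
    mutate(
      precision = safe_div(.data$tp, .data$tp + .data$fp),
      recall = safe_div(.data$tp, .data$tp + .data$fn),
      f1 = safe_div(2 * .data$precision * .data$recall,
                    .data$precision + .data$recall),
      zero_denominator = (.data$tp + .data$fp == 0) | (.data$tp + .data$fn == 0)
    )
  macro <- tibble(
    class = "macro", tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
    precision = mean(per$precision), recall = mean(per$recall),
    f1 = mean(per$f1), zero_denominator = any(per$zero_denominator)
  )
  out <- dplyr::bind_rows(per, macro)
  class(out) <- c("metrics_tbl", class(out))
  out
}

#' Class-blind detection metrics
#'
#' Detection-level precision and recall ignoring class labels: every matched
#' pair is a true positive, unmatched non-Unknown annotations are false
#' negatives (undetected Unknown calls are not penalized), and unmatched
#' predictions are false positives.
#'
#' @inheritParams confusion_counts
#' @return A one-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
detection_metrics <- function(match, cfg = eval_config()) {
  tp <- nrow(match$pairs)
  fn <- sum(match$annotations$label[match$unmatched_annotations] != cfg$unknown_label)
  fp <- length(match$unmatched_predictions)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble(tp = tp, fp = fp, fn = as.integer(fn), precision = p, recall = r, f1 = f1)
}

#' Evaluate predictions against annotations
#'
#' One-stop evaluation: matches boxes, tallies per-class confusion counts
#' and computes the metrics table.
#'
#' @inheritParams match_boxes
#' @return A list of class `box_eval` with `match`, `counts`, `metrics` and
#'   `detection` (class-blind metrics).
#' @export
evaluate_detections <- function(annotations, predictions, cfg = eval_config()) {
  match <- match_boxes(annotations, predictions, cfg)
  counts <- confusion_counts(match, cfg)
  structure(list(
    match = match, counts = counts,
    metrics = compute_metrics(counts),
    detection = detection_metrics(match, cfg),
    cfg = cfg
  ), class = "box_eval")
}

#' @export
print.box_eval <- function(x, ...) {
  cat(sprintf("Detection evaluation (IoU > %g, one-to-one matching)\n",
              x$cfg$iou_threshold))
  cat(sprintf("  %d annotations, %d predictions, %d matched pairs\n",
              nrow(x$match$annotations), nrow(x$match$predictions),
              nrow(x$match$pairs)))
  print(as_tibble(x$metrics))
  invisible(x)
}
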