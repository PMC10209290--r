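#' Match detected beats against reference annotations
#'
#' Beat-by-beat comparison with a fixed time tolerance: each reference beat,
#' in temporal order, is paired one-to-one with the nearest still-unmatched
#' detection within `round(tol_s * fs)` samples (ties go to the earlier
#' detection). Paired beats are true positives; unpaired detections false
#' positives; unpaired references false negatives. The default 150 ms window
#' is the established beat-by-beat comparison convention.
#'
#' @param detected A [beat_annotations] from a detector.
#' @param reference A [beat_annotations] of ground truth, same fs.
#' @param tol_s Matching tolerance in seconds (default 0.15).
#' @return A list of class `match_counts` with fields `tp`, `fp`, `fn`.
#' @export
match_beats <- function(detected, reference, tol_s = 0.15) {
  stopifnot(inherits(detected, "beat_annotations"),
            inherits(reference, "beat_annotations"))
  if (detected$fs != reference$fs)
    stop("detected and reference annotations have different sampling rates")
  tol <- round(tol_s * detected$fs)
  d <- detected$indices
  used <- logical(length(d))
  tp <- 0L
  for (r in reference$indices) {
    if (!length(d)) break
    dist <- abs(d - r)
    dist[used] <- Inf
    k <- which.min(dist)    # which.min takes the first (earlier) minimum
    if (length(k) && dist[k] <= tol) {
      used[k] <- TRUE
      tp <- tp + 1L
    }
  }
  structure(list(tp = tp, fp = length(d) - tp,
                 fn = length(reference$indices) - tp),
            class = "match_counts")
}

#' @export
print.match_counts <- function(x, ...) {
  cat(sprintf("<match_counts> TP=%d FP=%d FN=%d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Beat-detection performance metrics
#'
#' From TP/FP/FN tallies computes, as percentages:
#' \deqn{TPR = 100 \cdot TP / (TP + FN)}
#' \deqn{PPV = 100 \cdot TP / (TP + FP)}
#' \deqn{ACC = 100 \cdot TP / (TP + FP + FN)}
#' TPR is the probability that a true beat is detected, PPV the probability
#' that a detection is a true beat, and ACC the overall agreement; ACC never
#' exceeds either of the other two. A ratio with zero denominator is
#' returned as `NA` (not applicable), never as zero.
#'
#' @param counts A `match_counts` object (or a list with `tp`, `fp`, `fn`).
#' @return A list of class `beat_metrics` with full-precision fields `tpr`,
#'   `ppv`, `acc` plus the counts; printing shows 3 decimals.
#' @export
#' @examples
#' beat_metrics(list(tp = 9, fp = 0, fn = 1))
beat_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fn == 0 && tp + fp == 0)
    stop("no reference beats and no detections: metrics undefined")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(tpr = rate(tp, tp + fn), ppv = rate(tp, tp + fp),
                 acc = rate(tp, tp + fp + fn), tp = tp, fp = fp, fn = fn),
            class = "beat_metrics")
}

#' @export
print.beat_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.3f", v)
  cat(sprintf("<beat_metrics> TPR=%s PPV=%s ACC=%s (TP=%d FP=%d FN=%d)\n",
              fmt(x$tpr), fmt(x$ppv), fmt(x$acc), x$tp, x$fp, x$fn))
  invisible(x)
}

#' Evaluate a detector against reference annotations
#'
#' Convenience wrapper chaining [match_beats()] and [beat_metrics()].
#'
#' @inheritParams match_beats
#' @return A `beat_metrics` object.
#' @export
evaluate_detection <- function(detected, reference, tol_s = 0.15) {
  beat_metrics(match_beats(detected, reference, tol_s))
}

#' Format evaluation results as a TSV report
#'
#' One row per record with the tallies and the three metrics printed to
#' 3 decimals.
#'
#' @param results Named list of `beat_metrics` objects (names = record ids).
#' @return Character vector of TSV lines (header first).
#' @export
metrics_report <- function(results) {
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.3f", v)
  c("record\ttp\tfp\tfn\ttpr\tppv\tacc",
    vapply(names(results), USE.NAMES = FALSE, function(nm) {
      m <- results[[nm]]
      sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%s", nm, m$tp, m$fp, m$fn,
              fmt(m$tpr), fmt(m$ppv), fmt(m$acc))
    }, ""))
}
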