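#' Confusion counts at a score cutoff
#'
#' A residue is predicted positive iff its score is strictly greater
#' than the cutoff ("positive if the output is more than a cutoff"); the
#' strict inequality matters at tied scores.
#'
#' @param scores Tibble (or data frame) with numeric `score` and binary
#'   `label` (1/`TRUE` = binding) columns, e.g. from
#'   [jackknife_evaluate()].
#' @param cutoff Decision threshold.
#' @return One-row tibble `tp`, `fp`, `tn`, `fn` (sums to
#'   `nrow(scores)`).
#' @export
confusion_at_cutoff <- function(scores, cutoff) {
  y <- as.integer(scores$label)
  pos <- scores$score > cutoff
  tibble(
    tp = sum(pos & y == 1L), fp = sum(pos & y == 0L),
    tn = sum(!pos & y == 0L), fn = sum(!pos & y == 1L)
  )
}

#' Threshold metrics from confusion counts
#'
#' Sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, precision `TP/(TP+FP)` and the F-measure, all as
#' percentages.  The F-measure defaults to the harmonic mean
#' `2*precision*recall/(precision+recall)` (F1); a geometric-mean
#' variant `sqrt(precision*recall)` is available via
#' `f_mode = "geometric"`.  A metric whose denominator is zero is `NaN`
#' with a warning.
#'
#' @param counts One-row confusion tibble from [confusion_at_cutoff()].
#' @param f_mode `"harmonic"` (default) or `"geometric"`.
#' @return One-row tibble `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f_measure`, in percent.
#' @export
threshold_metrics <- function(counts, f_mode = c("harmonic", "geometric")) {
  f_mode <- match.arg(f_mode)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  frac <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined (zero denominator)", what))
      return(NaN)
    }
    num / den
  }
  sens <- frac(tp, tp + fn, "sensitivity")
  spec <- frac(tn, tn + fp, "specificity")
  acc <- frac(tp + tn, tp + fp + tn + fn, "accuracy")
  prec <- frac(tp, tp + fp, "precision")
  f <- if (!is.finite(sens) || !is.finite(prec)) {
    NaN
  } else if (f_mode == "harmonic") {
    if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  } else {
    sqrt(prec * sens)
  }
  tibble(accuracy = 100 * acc, sensitivity = 100 * sens,
         specificity = 100 * spec, precision = 100 * prec,
         f_measure = 100 * f)
}

#' ROC curve points
#'
#' Sweeps every distinct score as a threshold and returns the
#' (1 - specificity, sensitivity) operating points, including the (0,0)
#' and (1,1) endpoints.  Point k corresponds to predicting positive iff
#' `score >= cutoff[k]`.
#'
#' @inheritParams confusion_at_cutoff
#' @return A `roc_curve` tibble with columns `cutoff`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores) {
  y <- as.integer(scores$label)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("ROC requires both classes present")
  }
  o <- order(scores$score, decreasing = TRUE)
  s <- scores$score[o]; yo <- y[o]
  cum_tp <- cumsum(yo)
  cum_fp <- cumsum(1L - yo)
  last <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  out <- tibble(
    cutoff = c(Inf, s[last]),
    fpr = c(0, cum_fp[last] / n_neg),
    tpr = c(0, cum_tp[last] / n_pos)
  )
  structure(out, class = c("roc_curve", class(out)))
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the ROC points of [roc_curve()].  With ties
#' handled by the diagonal segments this equals the Mann-Whitney
#' U statistic normalised by `n_pos * n_neg` (tied pairs counting 1/2).
#'
#' @inheritParams confusion_at_cutoff
#' @return AUC as a fraction in \[0, 1\].
#' @export
roc_auc <- function(scores) {
  rc <- roc_curve(scores)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}

#' Scan cutoffs for the best F-measure
#'
#' Evaluates the F-measure at every distinct score value (plus a
#' sentinel below the minimum, i.e. the all-positive prediction) and
#' returns the maximiser; ties go to the lowest cutoff.
#'
#' @inheritParams confusion_at_cutoff
#' @inheritParams threshold_metrics
#' @return One-row tibble: `cutoff` plus the [threshold_metrics()]
#'   columns at that cutoff.
#' @export
best_f_scan <- function(scores, f_mode = c("harmonic", "geometric")) {
  f_mode <- match.arg(f_mode)
  cand <- sort(unique(scores$score))
  cand <- c(cand[1] - 1, cand)
  fs <- vapply(cand, function(ct) {
    m <- suppressWarnings(threshold_metrics(confusion_at_cutoff(scores, ct),
                                            f_mode))
    if (is.finite(m$f_measure)) m$f_measure else -Inf
  }, numeric(1))
  best <- cand[which.max(fs)]   # which.max takes the first (lowest) maximiser
  m <- suppressWarnings(threshold_metrics(confusion_at_cutoff(scores, best),
                                          f_mode))
  dplyr::bind_cols(tibble(cutoff = best), m)
}

#' Prediction performance report
#'
#' The package's summary of a score set, in the layout of a per-ligand
#' performance table: threshold metrics at the best-F cutoff plus the
#' cutoff-free AUC, all in percent.
#'
#' @inheritParams confusion_at_cutoff
#' @inheritParams threshold_metrics
#' @return One-row tibble `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f_measure`, `auc` (percent), `cutoff_at_best_f`.
#' @export
prediction_report <- function(scores, f_mode = c("harmonic", "geometric")) {
  bf <- best_f_scan(scores, f_mode)
  tibble(
    accuracy = bf$accuracy, sensitivity = bf$sensitivity,
    specificity = bf$specificity, precision = bf$precision,
    f_measure = bf$f_measure, auc = 100 * roc_auc(scores),
    cutoff_at_best_f = bf$cutoff
  )
}
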