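# Confusion-based performance metrics, rank-based AUC, per-action breakdown,
# and mean +/- SD aggregation over the re-training repeats.

#' Confusion-based metrics for binary tremor/voluntary labels
#'
#' Positive class = tremulous motion. Computes the confusion counts and
#' accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and F1
#' `2*precision*sensitivity/(precision+sensitivity)`. A metric with a zero
#' denominator is reported as `NA` and listed in the `undefined` element —
#' never silently coerced to 0, which would corrupt aggregation.
#'
#' @param y_true,y_pred binary vectors of equal length.
#' @return A list of class `metrics_report`: `counts` (TP, TN, FP, FN),
#'   `accuracy`, `precision`, `sensitivity`, `specificity`, `f1`,
#'   `undefined` (character vector of flagged metrics), and `n`.
#' @export
#' @examples
#' confusion_metrics(c(1,1,1,1,0,0,0,0,0,0), c(1,1,1,0,1,0,0,0,0,0))
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("confusion_metrics: empty input")
  if (length(y_true) != length(y_pred))
    stop("confusion_metrics: length mismatch")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% 0:1))
    stop("confusion_metrics: labels must be binary 0/1")
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  sensitivity <- ratio(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            precision + sensitivity == 0) NA_real_
        else 2 * precision * sensitivity / (precision + sensitivity)
  out <- list(counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
              accuracy = (tp + tn) / length(y_true),
              precision = precision, sensitivity = sensitivity,
              specificity = ratio(tn, tn + fp), f1 = f1,
              n = length(y_true))
  out$undefined <- names(which(vapply(
    out[c("precision", "sensitivity", "specificity", "f1")], is.na,
    logical(1))))
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report: n=%d  acc=%.3f  prec=%s  sens=%s  ",
                     "spec=%s  f1=%s%s>\n"),
              x$n, x$accuracy, fmt_na(x$precision), fmt_na(x$sensitivity),
              fmt_na(x$specificity), fmt_na(x$f1),
              if (!is.null(x$auc_roc)) sprintf("  auc=%.3f", x$auc_roc)
              else ""))
  invisible(x)
}

fmt_na <- function(v) if (is.na(v)) "undef" else sprintf("%.3f", v)

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with midranks for tied scores;
#' equivalent to trapezoidal integration of the ROC curve and invariant under
#' strictly monotone transforms of the scores.
#'
#' @param y_true binary labels (both classes required).
#' @param scores numeric classifier scores (higher = more tremulous).
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0)
    stop("auc_roc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate predictions into a full metrics report
#'
#' [confusion_metrics()] plus [auc_roc()] when scores are supplied.
#'
#' @inheritParams confusion_metrics
#' @param scores optional numeric scores for the AUC.
#' @return a `metrics_report` with an `auc_roc` element when scores given.
#' @export
evaluate_predictions <- function(y_true, y_pred, scores = NULL) {
  rep <- confusion_metrics(y_true, y_pred)
  if (!is.null(scores)) rep$auc_roc <- auc_roc(y_true, scores)
  rep
}

#' Aggregate metric reports over re-training repeats
#'
#' Per-metric sample mean and sample standard deviation (n-1 denominator)
#' across repeats; `NA` (undefined) values are dropped per metric, with the
#' count of contributing repeats reported.
#'
#' @param reports list of `metrics_report`s (>= 2 for an SD).
#' @return data frame: `metric`, `mean`, `sd`, `n_defined`.
#' @export
aggregate_repeats <- function(reports) {
  metrics <- c("accuracy", "precision", "sensitivity", "specificity", "f1",
               "auc_roc")
  rows <- lapply(metrics, function(m) {
    v <- vapply(reports, function(r)
      if (is.null(r[[m]])) NA_real_ else r[[m]], numeric(1))
    v_ok <- v[!is.na(v)]
    if (length(v_ok) == 0) return(NULL)
    data.frame(metric = m, mean = mean(v_ok),
               sd = if (length(v_ok) > 1) sd(v_ok) else NA_real_,
               n_defined = length(v_ok))
  })
  do.call(rbind, rows)
}

#' Per-activity metrics breakdown
#'
#' Restricts the confusion metrics to each activity's windows; pooled counts
#' across activities partition the overall counts.
#'
#' @inheritParams confusion_metrics
#' @param action_tags character/factor vector tagging each window with its
#'   activity; must have no missing entries.
#' @param scores optional scores for per-action AUC (computed only where both
#'   classes occur).
#' @return named list of `metrics_report`s, one per activity.
#' @export
per_action_report <- function(y_true, y_pred, action_tags, scores = NULL) {
  if (length(action_tags) != length(y_true))
    stop("per_action_report: tags must cover all windows")
  if (anyNA(action_tags)) stop("per_action_report: unknown (NA) action tag")
  acts <- unique(as.character(action_tags))
  out <- lapply(acts, function(a) {
    i <- which(action_tags == a)
    rep <- confusion_metrics(y_true[i], y_pred[i])
    if (!is.null(scores) && length(unique(y_true[i])) == 2)
      rep$auc_roc <- auc_roc(y_true[i], scores[i])
    rep
  })
  stats::setNames(out, acts)
}

#' Export metric reports as a CSV table
#'
#' One row per report (e.g. per repeat or per action), columns shaped like a
#' published performance table: accuracy in percent, the remaining metrics as
#' proportions.
#'
#' @param reports named list of `metrics_report`s.
#' @param path CSV file path.
#' @return the data frame written, invisibly.
#' @export
write_metrics_csv <- function(reports, path) {
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(name = nm, n = r$n, accuracy_pct = 100 * r$accuracy,
               precision = r$precision, sensitivity = r$sensitivity,
               specificity = r$specificity, f1 = r$f1,
               auc_roc = if (is.null(r$auc_roc)) NA_real_ else r$auc_roc)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
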