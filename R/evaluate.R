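#' Collapse two-label model outputs to a single forecast score
#'
#' For two-label paradigms the per-minute classifier emits a
#' (pre-ictal, inter-ictal) score pair. The receiver-operator score is a
#' fixed linear combination, `pre - inter`: any strictly monotone linear
#' combination with a positive pre-ictal weight induces the same ROC
#' ordering once the threshold is swept, so the weights are not tunable.
#'
#' @param pre_score numeric vector of pre-ictal outputs in \[0, 1\].
#' @param inter_score numeric vector of inter-ictal outputs, same length.
#' @return numeric vector of scalar scores, higher = more pre-ictal.
#' @export
combine_scores <- function(pre_score, inter_score) {
  if (length(pre_score) != length(inter_score))
    stop("pre_score and inter_score must have the same length")
  pre_score - inter_score
}

#' ROC curve and AUC for a two-class forecast
#'
#' Sweeps a threshold over the unique scores (predict positive when
#' score >= threshold), producing the ROC curve; the AUC is computed by
#' trapezoidal integration, which with this sweep equals the
#' Mann-Whitney U statistic divided by `n_pos * n_neg` (ties counted at
#' rank midpoint, i.e. 1/2 per tied pair).
#'
#' @param scores numeric vector of forecast scores.
#' @param labels logical or 0/1 vector; `TRUE`/1 marks the positive
#'   (pre-ictal) class.
#' @return an object of class `roc_result` with elements `thresholds`,
#'   `tpr`, `fpr` (curve from (0,0) to (1,1)), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to form a ROC curve")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores so the curve moves diagonally through ties
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  tp_by_thr <- tapply(as.integer(y), grp, sum)
  n_by_thr <- tapply(rep(1L, length(y)), grp, sum)
  tp <- cumsum(tp_by_thr)
  fp <- cumsum(n_by_thr - tp_by_thr)
  thresholds <- s[!duplicated(grp)]

  tpr <- unname(c(0, tp / n_pos))
  fpr <- unname(c(0, fp / n_neg))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)

  structure(
    list(thresholds = c(Inf, thresholds), tpr = tpr, fpr = fpr,
         auc = unname(auc), n_pos = n_pos, n_neg = n_neg),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (n_pos = %d, n_neg = %d, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Closed-form standard error of the AUC based on its Mann-Whitney
#' interpretation:
#' `SE^2 = [A(1-A) + (n_pos-1)(Q1 - A^2) + (n_neg-1)(Q2 - A^2)] / (n_pos n_neg)`
#' with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`. The half-width is
#' `z * SE` at the requested level (1.96 at 95%).
#'
#' @param auc AUC in \[0, 1\].
#' @param n_pos,n_neg positive / negative sample counts (>= 1).
#' @param level confidence level, default 0.95.
#' @return an object of class `auc_ci` with `auc`, `se`, `half_width`,
#'   `lower`, `upper`, `n_pos`, `n_neg`, `level`.
#' @export
hanley_mcneil_ci <- function(auc, n_pos, n_neg, level = 0.95) {
  stopifnot(n_pos >= 1, n_neg >= 1, level > 0, level < 1)
  if (auc < 0 || auc > 1) stop("auc must lie in [0, 1]")
  a <- auc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se2 <- (a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
    (n_pos * n_neg)
  se <- sqrt(max(se2, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  hw <- z * se
  structure(
    list(auc = a, se = se, half_width = hw,
         lower = a - hw, upper = a + hw,
         n_pos = n_pos, n_neg = n_neg, level = level),
    class = "auc_ci")
}

#' @export
print.auc_ci <- function(x, ...) {
  cat(sprintf("AUC %.2f (±%.3f) [%d%% CI %.3f-%.3f], n+ = %d, n- = %d\n",
              x$auc, x$half_width, round(100 * x$level), x$lower, x$upper,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Significance rules for comparing AUCs
#'
#' Two AUCs differ significantly when their confidence intervals do not
#' overlap; an AUC beats a random predictor when the lower bound of its
#' confidence interval exceeds 0.5.
#'
#' @param a,b `auc_ci` objects (see [hanley_mcneil_ci()]).
#' @return `compare_aucs`: `TRUE` if the intervals do not overlap.
#' @export
compare_aucs <- function(a, b) {
  stopifnot(inherits(a, "auc_ci"), inherits(b, "auc_ci"))
  a$upper < b$lower || b$upper < a$lower
}

#' @rdname compare_aucs
#' @return `vs_random`: `TRUE` if the lower CI bound is above 0.5.
#' @export
vs_random <- function(a) {
  stopifnot(inherits(a, "auc_ci"))
  a$lower > 0.5
}

#' Sensitivity / time-in-high operating points along a ROC sweep
#'
#' Sample-level operating points: at each threshold, sensitivity is the
#' proportion of pre-ictal samples predicted pre-ictal and time-in-high
#' is the proportion of *all* samples predicted pre-ictal (time spent in
#' warning). Both are monotone non-increasing in the threshold.
#'
#' @param roc a `roc_result`.
#' @return data.frame with columns `threshold`, `sensitivity`,
#'   `time_in_high`.
#' @export
operating_points <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  sens <- roc$tpr
  tih <- (roc$tpr * roc$n_pos + roc$fpr * roc$n_neg) / (roc$n_pos + roc$n_neg)
  data.frame(threshold = roc$thresholds, sensitivity = sens,
             time_in_high = tih)
}

#' Find the operating point closest to a target
#'
#' Looks up the threshold whose achieved sensitivity (or time-in-high)
#' is closest to the target, enabling direct comparison with published
#' operating points; ties break toward the lower time-in-high.
#'
#' @param roc a `roc_result`.
#' @param target_sensitivity,target_time_in_high exactly one must be
#'   given; the quantity to match.
#' @return one-row data.frame as in [operating_points()].
#' @export
match_point <- function(roc, target_sensitivity = NULL,
                        target_time_in_high = NULL) {
  op <- operating_points(roc)
  if (is.null(target_sensitivity) == is.null(target_time_in_high))
    stop("give exactly one of target_sensitivity or target_time_in_high")
  achieved <- if (!is.null(target_sensitivity)) op$sensitivity else op$time_in_high
  target <- if (!is.null(target_sensitivity)) target_sensitivity else target_time_in_high
  d <- abs(achieved - target)
  best <- which(d == min(d))
  best <- best[which.min(op$time_in_high[best])]
  op[best, , drop = FALSE]
}

#' Multi-class confusion matrix with a time-matched random baseline
#'
#' Builds the confusion matrix (rows = actual, columns = predicted), its
#' row-normalized view, total accuracy, and per-label selection
#' proportions. The baseline is a random predictor that selects each
#' label with the model's own selection proportion: its expected
#' row-normalized sensitivity for a label equals that proportion. The
#' report flags labels where the model's sensitivity exceeds the
#' baseline, and where it exceeds it by more than 0.1.
#'
#' @param predictions,labels integer vectors of predicted / actual
#'   labels in `0:(n_labels-1)`.
#' @param n_labels number of labels.
#' @return an object of class `confusion_report`.
#' @export
confusion_and_baseline <- function(predictions, labels, n_labels) {
  stopifnot(length(predictions) == length(labels), n_labels >= 2)
  if (any(predictions < 0 | predictions >= n_labels) ||
      any(labels < 0 | labels >= n_labels))
    stop("labels and predictions must lie in 0:(n_labels-1)")
  lv <- 0:(n_labels - 1)
  counts <- table(factor(labels, levels = lv), factor(predictions, levels = lv))
  counts <- matrix(as.integer(counts), n_labels, n_labels,
                   dimnames = list(actual = lv, predicted = lv))
  n <- sum(counts)
  row_tot <- rowSums(counts)
  normalized <- counts / ifelse(row_tot == 0, NA_real_, row_tot)
  accuracy <- sum(diag(counts)) / n
  selection <- colSums(counts) / n          # proportion of time each label chosen
  sensitivity <- diag(counts) / ifelse(row_tot == 0, NA_real_, row_tot)
  structure(
    list(counts = counts, normalized = normalized, accuracy = accuracy,
         selection = selection, sensitivity = sensitivity,
         baseline = selection,
         beats_baseline = sensitivity > selection,
         beats_baseline_by_0.1 = sensitivity > selection + 0.1,
         n = n),
    class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("Confusion matrix (%d samples), total accuracy %.3f\n",
              x$n, x$accuracy))
  print(x$counts)
  cat("Per-label sensitivity vs time-matched random baseline:\n")
  print(round(rbind(sensitivity = x$sensitivity, baseline = x$baseline), 3))
  invisible(x)
}
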