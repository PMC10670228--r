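# Confusion matrix, one-vs-rest sensitivity/specificity, ROC/AUC and
# patient-grouped accuracy reporting.

#' Confusion matrix over the three grades
#'
#' Rows are true classes, columns predicted, in the canonical order
#' (IA, MIA, NOR).
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param normalize Also compute the row-normalized matrix.
#' @return Object of class `oct_confusion`: `counts` (3 x 3 integer
#'   matrix), `normalized` (row proportions, `NaN` rows for absent
#'   classes), `n`.
#' @export
#' @examples
#' cm <- confusion_matrix(c("IA", "MIA", "NOR"), c("IA", "MIA", "MIA"))
#' cm$counts
confusion_matrix <- function(true_labels, predicted_labels, normalize = TRUE) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) == 0) oct_abort("empty input")
  if (length(true_labels) != length(predicted_labels)) {
    oct_abort("label vectors must have equal length")
  }
  if (!all(c(true_labels, predicted_labels) %in% GRADE_LEVELS)) {
    oct_abort("labels must be in {", paste(GRADE_LEVELS, collapse = ", "), "}")
  }
  counts <- table(factor(true_labels, GRADE_LEVELS),
                  factor(predicted_labels, GRADE_LEVELS))
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(true = GRADE_LEVELS, predicted = GRADE_LEVELS))
  norm <- if (normalize) sweep(counts, 1, rowSums(counts), "/") else NULL
  structure(list(counts = counts, normalized = norm,
                 n = length(true_labels), class_order = GRADE_LEVELS),
            class = "oct_confusion")
}

#' @export
print.oct_confusion <- function(x, ...) {
  cat("<oct_confusion> rows = true, cols = predicted\n")
  print(x$counts)
  invisible(x)
}

#' Per-class sensitivity/specificity and overall accuracy
#'
#' One-vs-rest decomposition of the confusion matrix: for class c,
#' sensitivity = TP / (TP + FN) and specificity = TN / (TN + FP). Overall
#' accuracy is trace / total. Metrics undefined because a class has no true
#' (or no negative) samples are returned as `NA` with a warning, never as
#' silent zeros.
#'
#' @param cm An [confusion_matrix()] result.
#' @return Object of class `oct_class_metrics`: `sensitivity`,
#'   `specificity` (named per class), `overall_accuracy`.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "oct_confusion"))
  m <- cm$counts
  total <- sum(m)
  if (total == 0) oct_abort("empty confusion matrix")
  sens <- spec <- setNames(rep(NA_real_, 3), GRADE_LEVELS)
  for (i in 1:3) {
    tp <- m[i, i]
    fn <- sum(m[i, -i])
    fp <- sum(m[-i, i])
    tn <- total - tp - fn - fp
    if (tp + fn > 0) sens[i] <- tp / (tp + fn)
    if (tn + fp > 0) spec[i] <- tn / (tn + fp)
  }
  if (anyNA(c(sens, spec))) {
    warning("metrics undefined for classes without samples (returned NA)",
            call. = FALSE)
  }
  structure(list(sensitivity = sens, specificity = spec,
                 overall_accuracy = sum(diag(m)) / total),
            class = "oct_class_metrics")
}

#' @export
print.oct_class_metrics <- function(x, ...) {
  cat(sprintf("<oct_class_metrics> accuracy %.1f%%\n",
              100 * x$overall_accuracy))
  for (cl in names(x$sensitivity)) {
    cat(sprintf("  %s: sensitivity %.1f%%, specificity %.1f%%\n", cl,
                100 * x$sensitivity[cl], 100 * x$specificity[cl]))
  }
  invisible(x)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps the decision threshold over the scores of the target class and
#' reports the true/false positive rates. The AUC is computed by the rank
#' (concordance) formula: the probability that a random positive outranks a
#' random negative, ties counted one half — identical (to numerical
#' precision) to trapezoidal integration of the ROC curve with midpoint tie
#' handling.
#'
#' @param true_labels Label vector.
#' @param scores Numeric score for the target class (e.g. its predicted
#'   probability), same length.
#' @param target_class The positive class.
#' @return Object of class `oct_roc`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
#' @examples
#' roc_auc(c("IA", "IA", "NOR", "NOR"), c(0.9, 0.6, 0.7, 0.2), "IA")$auc
roc_auc <- function(true_labels, scores, target_class) {
  target_class <- check_class_label(target_class)
  true_labels <- as.character(true_labels)
  if (length(true_labels) != length(scores)) {
    oct_abort("`true_labels` and `scores` must have equal length")
  }
  pos <- true_labels == target_class
  if (!any(pos) || all(pos)) {
    oct_abort("need both positive and negative examples for a ROC curve")
  }
  # rank formula with midpoint ties
  r <- rank(scores)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 target_class = target_class),
            class = "oct_roc")
}

#' @export
print.oct_roc <- function(x, ...) {
  cat(sprintf("<oct_roc> %s vs rest: AUC %.3f (%d thresholds)\n",
              x$target_class, x$auc, length(x$thresholds)))
  invisible(x)
}

#' Trapezoidal AUC from a ROC curve
#'
#' Independent integration route over the (FPR, TPR) polyline; agrees with
#' the rank formula of [roc_auc()] to numerical precision.
#'
#' @param roc An `oct_roc`.
#' @return Scalar AUC.
#' @export
roc_trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  fpr <- roc$fpr[o]; tpr <- roc$tpr[o]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Guard against patient leakage between splits
#'
#' Errors when any patient identifier occurs in more than one split; all
#' data separations must be based on individual patients, never frames.
#'
#' @param patients Patient identifier per observation.
#' @param split Split tag per observation (e.g. "train"/"test").
#' @return Invisibly `TRUE` when the split is patient-disjoint.
#' @export
assert_patient_disjoint <- function(patients, split) {
  if (length(patients) != length(split)) {
    oct_abort("`patients` and `split` must have equal length")
  }
  tab <- unique(data.frame(patients = as.character(patients),
                           split = as.character(split)))
  dup <- tab$patients[duplicated(tab$patients)]
  if (length(dup) > 0) {
    oct_abort("patients present in multiple splits: ",
              paste(unique(dup), collapse = ", "))
  }
  invisible(TRUE)
}

#' Frame-level and volume-level evaluation of predictions
#'
#' Computes the confusion matrix and class metrics at frame level and,
#' when volume identifiers are given, at volume level by majority vote over
#' each volume's frames (probability-sum tie-break). If `patients` and
#' `split` are provided the split must be patient-disjoint.
#'
#' @param true_labels Frame-level true labels.
#' @param predictions Data frame from [predict.oct_model()] (or any frame
#'   with `IA`, `MIA`, `NOR`, `predicted_class`).
#' @param volumes Optional volume id per frame.
#' @param patients,split Optional patient ids and split tags (checked with
#'   [assert_patient_disjoint()]).
#' @return List with `frame` (`oct_class_metrics`), `frame_confusion`, and
#'   when volumes are given `volume` / `volume_confusion`.
#' @export
evaluate_predictions <- function(true_labels, predictions, volumes = NULL,
                                 patients = NULL, split = NULL) {
  if (!is.null(patients) && !is.null(split)) {
    assert_patient_disjoint(patients, split)
  }
  cm <- confusion_matrix(true_labels, predictions$predicted_class)
  out <- list(frame_confusion = cm, frame = class_metrics(cm))
  if (!is.null(volumes)) {
    agg_true <- tapply(as.character(true_labels), volumes, function(v) v[1])
    probs <- as.matrix(predictions[, GRADE_LEVELS])
    agg_pred <- vapply(split(seq_along(volumes), volumes), function(idx) {
      votes <- table(factor(predictions$predicted_class[idx], GRADE_LEVELS))
      top <- names(votes)[votes == max(votes)]
      if (length(top) == 1) return(top)
      # tie: highest summed probability, canonical order breaking exact ties
      sums <- colSums(probs[idx, top, drop = FALSE])
      top[which.max(sums)]
    }, character(1))
    vcm <- confusion_matrix(as.character(agg_true), agg_pred[names(agg_true)])
    out$volume_confusion <- vcm
    out$volume <- class_metrics(vcm)
  }
  out
}
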