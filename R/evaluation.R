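#' Confusion counts for a binary comparison
#'
#' @param predicted_labels,true_labels Equal-length label vectors; the
#'   truth must contain at most two distinct labels.
#' @param positive_label Label counted as "case".
#' @return A `confusion_table`: list with `tp`, `fn`, `tn`, `fp`.
#' @export
confusion <- function(predicted_labels, true_labels, positive_label) {
  if (length(predicted_labels) != length(true_labels))
    stop_("predicted and true label vectors differ in length")
  lev <- unique(as.character(true_labels))
  if (length(lev) > 2L)
    stop_("truth must be binary; got labels: %s", paste(lev, collapse = ", "))
  if (!positive_label %in% lev)
    stop_("positive_label %s absent from truth", sQuote(positive_label))
  bad <- setdiff(unique(as.character(predicted_labels)), lev)
  if (length(bad) > 0L)
    stop_("predicted label(s) outside truth labels: %s",
          paste(bad, collapse = ", "))
  pos_t <- true_labels == positive_label
  pos_p <- predicted_labels == positive_label
  structure(list(tp = sum(pos_t & pos_p), fn = sum(pos_t & !pos_p),
                 tn = sum(!pos_t & !pos_p), fp = sum(!pos_t & pos_p)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  TN %d  FP %d\n", x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Sensitivity and specificity of a confusion table
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).  Errors (rather
#' than silently returning 0) when a class is empty and the metric is
#' undefined.
#'
#' @param table A `confusion_table`.
#' @return List with `sensitivity` and `specificity`.
#' @export
sens_spec <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  if (table$tp + table$fn == 0L)
    stop_("no true cases: sensitivity undefined")
  if (table$tn + table$fp == 0L)
    stop_("no true controls: specificity undefined")
  list(sensitivity = table$tp / (table$tp + table$fn),
       specificity = table$tn / (table$tn + table$fp))
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p by summation of hypergeometric probabilities at most that
#' of the observed table (with the customary 1 + 1e-7 relative tolerance
#' for ties), margins fixed.  Implemented by direct enumeration over the
#' support; the suite checks agreement with the reference implementation
#' to 1e-10.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p value.
#' @export
fisher_exact <- function(table) {
  if (!all(dim(table) == c(2L, 2L))) stop_("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop_("counts must be nonnegative integers")
  a <- table[1, 1]
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps score thresholds (tied scores grouped), producing one
#' (FPR, TPR) point per distinct score plus the (0,0) and (1,1) anchors;
#' AUC by the trapezoid rule, which for a finite score set equals the
#' Mann-Whitney exceedance probability P(case score > control score) +
#' 0.5 P(tie).
#'
#' @param decision_scores Numeric scores, larger = more case-like.
#' @param true_labels Labels, two classes.
#' @param positive_label Case label.
#' @return List with `roc_points` (data frame `threshold`, `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_auc <- function(decision_scores, true_labels, positive_label) {
  if (length(decision_scores) != length(true_labels))
    stop_("scores and labels differ in length")
  pos <- true_labels == positive_label
  if (!any(pos) || all(pos))
    stop_("need at least one case and one control")
  if (length(unique(decision_scores)) == 1L) {
    warning("constant decision scores: AUC is 0.5", call. = FALSE)
    pts <- data.frame(threshold = c(Inf, unique(decision_scores)),
                      fpr = c(0, 1), tpr = c(0, 1))
    return(list(roc_points = pts, auc = 0.5))
  }
  thr <- sort(unique(decision_scores), decreasing = TRUE)
  np <- sum(pos); nn <- sum(!pos)
  tpr <- vapply(thr, function(t) sum(decision_scores >= t & pos) / np,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(decision_scores >= t & !pos) / nn,
                numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(roc_points = pts, auc = auc)
}

#' Full evaluation of one binary comparison
#'
#' @param decision_scores Numeric scores (larger = case-like).
#' @param true_labels Truth labels.
#' @param positive_label Case label.
#' @param threshold Calls are positive when the score strictly exceeds
#'   this (default 0, the kernel-classifier decision boundary; use 0.5
#'   with integer ratioscores so that scores >= 1 are positive).
#' @param comparison Optional comparison name for reports.
#' @return An `eval_report`: list with `comparison`, `confusion`,
#'   `sensitivity`, `specificity`, `roc_points`, `auc`.
#' @export
eval_report <- function(decision_scores, true_labels, positive_label,
                        threshold = 0, comparison = NULL) {
  lev <- unique(as.character(true_labels))
  negative <- setdiff(lev, positive_label)
  if (length(negative) != 1L) stop_("truth must have exactly two labels")
  pred <- ifelse(decision_scores > threshold, positive_label, negative)
  cm <- confusion(pred, true_labels, positive_label)
  ss <- sens_spec(cm)
  roc <- roc_auc(decision_scores, true_labels, positive_label)
  structure(list(comparison = comparison %||%
                   paste(positive_label, "vs", negative),
                 confusion = cm, sensitivity = ss$sensitivity,
                 specificity = ss$specificity,
                 roc_points = roc$roc_points, auc = roc$auc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s: sens %.3f, spec %.3f, AUC %.3f  (TP %d FN %d TN %d FP %d)\n",
              x$comparison, x$sensitivity, x$specificity, x$auc,
              x$confusion$tp, x$confusion$fn, x$confusion$tn, x$confusion$fp))
  invisible(x)
}

#' Confusion-count report (one row per comparison)
#'
#' @param reports List of `eval_report`s.
#' @return Data frame with columns Comparison, Total, TP, FN, TN, FP.
#' @export
confusion_report <- function(reports) {
  if (length(reports) == 0L)
    return(data.frame(Comparison = character(0), Total = integer(0),
                      TP = integer(0), FN = integer(0), TN = integer(0),
                      FP = integer(0)))
  do.call(rbind, lapply(reports, function(r) {
    cm <- r$confusion
    data.frame(Comparison = r$comparison,
               Total = cm$tp + cm$fn + cm$tn + cm$fp,
               TP = cm$tp, FN = cm$fn, TN = cm$tn, FP = cm$fp,
               stringsAsFactors = FALSE)
  }))
}

#' Accuracy report across total/training/validation sets
#'
#' Binds the per-set Tc/Ti/TOTAL/%I blocks of several cross-validated
#' holdout fits into one table.
#'
#' @param fits Named list of [train_cv_holdout()] results.
#' @return Data frame with columns comparison, set, Tc, Ti, TOTAL, pct_I.
#' @export
accuracy_report <- function(fits) {
  if (length(fits) == 0L)
    return(data.frame(comparison = character(0), set = character(0),
                      Tc = integer(0), Ti = integer(0), TOTAL = integer(0),
                      pct_I = numeric(0)))
  do.call(rbind, lapply(names(fits), function(nm) {
    cbind(comparison = nm, fits[[nm]]$report)
  }))
}

#' Sensitivity/specificity report across methods and comparisons
#'
#' @param entries Data frame-able list: each element a list with
#'   `comparison`, `method`, `sensitivity`, `specificity`.
#' @return Data frame, one row per (comparison, method).
#' @export
sens_spec_report <- function(entries) {
  if (length(entries) == 0L)
    return(data.frame(comparison = character(0), method = character(0),
                      sensitivity = numeric(0), specificity = numeric(0)))
  do.call(rbind, lapply(entries, function(e) {
    data.frame(comparison = e$comparison, method = e$method,
               sensitivity = e$sensitivity, specificity = e$specificity,
               stringsAsFactors = FALSE)
  }))
}

#' Write any report data frame as TSV
#'
#' @param report A data frame.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report)
}
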