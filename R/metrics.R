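## Evaluation suite: confusion matrix, one-vs-rest per-class rates,
## total accuracy, and trapezoidal ROC/AUC.

#' Confusion matrix
#'
#' @param y_true,y_pred Integer labels in `1..K` (equal length).
#' @param K Number of classes.
#' @return K x K integer matrix; rows are truth, columns prediction.
#' @export
confusion_matrix <- function(y_true, y_pred, K) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  y_true <- factor(as.integer(y_true), levels = seq_len(K))
  y_pred <- factor(as.integer(y_pred), levels = seq_len(K))
  m <- table(truth = y_true, prediction = y_pred)
  matrix(as.integer(m), K, K, dimnames = dimnames(m))
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For every class the matrix is collapsed one-vs-rest into TP/FN/FP/TN and
#' the standard rates are computed: accuracy (TP+TN)/N, sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), positive and negative predictive
#' values, and F1 (harmonic mean of sensitivity and PPV).  Total accuracy
#' is the number of correctly predicted samples over N (the trace).
#' Zero-denominator rates are reported as `NA` (undefined), never coerced
#' to 0, with the affected cells flagged.
#'
#' @param confusion K x K confusion matrix (rows truth, columns prediction).
#' @return List with `per_class` (data.frame: class, TP, FN, FP, TN, ACC,
#'   SEN, SPE, PPV, NPV, F1), `total_accuracy`, `macro` (mean of defined
#'   per-class rates), and `undefined` (logical matrix flagging NA rates).
#' @export
per_class_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  K <- nrow(confusion)
  stopifnot(K == ncol(confusion))
  N <- sum(confusion)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  rows <- lapply(seq_len(K), function(c) {
    TP <- confusion[c, c]
    FN <- sum(confusion[c, ]) - TP
    FP <- sum(confusion[, c]) - TP
    TN <- N - TP - FN - FP
    SEN <- safe_div(TP, TP + FN)
    PPV <- safe_div(TP, TP + FP)
    data.frame(
      class = c, TP = TP, FN = FN, FP = FP, TN = TN,
      ACC = safe_div(TP + TN, N),
      SEN = SEN,
      SPE = safe_div(TN, TN + FP),
      PPV = PPV,
      NPV = safe_div(TN, TN + FN),
      F1 = if (!is.na(SEN) && !is.na(PPV) && (SEN + PPV) > 0) {
        2 * SEN * PPV / (SEN + PPV)
      } else NA_real_
    )
  })
  per_class <- do.call(rbind, rows)
  rates <- per_class[, c("ACC", "SEN", "SPE", "PPV", "NPV", "F1")]
  list(
    per_class = per_class,
    total_accuracy = sum(diag(confusion)) / N,
    macro = colMeans(rates, na.rm = TRUE),
    undefined = is.na(as.matrix(rates))
  )
}

#' One-vs-rest ROC AUC per class (trapezoidal rule)
#'
#' @param scores Numeric matrix `(N, K)` of class probabilities (rows
#'   should sum to 1, e.g. softmax of the main-head logits).
#' @param y_true Integer labels in `1..K`.
#' @return Numeric vector of K AUC values; `NA` for classes absent from
#'   (or filling) the truth vector.
#' @export
roc_auc <- function(scores, y_true) {
  scores <- as.matrix(scores)
  K <- ncol(scores)
  y_true <- as.integer(y_true)
  vapply(seq_len(K), function(k) {
    pos <- y_true == k
    if (!any(pos) || all(pos)) return(NA_real_)
    binary_auc(scores[, k], pos)
  }, numeric(1))
}

## trapezoidal AUC of score vs binary truth; ties handled by grouping
## equal scores into a single threshold step (equivalent to counting
## tied positive-negative pairs at 1/2)
binary_auc <- function(score, pos) {
  o <- order(score, decreasing = TRUE)
  score <- score[o]; pos <- pos[o]
  P <- sum(pos); Ng <- sum(!pos)
  ## step once per distinct threshold (ties grouped: equivalent to
  ## counting tied positive-negative pairs at 1/2)
  grp_end <- which(c(score[-1] != score[-length(score)], TRUE))
  tp <- cumsum(pos)[grp_end]
  fp <- cumsum(!pos)[grp_end]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / Ng)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Full metrics report for a set of predictions
#'
#' @param y_true Integer labels `1..K`.
#' @param y_pred Predicted labels `1..K`.
#' @param scores Optional `(N, K)` probability matrix for AUC.
#' @param K Number of classes (default: max label seen).
#' @return Object of class `metrics_report`: confusion, per-class table,
#'   total accuracy, macro averages, and per-class AUC (if scores given).
#' @export
metrics_report <- function(y_true, y_pred, scores = NULL,
                           K = max(c(y_true, y_pred))) {
  cm <- confusion_matrix(y_true, y_pred, K)
  pm <- per_class_metrics(cm)
  auc <- if (!is.null(scores)) roc_auc(scores, y_true) else NULL
  structure(list(confusion = cm, per_class = pm$per_class,
                 total_accuracy = pm$total_accuracy, macro = pm$macro,
                 undefined = pm$undefined, auc = auc, n = sum(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics report (n = ", x$n, ")\n", sep = "")
  cat("Total accuracy:", formatC(x$total_accuracy, digits = 4, format = "f"),
      "\n")
  tab <- metrics_table(x)
  print(round(tab, 4))
  invisible(x)
}

#' Metrics table shaped rows = metric, columns = class
#'
#' @param report A `metrics_report`.
#' @return Numeric matrix with rows ACC/SEN/SPE/PPV/NPV/F1 (and AUC when
#'   available) and one column per class.
#' @export
metrics_table <- function(report) {
  pc <- report$per_class
  tab <- t(as.matrix(pc[, c("ACC", "SEN", "SPE", "PPV", "NPV", "F1")]))
  colnames(tab) <- paste0("class_", pc$class)
  if (!is.null(report$auc)) tab <- rbind(tab, AUC = report$auc)
  tab
}

#' Serialize a metrics report to JSON and CSV
#'
#' @param report A `metrics_report`.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_metrics_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(csv_path)) {
    tab <- metrics_table(report)
    utils::write.csv(data.frame(metric = rownames(tab), tab,
                                check.names = FALSE),
                     csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    obj <- list(confusion = unname(report$confusion),
                total_accuracy = report$total_accuracy,
                per_class = report$per_class,
                auc = report$auc)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                na = "null"),
               json_path)
  }
  invisible(report)
}
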