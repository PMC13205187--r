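#' Stratified train/validation/test split
#'
#' Per class, `train_frac` of the samples go to training (of which
#' `val_frac_of_train` are carved out for validation) and the rest to the
#' test set; class proportions are preserved within one sample. The split
#' is deterministic per seed; partitions are disjoint and exhaustive.
#'
#' @param labels Class label vector (each class needs >= 3 samples).
#' @param train_frac Fraction assigned to training, default 0.85.
#' @param val_frac_of_train Fraction of the training part held out for
#'   validation, default 0.20 (set 0 for a plain train/test split).
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.85,
                             val_frac_of_train = 0.20, seed = 1L) {
  y <- as.factor(labels)
  counts <- table(y)
  if (any(counts < 3L)) stop("every class needs >= 3 samples", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac in (0,1)", call. = FALSE)
  set.seed(seed)
  train <- integer(0); val <- integer(0); test <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    n_train <- round(train_frac * length(idx))
    n_train <- min(max(n_train, 1L), length(idx) - 1L)
    tr <- idx[seq_len(n_train)]
    test <- c(test, idx[-seq_len(n_train)])
    n_val <- round(val_frac_of_train * length(tr))
    if (n_val > 0L) {
      val <- c(val, tr[seq_len(n_val)])
      tr <- tr[-seq_len(n_val)]
    }
    train <- c(train, tr)
  }
  list(train = sort(train), validation = sort(val), test = sort(test))
}

#' Confusion matrix (rows = true class, columns = predicted class)
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param levels Class levels fixing row/column order; default the sorted
#'   union of observed labels.
#' @return Integer matrix of counts.
#' @export
confusion <- function(y_true, y_pred, levels = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (is.null(levels)) levels <- sort(unique(c(as.character(y_true),
                                               as.character(y_pred))))
  ft <- factor(y_true, levels = levels)
  fp <- factor(y_pred, levels = levels)
  if (any(is.na(ft)) || any(is.na(fp))) {
    stop("label outside the declared levels", call. = FALSE)
  }
  m <- table(ft, fp)
  matrix(as.integer(m), nrow = length(levels),
         dimnames = list(true = levels, predicted = levels))
}

#' Macro-averaged classification report from a confusion matrix
#'
#' Per class c: `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`; macro metrics are the unweighted class means and
#' overall accuracy is `trace / total`. A class never predicted (or never
#' present) contributes 0 to the affected metric, with a warning.
#'
#' @param matrix Square confusion-count matrix (rows = true).
#' @return A `classification_report`: list with `confusion_matrix`,
#'   `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`, and a
#'   `per_class` data frame (TP/FP/FN/TN, precision, recall, f1).
#' @export
macro_report <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square", call. = FALSE)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  k <- nrow(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  if (any(tp + fp == 0) || any(tp + fn == 0)) {
    warning("class with no predicted (or no true) instances: metric set to 0")
  }
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  cls <- rownames(m)
  if (is.null(cls)) cls <- as.character(seq_len(k))
  structure(
    list(
      confusion_matrix = m,
      accuracy = sum(tp) / total,
      macro_precision = mean(prec),
      macro_recall = mean(rec),
      macro_f1 = mean(f1),
      per_class = data.frame(class = cls, TP = tp, FP = fp, FN = fn, TN = tn,
                             precision = prec, recall = rec, f1 = f1,
                             row.names = NULL)
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> accuracy %.2f%% | macro P %.2f%% R %.2f%% F1 %.2f%%\n",
    100 * x$accuracy, 100 * x$macro_precision, 100 * x$macro_recall,
    100 * x$macro_f1))
  print(x$confusion_matrix)
  invisible(x)
}

#' McNemar's paired test of two classifiers
#'
#' Counts test samples where classifier A is right and B wrong (`b`) and
#' vice versa (`c`); the statistic is `(|b - c| - 1)^2 / (b + c)` with the
#' continuity correction (default) or `(b - c)^2 / (b + c)` without, with a
#' chi-square (1 df) p value. `b + c = 0` gives statistic 0, p 1.
#'
#' @param y_true True labels.
#' @param pred_a,pred_b Predictions of the two classifiers.
#' @param correction Apply the continuity correction (default `TRUE`).
#' @return A `mcnemar_result`: list with `b`, `c`, `chi_square`, `p_value`.
#' @export
mcnemar <- function(y_true, pred_a, pred_b, correction = TRUE) {
  if (length(y_true) != length(pred_a) || length(y_true) != length(pred_b)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  right_a <- pred_a == y_true
  right_b <- pred_b == y_true
  b <- sum(right_a & !right_b)
  c_ <- sum(!right_a & right_b)
  if (b + c_ == 0) {
    stat <- 0; p <- 1
  } else {
    num <- if (correction) (abs(b - c_) - 1)^2 else (b - c_)^2
    stat <- num / (b + c_)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(b = as.integer(b), c = as.integer(c_), chi_square = stat,
                 p_value = p),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("<mcnemar_result> b=%d c=%d chi2=%.3f p=%.4g\n",
              x$b, x$c, x$chi_square, x$p_value))
  invisible(x)
}
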