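#' Confusion counts
#'
#' Counts true/false positives/negatives with +1 = nodule as the positive
#' class.
#'
#' @param y_true,y_pred label vectors of equal length (any dialect accepted
#'   by [canonical_labels()]).
#' @return an object of class `confusion_counts` with elements `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- canonical_labels(y_true)
  y_pred <- canonical_labels(y_pred)
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length: ", length(y_true), " vs ",
         length(y_pred))
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 TN = sum(y_true == -1L & y_pred == -1L),
                 FP = sum(y_true == -1L & y_pred == 1L),
                 FN = sum(y_true == 1L & y_pred == -1L)),
            class = "confusion_counts")
}

#' Confusion-matrix metrics
#'
#' \deqn{ACC = \frac{TP+TN}{TP+TN+FP+FN}, \; SEN = \frac{TP}{TP+FN}, \;
#'       SPE = \frac{TN}{TN+FP}, \; PRE = \frac{TP}{TP+FP},}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' A metric with a zero denominator is reported as `NA` (an explicit
#' "undefined" marker) rather than silently as 0, so summary statistics over
#' repeats are not corrupted.
#'
#' @param counts a `confusion_counts` object.
#' @return named numeric vector `ACC`, `SEN`, `SPE`, `PRE`, `MCC`.
#' @export
basic_metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts"))
    stop("'counts' must be a confusion_counts object")
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  n <- tp + tn + fp + fn
  if (n == 0) stop("empty confusion table")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  c(ACC = (tp + tn) / n,
    SEN = rat(tp, tp + fn),
    SPE = rat(tn, tn + fp),
    PRE = rat(tp, tp + fp),
    MCC = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_)
}

#' Harmonic-mean F-score of accuracy and sensitivity
#'
#' \deqn{F = \frac{2 \cdot SEN \cdot ACC}{SEN + ACC}.}
#' This is the model's fitness and headline index: it balances the overall
#' recognition rate against the nodule detection rate (note it differs from
#' the conventional precision-recall F1).
#'
#' @param ACC accuracy in \[0, 1\].
#' @param SEN sensitivity in \[0, 1\].
#' @return the F-score; `NA` when both inputs are 0 or either is `NA`.
#' @export
f_score <- function(ACC, SEN) {
  if (is.na(ACC) || is.na(SEN)) return(NA_real_)
  if (ACC < 0 || ACC > 1 || SEN < 0 || SEN > 1)
    stop("ACC and SEN must lie in [0, 1]")
  if (ACC + SEN == 0) return(NA_real_)
  2 * SEN * ACC / (SEN + ACC)
}

#' ROC curve and AUC
#'
#' Sweeps a decision threshold over the unique scores (convention: score >=
#' threshold predicts positive), returning the ROC points and the
#' trapezoidal AUC — equal to the Mann-Whitney pair-concordance statistic
#' with ties counted one half.
#'
#' @param scores continuous decision scores.
#' @param y_true labels (both classes must be present).
#' @return list with `roc` (data frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, y_true) {
  y <- canonical_labels(y_true)
  if (length(scores) != length(y)) stop("lengths differ")
  if (length(unique(y)) < 2L)
    stop("ROC requires both classes in 'y_true'")
  np <- sum(y == 1L); nn <- sum(y == -1L)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # cumulative counts at each unique threshold (>= convention)
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(ys == 1L); fp <- cumsum(ys == -1L)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- data.frame(threshold = ss[last],
                    fpr = fp[last] / nn, tpr = tp[last] / np)
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), roc)
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc = roc, auc = auc)
}

#' Stratified fold assignment
#'
#' Assigns each sample a fold label 1..k with per-class balance: within each
#' class, fold sizes differ by at most one.
#'
#' @param y labels.
#' @param k number of folds; each class must have at least k members.
#' @param seed RNG seed (same seed, same folds).
#' @return integer fold vector.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  y <- canonical_labels(y)
  folds <- integer(length(y))
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  for (cl in c(1L, -1L)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stop("class ", cl, " has ", length(idx), " members; needs at least k = ", k)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

#' Cross-validated evaluation of a kernel/C configuration
#'
#' Stratified k-fold cross-validation: per fold, z-score normalization is
#' learned on the training part, the Gram matrix is built with `spec`, the
#' SVM is fit at box constraint `C`, and the held-out fold is predicted.
#' Fold predictions are pooled into a single confusion table (micro
#' aggregation) from which all metrics and the pooled-score AUC derive.
#'
#' @param table `feature_table` or feature matrix.
#' @param y labels if `table` is a matrix.
#' @param spec a [kernel_spec()].
#' @param C box constraint.
#' @param k folds.
#' @param seed fold-assignment seed.
#' @param normalize fold-local z-scoring.
#' @return an object of class `metrics_report`.
#' @export
cross_validate <- function(table, y = NULL, spec = kernel_spec("mix"), C = 1,
                           k = 5L, seed = 1L, normalize = TRUE) {
  if (inherits(table, "feature_table")) { y <- table$y; table <- table$x }
  x <- as_sample_matrix(table)
  y <- canonical_labels(y)
  folds <- stratified_folds(y, k, seed)
  pred <- integer(length(y)); score <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    xtr <- x[tr, , drop = FALSE]; xte <- x[!tr, , drop = FALSE]
    if (normalize) {
      norm <- fit_normalizer(xtr, warn = FALSE)
      xtr <- apply_normalizer(norm, xtr)
      xte <- apply_normalizer(norm, xte)
    }
    K <- kernel_matrix(spec, xtr)
    dual <- fit_svm(K, y[tr], C, kernel = spec, warn_indefinite = FALSE)
    Kt <- kernel_matrix(spec, xte, xtr)
    score[!tr] <- decision_values(dual, Kt)
    pred[!tr] <- predict_labels(dual, Kt)
  }
  metrics_report(y, pred, score, folds = folds)
}

#' Assemble a metrics report
#'
#' @param y_true,y_pred labels.
#' @param scores optional decision scores for ROC/AUC.
#' @param folds optional fold assignment stored alongside.
#' @return an object of class `metrics_report`: confusion counts, `ACC`,
#'   `SEN`, `SPE`, `PRE`, `MCC`, `F_score`, and `AUC`/`roc` when scores are
#'   supplied.
#' @export
metrics_report <- function(y_true, y_pred, scores = NULL, folds = NULL) {
  cc <- confusion(y_true, y_pred)
  m <- basic_metrics(cc)
  rep <- c(as.list(m), list(F_score = f_score(m[["ACC"]], m[["SEN"]]),
                            counts = cc, folds = folds))
  if (!is.null(scores)) {
    ra <- roc_auc(scores, y_true)
    rep$AUC <- ra$auc
    rep$roc <- ra$roc
    rep$scores <- scores
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cc <- x$counts
  cat("Recognition metrics (", cc$TP + cc$TN + cc$FP + cc$FN,
      " samples)\n", sep = "")
  cat("  TP =", cc$TP, " TN =", cc$TN, " FP =", cc$FP, " FN =", cc$FN, "\n")
  v <- c(ACC = x$ACC, SEN = x$SEN, SPE = x$SPE, PRE = x$PRE, MCC = x$MCC,
         F_score = x$F_score)
  if (!is.null(x$AUC)) v <- c(v, AUC = x$AUC)
  print(round(v, digits))
  invisible(x)
}

#' Repeat a stochastic procedure and summarize
#'
#' Runs `procedure(seed)` once per seed and reports per-metric mean, max,
#' median and min over the repeats (the standard 10-repeat protocol).
#'
#' @param procedure `function(seed)` returning a named numeric vector or a
#'   `metrics_report`.
#' @param n_repeats number of repeats.
#' @param seeds seeds, defaults to `1:n_repeats`.
#' @return an object of class `repeat_summary`: matrix `runs` (repeats x
#'   metrics) and data frame `summary` with rows mean/max/median/min.
#' @export
repeat_runs <- function(procedure, n_repeats = 10L, seeds = NULL) {
  if (n_repeats < 1L) stop("'n_repeats' must be at least 1")
  if (is.null(seeds)) seeds <- seq_len(n_repeats)
  if (length(seeds) != n_repeats) stop("need one seed per repeat")
  rows <- lapply(seeds, function(s) {
    out <- procedure(s)
    if (inherits(out, "metrics_report"))
      out <- c(F_score = out$F_score, ACC = out$ACC, SEN = out$SEN,
               SPE = out$SPE, PRE = out$PRE, MCC = out$MCC,
               if (!is.null(out$AUC)) c(AUC = out$AUC))
    out
  })
  runs <- do.call(rbind, rows)
  rownames(runs) <- paste0("run", seq_len(n_repeats))
  summ <- data.frame(
    mean = apply(runs, 2L, mean, na.rm = TRUE),
    max = apply(runs, 2L, max, na.rm = TRUE),
    median = apply(runs, 2L, median, na.rm = TRUE),
    min = apply(runs, 2L, min, na.rm = TRUE))
  structure(list(runs = runs, summary = summ, seeds = seeds),
            class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, digits = 4, ...) {
  cat("Summary over", nrow(x$runs), "repeats\n")
  print(round(t(as.matrix(x$summary)), digits))
  invisible(x)
}

#' Write a metrics report as delimited text
#'
#' One row of named metric columns; ROC points (if present) go to
#' `<path>_roc.csv`.
#'
#' @param report a `metrics_report`.
#' @param path output CSV path.
#' @export
write_metrics_report <- function(report, path) {
  cc <- report$counts
  row <- data.frame(TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
                    ACC = report$ACC, SEN = report$SEN, SPE = report$SPE,
                    PRE = report$PRE, MCC = report$MCC,
                    F_score = report$F_score,
                    AUC = if (is.null(report$AUC)) NA_real_ else report$AUC)
  write.csv(row, path, row.names = FALSE)
  if (!is.null(report$roc)) {
    write.csv(report$roc, sub("\\.csv$", "_roc.csv", path), row.names = FALSE)
  }
  invisible(path)
}
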