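# Independent scalar oracles used across the suite. All are deliberately
# naive (elementwise loops, O(n^2) enumeration) so they cannot share code
# paths with the vectorized implementations they check.

# elementwise kernel evaluation via explicit loops over sample pairs
oracle_gram <- function(X, Y, f) {
  K <- matrix(NA_real_, nrow(X), nrow(Y))
  for (i in seq_len(nrow(X)))
    for (j in seq_len(nrow(Y)))
      K[i, j] <- f(X[i, ], Y[j, ])
  K
}

# recursive flood fill, 8-neighbourhood, labelling from scratch
oracle_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  fill <- function(r, c, comp) {
    stack <- list(c(r, c))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      r <- p[1L]; c <- p[2L]
      if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask)) next
      if (!mask[r, c] || lab[r, c] != 0L) next
      lab[r, c] <<- comp
      for (dr in -1:1) for (dc in -1:1)
        if (dr != 0 || dc != 0) stack[[length(stack) + 1L]] <- c(r + dr, c + dc)
    }
  }
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    if (mask[r, c] && lab[r, c] == 0L) {
      comp <- comp + 1L
      fill(r, c, comp)
    }
  lab
}

# scalar confusion counting
oracle_confusion <- function(y_true, y_pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1L
    if (y_true[i] == -1 && y_pred[i] == -1) tn <- tn + 1L
    if (y_true[i] == -1 && y_pred[i] == 1) fp <- fp + 1L
    if (y_true[i] == 1 && y_pred[i] == -1) fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# all-pairs concordance AUC with ties counted one half
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == -1]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# brute-force metric formulas from counts
oracle_metrics <- function(cc) {
  tp <- cc$TP; tn <- cc$TN; fp <- cc$FP; fn <- cc$FN
  n <- tp + tn + fp + fn
  c(ACC = (tp + tn) / n,
    SEN = tp / (tp + fn),
    SPE = tn / (tn + fp),
    PRE = tp / (tp + fp),
    MCC = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
}

make_separable_table <- function(n_per_class = 30, dim = 5, delta = 8,
                                 seed = 99) {
  gen_feature_table(n_per_class, dim = dim, delta = delta, seed = seed)
}
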