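#' Cross-validated F-score fitness evaluator
#'
#' Builds the objective the hyperparameter search maximizes: for a candidate
#' position \eqn{(\lambda, C, a, r)} it assembles the mix kernel
#' \eqn{\lambda K_{poly}(d) + (1-\lambda) K_{sigmoid}(a, r)}, runs
#' stratified k-fold cross-validation on the feature table (z-score
#' normalization learned per training fold), pools the fold predictions into
#' one confusion table, and returns the harmonic mean
#' \eqn{F = 2 \cdot SEN \cdot ACC / (SEN + ACC)} of the pooled accuracy and
#' sensitivity.
#'
#' Fold assignment is fixed once at construction (same seed, same folds), so
#' the fitness is a deterministic function of the position. The fold-wise
#' feature inner products are precomputed, which makes each evaluation an
#' elementwise kernel assembly plus k SMO solves.
#'
#' @param table a `feature_table` (see [gen_feature_table()] /
#'   [read_feature_table()]), or a feature matrix.
#' @param y labels if `table` is a matrix.
#' @param k number of folds (each class must have at least k members).
#' @param d polynomial degree of the mix kernel.
#' @param seed RNG seed for the fold assignment.
#' @param tol,max_iter SMO solver settings.
#' @return an object of class `fitness_evaluator`.
#' @export
fitness_evaluator <- function(table, y = NULL, k = 5L, d = 2L, seed = 1L,
                              tol = 1e-3, max_iter = 200000L) {
  if (inherits(table, "feature_table")) { y <- table$y; table <- table$x }
  x <- as_sample_matrix(table)
  y <- canonical_labels(y)
  folds <- stratified_folds(y, k, seed)
  pre <- lapply(seq_len(k), function(f) {
    tr <- folds != f
    norm <- fit_normalizer(x[tr, , drop = FALSE], warn = FALSE)
    xtr <- apply_normalizer(norm, x[tr, , drop = FALSE])
    xte <- apply_normalizer(norm, x[!tr, , drop = FALSE])
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
      stop("fold ", f, " contains a single class")
    list(G_tr = tcrossprod(xtr), G_te = tcrossprod(xte, xtr),
         y_tr = y[tr], y_te = y[!tr])
  })
  structure(list(pre = pre, k = as.integer(k), d = as.integer(d),
                 seed = seed, n = length(y), tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "fitness_evaluator")
}

#' Evaluate the cross-validated F-score at a hyperparameter position
#'
#' @param position numeric 4-vector (lambda, C, a, r).
#' @param ev a [fitness_evaluator()].
#' @return fitness in \[0, 1\].
#' @export
evaluate_fitness <- function(position, ev) {
  if (!inherits(ev, "fitness_evaluator")) stop("'ev' must be a fitness_evaluator")
  if (length(position) != 4L || any(!is.finite(position)))
    stop("position must be a finite 4-vector (lambda, C, a, r)")
  lam <- position[[1L]]; C <- position[[2L]]
  a <- position[[3L]]; r <- position[[4L]]
  if (lam < 0 || lam > 1) stop("lambda outside [0, 1]: ", format(lam))
  if (C <= 0) stop("box constraint must be positive: ", format(C))
  tp <- tn <- fp <- fn <- 0L
  for (fold in ev$pre) {
    K <- lam * (fold$G_tr + 1)^ev$d + (1 - lam) * tanh(a * fold$G_tr + r)
    Kt <- lam * (fold$G_te + 1)^ev$d + (1 - lam) * tanh(a * fold$G_te + r)
    dual <- fit_svm(K, fold$y_tr, C, tol = ev$tol, max_iter = ev$max_iter,
                    warn_indefinite = FALSE)
    pred <- predict_labels(dual, Kt)
    tp <- tp + sum(pred == 1L & fold$y_te == 1L)
    tn <- tn + sum(pred == -1L & fold$y_te == -1L)
    fp <- fp + sum(pred == 1L & fold$y_te == -1L)
    fn <- fn + sum(pred == -1L & fold$y_te == 1L)
  }
  acc <- (tp + tn) / ev$n
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- f_score(acc, sen)
  if (is.na(f)) 0 else f
}

#' @export
print.fitness_evaluator <- function(x, ...) {
  cat("Cross-validated F-score fitness evaluator\n")
  cat("  samples:", x$n, " folds:", x$k, " poly degree d:", x$d,
      " fold seed:", x$seed, "\n")
  invisible(x)
}

#' Tune the multiple-kernel SVM hyperparameters
#'
#' Front end tying the optimizers to the cross-validated fitness: searches
#' \eqn{(\lambda, C, a, r)} with SAPSO (default), plain PSO, or grid search,
#' then refits the mix-kernel SVM at the best position on the full table.
#'
#' @param table a `feature_table` or feature matrix.
#' @param y labels if `table` is a matrix.
#' @param method `"sapso"`, `"pso"` or `"grid"`.
#' @param config a [swarm_config()] (ignored for `"grid"`).
#' @param grid named list of component value vectors for `"grid"`.
#' @param k folds of the fitness evaluator.
#' @param d polynomial degree of the mix kernel.
#' @param fold_seed seed for fold assignment.
#' @param refit also fit the final model at the best position.
#' @return an object of class `mkl_tune`: the underlying `swarm_result`
#'   plus `fitness`, `d`, and (if `refit`) the fitted `model`.
#' @export
tune_mklsvm <- function(table, y = NULL, method = c("sapso", "pso", "grid"),
                        config = swarm_config(), grid = NULL, k = 5L, d = 2L,
                        fold_seed = 1L, refit = TRUE) {
  method <- match.arg(method)
  if (inherits(table, "feature_table")) { y <- table$y; table <- table$x }
  ev <- fitness_evaluator(table, y, k = k, d = d, seed = fold_seed)
  res <- switch(method,
    sapso = run_sapso(ev, config),
    pso = run_pso(ev, config),
    grid = {
      if (is.null(grid)) grid <- default_grid()
      run_grid(ev, grid)
    })
  out <- list(result = res, best_position = res$best_position,
              best_fitness = res$best_fitness, method = method, d = d,
              k = k, fold_seed = fold_seed)
  if (refit) {
    p <- res$best_position
    ks <- kernel_spec("mix", d = d, a = p[[3L]], r = p[[4L]],
                      mix_weight = p[[1L]])
    out$model <- mkl_svm(table, y, kernel = ks, C = p[[2L]],
                         warn_indefinite = FALSE)
  }
  structure(out, class = "mkl_tune")
}

#' Default coarse hyperparameter grid
#'
#' Four values per component spanning the search box (C and a on a
#' geometric ladder, matching their power-of-two ranges).
#'
#' @param n_per_component grid points per component.
#' @return named list of value vectors.
#' @export
default_grid <- function(n_per_component = 4L) {
  n <- n_per_component
  list(lambda = seq(0.1, 0.9, length.out = n),
       C = 2^seq(-9, 9, length.out = n),
       a = 2^seq(-7, 7, length.out = n),
       r = seq(-3, 3, length.out = n))
}

#' @export
print.mkl_tune <- function(x, ...) {
  cat("Multiple-kernel SVM hyperparameter search (", x$method, ")\n", sep = "")
  cat("  best CV F-score:", signif(x$best_fitness, 6), "\n")
  p <- x$best_position
  cat(sprintf("  lambda = %.4f  C = %.4g  a = %.4g  r = %.4f  (d = %d)\n",
              p[[1L]], p[[2L]], p[[3L]], p[[4L]], x$d))
  invisible(x)
}

#' @export
plot.mkl_tune <- function(x, ...) plot(x$result, ...)
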