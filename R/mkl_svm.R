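#' Multiple-kernel SVM classifier
#'
#' The package's central model: a binary soft-margin SVM trained on the
#' convex-combination kernel
#' \eqn{K = \lambda K_{poly}(d) + (1 - \lambda) K_{sigmoid}(a, r)}
#' (or any other [kernel_spec()]). Features are z-scored with parameters
#' learned on the training data; the fitted object retains the support-vector
#' rows so new samples can be scored through the kernel trick.
#'
#' @param x numeric matrix of training features (rows = samples), or a
#'   `feature_table`.
#' @param y labels (any dialect accepted by [canonical_labels()]); ignored
#'   when `x` is a `feature_table`.
#' @param kernel a [kernel_spec()]; default mix kernel.
#' @param C box constraint.
#' @param normalize z-score the features using training-set parameters.
#' @param ... passed to [fit_svm()] (`tol`, `max_iter`, `warn_indefinite`).
#' @return an object of class `mkl_svm`.
#' @examples
#' tab <- gen_feature_table(30, dim = 4, delta = 3, seed = 1)
#' fit <- mkl_svm(tab, kernel = kernel_spec("mix", d = 2, a = 0.01, r = 0),
#'                C = 10)
#' table(truth = tab$y, pred = predict(fit, tab$x))
#' @export
mkl_svm <- function(x, y = NULL, kernel = kernel_spec("mix"), C = 1,
                    normalize = TRUE, ...) {
  if (inherits(x, "feature_table")) { y <- x$y; x <- x$x }
  x <- as_sample_matrix(x)
  y <- canonical_labels(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  norm <- if (normalize) fit_normalizer(x) else NULL
  xs <- if (normalize) apply_normalizer(norm, x) else x
  K <- kernel_matrix(kernel, xs)
  dual <- fit_svm(K, y, C, kernel = kernel, ...)
  structure(
    list(dual = dual,
         kernel = kernel,
         C = C,
         normalizer = norm,
         train_refs = xs[dual$support_indices, , drop = FALSE],
         y = y,
         n_features = ncol(x),
         levels_positive = "nodule"),
    class = "mkl_svm")
}

#' Predict method for multiple-kernel SVM fits
#'
#' @param object an `mkl_svm` fit.
#' @param newdata feature matrix or `feature_table`.
#' @param type `"class"` for -1/+1 labels, `"decision"` for continuous
#'   scores.
#' @param ... unused.
#' @return integer labels or numeric scores.
#' @export
predict.mkl_svm <- function(object, newdata,
                            type = c("class", "decision"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_table")) newdata <- newdata$x
  newdata <- as_sample_matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("newdata has ", ncol(newdata), " features; model expects ",
         object$n_features)
  xs <- if (!is.null(object$normalizer))
    apply_normalizer(object$normalizer, newdata) else newdata
  K_test <- kernel_matrix(object$kernel, xs, object$train_refs)
  if (type == "decision") decision_values(object$dual, K_test)
  else predict_labels(object$dual, K_test)
}

#' @export
print.mkl_svm <- function(x, ...) {
  cat("Multiple-kernel SVM fit\n")
  cat("  n =", length(x$y), " features =", x$n_features,
      " support vectors =", length(x$dual$support_indices), "\n")
  cat("  C =", x$C, "\n")
  print(x$kernel)
  invisible(x)
}

#' @export
summary.mkl_svm <- function(object, ...) {
  cat("Multiple-kernel SVM fit\n")
  cat("  training samples:     ", length(object$y), "\n")
  cat("  class balance (+/-):  ", sum(object$y == 1), "/",
      sum(object$y == -1), "\n")
  cat("  support vectors:      ", length(object$dual$support_indices),
      sprintf(" (%.1f%%)", 100 * length(object$dual$support_indices) /
                length(object$y)), "\n")
  cat("  bias:                 ", signif(object$dual$bias, 6), "\n")
  cat("  dual coef range:      ",
      paste(signif(range(object$dual$dual_coefs), 4), collapse = " .. "),
      " (|coef| <= C =", object$C, ")\n")
  invisible(object)
}

#' @export
coef.mkl_svm <- function(object, ...) {
  structure(object$dual$dual_coefs,
            names = paste0("sv", object$dual$support_indices),
            bias = object$dual$bias)
}

#' Save / load a fitted multiple-kernel SVM
#'
#' The model is written as a flat structured text (YAML) file holding the
#' support indices, dual coefficients, bias, box constraint, kernel
#' specification, normalizer and support-vector rows; a round trip restores
#' identical decision values.
#'
#' @param model an `mkl_svm`.
#' @param path file path.
#' @return `write_mkl_svm` returns `path` invisibly; `read_mkl_svm` the model.
#' @export
write_mkl_svm <- function(model, path) {
  if (!inherits(model, "mkl_svm")) stop("'model' must be an mkl_svm")
  obj <- list(
    type = "mklsvm_model",
    kernel = kernel_spec_to_list(model$kernel),
    C = model$C,
    bias = model$dual$bias,
    support_indices = model$dual$support_indices,
    dual_coefs = model$dual$dual_coefs,
    n_train = model$dual$n_train,
    n_features = model$n_features,
    y = model$y,
    normalizer = if (is.null(model$normalizer)) NULL else
      list(mean = model$normalizer$mean, sd = model$normalizer$sd),
    train_refs = apply(model$train_refs, 1L, paste, collapse = ","))
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_mkl_svm
#' @export
read_mkl_svm <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$type) || obj$type != "mklsvm_model")
    stop("not an mklsvm model file: ", path)
  refs <- do.call(rbind, lapply(obj$train_refs, function(s)
    as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]])))
  dual <- structure(
    list(support_indices = as.integer(obj$support_indices),
         dual_coefs = as.numeric(obj$dual_coefs),
         bias = obj$bias, C = obj$C,
         kernel = kernel_spec_from_list(obj$kernel),
         n_train = obj$n_train, iterations = NA_integer_, converged = TRUE),
    class = "svm_dual")
  norm <- if (is.null(obj$normalizer)) NULL else
    structure(list(mean = as.numeric(obj$normalizer$mean),
                   sd = as.numeric(obj$normalizer$sd)),
              class = "feature_normalizer")
  structure(
    list(dual = dual, kernel = dual$kernel, C = obj$C, normalizer = norm,
         train_refs = refs, y = as.integer(obj$y),
         n_features = obj$n_features, levels_positive = "nodule"),
    class = "mkl_svm")
}
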