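#' Fit a soft-margin SVM on a precomputed Gram matrix
#'
#' Solves the standard C-SVC dual
#' \deqn{\min_\alpha \tfrac12 \alpha^\top Q \alpha - e^\top \alpha, \quad
#'       0 \le \alpha_i \le C, \; y^\top \alpha = 0, \; Q_{ij} = y_i y_j K_{ij}}
#' by sequential minimal optimization with maximal-violating-pair working-set
#' selection. The contract is the KKT conditions at tolerance `tol`, not a
#' particular algorithm. Indefinite Gram matrices (possible for sigmoid and
#' mix kernels) are trained as-is; a single warning is raised per fit when
#' negative curvature is encountered.
#'
#' @param K square symmetric Gram matrix over the training samples.
#' @param y labels in \{-1, +1\}, both classes present.
#' @param C box constraint, positive.
#' @param kernel optional [kernel_spec()] recorded in the model (required for
#'   predicting from raw feature rows later).
#' @param tol KKT violation tolerance of the dual solver.
#' @param max_iter iteration cap of the solver.
#' @param warn_indefinite warn when the solver meets negative curvature.
#' @return an object of class `svm_dual` with elements `support_indices`,
#'   `dual_coefs` (\eqn{\alpha_i y_i} per support vector), `bias`, `C`,
#'   `kernel`, `converged`.
#' @export
fit_svm <- function(K, y, C, kernel = NULL, tol = 1e-3, max_iter = 200000L,
                    warn_indefinite = TRUE) {
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop("Gram matrix 'K' must be square, got ", nrow(K), " x ", ncol(K))
  if (any(!is.finite(K))) stop("Gram matrix contains non-finite entries")
  asym <- max(abs(K - t(K)))
  if (asym > 1e-8 * max(1, max(abs(K))))
    stop("Gram matrix is not symmetric (max asymmetry ", format(asym), ")")
  y <- canonical_labels(y)
  if (length(y) != nrow(K)) stop("length(y) must equal nrow(K)")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; both classes are required")
  if (!is.finite(C) || C <= 0) stop("box constraint 'C' must be > 0")

  sol <- .smo_solve(K, as.integer(y), C, tol, as.integer(max_iter))
  if (warn_indefinite) {
    ev_min <- min(eigen((K + t(K)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values)
    if (ev_min < -1e-8 * max(1, max(abs(K))))
      warning("Gram matrix is indefinite (smallest eigenvalue ",
              format(ev_min, digits = 3), "); trained anyway", call. = FALSE)
  }
  if (!isTRUE(sol$converged))
    warning("SMO iteration cap reached before KKT tolerance", call. = FALSE)

  alpha <- sol$alpha
  sv <- which(alpha > 1e-8 * max(C, 1))
  structure(
    list(support_indices = sv,
         dual_coefs = alpha[sv] * y[sv],
         bias = sol$b,
         C = C,
         kernel = kernel,
         n_train = nrow(K),
         iterations = sol$iterations,
         converged = isTRUE(sol$converged)),
    class = "svm_dual")
}

#' Canonical -1/+1 labels
#'
#' Maps the accepted label dialects onto the internal \{-1, +1\} coding with
#' +1 = nodule: numeric \{-1, +1\}, numeric/character \{0, 1\}, and
#' character/factor \{"nodule", "nonnodule"\}.
#'
#' @param y label vector.
#' @return integer vector of -1/+1.
#' @export
canonical_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    low <- tolower(trimws(y))
    if (all(low %in% c("nodule", "nonnodule"))) {
      return(ifelse(low == "nodule", 1L, -1L))
    }
    sup <- suppressWarnings(as.numeric(y))
    if (any(is.na(sup))) stop("unrecognized labels: ",
                              paste(unique(y[is.na(sup)]), collapse = ", "))
    y <- sup
  }
  if (all(y %in% c(0, 1))) return(ifelse(y == 1, 1L, -1L))
  if (all(y %in% c(-1, 1))) return(as.integer(y))
  stop("labels must be {-1,+1}, {0,1} or {nodule,nonnodule}")
}

#' Decision values of a fitted SVM
#'
#' Continuous scores \eqn{f_j = \sum_i \alpha_i y_i K(x_i, t_j) + b}. The
#' sign of a score is the predicted label; the scores feed ROC analysis.
#'
#' @param model an `svm_dual` from [fit_svm()].
#' @param K_test cross-Gram matrix, rows = test samples, columns = either all
#'   training samples (the model selects its support columns) or exactly the
#'   support vectors.
#' @return numeric score vector, one per test row.
#' @export
decision_values <- function(model, K_test) {
  if (!inherits(model, "svm_dual")) stop("'model' must be an svm_dual")
  if (is.vector(K_test)) K_test <- matrix(K_test, nrow = 1L)
  nsv <- length(model$support_indices)
  if (ncol(K_test) == model$n_train) {
    K_test <- K_test[, model$support_indices, drop = FALSE]
  } else if (ncol(K_test) != nsv) {
    stop("K_test has ", ncol(K_test), " columns; expected ", model$n_train,
         " (all training points) or ", nsv, " (support vectors)")
  }
  as.vector(K_test %*% model$dual_coefs + model$bias)
}

#' Predicted labels of a fitted SVM
#'
#' Sign of the decision values with the fixed tie rule sign(0) -> +1.
#'
#' @inheritParams decision_values
#' @return integer vector of -1/+1.
#' @export
predict_labels <- function(model, K_test) {
  f <- decision_values(model, K_test)
  ifelse(f >= 0, 1L, -1L)
}

#' @export
print.svm_dual <- function(x, ...) {
  cat("Soft-margin SVM dual solution\n")
  cat("  training points:", x$n_train,
      " support vectors:", length(x$support_indices), "\n")
  cat("  C:", x$C, " bias:", signif(x$bias, 6),
      " converged:", x$converged, "\n")
  if (!is.null(x$kernel)) print(x$kernel)
  invisible(x)
}
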