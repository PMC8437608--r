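#' Kernel specification
#'
#' Describes a kernel family and its parameters. The workhorse for nodule
#' recognition is `family = "mix"`, the convex combination
#' \deqn{K_{mix}(x, x') = \lambda K_{poly}(x, x') + (1 - \lambda) K_{sigmoid}(x, x'),}
#' which pairs the global generalization of the polynomial kernel with the
#' strong nonlinear fitting of the sigmoid kernel. The general N-kernel form
#' \eqn{\sum_p \alpha_p K_p} with \eqn{\sum_p \alpha_p = 1} is supported via
#' `weights`/`base_families`.
#'
#' @param family one of `"linear"`, `"poly"`, `"rbf"`, `"sigmoid"`, `"mix"`.
#' @param d polynomial degree, integer greater than 1.
#' @param g RBF kernel width, positive.
#' @param a sigmoid regulation parameter.
#' @param r sigmoid displacement parameter.
#' @param mix_weight mix weight \eqn{\lambda} in \eqn{[0, 1]} (the open
#'   interval in normal use; the endpoints degenerate to the pure base
#'   kernels and are permitted so the identities can be exercised).
#' @param base_families ordered character vector of base kernels for
#'   `family = "mix"`; default polynomial then sigmoid.
#' @param weights optional convex weights for the general N-kernel form;
#'   defaults to `c(mix_weight, 1 - mix_weight)`.
#' @return an object of class `kernel_spec`.
#' @examples
#' ks <- kernel_spec("mix", d = 2, a = 0.01, r = 0, mix_weight = 0.5)
#' X <- matrix(rnorm(20), 5, 4)
#' K <- kernel_matrix(ks, X)
#' @export
kernel_spec <- function(family = c("mix", "linear", "poly", "rbf", "sigmoid"),
                        d = 2L, g = 1, a = 1, r = 0, mix_weight = 0.5,
                        base_families = c("poly", "sigmoid"),
                        weights = NULL) {
  family <- match.arg(family)
  if (family %in% c("poly", "mix")) {
    if (length(d) != 1L || !is.finite(d) || d != round(d) || d < 2)
      stop("polynomial degree 'd' must be an integer > 1, got ", format(d))
    d <- as.integer(d)
  }
  if (family == "rbf" && (!is.finite(g) || g <= 0))
    stop("RBF width 'g' must be > 0, got ", format(g))
  if (family == "mix") {
    if (is.null(weights)) {
      if (!is.finite(mix_weight) || mix_weight < 0 || mix_weight > 1)
        stop("mix_weight must lie in [0, 1], got ", format(mix_weight))
      weights <- c(mix_weight, 1 - mix_weight)
    }
    if (length(weights) != length(base_families))
      stop("'weights' and 'base_families' lengths differ")
    if (any(!is.finite(weights)) || any(weights < 0) || any(weights > 1) ||
        abs(sum(weights) - 1) > 1e-8)
      stop("mix weights must lie in [0, 1] and sum to 1")
    if (!all(base_families %in% c("linear", "poly", "rbf", "sigmoid")))
      stop("unknown base kernel family in 'base_families'")
    mix_weight <- weights[[1L]]
  }
  structure(
    list(family = family, d = d, g = g, a = a, r = r,
         mix_weight = mix_weight, base_families = base_families,
         weights = weights),
    class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("Kernel spec:", x$family, "\n")
  switch(x$family,
    poly = cat("  degree d =", x$d, "\n"),
    rbf = cat("  width g =", x$g, "\n"),
    sigmoid = cat("  a =", x$a, " r =", x$r, "\n"),
    mix = cat("  bases:", paste(x$base_families, collapse = " + "),
              " weights:", paste(signif(x$weights, 4), collapse = ", "),
              "\n  d =", x$d, " a =", x$a, " r =", x$r, "\n"))
  invisible(x)
}

as_sample_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (!is.matrix(X) || !is.numeric(X))
    stop("sample set must be a numeric matrix (rows = samples)")
  X
}

check_dims <- function(X, Y) {
  if (ncol(X) != ncol(Y))
    stop("feature dimensions differ: ", ncol(X), " vs ", ncol(Y))
}

#' Linear kernel Gram matrix
#'
#' Entry (i, j) is the inner product of row i of `X` and row j of `Y`.
#'
#' @param X,Y numeric sample matrices (rows = samples) with equal numbers of
#'   columns; `Y` defaults to `X` (self-Gram).
#' @return a `nrow(X)` by `nrow(Y)` matrix.
#' @export
kernel_linear <- function(X, Y = X) {
  X <- as_sample_matrix(X); Y <- as_sample_matrix(Y)
  check_dims(X, Y)
  tcrossprod(X, Y)
}

#' Polynomial kernel Gram matrix
#'
#' Entry (i, j) is \eqn{(\langle x_i, y_j \rangle + 1)^d}.
#'
#' @inheritParams kernel_linear
#' @param d polynomial degree, integer greater than 1.
#' @export
kernel_poly <- function(X, Y = X, d = 2L) {
  if (length(d) != 1L || !is.finite(d) || d != round(d) || d < 2)
    stop("polynomial degree 'd' must be an integer > 1, got ", format(d))
  (kernel_linear(X, Y) + 1)^d
}

#' Gaussian (RBF) kernel Gram matrix
#'
#' Entry (i, j) is \eqn{\exp(-\|x_i - y_j\|^2 / (2 g^2))}; the diagonal of a
#' self-Gram is identically 1.
#'
#' @inheritParams kernel_linear
#' @param g kernel width, positive.
#' @export
kernel_rbf <- function(X, Y = X, g = 1) {
  if (!is.finite(g) || g <= 0) stop("RBF width 'g' must be > 0, got ", format(g))
  X <- as_sample_matrix(X); Y <- as_sample_matrix(Y)
  check_dims(X, Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0  # guard roundoff on near-identical rows
  exp(-d2 / (2 * g^2))
}

#' Sigmoid kernel Gram matrix
#'
#' Entry (i, j) is \eqn{\tanh(a \langle x_i, y_j \rangle + r)}; all entries
#' lie in (-1, 1). The sigmoid kernel is not positive semidefinite for every
#' (a, r); training proceeds regardless (see [spectral_clip()] for an
#' optional repair).
#'
#' @inheritParams kernel_linear
#' @param a regulation parameter.
#' @param r displacement parameter.
#' @export
kernel_sigmoid <- function(X, Y = X, a = 1, r = 0) {
  if (!is.finite(a) || !is.finite(r)) stop("sigmoid parameters must be finite")
  tanh(a * kernel_linear(X, Y) + r)
}

#' Convex-combination (multiple) kernel Gram matrix
#'
#' Computes \eqn{\sum_p \alpha_p K_p(X, Y)} for the base kernels and convex
#' weights of `spec`; with the default two bases this is
#' \eqn{\lambda K_{poly} + (1-\lambda) K_{sigmoid}}.
#'
#' @inheritParams kernel_linear
#' @param spec a [kernel_spec()] with `family = "mix"`.
#' @export
kernel_mix <- function(X, Y = X, spec) {
  if (!inherits(spec, "kernel_spec") || spec$family != "mix")
    stop("'spec' must be a kernel_spec with family = \"mix\"")
  K <- 0
  for (p in seq_along(spec$base_families)) {
    K <- K + spec$weights[[p]] *
      kernel_single(spec$base_families[[p]], X, Y, spec)
  }
  K
}

kernel_single <- function(family, X, Y, spec) {
  switch(family,
    linear = kernel_linear(X, Y),
    poly = kernel_poly(X, Y, spec$d),
    rbf = kernel_rbf(X, Y, spec$g),
    sigmoid = kernel_sigmoid(X, Y, spec$a, spec$r),
    stop("unknown kernel family: ", family))
}

#' Gram matrix for an arbitrary kernel specification
#'
#' @inheritParams kernel_linear
#' @param spec a [kernel_spec()].
#' @export
kernel_matrix <- function(spec, X, Y = X) {
  if (!inherits(spec, "kernel_spec")) stop("'spec' must be a kernel_spec")
  if (spec$family == "mix") kernel_mix(X, Y, spec)
  else kernel_single(spec$family, X, Y, spec)
}

#' Spectral clip of an indefinite Gram matrix
#'
#' Sets negative eigenvalues of a symmetric Gram matrix to zero, returning
#' the nearest positive semidefinite matrix in Frobenius norm. Disabled by
#' default throughout the package: the sigmoid (and hence mix) kernel can be
#' indefinite for some (a, r), but SMO-type solvers tolerate mild
#' indefiniteness and training directly with the raw kernel is the intended
#' behaviour.
#'
#' @param K symmetric numeric matrix.
#' @return positive semidefinite matrix of the same dimension.
#' @export
spectral_clip <- function(K) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop("'K' must be square")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (v * t(e$vectors))
}

#' Serialize / restore a kernel specification
#'
#' `kernel_spec_to_list()` flattens a spec to a plain named list (the config
#' dialect); `kernel_spec_from_list()` rebuilds it.
#'
#' @param spec a [kernel_spec()].
#' @param x a named list as produced by `kernel_spec_to_list()`.
#' @return a list, respectively a `kernel_spec`.
#' @export
kernel_spec_to_list <- function(spec) {
  list(family = spec$family, d = spec$d, g = spec$g, a = spec$a, r = spec$r,
       mix_weight = spec$mix_weight)
}

#' @rdname kernel_spec_to_list
#' @export
kernel_spec_from_list <- function(x) {
  kernel_spec(family = x$family, d = if (is.null(x$d)) 2L else x$d,
              g = if (is.null(x$g)) 1 else x$g,
              a = if (is.null(x$a)) 1 else x$a,
              r = if (is.null(x$r)) 0 else x$r,
              mix_weight = if (is.null(x$mix_weight)) 0.5 else x$mix_weight)
}
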