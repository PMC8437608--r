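#' Binarize an ROI and keep the largest 8-connected region
#'
#' Thresholds the grayscale region of interest (Otsu's method by default),
#' labels the foreground under 8-connectivity (diagonal neighbours touch),
#' and retains only the largest connected component — the standard
#' reconstruction that removes background clutter around an isolated nodule
#' candidate.
#'
#' @param image numeric matrix of nonnegative intensities, at least 8 x 8.
#' @param threshold fixed binarization threshold (pixels strictly above are
#'   foreground); `NULL` selects it by Otsu's method.
#' @return logical mask matrix of the largest foreground component.
#' @export
preprocess_roi <- function(image, threshold = NULL) {
  image <- check_roi(image)
  if (is.null(threshold)) {
    rng <- range(image)
    if (rng[1L] == rng[2L])
      stop("no object: image is constant, Otsu threshold undefined")
    scaled <- (image - rng[1L]) / (rng[2L] - rng[1L])
    threshold <- rng[1L] +
      EBImage::otsu(EBImage::Image(scaled)) * (rng[2L] - rng[1L])
  }
  fg <- image > threshold
  if (!any(fg)) stop("no object: empty foreground after thresholding")
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

check_roi <- function(image) {
  if (is.data.frame(image)) image <- as.matrix(image)
  if (!is.matrix(image) || !is.numeric(image))
    stop("ROI image must be a numeric matrix")
  if (any(!is.finite(image))) stop("ROI image contains non-finite values")
  if (nrow(image) < 8L || ncol(image) < 8L)
    stop("ROI image must be at least 8 x 8 pixels")
  image
}

#' Label connected components under 8-connectivity
#'
#' Breadth-first labeling where diagonal neighbours belong to the same
#' component.
#'
#' @param mask logical matrix.
#' @return integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  queue <- integer(nr * nc)
  comp <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    lab[start] <- comp
    queue[1L] <- start; qlen <- 1L
    while (qlen > 0L) {
      cur <- queue[qlen]; qlen <- qlen - 1L
      r <- (cur - 1L) %% nr + 1L
      cc <- (cur - 1L) %/% nr + 1L
      for (dr in -1L:1L) for (dc in -1L:1L) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        idx <- (c2 - 1L) * nr + r2
        if (mask[idx] && lab[idx] == 0L) {
          lab[idx] <- comp
          qlen <- qlen + 1L
          queue[qlen] <- idx
        }
      }
    }
  }
  lab
}

#' Handcrafted ROI features (13 dimensions)
#'
#' The fixed-order descriptor set used as the classifier's handcrafted
#' block: 7 morphological features of the mask — area, boundary perimeter
#' (Cauchy–Crofton estimate from exposed pixel edges), circularity
#' \eqn{4\pi A/P^2}, rectangularity \eqn{A/(\mathrm{bounding\ box\ area})},
#' elongation (minor/major axis ratio from second-order moments), convexity
#' deficiency \eqn{1 - A/A_{hull}}, equivalent diameter
#' \eqn{\sqrt{4A/\pi}} — 2 grayscale features (mean and standard deviation
#' of intensities inside the mask) and 4 texture features (gray-level
#' co-occurrence energy, contrast, correlation and entropy, 16 gray levels,
#' distance 1, averaged over the 0/45/90/135 degree directions inside the
#' mask bounding box).
#'
#' @param image numeric intensity matrix.
#' @param mask logical mask (defaults to [preprocess_roi()] of the image).
#' @return named numeric vector of length 13.
#' @export
handcrafted_features <- function(image, mask = preprocess_roi(image)) {
  image <- check_roi(image)
  if (!any(mask)) stop("mask is empty")
  area <- sum(mask)
  if (area < 4L)
    stop("degenerate mask (", area, " px): perimeter, elongation and ",
         "texture features are undefined")
  idx <- which(mask, arr.ind = TRUE)
  per <- boundary_perimeter(mask)
  bbox_r <- range(idx[, 1L]); bbox_c <- range(idx[, 2L])
  bbox_area <- (diff(bbox_r) + 1L) * (diff(bbox_c) + 1L)

  ctr <- colMeans(idx)
  d <- sweep(idx, 2L, ctr)
  mom <- crossprod(d) / area
  ev <- sort(eigen(mom, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  elong <- if (ev[1L] > 0) sqrt(max(ev[2L], 0) / ev[1L]) else 0

  hull_area <- convex_hull_area(idx)
  convex_def <- max(0, 1 - area / max(area, hull_area))

  vals <- image[mask]
  gl <- glcm_features(image, mask)

  c(area = area,
    perimeter = per,
    circularity = 4 * pi * area / per^2,
    rectangularity = area / bbox_area,
    elongation = elong,
    convex_deficiency = convex_def,
    eq_diameter = sqrt(4 * area / pi),
    gray_mean = mean(vals),
    gray_sd = sd(vals),
    glcm_energy = gl[["energy"]],
    glcm_contrast = gl[["contrast"]],
    glcm_correlation = gl[["correlation"]],
    glcm_entropy = gl[["entropy"]])
}

# Cauchy-Crofton perimeter estimate: pi/4 times the number of exposed
# 4-neighbour edges (grid border counts as background). Unbiased for
# isotropically oriented smooth boundaries; a digital disk of radius R
# yields ~2*pi*R.
boundary_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(FALSE, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- m[2:(nr + 1L), 2:(nc + 1L)]
  exposed <- (inner & !m[1:nr, 2:(nc + 1L)]) +        # north
    (inner & !m[3:(nr + 2L), 2:(nc + 1L)]) +          # south
    (inner & !m[2:(nr + 1L), 1:nc]) +                 # west
    (inner & !m[2:(nr + 1L), 3:(nc + 2L)])            # east
  (pi / 4) * sum(exposed)
}

convex_hull_area <- function(idx) {
  if (nrow(idx) < 3L) return(nrow(idx))
  h <- chull(idx[, 2L], idx[, 1L])
  xs <- idx[h, 2L]; ys <- idx[h, 1L]
  n <- length(h)
  abs(sum(xs * ys[c(2:n, 1L)] - xs[c(2:n, 1L)] * ys)) / 2
}

# Gray-level co-occurrence features: 16 levels quantized inside the mask
# bounding box, distance 1, directions 0/45/90/135 degrees, symmetric
# normalized matrices, features averaged over directions.
glcm_features <- function(image, mask, levels = 16L) {
  idx <- which(mask, arr.ind = TRUE)
  rr <- range(idx[, 1L]); cr <- range(idx[, 2L])
  box <- image[rr[1L]:rr[2L], cr[1L]:cr[2L], drop = FALSE]
  vmin <- min(box); vmax <- max(box)
  q <- box
  q[] <- if (vmax > vmin)
    pmin(levels, floor((box - vmin) / (vmax - vmin) * levels) + 1L)
  else 1L
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  feats <- sapply(offsets, function(off) {
    nr <- nrow(q); nc <- ncol(q)
    r1 <- max(1L, 1L - off[1L]):min(nr, nr - off[1L])
    c1 <- max(1L, 1L - off[2L]):min(nc, nc - off[2L])
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + off[1L], c1 + off[2L], drop = FALSE]
    tab <- table(factor(a, levels = 1:levels), factor(b, levels = 1:levels))
    P <- unclass(tab) + t(unclass(tab))  # symmetric
    P <- P / sum(P)
    i <- row(P); j <- col(P)
    mu_i <- sum(i * P); mu_j <- sum(j * P)
    s_i <- sqrt(sum((i - mu_i)^2 * P)); s_j <- sqrt(sum((j - mu_j)^2 * P))
    corr <- if (s_i > 0 && s_j > 0)
      sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j) else 0
    pz <- P[P > 0]
    c(energy = sum(P^2),
      contrast = sum((i - j)^2 * P),
      correlation = corr,
      entropy = -sum(pz * log2(pz)))
  })
  rowMeans(feats)
}

#' Embed an image through a pluggable embedding function
#'
#' The embedding contract stands in for a pretrained convolutional feature
#' extractor: any deterministic `function(image) -> numeric vector` of fixed
#' length qualifies. The built-in [default_embedder()] is a fixed-seed
#' random projection of the resized image.
#'
#' @param image numeric intensity matrix.
#' @param embedder embedding function.
#' @return numeric embedding vector.
#' @export
embed_image <- function(image, embedder = default_embedder()) {
  v <- embedder(check_roi(image))
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("embedder returned non-finite or non-numeric output")
  want <- attr(embedder, "embed_dim")
  if (!is.null(want) && length(v) != want)
    stop("embedder returned length ", length(v), "; expected ", want)
  as.numeric(v)
}

#' Built-in random-projection embedder
#'
#' A deterministic linear projection of the (nearest-neighbour resized)
#' image onto `embed_dim` directions drawn once from a fixed seed. It
#' preserves enough geometry for the cascade pipeline to be exercised at
#' test scale while keeping the package free of any pretrained network;
#' swap in a real CNN embedding by supplying any function that satisfies
#' the contract of [embed_image()].
#'
#' @param embed_dim output dimension.
#' @param input_size images are resized (nearest neighbour) to this square
#'   side before projection.
#' @param seed seed of the fixed projection matrix.
#' @return an embedding function with attribute `embed_dim`.
#' @export
default_embedder <- function(embed_dim = 512L, input_size = 64L,
                             seed = 2025L) {
  npix <- input_size^2
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  P <- matrix(rnorm(embed_dim * npix) / sqrt(npix), embed_dim, npix)
  if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv)
  f <- function(image) {
    if (nrow(image) != input_size || ncol(image) != input_size) {
      ri <- pmax(1L, round(seq(1L, nrow(image), length.out = input_size)))
      ci <- pmax(1L, round(seq(1L, ncol(image), length.out = input_size)))
      image <- image[ri, ci, drop = FALSE]
    }
    as.vector(P %*% as.vector(image))
  }
  attr(f, "embed_dim") <- as.integer(embed_dim)
  f
}

#' Principal-component reduction of embeddings
#'
#' Centered PCA of the embedding matrix. Either a fixed output dimension or
#' a cumulative explained-variance target may be requested; a dimension
#' beyond the matrix rank is reduced to the rank with a warning.
#'
#' @param X embedding matrix (rows = samples, at least 2).
#' @param pca_dim requested output dimension.
#' @param var_target cumulative explained-variance fraction in (0, 1\];
#'   selects the smallest dimension reaching it (overrides `pca_dim`).
#' @return an object of class `pca_model` with `rotation`, `center`,
#'   `sdev`, `dim`, `explained` (variance ratios).
#' @export
fit_pca <- function(X, pca_dim = 98L, var_target = NULL) {
  X <- as_sample_matrix(X)
  if (nrow(X) < 2L) stop("PCA requires at least 2 samples")
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  pos <- pr$sdev > max(pr$sdev) * 1e-12
  rank <- sum(pos)
  explained <- pr$sdev^2 / sum(pr$sdev^2)
  if (!is.null(var_target)) {
    if (var_target <= 0 || var_target > 1)
      stop("'var_target' must lie in (0, 1]")
    pca_dim <- which(cumsum(explained) >= var_target - 1e-12)[1L]
  }
  if (pca_dim > rank) {
    warning("requested ", pca_dim, " components but rank is ", rank,
            "; reduced", call. = FALSE)
    pca_dim <- rank
  }
  structure(list(rotation = pr$rotation[, seq_len(pca_dim), drop = FALSE],
                 center = pr$center, sdev = pr$sdev,
                 dim = as.integer(pca_dim), explained = explained),
            class = "pca_model")
}

#' Project embeddings with a fitted PCA model
#'
#' @param model a `pca_model`.
#' @param X embedding matrix.
#' @return scores matrix (rows = samples, `model$dim` columns).
#' @export
apply_pca <- function(model, X) {
  if (!inherits(model, "pca_model")) stop("'model' must be a pca_model")
  X <- as_sample_matrix(X)
  sweep(X, 2L, model$center) %*% model$rotation
}

#' Concatenate handcrafted and reduced deep-style features
#'
#' Handcrafted features come first, then the principal-component scores;
#' at the defaults (13 + 98) the cascade vector has 111 dimensions.
#'
#' @param handcrafted numeric 13-vector (or matrix of rows).
#' @param reduced principal-component vector/matrix (may have 0 columns).
#' @param handcrafted_dim expected handcrafted length.
#' @param pca_dim expected reduced length; `NULL` skips the check.
#' @return concatenated vector or matrix, `hc_*` columns then `pc_*`.
#' @export
cascade_features <- function(handcrafted, reduced,
                             handcrafted_dim = 13L, pca_dim = NULL) {
  hmat <- if (is.matrix(handcrafted)) handcrafted else
    matrix(handcrafted, nrow = 1L)
  rmat <- if (is.matrix(reduced)) reduced else if (length(reduced) == 0L)
    matrix(numeric(0), nrow(hmat), 0L) else matrix(reduced, nrow = 1L)
  if (ncol(hmat) != handcrafted_dim)
    stop("handcrafted block has ", ncol(hmat), " columns; expected ",
         handcrafted_dim)
  if (!is.null(pca_dim) && ncol(rmat) != pca_dim)
    stop("reduced block has ", ncol(rmat), " columns; expected ", pca_dim)
  if (nrow(hmat) != nrow(rmat)) stop("row counts differ between blocks")
  if (any(!is.finite(hmat)) || any(!is.finite(rmat)))
    stop("non-finite feature values")
  out <- cbind(hmat, rmat)
  colnames(out) <- c(sprintf("hc_%02d", seq_len(ncol(hmat))),
                     if (ncol(rmat) > 0) sprintf("pc_%03d", seq_len(ncol(rmat))))
  if (is.matrix(handcrafted) || is.matrix(reduced)) out else drop(out)
}

#' Feature z-score normalizer
#'
#' `fit_normalizer()` estimates per-feature mean and standard deviation on
#' the training table only; `apply_normalizer()` applies them to any table
#' (no re-estimation). Zero-variance features pass through unscaled with a
#' warning.
#'
#' @param x training feature matrix.
#' @param warn warn about constant columns.
#' @return a `feature_normalizer`.
#' @export
fit_normalizer <- function(x, warn = TRUE) {
  x <- as_sample_matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  const <- !is.finite(s) | s == 0
  if (any(const)) {
    if (warn) warning(sum(const), " zero-variance feature(s) left unscaled",
                      call. = FALSE)
    s[const] <- 1
    mu[const] <- 0
  }
  structure(list(mean = mu, sd = s), class = "feature_normalizer")
}

#' @rdname fit_normalizer
#' @param norm a fitted `feature_normalizer`.
#' @export
apply_normalizer <- function(norm, x) {
  if (!inherits(norm, "feature_normalizer"))
    stop("'norm' must be a feature_normalizer")
  x <- as_sample_matrix(x)
  sweep(sweep(x, 2L, norm$mean), 2L, norm$sd, "/")
}

#' Full image-to-cascade feature extraction
#'
#' Runs every ROI through binarization and largest-region reconstruction,
#' extracts the 13 handcrafted descriptors, embeds each image, reduces the
#' embeddings with PCA (fit on these images unless a fitted model is
#' supplied), and cascades the two blocks.
#'
#' @param images list of ROI intensity matrices.
#' @param labels optional labels attached to the resulting table.
#' @param embedder embedding function.
#' @param pca_dim principal components kept (default 98).
#' @param pca optional pre-fitted `pca_model` (e.g. from the training set,
#'   avoiding leakage into a held-out set).
#' @param threshold passed to [preprocess_roi()].
#' @return a `feature_table` with columns `hc_01..hc_13`, `pc_001..`;
#'   attributes `pca` (the fitted model) and `embed_dim`.
#' @export
extract_cascade <- function(images, labels = NULL,
                            embedder = default_embedder(), pca_dim = 98L,
                            pca = NULL, threshold = NULL) {
  if (!is.list(images) || !length(images)) stop("'images' must be a non-empty list")
  hc <- t(vapply(images, function(im)
    handcrafted_features(im, preprocess_roi(im, threshold)),
    numeric(13L)))
  emb <- t(vapply(images, function(im) embed_image(im, embedder),
                  numeric(attr(embedder, "embed_dim"))))
  if (pca_dim > 0L) {
    if (is.null(pca)) pca <- fit_pca(emb, pca_dim = pca_dim)
    pc <- apply_pca(pca, emb)
  } else {
    pca <- NULL
    pc <- matrix(numeric(0), nrow(hc), 0L)
  }
  x <- cascade_features(hc, pc)
  tab <- feature_table(x, if (is.null(labels)) rep(1L, nrow(x)) else labels)
  attr(tab, "pca") <- pca
  attr(tab, "embed_dim") <- attr(embedder, "embed_dim")
  tab
}
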