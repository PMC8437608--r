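#' Synthetic ROI image specification
#'
#' Settings of the image generator that emulates isolated-nodule ROIs:
#' nodule-class images contain one bright, approximately round radial
#' Gaussian blob; non-nodule images contain an elongated ridge (or a pure
#' noise patch), over Gaussian background noise. The radial-Gaussian blob
#' (rather than a hard disk) keeps Otsu thresholding nontrivial; 64 x 64
#' pixels keeps the full pipeline fast.
#'
#' @param image_size square image side in pixels.
#' @param nodule_radius range the blob radius is drawn from (pixels).
#' @param nodule_peak range of the blob peak intensity (in \[0, 1\]).
#' @param ridge_length,ridge_width,ridge_intensity ranges of the
#'   non-nodule ridge geometry and peak intensity.
#' @param noise_sd background Gaussian noise standard deviation.
#' @param nonnodule_type `"ridge"`, `"noise"`, or `"mixed"` (half each).
#' @return an object of class `synth_image_spec`.
#' @export
synth_image_spec <- function(image_size = 64L,
                             nodule_radius = c(6, 12),
                             nodule_peak = c(0.7, 1.0),
                             ridge_length = c(30, 50),
                             ridge_width = c(2, 4),
                             ridge_intensity = c(0.6, 0.9),
                             noise_sd = 0.05,
                             nonnodule_type = c("ridge", "noise", "mixed")) {
  nonnodule_type <- match.arg(nonnodule_type)
  if (max(nodule_radius) >= image_size / 2)
    stop("nodule radius must stay below half the image size")
  if (min(nodule_peak) < 0 || max(nodule_peak) > 1)
    stop("intensities must lie in [0, 1]")
  structure(list(image_size = as.integer(image_size),
                 nodule_radius = nodule_radius, nodule_peak = nodule_peak,
                 ridge_length = ridge_length, ridge_width = ridge_width,
                 ridge_intensity = ridge_intensity, noise_sd = noise_sd,
                 nonnodule_type = nonnodule_type),
            class = "synth_image_spec")
}

#' Generate labeled synthetic ROI images
#'
#' Deterministic under a fixed seed. Nodules (+1) are radial Gaussian
#' blobs; non-nodules (-1) are elongated ridges or noise patches according
#' to the spec. Pixel values are clipped to \[0, 1\].
#'
#' @param n_per_class images per class.
#' @param spec a [synth_image_spec()].
#' @param seed RNG seed.
#' @return list with `images` (list of matrices) and `labels` (+1/-1).
#' @export
gen_roi_images <- function(n_per_class, spec = synth_image_spec(),
                           seed = 1L) {
  set.seed(seed)
  sz <- spec$image_size
  coords <- expand.grid(r = seq_len(sz), c = seq_len(sz))
  imgs <- vector("list", 2L * n_per_class)
  labs <- integer(2L * n_per_class)
  runif1 <- function(rg) runif(1, rg[1L], rg[2L])
  for (i in seq_len(2L * n_per_class)) {
    is_nodule <- i <= n_per_class
    img <- matrix(if (spec$noise_sd > 0)
      pmax(rnorm(sz * sz, 0, spec$noise_sd), 0) else 0, sz, sz)
    cr <- runif(2, sz * 0.35, sz * 0.65)  # keep the object inside the frame
    if (is_nodule) {
      rad <- runif1(spec$nodule_radius)
      peak <- runif1(spec$nodule_peak)
      d2 <- (coords$r - cr[1L])^2 + (coords$c - cr[2L])^2
      img <- img + matrix(peak * exp(-d2 / (2 * (rad / 2)^2)), sz, sz)
    } else {
      type <- switch(spec$nonnodule_type,
                     ridge = "ridge", noise = "noise",
                     mixed = if (i %% 2L == 0L) "ridge" else "noise")
      if (type == "ridge") {
        len <- runif1(spec$ridge_length)
        wid <- runif1(spec$ridge_width)
        peak <- runif1(spec$ridge_intensity)
        th <- runif(1, 0, pi)
        u <- c(cos(th), sin(th))
        dr <- coords$r - cr[1L]; dc <- coords$c - cr[2L]
        along <- dr * u[1L] + dc * u[2L]
        across <- -dr * u[2L] + dc * u[1L]
        prof <- peak * exp(-across^2 / (2 * (wid / 2)^2)) *
          (abs(along) <= len / 2)
        img <- img + matrix(prof, sz, sz)
      } else {
        # speckled noise patch: scattered bright granules
        k <- sample(20:40, 1L)
        pr <- sample.int(sz, k, replace = TRUE)
        pc <- sample.int(sz, k, replace = TRUE)
        amp <- runif(k, 0.4, 0.9)
        for (g in seq_len(k)) {
          d2 <- (coords$r - pr[g])^2 + (coords$c - pc[g])^2
          img <- img + matrix(amp[g] * exp(-d2 / 2), sz, sz)
        }
      }
    }
    imgs[[i]] <- pmin(pmax(img, 0), 1)
    labs[i] <- if (is_nodule) 1L else -1L
  }
  list(images = imgs, labels = labs)
}

#' Synthetic two-class Gaussian feature table
#'
#' Two multivariate normal clouds with identity-scaled covariance: the
#' positive class (+1, nodule) has mean `delta` in every feature, the
#' negative class mean zero, so `delta` controls the Bayes separability
#' (class-mean Mahalanobis distance \eqn{\delta \sqrt{dim} / \sigma}).
#'
#' @param n_per_class samples per class, or a length-2 vector
#'   `c(n_pos, n_neg)`.
#' @param dim feature dimension.
#' @param delta per-feature class-mean shift (nonnegative).
#' @param sigma covariance scale (standard deviation per feature).
#' @param seed RNG seed.
#' @return a `feature_table`.
#' @export
gen_feature_table <- function(n_per_class, dim = 13L, delta = 1, sigma = 1,
                              seed = 1L) {
  if (delta < 0) stop("'delta' must be nonnegative")
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 2L)
  if (any(n_per_class < 1L)) stop("need at least 1 sample per class")
  set.seed(seed)
  Sig <- diag(sigma^2, dim)
  xp <- MASS::mvrnorm(n_per_class[1L], rep(delta, dim), Sig)
  xn <- MASS::mvrnorm(n_per_class[2L], rep(0, dim), Sig)
  if (n_per_class[1L] == 1L) xp <- matrix(xp, 1L)
  if (n_per_class[2L] == 1L) xn <- matrix(xn, 1L)
  x <- rbind(xp, xn)
  colnames(x) <- sprintf("f_%02d", seq_len(dim))
  feature_table(x, c(rep(1L, n_per_class[1L]), rep(-1L, n_per_class[2L])))
}

#' Synthetic imbalanced feature table
#'
#' As [gen_feature_table()] with class sizes in a given ratio; the default
#' emulates a candidate-ROI pool of 80 nodules against 190 non-nodules
#' (270 samples).
#'
#' @param n_total total sample count.
#' @param ratio positive:negative class ratio (length-2 numeric).
#' @param ... passed to [gen_feature_table()] (`dim`, `delta`, `sigma`,
#'   `seed`).
#' @return a `feature_table`.
#' @export
gen_imbalanced_table <- function(n_total = 270L, ratio = c(80, 190), ...) {
  if (length(ratio) != 2L || any(ratio <= 0)) stop("'ratio' must be 2 positive numbers")
  n_pos <- round(n_total * ratio[1L] / sum(ratio))
  gen_feature_table(c(n_pos, n_total - n_pos), ...)
}
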