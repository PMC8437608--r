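disk_image <- function(size = 64, radius = 18, center = c(32, 32),
                       value = 0.9) {
  d2 <- outer(seq_len(size), seq_len(size),
              function(r, c) (r - center[1])^2 + (c - center[2])^2)
   0.05 + value * (d2 <= radius^2)
}

test_that("largest 8-connected region extraction matches a flood-fill oracle", {
  # 5x5 toy: one 3-pixel component, one isolated pixel
  img <- matrix(0, 5, 5)
  img[1, 1] <- img[2, 2] <- img[3, 2] <- 1  # diagonal + edge connected
  img[5, 5] <- 1
  mask <- preprocess_roi(rbind(img, matrix(0, 3, 5)) |>
                           cbind(matrix(0, 8, 3)), threshold = 0.5)
  expect_equal(sum(mask), 3)
  expect_true(mask[2, 2] && mask[1, 1] && mask[3, 2])
  expect_false(mask[5, 5])
  # random masks: labelling agrees with the recursive oracle up to renaming
  set.seed(61)
  for (i in 1:5) {
    m <- matrix(runif(100) < 0.35, 10, 10)
    lab <- label_components(m)
    orc <- oracle_components(m)
    expect_equal(max(lab), max(orc))
    # same partition: component of each pixel has identical membership
    for (comp in seq_len(max(lab))) {
      members <- which(lab == comp)
      expect_true(length(unique(orc[members])) == 1L)
    }
  }
})

test_that("diagonal-touching pixels form one component under 8-connectivity", {
  m <- matrix(FALSE, 6, 6)
  m[cbind(1:4, 1:4)] <- TRUE
  expect_equal(max(label_components(m)), 1L)
})

test_that("thresholding edge cases behave as documented", {
  img <- matrix(1, 10, 10)
  expect_equal(sum(preprocess_roi(img, threshold = 0.5)), 100)
  expect_error(preprocess_roi(img, threshold = 2), "foreground")
  expect_error(preprocess_roi(img), "constant")
  expect_error(preprocess_roi(matrix(1, 4, 4), threshold = 0.5), "8 x 8")
})

test_that("morphological features behave on canonical shapes", {
  img <- disk_image()
  mask <- img > 0.5
  f <- handcrafted_features(img, mask)
  expect_gt(f[["circularity"]], 0.85)
  expect_lt(f[["circularity"]], 1.1)
  expect_gt(f[["elongation"]], 0.95)  # disk is isotropic
  expect_equal(f[["eq_diameter"]], sqrt(4 * sum(mask) / pi))
  expect_lt(f[["convex_deficiency"]], 0.05)
  # filled square: rectangularity ~ 1
  sq <- matrix(FALSE, 32, 32); sq[8:24, 8:24] <- TRUE
  fs <- handcrafted_features(matrix(0.7, 32, 32) + 0.1 * sq, sq)
  expect_equal(fs[["rectangularity"]], 1)
})

test_that("constant-intensity regions give degenerate texture features", {
  sq <- matrix(FALSE, 20, 20); sq[5:15, 5:15] <- TRUE
  img <- matrix(0, 20, 20); img[sq] <- 0.8
  f <- handcrafted_features(img, sq)
  # inside the mask bounding box every pixel has one gray level
  expect_equal(f[["gray_sd"]], 0)
  expect_equal(f[["glcm_energy"]], 1)
  expect_equal(f[["glcm_contrast"]], 0)
  expect_equal(f[["glcm_entropy"]], 0)
})

test_that("morphological features tolerate translation within the frame", {
  a <- disk_image(center = c(26, 26))
  b <- disk_image(center = c(38, 40))
  fa <- handcrafted_features(a, a > 0.5)
  fb <- handcrafted_features(b, b > 0.5)
  morph <- c("area", "perimeter", "circularity", "rectangularity",
             "elongation", "eq_diameter")
  expect_true(all(abs(fa[morph] - fb[morph]) / abs(fa[morph]) < 0.05))
})

test_that("degenerate masks raise an informative error", {
  img <- matrix(0.5, 10, 10)
  m <- matrix(FALSE, 10, 10); m[3, 3] <- TRUE
  expect_error(handcrafted_features(img, m), "degenerate")
})

test_that("the embedding hook is deterministic, linear and shape-checked", {
  emb <- default_embedder(embed_dim = 64, input_size = 32, seed = 7)
  img <- matrix(runif(32 * 32), 32, 32)
  v1 <- embed_image(img, emb)
  expect_length(v1, 64)
  expect_identical(v1, embed_image(img, emb))
  expect_equal(embed_image(matrix(0, 32, 32), emb), rep(0, 64))
  # resizing path accepts other image sizes
  expect_length(embed_image(matrix(runif(48 * 48), 48, 48), emb), 64)
  bad <- function(image) c(1, NA)
  expect_error(embed_image(img, bad), "non-finite")
  bad2 <- structure(function(image) rep(1, 3), embed_dim = 5L)
  expect_error(embed_image(img, bad2), "expected 5")
})

test_that("PCA reduction matches hand-computed variance structure", {
  # rank-1 data: first component explains everything
  t_ <- seq(-2, 2, length.out = 10)
  X1 <- cbind(t_, 2 * t_, -t_)
  p1 <- fit_pca(X1, pca_dim = 1)
  expect_equal(p1$explained[1], 1, tolerance = 1e-12)
  # toy 2-D cloud with axis variances 4:1 -> ratios (0.8, 0.2)
  X2 <- rbind(c(2, 0), c(-2, 0), c(0, 1), c(0, -1))
  p2 <- fit_pca(X2, pca_dim = 2)
  expect_equal(p2$explained, c(0.8, 0.2), tolerance = 1e-12)
  # full-rank projection preserves pairwise distances
  set.seed(62)
  X <- matrix(rnorm(20 * 6), 20, 6)
  pf <- fit_pca(X, pca_dim = 6)
  S <- apply_pca(pf, X)
  expect_equal(as.matrix(dist(S)), as.matrix(dist(X)), tolerance = 1e-8)
  # rank overflow warns and truncates; variance targets select dims
  expect_warning(pr <- fit_pca(X1, pca_dim = 3), "rank")
  expect_equal(pr$dim, 1L)
  pv <- fit_pca(X2, var_target = 0.8)
  expect_equal(pv$dim, 1L)
  expect_error(fit_pca(X[1, , drop = FALSE]), "2 samples")
})

test_that("cascade concatenation is ordered, sized and validated", {
  hc <- seq_len(13) / 10
  pc <- rnorm(98)
  v <- cascade_features(hc, pc)
  expect_length(v, 111)
  expect_equal(unname(v[1:13]), hc)
  expect_equal(names(v)[c(1, 14)], c("hc_01", "pc_001"))
  expect_equal(unname(cascade_features(hc, numeric(0))), hc)
  expect_error(cascade_features(hc[1:5], pc), "expected 13")
  expect_error(cascade_features(hc, pc, pca_dim = 8), "expected 8")
})

test_that("z-score normalization learns on train only and flags constants", {
  set.seed(63)
  x <- matrix(rnorm(60), 20, 3)
  norm <- fit_normalizer(x)
  xs <- apply_normalizer(norm, x)
  expect_equal(colMeans(xs), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(xs, 2, sd), rep(1, 3), tolerance = 1e-12)
  # translation of the test set passes straight through the frozen params
  shift <- apply_normalizer(norm, x + 2)
  expect_equal(shift - xs, matrix(2 / norm$sd, 20, 3, byrow = TRUE),
               tolerance = 1e-12)
  xc <- cbind(x, 5)
  expect_warning(nc <- fit_normalizer(xc), "zero-variance")
  expect_equal(apply_normalizer(nc, xc)[, 4], rep(5, 20))
})

test_that("image-to-cascade pipeline is deterministic and shaped 13 + pca_dim", {
  set <- gen_roi_images(12, seed = 19)
  emb <- default_embedder(embed_dim = 32, input_size = 64, seed = 2)
  tab <- extract_cascade(set$images, set$labels, embedder = emb,
                         pca_dim = 10)
  expect_equal(dim(tab$x), c(24L, 23L))
  expect_equal(colnames(tab$x)[1:14], c(sprintf("hc_%02d", 1:13), "pc_001"))
  tab2 <- extract_cascade(set$images, set$labels, embedder = emb,
                          pca_dim = 10)
  expect_identical(tab$x, tab2$x)
  # a pre-fitted PCA reproduces the training projection on new data
  pca <- attr(tab, "pca")
  tab3 <- extract_cascade(set$images[1:4], set$labels[1:4], embedder = emb,
                          pca_dim = 10, pca = pca)
  expect_equal(tab3$x, tab$x[1:4, , drop = FALSE])
})
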