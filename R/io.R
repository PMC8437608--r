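#' Feature table container
#'
#' A lightweight samples-by-features container: numeric matrix `x` plus
#' canonical -1/+1 labels `y` (+1 = nodule).
#'
#' @param x numeric feature matrix.
#' @param y labels (any dialect accepted by [canonical_labels()]).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(x, y) {
  x <- as_sample_matrix(x)
  y <- canonical_labels(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (is.null(colnames(x))) colnames(x) <- sprintf("f_%02d", seq_len(ncol(x)))
  structure(list(x = x, y = y), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x$x), "samples x", ncol(x$x), "features\n")
  cat("  classes: +1 (nodule) =", sum(x$y == 1L),
      " -1 (nonnodule) =", sum(x$y == -1L), "\n")
  invisible(x)
}

#' Read / write a labeled feature table as delimited text
#'
#' Comma-separated UTF-8 text with a header row and one `label` column
#' (accepted dialects: \{1, 0\}, \{+1, -1\}, \{nodule, nonnodule\}); all
#' other columns are numeric features. Row order is preserved.
#'
#' @param path CSV file path.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty feature table: ", path)
  if (!("label" %in% names(df)))
    stop("feature table is missing the 'label' column: ", path)
  y <- canonical_labels(df$label)
  feats <- df[setdiff(names(df), "label")]
  bad <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "))
  feature_table(as.matrix(feats), y)
}

#' @rdname read_feature_table
#' @param table a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  if (!inherits(table, "feature_table")) stop("'table' must be a feature_table")
  df <- data.frame(label = table$y, table$x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read ROI images as PNG plus a label manifest
#'
#' Images are written as 8-bit grayscale PNG files `roi_0001.png`, ... in
#' `dir`, with a `manifest.csv` (columns `filename`, `label`).
#'
#' @param images list of intensity matrices with values in \[0, 1\].
#' @param labels labels, one per image.
#' @param dir output directory (created if needed).
#' @return `write_roi_images` returns the manifest path invisibly;
#'   `read_roi_images` a list with `images` and `labels`.
#' @export
write_roi_images <- function(images, labels, dir) {
  if (length(images) != length(labels)) stop("one label per image required")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- canonical_labels(labels)
  fn <- sprintf("roi_%04d.png", seq_along(images))
  for (i in seq_along(images))
    png::writePNG(t(images[[i]]), file.path(dir, fn[i]))
  manifest <- data.frame(filename = fn,
                         label = ifelse(labels == 1L, "nodule", "nonnodule"))
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' @rdname write_roi_images
#' @export
read_roi_images <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- read.csv(mpath)
  images <- lapply(file.path(dir, manifest$filename), function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    t(a)
  })
  list(images = images, labels = canonical_labels(manifest$label))
}

#' Default run configuration
#'
#' Every tunable of the pipeline with its default: swarm settings, search
#' ranges, kernel degree, folds, repeats, PCA dimension and seeds. A config
#' file (flat YAML mapping) may override any subset; unknown keys are
#' rejected.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  rg <- default_ranges()
  list(
    n_particles = 20L, max_iters = 200L,
    c1 = 1.5, c2 = 1.7, phi = 0.729, v_scale = 0.6,
    cooling_rate = 0.95, gbest_mode = "roulette",
    inertia_start = 0.9, inertia_end = 0.4,
    lambda_range = as.numeric(rg["lambda", ]),
    C_range = as.numeric(rg["C", ]),
    a_range = as.numeric(rg["a", ]),
    r_range = as.numeric(rg["r", ]),
    degree = 2L, k_folds = 5L, n_repeats = 10L,
    pca_dim = 98L, embed_dim = 512L,
    svm_C = 1, svm_tol = 1e-3,
    normalize = TRUE,
    grid_points = 4L,
    image_size = 64L, noise_sd = 0.05,
    n_per_class = 50L, table_dim = 13L, table_delta = 1,
    seed = 1L)
}

#' Load a run configuration
#'
#' Reads a YAML mapping and merges it over [default_config()]; unknown
#' keys raise an error, and a fully-defaulted (missing/empty) file is
#' valid.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return named configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

config_to_swarm <- function(cfg, ranges = NULL) {
  if (is.null(ranges))
    ranges <- rbind(lambda = cfg$lambda_range, C = cfg$C_range,
                    a = cfg$a_range, r = cfg$r_range)
  swarm_config(n_particles = cfg$n_particles, max_iters = cfg$max_iters,
               ranges = ranges, c1 = cfg$c1, c2 = cfg$c2, phi = cfg$phi,
               v_scale = cfg$v_scale, cooling_rate = cfg$cooling_rate,
               gbest_mode = cfg$gbest_mode,
               inertia = c(cfg$inertia_start, cfg$inertia_end),
               seed = cfg$seed)
}
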