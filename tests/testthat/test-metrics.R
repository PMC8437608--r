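test_that("confusion counts match the scalar counting oracle", {
  expect_equal(unclass(confusion(c(1, -1), c(1, -1)))[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  y <- c(rep(1, 5), rep(-1, 5))
  expect_equal(confusion(y, rep(1, 10))$FP, 5L)
  set.seed(71)
  for (i in 1:5) {
    yt <- sample(c(-1, 1), 100, replace = TRUE)
    yp <- sample(c(-1, 1), 100, replace = TRUE)
    cc <- confusion(yt, yp)
    orc <- oracle_confusion(yt, yp)
    expect_equal(unclass(cc)[names(orc)], orc)
  }
  expect_error(confusion(c(1, -1), c(1)), "length")
})

test_that("metric formulas match hand computation and the brute-force oracle", {
  perfect <- confusion(c(rep(1, 5), rep(-1, 5)), c(rep(1, 5), rep(-1, 5)))
  expect_equal(unname(basic_metrics(perfect)), c(1, 1, 1, 1, 1))
  inverted <- confusion(c(rep(1, 5), rep(-1, 5)), c(rep(-1, 5), rep(1, 5)))
  expect_equal(basic_metrics(inverted)[["MCC"]], -1)
  # hand-computed case: TP=26, FN=1, TN=63, FP=10
  cc <- structure(list(TP = 26L, TN = 63L, FP = 10L, FN = 1L),
                  class = "confusion_counts")
  m <- basic_metrics(cc)
  expect_equal(m[["ACC"]], 0.89)
  expect_equal(m[["SEN"]], 26 / 27)
  expect_equal(m[["SPE"]], 63 / 73)
  expect_equal(m[["PRE"]], 26 / 36)
  expect_equal(m[["MCC"]],
               (26 * 63 - 10 * 1) / sqrt(36 * 27 * 73 * 64))
  set.seed(72)
  for (i in 1:20) {
    yt <- sample(c(-1, 1), 50, replace = TRUE)
    yp <- sample(c(-1, 1), 50, replace = TRUE)
    cc <- confusion(yt, yp)
    if (any(c(cc$TP + cc$FN, cc$TN + cc$FP, cc$TP + cc$FP,
              cc$TN + cc$FN) == 0)) next
    expect_equal(basic_metrics(cc), oracle_metrics(cc))
  }
})

test_that("zero-denominator metrics surface as undefined markers", {
  allneg <- confusion(rep(-1, 4), rep(-1, 4))
  m <- basic_metrics(allneg)
  expect_true(is.na(m[["SEN"]]))
  expect_true(is.na(m[["PRE"]]))
  expect_true(is.na(m[["MCC"]]))
  expect_equal(m[["ACC"]], 1)
  expect_true(is.na(f_score(0, 0)))
  expect_true(is.na(f_score(NA, 0.5)))
})

test_that("the F-score is the harmonic mean of ACC and SEN", {
  expect_equal(f_score(0.9, 0.9), 0.9)
  expect_equal(f_score(0.89, 26 / 27), 2 * 0.89 * (26 / 27) / (0.89 + 26 / 27))
  # bounded between its arguments
  set.seed(73)
  for (i in 1:50) {
    acc <- runif(1); sen <- runif(1)
    f <- f_score(acc, sen)
    expect_gte(f, min(acc, sen) - 1e-12)
    expect_lte(f, max(acc, sen) + 1e-12)
  }
  expect_error(f_score(1.2, 0.5), "0, 1")
})

test_that("MCC flips sign when the positive class is swapped", {
  set.seed(74)
  yt <- sample(c(-1, 1), 60, replace = TRUE)
  yp <- sample(c(-1, 1), 60, replace = TRUE)
  m1 <- basic_metrics(confusion(yt, yp))
  m2 <- basic_metrics(confusion(-yt, yp))
  expect_equal(m1[["MCC"]], -m2[["MCC"]], tolerance = 1e-12)
})

test_that("trapezoid AUC equals all-pairs concordance", {
  # perfectly ranked
  expect_equal(roc_auc(c(3, 2, 1, 0), c(1, 1, -1, -1))$auc, 1)
  # all tied
  expect_equal(roc_auc(rep(0.4, 6), c(1, 1, 1, -1, -1, -1))$auc, 0.5)
  # 6-sample toy with a tie
  s <- c(0.9, 0.7, 0.7, 0.4, 0.2, 0.1)
  y <- c(1, -1, 1, 1, -1, -1)
  expect_equal(roc_auc(s, y)$auc, oracle_auc(s, y))
  set.seed(75)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    s <- round(rnorm(n), 1)  # rounding forces frequent ties
    expect_equal(roc_auc(s, y)$auc, oracle_auc(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(76)
  y <- sample(c(-1, 1), 40, replace = TRUE)
  s <- rnorm(40) + 0.8 * y
  expect_equal(roc_auc(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("ROC points step from (0,0) to (1,1) monotonically", {
  set.seed(77)
  y <- sample(c(-1, 1), 30, replace = TRUE)
  s <- rnorm(30)
  roc <- roc_auc(s, y)$roc
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})

test_that("stratified folds balance classes and partition the data", {
  tab <- gen_imbalanced_table(seed = 6)
  folds <- stratified_folds(tab$y, k = 5, seed = 2)
  expect_identical(folds, stratified_folds(tab$y, k = 5, seed = 2))
  expect_equal(sort(unique(folds)), 1:5)
  for (f in 1:5) {
    expect_equal(sum(tab$y == 1 & folds == f), 16)  # 80 nodules / 5
    expect_equal(sum(tab$y == -1 & folds == f), 38)
  }
  expect_error(stratified_folds(c(1, -1, -1, -1, -1, -1), k = 5), "members")
})

test_that("cross-validation pools folds and is perfect on separable data", {
  tab <- make_separable_table(n_per_class = 25, delta = 8)
  rep <- cross_validate(tab, spec = kernel_spec("mix", d = 2, a = 0.01,
                                                r = 0, mix_weight = 0.5),
                        C = 10, k = 5, seed = 1)
  cc <- rep$counts
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 50)
  expect_equal(rep$F_score, 1)
  expect_equal(rep$AUC, 1)
})

test_that("chance-level data yields chance-level cross-validated accuracy", {
  # delta = 0: the classes are identical; 400 samples give a 99% binomial
  # band of 0.5 +/- 2.58 * sqrt(.25/400) ~ 0.5 +/- 0.0645
  tab <- gen_feature_table(200, dim = 5, delta = 0, seed = 41)
  rep <- cross_validate(tab, spec = kernel_spec("mix", d = 2, a = 0.01,
                                                r = 0, mix_weight = 0.5),
                        C = 1, k = 5, seed = 3)
  expect_lt(abs(rep$ACC - 0.5), 0.0645)
})

test_that("repeat summaries mirror the per-run list", {
  out <- repeat_runs(function(seed) c(F_score = c(1, 2, 3)[seed]),
                     n_repeats = 3)
  expect_equal(out$summary["F_score", "mean"], 2)
  expect_equal(out$summary["F_score", "median"], 2)
  expect_equal(out$summary["F_score", "max"], 3)
  expect_equal(out$summary["F_score", "min"], 1)
  const <- repeat_runs(function(seed) c(ACC = 0.7), n_repeats = 4)
  expect_true(all(const$summary["ACC", ] == 0.7))
  # summary recomputable from the stored runs
  set.seed(78)
  rr <- repeat_runs(function(seed) c(m = rnorm(1)), n_repeats = 10)
  expect_equal(rr$summary["m", "mean"], mean(rr$runs[, "m"]))
  expect_equal(rr$summary["m", "median"], median(rr$runs[, "m"]))
})
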