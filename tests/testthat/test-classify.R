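# Classifier: feature building, standardization contracts, balancing,
# SVM training/prediction, cross-validation and AUC.

test_that("feature building uses log10 dwell and rejects bad input", {
  ev <- data.frame(I_B = 0.8, t_D_us = 1000, i_rms_nA = 0.2)
  fs <- build_features(ev)
  expect_equal(unname(fs$x[1, "log10_tD"]), 3)
  expect_error(build_features(data.frame(I_B = 1, t_D_us = 0,
                                         i_rms_nA = 1)), "dwell")
  expect_error(build_features(data.frame(I_B = 1)), "columns")
})

test_that("standardization is a z-score and is reused, not refit, on new data", {
  x <- separable_features(200, seed = 41)
  fs <- build_features(x)
  std <- fit_standardization(fs$x)
  z <- apply_standardization(fs$x, std)
  expect_equal(unname(colMeans(z)), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1, 1), tolerance = 1e-9)
  # shifted new data standardized with the stored record keeps the shift
  z2 <- apply_standardization(fs$x + 1, std)
  expect_equal(z2 - z, (1 / matrix(std$scale, nrow(z), 3, byrow = TRUE)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(fit_standardization(cbind(a = rep(1, 5), b = 1:5)),
               "zero-variance")
})

test_that("class balancing downsamples to the minority count", {
  ev <- rbind(sample_event_features(class_defaults("fragment"), 1000, seed = 1),
              sample_event_features(class_defaults("mtDNA"), 500, seed = 2),
              sample_event_features(class_defaults("syDNA"), 700, seed = 3))
  fs <- build_features(ev)
  bal <- balance_classes(fs, seed = 4)
  expect_equal(unname(table(bal$label)), rep(500L, 3), ignore_attr = TRUE)
  # already balanced input: a permutation of itself
  bal2 <- balance_classes(bal, seed = 5)
  expect_equal(nrow(bal2$x), nrow(bal$x))
  expect_equal(sort(bal2$x[, "i_rms"]), sort(bal$x[, "i_rms"]))
  # different seeds choose different subsets but identical counts
  b1 <- balance_classes(fs, seed = 6)
  b2 <- balance_classes(fs, seed = 7)
  expect_equal(table(b1$label), table(b2$label))
  expect_false(identical(sort(b1$x[, "log10_tD"]), sort(b2$x[, "log10_tD"])))
})

test_that("separable classes train to perfect accuracy and self-prediction", {
  fs <- build_features(separable_features(100, gap = 10, seed = 42))
  art <- train_svm(fs, svm_config(seed = 1))
  pr <- predict(art, fs)
  expect_equal(as.character(pr$label), as.character(fs$label))
  rep <- cross_validate(fs, svm_config(seed = 1))
  expect_equal(rep$accuracy_pct, 100)
  expect_true(all(diag(rep$confusion) == table(fs$label)))
  expect_equal(unname(rep$auc), c(1, 1))
})

test_that("identical class distributions cross-validate at chance level", {
  n <- 2000
  x <- withr::with_seed(43, data.frame(
    I_B = rnorm(n, 0.8, 0.05),
    t_D_us = rlnorm(n, log(300), 0.5),
    i_rms_nA = rlnorm(n, log(0.2), 0.3),
    class_label = rep(c("a", "b"), n / 2)))
  rep <- cross_validate(build_features(x), svm_config(seed = 44))
  se <- 100 * sqrt(0.25 / n)
  expect_lt(abs(rep$accuracy_pct - 50), 3 * se)
  expect_lt(abs(rep$macro_auc - 0.5), 3 * sqrt(1 / 12) / sqrt(n / 4))
})

test_that("cross-validation bookkeeping: folds, confusion sums, determinism", {
  ev <- rbind(sample_event_features(class_defaults("mtDNA"), 300, seed = 8),
              sample_event_features(class_defaults("syDNA"), 300, seed = 9))
  fs <- build_features(ev)
  cfg <- svm_config(n_folds = 5, seed = 45)
  rep1 <- cross_validate(fs, cfg)
  rep2 <- cross_validate(fs, cfg)
  expect_identical(rep1$folds, rep2$folds)
  expect_identical(rep1$confusion, rep2$confusion)
  expect_equal(unname(rowSums(rep1$confusion)), unname(table(fs$label)),
               ignore_attr = TRUE)
  expect_equal(unname(rep1$tpr + rep1$fnr), c(1, 1))
  # folds are stratified: each fold holds ~1/5 of each class
  for (k in 1:5)
    expect_equal(unname(table(fs$label[rep1$folds == k])), c(60, 60),
                 ignore_attr = TRUE)
  expect_error(cross_validate(fs, svm_config(n_folds = 400)), "minority")
})

test_that("prediction is row-permutation equivariant with stable scores", {
  ev <- rbind(sample_event_features(class_defaults("mtDNA"), 200, seed = 10),
              sample_event_features(class_defaults("fragment"), 200, seed = 11))
  fs <- build_features(ev)
  art <- train_svm(fs, svm_config(seed = 1))
  new <- sample_event_features(class_defaults("mtDNA"), 50, seed = 12)
  pr <- predict(art, build_features(new))
  perm <- withr::with_seed(13, sample(50))
  pr_p <- predict(art, build_features(new[perm, ]))
  expect_equal(pr_p$scores, pr$scores[perm, ], ignore_attr = TRUE)
  expect_identical(as.character(pr_p$label), as.character(pr$label[perm]))
  # schema mismatch rejected
  bad <- fs$x[, c(2, 1, 3)]
  expect_error(predict(art, bad), "schema")
})

test_that("rank-statistic AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  sc <- withr::with_seed(46, c(rnorm(300), rnorm(300, 1)))
  lab <- rep(c(FALSE, TRUE), each = 300)
  ours <- mitopore:::auc_rank(sc, lab)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("accuracy degrades monotonically as class separation shrinks", {
  make <- function(delta, seed) {
    withr::with_seed(seed, {
      n <- 300
      a <- data.frame(I_B = rnorm(n, 0.8, 0.03),
                      t_D_us = rlnorm(n, log(300), 0.3),
                      i_rms_nA = rlnorm(n, log(0.2), 0.3),
                      class_label = "a")
      b <- a
      b$I_B <- b$I_B - delta * 0.03
      b$class_label <- "b"
      rbind(a, b)
    })
  }
  accs <- vapply(c(3, 1.5, 0.3), function(d)
    cross_validate(build_features(make(d, 47)),
                   svm_config(seed = 48))$accuracy_pct, numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("fold-internal standardization differs from leaky global fitting", {
  ev <- separable_features(50, gap = 4, seed = 49)
  ev$i_rms_nA[1] <- 500 # gross outlier dominates any global scale
  fs <- build_features(ev)
  cfg <- svm_config(seed = 50)
  rep_fold <- cross_validate(fs, cfg, fold_standardize = TRUE)
  rep_glob <- cross_validate(fs, cfg, fold_standardize = FALSE)
  expect_false(identical(rep_fold$oof_scores, rep_glob$oof_scores))
  expect_false(identical(rep_fold$confusion, rep_glob$confusion))
})

test_that("structural feature rate works with classifier or threshold", {
  ev <- rbind(sample_event_features(class_defaults("mtDNA"), 300, seed = 14),
              sample_event_features(class_defaults("syDNA"), 300, seed = 15))
  art <- train_svm(build_features(ev), svm_config(seed = 1))
  mt <- sample_event_features(class_defaults("mtDNA"), 200, seed = 16)
  expect_gt(structural_feature_rate(build_features(mt), art), 0.8)
  expect_equal(structural_feature_rate(mt, threshold = 1e6), 0)
  expect_equal(structural_feature_rate(mt, threshold = 0), 1)
  expect_error(structural_feature_rate(mt[0, ], art), "no events")
  expect_error(structural_feature_rate(mt), "threshold")
})
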