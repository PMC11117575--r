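test_that("the 80/20 split is stratified, exhaustive and reproducible", {
  fm <- blob_fm(n_per = 25)  # 50 exams, 25 per class
  sp <- split_cohort(fm, seed = 3)
  expect_equal(nrow(sp$train$x), 40)
  expect_equal(nrow(sp$validation$x), 10)
  expect_equal(as.vector(table(sp$validation$labels)), c(5, 5))
  expect_equal(sort(c(sp$validation_idx,
                      which(!seq_len(50) %in% sp$validation_idx))),
               1:50)
  sp2 <- split_cohort(fm, seed = 3)
  expect_identical(sp$validation_idx, sp2$validation_idx)
  expect_false(identical(sp$validation_idx,
                         split_cohort(fm, seed = 4)$validation_idx))
})

test_that("a linearly separable toy cohort is fit perfectly by the forest", {
  fm <- blob_fm()
  b <- train_models(fm, seed = 1)
  rep <- evaluate_bundle(b, fm, dataset = "training")
  expect_equal(rep$reports$random_forest$accuracy, 1)
  expect_equal(rep$reports$random_forest$auc, 1)
  expect_true(all(rep$summary$auc == 1))
})

test_that("shuffled labels give chance-level cross-validated AUC", {
  fm <- blob_fm(n_per = 25)
  fm$labels <- withr::with_seed(11, sample(fm$labels))
  cv <- cross_validate(fm, k = 5, seed = 11)
  expect_true(all(cv$auc > 0.3 & cv$auc < 0.7))
})

test_that("training is deterministic under a fixed seed", {
  fm <- blob_fm(shift = 1)
  b1 <- train_models(fm, seed = 5)
  b2 <- train_models(fm, seed = 5)
  expect_equal(predict_bundle(b1, fm), predict_bundle(b2, fm))
})

test_that("the voting score is exactly the mean of NB and RF probabilities", {
  fm <- blob_fm(shift = 1.5)
  b <- train_models(fm, seed = 2)
  p <- predict_bundle(b, fm)
  expect_identical(p[, "voting"],
                   (p[, "naive_bayes"] + p[, "random_forest"]) / 2)
})

test_that("standardization is fitted on training rows only (no leakage)", {
  fm <- blob_fm(n_per = 25, shift = 1.5)
  sp <- split_cohort(fm, seed = 9)
  b <- train_models(sp$train, seed = 9)
  expect_equal(b$standardizer$mu, colMeans(sp$train$x))
  # pre-standardizing validation rows with the *train* parameters and
  # disabling the bundle standardizer leaves the standardized models
  # unchanged
  xs <- airDIC:::apply_standardizer(b$standardizer, sp$validation$x)
  fm_pre <- sp$validation
  fm_pre$x <- xs
  b_id <- b
  b_id$standardizer <- list(mu = setNames(rep(0, ncol(xs)), colnames(xs)),
                            sd = setNames(rep(1, ncol(xs)), colnames(xs)),
                            keep = rep(TRUE, ncol(xs)))
  p1 <- predict_bundle(b, sp$validation)
  p2 <- predict_bundle(b_id, fm_pre)
  expect_equal(p1[, "naive_bayes"], p2[, "naive_bayes"], tolerance = 1e-12)
  expect_equal(p1[, "logistic"], p2[, "logistic"], tolerance = 1e-12)
})

test_that("constant columns are dropped with a warning", {
  fm <- blob_fm()
  fm$x[, 3] <- 5
  expect_warning(b <- train_models(fm, seed = 1), "constant feature")
  expect_equal(sum(!b$standardizer$keep), 1)
  expect_silent(p <- predict_bundle(b, fm))
  expect_false(anyNA(p))
})

test_that("evaluation handles degenerate probability patterns", {
  cm <- confusion_matrix(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(confusion_metrics(cm)$accuracy, 1)
  # single-class data: AUC reported missing
  fm <- blob_fm()
  one <- airDIC:::subset_fm(fm, which(fm$labels == "ffkc"))
  b <- train_models(fm, seed = 1)
  rep1 <- evaluate_bundle(b, one)
  expect_true(is.na(rep1$reports$voting$auc))
  expect_equal(rep1$reports$voting$recall, 1)
})

test_that("the time-point sweep at the full length equals the standard
           evaluation", {
  co <- mini_cohort()
  fm <- assemble_feature_matrix(co)
  sw <- timepoint_sweep(co, k_list = 140, seed = 13)
  sp <- split_cohort(fm, seed = 13)
  b <- train_models(sp$train, seed = 13)
  auc <- evaluate_bundle(b, sp$validation)$summary$auc
  expect_equal(unlist(sw[1, -1], use.names = FALSE), auc)
  expect_error(timepoint_sweep(co, k_list = integer(0)), "empty")
})

test_that("feature importance is normalized, reproducible and finds a
           planted signal", {
  withr::with_seed(31, {
    x <- matrix(rnorm(60 * 12), 60, 12)
    y <- factor(rep(c("normal", "ffkc"), each = 30),
                levels = c("normal", "ffkc"))
    x[, 7] <- x[, 7] + 3 * (y == "ffkc")  # the informative column
  })
  colnames(x) <- paste0("c@", seq_len(12) - 1)
  fm <- structure(list(x = x, labels = y, exam_ids = as.character(1:60),
                       curve_subset = "c", k = 12),
                  class = "feature_matrix")
  b <- train_models(fm, seed = 3)
  imp <- feature_importance(b)
  expect_equal(imp$feature[1], "c@6")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  b2 <- train_models(fm, seed = 3)
  expect_identical(feature_importance(b2), imp)
})
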