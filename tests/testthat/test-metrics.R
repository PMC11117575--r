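test_that("confusion metrics follow the published definitions", {
  # printed NB validation row: precision 0.73, recall 1.00 -> F1 0.84 (2 dp)
  cm <- confusion_matrix(tp = 8, fp = 3, tn = 9, fn = 0)
  met <- confusion_metrics(cm)
  expect_equal(met$accuracy, 0.85)
  expect_equal(met$precision, 8 / 11, tolerance = 1e-12)
  expect_equal(round_half_up(met$precision), 0.73)
  expect_equal(met$recall, 1)
  expect_equal(met$sensitivity, met$recall)
  expect_equal(met$specificity, 0.75)
  expect_equal(round_half_up(met$f1), 0.84)
  # perfect 2-sample matrix
  met1 <- confusion_metrics(confusion_matrix(1, 0, 1, 0))
  expect_true(all(unlist(met1) == 1))
  # zero denominators are reported missing
  met0 <- confusion_metrics(confusion_matrix(0, 0, 4, 0))
  expect_true(is.na(met0$precision))
  expect_true(is.na(met0$recall))
  expect_equal(met0$accuracy, 1)
  expect_error(confusion_matrix(-1, 0, 1, 0), "non-negative")
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_up(0.845), 0.85)
  expect_equal(round_half_up(0.125), 0.13)
  expect_equal(round_half_up(-0.125), -0.13)
  expect_equal(round_half_up(86.255, 1), 86.3)
})

test_that("trapezoidal AUC matches the concordant-pair count", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)  # 3 of 4 pairs concordant
  # perfect separation: AUC 1, Youden cut-off between the classes
  r2 <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r2$auc, 1)
  expect_gt(r2$optimal_cutoff, 3)
  expect_lt(r2$optimal_cutoff, 10)
  expect_equal(r2$youden, 1)
  # ties: all scores equal
  expect_equal(roc_auc(rep(1, 8), rep(c(0, 1), 4))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC equals the Mann-Whitney concordance on random instances", {
  withr::with_seed(17, {
    for (i in 1:50) {
      n <- sample(4:30, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
      expect_equal(roc_auc(scores, labels)$auc, mw_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("confusion reconstruction inverts printed table rows", {
  # unique solution for the NB validation row, reproducing accuracy 85%
  sol <- reconstruct_confusion(20, precision = 0.73, recall = 1.00,
                               specificity = 0.75)
  expect_equal(nrow(sol), 1)
  expect_equal(unlist(sol[1, ]), c(tp = 8, fp = 3, tn = 9, fn = 0))
  expect_equal(100 * (sol$tp + sol$tn) / 20, 85.00)
  # trivial 2-sample case
  sol2 <- reconstruct_confusion(2, precision = 1, recall = 1,
                                specificity = 1)
  expect_equal(unlist(sol2[1, ]), c(tp = 1, fp = 0, tn = 1, fn = 0))
  # the published logistic validation row is internally inconsistent
  bad <- reconstruct_confusion(20, precision = 0.89, recall = 1.00,
                               f1 = 1.00)
  expect_equal(nrow(bad), 0)
})

test_that("reconstruction round-trips the rounded metrics", {
  withr::with_seed(23, {
    for (i in 1:10) {
      cm <- confusion_matrix(sample(0:10, 1) + 1, sample(0:6, 1),
                             sample(0:10, 1) + 1, sample(0:6, 1))
      met <- confusion_metrics(cm)
      tot <- cm$tp + cm$fp + cm$tn + cm$fn
      sols <- reconstruct_confusion(tot,
                                    precision = round_half_up(met$precision),
                                    recall = round_half_up(met$recall),
                                    specificity = round_half_up(met$specificity))
      expect_gt(nrow(sols), 0)
      # the true matrix is among the solutions, and every solution
      # reproduces the rounded inputs
      expect_true(any(sols$tp == cm$tp & sols$fp == cm$fp &
                        sols$tn == cm$tn & sols$fn == cm$fn))
      for (j in seq_len(nrow(sols))) {
        mj <- confusion_metrics(do.call(confusion_matrix, as.list(sols[j, ])))
        expect_equal(round_half_up(mj$precision),
                     round_half_up(met$precision))
        expect_equal(round_half_up(mj$recall), round_half_up(met$recall))
      }
    }
  })
})

test_that("the pooled t statistic reproduces published demographics", {
  cct <- two_sample_t(558.58, 26.55, 50, 530.12, 26.51, 50)
  expect_equal(round_half_up(cct$t), 5.36)
  expect_lt(cct$p, 0.001)
  biop <- two_sample_t(16.63, 2.88, 50, 13.70, 2.01, 50)
  expect_equal(round_half_up(biop$t), 5.90)
  expect_equal(two_sample_t(5, 1, 10, 5, 1, 10)$t, 0)
  # antisymmetry under group swap
  a <- two_sample_t(12, 2, 20, 10, 3, 25)
  b <- two_sample_t(10, 3, 25, 12, 2, 20)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
})

test_that("the uncorrected chi-square reproduces the published gender test", {
  g <- chi_square_2x2(35, 15, 39, 11)
  expect_equal(round_half_up(g$x2), 0.83)
  expect_gt(g$p, 0.05)
  expect_equal(chi_square_2x2(10, 5, 10, 5)$x2, 0)
  expect_equal(chi_square_2x2(10, 0, 0, 10)$x2, 20)
  # invariance under row and column permutation
  expect_equal(chi_square_2x2(39, 11, 35, 15)$x2, g$x2)
  expect_equal(chi_square_2x2(15, 35, 11, 39)$x2, g$x2)
  expect_error(chi_square_2x2(5, 0, 7, 0), "marginals")
})
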