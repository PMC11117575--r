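#' Split a cohort feature matrix into training and validation sets
#'
#' Deterministic under `seed`; stratified by class by default, so a 50/50
#' cohort of 100 exams yields 80 training and 20 validation exams with 10
#' of each class held out.
#'
#' @param fm A [assemble_feature_matrix()] result.
#' @param train_frac Training fraction (default 0.8).
#' @param stratified Stratify by class label.
#' @param seed Integer seed.
#' @return `list(train =, validation =, validation_idx =)`.
#' @export
split_cohort <- function(fm, train_frac = 0.8, stratified = TRUE, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"), train_frac > 0, train_frac < 1)
  n <- nrow(fm$x)
  if (min(table(fm$labels)) < 2)
    stop("need at least 2 exams per class")
  val_idx <- withr::with_seed(as.integer(seed), {
    if (stratified) {
      unlist(lapply(levels(fm$labels), function(lv) {
        pool <- which(fm$labels == lv)
        sample(pool, round((1 - train_frac) * length(pool)))
      }))
    } else {
      sample(n, round((1 - train_frac) * n))
    }
  })
  val_idx <- sort(val_idx)
  train <- subset_fm(fm, setdiff(seq_len(n), val_idx))
  validation <- subset_fm(fm, val_idx)
  if (nlevels(droplevels(train$labels)) < 2 ||
      nlevels(droplevels(validation$labels)) < 2)
    stop("a class is absent from the training or validation set")
  list(train = train, validation = validation, validation_idx = val_idx)
}

# z-score standardizer fitted on training rows only (leakage guard)
fit_standardizer <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  keep <- s > 0
  list(mu = mu, sd = s, keep = keep)
}

apply_standardizer <- function(std, x) {
  xs <- sweep(x[, std$keep, drop = FALSE], 2, std$mu[std$keep])
  sweep(xs, 2, std$sd[std$keep], "/")
}

#' Train the model bundle
#'
#' Fits, on the training rows only, a Gaussian Naive Bayes and a
#' ridge-penalized logistic regression on z-scored features (the
#' standardizer is itself fitted on the training rows), and a Random
#' Forest on the raw features. The soft-voting ensemble scores with the
#' arithmetic mean of the NB and RF class probabilities. Constant feature
#' columns are dropped (with a warning) for the standardized models, and
#' the NB per-class standard deviations are floored at
#' `sqrt(1e-9 * max column variance)` to guard against degenerate
#' class-conditional fits. All randomness is governed by `seed`.
#'
#' @param train A `feature_matrix` of training exams.
#' @param seed Integer seed (Random Forest bootstrap).
#' @param ntree Random Forest size (default 100).
#' @param ridge_lambda Ridge penalty for the logistic model; default
#'   `1 / n_train` (unit total penalty strength).
#' @return A `model_bundle`.
#' @export
train_models <- function(train, seed = 1L, ntree = 100,
                         ridge_lambda = NULL) {
  stopifnot(inherits(train, "feature_matrix"))
  if (nlevels(droplevels(train$labels)) < 2)
    stop("training data must contain both classes")
  std <- fit_standardizer(train$x)
  if (!all(std$keep))
    warning(sum(!std$keep), " constant feature column(s) dropped for the ",
            "standardized models")
  xs <- apply_standardizer(std, train$x)
  y <- train$labels

  nb <- e1071::naiveBayes(as.data.frame(xs), y)
  floor_sd <- sqrt(1e-9 * max(apply(xs, 2, stats::var)))
  nb$tables <- lapply(nb$tables, function(tab) {
    tab[, 2] <- pmax(tab[, 2], floor_sd)
    tab
  })

  rf <- withr::with_seed(as.integer(seed),
    randomForest::randomForest(x = train$x, y = y, ntree = ntree))

  if (is.null(ridge_lambda)) ridge_lambda <- 1 / nrow(xs)
  lr <- withCallingHandlers(
    glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                   lambda = ridge_lambda, standardize = FALSE),
    warning = function(w) {
      # advisory about very small class counts; expected on toy cohorts
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })

  structure(list(nb = nb, rf = rf, lr = lr, standardizer = std,
                 levels = levels(y), seed = as.integer(seed),
                 ridge_lambda = ridge_lambda),
            class = "model_bundle")
}

#' Class-1 (FFKC) probabilities from every model
#'
#' @param bundle A [train_models()] bundle.
#' @param fm A `feature_matrix`.
#' @return Numeric matrix `n x 4`, columns `naive_bayes`, `random_forest`,
#'   `voting`, `logistic`; the voting column is exactly the mean of the
#'   first two.
#' @export
predict_bundle <- function(bundle, fm) {
  xs <- apply_standardizer(bundle$standardizer, fm$x)
  pos <- bundle$levels[2]
  tiny <- .Machine$double.xmin
  p_nb <- predict(bundle$nb, as.data.frame(xs), type = "raw",
                  threshold = tiny, eps = tiny)[, pos]
  p_rf <- predict(bundle$rf, fm$x, type = "prob")[, pos]
  p_lr <- as.vector(predict(bundle$lr, xs, type = "response"))
  cbind(naive_bayes = p_nb, random_forest = p_rf,
        voting = (p_nb + p_rf) / 2, logistic = p_lr)
}

#' Evaluate the bundle on a dataset
#'
#' Hard labels at probability threshold 0.5; confusion-matrix metrics via
#' [confusion_metrics()]; ROC and AUC from the continuous scores via
#' [roc_auc()] (reported as `NA` when only one class is present).
#'
#' @param bundle A `model_bundle`.
#' @param fm A `feature_matrix` (nonempty).
#' @param dataset Tag recorded in the reports, e.g. `"validation"`.
#' @return A `bundle_report`: per-model `classifier_report` lists plus a
#'   `summary` data frame shaped like a performance table (accuracy in %,
#'   then precision, recall, F1, sensitivity, specificity, AUC).
#' @export
evaluate_bundle <- function(bundle, fm, dataset = "validation") {
  stopifnot(nrow(fm$x) >= 1)
  probs <- predict_bundle(bundle, fm)
  pos <- bundle$levels[2]
  truth <- fm$labels == pos
  one_class <- length(unique(truth)) < 2
  reports <- lapply(colnames(probs), function(mod) {
    p <- probs[, mod]
    pred <- p >= 0.5
    cm <- confusion_matrix(tp = sum(pred & truth), fp = sum(pred & !truth),
                           tn = sum(!pred & !truth), fn = sum(!pred & truth))
    met <- confusion_metrics(cm)
    roc <- if (one_class) NULL else roc_auc(p, truth, auto_orient = FALSE)
    c(list(model = mod, dataset = dataset, cm = cm,
           auc = if (is.null(roc)) NA_real_ else roc$auc, roc = roc), met)
  })
  names(reports) <- colnames(probs)
  summary <- do.call(rbind, lapply(reports, function(r)
    data.frame(model = r$model, dataset = r$dataset,
               accuracy_pct = 100 * r$accuracy, precision = r$precision,
               recall = r$recall, f1 = r$f1, sensitivity = r$sensitivity,
               specificity = r$specificity, auc = r$auc)))
  rownames(summary) <- NULL
  structure(list(reports = reports, summary = summary, dataset = dataset),
            class = "bundle_report")
}

#' @export
print.bundle_report <- function(x, ...) {
  cat(sprintf("model performance (%s):\n", x$dataset))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' @param fm A `feature_matrix`.
#' @param k Fold count (default 5).
#' @param seed Integer seed (fold assignment and model fits).
#' @param ... Passed to [train_models()].
#' @return List with `auc` (mean validation AUC per model) and `folds`
#'   (per-fold AUC matrix).
#' @export
cross_validate <- function(fm, k = 5, seed = 1L, ...) {
  n <- nrow(fm$x)
  folds <- withr::with_seed(as.integer(seed), {
    f <- integer(n)
    for (lv in levels(fm$labels)) {
      pool <- sample(which(fm$labels == lv))
      f[pool] <- rep_len(seq_len(k), length(pool))
    }
    f
  })
  per_fold <- t(vapply(seq_len(k), function(fold) {
    tr <- subset_fm(fm, which(folds != fold))
    te <- subset_fm(fm, which(folds == fold))
    bundle <- train_models(tr, seed = seed, ...)
    evaluate_bundle(bundle, te, dataset = sprintf("fold-%d", fold))$
      summary$auc
  }, numeric(4)))
  colnames(per_fold) <- c("naive_bayes", "random_forest", "voting",
                          "logistic")
  list(auc = colMeans(per_fold, na.rm = TRUE), folds = per_fold)
}

#' Validation AUC as a function of the number of time points
#'
#' Re-assembles the features with the first `k` frames of each selected
#' curve, re-splits with the same seed (hence the same exams), re-trains
#' and reports the validation AUC of every model -- the incremental
#' time-point experiment.
#'
#' @param cohort A cohort (as for [assemble_feature_matrix()]) or an
#'   already-assembled `feature_matrix` whose columns are then truncated.
#' @param k_list Increasing counts of leading time points, e.g.
#'   `c(1, 5, 10, 35, 70, 140)`.
#' @param curve_subset Curves to use (default the four ave- curves).
#' @param train_frac,seed Split specification.
#' @param csv Optional path: write the result table as CSV.
#' @param ... Passed to [train_models()].
#' @return Data frame with columns `k` and one AUC column per model.
#' @export
timepoint_sweep <- function(cohort, k_list = c(1, 5, 10, 35, 70, 140),
                            curve_subset = c("ave_V", "ave_gxy",
                                             "ave_VR", "ave_gxyR"),
                            train_frac = 0.8, seed = 1L, csv = NULL, ...) {
  if (length(k_list) == 0) stop("k_list is empty")
  fm_full <- if (inherits(cohort, "feature_matrix")) cohort
    else assemble_feature_matrix(cohort, curve_subset,
                                 k_timepoints = max(k_list))
  if (max(k_list) > fm_full$k)
    stop("k_list exceeds the available number of time points")
  rows <- lapply(k_list, function(k) {
    fm <- fm_first_k(fm_full, k)
    sp <- split_cohort(fm, train_frac = train_frac, seed = seed)
    bundle <- train_models(sp$train, seed = seed, ...)
    auc <- evaluate_bundle(bundle, sp$validation)$summary$auc
    data.frame(k = k, naive_bayes = auc[1], random_forest = auc[2],
               voting = auc[3], logistic = auc[4])
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  out
}

#' Random-Forest feature importance
#'
#' Impurity-based (mean decrease in Gini) importances of the fitted forest,
#' normalized to sum to one; ties are broken by column order.
#'
#' @param bundle A `model_bundle`.
#' @return Data frame `feature`, `importance`, `rank`, sorted by rank.
#' @export
feature_importance <- function(bundle) {
  imp <- randomForest::importance(bundle$rf)[, 1]
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  ord <- order(-imp)  # stable: ties keep column order
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             rank = seq_along(imp))
}
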