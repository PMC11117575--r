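#' Confusion matrix
#'
#' @param tp,fp,tn,fn Non-negative integer counts; total >= 1.
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (any(counts != round(counts))) stop("confusion counts must be integers")
  if (sum(counts) < 1) stop("confusion matrix is empty")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              actual = c("positive", "negative")))
  print(t(m))
  invisible(x)
}

#' Metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, `F1 = 2 * precision * recall / (precision + recall)`,
#' sensitivity (= recall) and specificity `TN/(TN+FP)`. A metric whose
#' denominator is zero is reported as `NA` rather than propagated as NaN.
#'
#' @param cm A [confusion_matrix()].
#' @return Named list of the six fractions.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- frac(cm$tp, cm$tp + cm$fp)
  recall <- frac(cm$tp, cm$tp + cm$fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(accuracy = frac(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn),
       precision = precision, recall = recall, f1 = f1,
       sensitivity = recall,
       specificity = frac(cm$tn, cm$tn + cm$fp))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.845 -> 0.85), the convention of
#' most clinical tables, unlike R's round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' ROC curve, AUC and Youden-optimal cut-off
#'
#' Threshold sweep over the unique scores (trapezoidal AUC, ties
#' contributing half), computed with \pkg{pROC}. The orientation is chosen
#' so that AUC >= 0.5 and reported in `direction` (`"<"` means larger
#' scores indicate the positive class). The optimal cut-off maximizes the
#' Youden index J = sensitivity + specificity - 1.
#'
#' @param scores Continuous scores.
#' @param labels Binary labels: logical, 0/1, or a 2-level factor whose
#'   last level is the positive class.
#' @param auto_orient If `TRUE` (the default, appropriate when scoring a
#'   raw parameter whose polarity is unknown) the direction is chosen so
#'   that AUC >= 0.5. Classifier evaluation fixes the direction instead
#'   (`FALSE`): higher score means positive class, and a model below
#'   chance reports AUC < 0.5.
#' @return List: `points` (threshold, sensitivity, specificity),
#'   `auc`, `optimal_cutoff`, `youden`, `direction`.
#' @export
roc_auc <- function(scores, labels, auto_orient = TRUE) {
  if (is.factor(labels)) labels <- labels == levels(labels)[nlevels(labels)]
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  direction <- "<"
  if (auto_orient && as.numeric(r$auc) < 0.5) {
    r <- pROC::roc(response = labels, predictor = scores,
                   levels = c(0, 1), direction = ">", quiet = TRUE)
    direction <- ">"
  }
  pts <- data.frame(threshold = r$thresholds,
                    sensitivity = r$sensitivities,
                    specificity = r$specificities)
  j <- pts$sensitivity + pts$specificity - 1
  best <- which.max(j)
  list(points = pts, auc = as.numeric(r$auc),
       optimal_cutoff = pts$threshold[best], youden = j[best],
       direction = direction)
}

#' Enumerate confusion matrices consistent with rounded printed metrics
#'
#' Brute-force oracle for published performance tables: finds every integer
#' `(TP, FP, TN, FN)` summing to `total` whose metrics round (half away
#' from zero, `digits` places) to the supplied values. An empty result
#' means the printed row is internally inconsistent.
#'
#' @param total Total count (<= 10000; the recall/precision constraints
#'   prune the search, so unconstrained enumeration is refused above 500).
#' @param precision,recall,specificity,f1,accuracy Rounded published
#'   values (any subset; `accuracy` on the 0-1 scale).
#' @param digits Decimals of the published values.
#' @return Data frame with columns `tp`, `fp`, `tn`, `fn` (0 rows if
#'   inconsistent).
#' @export
reconstruct_confusion <- function(total, precision = NULL, recall = NULL,
                                  specificity = NULL, f1 = NULL,
                                  accuracy = NULL, digits = 2) {
  stopifnot(total >= 1, total <= 1e4)
  if (total > 500 && is.null(recall) && is.null(precision))
    stop("unconstrained enumeration refused for total > 500")
  matches <- function(value, target)
    is.null(target) || (!is.na(value) &&
                          round_half_up(value, digits) ==
                          round_half_up(target, digits))
  hits <- list()
  for (tp in 0:total) {
    for (fn in 0:(total - tp)) {
      rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      if (!matches(rec, recall)) next
      for (fp in 0:(total - tp - fn)) {
        tn <- total - tp - fn - fp
        prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
        if (!matches(prec, precision)) next
        spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
        if (!matches(spec, specificity)) next
        acc <- (tp + tn) / total
        if (!matches(acc, accuracy)) next
        fv <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
          2 * prec * rec / (prec + rec) else NA_real_
        if (!matches(fv, f1)) next
        hits[[length(hits) + 1]] <- c(tp = tp, fp = fp, tn = tn, fn = fn)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(tp = integer(), fp = integer(),
                      tn = integer(), fn = integer()))
  as.data.frame(do.call(rbind, hits))
}

#' Pooled two-sample t test from summary statistics
#'
#' Student's t with pooled variance,
#' `t = (m1 - m2) / sqrt(sp^2 (1/n1 + 1/n2))`, two-sided p-value on
#' `n1 + n2 - 2` degrees of freedom -- the form that reproduces published
#' group-comparison tables computed from means and SDs.
#'
#' @param mean1,sd1,n1 First group summary (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 Second group summary.
#' @return List `t`, `df`, `p`.
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    t <- if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf
  } else {
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson X^2; the convention
#' that matches published demographic tables here.
#'
#' @param a,b First row counts.
#' @param c,d Second row counts.
#' @return List `x2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, c, b, d), 2, 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all marginals must be positive")
  res <- stats::chisq.test(m, correct = FALSE)
  list(x2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
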