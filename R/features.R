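#' Reduce kinematic field histories to the eight evolution curves
#'
#' Per frame, over the valid grid points, takes the maximum and the average
#' of the magnitudes of the vertical displacement V, engineering shear
#' gamma_xy, vertical velocity VR and shear strain rate gamma_xyR, giving
#' eight scalar time series: `max_V`, `max_gxy`, `max_VR`, `max_gxyR`,
#' `ave_V`, `ave_gxy`, `ave_VR`, `ave_gxyR`. Magnitudes (`|Q|`) are used
#' because the sign of V is a pure orientation convention and signed maxima
#' are dominated by noise polarity; set `signed = TRUE` for raw signed
#' statistics. Invalid points are excluded, not in-filled.
#'
#' @param V,gxy,VR,gxyR `T x N` matrices (e.g. from a `dic_field`,
#'   `strain_field`, `rate_field`, or [evaluate_truth()]).
#' @param valid Optional `T x N` logical mask; default all valid.
#' @param exam_id Identifier attached to the curves.
#' @param signed Use signed values instead of magnitudes.
#' @return An `evolution_curves` data frame with columns `frame` (0-based)
#'   and the eight curves.
#' @export
extract_evolution_curves <- function(V, gxy, VR, gxyR, valid = NULL,
                                     exam_id = "", signed = FALSE) {
  stopifnot(is.matrix(V), all(dim(gxy) == dim(V)), all(dim(VR) == dim(V)),
            all(dim(gxyR) == dim(V)))
  T_ <- nrow(V); N <- ncol(V)
  if (is.null(valid)) valid <- matrix(TRUE, T_, N)
  if (any(rowSums(valid) == 0))
    stop("a frame has zero valid grid points")
  stat <- function(m, fun) {
    vapply(seq_len(T_), function(t) {
      q <- m[t, valid[t, ]]
      q <- q[is.finite(q)]  # rates at freshly invalidated points are NA
      if (length(q) == 0) stop("a frame has zero valid grid points")
      if (!signed) q <- abs(q)
      fun(q)
    }, 0.0)
  }
  out <- data.frame(frame = seq_len(T_) - 1L,
                    max_V = stat(V, max), max_gxy = stat(gxy, max),
                    max_VR = stat(VR, max), max_gxyR = stat(gxyR, max),
                    ave_V = stat(V, mean), ave_gxy = stat(gxy, mean),
                    ave_VR = stat(VR, mean), ave_gxyR = stat(gxyR, mean))
  attr(out, "exam_id") <- exam_id
  class(out) <- c("evolution_curves", "data.frame")
  out
}

#' Evolution curves from a tracked exam
#'
#' Convenience chain: strains by pointwise least squares, rates by finite
#' differences, then [extract_evolution_curves()] on the intersection of
#' the displacement and strain validity masks.
#'
#' @param field A `dic_field`.
#' @param window_radius Passed to [pointwise_ls_strain()].
#' @return An `evolution_curves` data frame.
#' @export
curves_from_field <- function(field, window_radius = 2 * field$grid$step) {
  strain <- pointwise_ls_strain(field, window_radius)
  rates <- compute_rates(field, strain)
  both <- field$valid & strain$valid
  extract_evolution_curves(field$V, strain$gxy, rates$VR, rates$gxyR,
                           valid = both, exam_id = field$exam_id)
}

curve_names <- c("max_V", "max_gxy", "max_VR", "max_gxyR",
                 "ave_V", "ave_gxy", "ave_VR", "ave_gxyR")

#' Assemble the cohort feature matrix
#'
#' Flattens per-exam evolution curves into one row per exam: for each
#' selected curve, the first `k_timepoints` frames become columns named
#' `curve@frame` (0-based frame index), curve-major, in deterministic
#' order. The default keeps the four ave- curves over all frames (with
#' `T = 140` that is 560 features), the culling that proved more robust
#' than including the noisier max- statistics.
#'
#' @param cohort A `cohort` (fast mode) or any list of elements with
#'   `$curves` (an [extract_evolution_curves()] frame) and `$label`.
#' @param curve_subset Curve names to keep.
#' @param k_timepoints Number of leading frames per curve; default all.
#' @return A `feature_matrix`: list with `x` (numeric matrix), `labels`
#'   (factor, levels `normal < ffkc`), `exam_ids`, `curve_subset`, `k`.
#' @export
assemble_feature_matrix <- function(cohort,
                                    curve_subset = c("ave_V", "ave_gxy",
                                                     "ave_VR", "ave_gxyR"),
                                    k_timepoints = NULL) {
  if (!all(curve_subset %in% curve_names))
    stop("unknown curve name(s): ",
         paste(setdiff(curve_subset, curve_names), collapse = ", "))
  Ts <- vapply(cohort, function(e) nrow(e$curves), 0L)
  if (length(unique(Ts)) != 1)
    stop("exams have mismatched frame counts")
  T_ <- Ts[1]
  if (is.null(k_timepoints)) k_timepoints <- T_
  stopifnot(k_timepoints >= 1, k_timepoints <= T_)
  x <- t(vapply(cohort, function(e) {
    unlist(lapply(curve_subset,
                  function(nm) e$curves[[nm]][seq_len(k_timepoints)]),
           use.names = FALSE)
  }, numeric(length(curve_subset) * k_timepoints)))
  colnames(x) <- unlist(lapply(curve_subset, function(nm)
    paste0(nm, "@", seq_len(k_timepoints) - 1L)))
  if (anyNA(x)) stop("feature matrix contains missing values")
  labels <- factor(vapply(cohort, `[[`, "", "label"),
                   levels = c("normal", "ffkc"))
  ids <- vapply(seq_along(cohort), function(k) {
    id <- attr(cohort[[k]]$curves, "exam_id")
    if (is.null(id) || id == "") sprintf("exam-%03d", k) else id
  }, "")
  structure(list(x = x, labels = labels, exam_ids = ids,
                 curve_subset = curve_subset, k = k_timepoints),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "feature_matrix: %d exams x %d features (%s; first %d frames)\n",
    nrow(x$x), ncol(x$x), paste(x$curve_subset, collapse = ", "), x$k))
  print(table(x$labels))
  invisible(x)
}

# keep only the first k frames of every curve (column names are
# "curve@frame" with 0-based frames, curve-major order preserved)
fm_first_k <- function(fm, k) {
  stopifnot(k >= 1, k <= fm$k)
  frame_of <- as.integer(sub(".*@", "", colnames(fm$x)))
  keep <- frame_of < k
  structure(list(x = fm$x[, keep, drop = FALSE], labels = fm$labels,
                 exam_ids = fm$exam_ids, curve_subset = fm$curve_subset,
                 k = as.integer(k)),
            class = "feature_matrix")
}

# row subset preserving structure
subset_fm <- function(fm, idx) {
  structure(list(x = fm$x[idx, , drop = FALSE], labels = fm$labels[idx],
                 exam_ids = fm$exam_ids[idx],
                 curve_subset = fm$curve_subset, k = fm$k),
            class = "feature_matrix")
}
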