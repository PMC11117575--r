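#' Cauchy strains by pointwise least squares
#'
#' For every grid point and frame, fits the local planes
#' `u = a0 + a1 x + a2 y` and `v = b0 + b1 x + b2 y` by ordinary least
#' squares over the valid neighbours within `window_radius`, and reads the
#' strain components off the slopes: `epsilon_xx = a1`, `epsilon_yy = b2`
#' and the engineering shear `gamma_xy = a2 + b1` (set
#' `engineering = FALSE` for the tensor half-shear). The plane fit
#' interpolates affine fields exactly and is invariant to adding a constant
#' to U or V. Points with fewer than 6 valid neighbours, or a collinear
#' (rank-deficient) neighbourhood, are marked invalid for that frame.
#'
#' @param field A `dic_field` from [track_incremental()] (any list with
#'   `U`, `V`, `valid` matrices and a `grid` works).
#' @param window_radius Neighbourhood radius in px; default two grid steps
#'   (about a 5 x 5 point stencil).
#' @param engineering If `TRUE` (default) `gxy` is the engineering shear
#'   `du/dy + dv/dx`, the usual DIC convention; otherwise half of it.
#' @return A `strain_field`: matrices `exx`, `eyy`, `gxy` (`T x N`),
#'   logical `valid`, plus window metadata.
#' @export
pointwise_ls_strain <- function(field, window_radius = 2 * field$grid$step,
                                engineering = TRUE) {
  grid <- field$grid
  N <- length(grid$x)
  T_ <- nrow(field$U)
  exx <- eyy <- gxy <- matrix(NA_real_, T_, N)
  sval <- matrix(FALSE, T_, N)
  nb <- lapply(seq_len(N), function(k) {
    which((grid$x - grid$x[k])^2 + (grid$y - grid$y[k])^2 <=
            window_radius^2)  # includes the point itself
  })
  for (k in seq_len(N)) {
    idx <- nb[[k]]
    # group frames by the validity pattern of the neighbourhood so the
    # normal-equation inverse is factored once per pattern
    pat <- apply(field$valid[, idx, drop = FALSE], 1, paste, collapse = "")
    for (p in unique(pat)) {
      frames <- which(pat == p)
      use <- idx[field$valid[frames[1], idx]]
      if (length(use) < 6) next
      dx <- grid$x[use] - grid$x[k]
      dy <- grid$y[use] - grid$y[k]
      A <- cbind(1, dx, dy)
      qrA <- qr(A)
      if (qrA$rank < 3) next  # collinear neighbourhood
      cu <- qr.coef(qrA, t(field$U[frames, use, drop = FALSE]))
      cv <- qr.coef(qrA, t(field$V[frames, use, drop = FALSE]))
      exx[frames, k] <- cu[2, ]
      eyy[frames, k] <- cv[3, ]
      gxy[frames, k] <- cu[3, ] + cv[2, ]
      sval[frames, k] <- TRUE
    }
  }
  if (!engineering) gxy <- gxy / 2
  structure(list(exx = exx, eyy = eyy, gxy = gxy, valid = sval,
                 window_radius = window_radius, engineering = engineering,
                 grid = grid, frame_interval = field$frame_interval,
                 exam_id = field$exam_id),
            class = "strain_field")
}

#' Temporal rate of a per-point time series
#'
#' Finite differences along time: central `(f[t+1] - f[t-1]) / (2 dt)` at
#' interior frames, one-sided at the two ends. Exact for series linear in
#' time, including the endpoints, and linear as an operator.
#'
#' @param series Numeric vector (length `T`) or `T x N` matrix, one column
#'   per point.
#' @param frame_interval Frame spacing (ms, > 0).
#' @return Object of the same shape, in units of `series` per ms, with a
#'   `scheme` attribute (`"forward"`, `"central"` ..., `"backward"`).
#' @export
temporal_rate <- function(series, frame_interval) {
  if (frame_interval <= 0) stop("frame_interval must be positive")
  m <- if (is.matrix(series)) series else matrix(series, ncol = 1)
  T_ <- nrow(m)
  if (T_ < 2) stop("need at least two frames")
  out <- m
  out[1, ] <- (m[2, ] - m[1, ]) / frame_interval
  out[T_, ] <- (m[T_, ] - m[T_ - 1, ]) / frame_interval
  if (T_ > 2)
    out[2:(T_ - 1), ] <- (m[3:T_, , drop = FALSE] -
                            m[1:(T_ - 2), , drop = FALSE]) /
      (2 * frame_interval)
  if (!is.matrix(series)) out <- drop(out)
  attr(out, "scheme") <- c("forward", rep("central", max(T_ - 2, 0)),
                           "backward")
  out
}

#' Velocity and strain-rate fields
#'
#' Applies [temporal_rate()] to the displacement components (giving UR, VR
#' in px/ms, or mm/ms when the sequence carries a scale) and to each strain
#' component (giving rates in 1/ms).
#'
#' @param field A `dic_field`.
#' @param strain A `strain_field` from [pointwise_ls_strain()].
#' @return A `rate_field` with matrices `UR`, `VR`, `exxR`, `eyyR`, `gxyR`
#'   and the validity masks of their sources.
#' @export
compute_rates <- function(field, strain) {
  dt <- field$frame_interval
  sc <- if (is.null(field$scale)) 1 else field$scale
  structure(list(UR = temporal_rate(field$U, dt) * sc,
                 VR = temporal_rate(field$V, dt) * sc,
                 exxR = temporal_rate(strain$exx, dt),
                 eyyR = temporal_rate(strain$eyy, dt),
                 gxyR = temporal_rate(strain$gxy, dt),
                 valid_disp = field$valid, valid_strain = strain$valid,
                 frame_interval = dt, exam_id = field$exam_id),
            class = "rate_field")
}

#' Remove whole-eye rigid motion from a displacement field
#'
#' Estimates, for every frame, the best-fit uniform translation from a
#' peripheral band of grid points -- the outermost `peripheral_frac` of
#' points by `|x - apex_x|`, where the deformation bump has decayed -- and
#' subtracts it from all points. Off by default in the pipeline; apply it
#' when the exam shows whole-eye drift.
#'
#' @param field A `dic_field`.
#' @param peripheral_frac Fraction of points (by distance from the apex)
#'   used to estimate the translation; at least 3 points are required.
#' @param apex_x Apex column; defaults to the midpoint of the grid x-range.
#' @return A `dic_field` copy with the translation removed and an attribute
#'   `rigid_compensated = TRUE`.
#' @export
compensate_rigid_motion <- function(field, peripheral_frac = 0.1,
                                    apex_x = NULL) {
  grid <- field$grid
  if (is.null(apex_x)) apex_x <- (min(grid$x) + max(grid$x)) / 2
  N <- length(grid$x)
  n_per <- max(3, ceiling(peripheral_frac * N))
  ord <- order(-abs(grid$x - apex_x), seq_len(N))  # deterministic ties
  periph <- ord[seq_len(n_per)]
  out <- field
  for (t in seq_len(nrow(field$U))) {
    use <- periph[field$valid[t, periph]]
    if (length(use) < 3)
      stop(sprintf("peripheral band empty at frame %d", t - 1))
    out$U[t, ] <- field$U[t, ] - mean(field$U[t, use])
    out$V[t, ] <- field$V[t, ] - mean(field$V[t, use])
  }
  out$dU <- rbind(out$U[1, , drop = FALSE], diff(out$U))
  out$dV <- rbind(out$V[1, , drop = FALSE], diff(out$V))
  attr(out, "rigid_compensated") <- TRUE
  out
}
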