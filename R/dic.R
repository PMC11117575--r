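#' Ordered grayscale image sequence
#'
#' Container for an air-puff exam: `T >= 2` frames of identical shape with a
#' frame interval in milliseconds and an optional spatial scale.
#'
#' @param frames List of numeric matrices (gray values in `[0, 255]`).
#' @param frame_interval Frame spacing, ms.
#' @param scale Optional mm/px.
#' @param exam_id Identifier string.
#' @return An `image_sequence` object.
#' @export
image_sequence <- function(frames, frame_interval = 30 / 139, scale = NULL,
                           exam_id = "") {
  stopifnot(is.list(frames), length(frames) >= 2, frame_interval > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same shape")
  if (!all(vapply(frames, function(f) all(is.finite(f)), TRUE)))
    stop("frame intensities must be finite")
  structure(list(frames = frames, frame_interval = frame_interval,
                 scale = scale, exam_id = exam_id),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_sequence '%s': %d frames of %dx%d px @ %.4f ms\n",
              x$exam_id, length(x$frames), d[1], d[2], x$frame_interval))
  invisible(x)
}

#' Segment the corneal band in a reference frame
#'
#' Default region-of-interest extraction: Otsu threshold on the frame,
#' largest connected component, morphological closing with a disc brush.
#' Intended for bright-band-on-dark-background cross-sections; supply your
#' own mask to [build_grid()] when the heuristic fails.
#'
#' @param frame Numeric matrix, gray values in `[0, 255]`.
#' @param closing_radius Disc radius (px) of the closing brush.
#' @return Logical matrix of the same shape.
#' @export
corneal_roi <- function(frame, closing_radius = 5) {
  img <- EBImage::Image(frame / 255)
  th <- EBImage::otsu(img)
  mask <- EBImage::Image(frame / 255 > th)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(tab) == 0) stop("no foreground found in reference frame")
  keep <- which.max(tab)
  mask <- EBImage::Image(EBImage::imageData(lab) == keep)
  brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
  out <- EBImage::imageData(EBImage::closing(mask, brush))
  matrix(as.logical(out), nrow(frame), ncol(frame))
}

# summed-area table lookup: number of TRUE mask pixels in the window
# rows [r0, r1], cols [c0, c1] (1-based, inclusive)
window_sums <- function(sat, r0, r1, c0, c1) {
  sat[cbind(r1 + 1, c1 + 1)] - sat[cbind(r0, c1 + 1)] -
    sat[cbind(r1 + 1, c0)] + sat[cbind(r0, c0)]
}

#' Build the DIC measurement grid
#'
#' Regular lattice of spacing `step` restricted to points that lie inside
#' the mask and whose full correlation subset fits both inside the image
#' interior (one-pixel interpolation margin) and inside the mask dilated by
#' `dilate_px`. Ordering is row-major and deterministic. Coordinates are
#' 0-based pixels (x = column, y = row).
#'
#' @param mask Logical matrix marking the corneal band.
#' @param step Lattice spacing, px.
#' @param subset_size Subset edge length, px; odd, >= 11.
#' @param dilate_px Mask dilation half-width applied before the
#'   subset-containment test.
#' @return A `dic_grid` object with fields `x`, `y`, `step`, `subset_size`.
#' @export
build_grid <- function(mask, step = 8, subset_size = 25, dilate_px = 2) {
  stopifnot(is.matrix(mask), subset_size %% 2 == 1, subset_size >= 11,
            step >= 1)
  if (!any(mask)) stop("mask is empty")
  half <- (subset_size - 1) %/% 2
  h <- nrow(mask); w <- ncol(mask)
  dm <- if (dilate_px > 0) {
    brush <- EBImage::makeBrush(2 * dilate_px + 1, shape = "box")
    matrix(as.logical(EBImage::imageData(
      EBImage::dilate(EBImage::Image(mask), brush))), h, w)
  } else mask
  sat <- matrix(0, h + 1, w + 1)
  cs <- apply(dm * 1, 2, cumsum)            # cumulative over rows
  sat[-1, -1] <- t(apply(cs, 1, cumsum))    # then over columns

  xs <- seq(half + 1, w - half - 2, by = step)  # 0-based columns
  ys <- seq(half + 1, h - half - 2, by = step)  # 0-based rows
  if (length(xs) == 0 || length(ys) == 0) stop("empty measurement grid")
  gx <- rep(xs, times = length(ys))  # row-major ordering
  gy <- rep(ys, each = length(xs))
  inside <- mask[cbind(gy + 1, gx + 1)]
  full <- window_sums(sat, gy + 1 - half, gy + 1 + half,
                      gx + 1 - half, gx + 1 + half) == subset_size^2
  keep <- inside & full
  if (!any(keep)) stop("empty measurement grid")
  structure(list(x = gx[keep], y = gy[keep], step = step,
                 subset_size = subset_size),
            class = "dic_grid")
}

#' @export
print.dic_grid <- function(x, ...) {
  cat(sprintf("dic_grid: %d points, step %d px, subset %d px\n",
              length(x$x), x$step, x$subset_size))
  invisible(x)
}

#' Match one subset between two frames
#'
#' Finds the in-plane translation of a square subset centred at `point`
#' (frame-`ref` coordinates, possibly subpixel) that minimizes the
#' zero-normalized sum of squared differences (ZNSSD) against `cur`:
#' exhaustive integer search of `search_radius` px around `init_guess`,
#' then translation-only Gauss-Newton refinement on a cubic B-spline
#' interpolant
#' (paraboloid fit of the 3x3 correlation surface as fallback). Quality is
#' the ZNCC at the optimum; ZNSSD/ZNCC make the match invariant to affine
#' intensity changes.
#'
#' @param ref_frame,cur_frame Numeric matrices.
#' @param point Length-2 numeric `(x, y)`, 0-based px.
#' @param init_guess Length-2 numeric displacement guess, px.
#' @param subset_size Odd subset edge, px.
#' @param search_radius Integer search half-width, px.
#' @param max_iter,tol Gauss-Newton iteration cap and step tolerance (px).
#' @return `list(du, dv, quality, flag)`; `flag` is `"ok"`,
#'   `"border"` (optimum on the search border: low confidence),
#'   `"invalid"` (flat or out-of-bounds subset) or `"paraboloid"`.
#' @export
match_subset <- function(ref_frame, cur_frame, point, init_guess = c(0, 0),
                         subset_size = 25, search_radius = 6,
                         max_iter = 20, tol = 1e-4) {
  stopifnot(subset_size %% 2 == 1)
  half <- (subset_size - 1) %/% 2
  r <- cpp_match_subset(cpp_bspline_coef(ref_frame), cur_frame,
                        cpp_bspline_coef(cur_frame),
                        point[1], point[2], half,
                        search_radius, init_guess[1], init_guess[2],
                        max_iter, tol)
  list(du = r[1], dv = r[2], quality = r[3],
       flag = c("ok", "border", "invalid", "paraboloid")[r[4] + 1])
}

#' Track a sequence by incremental DIC
#'
#' Frame-to-frame matching with accumulated totals: for each consecutive
#' pair `(t-1, t)` every grid point is matched with its previous increment
#' as the initial guess, the reference subset being re-extracted from frame
#' `t-1` at the integer pixel nearest the point's accumulated position --
#' incremental referencing with a translation-only shape function per
#' increment, the core assumption being that per-frame deformation is
#' small. Anchoring the reference on the pixel grid avoids resampling it,
#' so interpolation-phase bias cannot build up over the sequence; the
#' sub-pixel anchor offset (at most half a pixel) is compensated to first
#' order using a local plane fit of the increment field over neighbouring
#' grid points. Accumulated U, V are running sums of the corrected
#' increments. Points whose ZNCC
#' quality drops below `quality_threshold` (or whose match is flagged) are
#' marked invalid from that frame onward; their increments are in-filled
#' with the median increment of valid neighbours within ~one grid step
#' (recorded in `filled`, never silently).
#'
#' @param sequence An [image_sequence()].
#' @param grid A [build_grid()] result.
#' @param search_radius,quality_threshold,max_iter,tol Matching controls.
#' @return A `dic_field`: matrices `U`, `V`, `dU`, `dV`, `quality` (`T x N`),
#'   logical `valid` and `filled`, plus the grid and frame interval.
#' @export
track_incremental <- function(sequence, grid, search_radius = 6,
                              quality_threshold = 0.8,
                              max_iter = 20, tol = 1e-4) {
  stopifnot(inherits(sequence, "image_sequence"), inherits(grid, "dic_grid"))
  frames <- sequence$frames
  T_ <- length(frames)
  N <- length(grid$x)
  half <- (grid$subset_size - 1) %/% 2
  U <- V <- dU <- dV <- Q <- matrix(0, T_, N)
  Q[1, ] <- 1
  valid <- matrix(TRUE, T_, N)
  filled <- matrix(FALSE, T_, N)
  alive <- rep(TRUE, N)
  prev_du <- prev_dv <- rep(0, N)
  nb <- lapply(seq_len(N), function(k) {
    which(abs(grid$x - grid$x[k]) <= grid$step &
            abs(grid$y - grid$y[k]) <= grid$step &
            seq_len(N) != k)
  })
  # neighbourhoods and pseudo-inverses for the anchor-offset correction
  # (local plane fit of the increment field, see below)
  nb2 <- lapply(seq_len(N), function(k) {
    which((grid$x - grid$x[k])^2 + (grid$y - grid$y[k])^2 <=
            (2 * grid$step)^2)
  })
  pinv <- lapply(seq_len(N), function(k) {
    A <- cbind(1, grid$x[nb2[[k]]] - grid$x[k],
               grid$y[nb2[[k]]] - grid$y[k])
    if (length(nb2[[k]]) >= 6 && qr(A)$rank == 3)
      solve(crossprod(A), t(A))
    else NULL
  })
  ref_coef <- cpp_bspline_coef(frames[[1]])
  for (t in 2:T_) {
    cur_coef <- cpp_bspline_coef(frames[[t]])
    du_t <- dv_t <- rep(NA_real_, N)
    ok <- rep(FALSE, N)
    # Reference subsets are anchored at the integer pixel nearest the
    # accumulated position: raw pixel values, no resampling, so coherent
    # interpolation-phase bias cannot build up over the sequence. The
    # measured increment belongs to the anchor, not to the tracked point
    # (offset <= 0.5 px); it is corrected to first order below using the
    # local plane fit of the increment field.
    px <- grid$x + U[t - 1, ]
    py <- grid$y + V[t - 1, ]
    ax <- round(px); ay <- round(py)
    if (any(alive)) {
      idx <- which(alive)
      res <- cpp_match_frame(ref_coef, frames[[t]], cur_coef,
                             ax[idx], ay[idx],
                             half, search_radius,
                             prev_du[idx], prev_dv[idx], max_iter, tol)
      good <- res[, 4] %in% c(0, 3) & !is.na(res[, 3]) &
        res[, 3] >= quality_threshold
      du_t[idx] <- res[, 1]
      dv_t[idx] <- res[, 2]
      Q[t, idx] <- res[, 3]
      ok[idx] <- good
    }
    # first-order anchor-offset correction of the increments
    if (any(ok)) {
      fx <- px - ax; fy <- py - ay
      du_c <- du_t; dv_c <- dv_t
      for (k in which(ok)) {
        nbk <- nb2[[k]]
        use <- ok[nbk]
        if (sum(use) < 6) next
        if (all(use) && !is.null(pinv[[k]])) {
          cu <- pinv[[k]] %*% du_t[nbk]
          cv <- pinv[[k]] %*% dv_t[nbk]
        } else {
          A <- cbind(1, grid$x[nbk[use]] - grid$x[k],
                     grid$y[nbk[use]] - grid$y[k])
          if (qr(A)$rank < 3) next
          cu <- qr.coef(qr(A), du_t[nbk[use]])
          cv <- qr.coef(qr(A), dv_t[nbk[use]])
        }
        du_c[k] <- du_t[k] + cu[2] * fx[k] + cu[3] * fy[k]
        dv_c[k] <- dv_t[k] + cv[2] * fx[k] + cv[3] * fy[k]
      }
      du_t <- du_c; dv_t <- dv_c
    }
    alive <- alive & ok
    if (sum(!alive) > 0.5 * N)
      stop(sprintf("tracking failed: >50%% of points invalid at frame %d",
                   t - 1))
    # in-fill increments of dead points from valid neighbours
    for (k in which(!alive)) {
      cand <- nb[[k]][ok[nb[[k]]]]
      if (length(cand) > 0) {
        du_t[k] <- median(du_t[cand])
        dv_t[k] <- median(dv_t[cand])
      } else {
        du_t[k] <- 0; dv_t[k] <- 0
      }
      filled[t, k] <- TRUE
    }
    valid[t, ] <- alive
    dU[t, ] <- du_t; dV[t, ] <- dv_t
    U[t, ] <- U[t - 1, ] + du_t
    V[t, ] <- V[t - 1, ] + dv_t
    prev_du <- ifelse(is.na(du_t), 0, du_t)
    prev_dv <- ifelse(is.na(dv_t), 0, dv_t)
    ref_coef <- cur_coef
  }
  structure(list(U = U, V = V, dU = dU, dV = dV, quality = Q,
                 valid = valid, filled = filled, grid = grid,
                 frame_interval = sequence$frame_interval,
                 scale = sequence$scale, exam_id = sequence$exam_id),
            class = "dic_field")
}

#' @export
print.dic_field <- function(x, ...) {
  cat(sprintf(
    "dic_field '%s': %d frames x %d points; %.1f%% valid at last frame\n",
    x$exam_id, nrow(x$U), ncol(x$U),
    100 * mean(x$valid[nrow(x$valid), ])))
  invisible(x)
}
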