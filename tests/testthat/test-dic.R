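test_that("grid construction restricts the lattice to admissible sites", {
  full <- matrix(TRUE, 100, 100)
  g <- build_grid(full, step = 10, subset_size = 21)
  half <- 10
  expect_true(all(g$x - half >= 1 & g$x + half <= 97))
  expect_true(all(g$y - half >= 1 & g$y + half <= 97))

  thin <- matrix(FALSE, 100, 100)
  thin[45:52, ] <- TRUE  # thinner than the subset
  expect_error(build_grid(thin, step = 8, subset_size = 21, dilate_px = 0),
               "empty measurement grid")

  # brute-force recount on a synthetic band mask
  cfg <- small_cfg()
  mask <- band_mask(cfg)
  g2 <- build_grid(mask, step = 8, subset_size = 25, dilate_px = 2)
  dm <- matrix(as.logical(EBImage::imageData(EBImage::dilate(
    EBImage::Image(mask), EBImage::makeBrush(5, "box")))),
    nrow(mask), ncol(mask))
  half <- 12
  count <- 0
  for (y in seq(half + 1, nrow(mask) - half - 2, by = 8))
    for (x in seq(half + 1, ncol(mask) - half - 2, by = 8))
      if (mask[y + 1, x + 1] &&
          all(dm[(y - half):(y + half) + 1, (x - half):(x + half) + 1]))
        count <- count + 1
  expect_equal(length(g2$x), count)
})

test_that("subset matching recovers identity and integer shifts exactly", {
  f0 <- small_static()$sequence$frames[[1]]
  m <- match_subset(f0, f0, c(144, 30))
  expect_equal(m$du, 0)
  expect_equal(m$dv, 0)
  expect_equal(m$quality, 1, tolerance = 1e-12)
  expect_equal(m$flag, "ok")

  h <- nrow(f0); w <- ncol(f0)
  fs <- matrix(0, h, w)
  fs[3:h, 4:w] <- f0[1:(h - 2), 1:(w - 3)]  # shift by (3, 2)
  m2 <- match_subset(f0, fs, c(144, 30))
  expect_equal(m2$du, 3, tolerance = 1e-8)
  expect_equal(m2$dv, 2, tolerance = 1e-8)
  expect_gt(m2$quality, 0.999)
})

test_that("subpixel shifts are recovered within 0.02 px", {
  f0 <- small_static()$sequence$frames[[1]]
  h <- nrow(f0); w <- ncol(f0)
  co <- airDIC:::cpp_bspline_coef(f0)
  xs <- rep(seq(0, w - 1), each = h) - 0.50
  ys <- rep(seq(0, h - 1), w) + 0.25
  fs <- matrix(airDIC:::cpp_interp_coef(co, xs, ys), h, w)
  m <- match_subset(f0, fs, c(144, 30))
  expect_lt(abs(m$du - 0.50), 0.02)
  expect_lt(abs(m$dv + 0.25), 0.02)
})

test_that("flat subsets are flagged invalid, not thrown", {
  flat <- matrix(128, 64, 64)
  m <- match_subset(flat, flat, c(31, 31))
  expect_equal(m$flag, "invalid")
  expect_true(is.na(m$du))
})

test_that("a static sequence tracks to a zero field with high quality", {
  rs <- small_static()
  grid <- build_grid(corneal_roi(rs$sequence$frames[[1]]), 8, 21)
  fld <- track_incremental(rs$sequence, grid)
  expect_equal(max(abs(fld$U)), 0, tolerance = 1e-8)
  expect_equal(max(abs(fld$V)), 0, tolerance = 1e-8)
  expect_true(all(fld$quality > 0.999))
  expect_true(all(fld$valid))
  # frame-0 zero field and increment-sum identity
  expect_true(all(fld$U[1, ] == 0 & fld$V[1, ] == 0))
  expect_equal(fld$U, apply(fld$dU, 2, cumsum), tolerance = 1e-12)
})

test_that("tracking is equivariant under integer frame translation", {
  cfg <- small_cfg(amplitude_peak = 3, n_frames = 10, peak_frame = 5)
  rs <- render_sequence(cfg)
  grid <- build_grid(band_mask(cfg), 12, 21)
  fld <- track_incremental(rs$sequence, grid)
  # shift every frame down/right by (2, 1) px
  sh <- lapply(rs$sequence$frames, function(f) {
    g <- matrix(20, nrow(f), ncol(f))
    g[2:nrow(f), 3:ncol(f)] <- f[1:(nrow(f) - 1), 1:(ncol(f) - 3 + 1)]
    g
  })
  seq2 <- image_sequence(sh, rs$sequence$frame_interval)
  grid2 <- grid
  grid2$x <- grid$x + 2
  grid2$y <- grid$y + 1
  fld2 <- track_incremental(seq2, grid2)
  keep <- fld$valid & fld2$valid
  expect_lt(max(abs((fld2$U - fld$U)[keep])), 1e-6)
  expect_lt(max(abs((fld2$V - fld$V)[keep])), 1e-6)
})

test_that("matching is invariant to affine intensity rescaling", {
  cfg <- small_cfg(amplitude_peak = 3, n_frames = 4, peak_frame = 2)
  rs <- render_sequence(cfg)
  f1 <- rs$sequence$frames[[1]]
  f2 <- rs$sequence$frames[[3]]
  m <- match_subset(f1, f2, c(144, 30))
  m2 <- match_subset(1.7 * f1 + 11, 1.7 * f2 + 11, c(144, 30))
  expect_equal(m2$du, m$du, tolerance = 1e-9)
  expect_equal(m2$dv, m$dv, tolerance = 1e-9)
  expect_equal(m2$quality, m$quality, tolerance = 1e-9)
})

test_that("accumulated drift error grows sublinearly with frame count", {
  errs <- vapply(c(35, 70, 140), function(T_) {
    cfg <- sim_config(image_width = 288, image_height = 96, apex_row = 30,
                      curvature = 16 / 144^2, band_thickness = 34,
                      spatial_sigma = 40, amplitude_peak = 0, noise_sd = 0,
                      n_frames = T_, peak_frame = T_ %/% 2,
                      rigid_drift = c(0.08, 0.04), seed = 21)
    rs <- render_sequence(cfg)
    grid <- build_grid(band_mask(cfg), 12, 21)
    fld <- track_incremental(rs$sequence, grid)
    v <- fld$valid[T_, ]
    tru <- (T_ - 1) * cfg$rigid_drift
    sqrt(mean((fld$U[T_, v] - tru[1])^2 + (fld$V[T_, v] - tru[2])^2))
  }, 0.0)
  # quadrupling the frame count must not quadruple the error (absolute
  # floor covers the regime where both errors sit at the noise floor)
  expect_lt(errs[3], 4 * errs[1] + 0.02)
  expect_lt(errs[3], 0.24)  # random-walk bound at <= 0.02 px per increment
})

test_that("whole-eye drift is recovered to within the random-walk bound", {
  cfg <- small_cfg(amplitude_peak = 0, noise_sd = 0, n_frames = 70,
                   peak_frame = 35, rigid_drift = c(0.2, 0.1))
  rs <- render_sequence(cfg)
  grid <- build_grid(band_mask(cfg), 12, 21)
  fld <- track_incremental(rs$sequence, grid)
  v <- fld$valid[70, ]
  expect_lt(abs(mean(fld$U[70, v]) - 69 * 0.2), 0.24)
  expect_lt(abs(mean(fld$V[70, v]) - 69 * 0.1), 0.24)
})
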