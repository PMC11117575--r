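# build a dic_field-shaped object directly from closed-form displacements
synth_field <- function(grid, ufun, vfun, T_ = 5, frame_interval = 1) {
  U <- V <- matrix(0, T_, length(grid$x))
  for (t in seq_len(T_)) {
    U[t, ] <- ufun(grid$x, grid$y, t - 1)
    V[t, ] <- vfun(grid$x, grid$y, t - 1)
  }
  list(U = U, V = V, valid = matrix(TRUE, T_, length(grid$x)),
       grid = grid, frame_interval = frame_interval, exam_id = "synth",
       scale = NULL)
}

rect_grid <- function(nx = 9, ny = 5, step = 8) {
  structure(list(x = rep(seq(16, by = step, length.out = nx), times = ny),
                 y = rep(seq(16, by = step, length.out = ny), each = nx),
                 step = step, subset_size = 21),
            class = "dic_grid")
}

test_that("pointwise least squares is exact on affine displacement fields", {
  g <- rect_grid()
  fld <- synth_field(g, function(x, y, t) 0.01 * x, function(x, y, t) 0 * x)
  st <- pointwise_ls_strain(fld)
  expect_true(all(st$valid))
  expect_equal(max(abs(st$exx - 0.01)), 0, tolerance = 1e-12)
  expect_equal(max(abs(st$eyy)), 0, tolerance = 1e-12)
  expect_equal(max(abs(st$gxy)), 0, tolerance = 1e-12)

  # pure shear
  fld2 <- synth_field(g, function(x, y, t) 0.005 * y,
                      function(x, y, t) 0.005 * x)
  st2 <- pointwise_ls_strain(fld2)
  expect_equal(max(abs(st2$gxy - 0.01)), 0, tolerance = 1e-12)
  st2t <- pointwise_ls_strain(fld2, engineering = FALSE)
  expect_equal(max(abs(st2t$gxy - 0.005)), 0, tolerance = 1e-12)
})

test_that("strains are invariant to adding a constant displacement", {
  g <- rect_grid()
  f1 <- synth_field(g, function(x, y, t) 0.002 * x + 0.004 * y,
                    function(x, y, t) -0.003 * x)
  f2 <- f1
  f2$U <- f1$U + 7.7
  f2$V <- f1$V - 3.1
  s1 <- pointwise_ls_strain(f1)
  s2 <- pointwise_ls_strain(f2)
  expect_equal(s1$exx, s2$exx, tolerance = 1e-12)
  expect_equal(s1$gxy, s2$gxy, tolerance = 1e-12)
})

test_that("collinear neighbourhoods are marked invalid", {
  g <- structure(list(x = seq(16, by = 8, length.out = 12),
                      y = rep(40, 12), step = 8, subset_size = 21),
                 class = "dic_grid")  # a single row: no y information
  fld <- synth_field(g, function(x, y, t) 0.01 * x,
                     function(x, y, t) 0 * x)
  st <- pointwise_ls_strain(fld)
  expect_false(any(st$valid))
  expect_true(all(is.na(st$gxy)))
})

test_that("temporal rates are exact for linear series and match the
           hand finite-difference for t^2", {
  # linear: exact everywhere including endpoints
  f <- matrix(3.5 * (0:9), 10, 4)
  r <- temporal_rate(f, frame_interval = 1)
  expect_equal(max(abs(r - 3.5)), 0, tolerance = 1e-12)
  expect_equal(attr(r, "scheme")[c(1, 5, 10)],
               c("forward", "central", "backward"))
  # constant: zero
  expect_equal(max(abs(temporal_rate(matrix(2, 6, 3), 0.5))), 0)
  # quadratic with dt = 1: central 2t interior, 1 and 2T-3 at the ends
  T_ <- 8
  q <- (0:(T_ - 1))^2
  rq <- temporal_rate(q, 1)
  expect_equal(rq[1], 1)
  expect_equal(rq[T_], 2 * T_ - 3)
  expect_equal(rq[2:(T_ - 1)], 2 * (1:(T_ - 2)))
  expect_error(temporal_rate(q, 0), "positive")
})

test_that("the rate operator is linear", {
  withr::with_seed(2, {
    f <- matrix(rnorm(40), 8, 5)
    g <- matrix(rnorm(40), 8, 5)
  })
  r <- temporal_rate(3 * f - 2 * g, 0.25)
  expect_equal(as.vector(r),
               as.vector(3 * temporal_rate(f, 0.25) -
                           2 * temporal_rate(g, 0.25)),
               tolerance = 1e-12)
})

test_that("rigid-motion compensation removes pure drift and keeps zero
           fields zero", {
  g <- rect_grid(nx = 15)
  drift <- synth_field(g, function(x, y, t) 0.2 * t,
                       function(x, y, t) 0.1 * t, T_ = 10)
  out <- compensate_rigid_motion(drift)
  expect_lt(max(abs(out$U)), 1e-9)
  expect_lt(max(abs(out$V)), 1e-9)
  zero <- synth_field(g, function(x, y, t) 0 * x, function(x, y, t) 0 * x)
  z <- compensate_rigid_motion(zero)
  expect_equal(max(abs(z$V)), 0)
})

test_that("compensation leaves a drift-free puff almost untouched", {
  cfg <- small_cfg(amplitude_peak = 5)
  grid <- build_grid(band_mask(cfg), 8, 21)
  tr <- evaluate_truth(cfg, grid$x, grid$y)
  fld <- list(U = tr$U, V = tr$V,
              valid = matrix(TRUE, nrow(tr$V), ncol(tr$V)), grid = grid,
              frame_interval = cfg$frame_interval, exam_id = "t",
              scale = NULL)
  out <- compensate_rigid_motion(fld, apex_x = cfg$apex_x)
  # bound: twice the peripheral |V| magnitude
  n_per <- max(3, ceiling(0.1 * length(grid$x)))
  periph <- order(-abs(grid$x - cfg$apex_x))[seq_len(n_per)]
  bound <- 2 * max(abs(tr$V[, periph]))
  expect_lt(max(abs(out$V - fld$V)), bound + 1e-12)
})

test_that("tracked strains reproduce the closed-form shear within 5%", {
  fp <- full_puff_clean()
  st <- pointwise_ls_strain(fp$field)
  tr <- evaluate_truth(fp$truth, fp$grid$x, fp$grid$y)
  t_pk <- fp$cfg$peak_frame + 1
  v <- fp$field$valid[t_pk, ] & st$valid[t_pk, ]
  got <- max(abs(st$gxy[t_pk, v]))
  want <- max(abs(tr$gxy[t_pk, v]))
  expect_lt(abs(got - want) / want, 0.05)
})
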