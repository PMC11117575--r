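# Shared fixtures, built lazily once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# compact geometry used by most rendering tests
small_cfg <- function(...) {
  args <- list(image_width = 288, image_height = 96, n_frames = 36,
               apex_row = 30, curvature = 16 / 144^2, band_thickness = 34,
               spatial_sigma = 40, amplitude_peak = 5, peak_frame = 18,
               recovery_lag = 8, noise_sd = 0, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

small_static <- function() memo("small_static", {
  render_sequence(small_cfg(amplitude_peak = 0))
})

# the acceptance-scale exam: amplitude 8 px, sensor noise 2 gray levels,
# tracked at the default grid density
full_puff <- function() memo("full_puff", {
  cfg <- sim_config(amplitude_peak = 8, noise_sd = 2, seed = 3)
  rs <- render_sequence(cfg)
  grid <- build_grid(corneal_roi(rs$sequence$frames[[1]]), 8, 25)
  field <- track_incremental(rs$sequence, grid)
  list(cfg = cfg, truth = rs$truth, sequence = rs$sequence,
       grid = grid, field = field)
})

# same exam without sensor noise (strain-accuracy oracle)
full_puff_clean <- function() memo("full_puff_clean", {
  cfg <- sim_config(amplitude_peak = 8, noise_sd = 0, seed = 3)
  rs <- render_sequence(cfg)
  grid <- build_grid(corneal_roi(rs$sequence$frames[[1]]), 8, 25)
  field <- track_incremental(rs$sequence, grid)
  list(cfg = cfg, truth = rs$truth, grid = grid, field = field)
})

# small fast-mode cohort for feature/classifier plumbing tests
mini_cohort <- function() memo("mini_cohort", {
  generate_cohort(10, 10, seed = 99)
})

# two well-separated Gaussian blobs as a feature matrix
blob_fm <- function(n_per = 20, p = 10, shift = 3, seed = 7) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * p), n_per),
               matrix(rnorm(n_per * p, mean = shift), n_per))
    colnames(x) <- paste0("f@", seq_len(p) - 1)
    structure(list(x = x,
                   labels = factor(rep(c("normal", "ffkc"), each = n_per),
                                   levels = c("normal", "ffkc")),
                   exam_ids = sprintf("b%02d", seq_len(2 * n_per)),
                   curve_subset = "f", k = p),
              class = "feature_matrix")
  })
}

# brute-force Mann-Whitney concordance (ties count half), oriented so the
# result is >= 0.5 -- independent oracle for trapezoidal AUC
mw_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  conc <- 0
  for (p in pos)
    for (n in neg)
      conc <- conc + (p > n) + 0.5 * (p == n)
  c <- conc / (length(pos) * length(neg))
  max(c, 1 - c)
}
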