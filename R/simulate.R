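#' Simulation configuration for a synthetic air-puff corneal sequence
#'
#' Describes one synthetic exam: a bright, speckle-textured corneal band on a
#' dark background, deformed over time by an analytic inward-then-recovering
#' vertical pulse. The pulse amplitude at the apex rises as
#' `(t / peak_frame)^rise_power` up to `peak_frame` and then decays as
#' `exp(-(t - peak_frame) / recovery_lag)`; the spatial profile is a Gaussian
#' bump of width `spatial_sigma` centred at `apex_x`, optionally augmented by
#' a second, narrower bump (`local_weakening`) mimicking a focally weakened
#' region. An optional whole-eye rigid drift adds `rigid_drift * t` pixels to
#' every material point.
#'
#' The frame geometry defaults (576 x 200 px, 140 frames over ~30 ms) are a
#' fixture choice: the device's true pixel pitch and frame geometry are not
#' public, so only the qualitative structure (thin bright arc, ~0.2 ms frame
#' interval, a few px of apex displacement) is emulated.
#'
#' @param image_width,image_height Frame size in px.
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval Frame spacing in ms. Default `30/139` (140 frames
#'   spanning 30 ms).
#' @param apex_row Row of the band centreline at the apex (0-based).
#' @param curvature Quadratic coefficient of the band centreline
#'   `y_c(x) = apex_row + curvature * (x - apex_x)^2` (px^-1).
#' @param apex_x Column of the apex; default image centre.
#' @param band_thickness Band thickness in px.
#' @param speckle_density Fraction of band area covered by speckle disks.
#' @param speckle_radius Mean speckle disk radius in px.
#' @param noise_sd Sensor noise standard deviation in gray levels; i.i.d.
#'   Gaussian, clipped to `[0, 255]`.
#' @param class_label `"normal"` or `"ffkc"` (metadata only; the dynamics are
#'   set by the numeric parameters).
#' @param amplitude_peak Apex vertical deformation at `peak_frame`, px.
#' @param peak_frame 0-based frame index of maximum deformation,
#'   `0 < peak_frame < n_frames - 1`.
#' @param rise_power Exponent of the rising branch (>= 1).
#' @param recovery_lag Viscoelastic recovery time constant in frames; larger
#'   values mean slower restoration (FFKC-like).
#' @param spatial_sigma Gaussian width of the deformation bump, px.
#' @param lateral_coef Coupling (px) of the small horizontal displacement
#'   `U = -lateral_coef * d(bump)/dx`; gives the field a nonzero
#'   `epsilon_xx` without changing the vertical pulse.
#' @param local_weakening `NULL` or `list(center_x=, extra_amplitude=,
#'   sigma=)`: a second Gaussian bump sharing the temporal pulse.
#' @param rigid_drift Length-2 numeric `(dx, dy)` px/frame whole-eye drift.
#' @param seed Integer; fully determines the rendered output.
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(image_width = 576, image_height = 200,
                       n_frames = 140, frame_interval = 30 / 139,
                       apex_row = 60, curvature = 30 / 288^2,
                       apex_x = (image_width - 1) / 2,
                       band_thickness = 40,
                       speckle_density = 0.35, speckle_radius = 2,
                       noise_sd = 2, class_label = c("normal", "ffkc"),
                       amplitude_peak = 7, peak_frame = 70, rise_power = 2,
                       recovery_lag = 12, spatial_sigma = 60,
                       lateral_coef = 3, local_weakening = NULL,
                       rigid_drift = c(0, 0), seed = 1L) {
  class_label <- match.arg(class_label)
  stopifnot(n_frames >= 2, amplitude_peak >= 0,
            peak_frame > 0, peak_frame < n_frames - 1,
            rise_power >= 1, recovery_lag > 0, spatial_sigma > 0,
            band_thickness > 0, length(rigid_drift) == 2,
            speckle_density >= 0, speckle_density <= 1,
            frame_interval > 0)
  if (!is.null(local_weakening)) {
    stopifnot(is.list(local_weakening),
              all(c("center_x", "extra_amplitude", "sigma") %in%
                    names(local_weakening)),
              local_weakening$sigma > 0,
              local_weakening$extra_amplitude >= 0)
  }
  cfg <- list(image_width = as.integer(image_width),
              image_height = as.integer(image_height),
              n_frames = as.integer(n_frames),
              frame_interval = frame_interval,
              apex_row = apex_row, curvature = curvature, apex_x = apex_x,
              band_thickness = band_thickness,
              speckle_density = speckle_density,
              speckle_radius = speckle_radius,
              noise_sd = noise_sd, class_label = class_label,
              amplitude_peak = amplitude_peak,
              peak_frame = peak_frame, rise_power = rise_power,
              recovery_lag = recovery_lag, spatial_sigma = spatial_sigma,
              lateral_coef = lateral_coef,
              local_weakening = local_weakening,
              rigid_drift = as.numeric(rigid_drift),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  # the undeformed band must fit inside the frame with an interpolation margin
  x <- seq(0, cfg$image_width - 1)
  yc <- band_centerline(x, cfg)
  if (min(yc) - band_thickness / 2 < 2 ||
      max(yc) + band_thickness / 2 > cfg$image_height - 3)
    stop("corneal band does not fit inside the image")
  cfg
}

band_centerline <- function(x, cfg) {
  cfg$apex_row + cfg$curvature * (x - cfg$apex_x)^2
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %dx%d px, %d frames @ %.4f ms, class=%s\n",
    x$image_width, x$image_height, x$n_frames, x$frame_interval,
    x$class_label))
  cat(sprintf(
    "  pulse: amplitude %.2f px at frame %d, sigma %.0f px, lag %.1f fr%s\n",
    x$amplitude_peak, x$peak_frame, x$spatial_sigma, x$recovery_lag,
    if (is.null(x$local_weakening)) "" else ", local weakening"))
  invisible(x)
}

# Normalized temporal pulse a(t) in [0, 1] and its per-frame derivative.
# t is a 0-based frame index (vectorized). The derivative uses the falling
# branch at the kink t == peak_frame.
pulse_shape <- function(t, cfg) {
  p <- cfg$peak_frame
  ifelse(t <= p, (t / p)^cfg$rise_power, exp(-(t - p) / cfg$recovery_lag))
}

pulse_shape_dt <- function(t, cfg) {
  p <- cfg$peak_frame
  ifelse(t < p,
         cfg$rise_power * t^(cfg$rise_power - 1) / p^cfg$rise_power,
         -exp(-(t - p) / cfg$recovery_lag) / cfg$recovery_lag)
}

# Spatial bump B(x) in px (at unit pulse) and its first two x-derivatives.
bump_profile <- function(x, cfg, deriv = 0) {
  g_term <- function(amp, cx, sg) {
    u <- (x - cx) / sg
    g <- exp(-u^2 / 2)
    switch(as.character(deriv),
           "0" = amp * g,
           "1" = amp * g * (-u / sg),
           "2" = amp * g * (u^2 - 1) / sg^2)
  }
  out <- g_term(cfg$amplitude_peak, cfg$apex_x, cfg$spatial_sigma)
  if (!is.null(cfg$local_weakening)) {
    w <- cfg$local_weakening
    out <- out + g_term(w$extra_amplitude, w$center_x, w$sigma)
  }
  out
}

#' Analytic displacement of a material point
#'
#' Evaluates the closed-form displacement field that drives the synthetic
#' renderer: `V(x, y, t) = -a(t) B(x) + drift_y t` and
#' `U(x, y, t) = -lateral_coef a(t) B'(x) + drift_x t`, where `a(t)` is the
#' rise-fall pulse and `B(x)` the (possibly two-bump) Gaussian spatial
#' profile. The depth profile through the band thickness is uniform, so the
#' field does not depend on `y`. The sign convention is V positive toward
#' the image bottom; the pulse term `-a(t) B(x)` is negative, so the band
#' bows toward the top of the image during the puff and recovers afterwards.
#' Downstream evolution curves summarize magnitudes, so the orientation is a
#' pure convention.
#'
#' @param x,y Coordinates in frame-0 (material) pixels, 0-based; vectorized.
#' @param t 0-based frame index (scalar or vector recycled against `x`).
#' @param config A [sim_config()].
#' @return `list(U =, V =)` in px.
#' @export
analytic_displacement <- function(x, y, t, config) {
  a <- pulse_shape(t, config)
  list(U = -config$lateral_coef * a * bump_profile(x, config, 1) +
         config$rigid_drift[1] * t,
       V = -a * bump_profile(x, config, 0) + config$rigid_drift[2] * t)
}

#' Exact kinematic fields of a synthetic exam on a set of points
#'
#' Evaluates the analytic displacement, strain, velocity and strain-rate
#' fields of a ground-truth object on arbitrary material points, for all
#' frames. Spatial derivatives (strains) and temporal derivatives (rates)
#' are closed-form, so these values serve as a machine-precision oracle for
#' the DIC and strain stages. Rates are per millisecond.
#'
#' @param truth A `ground_truth` object from [render_sequence()], or a
#'   `sim_config` directly.
#' @param x,y Material coordinates (0-based px), equal length.
#' @return List of `n_frames x length(x)` matrices: `U`, `V`, `exx`, `eyy`,
#'   `gxy` (engineering shear), `UR`, `VR`, `exxR`, `eyyR`, `gxyR`.
#' @export
evaluate_truth <- function(truth, x, y) {
  cfg <- if (inherits(truth, "ground_truth")) truth$config else truth
  stopifnot(inherits(cfg, "sim_config"), length(x) == length(y))
  t <- seq_len(cfg$n_frames) - 1
  a <- pulse_shape(t, cfg)
  da <- pulse_shape_dt(t, cfg) / cfg$frame_interval  # per ms
  b0 <- bump_profile(x, cfg, 0)
  b1 <- bump_profile(x, cfg, 1)
  b2 <- bump_profile(x, cfg, 2)
  drift <- cfg$rigid_drift
  tmat <- matrix(t, length(t), length(x))
  list(U = -cfg$lateral_coef * outer(a, b1) + drift[1] * tmat,
       V = -outer(a, b0) + drift[2] * tmat,
       exx = -cfg$lateral_coef * outer(a, b2),
       eyy = matrix(0, length(t), length(x)),
       gxy = -outer(a, b1),
       UR = -cfg$lateral_coef * outer(da, b1) +
         drift[1] / cfg$frame_interval,
       VR = -outer(da, b0) + drift[2] / cfg$frame_interval,
       exxR = -cfg$lateral_coef * outer(da, b2),
       eyyR = matrix(0, length(t), length(x)),
       gxyR = -outer(da, b1))
}

#' Logical mask of the undeformed corneal band
#'
#' @param config A [sim_config()].
#' @return Logical `image_height x image_width` matrix, `TRUE` inside the
#'   band at frame 0.
#' @export
band_mask <- function(config) {
  x <- seq(0, config$image_width - 1)
  yc <- band_centerline(x, config)
  ygrid <- matrix(seq(0, config$image_height - 1),
                  config$image_height, config$image_width)
  abs(sweep(ygrid, 2, yc)) <= config$band_thickness / 2
}

# The speckle texture is an analytic function of material coordinates:
# disks with a logistic (soft, ~1.5 px wide) edge darken the smooth band
# profile. Because it is analytic, every deformed frame can be rendered as
# exact point samples of the warped texture -- no resampling of a raster,
# hence no image-formation interpolation bias, exactly as a camera samples
# a continuous scene. Edge softness guarantees subpixel-interpolable
# gradients for the DIC engine.
speckle_edge_w <- 0.7   # logistic edge scale, px
speckle_depth <- 0.75   # fractional intensity dip inside a disk

draw_speckle <- function(cfg) {
  x <- seq(0, cfg$image_width - 1)
  yc <- band_centerline(x, cfg)
  band_area <- cfg$image_width * cfg$band_thickness
  r_mean <- cfg$speckle_radius
  n_disk <- round(cfg$speckle_density * band_area / (pi * r_mean^2))
  if (n_disk == 0) return(data.frame(cx = numeric(), cy = numeric(),
                                     r = numeric()))
  cx <- runif(n_disk, 0, cfg$image_width - 1)
  cy <- band_centerline(cx, cfg) +
    runif(n_disk, -cfg$band_thickness / 2, cfg$band_thickness / 2)
  data.frame(cx = cx, cy = cy,
             r = runif(n_disk, 0.5 * r_mean, 1.5 * r_mean))
}

# Evaluate the analytic texture on frame t's pixel grid: X, V are the
# per-column material abscissa and vertical displacement (X = x, V = 0 for
# the reference frame).
texture_frame <- function(cfg, disks, X, V) {
  h <- cfg$image_height
  yrow <- seq(0, h - 1)
  ycX <- band_centerline(X, cfg)
  # material y of each pixel is y - V(column); band profile with 2 px
  # cosine roll-off at the edges
  Ym <- outer(yrow, V, `-`)
  d <- cfg$band_thickness / 2 - abs(sweep(Ym, 2, ycX))
  s <- pmin(pmax(d / 2, 0), 1)
  img <- 20 + 180 * (0.5 - 0.5 * cos(pi * s))
  Rmax <- 4 * speckle_edge_w
  for (k in seq_len(nrow(disks))) {
    rk <- disks$r[k]
    cols <- which(abs(X - disks$cx[k]) <= rk + Rmax)
    if (length(cols) == 0) next
    ylo <- disks$cy[k] + min(V[cols]) - rk - Rmax
    yhi <- disks$cy[k] + max(V[cols]) + rk + Rmax
    rows <- max(1, floor(ylo) + 1):min(h, ceiling(yhi) + 1)
    if (length(rows) == 0) next
    d2 <- sweep((Ym[rows, cols, drop = FALSE] - disks$cy[k])^2, 2,
                (X[cols] - disks$cx[k])^2, `+`)
    dip <- speckle_depth / (1 + exp((sqrt(d2) - rk) / speckle_edge_w))
    img[rows, cols] <- img[rows, cols] * (1 - dip)
  }
  pmin(pmax(img, 0), 255)
}

quantize16 <- function(img) round(img / 255 * 65535) / 65535 * 255

#' Render a synthetic air-puff sequence with analytic ground truth
#'
#' Frame 0 is the undeformed speckled band. Frame `t` is produced by
#' inverse-mapping each pixel through the analytic displacement field
#' (fixed-point inversion of `x = X + u(X, t)`, 8 iterations) and
#' evaluating the analytic texture at the recovered material coordinates
#' -- exact point sampling of the warped scene, the way a camera samples a
#' continuous object, so the rendering itself introduces no interpolation
#' bias. Clipped i.i.d. Gaussian sensor noise is added per frame and
#' intensities are quantized to a 16-bit gray grid within `[0, 255]` so
#' that TIFF round trips are lossless. The same seed gives bit-identical
#' output.
#'
#' @param config A [sim_config()].
#' @return `list(sequence =, truth =)`: an `image_sequence` and a
#'   `ground_truth` object (evaluate it with [evaluate_truth()]).
#' @export
render_sequence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  # sizing check: the deformed band must stay inside the frame
  x <- seq(0, config$image_width - 1)
  yc <- band_centerline(x, config)
  tmax <- config$n_frames - 1
  bmax <- max(bump_profile(x, config, 0))
  dx_tot <- abs(config$rigid_drift[1]) * tmax
  dy_tot <- abs(config$rigid_drift[2]) * tmax
  if (min(yc) - config$band_thickness / 2 - bmax - dy_tot < 2 ||
      max(yc) + config$band_thickness / 2 + dy_tot > config$image_height - 3 ||
      dx_tot > config$apex_x / 2)
    stop("deformation pushes the corneal band outside the image; ",
         "reduce amplitude_peak or rigid_drift, or enlarge the frame")

  frames <- withr::with_seed(config$seed, {
    disks <- draw_speckle(config)
    h <- config$image_height; w <- config$image_width
    xcol <- seq(0, w - 1)
    out <- vector("list", config$n_frames)
    for (t in seq(0, config$n_frames - 1)) {
      # invert x = X + u(X, t); the field is y-independent (uniform depth
      # profile), so the fixed point is solved once per column
      X <- xcol
      if (t > 0)
        for (it in 1:8)
          X <- xcol - analytic_displacement(X, 0, t, config)$U
      V <- analytic_displacement(X, 0, t, config)$V
      fr <- texture_frame(config, disks, X, V)
      if (config$noise_sd > 0)
        fr <- pmin(pmax(fr + rnorm(h * w, 0, config$noise_sd), 0), 255)
      out[[t + 1]] <- quantize16(fr)
    }
    out
  })
  seq_obj <- image_sequence(frames, frame_interval = config$frame_interval,
                            exam_id = sprintf("sim-%s-%d",
                                              config$class_label, config$seed))
  truth <- structure(list(config = config), class = "ground_truth")
  list(sequence = seq_obj, truth = truth)
}

#' Class-conditional parameter priors for synthetic cohorts
#'
#' The frozen generative fixture used for cohort-level validation. The two
#' classes differ in pulse amplitude, recovery lag (the FFKC mean is twice
#' the normal mean, encoding a stronger viscoelastic asymmetry) and the
#' presence of a focal weakening bump; all parameters carry within-class
#' Gaussian variation. `curve_noise_sd` is the relative amplitude of the
#' additive measurement noise applied to ground-truth evolution curves in
#' fast mode (a stand-in for DIC estimation noise). These are documented
#' fixture values, not a physiological claim.
#'
#' @param separation Scales the between-class mean differences; `0` gives
#'   identical classes (a null cohort), `1` the default fixture.
#' @param curve_noise_sd Relative (to each curve's peak) noise sd in fast
#'   mode.
#' @return A `cohort_priors` list with `normal` and `ffkc` sub-lists of
#'   `c(mean, sd)` pairs.
#' @export
cohort_priors <- function(separation = 1, curve_noise_sd = 0.15) {
  base <- list(amplitude_peak = c(7.0, 1.2), peak_frame = c(70, 4),
               recovery_lag = c(12, 4), weakening_amplitude = c(0, 0))
  shift <- list(amplitude_peak = 1.0, peak_frame = 2,
                recovery_lag = 12, weakening_amplitude = 1.0)
  ffkc <- base
  for (nm in names(base)) ffkc[[nm]][1] <- base[[nm]][1] + separation * shift[[nm]]
  ffkc$recovery_lag[2] <- 6
  ffkc$weakening_amplitude[2] <- 0.5 * separation
  structure(list(normal = base, ffkc = ffkc,
                 weakening_sigma = 30, weakening_offset_range = c(-150, 150),
                 curve_noise_sd = curve_noise_sd),
            class = "cohort_priors")
}

draw_exam_config <- function(label, priors, template, seed) {
  p <- priors[[label]]
  draw <- function(par, lo, hi) {
    v <- rnorm(1, par[1], par[2])
    min(max(v, lo), hi)
  }
  amp <- draw(p$amplitude_peak, 1, 20)
  pk <- round(draw(p$peak_frame, 2, template$n_frames - 2))
  lag <- draw(p$recovery_lag, 3, 80)
  wk_amp <- if (p$weakening_amplitude[1] > 0 || p$weakening_amplitude[2] > 0)
    max(rnorm(1, p$weakening_amplitude[1], p$weakening_amplitude[2]), 0)
  else 0
  wk <- NULL
  if (wk_amp > 1e-8) {
    off <- runif(1, priors$weakening_offset_range[1],
                 priors$weakening_offset_range[2])
    wk <- list(center_x = template$apex_x + off,
               extra_amplitude = wk_amp, sigma = priors$weakening_sigma)
  }
  sim_config(image_width = template$image_width,
             image_height = template$image_height,
             n_frames = template$n_frames,
             frame_interval = template$frame_interval,
             apex_row = template$apex_row, curvature = template$curvature,
             apex_x = template$apex_x,
             band_thickness = template$band_thickness,
             speckle_density = template$speckle_density,
             speckle_radius = template$speckle_radius,
             noise_sd = template$noise_sd, class_label = label,
             amplitude_peak = amp, peak_frame = pk,
             rise_power = template$rise_power, recovery_lag = lag,
             spatial_sigma = template$spatial_sigma,
             lateral_coef = template$lateral_coef,
             local_weakening = wk, rigid_drift = template$rigid_drift,
             seed = seed)
}

# Ground-truth evolution curves for one exam (fast mode): analytic fields on
# the default measurement lattice of the undeformed band, plus additive
# measurement noise on every curve.
truth_curves <- function(cfg, priors, step = 8, subset_size = 25) {
  grid <- build_grid(band_mask(cfg), step = step, subset_size = subset_size)
  f <- evaluate_truth(cfg, grid$x, grid$y)
  curves <- extract_evolution_curves(f$V, f$gxy, f$VR, f$gxyR,
                                     exam_id = sprintf("sim-%s-%d",
                                                       cfg$class_label,
                                                       cfg$seed))
  nsd <- priors$curve_noise_sd
  if (nsd > 0) {
    for (nm in setdiff(names(curves), "frame")) {
      sc <- max(abs(curves[[nm]]))
      curves[[nm]] <- curves[[nm]] + rnorm(nrow(curves), 0, nsd * sc)
    }
  }
  curves
}

#' Generate a labeled synthetic cohort
#'
#' Draws per-exam deformation parameters from class-conditional priors and
#' returns a labeled cohort. In `fast` mode (the default) the eight
#' evolution curves are computed directly from the analytic ground truth on
#' the standard measurement lattice with additive measurement noise -- no
#' images are rendered -- which makes cohort-scale validation cheap. With
#' `fast = FALSE` full image sequences are rendered (and optionally written
#' to `dir` as multi-page TIFFs with JSON sidecars and a manifest CSV).
#'
#' @param n_normal,n_ffkc Exams per class (> 0).
#' @param priors A [cohort_priors()] object.
#' @param seed Integer; fully determines the cohort.
#' @param template A `sim_config` supplying geometry/texture defaults.
#' @param fast If `TRUE`, emit ground-truth curves instead of images.
#' @param dir Output directory for `fast = FALSE` (optional).
#' @return A `cohort` list: elements have `$label` and either `$curves`
#'   (fast) or `$sequence` + `$truth`; attributes record priors and seed.
#' @export
generate_cohort <- function(n_normal, n_ffkc, priors = cohort_priors(),
                            seed = 1L, template = sim_config(),
                            fast = TRUE, dir = NULL) {
  stopifnot(n_normal > 0, n_ffkc > 0, inherits(priors, "cohort_priors"))
  labels <- c(rep("normal", n_normal), rep("ffkc", n_ffkc))
  cohort <- withr::with_seed(as.integer(seed), {
    exam_seeds <- sample.int(2^31 - 2, length(labels))
    lapply(seq_along(labels), function(k) {
      cfg <- draw_exam_config(labels[k], priors, template, exam_seeds[k])
      if (fast) {
        list(label = labels[k], config = cfg,
             curves = truth_curves(cfg, priors))
      } else {
        rs <- render_sequence(cfg)
        list(label = labels[k], config = cfg,
             sequence = rs$sequence, truth = rs$truth)
      }
    })
  })
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "priors") <- priors
  class(cohort) <- "cohort"
  if (!fast && !is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat(sprintf("synthetic cohort: %d exams (%d normal, %d ffkc), %s\n",
              length(x), sum(labs == "normal"), sum(labs == "ffkc"),
              if (is.null(x[[1]]$curves)) "rendered sequences"
              else "ground-truth curves (fast mode)"))
  invisible(x)
}
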