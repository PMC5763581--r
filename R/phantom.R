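# Separable Gaussian smoothing (zero-padded) used for textures, parameter
# maps and mask tapers.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel_cpp(sigma)
  rad <- (length(k) - 1) / 2
  smooth1 <- function(x) {   # along rows of a matrix
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    for (i in seq_along(k)) {
      off <- i - 1 - rad
      src <- seq_len(n) + off
      okk <- src >= 1 & src <= n
      out[okk, ] <- out[okk, ] + k[i] * x[src[okk], , drop = FALSE]
    }
    out
  }
  t(smooth1(t(smooth1(m))))
}

phantom_geometry <- function(size) {
  v <- (row(matrix(0, size, size)) - 1) / (size - 1)   # axis 1, down
  u <- (col(matrix(0, size, size)) - 1) / (size - 1)   # axis 2, across
  inside <- function(cu, cv, au, av) ((u - cu) / au)^2 + ((v - cv) / av)^2 <= 1
  list(u = u, v = v,
       body = inside(0.5, 0.52, 0.42, 0.44),
       lung_l = inside(0.33, 0.42, 0.155, 0.26),
       lung_r = inside(0.67, 0.42, 0.155, 0.26))
}

#' Generate the lung-like 2D phantom
#'
#' A deterministic (per seed) synthetic thorax section: an elliptical body of
#' soft-tissue intensity with gentle smooth texture, two low-intensity lung
#' fields containing bright vessel-like Gaussian blobs and a tumour-like disc,
#' on a zero (air) background.  Intensities are rescaled so the maximum is
#' exactly `max_intensity`.
#'
#' @param size image side length in pixels (>= 64; the proportions of the
#'   phantom are the same at every size).
#' @param seed integer seed controlling the texture and vessel placement.
#' @param max_intensity maximum intensity after rescaling.
#' @return A [raster_image()] with attributes `body_mask` and `lung_mask`
#'   (logical matrices).
#' @export
make_phantom <- function(size, seed = 1L, max_intensity = 1500) {
  if (size < 64) stop("phantom size must be >= 64")
  geom <- phantom_geometry(size)
  set.seed(as.integer(seed))
  tex <- function(sigma_frac, amp) {
    n <- matrix(rnorm(size * size), size, size)
    s <- gauss_smooth(n, sigma_frac * size)
    amp * s / max(abs(s))
  }
  img <- matrix(0, size, size)
  img[geom$body] <- 900
  img <- img + geom$body * (tex(0.06, 150) + tex(0.02, 100))
  lungs <- geom$lung_l | geom$lung_r
  img[lungs] <- 180
  img <- img + lungs * (tex(0.04, 90) + tex(0.015, 70))
  # vessel-like blobs scattered through each lung field
  add_blob <- function(img, cu, cv, amp, sg) {
    img + amp * exp(-(((geom$u - cu))^2 + ((geom$v - cv))^2) / (2 * sg^2))
  }
  for (lung in list(c(0.33, 0.42), c(0.67, 0.42))) {
    for (b in seq_len(12)) {
      ang <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * 0.85
      cu <- lung[1] + rr * 0.155 * cos(ang)
      cv <- lung[2] + rr * 0.26 * sin(ang)
      img <- add_blob(img, cu, cv, runif(1, 400, 1000), runif(1, 0.008, 0.025))
    }
  }
  # tumour-like disc in the right lung
  d <- sqrt((geom$u - 0.68)^2 + (geom$v - 0.55)^2)
  img <- img + 950 / (1 + exp((d - 0.05) / 0.008))
  img[!geom$body] <- 0
  img <- gauss_smooth(img, max(1, size / 128))
  img <- img * max_intensity / max(img)
  out <- raster_image(img)
  attr(out, "body_mask") <- geom$body
  attr(out, "lung_mask") <- lungs
  out
}

# Spatial motion envelope from the phantom geometry; contrast < 1 flattens
# the motion distribution over the body, > 1 sharpens the lung/soft-tissue
# difference (the magnitude scale is recalibrated downstream).
default_envelope <- function(size, contrast = 1) {
  geom <- phantom_geometry(size)
  b <- gauss_smooth((geom$lung_l | geom$lung_r) * 1, 0.12 * size)
  taper <- pmax(0, gauss_smooth(geom$body * 1, 0.1 * size) - 0.5) / 0.5
  env <- taper * (0.25 + 0.75 * b / max(b))
  (env / max(env))^contrast
}

#' Smoothly varying correspondence-model parameter maps
#'
#' Four per-pixel model-parameter maps (row/column displacement coupled to the
#' surrogate value and to its temporal derivative), realised as band-limited
#' random fields: Gaussian-smoothed white noise scaled by `amplitude` and by a
#' spatial envelope that is largest in the lung interior and tapers to zero at
#' the body boundary, so the simulated anatomy deforms most inside the lungs
#' and the background stays still.
#'
#' @param size image side length (pixels).
#' @param smoothness Gaussian smoothing scale of the random fields, in pixels.
#' @param amplitude scale of the value-coupled maps, in pixels of displacement
#'   per unit surrogate; the derivative-coupled maps are drawn with
#'   `hysteresis * amplitude` (their surrogate is rescaled downstream).
#' @param seed integer seed.
#' @param envelope optional custom spatial envelope matrix in `[0, 1]`
#'   (default: built from the phantom's lung/body masks).
#' @param hysteresis relative size of the derivative-coupled maps.
#' @return `list(my1, my2, mx1, mx2)` of `size x size` matrices: row- and
#'   column-displacement maps coupled to the signal value (`*1`) and to its
#'   temporal derivative (`*2`).
#' @export
make_parameter_maps <- function(size, smoothness = 0.25 * size, amplitude = 8,
                                seed = 1L, envelope = NULL, hysteresis = 0.15) {
  set.seed(as.integer(seed) + 1L)
  if (is.null(envelope)) envelope <- default_envelope(size)
  field <- function() {
    n <- matrix(rnorm(size * size), size, size)
    s <- gauss_smooth(n, smoothness)
    s / max(abs(s))
  }
  # value-coupled maps: a dominant coherent displacement (inferior for the
  # row axis, a seeded lateral sign for the column axis) with smooth spatial
  # variation, as in manually drawn respiratory parameter maps; the small
  # derivative-coupled (hysteresis) maps are free smooth fields
  sgn <- sample(c(-1, 1), 1)
  list(my1 = amplitude * envelope * (0.7 + 0.3 * field()),
       my2 = hysteresis * amplitude * envelope * field(),
       mx1 = 0.5 * amplitude * envelope * sgn * (0.7 + 0.3 * field()),
       mx2 = hysteresis * amplitude * envelope * field())
}

#' Surrogate-signal generators for the phantom
#'
#' `cos4`: one idealised respiratory cycle, `s(t) = cos^4(pi t / n)` sampled at
#' `n` uniformly spaced time-points, with the respiratory phase
#' `theta_t = t / n`; mimics a single sorted breath cycle.
#' `quasiperiodic`: a free-breathing-like trace of consecutive `cos^4` cycles
#' whose amplitude and period are jittered per cycle (defaults +-20% and
#' +-15%), emulating the intra- and inter-cycle variation of a real belt or
#' spirometry trace.
#'
#' Signals are mean-centred (see [normalize_surrogate()]) and their temporal
#' derivative is filled in.
#'
#' @param kind `"cos4"` or `"quasiperiodic"`.
#' @param n_frames number of samples.
#' @param seed integer seed (jitter only).
#' @param dt sample interval, seconds.
#' @param period mean breath period, seconds (`quasiperiodic`).
#' @param amp_jitter,period_jitter per-cycle relative jitter.
#' @param exponent cosine exponent of the quasiperiodic waveform: 4 gives the
#'   exhale-dwelling shape typical of marker-block (RPM-style) traces, 2 a
#'   more sinusoidal belt-like trace.
#' @return A normalized [surrogate_series()] with derivative (and, for
#'   `cos4`, phase) columns.
#' @export
make_surrogate <- function(kind = c("cos4", "quasiperiodic"), n_frames,
                           seed = 1L, dt = 0.4, period = 4,
                           amp_jitter = 0.2, period_jitter = 0.15,
                           exponent = 4) {
  kind <- match.arg(kind)
  if (n_frames < 2) stop("need at least 2 frames")
  if (kind == "cos4") {
    t <- seq_len(n_frames) - 1
    s <- cos(pi * t / n_frames)^4
    ser <- surrogate_series(time = t, values = s, phase = t / n_frames)
    ser <- temporal_derivative(ser)
    # idealized signal: use its analytic (periodic) temporal derivative
    ser$sdot1 <- -4 * pi / n_frames * cos(pi * t / n_frames)^3 * sin(pi * t / n_frames)
    return(normalize_surrogate(ser))
  } else {
    set.seed(as.integer(seed) + 2L)
    t <- (seq_len(n_frames) - 1) * dt
    total <- t[n_frames] + dt
    starts <- 0; periods <- numeric(0); amps <- numeric(0)
    while (tail(starts, 1) < total) {
      periods <- c(periods, period * (1 + runif(1, -period_jitter, period_jitter)))
      amps <- c(amps, 1 + runif(1, -amp_jitter, amp_jitter))
      starts <- c(starts, tail(starts, 1) + tail(periods, 1))
    }
    cyc <- findInterval(t, starts)
    u <- (t - starts[cyc]) / periods[cyc]
    s <- amps[cyc] * cos(pi * u)^exponent
    ser <- surrogate_series(time = t, values = s)
  }
  normalize_surrogate(temporal_derivative(ser))
}

regime_size <- c(full = 128L, slab = 136L, thin_slice = 301L, thick_slice = 150L)

#' Phantom study specification
#'
#' The canonical simulation conditions for the four acquisition regimes:
#' 10 full frames over one idealised cycle (128 px); 187 slabs of 8 rows at 17
#' contiguous positions x 11 times (136 px); 3010 single rows from 10
#' alternating-direction sweeps, with per-row surrogate samples and twice the
#' motion amplitude (301 px); 150 overlapping thick rows with a 5-pixel
#' Gaussian slice profile, 30 positions at 5-px pitch x 5 single-pixel-shifted
#' passes (150 px).  Gaussian noise with standard deviation
#' `noise_sigma_fraction` of the maximum intensity (default 3% of 1500) is
#' added to every simulated frame.
#'
#' @param regime one of `"full"`, `"slab"`, `"thin_slice"`, `"thick_slice"`.
#' @param seed integer seed for all randomness (phantom, maps, surrogate
#'   jitter, noise).
#' @param size image side length (defaults to the canonical size per regime).
#' @param noise_sigma_fraction noise sigma as a fraction of `max_intensity`.
#' @param max_intensity maximum phantom intensity.
#' @param amplitude motion-amplitude scale passed to [make_parameter_maps()]
#'   (doubled internally for `thin_slice`).
#' @param smoothness parameter-map smoothness scale in pixels.
#' @param target_dfe optional calibration target: rescale the maps so the mean
#'   no-motion displacement-field error equals this value (pixels).
#' @param target_p95 optional second calibration target: adjust the motion
#'   envelope contrast (by bisection) so the pooled no-motion DFE has this 95th
#'   percentile (pixels), i.e. the baseline distribution shape matches a
#'   reported one, then rescale for the mean.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(regime = c("full", "slab", "thin_slice", "thick_slice"),
                         seed = 1L, size = NULL, noise_sigma_fraction = 0.03,
                         max_intensity = 1500, amplitude = 8,
                         smoothness = NULL, target_dfe = NULL,
                         target_p95 = NULL) {
  regime <- match.arg(regime)
  if (is.null(size)) size <- regime_size[[regime]]
  if (is.null(smoothness)) smoothness <- 0.25 * size
  structure(list(regime = regime, seed = as.integer(seed), size = as.integer(size),
                 noise_sigma_fraction = noise_sigma_fraction,
                 max_intensity = max_intensity, amplitude = amplitude,
                 smoothness = smoothness, target_dfe = target_dfe,
                 target_p95 = target_p95),
            class = "phantom_spec")
}

regime_layout <- function(regime, size) {
  switch(regime,
    full = {
      n <- 10L
      list(specs = rep(list(acq_spec("full")), n), n_frames = n, kind = "cos4")
    },
    slab = {
      n_pos <- 17L; n_rep <- 11L
      n_rows <- size %/% n_pos
      specs <- vector("list", n_pos * n_rep)
      i <- 1L
      for (p in seq_len(n_pos) - 1L) for (r in seq_len(n_rep)) {
        specs[[i]] <- acq_spec("slab", row_start = p * n_rows, n_rows = n_rows)
        i <- i + 1L
      }
      list(specs = specs, n_frames = n_pos * n_rep, kind = "quasiperiodic",
           dt = 0.4)
    },
    thin_slice = {
      n_sweeps <- 10L
      specs <- vector("list", n_sweeps * size)
      i <- 1L
      for (sw in seq_len(n_sweeps) - 1L) {
        rows <- if (sw %% 2L == 0L) seq_len(size) - 1L else rev(seq_len(size) - 1L)
        for (r in rows) {
          specs[[i]] <- acq_spec("slice", row_start = r, n_rows = 1L)
          i <- i + 1L
        }
      }
      list(specs = specs, n_frames = n_sweeps * size, kind = "quasiperiodic",
           dt = 5 / size, exponent = 2)
    },
    thick_slice = {
      n_pos <- 30L; n_pass <- 5L; n_rep <- 10L
      pitch <- size %/% n_pos
      sg <- sigma_from_fwhm(5)
      specs <- vector("list", n_pos * n_pass * n_rep)
      i <- 1L
      for (pass in seq_len(n_pass) - 1L) for (p in seq_len(n_pos) - 1L)
        for (r in seq_len(n_rep)) {
          specs[[i]] <- acq_spec("thick_slice", row_start = p * pitch + pass,
                                 n_rows = 1L, profile_sigma = sg)
          i <- i + 1L
        }
      list(specs = specs, n_frames = n_pos * n_pass * n_rep,
           kind = "quasiperiodic", dt = 0.2, exponent = 2)
    })
}

#' Simulate a phantom dataset
#'
#' Generates the phantom, its parameter maps and surrogate trace, animates it
#' with the linear correspondence model
#' `M_t(p) = r_1(p) s_t + r_2(p) sdot_t` per pixel, acquires every frame with
#' the regime's acquisition operator and adds Gaussian intensity noise.  When
#' `target_dfe` is set the maps are rescaled so the pooled mean no-motion
#' displacement-field error (the mean true displacement magnitude inside the
#' deformed phantom, over all frames) matches the target to within 2%.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_dataset` with elements `I_true`
#'   ([raster_image()]), `maps`, `surrogate`, `frames`, `specs`, `body_mask`,
#'   `lung_mask`, and the generating `spec`.
#' @export
simulate_dataset <- function(spec) {
  size <- spec$size
  lay <- regime_layout(spec$regime, size)
  phant <- make_phantom(size, seed = spec$seed, max_intensity = spec$max_intensity)
  amp <- spec$amplitude * if (spec$regime == "thin_slice") 2 else 1
  sur <- if (lay$kind == "cos4") make_surrogate("cos4", lay$n_frames)
         else make_surrogate("quasiperiodic", lay$n_frames, seed = spec$seed,
                             dt = lay$dt, exponent = lay$exponent %||% 4)
  body <- attr(phant, "body_mask") * 1
  build_maps <- function(contrast) {
    m <- make_parameter_maps(size, smoothness = spec$smoothness,
                             amplitude = amp, seed = spec$seed,
                             envelope = default_envelope(size, contrast))
    # the derivative-coupled maps were drawn in value-signal units: rescale so
    # the hysteresis term has the intended relative magnitude
    r <- sd(sur$s1) / sd(sur$sdot1)
    m$my2 <- m$my2 * r
    m$mx2 <- m$mx2 * r
    m
  }
  nomotion <- function(maps) {
    st <- dfe_stream_cpp(maps$my1, maps$my2, maps$mx1, maps$mx2,
                         sur$s1, sur$sdot1, body, NULL, NULL,
                         integer(2), 1, 0.01, 12000L)
    stats_from_stream(st)
  }
  contrast <- 1
  if (!is.null(spec$target_p95) && !is.null(spec$target_dfe)) {
    # bisect the envelope contrast so the baseline p95/mean ratio matches the
    # requested distribution shape (amplitude-invariant), then scale the mean
    ratio_target <- spec$target_p95 / spec$target_dfe
    lo <- 0.15; hi <- 3
    for (i in 1:10) {
      contrast <- sqrt(lo * hi)
      stc <- nomotion(build_maps(contrast))
      ratio <- stc$p95 / stc$mean
      if (abs(ratio - ratio_target) / ratio_target < 0.01) break
      if (ratio > ratio_target) hi <- contrast else lo <- contrast
    }
  }
  maps <- build_maps(contrast)
  if (!is.null(spec$target_dfe)) {
    for (i in 1:6) {
      m <- nomotion(maps)$mean
      if (abs(m - spec$target_dfe) / spec$target_dfe < 0.02) break
      f <- spec$target_dfe / m
      maps <- lapply(maps, function(x) x * f)
    }
  }

  set.seed(spec$seed + 3L)
  frames <- vector("list", lay$n_frames)
  noise_sd <- spec$noise_sigma_fraction * spec$max_intensity
  for (t in seq_len(lay$n_frames)) {
    sp <- lay$specs[[t]]
    rows <- spec_support_rows(sp, size)
    fld <- true_field_rows(maps, sur[t, ], rows, size)
    W <- warp_rows_cpp(phant$data, fld$dy, fld$dx, rows, 0, FALSE)$warped
    P <- acquire_from_rows(W, rows, sp, size)
    if (noise_sd > 0) P <- P + matrix(rnorm(length(P), sd = noise_sd), nrow(P))
    frames[[t]] <- P
  }
  structure(list(I_true = phant, maps = maps, surrogate = sur, frames = frames,
                 specs = lay$specs, body_mask = attr(phant, "body_mask"),
                 lung_mask = attr(phant, "lung_mask"), spec = spec),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> regime %s, %d x %d px, %d frames, seed %d\n",
              x$spec$regime, x$spec$size, x$spec$size, length(x$frames),
              x$spec$seed))
  invisible(x)
}

#' True displacement field of a phantom dataset at one time-point
#'
#' `M_t(p) = r_1(p) s_t + r_2(p) sdot_t` per pixel, exactly as used to animate
#' the phantom.
#'
#' @param dataset a `phantom_dataset` (or its `maps` element via
#'   `true_field_rows`).
#' @param t frame index (1-based).
#' @param rows optional 0-based integer rows to evaluate.
#' @return A [disp_field()].
#' @export
true_field <- function(dataset, t, rows = NULL) {
  size <- dataset$spec$size
  if (is.null(rows)) rows <- seq_len(size) - 1
  true_field_rows(dataset$maps, dataset$surrogate[t, ], rows, size)
}

true_field_rows <- function(maps, sample, rows, ncol_img) {
  i <- as.integer(rows) + 1L
  s <- sample$s1; sd_ <- sample$sdot1
  disp_field(maps$my1[i, , drop = FALSE] * s + maps$my2[i, , drop = FALSE] * sd_,
             maps$mx1[i, , drop = FALSE] * s + maps$mx2[i, , drop = FALSE] * sd_)
}

#' Per-frame body mask of the deformed phantom
#'
#' A pixel of frame `t` lies inside the deformed phantom when the point it
#' samples, `x + M_t(x)`, falls inside the reference body mask.
#'
#' @param dataset a `phantom_dataset`.
#' @param t frame index.
#' @return Logical matrix.
#' @export
frame_body_mask <- function(dataset, t) {
  fld <- true_field(dataset, t)
  warp_pull(dataset$body_mask * 1, fld, pad = 0) >= 0.5
}
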