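#' Fit configuration
#'
#' Tunable settings for [fit_model()].
#'
#' @param cpg_spacing B-spline control-point spacing in pixels (>= 1).
#' @param levels multi-resolution pyramid depth (images downsampled by 2 per
#'   level; >= 1).
#' @param max_iter maximum conjugate-gradient iterations per level.
#' @param tol relative gradient tolerance: stop when the gradient max-norm
#'   falls below `tol` times its initial value at that level.
#' @param pad out-of-bounds padding intensity used when warping.
#' @param step0 initial line-search step, expressed as the largest
#'   control-point move in pixels it may produce.
#' @param verbose print per-iteration cost?
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(cpg_spacing = 5, levels = 3, max_iter = 100,
                       tol = 1e-3, pad = 0, step0 = 0.4, verbose = FALSE) {
  if (cpg_spacing < 1) stop("cpg_spacing must be >= 1")
  if (levels < 1) stop("levels must be >= 1")
  structure(list(cpg_spacing = cpg_spacing, levels = as.integer(levels),
                 max_iter = as.integer(max_iter), tol = tol, pad = pad,
                 step0 = step0, verbose = isTRUE(verbose)),
            class = "fit_config")
}

#' Sum-of-squared-differences similarity and its gradient
#'
#' `cost = sum((P_A - P)^2)` (raw sum, no normalisation, so gradients compose
#' exactly through the chain rule) and `gradient = 2 (P_A - P)` with respect
#' to the simulated data `P_A`.
#'
#' @param P measured partial data (matrix).
#' @param P_A simulated partial data, same shape.
#' @return `list(cost =, gradient =)`.
#' @export
ssd_and_gradient <- function(P, P_A) {
  if (!identical(dim(as.matrix(P)), dim(as.matrix(P_A))))
    stop("measured and simulated data shapes differ")
  d <- P_A - P
  list(cost = sum(d * d), gradient = 2 * d)
}

#' Cost and coefficient gradient for a single frame
#'
#' The registration cost of one frame under the current correspondence model,
#' `C_t = SSD(P_t, A_t(T(I_0, M_t)))` with `M_t = sum_n R_n phi_n(S_t)`, and
#' its analytic gradient with respect to every model coefficient set via the
#' chain rule: the SSD gradient in partial-data space is mapped back through
#' the acquisition adjoint, multiplied by the spatial gradient of the warped
#' reference image, projected onto the control-point lattice, and scaled by
#' each basis value `phi_n`.
#'
#' @param P_t measured partial data for the frame.
#' @param I0 reference-state image (`raster_image` or matrix).
#' @param model a [corr_model()].
#' @param sample the frame's surrogate sample (one row of a
#'   [surrogate_series()]).
#' @param spec the frame's [acq_spec()].
#' @param pad warp padding intensity.
#' @return `list(cost =, gradients = list of N_r coefficient-shaped arrays)`.
#' @export
frame_cost_gradient <- function(P_t, I0, model, sample, spec, pad = 0) {
  img <- as_matrix_image(I0)
  phi <- basis(model$kind, sample, model$n_terms)
  mt <- model_motion(model, phi)
  fld <- evaluate_displacement(mt)
  w <- warp_rows_cpp(img, fld$dy, fld$dx, seq_len(nrow(img)) - 1, pad, TRUE)
  P_A <- acquire(w$warped, spec)
  sg <- ssd_and_gradient(P_t, P_A)
  if (!is.finite(sg$cost)) stop("non-finite cost for frame")
  g_img <- acquire_adjoint(sg$gradient, spec, dim(img))
  pix <- list(dy = g_img * w$gy, dx = g_img * w$gx)
  Gc <- project_gradient_to_cpg(pix, mt)
  list(cost = sg$cost,
       gradients = lapply(phi, function(p) p * Gc))
}

encode_specs <- function(specs) {
  specm <- t(vapply(specs, function(s)
    c(spec_mode_code(s), s$row_start, s$n_rows), integer(3)))
  sigmas <- vapply(specs, function(s)
    if (s$mode == "thick_slice") s$profile_sigma else 0, numeric(1))
  list(specm = specm, sigmas = sigmas)
}

# Total cost (and gradient) over all frames through the fused C++ driver.
total_cost_grad <- function(I0, coefs, Phi, frames, enc, kdim, spacing, pad,
                            want_grad = TRUE) {
  cost_grad_total_cpp(I0, coefs, Phi, frames, enc$specm, enc$sigmas,
                      kdim, spacing, nrow(I0), ncol(I0), pad, want_grad)
}

# ---- multi-resolution helpers -------------------------------------------------

downsample_matrix <- function(m, axes = c(TRUE, TRUE)) {
  if (axes[1]) {
    nr <- 2 * (nrow(m) %/% 2)
    m <- (m[seq(1, nr, 2), , drop = FALSE] + m[seq(2, nr, 2), , drop = FALSE]) / 2
  }
  if (axes[2]) {
    nc <- 2 * (ncol(m) %/% 2)
    m <- (m[, seq(1, nc, 2), drop = FALSE] + m[, seq(2, nc, 2), drop = FALSE]) / 2
  }
  m
}

# One pyramid step for a dataset: 2x2 block-mean image; partial-data rows are
# downsampled consistently with the image axis they live on (slab rows pair-
# averaged, single rows re-indexed, thick-slice sigma halved).
downsample_dataset <- function(I0, frames, specs) {
  I0d <- downsample_matrix(I0)
  nrd <- nrow(I0d)
  fr <- vector("list", length(frames))
  sp <- vector("list", length(specs))
  for (i in seq_along(frames)) {
    s <- specs[[i]]
    P <- frames[[i]]
    if (s$mode == "full") {
      fr[[i]] <- downsample_matrix(P)
      sp[[i]] <- s
    } else if (s$mode == "slab" && s$n_rows >= 2) {
      fr[[i]] <- downsample_matrix(P)
      sp[[i]] <- acq_spec("slab", row_start = s$row_start %/% 2L,
                          n_rows = nrow(fr[[i]]))
    } else if (s$mode %in% c("slab", "slice")) {
      fr[[i]] <- downsample_matrix(P, axes = c(FALSE, TRUE))
      sp[[i]] <- acq_spec("slice", row_start = min(s$row_start %/% 2L, nrd - 1L),
                          n_rows = 1L)
    } else {
      fr[[i]] <- downsample_matrix(P, axes = c(FALSE, TRUE))
      rs <- as.integer(round((s$row_start - 0.5) / 2))
      rs <- max(0L, min(rs, nrd - s$n_rows))
      sp[[i]] <- acq_spec("thick_slice", row_start = rs, n_rows = s$n_rows,
                          profile_sigma = s$profile_sigma / 2)
    }
    storage.mode(fr[[i]]) <- "double"
  }
  list(I0 = I0d, frames = fr, specs = sp)
}

# Initialize a fine-level coefficient set from a coarse-level model: sample the
# coarse field at each fine control-point position (in coarse coordinates) and
# double it, clamping positions to the coarse domain.
upsample_coefs <- function(coefs, cpg_coarse, cpg_fine) {
  fine_pos <- function(K) ((seq_len(K)) - 3) * cpg_fine$spacing
  py <- pmin(pmax((fine_pos(cpg_fine$kdim[1]) - 0.5) / 2, 0), cpg_coarse$img_dim[1] - 1)
  px <- pmin(pmax((fine_pos(cpg_fine$kdim[2]) - 0.5) / 2, 0), cpg_coarse$img_dim[2] - 1)
  lapply(coefs, function(co) {
    out <- array(0, dim = c(cpg_fine$kdim, 2L))
    cg <- control_point_grid(cpg_coarse$img_dim, cpg_coarse$spacing, coef = co)
    for (b in seq_along(px)) {
      fb <- eval_at_points(cg, py, px[b])
      out[, b, 1] <- 2 * fb$fy
      out[, b, 2] <- 2 * fb$fx
    }
    out
  })
}

# Evaluate a CPG at arbitrary (row, col) positions sharing one column coord.
eval_at_points <- function(cpg, ys, x) {
  w4 <- function(j) c((1 - j)^3, 3 * j^3 - 6 * j^2 + 4,
                      -3 * j^3 + 3 * j^2 + 3 * j + 1, j^3) / 6
  ux <- x / cpg$spacing; lx <- floor(ux); wx <- w4(ux - lx)
  K1 <- cpg$kdim[1]
  fy <- numeric(length(ys)); fx <- numeric(length(ys))
  for (i in seq_along(ys)) {
    uy <- ys[i] / cpg$spacing; ly <- floor(uy); wy <- w4(uy - ly)
    sy <- 0; sx <- 0
    for (b in 0:3) for (a in 0:3) {
      w <- wy[a + 1] * wx[b + 1]
      sy <- sy + w * cpg$coef[ly + a + 1, lx + b + 1, 1]
      sx <- sx + w * cpg$coef[ly + a + 1, lx + b + 1, 2]
    }
    fy[i] <- sy; fx[i] <- sx
  }
  list(fy = fy, fx = fx)
}

# ---- conjugate gradient -------------------------------------------------------

# Polak-Ribiere (+restart) nonlinear conjugate gradient with Armijo
# backtracking on the flattened coefficient stack.
cg_minimize <- function(fn_cost, fn_both, x0, max_iter, tol, step0_px,
                        verbose = FALSE) {
  x <- x0
  fb <- fn_both(x)
  f <- fb$cost; g <- fb$grad
  g0norm <- max(abs(g))
  trace <- f
  if (g0norm == 0) return(list(x = x, cost = f, trace = trace, iter = 0L))
  d <- -g
  alpha <- NA
  for (it in seq_len(max_iter)) {
    gd <- sum(g * d)
    if (gd >= 0) { d <- -g; gd <- sum(g * d) }   # restart on non-descent
    if (is.na(alpha)) alpha <- step0_px / max(abs(d))
    ok <- FALSE
    a <- alpha
    for (ls in 1:30) {
      fnew <- fn_cost(x + a * d)
      if (is.finite(fnew) && fnew <= f + 1e-4 * a * gd) { ok <- TRUE; break }
      a <- a / 2
    }
    if (ok) {
      # greedy expansion: keep doubling while the cost keeps dropping
      for (ex in 1:8) {
        fbig <- fn_cost(x + 2 * a * d)
        if (!is.finite(fbig) || fbig >= fnew) break
        a <- 2 * a
        fnew <- fbig
      }
    }
    if (!ok) {
      if (identical(d, -g)) break        # no descent along steepest: converged
      d <- -g
      alpha <- NA
      next
    }
    x <- x + a * d
    fb <- fn_both(x)
    gnew <- fb$grad
    beta <- max(0, sum(gnew * (gnew - g)) / sum(g * g))
    d <- -gnew + beta * d
    g <- gnew
    f <- fb$cost
    trace <- c(trace, f)
    alpha <- a * 2
    if (verbose) message(sprintf("  iter %3d  cost %.6g  |g| %.3g", it, f, max(abs(g))))
    if (max(abs(g)) < tol * g0norm) break
  }
  list(x = x, cost = f, trace = trace, iter = length(trace) - 1L)
}

#' Fit a correspondence model to dynamic image data
#'
#' Minimises the total registration cost `C_total = sum_t C_t` over all frames
#' with respect to the correspondence-model coefficients, using the analytic
#' chain-rule gradient and Polak-Ribiere conjugate gradient with an Armijo
#' backtracking line search, inside a multi-resolution scheme (the image and
#' the partial data are downsampled by 2 per level; the control-point spacing
#' is held constant in pixels, and coefficients are upsampled between levels).
#' No constraint/regularisation term is used.
#'
#' @param frames list of partial-data matrices, one per time-point.
#' @param specs list of [acq_spec()], one per frame.
#' @param surrogate a [surrogate_series()] with one row per frame (normalized;
#'   derivative/phase columns filled as the model kind requires).
#' @param I0 reference-state image (`raster_image` or matrix).
#' @param kind correspondence-model kind, see [basis()].
#' @param config a [fit_config()].
#' @param n_terms number of terms for the `periodic_bspline` kind.
#' @param init optional [corr_model()] to warm-start from (default: all-zero
#'   coefficients).
#' @return A fitted [corr_model()] with attributes `trace` (per-level cost
#'   traces) and `cost` (final total cost).
#' @export
fit_model <- function(frames, specs, surrogate, I0, kind,
                      config = fit_config(), n_terms = 4, init = NULL) {
  if (length(frames) < 1) stop("at least one frame is required")
  if (length(frames) != length(specs) || length(frames) != nrow(surrogate))
    stop("frames, specs and surrogate rows must align")
  img <- as_matrix_image(I0)
  storage.mode(img) <- "double"
  frames <- lapply(frames, function(m) { m <- as.matrix(m); storage.mode(m) <- "double"; m })
  Nr <- n_basis_terms(kind, n_terms)
  Phi <- basis_matrix(kind, surrogate, n_terms)

  # build the pyramid (level 1 = native)
  pyr <- list(list(I0 = img, frames = frames, specs = specs))
  lv <- 1
  while (lv < config$levels && min(dim(pyr[[lv]]$I0)) >= 32) {
    pyr[[lv + 1]] <- downsample_dataset(pyr[[lv]]$I0, pyr[[lv]]$frames,
                                        pyr[[lv]]$specs)
    lv <- lv + 1
  }

  coefs <- NULL
  cpg_prev <- NULL
  traces <- list()
  res <- NULL
  for (level in rev(seq_along(pyr))) {
    dat <- pyr[[level]]
    cpg <- control_point_grid(dim(dat$I0), config$cpg_spacing)
    if (is.null(coefs)) {
      if (!is.null(init)) {
        if (!identical(init$cpg$img_dim, cpg$img_dim) && level == 1)
          stop("warm-start model lattice does not match the image")
        coefs <- if (identical(init$cpg$img_dim, cpg$img_dim)) init$coefficients
                 else lapply(seq_len(Nr), function(n) array(0, dim = c(cpg$kdim, 2L)))
      } else {
        coefs <- lapply(seq_len(Nr), function(n) array(0, dim = c(cpg$kdim, 2L)))
      }
    } else if (!identical(cpg_prev$img_dim, cpg$img_dim)) {
      coefs <- upsample_coefs(coefs, cpg_prev, cpg)
    }
    enc <- encode_specs(dat$specs)
    csz <- prod(cpg$kdim) * 2
    flat <- function(lst) unlist(lst, use.names = FALSE)
    unflat <- function(x) lapply(seq_len(Nr), function(n)
      array(x[((n - 1) * csz + 1):(n * csz)], dim = c(cpg$kdim, 2L)))
    fn_cost <- function(x)
      total_cost_grad(dat$I0, unflat(x), Phi, dat$frames, enc, cpg$kdim,
                      config$cpg_spacing, config$pad, FALSE)$cost
    fn_both <- function(x) {
      r <- total_cost_grad(dat$I0, unflat(x), Phi, dat$frames, enc, cpg$kdim,
                           config$cpg_spacing, config$pad, TRUE)
      list(cost = r$cost, grad = flat(r$grads))
    }
    if (config$verbose) message(sprintf("level %d (%d x %d)", level,
                                        nrow(dat$I0), ncol(dat$I0)))
    res <- cg_minimize(fn_cost, fn_both, flat(coefs), config$max_iter,
                       config$tol, config$step0, config$verbose)
    coefs <- unflat(res$x)
    traces[[length(traces) + 1]] <- res$trace
    cpg_prev <- cpg
  }
  model <- corr_model(kind, coefs, cpg_prev)
  attr(model, "trace") <- traces
  attr(model, "cost") <- res$cost
  model
}

#' Pairwise registration of a reference image to one frame
#'
#' The single-frame special case of the unified fit: a `direct` model with a
#' single constant term, so the optimisation reduces to a standard B-spline
#' registration of `I0` to the frame.
#'
#' @inheritParams fit_model
#' @param frame one frame of data.
#' @param spec the frame's [acq_spec()].
#' @return A fitted [corr_model()] of kind `direct` (one coefficient set equal
#'   to the transformation parameters).
#' @export
register_pair <- function(frame, spec, I0, config = fit_config()) {
  sur <- surrogate_series(time = 0:1, values = c(0, 0))[1, ]
  class(sur) <- c("surrogate_series", "data.frame")
  fit_model(list(frame), list(spec), sur, I0, "direct", config)
}
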