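# Acquisition restricted to precomputed support rows: `W` holds the deformed
# image on `rows` (0-based), which covers the full support of the spec.
acquire_from_rows <- function(W, rows, spec, nrow_img) {
  if (spec$mode == "full") return(W)
  if (spec$mode != "thick_slice") {
    idx <- match(spec$row_start + seq_len(spec$n_rows) - 1L, rows)
    return(W[idx, , drop = FALSE])
  }
  k <- gauss_kernel_cpp(spec$profile_sigma)
  rad <- (length(k) - 1) / 2
  out <- matrix(0, spec$n_rows, ncol(W))
  for (s in seq_len(spec$n_rows)) {
    centre <- spec$row_start + s - 1L
    for (y in max(0, centre - rad):min(nrow_img - 1, centre + rad)) {
      i <- match(y, rows)
      out[s, ] <- out[s, ] + k[y - centre + rad + 1] * W[i, ]
    }
  }
  out
}

# Adjoint restricted to the same support rows (rows x ncol output).
adjoint_to_rows <- function(partial, rows, spec, nrow_img) {
  out <- matrix(0, length(rows), ncol(partial))
  if (spec$mode == "full") return(partial)
  if (spec$mode != "thick_slice") {
    idx <- match(spec$row_start + seq_len(spec$n_rows) - 1L, rows)
    out[idx, ] <- partial
    return(out)
  }
  k <- gauss_kernel_cpp(spec$profile_sigma)
  rad <- (length(k) - 1) / 2
  for (s in seq_len(spec$n_rows)) {
    centre <- spec$row_start + s - 1L
    for (y in max(0, centre - rad):min(nrow_img - 1, centre + rad)) {
      i <- match(y, rows)
      out[i, ] <- out[i, ] + k[y - centre + rad + 1] * partial[s, ]
    }
  }
  out
}

# Per-frame model displacement field at given (possibly fractional) rows;
# model = NULL means an estimate of no motion.
frame_field_rows <- function(model, sample, rows, ncol_img) {
  if (is.null(model))
    return(disp_field(matrix(0, length(rows), ncol_img),
                      matrix(0, length(rows), ncol_img)))
  model_field(model, sample, rows = rows)
}

#' Motion-compensated reconstruction by weighted averaging
#'
#' For every frame the partial data are mapped back to full-image space with
#' the acquisition adjoint, deformed into the reference space by
#' push-interpolation with the model's motion at that time-point, and
#' accumulated together with their acquisition-occupancy weights; the
#' reconstruction is the accumulated intensity divided by the accumulated
#' weight.  Pixels whose total weight stays below `hole_eps` are holes; if any
#' remain the frame data are re-embedded at twice the row density (linear
#' interpolation) and the reconstruction is retried once, with a warning.
#'
#' @param frames list of partial-data matrices.
#' @param specs list of [acq_spec()] per frame.
#' @param model a fitted [corr_model()], or `NULL` for an estimate of no
#'   motion.
#' @param surrogate [surrogate_series()] with one row per frame.
#' @param img_dim length-2 reconstruction grid (the dynamic-data resolution).
#' @param hole_eps weight threshold below which a pixel counts as a hole.
#' @param upsample_rows internal: re-embed at 2x row density.
#' @return `list(image, weights, hole_count, holes)`; `image` is a
#'   [raster_image()].
#' @export
mcir_average <- function(frames, specs, model, surrogate, img_dim,
                         hole_eps = 1e-6, upsample_rows = FALSE) {
  acc <- matrix(0, img_dim[1], img_dim[2])
  wgt <- matrix(0, img_dim[1], img_dim[2])
  for (t in seq_along(frames)) {
    spec <- specs[[t]]
    rows <- spec_support_rows(spec, img_dim[1])
    E <- adjoint_to_rows(frames[[t]], rows, spec, img_dim[1])
    Wt <- adjoint_to_rows(matrix(1, nrow(frames[[t]]), ncol(frames[[t]])),
                          rows, spec, img_dim[1])
    if (upsample_rows && length(rows) > 1) {
      half <- head(rows, -1) + 0.5
      interp <- (E[-1, , drop = FALSE] + E[-nrow(E), , drop = FALSE]) / 2
      winterp <- (Wt[-1, , drop = FALSE] + Wt[-nrow(Wt), , drop = FALSE]) / 2
      ord <- order(c(rows, half))
      rows <- c(rows, half)[ord]
      E <- rbind(E, interp)[ord, , drop = FALSE] * 0.5
      Wt <- rbind(Wt, winterp)[ord, , drop = FALSE] * 0.5
    }
    fld <- frame_field_rows(model, surrogate[t, , drop = FALSE], rows, img_dim[2])
    pa <- push_rows_cpp(E, fld$dy, fld$dx, rows, img_dim[1], img_dim[2])
    pw <- push_rows_cpp(Wt, fld$dy, fld$dx, rows, img_dim[1], img_dim[2])
    acc <- acc + pa$acc
    wgt <- wgt + pw$acc
  }
  holes <- which(wgt <= hole_eps, arr.ind = TRUE)
  if (nrow(holes) > 0 && !upsample_rows) {
    warning(nrow(holes), " hole(s) in the reconstruction; retrying at 2x row density")
    return(mcir_average(frames, specs, model, surrogate, img_dim,
                        hole_eps = hole_eps, upsample_rows = TRUE))
  }
  out <- matrix(0, img_dim[1], img_dim[2])
  ok <- wgt > hole_eps
  out[ok] <- acc[ok] / wgt[ok]
  list(image = raster_image(out), weights = wgt,
       hole_count = nrow(holes), holes = holes)
}

#' Super-resolution reconstruction by iterative back-projection
#'
#' Starts from the averaging reconstruction and iteratively refines it: each
#' frame is simulated from the current estimate (pull-warp then acquisition),
#' the residuals are back-projected (acquisition adjoint, then push-warp into
#' reference space with the acquisition Gaussian as the back-projection
#' kernel) and added as a weighted-average correction.  Stops after `n_iter`
#' iterations or as soon as the data residual has increased for three
#' consecutive iterations, returning the best iterate.
#'
#' @inheritParams mcir_average
#' @param n_iter maximum number of back-projection iterations.
#' @return `list(image, residual_trace, hole_count)`.
#' @export
mcir_superres <- function(frames, specs, model, surrogate, img_dim,
                          n_iter = 10, hole_eps = 1e-6) {
  avg <- mcir_average(frames, specs, model, surrogate, img_dim,
                      hole_eps = hole_eps)
  X <- avg$image$data
  # per-frame fields and denominators are fixed during the iteration
  nfr <- length(frames)
  flds <- vector("list", nfr)
  rowss <- vector("list", nfr)
  denom <- matrix(0, img_dim[1], img_dim[2])
  for (t in seq_len(nfr)) {
    rows <- spec_support_rows(specs[[t]], img_dim[1])
    Wt <- adjoint_to_rows(matrix(1, nrow(frames[[t]]), ncol(frames[[t]])),
                          rows, specs[[t]], img_dim[1])
    fld <- frame_field_rows(model, surrogate[t, , drop = FALSE], rows, img_dim[2])
    denom <- denom + push_rows_cpp(Wt, fld$dy, fld$dx, rows,
                                   img_dim[1], img_dim[2])$acc
    flds[[t]] <- fld
    rowss[[t]] <- rows
  }
  ok <- denom > hole_eps
  best <- X; best_res <- Inf
  res_trace <- numeric(0)
  bad <- 0L
  for (it in seq_len(n_iter)) {
    num <- matrix(0, img_dim[1], img_dim[2])
    resnorm <- 0
    for (t in seq_len(nfr)) {
      rows <- rowss[[t]]
      fld <- flds[[t]]
      W <- warp_rows_cpp(X, fld$dy, fld$dx, rows, 0, FALSE)$warped
      P_sim <- acquire_from_rows(W, rows, specs[[t]], img_dim[1])
      resid <- frames[[t]] - P_sim
      resnorm <- resnorm + sum(resid^2)
      bp <- adjoint_to_rows(resid, rows, specs[[t]], img_dim[1])
      num <- num + push_rows_cpp(bp, fld$dy, fld$dx, rows,
                                 img_dim[1], img_dim[2])$acc
    }
    res_trace <- c(res_trace, resnorm)
    if (resnorm < best_res) { best <- X; best_res <- resnorm; bad <- 0L }
    else bad <- bad + 1L
    if (bad >= 3L) break
    X[ok] <- X[ok] + num[ok] / denom[ok]
  }
  # score the final iterate too
  list(image = raster_image(best), residual_trace = res_trace,
       hole_count = avg$hole_count)
}

#' Alternate model fitting with motion-compensated reconstruction
#'
#' Implements the iterative scheme for data without a reference image: an
#' initial reconstruction assuming no motion provides `I_0`, the model is
#' fitted to the partial data, the reconstruction is repeated under the fitted
#' model, and so on.  Rounds after the first warm-start the coefficients at
#' native resolution.  If the total cost increases between rounds the previous
#' round's model/reconstruction pair is returned.
#'
#' @inheritParams fit_model
#' @param n_outer number of fit/reconstruct rounds (>= 1).
#' @param mcir `"average"` or `"superres"`.
#' @param n_iter_sr back-projection iterations for `"superres"`.
#' @return `list(model, I0, cost_trace, recon)`.
#' @export
fit_with_mcir <- function(frames, specs, surrogate, kind,
                          config = fit_config(), n_terms = 4,
                          n_outer = 3, mcir = c("average", "superres"),
                          n_iter_sr = 10) {
  mcir <- match.arg(mcir)
  if (n_outer < 1) stop("n_outer must be >= 1")
  # the reconstruction sits at the mean anatomical position (mean-zero
  # surrogates), so the constant offset term would be a pure gauge freedom of
  # the joint (image, model) problem; drop it
  if (kind == "linear_sdot") kind <- "linear_sdot0"
  img_dim <- c(nrow(frames[[1]]), ncol(frames[[1]]))
  if (specs[[1]]$mode != "full")
    img_dim <- c(attr(specs, "img_nrow") %||% guess_nrow(specs), ncol(frames[[1]]))
  model <- NULL
  best <- NULL
  cost_trace <- numeric(0)
  recon <- NULL
  for (round in seq_len(n_outer)) {
    recon <- if (mcir == "average")
      mcir_average(frames, specs, model, surrogate, img_dim)
    else
      mcir_superres(frames, specs, model, surrogate, img_dim, n_iter = n_iter_sr)
    # each round re-fits with the full multi-resolution schedule: the early
    # reconstructions are motion-blurred, and a model warm-started from a fit
    # against them can be stuck in their local optimum.  Early rounds get a
    # reduced iteration budget - their reference will be rebuilt anyway.
    cfg <- config
    if (round < n_outer) cfg$max_iter <- max(60L, config$max_iter %/% 2L)
    model <- fit_model(frames, specs, surrogate, recon$image, kind,
                       config = cfg, n_terms = n_terms)
    cost <- attr(model, "cost")
    if (length(cost_trace) > 0 && cost > tail(cost_trace, 1)) {
      model <- best$model; recon <- best$recon
      cost_trace <- c(cost_trace, cost)
      break
    }
    cost_trace <- c(cost_trace, cost)
    best <- list(model = model, recon = recon)
  }
  list(model = model, I0 = recon$image, cost_trace = cost_trace, recon = recon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_nrow <- function(specs) {
  max(vapply(specs, function(s) s$row_start + s$n_rows, integer(1)))
}
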