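#' Surrogate signal series
#'
#' A data frame with a `time` column and one or more signal columns
#' (`s1`, `s2`, ...), plus optional `sdot1`, ... temporal-derivative columns
#' (filled by [temporal_derivative()]) and an optional `phase` column with the
#' respiratory phase in `[0, 1)`.
#'
#' @param time sample times (seconds or frame index), strictly monotone.
#' @param values numeric vector or matrix of signal samples (one column per
#'   signal).
#' @param phase optional per-sample respiratory phase.
#' @return A `data.frame` of class `surrogate_series`.
#' @export
surrogate_series <- function(time, values, phase = NULL) {
  values <- as.matrix(values)
  if (length(time) != nrow(values)) stop("time and values lengths differ")
  if (nrow(values) < 2) stop("at least 2 surrogate samples are required")
  df <- data.frame(time = as.numeric(time))
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  df <- cbind(df, values)
  if (!is.null(phase)) df$phase <- as.numeric(phase)
  class(df) <- c("surrogate_series", "data.frame")
  df
}

signal_cols <- function(series) grep("^s[0-9]+$", names(series), value = TRUE)

#' Normalize surrogate signals to zero mean
#'
#' Subtracts each signal column's mean so that the model-free state (all
#' signals zero) corresponds to the average position of the anatomy over the
#' acquisition; the scale is left unchanged.  A zero-variance column makes the
#' corresponding model term degenerate and triggers a warning.
#'
#' @param series a [surrogate_series()].
#' @return The series with every signal (and derivative) column mean-centred.
#' @export
normalize_surrogate <- function(series) {
  for (col in c(signal_cols(series), grep("^sdot[0-9]+$", names(series), value = TRUE))) {
    v <- series[[col]]
    if (sd(v) == 0) warning("surrogate column '", col, "' is constant; the model is degenerate")
    series[[col]] <- v - mean(v)
  }
  series
}

#' Temporal derivative of the surrogate signals
#'
#' Three-point finite differences honouring non-uniform sample spacing:
#' central differences on interior samples, one-sided at the ends.  Adds
#' `sdot<k>` columns to the series.
#'
#' @param series a [surrogate_series()] with strictly monotone times.
#' @param smooth_sigma optional Gaussian pre-smoothing width, in samples
#'   (default none).
#' @return The series with derivative columns filled.
#' @export
temporal_derivative <- function(series, smooth_sigma = 0) {
  t <- series$time
  if (any(diff(t) == 0)) stop("duplicate sample times")
  if (any(diff(t) < 0)) stop("sample times must be monotone")
  n <- length(t)
  for (col in signal_cols(series)) {
    v <- series[[col]]
    if (smooth_sigma > 0) {
      k <- gauss_kernel_cpp(smooth_sigma)
      r <- (length(k) - 1) / 2
      vp <- c(rep(v[1], r), v, rep(v[n], r))
      v <- as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + n)]
    }
    d <- numeric(n)
    d[1] <- (v[2] - v[1]) / (t[2] - t[1])
    d[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
    if (n > 2) {
      i <- 2:(n - 1)
      # exact for quadratics on non-uniform grids
      h1 <- t[i] - t[i - 1]; h2 <- t[i + 1] - t[i]
      d[i] <- (-h2 / (h1 * (h1 + h2))) * v[i - 1] +
        ((h2 - h1) / (h1 * h2)) * v[i] +
        (h1 / (h2 * (h1 + h2))) * v[i + 1]
    }
    series[[sub("^s", "sdot", col)]] <- d
  }
  series
}

#' Correspondence-model basis values
#'
#' Evaluates the basis vector `phi` for one surrogate sample, so that the
#' motion parameters are the linear combination `M_t = sum_n R_n * phi_n`:
#'
#' * `linear_sdot`: `phi = (s, sdot, 1)` — a linear model on the signal value
#'   and its temporal derivative, with a constant offset term.
#' * `poly2`: `phi = (s^2, s, 1)` — a second-order polynomial in one signal.
#' * `periodic_bspline`: `phi_n = B_{i+1}(j)` with
#'   `i = (n - 2 - floor(N_r * theta)) mod N_r` and
#'   `j = N_r * theta - floor(N_r * theta)`, where `B_1..B_4` are the cubic
#'   B-spline basis polynomials and terms with `i > 3` vanish; the basis is a
#'   partition of unity over the phase `theta` in `[0, 1)` and periodic across
#'   the wrap.
#'
#' @param kind one of `"linear_sdot"`, `"linear_sdot0"` (the same linear model
#'   without the constant term, for fits whose reference image is an MCIR and
#'   already sits at the mean position), `"poly2"`, `"periodic_bspline"`,
#'   `"direct"` (a single constant term: plain pairwise registration).
#' @param sample a named list / one-row data frame with the fields the kind
#'   requires (`s1` and `sdot1`; `s1`; `phase`).
#' @param n_terms number of terms for `periodic_bspline` (>= 4).
#' @return Numeric basis vector of length `N_r`.
#' @export
basis <- function(kind, sample, n_terms = 4) {
  switch(kind,
    linear_sdot = c(as.numeric(sample$s1), as.numeric(sample$sdot1), 1),
    linear_sdot0 = c(as.numeric(sample$s1), as.numeric(sample$sdot1)),
    poly2 = c(as.numeric(sample$s1)^2, as.numeric(sample$s1), 1),
    direct = 1,
    periodic_bspline = {
      if (n_terms < 4) stop("periodic_bspline needs at least 4 terms")
      th <- as.numeric(sample$phase)
      if (is.na(th)) stop("periodic_bspline requires a phase value")
      if (th < 0 || th >= 1) {
        warning("phase outside [0,1); wrapped modulo 1")
        th <- th - floor(th)
      }
      u <- n_terms * th
      j <- u - floor(u)
      B <- c((1 - j)^3 / 6, (3 * j^3 - 6 * j^2 + 4) / 6,
             (-3 * j^3 + 3 * j^2 + 3 * j + 1) / 6, j^3 / 6)
      phi <- numeric(n_terms)
      for (n in seq_len(n_terms)) {
        i <- (n - 2 - floor(u)) %% n_terms
        if (i <= 3) phi[n] <- B[i + 1]
      }
      phi
    },
    stop("unknown correspondence-model kind: ", kind)
  )
}

#' Basis-value matrix for a whole surrogate series
#'
#' @param kind model kind, see [basis()].
#' @param series a [surrogate_series()] (derivatives/phase filled as needed).
#' @param n_terms number of terms for `periodic_bspline`.
#' @return `N_frames x N_r` matrix of basis values.
#' @export
basis_matrix <- function(kind, series, n_terms = 4) {
  t(vapply(seq_len(nrow(series)),
           function(i) basis(kind, series[i, , drop = FALSE], n_terms),
           numeric(n_basis_terms(kind, n_terms))))
}

n_basis_terms <- function(kind, n_terms = 4) {
  switch(kind, linear_sdot = 3L, linear_sdot0 = 2L, poly2 = 3L, direct = 1L,
         periodic_bspline = as.integer(n_terms),
         stop("unknown correspondence-model kind: ", kind))
}

#' Correspondence model
#'
#' A model kind together with its fitted coefficient stack: `N_r` coefficient
#' sets, each shaped like the motion parameterisation (a control-point lattice
#' `K1 x K2 x 2`).  `M_t = sum_n R_n phi_n(S_t)` and the gradient of `M_t`
#' with respect to each `R_n` is the scalar `phi_n`.
#'
#' @param kind model kind, see [basis()].
#' @param coefficients list of `N_r` coefficient arrays of identical shape.
#' @param cpg template [control_point_grid()] describing the lattice geometry.
#' @return An object of class `corr_model`.
#' @export
corr_model <- function(kind, coefficients, cpg) {
  nr <- n_basis_terms(kind, length(coefficients))
  if (length(coefficients) != nr)
    stop("kind '", kind, "' needs ", nr, " coefficient sets")
  shp <- dim(coefficients[[1]])
  for (co in coefficients)
    if (!identical(dim(co), shp)) stop("coefficient set shapes differ")
  structure(list(kind = kind, n_terms = length(coefficients),
                 coefficients = coefficients, cpg = cpg),
            class = "corr_model")
}

#' @export
print.corr_model <- function(x, ...) {
  cat(sprintf("<corr_model> kind %s, %d coefficient sets on a %d x %d lattice (spacing %g px)\n",
              x$kind, x$n_terms, x$cpg$kdim[1], x$cpg$kdim[2], x$cpg$spacing))
  invisible(x)
}

#' Motion parameters from a correspondence model
#'
#' `M_t = sum_n R_n phi_n`: the weighted sum of the coefficient sets, shaped
#' like one coefficient set.  Returned as a [control_point_grid()] ready for
#' [evaluate_displacement()].
#'
#' @param model a [corr_model()].
#' @param phi basis vector of length `N_r` (from [basis()]).
#' @return A [control_point_grid()] holding `M_t`.
#' @export
model_motion <- function(model, phi) {
  if (length(phi) != model$n_terms) stop("basis vector length does not match the model")
  m <- model$coefficients[[1]] * phi[1]
  if (model$n_terms > 1)
    for (n in 2:model$n_terms) m <- m + model$coefficients[[n]] * phi[n]
  control_point_grid(model$cpg$img_dim, model$cpg$spacing, coef = m)
}

#' Dense model displacement field at one time-point
#'
#' @param model a [corr_model()].
#' @param sample one surrogate sample (row of a [surrogate_series()]).
#' @param rows optional row coordinates, see [evaluate_displacement()].
#' @return A [disp_field()].
#' @export
model_field <- function(model, sample, rows = NULL) {
  evaluate_displacement(model_motion(model, basis(model$kind, sample, model$n_terms)),
                        rows = rows)
}

#' Serialize / load a correspondence model
#'
#' The coefficient stack is written as a single NIfTI volume
#' (`K1 x K2 x 2*N_r`) with a JSON sidecar holding the kind, lattice spacing
#' and covered image size.
#'
#' @param model a [corr_model()].
#' @param path base path (without extension).
#' @name model-io
#' @export
write_model <- function(model, path) {
  arr <- array(unlist(model$coefficients),
               dim = c(model$cpg$kdim, 2L * model$n_terms))
  RNifti::writeNifti(RNifti::asNifti(arr), paste0(path, ".nii.gz"))
  meta <- list(kind = model$kind, n_terms = model$n_terms,
               spacing = model$cpg$spacing, img_dim = model$cpg$img_dim)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), paste0(path, ".json"))
  invisible(path)
}

#' @rdname model-io
#' @export
read_model <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  arr <- as.array(RNifti::readNifti(paste0(path, ".nii.gz")))
  cpg <- control_point_grid(meta$img_dim, meta$spacing)
  coefs <- lapply(seq_len(meta$n_terms), function(n)
    array(arr[, , (2 * n - 1):(2 * n)], dim = c(dim(arr)[1:2], 2L)))
  corr_model(meta$kind, coefs, cpg)
}

#' Read / write surrogate series as CSV
#'
#' Columns `time`, `s1..sNs`, optional `sdot*` and `phase`.
#'
#' @param series a [surrogate_series()].
#' @param path CSV path.
#' @name surrogate-io
#' @export
write_surrogate_csv <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname surrogate-io
#' @export
read_surrogate_csv <- function(path) {
  df <- read.csv(path)
  if (!"time" %in% names(df) || !"s1" %in% names(df))
    stop("surrogate CSV needs at least 'time' and 's1' columns")
  class(df) <- c("surrogate_series", "data.frame")
  df
}
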