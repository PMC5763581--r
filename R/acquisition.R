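#' Image acquisition specification
#'
#' Describes how one frame of dynamic data samples the full image:
#'
#' * `full` — the identity (a complete 2D frame);
#' * `slab` / `slice` — extraction of `n_rows` contiguous rows starting at
#'   0-based `row_start` (a slab of several rows, or a single thin row);
#' * `thick_slice` — convolution along the through-slice (row) axis with a
#'   Gaussian slice profile of standard deviation `profile_sigma` pixels
#'   (truncated at three sigma and renormalised to sum 1, zero-padded at the
#'   image boundary so the operator stays exactly linear and self-adjoint),
#'   followed by sampling of the specified row(s).
#'
#' @param mode one of `"full"`, `"slab"`, `"slice"`, `"thick_slice"`.
#' @param row_start 0-based first sampled row (ignored for `full`).
#' @param n_rows number of sampled rows.
#' @param profile_sigma Gaussian slice-profile sigma in pixels
#'   (`thick_slice` only; `FWHM = 2.3548 * sigma`).
#' @return An object of class `acq_spec`.
#' @export
acq_spec <- function(mode, row_start = 0L, n_rows = 1L, profile_sigma = NA_real_) {
  mode <- match.arg(mode, c("full", "slab", "slice", "thick_slice"))
  if (mode == "thick_slice" && (is.na(profile_sigma) || profile_sigma <= 0))
    stop("thick_slice requires profile_sigma > 0")
  structure(list(mode = mode, row_start = as.integer(row_start),
                 n_rows = as.integer(n_rows),
                 profile_sigma = as.numeric(profile_sigma)),
            class = "acq_spec")
}

spec_mode_code <- function(spec) {
  switch(spec$mode, full = 0L, slab = 1L, slice = 1L, thick_slice = 2L)
}

#' Gaussian slice-profile / resolution kernel
#'
#' Discrete Gaussian truncated at `ceil(3 sigma)` taps each side and
#' renormalised to sum 1.  `sigma_from_fwhm()` converts a slice thickness
#' (full width at half maximum) to the matching sigma.
#'
#' @param sigma standard deviation in pixels.
#' @return Numeric kernel of odd length.
#' @export
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  gauss_kernel_cpp(sigma)
}

#' @rdname gaussian_kernel
#' @param fwhm full width at half maximum (e.g. slice thickness) in pixels.
#' @export
sigma_from_fwhm <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Zero-padded convolution along the row axis; exactly linear and, because the
# kernel is symmetric, self-adjoint.
conv_rows <- function(m, sigma) {
  k <- gauss_kernel_cpp(sigma)
  rad <- (length(k) - 1) / 2
  nr <- nrow(m)
  out <- matrix(0, nr, ncol(m))
  for (i in seq_along(k)) {
    off <- i - 1 - rad
    src <- seq_len(nr) + off
    ok <- src >= 1 & src <= nr
    out[ok, ] <- out[ok, ] + k[i] * m[src[ok], , drop = FALSE]
  }
  out
}

check_spec_rows <- function(spec, nrow_img) {
  if (spec$mode == "full") return(invisible(TRUE))
  if (spec$row_start < 0 || spec$row_start + spec$n_rows > nrow_img)
    stop("acquisition rows [", spec$row_start, ", ",
         spec$row_start + spec$n_rows - 1, "] out of image bounds")
  invisible(TRUE)
}

#' Apply an acquisition operator
#'
#' Simulates the acquisition of one frame of (partial) data from a full image:
#' `full` is the identity, `slab`/`slice` extract rows, `thick_slice`
#' convolves along the through-slice axis with the Gaussian slice profile and
#' then samples the specified row(s).  Noise is never added here.
#'
#' @param image a `raster_image` or matrix (the full image).
#' @param spec an [acq_spec()].
#' @return A matrix of partial data (`n_rows x ncol`; the full image for
#'   `full` mode).
#' @export
acquire <- function(image, spec) {
  m <- as_matrix_image(image)
  check_spec_rows(spec, nrow(m))
  rows <- spec$row_start + seq_len(spec$n_rows)
  switch(spec$mode,
    full = m,
    slab = m[rows, , drop = FALSE],
    slice = m[rows, , drop = FALSE],
    thick_slice = conv_rows(m, spec$profile_sigma)[rows, , drop = FALSE])
}

#' Adjoint of an acquisition operator
#'
#' Maps partial data (or a similarity gradient in partial-data space) back to
#' full-image space: `full` is the identity, `slab`/`slice` embed the rows at
#' their location with zeros elsewhere, `thick_slice` embeds and then
#' convolves with the same Gaussian kernel.  Exact adjoint of [acquire()]
#' under the pixel-sum inner product.
#'
#' @param partial matrix of partial data shaped per `spec`.
#' @param spec an [acq_spec()].
#' @param img_dim length-2 full-image grid size.
#' @return A full-size matrix.
#' @export
acquire_adjoint <- function(partial, spec, img_dim) {
  partial <- as.matrix(partial)
  check_spec_rows(spec, img_dim[1])
  if (spec$mode == "full") {
    if (!identical(dim(partial), as.integer(img_dim))) stop("partial data shape mismatch")
    return(partial)
  }
  if (nrow(partial) != spec$n_rows || ncol(partial) != img_dim[2])
    stop("partial data shape mismatch")
  out <- matrix(0, img_dim[1], img_dim[2])
  out[spec$row_start + seq_len(spec$n_rows), ] <- partial
  if (spec$mode == "thick_slice") out <- conv_rows(out, spec$profile_sigma)
  out
}

# Rows of the full image that an acquisition touches (support of A_t / A*_t).
spec_support_rows <- function(spec, nrow_img) {
  if (spec$mode == "full") return(seq_len(nrow_img) - 1L)
  r0 <- spec$row_start; r1 <- spec$row_start + spec$n_rows - 1L
  if (spec$mode == "thick_slice") {
    rad <- (length(gauss_kernel_cpp(spec$profile_sigma)) - 1) / 2
    r0 <- max(0L, r0 - as.integer(rad))
    r1 <- min(nrow_img - 1L, r1 + as.integer(rad))
  }
  seq.int(r0, r1)
}
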