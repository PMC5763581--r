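#' Raster image
#'
#' A minimal 2D scalar image container: an intensity matrix plus per-axis pixel
#' spacing and the world coordinate of the centre of pixel (0, 0).  Pixel
#' coordinates are 0-based throughout the package, with axis 1 running down the
#' matrix rows (the through-slice axis for slice data) and axis 2 across the
#' columns.
#'
#' @param data numeric matrix of intensities.
#' @param spacing length-2 positive numeric, pixel size per axis.
#' @param origin length-2 numeric, world coordinate of pixel (0, 0).
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(data, spacing = c(1, 1), origin = c(0, 0)) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("image intensities must be finite")
  if (length(spacing) != 2 || any(spacing <= 0)) stop("spacing must be two positive values")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, spacing (%g, %g), range [%g, %g]\n",
              nrow(x$data), ncol(x$data), x$spacing[1], x$spacing[2],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$data)

#' @export
plot.raster_image <- function(x, ...) {
  graphics::image(t(x$data)[, nrow(x$data):1], asp = nrow(x$data) / ncol(x$data),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE, ...)
  invisible(x)
}

as_matrix_image <- function(x) {
  if (inherits(x, "raster_image")) x$data else as.matrix(x)
}

#' Displacement field
#'
#' A per-pixel 2-vector displacement in pixels on the grid of an associated
#' image, stored as an `nrow x ncol x 2` array: component 1 is the
#' row-direction (axis-1) displacement, component 2 the column-direction.
#'
#' @param dy,dx matrices of per-pixel displacements (pixels).
#' @return An object of class `disp_field`.
#' @export
disp_field <- function(dy, dx) {
  dy <- as.matrix(dy); dx <- as.matrix(dx)
  if (!identical(dim(dy), dim(dx))) stop("field components must share a grid")
  if (!all(is.finite(dy)) || !all(is.finite(dx))) stop("displacements must be finite")
  structure(list(dy = dy, dx = dx), class = "disp_field")
}

#' @export
print.disp_field <- function(x, ...) {
  m <- sqrt(x$dy^2 + x$dx^2)
  cat(sprintf("<disp_field> %d x %d px, |d| mean %.3g, max %.3g px\n",
              nrow(x$dy), ncol(x$dy), mean(m), max(m)))
  invisible(x)
}

#' @export
dim.disp_field <- function(x) dim(x$dy)

#' Read / write images as NIfTI
#'
#' 2D images are stored as degenerate 3D NIfTI volumes; displacement fields as
#' a 3D volume whose third dimension indexes the (row, column) components.
#'
#' @param x a `raster_image` or `disp_field`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @name nifti-io
#' @export
write_image_nifti <- function(x, path) {
  if (inherits(x, "disp_field")) {
    arr <- array(c(x$dy, x$dx), dim = c(dim(x$dy), 2))
    RNifti::writeNifti(RNifti::asNifti(arr), path)
  } else {
    img <- if (inherits(x, "raster_image")) x else raster_image(x)
    arr <- array(img$data, dim = c(dim(img$data), 1))
    nif <- RNifti::asNifti(arr, pixdim = c(img$spacing, 1))
    RNifti::writeNifti(nif, path)
  }
  invisible(path)
}

#' @rdname nifti-io
#' @param field logical, read back as a displacement field?
#' @export
read_image_nifti <- function(path, field = FALSE) {
  arr <- as.array(RNifti::readNifti(path))
  strip <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))
  if (field) {
    if (length(dim(arr)) != 3 || dim(arr)[3] != 2)
      stop("not a 2-component displacement field: ", path)
    return(disp_field(strip(arr[, , 1]), strip(arr[, , 2])))
  }
  pd <- attr(arr, "pixdim")
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  spacing <- if (!is.null(pd) && length(pd) >= 2 && all(pd[1:2] > 0)) pd[1:2] else c(1, 1)
  raster_image(strip(arr), spacing = spacing)
}
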