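#' Cubic B-spline control-point grid
#'
#' Parameterises one spatial transformation as a lattice of 2-vector
#' control-point displacements with uniform spacing (pixels, equal in both
#' directions).  Control point `a` (1-based storage index) sits at pixel
#' coordinate `(a - 3) * spacing` on its axis, so the lattice covers the image
#' domain plus one B-spline support knot of margin on every side, and every
#' pixel of an `img_dim` image is supported by a full 4 x 4 neighbourhood.
#'
#' @param img_dim length-2 integer, the image grid the lattice covers.
#' @param spacing control-point spacing in pixels (>= 1).
#' @param coef optional coefficient array `K1 x K2 x 2` (row-displacement
#'   component first); defaults to all zero (identity transform).
#' @return An object of class `cpg`.
#' @export
control_point_grid <- function(img_dim, spacing, coef = NULL) {
  if (spacing < 1) stop("control-point spacing must be >= 1 pixel")
  img_dim <- as.integer(img_dim)
  if (any(img_dim < 1)) stop("image grid dimensions must be >= 1")
  kdim <- floor((img_dim - 1) / spacing) + 4L
  if (is.null(coef)) coef <- array(0, dim = c(kdim, 2L))
  coef <- as.array(coef)
  if (!identical(dim(coef)[1:2], as.integer(kdim)) || dim(coef)[3] != 2L)
    stop("coefficient array must be ", kdim[1], " x ", kdim[2], " x 2")
  structure(list(coef = coef, spacing = as.numeric(spacing),
                 img_dim = img_dim, kdim = as.integer(kdim)),
            class = "cpg")
}

#' @export
print.cpg <- function(x, ...) {
  cat(sprintf("<cpg> %d x %d control points, spacing %g px, image %d x %d\n",
              x$kdim[1], x$kdim[2], x$spacing, x$img_dim[1], x$img_dim[2]))
  invisible(x)
}

#' Evaluate a control-point grid as a dense displacement field
#'
#' Cubic B-spline tensor interpolation of the control-point displacements at
#' every pixel of the covered grid (or at the given, possibly fractional, row
#' coordinates).  The four basis functions form an exact partition of unity, so
#' constant coefficients give an exactly constant field.
#'
#' @param cpg a [control_point_grid()].
#' @param rows optional 0-based row coordinates to evaluate at (default: all
#'   integer rows of the covered grid).
#' @return A [disp_field()] on `length(rows) x img_dim[2]`.
#' @export
evaluate_displacement <- function(cpg, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(cpg$img_dim[1]) - 1
  r <- eval_disp_rows_cpp(cpg$coef, cpg$kdim, cpg$spacing, as.numeric(rows),
                          cpg$img_dim[2])
  disp_field(r$fy, r$fx)
}

#' Project a pixel-space gradient onto control-point space
#'
#' The exact transpose of [evaluate_displacement()]'s linear map: each control
#' point receives the B-spline-basis-weighted sum of the per-pixel gradient
#' vectors inside its support.  Used to turn the similarity gradient with
#' respect to the deformed image into a gradient with respect to the
#' transformation parameters.
#'
#' @param gradient a [disp_field()]-like pair of matrices (per-pixel gradient
#'   with respect to the row/column displacement components) on the image grid
#'   covered by `cpg`.
#' @param cpg a [control_point_grid()].
#' @param rows optional 0-based row coordinates matching `gradient`'s rows.
#' @return A coefficient-shaped array `K1 x K2 x 2`.
#' @export
project_gradient_to_cpg <- function(gradient, cpg, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(gradient$dy)) - 1
  if (ncol(gradient$dy) != cpg$img_dim[2])
    stop("gradient grid does not match the grid covered by the control points")
  proj_cpg_rows_cpp(gradient$dy, gradient$dx, cpg$kdim, cpg$spacing,
                    as.numeric(rows))
}

#' Pull-interpolation warp
#'
#' `output(x) = image(x + field(x))` with bilinear interpolation; out-of-bounds
#' samples take `pad`.  The output lives on the grid of `field`.
#'
#' @param image a `raster_image` or matrix (the moving image).
#' @param field a [disp_field()] (displacements in pixels of the output grid).
#' @param pad padding intensity for out-of-bounds samples.
#' @param rows optional 0-based row coordinates of `field`'s rows in the output
#'   grid (defaults to `0:(nrow-1)`).
#' @return A matrix shaped like `field`.
#' @export
warp_pull <- function(image, field, pad = 0, rows = NULL) {
  img <- as_matrix_image(image)
  if (is.null(rows)) rows <- seq_len(nrow(field$dy)) - 1
  warp_rows_cpp(img, field$dy, field$dx, as.numeric(rows), pad, FALSE)$warped
}

#' Push-interpolation warp (adjoint of the pull warp)
#'
#' Each input pixel's intensity is splatted with bilinear weights to the four
#' output pixels around its pushed position `x + field(x)`; the weight image
#' accumulates the same splat weights.  With zero padding this is the exact
#' adjoint of [warp_pull()] under the pixel-sum inner product.
#'
#' @param image a `raster_image` or matrix of values to push.
#' @param field a [disp_field()] defined on `image`'s grid.
#' @param out_dim length-2 output grid size (default: same as input).
#' @param rows optional 0-based source row coordinates.
#' @return `list(accumulated =, weights =)` matrices on `out_dim`.
#' @export
warp_push <- function(image, field, out_dim = NULL, rows = NULL) {
  img <- as_matrix_image(image)
  if (is.null(out_dim)) out_dim <- dim(img)
  if (is.null(rows)) rows <- seq_len(nrow(img)) - 1
  r <- push_rows_cpp(img, field$dy, field$dx, as.numeric(rows),
                     as.integer(out_dim[1]), as.integer(out_dim[2]))
  list(accumulated = r$acc, weights = r$wgt)
}

#' Finite-difference spatial image gradient
#'
#' Central differences in the interior, one-sided at the borders; units are
#' intensity per pixel.
#'
#' @param image a `raster_image` or matrix (>= 3 pixels per axis).
#' @return `list(dy =, dx =)` matrices of the axis-1 and axis-2 derivatives.
#' @export
image_gradient <- function(image) {
  m <- as_matrix_image(image)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) stop("image must be at least 3 pixels per axis")
  dy <- m; dx <- m
  dy[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  dy[1, ] <- m[2, ] - m[1, ]
  dy[nr, ] <- m[nr, ] - m[nr - 1, ]
  dx[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  dx[, 1] <- m[, 2] - m[, 1]
  dx[, nc] <- m[, nc] - m[, nc - 1]
  list(dy = dy, dx = dx)
}
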