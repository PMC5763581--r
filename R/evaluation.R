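#' Displacement-field-error statistics
#'
#' Pools the per-pixel 2D Euclidean distance between true and estimated
#' displacement fields over all masked pixels of all frames and returns the
#' mean, standard deviation and 95th percentile (linear interpolation between
#' order statistics).  Passing zero estimated fields gives the no-motion
#' baseline, i.e. the magnitude of the motion present in the data.
#'
#' @param true_fields list of [disp_field()] (one per frame).
#' @param est_fields list of [disp_field()] of matching shapes, or `NULL` for
#'   the no-motion baseline.
#' @param masks list of logical matrices (pixels to pool); `NULL` pools all.
#' @return A one-row `data.frame` with `mean`, `sd`, `p95`, `n`.
#' @export
dfe_stats <- function(true_fields, est_fields = NULL, masks = NULL) {
  ds <- unlist(lapply(seq_along(true_fields), function(t) {
    tf <- true_fields[[t]]
    ey <- if (is.null(est_fields)) 0 else est_fields[[t]]$dy
    ex <- if (is.null(est_fields)) 0 else est_fields[[t]]$dx
    if (!is.null(est_fields) && !identical(dim(tf$dy), dim(est_fields[[t]]$dy)))
      stop("field shapes differ for frame ", t)
    d <- sqrt((tf$dy - ey)^2 + (tf$dx - ex)^2)
    if (is.null(masks)) as.numeric(d) else d[masks[[t]]]
  }))
  if (length(ds) == 0) stop("empty mask union: no pixels to pool")
  data.frame(mean = mean(ds), sd = sd(ds),
             p95 = as.numeric(quantile(ds, 0.95)), n = length(ds))
}

#' Agreement between a reconstruction and the true image
#'
#' Absolute intensity difference statistics (mean, standard deviation, 95th
#' percentile) and the Pearson correlation coefficient over masked pixels.
#'
#' @param I0 reconstructed image (`raster_image` or matrix).
#' @param I_true true image, same grid.
#' @param mask logical matrix (default: all pixels).
#' @return A one-row `data.frame` with `mean`, `sd`, `p95`, `r`, `n`.
#' @export
image_agreement <- function(I0, I_true, mask = NULL) {
  a <- as_matrix_image(I0); b <- as_matrix_image(I_true)
  if (!identical(dim(a), dim(b))) stop("images must share a grid")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(a), ncol(a))
  av <- a[mask]; bv <- b[mask]
  d <- abs(av - bv)
  r <- if (sd(av) == 0 || sd(bv) == 0) NA_real_ else cor(av, bv)
  data.frame(mean = mean(d), sd = sd(d), p95 = as.numeric(quantile(d, 0.95)),
             r = r, n = length(d))
}

#' Snap-to-voxel landmark error
#'
#' Propagates each reference landmark by the displacement field (bilinear
#' interpolation of the field at the landmark), snaps the propagated position
#' to the nearest voxel centre (and optionally the target landmark too), and
#' reports Euclidean distance statistics in millimetres.  A zero field
#' measures the raw motion magnitude.  Landmarks outside the field domain are
#' excluded with a warning.
#'
#' @param landmarks_ref,landmarks_target `n x 2` matrices of 0-based (row,
#'   col) pixel positions, matched by row.
#' @param field a [disp_field()] (or `NULL` for zero field).
#' @param voxel_size length-2 voxel size in mm.
#' @param snap_target snap the target landmark as well? (default `TRUE`).
#' @return A one-row `data.frame` with `mean`, `sd`, `p95`, `n`.
#' @export
landmark_error <- function(landmarks_ref, landmarks_target, field = NULL,
                           voxel_size = c(1, 1), snap_target = TRUE) {
  ref <- as.matrix(landmarks_ref); tgt <- as.matrix(landmarks_target)
  if (nrow(ref) != nrow(tgt)) stop("landmark lists must be matched")
  interp_field <- function(p) {
    if (is.null(field)) return(c(0, 0))
    nr <- nrow(field$dy); nc <- ncol(field$dy)
    if (p[1] < 0 || p[1] > nr - 1 || p[2] < 0 || p[2] > nc - 1) return(NULL)
    iy <- min(floor(p[1]), nr - 2); ix <- min(floor(p[2]), nc - 2)
    dy <- p[1] - iy; dx <- p[2] - ix
    bil <- function(m) (1 - dy) * ((1 - dx) * m[iy + 1, ix + 1] + dx * m[iy + 1, ix + 2]) +
      dy * ((1 - dx) * m[iy + 2, ix + 1] + dx * m[iy + 2, ix + 2])
    c(bil(field$dy), bil(field$dx))
  }
  errs <- numeric(0)
  dropped <- 0L
  for (i in seq_len(nrow(ref))) {
    d <- interp_field(ref[i, ])
    if (is.null(d)) { dropped <- dropped + 1L; next }
    prop <- round(ref[i, ] + d)
    t2 <- if (snap_target) round(tgt[i, ]) else tgt[i, ]
    errs <- c(errs, sqrt(sum(((prop - t2) * voxel_size)^2)))
  }
  if (dropped > 0) warning(dropped, " landmark(s) outside the field domain excluded")
  data.frame(mean = mean(errs), sd = sd(errs),
             p95 = as.numeric(quantile(errs, 0.95)), n = length(errs))
}

#' Pooled DFE statistics for a phantom dataset and fitted model
#'
#' Streams the per-pixel displacement-field error over every pixel inside the
#' deformed phantom for every time-point (exact mean and standard deviation; a
#' 0.005-px-bin histogram percentile), comparing the dataset's known true
#' fields with the dense field of the fitted model — or with zero motion when
#' `model` is `NULL`.
#'
#' @param dataset a `phantom_dataset`.
#' @param model a fitted [corr_model()] on the dataset's grid, or `NULL`.
#' @return A one-row `data.frame` with `mean`, `sd`, `p95`, `n`.
#' @export
model_dfe_stats <- function(dataset, model = NULL) {
  maps <- dataset$maps
  sur <- dataset$surrogate
  body <- dataset$body_mask * 1
  if (is.null(model)) {
    st <- dfe_stream_cpp(maps$my1, maps$my2, maps$mx1, maps$mx2,
                         sur$s1, sur$sdot1, body, NULL, NULL,
                         integer(2), 1, 0.005, 20000L)
  } else {
    Phi <- basis_matrix(model$kind, sur, model$n_terms)
    st <- dfe_stream_cpp(maps$my1, maps$my2, maps$mx1, maps$mx2,
                         sur$s1, sur$sdot1, body, model$coefficients, Phi,
                         model$cpg$kdim, model$cpg$spacing, 0.005, 20000L)
  }
  stats_from_stream(st)
}

stats_from_stream <- function(st) {
  n <- st$n
  m <- st$sum / n
  v <- (st$sumsq - n * m^2) / (n - 1)
  cum <- cumsum(st$hist)
  target <- 0.95 * n
  b <- which(cum >= target)[1]
  inbin <- st$hist[b]
  frac <- if (inbin > 0) (target - (cum[b] - inbin)) / inbin else 0.5
  p95 <- (b - 1 + frac) * st$bin_width
  data.frame(mean = m, sd = sqrt(v), p95 = p95, n = n)
}

#' Read a plain-text landmark file
#'
#' Parses whitespace-separated landmark coordinate files (one landmark per
#' line, two or three numeric coordinates per line, as distributed with
#' public thoracic-CT landmark sets).  Coordinates are returned as given;
#' pair two files and a fitted field with [landmark_error()].
#'
#' @param path text file path.
#' @return A numeric matrix with one row per landmark.
#' @export
read_landmarks <- function(path) {
  m <- as.matrix(read.table(path))
  if (ncol(m) < 2 || !is.numeric(m)) stop("not a landmark coordinate table: ", path)
  dimnames(m) <- NULL
  m
}
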