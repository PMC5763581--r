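test_that("B-spline evaluation satisfies partition of unity and identity", {
  cpg <- control_point_grid(c(20, 17), 4)
  expect_equal(evaluate_displacement(cpg)$dy, matrix(0, 20, 17))
  cpg$coef[, , 1] <- 2.5
  cpg$coef[, , 2] <- -1.25
  f <- evaluate_displacement(cpg)
  expect_equal(max(abs(f$dy - 2.5)), 0, tolerance = 1e-12)
  expect_equal(max(abs(f$dx + 1.25)), 0, tolerance = 1e-12)
})

test_that("B-spline evaluation matches the direct 16-term tensor sum", {
  cpg <- random_cpg(c(20, 20), spacing = 4, seed = 11)
  f <- evaluate_displacement(cpg)
  # independent oracle: brute-force 16-term sum at one probe pixel
  B <- function(a, j) switch(a, (1 - j)^3 / 6, (3 * j^3 - 6 * j^2 + 4) / 6,
                             (-3 * j^3 + 3 * j^2 + 3 * j + 1) / 6, j^3 / 6)
  probe <- c(7, 13)  # 0-based (row, col)
  for (comp in 1:2) {
    acc <- 0
    u <- probe / 4
    l <- floor(u)
    j <- u - l
    for (a in 1:4) for (b in 1:4)
      acc <- acc + B(a, j[1]) * B(b, j[2]) * cpg$coef[l[1] + a, l[2] + b, comp]
    expect_equal(unname(if (comp == 1) f$dy else f$dx)[probe[1] + 1, probe[2] + 1],
                 acc, tolerance = 1e-12)
  }
})

test_that("evaluation errors when the grid leaves the control-point support", {
  cpg <- random_cpg(c(20, 17), spacing = 3)
  expect_error(evaluate_displacement(cpg, rows = c(0, 25)), "support")
})

test_that("pull warp: identity, analytic shift, and bilinear oracle", {
  img <- random_image()
  zero <- disp_field(matrix(0, 20, 17), matrix(0, 20, 17))
  expect_identical(warp_pull(img, zero), img)

  ramp <- matrix(rep(0:16, each = 20), 20, 17) * 10
  shift <- disp_field(matrix(0, 20, 17), matrix(1, 20, 17))
  w <- warp_pull(ramp, shift)
  expect_equal(w[, 1:15], ramp[, 2:16])

  fld <- random_field(seed = 21)
  w <- warp_pull(img, fld, pad = -5)
  # independent per-pixel bilinear lookup
  for (k in 1:25) {
    set.seed(30 + k)
    r <- sample(20, 1); c <- sample(17, 1)
    y <- (r - 1) + fld$dy[r, c]; x <- (c - 1) + fld$dx[r, c]
    iy <- floor(y); ix <- floor(x); dy <- y - iy; dx <- x - ix
    g <- function(rr, cc) if (rr < 0 || rr > 19 || cc < 0 || cc > 16) -5 else img[rr + 1, cc + 1]
    v <- (1 - dy) * ((1 - dx) * g(iy, ix) + dx * g(iy, ix + 1)) +
      dy * ((1 - dx) * g(iy + 1, ix) + dx * g(iy + 1, ix + 1))
    expect_equal(w[r, c], v, tolerance = 1e-12)
  }
})

test_that("push warp splats intensities and weights correctly", {
  img <- matrix(0, 9, 9); img[5, 5] <- 8
  zero <- disp_field(matrix(0, 9, 9), matrix(0, 9, 9))
  p <- warp_push(img, zero)
  expect_equal(p$accumulated, img)
  expect_equal(p$weights, matrix(1, 9, 9))

  half <- disp_field(matrix(0.5, 9, 9), matrix(0, 9, 9))
  p <- warp_push(img, half)
  expect_equal(p$accumulated[5, 5], 4)
  expect_equal(p$accumulated[6, 5], 4)
  expect_equal(p$weights[5, 5], 0.5 + 0.5)  # in-flow from rows 4 and 5
})

test_that("pull/push and evaluate/project are exact adjoint pairs", {
  set.seed(42)
  for (k in 1:20) {
    img <- random_image(seed = 100 + k)
    fld <- random_field(seed = 200 + k)
    v <- matrix(rnorm(20 * 17), 20, 17)
    lhs <- sum(warp_pull(img, fld, pad = 0) * v)
    rhs <- sum(img * warp_push(v, fld)$accumulated)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)

    cpg <- random_cpg(seed = 300 + k)
    g <- list(dy = matrix(rnorm(20 * 17), 20), dx = matrix(rnorm(20 * 17), 20))
    f <- evaluate_displacement(cpg)
    lhs <- sum(f$dy * g$dy) + sum(f$dx * g$dx)
    rhs <- sum(cpg$coef * project_gradient_to_cpg(g, cpg))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  }
})

test_that("delta pixel gradient projects the tensor kernel onto one control point", {
  cpg <- control_point_grid(c(13, 13), 4)
  g <- list(dy = matrix(0, 13, 13), dx = matrix(0, 13, 13))
  g$dy[9, 9] <- 1   # 0-based pixel (8, 8) = control-point position (8/4=2 exactly)
  G <- project_gradient_to_cpg(g, cpg)
  # at a lattice-coincident pixel the collocated control point gets B2(0)^2
  expect_equal(G[4, 4, 1], (4 / 6)^2, tolerance = 1e-12)
  expect_equal(sum(G[, , 1]), 1, tolerance = 1e-12)  # partition of unity
  expect_equal(max(abs(G[, , 2])), 0)
})

test_that("image gradient uses central differences with one-sided borders", {
  const <- matrix(7, 5, 6)
  g <- image_gradient(const)
  expect_equal(max(abs(g$dy)), 0)
  expect_equal(max(abs(g$dx)), 0)

  ramp <- matrix(rep(seq(0, 25, 5), each = 5), 5, 6)
  g <- image_gradient(ramp)
  expect_equal(g$dx[3, 3], 5)
  expect_equal(g$dy[3, 3], 0)

  img <- random_image(7, 8, seed = 9)
  g <- image_gradient(img)
  expect_equal(g$dy[4, 5], (img[5, 5] - img[3, 5]) / 2)
  expect_equal(g$dx[4, 5], (img[4, 6] - img[4, 4]) / 2)
  expect_equal(g$dy[1, 5], img[2, 5] - img[1, 5])
})

test_that("displacement fields round-trip through NIfTI", {
  fld <- random_field(seed = 77)
  path <- tempfile(fileext = ".nii.gz")
  write_image_nifti(fld, path)
  back <- read_image_nifti(path, field = TRUE)
  expect_equal(back$dy, fld$dy, tolerance = 1e-6)
  expect_equal(back$dx, fld$dx, tolerance = 1e-6)
})
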