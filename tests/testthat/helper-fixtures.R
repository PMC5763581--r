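# Small seeded fixtures shared across test files.

random_image <- function(nr = 20, nc = 17, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nr * nc, mean = 500, sd = 200), nr, nc)
}

random_field <- function(nr = 20, nc = 17, sd = 1.5, seed = 2) {
  set.seed(seed)
  disp_field(matrix(rnorm(nr * nc, sd = sd), nr, nc),
             matrix(rnorm(nr * nc, sd = sd), nr, nc))
}

random_cpg <- function(img_dim = c(20, 17), spacing = 3, sd = 1, seed = 3) {
  cpg <- control_point_grid(img_dim, spacing)
  set.seed(seed)
  control_point_grid(img_dim, spacing,
                     coef = array(rnorm(prod(dim(cpg$coef)), sd = sd),
                                  dim(cpg$coef)))
}

# A small structured image with gradients everywhere, for fitting tests.
bump_image <- function(n = 32, seed = 4) {
  set.seed(seed)
  x <- 0:(n - 1)
  img <- outer(exp(-(x - n * 0.45)^2 / (n * 1.2)), exp(-(x - n * 0.55)^2 / (n * 1.6))) * 1000
  img <- img + outer(exp(-(x - n * 0.7)^2 / n), exp(-(x - n * 0.25)^2 / n)) * 700
  img + matrix(runif(n * n, 0, 40), n, n)
}

# Tiny synthetic dynamic dataset generated by a known linear model on a
# smooth bump image; motion representable on the fit lattice.
toy_linear_dataset <- function(n = 32, n_frames = 6, amp = 1.5, noise = 0,
                               spacing = 8, seed = 5) {
  img <- bump_image(n, seed = seed)
  set.seed(seed + 1)
  s <- sin(seq(0, 2 * pi, length.out = n_frames + 1))[1:n_frames]
  sur <- temporal_derivative(surrogate_series(time = seq_len(n_frames) - 1, values = s))
  sur <- normalize_surrogate(sur)
  cpg <- control_point_grid(c(n, n), spacing)
  smooth_coef <- function(sd) {
    k <- dim(cpg$coef)
    co <- array(rnorm(prod(k), sd = sd), k)
    co[] <- apply(co, 3, function(m) {
      m[, ] <- outer(exp(-((seq_len(k[1]) - k[1] / 2)^2) / k[1]),
                     exp(-((seq_len(k[2]) - k[2] / 2)^2) / k[2])) * sd * 3
      m
    })
    co
  }
  R1 <- smooth_coef(amp)
  R2 <- smooth_coef(amp * 0.3)
  R3 <- array(0, dim(cpg$coef))
  model <- corr_model("linear_sdot", list(R1, R2, R3), cpg)
  frames <- lapply(seq_len(n_frames), function(t) {
    fld <- model_field(model, sur[t, ])
    w <- warp_pull(img, fld)
    if (noise > 0) w <- w + matrix(rnorm(n * n, sd = noise), n)
    w
  })
  list(img = img, surrogate = sur, frames = frames,
       specs = rep(list(acq_spec("full")), n_frames), model = model,
       cpg = cpg)
}
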