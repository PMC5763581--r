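test_that("SSD cost and gradient have their closed forms", {
  P <- matrix(c(0, 1), 1, 2)
  sg <- ssd_and_gradient(P, P)
  expect_equal(sg$cost, 0)
  expect_equal(max(abs(sg$gradient)), 0)
  sg <- ssd_and_gradient(matrix(0), matrix(3))
  expect_equal(sg$cost, 9)
  expect_equal(sg$gradient, matrix(6))
  expect_error(ssd_and_gradient(matrix(0, 2, 2), matrix(0, 3, 2)), "shape")

  set.seed(12)
  P <- matrix(rnorm(12), 3)
  PA <- matrix(rnorm(12), 3)
  sg <- ssd_and_gradient(P, PA)
  h <- 1e-6
  for (i in c(1, 7)) {
    PAp <- PA; PAp[i] <- PAp[i] + h
    fd <- (ssd_and_gradient(P, PAp)$cost - sg$cost) / h
    expect_equal(fd, sg$gradient[i], tolerance = 1e-5)
  }
})

test_that("frame cost is zero for self-consistent data and its gradient matches finite differences", {
  toy <- toy_linear_dataset(n = 32, n_frames = 4, spacing = 8)
  # data generated from (I0, model) at the current coefficients -> cost ~ 0
  fg <- frame_cost_gradient(toy$frames[[2]], toy$img, toy$model,
                            toy$surrogate[2, ], toy$specs[[2]])
  expect_lt(fg$cost, 1e-14 * sum(toy$frames[[2]]^2))
  expect_lt(max(abs(fg$gradients[[1]])), 1e-6)

  # zero model and static data
  zero_model <- corr_model("linear_sdot",
                           lapply(1:3, function(i) array(0, dim(toy$cpg$coef))),
                           toy$cpg)
  fg0 <- frame_cost_gradient(acquire(toy$img, acq_spec("slab", 4, 10)), toy$img,
                             zero_model, toy$surrogate[1, ],
                             acq_spec("slab", 4, 10))
  expect_equal(fg0$cost, 0)

  # random instance: central finite differences over sampled coefficients
  set.seed(13)
  coefs <- lapply(1:3, function(i) array(rnorm(prod(dim(toy$cpg$coef)), sd = 0.4),
                                         dim(toy$cpg$coef)))
  model <- corr_model("linear_sdot", coefs, toy$cpg)
  spec <- acq_spec("thick_slice", row_start = 10, n_rows = 3, profile_sigma = 1.8)
  P <- matrix(rnorm(3 * 32, 300, 150), 3)
  fg <- frame_cost_gradient(P, toy$img, model, toy$surrogate[3, ], spec)
  h <- 1e-5
  for (k in 1:20) {
    nidx <- sample(3, 1)
    idx <- sample(length(coefs[[1]]), 1)
    cp <- coefs; cp[[nidx]][idx] <- cp[[nidx]][idx] + h
    cm <- coefs; cm[[nidx]][idx] <- cm[[nidx]][idx] - h
    fp <- frame_cost_gradient(P, toy$img, corr_model("linear_sdot", cp, toy$cpg),
                              toy$surrogate[3, ], spec)$cost
    fm <- frame_cost_gradient(P, toy$img, corr_model("linear_sdot", cm, toy$cpg),
                              toy$surrogate[3, ], spec)$cost
    fd <- (fp - fm) / (2 * h)
    an <- fg$gradients[[nidx]][idx]
    if (max(abs(fd), abs(an)) > 1e-4)
      expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 1e-4)
  }
})

test_that("the fused multi-frame driver equals the sum of composed per-frame paths", {
  toy <- toy_linear_dataset(n = 32, n_frames = 5, spacing = 8)
  set.seed(14)
  coefs <- lapply(1:3, function(i) array(rnorm(prod(dim(toy$cpg$coef)), sd = 0.3),
                                         dim(toy$cpg$coef)))
  model <- corr_model("linear_sdot", coefs, toy$cpg)
  specs <- list(acq_spec("full"), acq_spec("slab", 6, 12),
                acq_spec("slice", 20, 1),
                acq_spec("thick_slice", 15, 2, profile_sigma = 2.1),
                acq_spec("full"))
  frames <- lapply(specs, function(s) {
    d <- acquire(toy$img, s)
    d + matrix(rnorm(length(d), sd = 30), nrow(d))
  })
  Phi <- basis_matrix("linear_sdot", toy$surrogate)
  enc <- respfit:::encode_specs(specs)
  fused <- respfit:::total_cost_grad(toy$img, coefs, Phi, frames, enc,
                                     toy$cpg$kdim, toy$cpg$spacing, 0, TRUE)
  tot <- 0
  gr <- lapply(1:3, function(i) array(0, dim(toy$cpg$coef)))
  for (t in 1:5) {
    fg <- frame_cost_gradient(frames[[t]], toy$img, model, toy$surrogate[t, ],
                              specs[[t]])
    tot <- tot + fg$cost
    for (n in 1:3) gr[[n]] <- gr[[n]] + fg$gradients[[n]]
  }
  expect_equal(fused$cost, tot, tolerance = 1e-12)
  for (n in 1:3) expect_equal(fused$grads[[n]], gr[[n]], tolerance = 1e-10)
})

test_that("zero-motion data recovers a near-zero model", {
  img <- bump_image(48)
  n_frames <- 5
  sur <- normalize_surrogate(temporal_derivative(
    surrogate_series(time = 0:(n_frames - 1), values = sin(1:n_frames))))
  frames <- lapply(seq_len(n_frames), function(t)
    img + matrix(rnorm(48 * 48, sd = 10), 48))
  m <- fit_model(frames, rep(list(acq_spec("full")), n_frames), sur, img,
                 "linear_sdot", fit_config(cpg_spacing = 8, levels = 2, max_iter = 40))
  f <- model_field(m, sur[2, ])
  expect_lt(mean(sqrt(f$dy^2 + f$dx^2)), 0.1)
})

test_that("representable motion is recovered far below the no-motion error", {
  toy <- toy_linear_dataset(n = 48, n_frames = 6, amp = 1.2, noise = 0, spacing = 8)
  m <- fit_model(toy$frames, toy$specs, toy$surrogate, toy$img, "linear_sdot",
                 fit_config(cpg_spacing = 8, levels = 2, max_iter = 80))
  true_fields <- lapply(1:6, function(t) model_field(toy$model, toy$surrogate[t, ]))
  est_fields <- lapply(1:6, function(t) model_field(m, toy$surrogate[t, ]))
  no_motion <- dfe_stats(true_fields)
  fitted <- dfe_stats(true_fields, est_fields)
  expect_lt(fitted$mean, 0.1 * no_motion$mean)
  # cost trace is monotone non-increasing within each level
  for (tr in attr(m, "trace")) expect_true(all(diff(tr) <= 1e-9))
})

test_that("a one-frame fit reduces to plain pairwise registration", {
  toy <- toy_linear_dataset(n = 32, n_frames = 3, amp = 1.0, spacing = 8)
  frame <- toy$frames[[2]]
  direct <- register_pair(frame, acq_spec("full"), toy$img,
                          fit_config(cpg_spacing = 8, levels = 2, max_iter = 60))
  sur1 <- toy$surrogate[2, , drop = FALSE]
  class(sur1) <- c("surrogate_series", "data.frame")
  lin <- fit_model(list(frame), list(acq_spec("full")), sur1, toy$img,
                   "linear_sdot", fit_config(cpg_spacing = 8, levels = 2, max_iter = 60))
  f_direct <- evaluate_displacement(model_motion(direct, 1))
  f_lin <- model_field(lin, sur1[1, ])
  # same optimum in M: fields agree and both match the generating motion
  f_true <- model_field(toy$model, sur1[1, ])
  expect_lt(mean(abs(f_direct$dy - f_lin$dy)), 0.08)
  expect_lt(mean(abs(f_direct$dx - f_lin$dx)), 0.08)
  expect_lt(mean(sqrt((f_direct$dy - f_true$dy)^2 + (f_direct$dx - f_true$dx)^2)), 0.15)
})
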