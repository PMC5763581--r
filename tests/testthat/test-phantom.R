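test_that("the phantom is deterministic, scaled to max intensity, and lung-contrasted", {
  p1 <- make_phantom(128, seed = 3)
  p2 <- make_phantom(128, seed = 3)
  expect_identical(p1$data, p2$data)
  expect_equal(max(p1$data), 1500)
  lung <- attr(p1, "lung_mask")
  body <- attr(p1, "body_mask")
  expect_lt(mean(p1$data[lung]), mean(p1$data[body & !lung]))
  outside <- !body & respfit:::gauss_smooth(body * 1, 3) < 0.01
  expect_lt(max(p1$data[outside]), 10)  # air stays air away from the edge bleed
})

test_that("parameter maps are smooth, enveloped, and zero at zero amplitude", {
  z <- make_parameter_maps(96, amplitude = 0, seed = 1)
  expect_equal(max(abs(unlist(z))), 0)
  m <- make_parameter_maps(128, smoothness = 20, amplitude = 4, seed = 2)
  for (map in m) {
    g <- image_gradient(map)
    expect_lt(max(sqrt(g$dy^2 + g$dx^2)), 4 / 4)  # bounded pixelwise gradient
  }
  # motion vanishes outside the body
  geom <- respfit:::phantom_geometry(128)
  expect_lt(max(abs(m$my1[!geom$body])), 1e-8)
})

test_that("the thin-slice regime doubles the motion amplitude", {
  d1 <- simulate_dataset(phantom_spec("slab", size = 68, seed = 5, amplitude = 2,
                                      noise_sigma_fraction = 0))
  d2 <- simulate_dataset(phantom_spec("thin_slice", size = 68, seed = 5, amplitude = 2,
                                      noise_sigma_fraction = 0))
  expect_equal(max(abs(d2$maps$my1)) / max(abs(d1$maps$my1)), 2, tolerance = 1e-10)
})

test_that("surrogate generators are normalized, phased, and jitter-controlled", {
  s <- make_surrogate("cos4", 10)
  expect_equal(mean(s$s1), 0, tolerance = 1e-12)
  expect_equal(s$phase, (0:9) / 10)
  # symmetric about the mid-cycle before normalization: s(k) = s(n-k)
  raw <- cos(pi * (0:9) / 10)^4
  expect_equal(raw[2:10], rev(raw[2:10]))

  q <- make_surrogate("quasiperiodic", 200, seed = 4, dt = 0.1,
                      amp_jitter = 0, period_jitter = 0)
  expect_equal(mean(q$s1), 0, tolerance = 1e-12)
  # zero jitter -> exactly periodic: cycle-to-cycle identical (period 4s = 40 samples)
  expect_equal(q$s1[1:40], q$s1[41:80], tolerance = 1e-10)
  qj <- make_surrogate("quasiperiodic", 200, seed = 4, dt = 0.1)
  expect_gt(max(abs(qj$s1[1:40] - qj$s1[41:80])), 0.01)
})

test_that("datasets are reproducible and noise lives only in the frames", {
  sp <- phantom_spec("slab", size = 68, seed = 11, amplitude = 2)
  d1 <- simulate_dataset(sp)
  d2 <- simulate_dataset(sp)
  expect_identical(d1$frames, d2$frames)
  expect_identical(d1$maps, d2$maps)
  d0 <- simulate_dataset(phantom_spec("slab", size = 68, seed = 11, amplitude = 2,
                                      noise_sigma_fraction = 0))
  expect_identical(d0$maps, d1$maps)          # noise never touches the maps
  expect_identical(d0$surrogate, d1$surrogate)
  expect_false(identical(d0$frames, d1$frames))
  # noise-free frames equal the acquired warped truth exactly
  t <- 7
  fld <- true_field(d0, t, rows = respfit:::spec_support_rows(d0$specs[[t]], 68))
  W <- respfit:::warp_rows_cpp(d0$I_true$data, fld$dy, fld$dx,
                     respfit:::spec_support_rows(d0$specs[[t]], 68), 0, FALSE)$warped
  expect_equal(d0$frames[[t]],
               respfit:::acquire_from_rows(W, respfit:::spec_support_rows(d0$specs[[t]], 68),
                                           d0$specs[[t]], 68))
})

test_that("zero amplitude and zero noise give static frames and zero fields", {
  d <- simulate_dataset(phantom_spec("slab", size = 68, seed = 2, amplitude = 0,
                                     noise_sigma_fraction = 0))
  for (t in c(1, 50)) {
    expect_equal(d$frames[[t]], acquire(d$I_true, d$specs[[t]]))
    f <- true_field(d, t)
    expect_equal(max(abs(f$dy)), 0)
  }
})

test_that("canonical regime layouts have the reported frame counts", {
  expect_length(respfit:::regime_layout("full", 128)$specs, 10)
  expect_length(respfit:::regime_layout("slab", 136)$specs, 187)
  expect_length(respfit:::regime_layout("thin_slice", 301)$specs, 3010)
  expect_length(respfit:::regime_layout("thick_slice", 150)$specs, 1500)
  # slabs: 17 positions x 8 rows covering the image, 11 repeats each
  sl <- respfit:::regime_layout("slab", 136)$specs
  starts <- unique(vapply(sl, function(s) s$row_start, integer(1)))
  expect_equal(sort(starts), seq(0, 128, by = 8))
  # thin: alternating sweep direction
  th <- respfit:::regime_layout("thin_slice", 301)$specs
  expect_equal(th[[1]]$row_start, 0)
  expect_equal(th[[302]]$row_start, 300)
})

test_that("amplitude calibration hits the requested no-motion DFE", {
  d <- simulate_dataset(phantom_spec("slab", size = 68, seed = 3, target_dfe = 3.5))
  st <- model_dfe_stats(d, NULL)
  expect_lt(abs(st$mean - 3.5) / 3.5, 0.05)
  # two-stage calibration also matches a requested baseline p95
  d2 <- simulate_dataset(phantom_spec("slab", size = 68, seed = 3,
                                      target_dfe = 3.5, target_p95 = 9.8))
  st2 <- model_dfe_stats(d2, NULL)
  expect_lt(abs(st2$mean - 3.5) / 3.5, 0.05)
  expect_lt(abs(st2$p95 - 9.8) / 9.8, 0.05)
})

test_that("true fields satisfy the generating linear model exactly", {
  d <- simulate_dataset(phantom_spec("slab", size = 68, seed = 6, amplitude = 2,
                                     noise_sigma_fraction = 0))
  # least-squares recovery of the maps from fields + surrogate is exact
  X <- cbind(d$surrogate$s1, d$surrogate$sdot1)
  H <- solve(t(X) %*% X) %*% t(X)
  Fy <- sapply(seq_len(nrow(d$surrogate)), function(t) as.numeric(true_field(d, t)$dy))
  rec <- H %*% t(Fy)
  expect_equal(matrix(rec[1, ], 68, 68), d$maps$my1, tolerance = 1e-9)
  expect_equal(matrix(rec[2, ], 68, 68), d$maps$my2, tolerance = 1e-9)
})
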