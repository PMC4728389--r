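test_that("a t = 0 frame carries the initial profile exactly at pixel centres", {
  cfg <- imaging_config(n_px = 64, pixel_size = 0.4, noise_rel = 0)
  img <- render_frame(ref$source, ref$initial, ref$transport, 0, cfg)
  # hand-check one off-centre pixel: row 10, col 25 (1-based)
  px <- c(x = (25 - 0.5) * 0.4, y = (10 - 0.5) * 0.4)
  d <- sqrt(sum((px - cfg$center)^2))
  expect_equal(img[10, 25], initial_condition_profile(d, ref$initial),
               tolerance = 1e-12)
  # radial symmetry: quarter-turn about the midpoint permutes pixel values
  expect_equal(sort(as.vector(img)),
               sort(as.vector(t(img[, rev(seq_len(64))]))), tolerance = 1e-12)
})

test_that("centre-pixel intensity rises then falls over the study horizon", {
  cfg <- imaging_config(n_px = 64, pixel_size = 0.4, noise_rel = 0)
  tt <- c(0, 2, 5, 10, 20, 40, 60)
  centre_px <- vapply(tt, function(t) {
    img <- render_frame(ref$source, ref$initial, ref$transport, t, cfg,
                        q = quick_quad(), op = quick_op())
    img[32, 32]
  }, numeric(1))
  k <- which.max(centre_px)
  expect_gt(k, 1)
  expect_lt(k, length(tt))
  expect_true(all(diff(centre_px[1:k]) > 0))
  expect_true(all(diff(centre_px[k:length(tt)]) < 0))
})

test_that("noise model is unbiased, clipped at zero, and seed-reproducible", {
  cfg0 <- imaging_config(n_px = 100, pixel_size = 0.2, noise_rel = 0,
                         noise_add = 0)
  img <- matrix(0.5, 100, 100)
  expect_identical(add_noise(img, cfg0), img)
  cfg <- imaging_config(n_px = 100, pixel_size = 0.2, noise_rel = 0.1,
                        noise_add = 0)
  noisy <- add_noise(img, cfg, seed = 42)
  # law of large numbers over 10^4 pixels: mean within 3 standard errors
  expect_lt(abs(mean(noisy) - 0.5), 3 * 0.5 * 0.1 / 100)
  expect_identical(add_noise(img, cfg, seed = 42), noisy)
  cfg_add <- imaging_config(n_px = 100, pixel_size = 0.2, noise_rel = 0,
                            noise_add = 5)
  expect_gte(min(add_noise(img, cfg_add, seed = 1)), 0)
})

test_that("stacks are deterministic in the seed and embed ground truth", {
  cfg <- imaging_config(n_px = 48, pixel_size = 0.4, noise_rel = 0.05,
                        seed = 9)
  st1 <- generate_stack(ref$source, ref$initial, ref$transport, c(0, 5),
                        cfg, q = quick_quad())
  st2 <- generate_stack(ref$source, ref$initial, ref$transport, c(0, 5),
                        cfg, q = quick_quad())
  expect_identical(st1$frames, st2$frames)
  cfg2 <- imaging_config(n_px = 48, pixel_size = 0.4, noise_rel = 0.05,
                         seed = 10)
  st3 <- generate_stack(ref$source, ref$initial, ref$transport, c(0, 5),
                        cfg2, q = quick_quad())
  expect_false(identical(st1$frames, st3$frames))
  # zero noise: frames equal the deterministic rendering
  cfg0 <- imaging_config(n_px = 48, pixel_size = 0.4, noise_rel = 0)
  st0 <- generate_stack(ref$source, ref$initial, ref$transport, 3, cfg0,
                        q = quick_quad())
  expect_equal(st0$frames[[1]],
               render_frame(ref$source, ref$initial, ref$transport, 3, cfg0,
                            q = quick_quad(), op = quick_op()),
               tolerance = 1e-12)
  expect_identical(st1$truth$transport$D, ref$transport$D)
  expect_error(generate_stack(ref$source, ref$initial, ref$transport,
                              c(5, 2), cfg), class = "geldiff_config_error")
})

test_that("azimuthal averaging recovers the radial model within discretisation error", {
  v <- 0.37
  flat <- matrix(v, 64, 64)
  got <- extract_radial_profile(flat, c(6.4, 6.4), c(1, 3, 5), 0.4, 0.2)
  expect_equal(unname(got), rep(v, 3), tolerance = 1e-12)
  cfg <- imaging_config(noise_rel = 0)   # 128 px, 0.2 mm
  img <- render_frame(ref$source, ref$initial, ref$transport, 10, cfg,
                      q = quick_quad(), op = quick_op())
  radii <- reference_radii()
  prof <- extract_radial_profile(img, cfg$center, radii,
                                 annulus_width = cfg$pixel_size,
                                 pixel_size = cfg$pixel_size)
  model <- solve_concentration(radii, 10, ref$source, ref$initial,
                               ref$transport, quick_quad(), op = quick_op(),
                               drop = FALSE)[, 1]
  expect_lt(max(abs(prof - model) / model), 0.02)
  expect_error(extract_radial_profile(img, cfg$center, 30, 0.01, 0.2),
               class = "geldiff_config_error")
})

test_that("centre localisation is exact for symmetric frames and translation-equivariant", {
  cfg <- imaging_config(n_px = 64, pixel_size = 0.4, noise_rel = 0)
  img <- render_frame(ref$source, ref$initial, ref$transport, 0, cfg)
  est <- estimate_center(img, pixel_size = 0.4)
  expect_lt(max(abs(est - cfg$center)), 0.1 * 0.4)
  # translation equivariance on a compactly supported blob; power-of-two
  # pixel size keeps the grid arithmetic exact so tied symmetric pixels
  # cannot be split asymmetrically at the intensity threshold
  blob_at <- function(centre) {
    xc <- (seq_len(64) - 0.5) * 0.25
    d2 <- outer((xc - centre[2])^2, (xc - centre[1])^2, "+")
    exp(-d2 / (2 * 1.5^2))
  }
  shift <- c(2, -1.25)   # integer pixel multiples of 0.25 mm
  e1 <- estimate_center(blob_at(c(8, 8)), pixel_size = 0.25)
  e2 <- estimate_center(blob_at(c(8, 8) + shift), pixel_size = 0.25)
  expect_equal(unname(e2 - e1), shift, tolerance = 1e-9)
  expect_error(estimate_center(matrix(1, 64, 64), pixel_size = 0.4),
               class = "geldiff_config_error")
})

test_that("TIFF + sidecar round trip is lossless at 32-bit float precision", {
  cfg <- imaging_config(n_px = 48, pixel_size = 0.4, noise_rel = 0.3,
                        seed = 5)
  st <- generate_stack(ref$source, ref$initial, ref$transport, c(0, 4), cfg,
                       q = quick_quad())
  expect_gt(max(st$frames[[1]]), 1)   # noise excursion above 1 must survive
  path <- file.path(tempdir(), "roundtrip.tiff")
  write_stack(st, path)
  back <- read_stack(path)
  for (j in 1:2)
    expect_lt(max(abs(back$frames[[j]] - st$frames[[j]])), 1e-6)
  expect_identical(back$times, st$times)
  expect_equal(back$config$center, cfg$center, tolerance = 1e-12)
  expect_equal(back$truth$source$lam, ref$source$lam, tolerance = 1e-12)
})

test_that("end-to-end: noiseless stack reproduces the model at the reference radii", {
  cfg <- imaging_config(noise_rel = 0, seed = 1)
  st <- generate_stack(ref$source, ref$initial, ref$transport,
                       c(0, 10, 30), cfg, q = quick_quad())
  obs <- stack_observations(st, reference_radii(), annulus_width = 0.4)
  model <- solve_concentration(reference_radii(), c(0, 10, 30), ref$source,
                               ref$initial, ref$transport, quick_quad(),
                               op = quick_op(), drop = FALSE)
  expect_lt(max(abs(obs$intensities - model) / model), 0.02)
})
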