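test_that("observations container validates shape and round-trips through CSV", {
  m <- matrix(runif(12), 3, 4)
  obs <- observations(c(1, 2, 3), c(0, 1, 2, 5), m)
  expect_error(observations(c(2, 1, 3), c(0, 1, 2, 5), m),
               class = "geldiff_config_error")
  expect_error(observations(c(1, 2, 3), c(0, 1, 2, 5), m[1:2, ]),
               class = "geldiff_config_error")
  m_bad <- m; m_bad[2, 2] <- NA
  expect_error(observations(c(1, 2, 3), c(0, 1, 2, 5), m_bad),
               class = "geldiff_config_error")
  path <- file.path(tempdir(), "obs.csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(back$intensities, obs$intensities, tolerance = 1e-12)
  expect_identical(back$radii, obs$radii)
  # long-format conversion is the same grid
  expect_equal(as_observations(as.data.frame(obs))$intensities,
               obs$intensities, tolerance = 1e-15)
})

test_that("model residuals are self-consistent, offset-linear, and correctly shaped", {
  q <- quick_quad()
  op <- quick_op()
  radii <- reference_radii()
  times <- seq(0, 20, by = 2)
  obs <- simulate_observations(ref$source, ref$initial, ref$transport,
                               radii, times, noise_rel = 0, q = q, op = op)
  res <- model_residuals(obs, ref$source, ref$initial, ref$transport, q,
                         op = op)
  expect_length(res, length(radii) * length(times))
  expect_lt(sqrt(sum(res^2)), 1e-4)
  obs2 <- obs
  obs2$intensities <- obs$intensities + 0.05
  res2 <- model_residuals(obs2, ref$source, ref$initial, ref$transport, q,
                          op = op)
  expect_equal(res2, res + 0.05, tolerance = 1e-12)
})

test_that("initial-condition fit recovers its generating parameters", {
  rr <- seq(0, 15, by = 0.5)
  prof <- data.frame(r = rr,
                     intensity = initial_condition_profile(rr, ref$initial))
  fit <- fit_initial_condition(prof)
  truth <- c(c0 = 0.1, c1 = 0.8, a = 0.16, alpha = 1.5)
  got <- c(c0 = fit$c0, c1 = fit$c1, a = fit$a, alpha = fit$alpha)
  expect_lt(max(abs(got - truth) / truth), 1e-3)
  expect_true(attr(fit, "fit")$converged)
  # degenerate flat profile: c1 -> 0 and shape parameters flagged
  flat <- data.frame(r = rr, intensity = rep(0.25, length(rr)))
  ffit <- fit_initial_condition(flat)
  expect_lt(ffit$c1, 1e-4)
  expect_setequal(attr(ffit, "fit")$unidentifiable, c("a", "alpha"))
  expect_error(fit_initial_condition(prof[1:4, ]),
               class = "geldiff_config_error")
})

test_that("initial-condition fit is robust to 5% noise across seeds", {
  rr <- seq(0, 15, by = 0.5)
  clean <- initial_condition_profile(rr, ref$initial)
  alphas <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    prof <- data.frame(r = rr, intensity = clean * (1 + rnorm(length(rr), 0, 0.05)))
    fit_initial_condition(prof)$alpha
  }, numeric(1))
  expect_lt(abs(median(alphas) - 1.5) / 1.5, 0.1)
})

test_that("diffusivity is recovered exactly from noiseless curves", {
  q <- quick_quad()
  op <- quick_op()
  obs <- simulate_observations(ref$source, ref$initial, ref$transport,
                               reference_radii(), seq(0, 60), noise_rel = 0,
                               q = q, op = op)
  fit <- fit_diffusivity(obs, ref$source, ref$initial, init_D = 8.64,
                         q = q, op = op)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates["D"] - 4.32) / 4.32, 1e-3)
})

test_that("degenerate and invalid fitting inputs are rejected", {
  flat <- observations(c(1, 2, 3), seq(0, 10),
                       matrix(0.1, 3, 11))
  expect_error(fit_diffusivity(flat, ref$source, ref$initial),
               class = "geldiff_numerical_error")
  small <- observations(c(1, 2), seq(0, 10), matrix(runif(22), 2, 11))
  expect_error(fit_diffusivity(small, ref$source, ref$initial),
               class = "geldiff_config_error")
  ok <- observations(c(1, 2, 3), seq(0, 10), matrix(runif(33), 3, 11))
  expect_error(fit_diffusivity(ok, ref$source, ref$initial, init_D = -1),
               class = "geldiff_config_error")
})

test_that("profile of the objective in log D has a single interior optimum", {
  q <- quick_quad()
  op <- quick_op()
  obs <- simulate_observations(ref$source, ref$initial, ref$transport,
                               reference_radii(), seq(0, 60, by = 4),
                               noise_rel = 0.05, seed = 31, q = q, op = op)
  J0m <- besselJ(outer(obs$radii, op$x), 0)
  rss_at <- function(D) {
    pred <- vapply(seq_along(obs$times), function(j) {
      m <- op$ichat * exp(-D * op$x^2 * obs$times[j]) +
        ref$source$A * op$fhat *
          geldiff:::.source_conv(D * op$x^2, obs$times[j], ref$source,
                                 q$tau_steps)
      as.vector(J0m %*% (op$w * op$x * m))
    }, numeric(length(obs$radii)))
    sum((obs$intensities - (pred + ref$initial$c0))^2)
  }
  Ds <- 4.32 * 2^seq(-2, 2, length.out = 13)
  vals <- vapply(Ds, rss_at, numeric(1))
  # strictly decreasing then strictly increasing: no spurious optima
  k <- which.min(vals)
  expect_gt(k, 1); expect_lt(k, length(vals))
  expect_true(all(diff(vals[1:k]) < 0))
  expect_true(all(diff(vals[k:length(vals)]) > 0))
})

test_that("rescaling intensities rescales amplitudes but not the diffusivity", {
  q <- quick_quad()
  # c1 modest so the 3x-scaled amplitude stays inside the [0, 1] bound
  ic0 <- initial_condition(c0 = 0, c1 = 0.25, a = 0.16, alpha = 1.5)
  obs <- simulate_observations(ref$source, ic0, ref$transport,
                               reference_radii(), seq(0, 20), noise_rel = 0,
                               q = q)
  s <- 3
  obs_scaled <- observations(obs$radii, obs$times, s * obs$intensities)
  expect_warning(
    fit1 <- fit_diffusivity(obs, ref$source, ic0, init_D = 6,
                            q = q, free = c("D", "A", "c1"), n_starts = 2),
    "identifiable")
  expect_warning(
    fit2 <- fit_diffusivity(obs_scaled, ref$source, ic0, init_D = 6,
                            q = q, free = c("D", "A", "c1"), n_starts = 2),
    "identifiable")
  expect_equal(unname(fit2$estimates["D"] / fit1$estimates["D"]), 1,
               tolerance = 0.02)
  expect_equal(unname(fit2$estimates["A"] / fit1$estimates["A"]), s,
               tolerance = 0.05)
  expect_equal(unname(fit2$estimates["c1"] / fit1$estimates["c1"]), s,
               tolerance = 0.05)
})

test_that("bootstrap intervals are tight for noiseless data and seed-stable", {
  q <- quadrature_config(beta_max = 60, n_panels = 120,
                         panel_rule_order = 8, tau_steps = 64)
  radii <- c(2.475, 4.243, 6.790, 8.770, 11.170)
  obs <- simulate_observations(ref$source, ref$initial, ref$transport,
                               radii, seq(0, 14), noise_rel = 0, q = q)
  fit <- fit_diffusivity(obs, ref$source, ref$initial, init_D = 4, q = q)
  expect_true(fit$converged)
  fit_ci <- bootstrap_ci(obs, fit, n_boot = 200, level = 0.9, seed = 7)
  width <- fit_ci$ci["D", "upper"] - fit_ci$ci["D", "lower"]
  expect_lt(width, 1e-3 * fit_ci$estimates["D"])
  fit_ci2 <- bootstrap_ci(obs, fit, n_boot = 200, level = 0.9, seed = 7)
  expect_identical(fit_ci$ci, fit_ci2$ci)
  expect_error(bootstrap_ci(obs, fit, n_boot = 50),
               class = "geldiff_config_error")
})

test_that("scale estimate reproduces the L^2 / tau heuristic", {
  expect_equal(diffusivity_scale_estimate(10, 20), 5, tolerance = 1e-15)
  expect_error(diffusivity_scale_estimate(-1, 20),
               class = "geldiff_config_error")
})
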