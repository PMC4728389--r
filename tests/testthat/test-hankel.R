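test_that("Hankel image of the initial excess has the zero-frequency and decay limits", {
  ic <- ref$initial
  # beta = 0: the transform equals the plane integral / 2 pi
  expect_equal(ic_hat(0, ic), initial_excess_mass(ic) / (2 * pi),
               tolerance = 1e-8)
  # zero excess maps to the zero function
  expect_identical(ic_hat(c(0, 1, 5), initial_condition(c1 = 0)),
                   c(0, 0, 0))
  # Riemann-Lebesgue decay: far spectrum is negligible
  expect_lt(abs(ic_hat(50, ic)), 1e-6 * ic_hat(0, ic))
  # the solver's gridded spectrum agrees with adaptive quadrature
  op <- quick_op()
  for (b in c(0.5, 2.1, 7.3)) {
    node <- which.min(abs(op$x - b))
    expect_equal(op$ichat[node], ic_hat(op$x[node], ic), tolerance = 1e-6)
  }
})

test_that("disk spectrum has the small-argument limit, first null, and bound", {
  src <- ref$source
  expect_equal(source_hat(0, src), src$R^2 / 2, tolerance = 1e-15)
  # continuity at the origin
  expect_equal(source_hat(1e-8, src), src$R^2 / 2, tolerance = 1e-10)
  # vanishes where beta R hits the first zero of J1
  expect_lt(abs(source_hat(3.8317059702 / src$R, src)), 1e-10)
  # bounded by the zero-frequency value over a broad scan
  bb <- seq(0, 120, by = 0.01)
  expect_true(all(abs(source_hat(bb, src)) <= src$R^2 / 2 + 1e-15))
})

test_that("mode evolution reduces to its limits", {
  ic <- ref$initial
  src <- ref$source
  tr <- ref$transport
  q <- quick_quad()
  bb <- c(0.3, 1.2, 4)
  expect_equal(mode_evolution(bb, 0, src, ic, tr, q), ic_hat(bb, ic),
               tolerance = 1e-10)
  src0 <- weibull_source(A = 0)
  expect_equal(mode_evolution(bb, 7, src0, ic, tr, q),
               ic_hat(bb, ic) * exp(-tr$D * bb^2 * 7), tolerance = 1e-10)
  # the source-fed amplitude shrinks like 1/D as diffusion outpaces release
  m6 <- max(abs(mode_evolution(bb, 1, src, ic, transport(1e6), q)))
  m10 <- max(abs(mode_evolution(bb, 1, src, ic, transport(1e10), q)))
  expect_lt(m10, 1e-8)
  expect_lt(m10, 1e-3 * m6)
})

test_that("transform inversion reproduces the initial profile", {
  rr <- c(0, 1, 5, 10)
  v <- solve_concentration(rr, 0, ref$source, ref$initial, ref$transport,
                           op = ref_op(), drop = FALSE)
  truth <- initial_condition_profile(rr, ref$initial)
  expect_lt(max(abs(v[, 1] - truth) / truth), 1e-4)
})

test_that("with no source, a Gaussian excess spreads as the 2-D heat kernel", {
  D <- ref$transport$D
  t0 <- 1
  src0 <- weibull_source(A = 0)
  icg <- initial_condition(c0 = 0.25, c1 = 0.5, a = 1 / (4 * D * t0),
                           alpha = 2)
  q <- quick_quad()
  rr <- c(0, 2, 5, 9)
  for (t in c(0.5, 2)) {
    got <- solve_concentration(rr, t, src0, icg, ref$transport, q,
                               drop = FALSE)[, 1]
    want <- icg$c0 + icg$c1 * t0 / (t0 + t) * exp(-rr^2 / (4 * D * (t0 + t)))
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("solution is linear in the source amplitude and initial excess", {
  q <- quick_quad()
  tr <- ref$transport
  rr <- c(0, 3, 8)
  t <- 12
  full <- solve_concentration(rr, t, ref$source, ref$initial, tr, q,
                              include_baseline = FALSE, drop = FALSE)
  ic_only <- solve_concentration(rr, t, weibull_source(A = 0), ref$initial,
                                 tr, q, include_baseline = FALSE, drop = FALSE)
  src_only <- solve_concentration(rr, t, ref$source,
                                  initial_condition(c0 = 0.1, c1 = 0,
                                                    a = 0.16, alpha = 1.5),
                                  tr, q, include_baseline = FALSE, drop = FALSE)
  expect_equal(full, ic_only + src_only, tolerance = 1e-8)
  # doubling both amplitudes doubles the excess field
  src2 <- weibull_source(A = 1000)
  ic2 <- initial_condition(c0 = 0.1, c1 = 1.6, a = 0.16, alpha = 1.5)
  twice <- solve_concentration(rr, t, src2, ic2, tr, q,
                               include_baseline = FALSE, drop = FALSE)
  expect_equal(twice, 2 * full, tolerance = 1e-8)
})

test_that("excess concentration stays non-negative up to quadrature ripple", {
  rr <- seq(0, 14, by = 1)
  tt <- c(0, 2, 10, 30, 60)
  u <- solve_concentration(rr, tt, ref$source, ref$initial, ref$transport,
                           include_baseline = FALSE, op = ref_op(),
                           drop = FALSE)
  expect_gt(min(u), -1e-6 * max(u))
})

test_that("spectral truncation guard raises a numerical error when unsatisfiable", {
  q_strict <- quadrature_config(beta_max = 15, n_panels = 50,
                                panel_rule_order = 8, tau_steps = 32,
                                rel_tol = 1e-12)
  expect_error(
    solve_concentration(1, 0.5, ref$source, ref$initial, ref$transport,
                        q_strict),
    class = "geldiff_numerical_error")
})

test_that("late-time centre field approaches the point-source asymptote", {
  tr <- ref$transport
  # 1/t functional form and linearity in total mass are exact
  a60 <- longtime_center_asymptote(60, ref$source, ref$initial, tr) - 0.1
  a120 <- longtime_center_asymptote(120, ref$source, ref$initial, tr) - 0.1
  expect_equal(a60 / a120, 2, tolerance = 1e-12)
  src2 <- weibull_source(A = 1000)
  ic2 <- initial_condition(c0 = 0.1, c1 = 1.6, a = 0.16, alpha = 1.5)
  expect_equal(longtime_center_asymptote(80, src2, ic2, tr) - 0.1,
               2 * (longtime_center_asymptote(80, ref$source, ref$initial,
                                              tr) - 0.1),
               tolerance = 1e-12)
  # hand value: excess(60) = (261.4 + 34.45) / (4 pi D 60)
  expect_equal(a60, 0.0908, tolerance = 2e-3)
  # the solved field converges onto the asymptote once release is long over
  got <- solve_concentration(0, 100, ref$source, ref$initial, tr,
                             op = ref_op()) - 0.1
  want <- longtime_center_asymptote(100, ref$source, ref$initial, tr) - 0.1
  expect_equal(got, want, tolerance = 0.15)
})
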