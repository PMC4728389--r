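#' Quadrature configuration for the Hankel-transform solver
#'
#' Controls the numerical evaluation of the integral solution: the spectral
#' variable \eqn{\beta} is truncated at \code{beta_max} and integrated with a
#' composite Gauss-Legendre rule (\code{n_panels} equal panels,
#' \code{panel_rule_order} points each); the temporal convolution with the
#' Weibull release history uses a uniform grid of \code{tau_steps} points per
#' evaluation time.
#'
#' @param beta_max spectral truncation (1/mm, > 0).
#' @param n_panels number of quadrature panels in beta (>= 8).
#' @param panel_rule_order Gauss-Legendre points per panel (>= 2).
#' @param tau_steps points on the temporal convolution grid (>= 16).
#' @param rel_tol target relative tolerance; the solver raises a numerical
#'   error when the spectral amplitude at \code{beta_max} has not decayed to
#'   \code{rel_tol} times its peak (truncation would then be unsafe).
#' @return An object of class \code{quadrature_config}.
#' @export
quadrature_config <- function(beta_max = 100, n_panels = 333,
                              panel_rule_order = 16, tau_steps = 256,
                              rel_tol = 1e-6) {
  beta_max <- check_scalar(beta_max, "beta_max", 0, strict = TRUE)
  n_panels <- check_scalar(n_panels, "n_panels", 8)
  panel_rule_order <- check_scalar(panel_rule_order, "panel_rule_order", 2)
  tau_steps <- check_scalar(tau_steps, "tau_steps", 16)
  rel_tol <- check_scalar(rel_tol, "rel_tol", 0, strict = TRUE)
  structure(list(beta_max = beta_max, n_panels = as.integer(n_panels),
                 panel_rule_order = as.integer(panel_rule_order),
                 tau_steps = as.integer(tau_steps), rel_tol = rel_tol),
            class = "quadrature_config")
}

#' Hankel image of the baseline-subtracted initial profile
#'
#' Order-zero Hankel transform
#' \eqn{\hat u_0(\beta) = \int_0^\infty \xi J_0(\beta\xi) c_1 e^{-a\xi^\alpha} d\xi}
#' of the initial excess. Computed by adaptive quadrature with the
#' integration range split at the zeros of \eqn{J_0(\beta\xi)} out to the
#' point where the profile has decayed below 1e-16 of its peak. At
#' \eqn{\beta = 0} this equals [initial_excess_mass()] / \eqn{2\pi}.
#'
#' @param beta spectral coordinate (1/mm, vectorised, >= 0).
#' @param ic an [initial_condition()].
#' @param rel_tol relative tolerance per segment.
#' @return Spectral amplitude (intensity mm^2), same length as \code{beta}.
#' @export
ic_hat <- function(beta, ic, rel_tol = 1e-10) {
  stopifnot(inherits(ic, "initial_condition"))
  if (any(beta < 0)) stop_config("'beta' must be non-negative")
  if (ic$c1 == 0) return(rep(0, length(beta)))
  xi_cut <- (-log(1e-16) / ic$a)^(1 / ic$alpha)
  f <- function(xi, b) xi * besselJ(b * xi, 0) * ic$c1 * exp(-ic$a * xi^ic$alpha)
  one <- function(b) {
    n_zero <- floor(b * xi_cut / pi)
    breaks <- if (n_zero >= 1) bessel_zeros_j0(n_zero) / b else numeric(0)
    breaks <- c(0, breaks[breaks < xi_cut], xi_cut)
    total <- 0
    for (s in seq_len(length(breaks) - 1)) {
      seg <- tryCatch(
        stats::integrate(f, breaks[s], breaks[s + 1], b = b,
                         rel.tol = rel_tol, abs.tol = 1e-14,
                         subdivisions = 200L),
        error = function(e) stop_numerical(
          "ic_hat quadrature failed on [%g, %g] at beta = %g: %s",
          breaks[s], breaks[s + 1], b, conditionMessage(e)))
      total <- total + seg$value
    }
    total
  }
  vapply(beta, one, numeric(1))
}

#' Hankel image of the unit gel disk
#'
#' Spatial spectral factor of the release source: the order-zero Hankel
#' transform of the indicator of the disk of radius \eqn{R}, i.e.
#' \eqn{R J_1(\beta R)/\beta} for \eqn{\beta > 0} and the continuous limit
#' \eqn{R^2/2} at \eqn{\beta = 0}. Bounded by \eqn{R^2/2} everywhere and
#' vanishing at \eqn{\beta = j_{1,1}/R}.
#'
#' @param beta spectral coordinate (1/mm, vectorised, >= 0).
#' @param src a [weibull_source()].
#' @return Spectral factor (mm^2), same length as \code{beta}.
#' @export
source_hat <- function(beta, src) {
  stopifnot(inherits(src, "weibull_source"))
  if (any(beta < 0)) stop_config("'beta' must be non-negative")
  out <- rep(src$R^2 / 2, length(beta))
  pos <- beta > 0
  out[pos] <- src$R * besselJ(beta[pos] * src$R, 1) / beta[pos]
  out
}

# stable helpers for exact per-interval integration of a linear function
# against the kernel exp(-kappa (t - tau)):
#   phi1(x) = (1 - e^-x)/x,  phi2(x) = (x - 1 + e^-x)/x^2
.phi1 <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-4
  xs <- x[small]
  out[small] <- 1 - xs / 2 + xs^2 / 6
  xl <- x[!small]
  out[!small] <- (1 - exp(-xl)) / xl
  out
}
.phi2 <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-4
  xs <- x[small]
  out[small] <- 0.5 - xs / 6 + xs^2 / 24
  xl <- x[!small]
  out[!small] <- (xl - 1 + exp(-xl)) / xl^2
  out
}

# temporal convolution integral(0, t) w(tau + T) exp(-kappa (t - tau)) dtau
# for a vector of decay rates kappa, by product integration: the Weibull
# history is piecewise linear on the tau grid, the stiff exponential kernel
# integrated exactly per interval -- uniformly accurate in kappa, unlike
# composite Simpson which fails once kappa * dtau >> 1
.source_conv <- function(kappa, t, src, tau_steps) {
  if (t <= 0) return(numeric(length(kappa)))
  kappa[!is.finite(kappa)] <- 1e12
  kappa <- pmin(kappa, 1e12)   # avoid exp(-Inf * 0) = NaN at tau = t
  tau <- seq(0, t, length.out = max(tau_steps, 16L))
  h <- tau[2L] - tau[1L]
  wv <- stats::dweibull(tau + src$T_, shape = src$k, scale = src$lam)
  n <- length(tau)
  E <- exp(-outer(kappa, t - tau[-1L]))      # kernel at right interval edges
  x <- kappa * h
  p1 <- .phi1(x)
  p2 <- .phi2(x)
  h * (p1 * as.vector(E %*% wv[-n]) + p2 * as.vector(E %*% diff(wv)))
}

# precomputes everything D-independent about the spectral representation:
# beta nodes/weights of the composite Gauss-Legendre rule, the Hankel image
# of the initial excess on those nodes (composite-Simpson xi grid resolving
# the fastest oscillation J0(beta_max xi), evaluated in chunks), and the
# disk image. Reused across evaluation times and across diffusivity values
# during fitting.
hankel_operator <- function(src, ic, q = quadrature_config()) {
  stopifnot(inherits(src, "weibull_source"), inherits(ic, "initial_condition"),
            inherits(q, "quadrature_config"))
  rule <- panel_gauss_rule(0, q$beta_max, q$n_panels, q$panel_rule_order)
  ichat <- rep(0, length(rule$x))
  if (ic$c1 > 0) {
    xi_cut <- (-log(1e-16) / ic$a)^(1 / ic$alpha)
    dxi <- min(0.01, (2 * pi / q$beta_max) / 16)
    n_xi <- ceiling(xi_cut / dxi)
    if (n_xi %% 2 == 1) n_xi <- n_xi + 1
    xi <- seq(0, xi_cut, length.out = n_xi + 1)
    sw <- simpson_weights(n_xi + 1, xi[2] - xi[1])
    u0 <- ic$c1 * exp(-ic$a * xi^ic$alpha)
    coef <- sw * xi * u0
    idx <- split(seq_along(rule$x),
                 ceiling(seq_along(rule$x) / 512))
    for (ii in idx) {
      J <- besselJ(outer(rule$x[ii], xi), 0)
      ichat[ii] <- as.vector(J %*% coef)
    }
  }
  list(x = rule$x, w = rule$w, order = rule$order,
       ichat = ichat, fhat = source_hat(rule$x, src),
       src = src, ic = ic, q = q)
}

# spectral amplitudes on the operator's beta nodes at one time
.mode_vector <- function(op, t, D) {
  op$ichat * exp(-D * op$x^2 * t) +
    op$src$A * op$fhat * .source_conv(D * op$x^2, t, op$src, op$q$tau_steps)
}

#' Spectral mode evolution
#'
#' Time evolution of a single Hankel mode \eqn{\beta}: the initial-excess
#' amplitude decays as \eqn{e^{-D\beta^2 t}} while the release source feeds
#' the mode through the convolution
#' \eqn{A \hat f(\beta) \int_0^t w(\tau + T) e^{-D\beta^2 (t-\tau)} d\tau},
#' evaluated by product integration on a uniform grid of
#' \code{q$tau_steps} points (the Weibull history is interpolated linearly,
#' the exponential kernel integrated exactly on each interval).
#'
#' @param beta spectral coordinate (1/mm, vectorised, >= 0).
#' @param t time (day, scalar, >= 0).
#' @param src a [weibull_source()].
#' @param ic an [initial_condition()].
#' @param tr a [transport()].
#' @param q a [quadrature_config()].
#' @return Spectral amplitude, same length as \code{beta}.
#' @export
mode_evolution <- function(beta, t, src, ic, tr, q = quadrature_config()) {
  stopifnot(inherits(tr, "transport"))
  t <- check_scalar(t, "t", 0)
  if (any(beta < 0)) stop_config("'beta' must be non-negative")
  ic_hat(beta, ic) * exp(-tr$D * beta^2 * t) +
    src$A * source_hat(beta, src) *
      .source_conv(tr$D * beta^2, t, src, q$tau_steps)
}

#' Concentration field from the Hankel-transform solution
#'
#' Evaluates the analytical solution of the axisymmetric diffusion problem
#' \deqn{\partial_t c = D \frac{1}{r}\partial_r (r \partial_r c) + S(r, t)}
#' with initial profile \eqn{c_0 + c_1 e^{-a r^\alpha}}, symmetry at
#' \eqn{r = 0} and decay to the baseline at infinity. The constant baseline
#' has no Hankel transform, so the excess \eqn{u = c - c_0} is solved for in
#' the spectral domain and the baseline added back on output:
#' \deqn{c(r,t) = c_0 + \int_0^\infty \beta J_0(\beta r)\,
#'   \hat u(\beta, t)\, d\beta}
#' with \eqn{\hat u} from [mode_evolution()]. The oscillatory outer integral
#' is computed with the composite panel rule of \code{q}; truncation at
#' \code{beta_max} is guarded by requiring the spectral amplitude over the
#' last panel to have decayed below \code{q$rel_tol} of its peak.
#'
#' @param r radial positions (mm, vectorised, >= 0).
#' @param t times (day, vectorised, >= 0).
#' @param src a [weibull_source()].
#' @param ic an [initial_condition()].
#' @param tr a [transport()].
#' @param q a [quadrature_config()].
#' @param include_baseline add the constant baseline \code{ic$c0} (default)
#'   or return the excess field only.
#' @param op optional precomputed spectral operator (internal reuse).
#' @param drop drop matrix dimensions when \code{r} and \code{t} are scalars.
#' @return Matrix of scaled concentration, \code{length(r)} rows by
#'   \code{length(t)} columns (a scalar when both are scalars and
#'   \code{drop = TRUE}).
#' @examples
#' p <- gel_params()
#' solve_concentration(2.475, 10, p$source, p$initial, p$transport)
#' @export
solve_concentration <- function(r, t, src, ic, tr, q = quadrature_config(),
                                include_baseline = TRUE, op = NULL,
                                drop = TRUE) {
  stopifnot(inherits(tr, "transport"))
  if (any(r < 0)) stop_config("'r' must be non-negative")
  if (any(t < 0)) stop_config("'t' must be non-negative")
  if (is.null(op)) op <- hankel_operator(src, ic, q)
  J0m <- besselJ(outer(r, op$x), 0)
  out <- matrix(NA_real_, length(r), length(t),
                dimnames = list(NULL, NULL))
  tail_idx <- seq(length(op$x) - op$order + 1L, length(op$x))
  for (j in seq_along(t)) {
    m <- .mode_vector(op, t[j], tr$D)
    peak <- max(abs(m))
    if (peak > 0 && max(abs(m[tail_idx])) > op$q$rel_tol * peak)
      stop_numerical(paste0(
        "spectral amplitude has not decayed at beta_max = %g ",
        "(tail/peak = %.3g > rel_tol = %g); increase beta_max"),
        op$q$beta_max, max(abs(m[tail_idx])) / peak, op$q$rel_tol)
    out[, j] <- as.vector(J0m %*% (op$w * op$x * m))
  }
  if (include_baseline) out <- out + ic$c0
  if (drop && length(r) == 1L && length(t) == 1L) out[1L, 1L] else out
}

#' Long-time point-source asymptote at the centre
#'
#' Once all mass is released and spread far beyond the source scale, the
#' field approaches the two-dimensional heat kernel of the total deposited
#' amount: \eqn{c(0, t) \to c_0 + M_{tot}/(4\pi D t)} with
#' \eqn{M_{tot}} = [released_mass()](Inf) + [initial_excess_mass()]. Used as
#' an independent late-time check on the solver.
#'
#' @param t time (day, vectorised); meaningful only for \code{t} well beyond
#'   \code{lam + T_}.
#' @param src a [weibull_source()].
#' @param ic an [initial_condition()].
#' @param tr a [transport()].
#' @return Scaled concentration at the centre.
#' @export
longtime_center_asymptote <- function(t, src, ic, tr) {
  stopifnot(inherits(tr, "transport"))
  m_tot <- released_mass(Inf, src) + initial_excess_mass(ic)
  ic$c0 + m_tot / (4 * pi * tr$D * t)
}
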