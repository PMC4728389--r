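#' @keywords internal
"_PACKAGE"

# classed conditions shared across the package:
#   geldiff_config_error    -- bad user input / configuration
#   geldiff_numerical_error -- solver / quadrature / fit failure
stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("geldiff_config_error", "error", "condition")))
}

stop_numerical <- function(msg, ..., data = NULL) {
  cond <- errorCondition(sprintf(msg, ...),
                         class = c("geldiff_numerical_error", "error", "condition"))
  if (!is.null(data)) attr(cond, "diagnostics") <- data
  stop(cond)
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config("'%s' must be a single finite number", name)
  if (strict && x <= lower) stop_config("'%s' must be > %g", name, lower)
  if (!strict && x < lower) stop_config("'%s' must be >= %g", name, lower)
  as.numeric(x)
}

#' Weibull release source of a degrading gel depot
#'
#' The fluorophore release from the injected gel is modelled as a separable
#' source \eqn{S(r,t) = A \, w(t + T;\, k, \lambda) \, H(R - r)} where
#' \eqn{w} is the Weibull probability density in time (growth then attenuation
#' of the signal as the gel degrades), \eqn{H(R - r)} is the complementary
#' Heaviside function restricting release to the gel disk of radius \eqn{R},
#' \eqn{A} scales the overall source strength and \eqn{T} is a phase lag that
#' aligns the release onset with the fitted initial profile.
#'
#' The convention at the jump is inclusive: \eqn{r = R} lies inside the gel,
#' so the order-zero Hankel image of the spatial factor is exactly
#' \eqn{R J_1(\beta R)/\beta}.
#'
#' @param A scaled source strength (intensity/day on the scaled-intensity
#'   axis); must be >= 0.
#' @param k Weibull shape factor (unitless, > 0).
#' @param lam Weibull scale parameter (day, > 0).
#' @param T_ phase lag (day, >= 0) shifting the Weibull argument.
#' @param R gel radius, i.e. inner radius of the injection needle (mm, > 0).
#' @return An object of class \code{weibull_source}.
#' @examples
#' src <- weibull_source(A = 500, k = 1.5, lam = 10, T_ = 1.5, R = 0.42)
#' source_term(0, 5, src)
#' @export
weibull_source <- function(A = 500, k = 1.5, lam = 10, T_ = 1.5, R = 0.42) {
  out <- list(A = check_scalar(A, "A", 0),
              k = check_scalar(k, "k", 0, strict = TRUE),
              lam = check_scalar(lam, "lam", 0, strict = TRUE),
              T_ = check_scalar(T_, "T_", 0),
              R = check_scalar(R, "R", 0, strict = TRUE))
  structure(out, class = "weibull_source")
}

#' Initial radial concentration profile
#'
#' A stretched-exponential profile
#' \eqn{c(r, 0) = c_0 + c_1 \exp(-a r^\alpha)}: a constant background
#' baseline \eqn{c_0} plus an excess of amplitude \eqn{c_1} at the injection
#' centre decaying radially with coefficient \eqn{a} and power \eqn{\alpha}.
#' All concentrations are on the dimensionless scaled-intensity axis
#' (intensities scaled by the maximum observable intensity), so
#' \eqn{c_0 + c_1 \le 1} is expected though not enforced.
#'
#' @param c0 baseline concentration (scaled intensity, >= 0).
#' @param c1 excess amplitude at the centre (scaled intensity, >= 0).
#' @param a radial decay coefficient (mm^-alpha, > 0).
#' @param alpha radial power (unitless, > 0).
#' @return An object of class \code{initial_condition}.
#' @export
initial_condition <- function(c0 = 0.1, c1 = 0.8, a = 0.16, alpha = 1.5) {
  out <- list(c0 = check_scalar(c0, "c0", 0),
              c1 = check_scalar(c1, "c1", 0),
              a = check_scalar(a, "a", 0, strict = TRUE),
              alpha = check_scalar(alpha, "alpha", 0, strict = TRUE))
  structure(out, class = "initial_condition")
}

#' Transport parameters
#'
#' Holds the apparent constant diffusivity \eqn{D} (mm^2/day), the single
#' empirical parameter lumping every in vivo transport process acting on the
#' released fluorophores into one Fickian coefficient.
#'
#' @param D apparent diffusivity (mm^2/day, > 0).
#' @return An object of class \code{transport}.
#' @export
transport <- function(D = 4.32) {
  structure(list(D = check_scalar(D, "D", 0, strict = TRUE)),
            class = "transport")
}

#' Reference model parameters
#'
#' The package's reference parameter set for the subcutaneous depot model:
#' source strength A = 500, Weibull shape 1.5 and scale 10 day, phase lag
#' 1.5 day, gel radius 0.42 mm (a modified gauge-18 indwelling needle),
#' initial profile 0.1 + 0.8 exp(-0.16 r^1.5), and apparent diffusivity
#' 4.32 mm^2/day.
#'
#' @return A list with elements \code{source}, \code{initial},
#'   \code{transport}.
#' @export
gel_params <- function() {
  list(source = weibull_source(),
       initial = initial_condition(),
       transport = transport())
}

#' Weibull probability density in time
#'
#' \eqn{w(t) = (k/\lambda)(t/\lambda)^{k-1} \exp(-(t/\lambda)^k)}; the
#' temporal shape of fluorophore release. Normalised to unit integral so that
#' the source amplitude \code{A} carries all strength. Thin validated wrapper
#' over [stats::dweibull()].
#'
#' @param t time (day, vectorised, >= 0).
#' @param k shape factor (> 0).
#' @param lam scale parameter (day, > 0).
#' @return Release rate density (1/day), same length as \code{t}.
#' @export
weibull_density <- function(t, k, lam) {
  k <- check_scalar(k, "k", 0, strict = TRUE)
  lam <- check_scalar(lam, "lam", 0, strict = TRUE)
  if (any(t < 0)) stop_config("'t' must be non-negative")
  stats::dweibull(t, shape = k, scale = lam)
}

#' Weibull cumulative distribution in time
#'
#' \eqn{1 - \exp(-(t/\lambda)^k)}: the fraction of the total releasable
#' amount already released by time \code{t} (before applying the phase lag).
#' Used by the mass bookkeeping.
#'
#' @inheritParams weibull_density
#' @return Released fraction in \[0, 1\].
#' @export
weibull_cdf <- function(t, k, lam) {
  k <- check_scalar(k, "k", 0, strict = TRUE)
  lam <- check_scalar(lam, "lam", 0, strict = TRUE)
  if (any(t < 0)) stop_config("'t' must be non-negative")
  stats::pweibull(t, shape = k, scale = lam)
}

#' Release source term S(r, t)
#'
#' \eqn{S(r,t) = A\, w(t + T)\, H(R - r)} with the inclusive convention
#' \eqn{H(0) = 1} (the rim \eqn{r = R} belongs to the gel). Zero outside the
#' gel disk and independent of angle.
#'
#' @param r radial position (mm, vectorised, >= 0).
#' @param t time (day, vectorised, >= 0); recycled against \code{r}.
#' @param src a [weibull_source()].
#' @return Release rate (scaled intensity / day).
#' @export
source_term <- function(r, t, src) {
  stopifnot(inherits(src, "weibull_source"))
  if (any(r < 0)) stop_config("'r' must be non-negative")
  if (any(t < 0)) stop_config("'t' must be non-negative")
  src$A * weibull_density(t + src$T_, src$k, src$lam) * as.numeric(r <= src$R)
}

#' Initial condition profile c(r, 0)
#'
#' Evaluates \eqn{c_0 + c_1 \exp(-a r^\alpha)}; tends to the baseline
#' \eqn{c_0} as \eqn{r \to \infty} and is strictly decreasing in \eqn{r}
#' whenever \eqn{c_1 > 0}.
#'
#' @param r radial position (mm, vectorised, >= 0).
#' @param ic an [initial_condition()].
#' @return Scaled concentration, same length as \code{r}.
#' @export
initial_condition_profile <- function(r, ic) {
  stopifnot(inherits(ic, "initial_condition"))
  if (any(r < 0)) stop_config("'r' must be non-negative")
  ic$c0 + ic$c1 * exp(-ic$a * r^ic$alpha)
}

#' Cumulative released amount
#'
#' Total amount released by the source over the plane and over \eqn{[0, t]}:
#' \eqn{\pi R^2 A [W(t + T) - W(T)]} with \eqn{W} the Weibull CDF. The phase
#' lag means a fraction \eqn{W(T)} of the distribution predates the start of
#' the observation and is never released.
#'
#' @param t time (day, vectorised, >= 0); \code{Inf} gives the total.
#' @param src a [weibull_source()].
#' @return Cumulative amount (intensity mm^2), monotone non-decreasing, 0 at
#'   \code{t = 0}.
#' @export
released_mass <- function(t, src) {
  stopifnot(inherits(src, "weibull_source"))
  if (any(t < 0)) stop_config("'t' must be non-negative")
  W <- function(x) stats::pweibull(x, shape = src$k, scale = src$lam)
  pi * src$R^2 * src$A * (W(t + src$T_) - W(src$T_))
}

#' Initial excess mass
#'
#' Plane integral of the baseline-subtracted initial profile:
#' \eqn{2\pi c_1 \int_0^\infty r e^{-a r^\alpha} dr =
#' (2\pi c_1/\alpha)\, a^{-2/\alpha}\, \Gamma(2/\alpha)}.
#'
#' @param ic an [initial_condition()].
#' @return Amount (intensity mm^2).
#' @export
initial_excess_mass <- function(ic) {
  stopifnot(inherits(ic, "initial_condition"))
  (2 * pi * ic$c1 / ic$alpha) * ic$a^(-2 / ic$alpha) * gamma(2 / ic$alpha)
}
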