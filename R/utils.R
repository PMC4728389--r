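`%||%` <- function(a, b) if (is.null(a)) b else a

#' Positive zeros of the Bessel function J0
#'
#' McMahon asymptotic estimates polished by two Newton steps
#' (J0'(x) = -J1(x)); accurate to machine precision for all m >= 1.
#'
#' @param n number of zeros.
#' @return The first \code{n} positive zeros of \eqn{J_0}.
#' @keywords internal
bessel_zeros_j0 <- function(n) {
  if (n < 1) return(numeric(0))
  b <- (seq_len(n) - 0.25) * pi
  z <- b + 1 / (8 * b) - 31 / (384 * b^3)
  for (it in 1:2) z <- z + besselJ(z, 0) / besselJ(z, 1)
  z
}

# composite Gauss-Legendre rule: `n_panels` equal panels on [a, b],
# `order` points per panel (via pracma::gaussLegendre on a base panel)
panel_gauss_rule <- function(a, b, n_panels, order) {
  base <- pracma::gaussLegendre(order, 0, 1)
  edges <- seq(a, b, length.out = n_panels + 1)
  lo <- edges[-length(edges)]
  width <- diff(edges)
  x <- as.vector(vapply(seq_len(n_panels),
                        function(i) lo[i] + base$x * width[i],
                        numeric(order)))
  w <- as.vector(vapply(seq_len(n_panels),
                        function(i) base$w * width[i],
                        numeric(order)))
  list(x = x, w = w, order = order, n_panels = n_panels)
}

# composite Simpson weights for an odd number of equally spaced points
simpson_weights <- function(n, h) {
  stopifnot(n >= 3, n %% 2 == 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w * h / 3
}
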