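#' Lag-logistic population density
#'
#' Closed form of the lag-logistic growth model: the population stays at
#' `x0` during the latency phase (`t < tau`) and follows the logistic
#' solution afterwards,
#' \deqn{x(t) = \frac{K x_0}{x_0 + (K - x_0)\, e^{-\mu (t - \tau)}},
#'   \qquad t \ge \tau,}
#' which is continuous at `t = tau` and converges to `K`.
#'
#' @param t Time(s) in hours, >= 0. Vectorized.
#' @param p A [growth_params()] object.
#' @return Population density (cfu cm^-2), same length as `t`.
#' @export
#' @examples
#' p <- growth_params(x0 = 2.7e4, mu = 0.94, K = 5.8e6, tau = 33)
#' logistic_value(c(0, 24, 48, 72), p)
logistic_value <- function(t, p) {
  validate_growth_params(p)
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be finite and >= 0", call. = FALSE)
  }
  dt <- pmax(t - p$tau, 0)
  # exp(-mu*dt) in the denominator is numerically safe: it lies in (0, 1]
  x <- p$K * p$x0 / (p$x0 + (p$K - p$x0) * exp(-p$mu * dt))
  x[t < p$tau] <- p$x0
  x
}

#' Right-hand side of the lag-logistic ODE
#'
#' The differential form of the growth model: zero during the latency
#' phase, `mu * x * (1 - x / K)` from the lag time onwards. Exposed so
#' that the closed form can be checked against numerical integration.
#'
#' @param t Time (h).
#' @param x Population density (cfu cm^-2), >= 0.
#' @param p A [growth_params()] object.
#' @return Growth rate dx/dt (cfu cm^-2 h^-1).
#' @export
growth_ode_rhs <- function(t, x, p) {
  validate_growth_params(p)
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  ifelse(t < p$tau, 0, p$mu * x * (1 - x / p$K))
}
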