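#' Lag-logistic growth parameters
#'
#' Bundle of the four parameters of the lag-logistic growth model used
#' throughout the package: a population sits at its post-adhesion density
#' `x0` until the lag time `tau`, then grows logistically at maximal rate
#' `mu` towards the carrying capacity `K`.
#'
#' @param x0 Initial density immediately after the adhesion step
#'   (cfu cm^-2, or cfu ml^-1 for planktonic cultures). Must be > 0.
#' @param mu Maximal growth rate (h^-1), >= 0. `mu = 0` yields a flat curve.
#' @param K Carrying capacity (cfu cm^-2), > 0.
#' @param tau Lag time (h), >= 0.
#'
#' @return An object of class `growth_params`.
#' @seealso [logistic_value()], [fit_growth()]
#' @export
#' @examples
#' growth_params(x0 = 2.7e4, mu = 0.94, K = 5.8e6, tau = 33)
growth_params <- function(x0, mu, K, tau) {
  p <- list(x0 = as.numeric(x0), mu = as.numeric(mu),
            K = as.numeric(K), tau = as.numeric(tau))
  validate_growth_params(p)
  structure(p, class = "growth_params")
}

validate_growth_params <- function(p) {
  for (nm in c("x0", "mu", "K", "tau")) {
    v <- p[[nm]]
    if (length(v) != 1L || !is.finite(v)) {
      stop("growth parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (p$x0 <= 0) stop("x0 must be > 0", call. = FALSE)
  if (p$K <= 0) stop("K must be > 0", call. = FALSE)
  if (p$mu < 0) stop("mu must be >= 0", call. = FALSE)
  if (p$tau < 0) stop("tau must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "<growth_params> x0 = %.3g cfu, mu = %.3g 1/h, K = %.3g cfu, tau = %.3g h\n",
    x$x0, x$mu, x$K, x$tau))
  invisible(x)
}

#' Box constraints for the growth-curve fitter
#'
#' Upper bounds on the growth rate and the lag time used by
#' [fit_growth()]. The defaults (`mu_max = 1` h^-1, `tau_max = 72` h)
#' are the bounds used for the biofilm time courses; `mu_max` is
#' configurable because fast growers such as *K. varians* in
#' mono-culture exceed 1 h^-1.
#'
#' @param mu_max Upper bound on `mu` (h^-1), > 0.
#' @param tau_max Upper bound on `tau` (h), > 0.
#' @return An object of class `fit_bounds`.
#' @export
fit_bounds <- function(mu_max = 1, tau_max = 72) {
  if (!is.finite(mu_max) || mu_max <= 0) stop("mu_max must be > 0", call. = FALSE)
  if (!is.finite(tau_max) || tau_max <= 0) stop("tau_max must be > 0", call. = FALSE)
  structure(list(mu_max = as.numeric(mu_max), tau_max = as.numeric(tau_max)),
            class = "fit_bounds")
}

#' An observed growth curve
#'
#' One colony-count time course: sampling times, observed counts, and
#' per-point censoring flags for observations below the plating detection
#' limit. Replicated designs are represented by repeating time points;
#' times must be non-decreasing (strictly increasing when each time occurs
#' once).
#'
#' @param times Sampling times (h), sorted non-decreasing.
#' @param counts Observed counts (cfu cm^-2); must be > 0 wherever not
#'   censored. Censored entries carry the detection limit as their value.
#' @param censored Logical vector, `TRUE` where the observation was below
#'   the detection limit. Default all `FALSE`.
#' @param detection_limit Detection limit (cfu cm^-2), default `1e3`.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(times, counts, censored = rep(FALSE, length(times)),
                         detection_limit = 1e3) {
  times <- as.numeric(times)
  counts <- as.numeric(counts)
  censored <- as.logical(censored)
  if (length(times) == 0L) stop("empty growth curve", call. = FALSE)
  if (length(counts) != length(times) || length(censored) != length(times)) {
    stop("times, counts and censored must have the same length", call. = FALSE)
  }
  if (is.unsorted(times)) stop("times must be sorted non-decreasing", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  bad <- !censored & (!is.finite(counts) | counts <= 0)
  if (any(bad)) {
    stop("non-censored counts must be finite and > 0 (offending index ",
         which(bad)[1L], ")", call. = FALSE)
  }
  structure(list(times = times, counts = counts, censored = censored,
                 detection_limit = as.numeric(detection_limit)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %d points over %g-%g h, %d censored (limit %g)\n",
              length(x$times), min(x$times), max(x$times),
              sum(x$censored), x$detection_limit))
  invisible(x)
}
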