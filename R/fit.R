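#' Detect apparent growth in a colony-count time course
#'
#' A curve is classified as growing when the largest replicate-averaged
#' log10 count exceeds the log10 count at the first sampling time by at
#' least `threshold` log10 units. The default of 0.5 (about 3-fold)
#' separates the flat *B. cereus*-type curves, whose net growth rate in
#' the biofilm is zero, from every curve for which the logistic fit is
#' meaningful.
#'
#' @param curve A [growth_curve()]; needs >= 2 non-censored points.
#' @param threshold Growth threshold in log10 units (default 0.5).
#' @return `TRUE` if growth is detected, `FALSE` otherwise.
#' @export
detect_growth <- function(curve, threshold = 0.5) {
  stopifnot(inherits(curve, "growth_curve"))
  ok <- !curve$censored
  if (!any(ok)) stop("all points are censored", call. = FALSE)
  if (sum(ok) < 2L) stop("need >= 2 non-censored points", call. = FALSE)
  lg <- tapply(log10(curve$counts[ok]), curve$times[ok], mean)
  unname(max(lg) - lg[[1L]] >= threshold)
}

# Least-squares objective on log10 counts; params as c(mu, tau, log10K).
# x0 fixed. Censored points are excluded upstream.
.logistic_sse <- function(theta, times, lcounts, x0) {
  mu <- theta[[1L]]; tau <- theta[[2L]]; K <- 10^theta[[3L]]
  dt <- pmax(times - tau, 0)
  x <- K * x0 / (x0 + (K - x0) * exp(-mu * dt))
  x[times < tau] <- x0
  sum((log10(x) - lcounts)^2)
}

#' Fit the lag-logistic model to a growth curve
#'
#' Constrained least squares on log10 counts: with `x0` fixed to the
#' count immediately after the adhesion step (the `t = 0` observation;
#' geometric mean when replicates are pooled), the fitter minimizes
#' \deqn{\sum_i \left(\log_{10} x_L(T_i) - \log_{10} X_i\right)^2}
#' over `mu` in `[0, mu_max]`, `tau` in `[0, tau_max]` and `K >= 0`.
#' Censored points are excluded from the sum. Optimization uses
#' multi-start box-constrained quasi-Newton ([stats::nlminb()]): a 4 x 4
#' grid of `(mu, tau)` starts over the bounded box plus one data-driven
#' start, `K` initialized at the maximum observed count; the best final
#' objective wins and exact ties are broken towards the smallest `tau`.
#'
#' Curves without apparent growth (see [detect_growth()]) are not fitted:
#' the returned status is `"no_growth"` and `K` is reported as the mean
#' of the observed counts, with `mu` and `tau` undefined (`NA`). Curves
#' whose `t = 0` point is censored, or with fewer than 4 usable points,
#' return status `"insufficient_data"`.
#'
#' @param curve A [growth_curve()] (replicates may be pooled as repeated
#'   time points).
#' @param bounds A [fit_bounds()] object.
#' @param growth_threshold Passed to [detect_growth()].
#' @return An object of class `fit_result`: a list with elements
#'   `params` ([growth_params()]), `status` (one of `"fitted"`,
#'   `"no_growth"`, `"insufficient_data"`), `sse` (objective value at the
#'   optimum, log10 units squared) and `n_points` (non-censored points
#'   used).
#' @export
#' @examples
#' p <- growth_params(x0 = 2.7e4, mu = 0.94, K = 5.8e6, tau = 33)
#' tt <- seq(0, 72, by = 6)
#' fit_growth(growth_curve(tt, logistic_value(tt, p)))
fit_growth <- function(curve, bounds = fit_bounds(), growth_threshold = 0.5) {
  stopifnot(inherits(curve, "growth_curve"), inherits(bounds, "fit_bounds"))
  ok <- !curve$censored
  times <- curve$times[ok]
  counts <- curve$counts[ok]
  n <- length(times)

  at0 <- times == min(curve$times) & times == 0
  if (!any(at0) || n < 4L) {
    return(new_fit_result(NULL, "insufficient_data", NA_real_, n))
  }
  x0 <- 10^mean(log10(counts[at0]))

  if (!detect_growth(curve, growth_threshold)) {
    params <- structure(list(x0 = x0, mu = NA_real_, K = mean(counts),
                             tau = NA_real_), class = "growth_params")
    return(new_fit_result(params, "no_growth", NA_real_, n))
  }

  lcounts <- log10(counts)
  lK_lo <- min(lcounts) - 3
  lK_hi <- max(lcounts) + 3
  lower <- c(0, 0, lK_lo)
  upper <- c(bounds$mu_max, bounds$tau_max, lK_hi)
  lK0 <- max(lcounts)

  starts <- expand.grid(
    mu = seq(bounds$mu_max / 8, bounds$mu_max, length.out = 4L),
    tau = seq(0, bounds$tau_max, length.out = 4L))
  # data-driven start: lag guessed as the last time the curve is still
  # within 0.25 log10 of x0, rate from the steepest log-linear segment
  lg <- tapply(lcounts, times, mean)
  ut <- as.numeric(names(lg))
  low <- which(lg - log10(x0) < 0.25)
  tau_guess <- if (length(low)) min(ut[max(low)], bounds$tau_max) else 0
  slopes <- diff(lg) / diff(ut) * log(10)
  mu_guess <- min(max(max(slopes), 0.01), bounds$mu_max)
  starts <- rbind(starts, data.frame(mu = mu_guess, tau = tau_guess))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nlminb(c(starts$mu[i], starts$tau[i], lK0), .logistic_sse,
                    lower = lower, upper = upper,
                    times = times, lcounts = lcounts, x0 = x0,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) ||
        fit$objective < best$objective - 1e-12 ||
        (abs(fit$objective - best$objective) <= 1e-12 &&
         fit$par[2L] < best$par[2L])) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("growth-curve fit failed to converge from any start (",
         nrow(starts), " starts, ", n, " points)", call. = FALSE)
  }

  params <- growth_params(x0 = x0, mu = best$par[1L], K = 10^best$par[3L],
                          tau = best$par[2L])
  new_fit_result(params, "fitted", best$objective, n)
}

new_fit_result <- function(params, status, sse, n_points) {
  structure(list(params = params, status = status, sse = sse,
                 n_points = n_points), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> status = %s, n = %d", x$status, x$n_points))
  if (x$status == "fitted") {
    cat(sprintf(", sse = %.4g\n", x$sse))
    print(x$params)
  } else if (x$status == "no_growth") {
    cat(sprintf("\n  mean population level K = %.3g cfu\n", x$params$K))
  } else {
    cat("\n")
  }
  invisible(x)
}

#' Fit every (species, context) time course of a count table
#'
#' Pools replicates into one residual sum per (species, context) cell and
#' runs [fit_growth()] on each.
#'
#' @param table A count table (see [read_count_table()]).
#' @param bounds A [fit_bounds()] object.
#' @param growth_threshold Passed to [detect_growth()].
#' @return A data.frame with one row per (species, context): columns
#'   `species`, `context`, `x0`, `mu`, `K`, `tau`, `status`, `sse`,
#'   `n_points`.
#' @export
fit_all_contexts <- function(table, bounds = fit_bounds(),
                             growth_threshold = 0.5) {
  table <- validate_count_table(table)
  cells <- unique(table[, c("context", "species")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- table[table$context == cells$context[i] &
                 table$species == cells$species[i], ]
    sub <- sub[order(sub$time_h, sub$replicate), ]
    curve <- growth_curve(sub$time_h, sub$cfu_per_cm2, sub$censored,
                          detection_limit = sub$detection_limit[1L])
    fit <- tryCatch(fit_growth(curve, bounds, growth_threshold),
                    error = function(e) new_fit_result(
                      NULL, "insufficient_data", NA_real_,
                      sum(!curve$censored)))
    data.frame(
      species = cells$species[i], context = cells$context[i],
      x0 = if (is.null(fit$params)) NA_real_ else fit$params$x0,
      mu = if (is.null(fit$params)) NA_real_ else fit$params$mu,
      K = if (is.null(fit$params)) NA_real_ else fit$params$K,
      tau = if (is.null(fit$params)) NA_real_ else fit$params$tau,
      status = fit$status, sse = fit$sse, n_points = fit$n_points,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$context, out$species), , drop = FALSE]
}
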