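test_that("logistic closed form handles latency, asymptote and fixed point", {
  p <- growth_params(x0 = 1e4, mu = 0.5, K = 1e7, tau = 20)
  expect_identical(logistic_value(10, p), 1e4)          # latency phase
  expect_equal(logistic_value(1e3, p), 1e7, tolerance = 1e-9)  # asymptote
  pf <- growth_params(x0 = 1e6, mu = 0.5, K = 1e6, tau = 0)
  expect_equal(logistic_value(50, pf), 1e6)             # x0 = K fixed point
  # continuity at t = tau
  expect_equal(logistic_value(p$tau, p), logistic_value(p$tau - 1e-12, p),
               tolerance = 1e-9)
})

test_that("logistic closed form is monotone as expected", {
  tt <- seq(0, 96, by = 0.5)
  up <- growth_params(x0 = 1e3, mu = 0.8, K = 1e7, tau = 5)
  down <- growth_params(x0 = 1e7, mu = 0.8, K = 1e3, tau = 5)
  flat <- growth_params(x0 = 1e5, mu = 0.8, K = 1e5, tau = 5)
  expect_true(all(diff(logistic_value(tt, up)) >= 0))
  expect_true(all(diff(logistic_value(tt, down)) <= 0))
  expect_equal(logistic_value(tt, flat), rep(1e5, length(tt)))
})

test_that("invalid parameters and times are rejected", {
  expect_error(growth_params(-1, 0.5, 1e6, 0), "x0")
  expect_error(growth_params(1e3, -0.5, 1e6, 0), "mu")
  expect_error(growth_params(1e3, 0.5, 0, 0), "K")
  expect_error(growth_params(1e3, 0.5, 1e6, -2), "tau")
  expect_error(growth_params(1e3, Inf, 1e6, 0), "finite")
  p <- growth_params(1e3, 0.5, 1e6, 0)
  expect_error(logistic_value(-1, p), "t must be")
})

test_that("ODE right-hand side matches its piecewise definition", {
  p <- growth_params(x0 = 1e4, mu = 0.4, K = 2e6, tau = 10)
  expect_identical(growth_ode_rhs(5, 1e4, p), 0)            # latency
  expect_equal(growth_ode_rhs(20, p$K, p), 0)               # at capacity
  expect_equal(growth_ode_rhs(20, p$K / 2, p), 0.1 * p$K)   # algebra
})

test_that("closed form agrees with RK4 integration of the ODE", {
  # the four-species P. fluorescens parameters at t = 48 h ...
  x <- rk4_logistic(48, x0 = 2.7e4, mu = 0.94, K = 5.8e6, tau = 33)
  p <- growth_params(x0 = 2.7e4, mu = 0.94, K = 5.8e6, tau = 33)
  expect_equal(logistic_value(48, p), x, tolerance = 1e-6)
  # ... and a randomized parameter grid
  set.seed(11)
  for (i in 1:100) {
    pr <- growth_params(x0 = 10^runif(1, 2, 5), mu = runif(1, 0.05, 2),
                        K = 10^runif(1, 5, 8), tau = runif(1, 0, 48))
    t_end <- runif(1, pr$tau, 96)
    expect_equal(logistic_value(t_end, pr),
                 rk4_logistic(t_end, pr$x0, pr$mu, pr$K, pr$tau),
                 tolerance = 1e-6)
  }
})

test_that("growth detection separates flat from growing curves", {
  tt <- c(0, 24, 48, 72)
  flat <- growth_curve(tt, c(7.9e4, 8e4, 7e4, 9e4))     # B. cereus-like
  expect_false(detect_growth(flat))
  expect_true(detect_growth(growth_curve(tt, c(1e4, 1e5, 1e6, 1e7))))
  just_below <- growth_curve(c(0, 24), c(1e5, 1e5 * 10^0.49))
  expect_false(detect_growth(just_below))
  expect_true(detect_growth(growth_curve(c(0, 24), c(1e5, 1e5 * 10^0.51))))
  all_cens <- growth_curve(tt, rep(1e3, 4), censored = rep(TRUE, 4))
  expect_error(detect_growth(all_cens), "censored")
})

test_that("noiseless curves return the generating parameters", {
  tt <- seq(0, 72, by = 6)
  p <- growth_params(x0 = 2.7e4, mu = 0.94, K = 5.8e6, tau = 33)
  fit <- fit_growth(growth_curve(tt, logistic_value(tt, p)), fit_bounds())
  expect_identical(fit$status, "fitted")
  expect_equal(fit$params$mu, p$mu, tolerance = 1e-3)
  expect_equal(fit$params$K, p$K, tolerance = 1e-3)
  expect_equal(fit$params$tau, p$tau, tolerance = 1e-3)
  # recovery across the identifiable regime (>= 3 mid-rise points)
  set.seed(4)
  for (i in 1:5) {
    pr <- growth_params(x0 = 10^runif(1, 3, 4.5), mu = runif(1, 0.15, 0.6),
                        K = 10^runif(1, 6.5, 7.5), tau = runif(1, 0, 30))
    fr <- fit_growth(growth_curve(tt, logistic_value(tt, pr)), fit_bounds())
    expect_equal(fr$params$mu, pr$mu, tolerance = 1e-3)
    expect_equal(log10(fr$params$K), log10(pr$K), tolerance = 1e-3)
    expect_equal(fr$params$tau, pr$tau, tolerance = 1e-2)
  }
})

test_that("flat curves are reported as no-growth with the mean level", {
  curve <- growth_curve(c(0, 24, 48, 72, 96), rep(2.3e5, 5))
  fit <- fit_growth(curve)
  expect_identical(fit$status, "no_growth")
  expect_equal(fit$params$K, 2.3e5)
  expect_true(is.na(fit$params$mu) && is.na(fit$params$tau))
})

test_that("censored early time points make the fit insufficient", {
  tt <- c(0, 24, 48, 72, 96)
  curve <- growth_curve(tt, c(1e3, 1e3, 5e6, 1.4e7, 1.5e7),
                        censored = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  fit <- fit_growth(curve)
  expect_identical(fit$status, "insufficient_data")
  expect_error(fit_growth(growth_curve(numeric(0), numeric(0))), "empty")
})

test_that("fitter optimum is no worse than a 20^3 grid search", {
  set.seed(21)
  p <- growth_params(x0 = 2.9e3, mu = 0.25, K = 8.3e6, tau = 0)
  curve <- make_noisy_curve(p, noise_sd = 0.1)
  fit <- fit_growth(curve, fit_bounds())
  ok <- !curve$censored
  lc <- log10(curve$counts[ok])
  x0 <- 10^mean(lc[curve$times[ok] == 0])
  grid <- expand.grid(mu = seq(1e-3, 1, length.out = 20),
                      tau = seq(0, 72, length.out = 20),
                      lK = seq(min(lc) - 1, max(lc) + 1, length.out = 20))
  g_best <- min(vapply(seq_len(nrow(grid)), function(i) {
    oracle_sse(grid$mu[i], grid$tau[i], 10^grid$lK[i], x0,
               curve$times[ok], lc)
  }, numeric(1)))
  expect_lte(fit$sse, g_best + 1e-9)
})

test_that("parameter recovery under plate-count noise is accurate", {
  # median relative error of mu-hat and log10 K-hat < 10% over 100 runs
  set.seed(99)
  p <- growth_params(x0 = 2.7e4, mu = 0.25, K = 1.7e7, tau = 0)
  err_mu <- err_lk <- numeric(100)
  for (i in 1:100) {
    fit <- fit_growth(make_noisy_curve(p), fit_bounds())
    err_mu[i] <- abs(fit$params$mu - p$mu) / p$mu
    err_lk[i] <- abs(log10(fit$params$K) - log10(p$K)) / log10(p$K)
  }
  expect_lt(stats::median(err_mu), 0.10)
  expect_lt(stats::median(err_lk), 0.10)
})

test_that("pooled fits run per (species, context) over a count table", {
  tab <- simulate_counts(default_scenario(seed = 3,
                                          times = seq(0, 72, by = 6)))
  fits <- fit_all_contexts(tab, fit_bounds(mu_max = 2.5))
  expect_setequal(
    fits$status[fits$species == "Bc"], "no_growth")
  expect_identical(
    fits$status[fits$species == "Rh" & fits$context == "mono_Rh"],
    "insufficient_data")
  expect_identical(
    fits$status[fits$species == "Kv" & fits$context == "four_species"],
    "no_growth")
  kv4 <- fits[fits$species == "Kv" & fits$context == "four_species", ]
  expect_equal(log10(kv4$K), log10(1.05e5), tolerance = 0.1)
  pf4 <- fits[fits$species == "Pf" & fits$context == "four_species", ]
  expect_identical(pf4$status, "fitted")
  expect_equal(pf4$tau, 33, tolerance = 4)
})
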