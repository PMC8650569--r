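# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantity they check.

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
mw_enumerate_p <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  n_tot <- length(pooled)
  u_stat <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_stat(seq_len(m))
  combos <- utils::combn(n_tot, m)
  us <- apply(combos, 2, u_stat)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Fixed-step classical RK4 integration of the lag-logistic ODE, with the
# latency phase handled analytically (x = x0 for t <= tau).
rk4_logistic <- function(t_end, x0, mu, K, tau, n_steps = 4000) {
  if (t_end <= tau) return(x0)
  rhs <- function(x) mu * x * (1 - x / K)
  h <- (t_end - tau) / n_steps
  x <- x0
  for (i in seq_len(n_steps)) {
    k1 <- rhs(x)
    k2 <- rhs(x + h / 2 * k1)
    k3 <- rhs(x + h / 2 * k2)
    k4 <- rhs(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# Independent closed-form SSE (re-derived here, not via logistic_value)
# for the grid-search oracle on the fitter.
oracle_sse <- function(mu, tau, K, x0, times, lcounts) {
  x <- ifelse(times < tau, x0,
              K * x0 / (x0 + (K - x0) * exp(-mu * pmax(times - tau, 0))))
  sum((log10(x) - lcounts)^2)
}

# Noisy pooled-replicate curve from known parameters.
make_noisy_curve <- function(p, noise_sd = 0.1, replicates = 5,
                             times = seq(0, 72, by = 6),
                             detection_limit = 0) {
  tt <- rep(times, replicates)
  truth <- logistic_value(tt, p)
  obs <- truth * 10^stats::rnorm(length(tt), sd = noise_sd)
  o <- order(tt)
  growth_curve(tt[o], obs[o], detection_limit = detection_limit)
}

# Minimal hand-built count table.
make_table <- function(context, species, counts, time_h = 72,
                       censored = FALSE, detection_limit = 1e3) {
  n <- length(counts)
  count_table(data.frame(
    context = context, species = species, replicate = seq_len(n),
    time_h = time_h, cfu_per_cm2 = counts,
    censored = rep(censored, length.out = n),
    detection_limit = detection_limit, stringsAsFactors = FALSE))
}
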