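# deterministic per-(context, replicate) sub-seed so that adding contexts
# never perturbs the draws of existing ones
stream_seed <- function(master, context, replicate) {
  txt <- paste(context, replicate, sep = "\r")
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(master) + h) %% 2147483647)
}

#' Simulate a colony-count data set
#'
#' For every (context, species in context, replicate, time) the expected
#' density is the lag-logistic value under the species'
#' [effective_params()] in that context; the observation multiplies it by
#' `10^eps` with `eps ~ Normal(0, noise_sd)` (lognormal plate-count
#' noise). Observations below the detection limit are recorded as the
#' detection limit with `censored = TRUE`. One RNG stream is derived per
#' (context, replicate) from the master seed, so the output is fully
#' reproducible and adding contexts never changes existing draws.
#'
#' @param config A [scenario_config()].
#' @param seed Master seed; defaults to `config$seed`. Required (an
#'   unseeded simulation would not be reproducible from its manifest).
#' @return A [count_table()].
#' @export
#' @examples
#' tab <- simulate_counts(default_scenario(seed = 1))
#' head(tab)
simulate_counts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(seed)) stop("a master seed is required", call. = FALSE)
  out <- vector("list", length(config$contexts) * config$replicates)
  k <- 0L
  for (ctx_name in names(config$contexts)) {
    ctx <- config$contexts[[ctx_name]]
    expected <- lapply(ctx, function(sp) {
      logistic_value(config$times, effective_params(sp, ctx, config))
    })
    names(expected) <- ctx
    for (rep_i in seq_len(config$replicates)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      set.seed(stream_seed(seed, ctx_name, rep_i))
      eps <- stats::rnorm(length(ctx) * length(config$times),
                          sd = config$noise_sd)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      obs <- unlist(expected, use.names = FALSE) * 10^eps
      cen <- obs < config$detection_limit
      obs[cen] <- config$detection_limit
      k <- k + 1L
      out[[k]] <- data.frame(
        context = ctx_name,
        species = rep(ctx, each = length(config$times)),
        replicate = rep_i,
        time_h = rep(config$times, times = length(ctx)),
        cfu_per_cm2 = obs,
        censored = cen,
        detection_limit = config$detection_limit,
        stringsAsFactors = FALSE)
    }
  }
  validate_count_table(do.call(rbind, out))
}

#' Simulate the planktonic coculture
#'
#' Convenience wrapper running [simulate_counts()] on the planktonic
#' preset (see [planktonic_scenario()]); densities are cfu ml^-1 and
#' context labels carry the `planktonic_` prefix.
#'
#' @param config A planktonic [scenario_config()].
#' @param seed Master seed; defaults to `config$seed`.
#' @return A [count_table()].
#' @export
simulate_planktonic <- function(config = planktonic_scenario(),
                                seed = config$seed) {
  simulate_counts(config, seed = seed)
}
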