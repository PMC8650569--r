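#' Species specification for the simulator
#'
#' A species' name, its mono-culture growth parameters, and the inoculum
#' density fed to the adhesion step (5e6 cfu ml^-1 of each species in the
#' standard design; the adhesion outcome itself is summarized by
#' `base_params$x0`).
#'
#' @param name Species label (e.g. `"Kv"`).
#' @param base_params [growth_params()] in mono-culture context.
#' @param adhesion_input Inoculum density (cfu ml^-1), default `5e6`.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(name, base_params, adhesion_input = 5e6) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  validate_growth_params(base_params)
  if (!is.finite(adhesion_input) || adhesion_input <= 0) {
    stop("adhesion_input must be > 0", call. = FALSE)
  }
  structure(list(name = name, base_params = base_params,
                 adhesion_input = adhesion_input), class = "species_spec")
}

#' Context-dependent parameter modifier
#'
#' Encodes one interspecies effect as a modification of a growth
#' parameter that is switched on by the community context. A modifier
#' fires for its `target` species in a context when
#' * `trigger = "all"`: every species in `source` is present among the
#'   other community members;
#' * `trigger = "any"`: at least one of them is (used for effects of
#'   "any multi-species context");
#' and, additionally, none of the species in `absent` is present. The
#' `absent` set expresses conditional (mitigated) effects: e.g. the
#' *B. cereus* suppression of *K. varians* deepens when a mitigating
#' species is missing.
#'
#' Multiplicative modifiers compose by product and additive ones by sum,
#' so the application order never matters.
#'
#' @param source Character vector of triggering species.
#' @param target Target species name.
#' @param parameter One of `"x0"`, `"mu"`, `"K"`, `"tau"`.
#' @param mode `"multiply"` or `"add"` (`"add"` is natural for `tau`, in
#'   hours).
#' @param value Factor (> 0) for `"multiply"`, offset for `"add"`.
#' @param trigger `"all"` (default) or `"any"`.
#' @param absent Character vector of species whose presence vetoes the
#'   modifier (default none).
#' @return An object of class `interaction_modifier`.
#' @export
interaction_modifier <- function(source, target, parameter,
                                 mode = c("multiply", "add"), value,
                                 trigger = c("all", "any"),
                                 absent = character()) {
  mode <- match.arg(mode)
  trigger <- match.arg(trigger)
  parameter <- match.arg(parameter, c("x0", "mu", "K", "tau"))
  if (mode == "multiply" && (!is.finite(value) || value <= 0)) {
    stop("multiplicative modifier value must be > 0", call. = FALSE)
  }
  structure(list(source = as.character(source), target = target,
                 parameter = parameter, mode = mode,
                 value = as.numeric(value), trigger = trigger,
                 absent = as.character(absent)),
            class = "interaction_modifier")
}

#' Simulation scenario
#'
#' Everything needed to generate a synthetic colony-count data set:
#' species with mono-culture parameters, context-dependent interaction
#' modifiers, the community contexts to simulate, sampling times,
#' replication, plate-count noise, detection limit and the RNG seed.
#'
#' @param species List of [species_spec()].
#' @param modifiers List of [interaction_modifier()].
#' @param contexts Named list of character vectors (species subsets); the
#'   names become the `context` labels of the output table.
#' @param times Sampling times (h), default `c(0, 24, 48, 72, 96)`.
#' @param replicates Independent replicates per context, default 5.
#' @param noise_sd Lognormal plate-count noise, sd in log10 units,
#'   default 0.1.
#' @param detection_limit Detection limit (cfu cm^-2), default `1e3`.
#' @param seed Master RNG seed (integer) or `NULL`.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(species, modifiers = list(), contexts,
                            times = c(0, 24, 48, 72, 96), replicates = 5L,
                            noise_sd = 0.1, detection_limit = 1e3,
                            seed = NULL) {
  stopifnot(length(species) >= 1L, is.list(contexts), length(contexts) >= 1L)
  names_sp <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(names_sp)) stop("duplicate species names", call. = FALSE)
  if (is.null(names(contexts)) || any(!nzchar(names(contexts)))) {
    stop("contexts must be a named list", call. = FALSE)
  }
  for (ctx in contexts) {
    unknown <- setdiff(ctx, names_sp)
    if (length(unknown)) {
      stop("context references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  for (m in modifiers) {
    unknown <- setdiff(c(m$source, m$target, m$absent), names_sp)
    if (length(unknown)) {
      stop("modifier references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(species = species, modifiers = modifiers,
                 contexts = contexts, times = as.numeric(times),
                 replicates = as.integer(replicates),
                 noise_sd = as.numeric(noise_sd),
                 detection_limit = as.numeric(detection_limit),
                 seed = seed),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %d species, %d modifiers, %d contexts, %d times x %d replicates, noise_sd = %g\n",
    length(x$species), length(x$modifiers), length(x$contexts),
    length(x$times), x$replicates, x$noise_sd))
  invisible(x)
}

#' Effective growth parameters of a species in a community context
#'
#' Applies to the species' mono-culture `base_params` every modifier that
#' fires in the given context (see [interaction_modifier()]).
#' Multiplicative modifiers compose by product and additive ones by sum,
#' so the result does not depend on the order of the modifier list.
#'
#' @param species Species name; must be a member of `context`.
#' @param context Character vector of species present (a subset of the
#'   scenario's species).
#' @param config A [scenario_config()].
#' @return A [growth_params()] object.
#' @export
effective_params <- function(species, context, config) {
  names_sp <- vapply(config$species, function(s) s$name, character(1))
  idx <- match(species, names_sp)
  if (is.na(idx)) stop("unknown species: ", species, call. = FALSE)
  unknown <- setdiff(context, names_sp)
  if (length(unknown)) {
    stop("unknown species in context: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!species %in% context) {
    stop("species '", species, "' is not part of the context", call. = FALSE)
  }
  p <- unclass(config$species[[idx]]$base_params)
  others <- setdiff(context, species)
  mult <- c(x0 = 1, mu = 1, K = 1, tau = 1)
  add <- c(x0 = 0, mu = 0, K = 0, tau = 0)
  for (m in config$modifiers) {
    if (!identical(m$target, species)) next
    fires <- if (m$trigger == "all") all(m$source %in% others)
             else any(m$source %in% others)
    if (!fires || any(m$absent %in% context)) next
    if (m$mode == "multiply") mult[[m$parameter]] <- mult[[m$parameter]] * m$value
    else add[[m$parameter]] <- add[[m$parameter]] + m$value
  }
  for (nm in names(mult)) {
    p[[nm]] <- p[[nm]] * mult[[nm]] + add[[nm]]
    if (p[[nm]] < 0) {
      stop("modifiers drive parameter '", nm, "' of ", species,
           " below zero", call. = FALSE)
    }
  }
  growth_params(p$x0, p$mu, p$K, p$tau)
}

# ---- presets -------------------------------------------------------------

#' Standard four-species biofilm scenario
#'
#' The default preset encodes the wild-type four-species biofilm: the
#' mono-culture parameter sets and the context-dependent modifiers that
#' reproduce the measured community behavior — the ~200-fold suppression
#' of the *K. varians* carrying capacity by *B. cereus* (deepened when a
#' mitigating species, *P. fluorescens* or *Rhodocyclus*, is absent), the
#' 33 h lag imposed on *P. fluorescens* in multi-species communities, and
#' the adhesion/early-development facilitation of *Rhodocyclus* by the
#' other species. Contexts are the four mono-cultures, the four
#' single-species omissions and the full community, sampled at
#' 0/24/48/72/96 h with 5 replicates and sigma = 0.1 log10 plate-count
#' noise.
#'
#' With `amensalism = FALSE` the thiocillin-null (Delta tclE-H) variant
#' is returned: the *B. cereus* -> *K. varians* modifiers are removed and
#' replaced by a mild generic community limitation, leaving the mutant
#' community *K. varians* level about 50-fold above the wild-type
#' community level; the *Rhodocyclus* community capacity drops about
#' 3-fold.
#'
#' @param amensalism Keep the *B. cereus* -> *K. varians* suppression
#'   (default `TRUE`).
#' @param seed Master RNG seed stored in the config.
#' @param replicates,noise_sd,times,detection_limit Overrides of the
#'   standard design.
#' @return A [scenario_config()].
#' @export
default_scenario <- function(amensalism = TRUE, seed = NULL, replicates = 5L,
                             noise_sd = 0.1, times = c(0, 24, 48, 72, 96),
                             detection_limit = 1e3) {
  species <- list(
    species_spec("Rh", growth_params(x0 = 5e2, mu = 0.5, K = 1.5e7, tau = 24)),
    species_spec("Pf", growth_params(x0 = 2.7e4, mu = 0.25, K = 1.7e7, tau = 0)),
    species_spec("Kv", growth_params(x0 = 7.7e4, mu = 1.93, K = 2.1e7, tau = 3)),
    species_spec("Bc", growth_params(x0 = 7.9e4, mu = 0, K = 7.9e4, tau = 0)))

  mod <- list(
    # Rhodocyclus: facilitation of adhesion and initial development by the
    # community; maps the mono preset onto the four-species fit
    # (x0 2.9e3, mu 0.25, K 8.3e6, tau 0)
    interaction_modifier(c("Pf", "Kv", "Bc"), "Rh", "x0", "multiply",
                         2.9e3 / 5e2, trigger = "any"),
    interaction_modifier(c("Pf", "Kv", "Bc"), "Rh", "mu", "multiply",
                         0.25 / 0.5, trigger = "any"),
    interaction_modifier(c("Pf", "Kv", "Bc"), "Rh", "K", "multiply",
                         8.3e6 / 1.5e7, trigger = "any"),
    interaction_modifier(c("Pf", "Kv", "Bc"), "Rh", "tau", "add", -24,
                         trigger = "any"),
    # P. fluorescens: delayed development in any multi-species context
    # (mu 0.25 -> 0.94, K 1.7e7 -> 5.8e6, tau 0 -> 33 h)
    interaction_modifier(c("Rh", "Kv", "Bc"), "Pf", "mu", "multiply",
                         0.94 / 0.25, trigger = "any"),
    interaction_modifier(c("Rh", "Kv", "Bc"), "Pf", "K", "multiply",
                         5.8e6 / 1.7e7, trigger = "any"),
    interaction_modifier(c("Rh", "Kv", "Bc"), "Pf", "tau", "add", 33,
                         trigger = "any"))

  if (amensalism) {
    mod <- c(mod, list(
      # B. cereus amensalism on K. varians: ~200-fold capacity suppression
      interaction_modifier("Bc", "Kv", "K", "multiply", 1 / 200),
      # mitigation by P. fluorescens / Rhodocyclus: suppression deepens
      # when the mitigating species is missing
      interaction_modifier("Bc", "Kv", "K", "multiply", 1.2e4 / 1.05e5,
                           absent = "Pf"),
      interaction_modifier("Bc", "Kv", "K", "multiply", 3.5e3 / 1.05e5,
                           absent = "Rh")))
  } else {
    mod <- c(mod, list(
      # thiocillin-null community: mild generic limitation keeps the mutant
      # community K. varians ~50-fold above the wild-type community level
      interaction_modifier(c("Rh", "Pf", "Bc"), "Kv", "K", "multiply", 0.25,
                           trigger = "any"),
      interaction_modifier(c("Pf", "Kv", "Bc"), "Rh", "K", "multiply", 1 / 3,
                           trigger = "any")))
  }

  all_sp <- c("Rh", "Pf", "Kv", "Bc")
  contexts <- c(
    stats::setNames(as.list(all_sp), paste0("mono_", all_sp)),
    stats::setNames(lapply(all_sp, function(s) setdiff(all_sp, s)),
                    paste0("no_", all_sp)),
    list(four_species = all_sp))

  scenario_config(species, mod, contexts, times = times,
                  replicates = replicates, noise_sd = noise_sd,
                  detection_limit = detection_limit, seed = seed)
}

#' Planktonic coculture scenario
#'
#' Liquid-culture counterpart of [default_scenario()]. The thiocillin
#' suppression of *K. varians* does not operate in the planktonic
#' coculture, and the 72-h community is far more even; carrying
#' capacities are set proportional to the expected 72-h proportions
#' (Bc 38.2, Rh 29.8, Pf 18.0, Kv 14.0 percent of 1e9 cfu ml^-1 total),
#' with all species starting from the 5e6 cfu ml^-1 inoculum. Context
#' labels carry the `planktonic_` prefix; densities are cfu ml^-1.
#'
#' @inheritParams default_scenario
#' @return A [scenario_config()].
#' @export
planktonic_scenario <- function(seed = NULL, replicates = 5L, noise_sd = 0.1,
                                times = c(0, 24, 48, 72, 96)) {
  pct <- c(Bc = 38.2, Rh = 29.8, Pf = 18.0, Kv = 14.0)
  species <- lapply(names(pct), function(nm) {
    species_spec(nm, growth_params(x0 = 5e6, mu = 0.5, K = pct[[nm]] * 1e7,
                                   tau = 0))
  })
  all_sp <- names(pct)
  contexts <- c(
    list(planktonic_four_species = all_sp),
    stats::setNames(as.list(all_sp), paste0("planktonic_mono_", all_sp)))
  scenario_config(species, list(), contexts, times = times,
                  replicates = replicates, noise_sd = noise_sd,
                  detection_limit = 1e3, seed = seed)
}

#' Perturbed-condition scenarios
#'
#' Variants of the standard full-community scenario used for robustness
#' analysis.
#'
#' `undiluted_medium_scenario()` emulates growth in non-diluted medium:
#' *Rhodocyclus* collapses below the detection limit, *P. fluorescens*
#' capacity increases ~20-fold, the *B. cereus* level ~18-fold, and
#' *K. varians* is slightly (~1.7-fold, not significantly) raised. Only
#' the `four_species` context is generated.
#'
#' `bc_inoculum_scenario()` emulates the transient perturbation where the
#' *B. cereus* inoculum is reduced (default 1000-fold, giving ~2.5e3
#' cfu cm^-2 after adhesion); *B. cereus* then grows back to its standard
#' community level, so the endpoint community is unchanged.
#'
#' @inheritParams default_scenario
#' @return A [scenario_config()] with the single `four_species` context.
#' @export
undiluted_medium_scenario <- function(seed = NULL, replicates = 5L,
                                      noise_sd = 0.1,
                                      times = c(0, 24, 48, 72, 96)) {
  cfg <- default_scenario(seed = seed, replicates = replicates,
                          noise_sd = noise_sd, times = times)
  cfg$contexts <- cfg$contexts["four_species"]
  others <- function(sp) setdiff(c("Rh", "Pf", "Kv", "Bc"), sp)
  cfg$modifiers <- c(cfg$modifiers, list(
    interaction_modifier(others("Rh"), "Rh", "K", "multiply", 1e-5,
                         trigger = "any"),
    interaction_modifier(others("Rh"), "Rh", "x0", "multiply", 0.2,
                         trigger = "any"),
    interaction_modifier(others("Pf"), "Pf", "K", "multiply", 20,
                         trigger = "any"),
    interaction_modifier(others("Bc"), "Bc", "x0", "multiply", 18,
                         trigger = "any"),
    interaction_modifier(others("Bc"), "Bc", "K", "multiply", 18,
                         trigger = "any"),
    interaction_modifier(others("Kv"), "Kv", "K", "multiply", 1.8e5 / 1.05e5,
                         trigger = "any")))
  cfg
}

#' @rdname undiluted_medium_scenario
#' @param dilution Fold-reduction of the *B. cereus* inoculum (10, 100 or
#'   1000).
#' @export
bc_inoculum_scenario <- function(dilution = 1000, seed = NULL,
                                 replicates = 5L, noise_sd = 0.1,
                                 times = c(0, 24, 48, 72, 96)) {
  x0_map <- c("10" = 2.5e4, "100" = 8e3, "1000" = 2.5e3)
  key <- as.character(dilution)
  if (!key %in% names(x0_map)) {
    stop("dilution must be one of 10, 100, 1000", call. = FALSE)
  }
  cfg <- default_scenario(seed = seed, replicates = replicates,
                          noise_sd = noise_sd, times = times)
  cfg$contexts <- cfg$contexts["four_species"]
  is_bc <- vapply(cfg$species, function(s) s$name == "Bc", logical(1))
  # diluted B. cereus regrows to its standard community level
  cfg$species[[which(is_bc)]] <- species_spec(
    "Bc", growth_params(x0 = x0_map[[key]], mu = 0.25, K = 7.9e4, tau = 0),
    adhesion_input = 5e6 / dilution)
  cfg
}
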