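#' Serialize a scenario to YAML
#'
#' Round-trips a [scenario_config()] through a plain YAML file so that
#' scenario presets can be stored, edited and passed to the command-line
#' interface.
#'
#' @param config A [scenario_config()].
#' @param path File path.
#' @export
write_scenario_yaml <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  obj <- list(
    species = lapply(config$species, function(s) list(
      name = s$name,
      x0 = s$base_params$x0, mu = s$base_params$mu,
      K = s$base_params$K, tau = s$base_params$tau,
      adhesion_input = s$adhesion_input)),
    modifiers = lapply(config$modifiers, function(m) list(
      source = as.list(m$source), target = m$target,
      parameter = m$parameter, mode = m$mode, value = m$value,
      trigger = m$trigger, absent = as.list(m$absent))),
    contexts = lapply(config$contexts, as.list),
    times = as.list(config$times),
    replicates = config$replicates,
    noise_sd = config$noise_sd,
    detection_limit = config$detection_limit,
    seed = config$seed)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  species <- lapply(obj$species, function(s) {
    species_spec(s$name, growth_params(s$x0, s$mu, s$K, s$tau),
                 adhesion_input = s$adhesion_input)
  })
  modifiers <- lapply(obj$modifiers, function(m) {
    interaction_modifier(unlist(m$source), m$target, m$parameter, m$mode,
                         m$value, trigger = m$trigger,
                         absent = as.character(unlist(m$absent)))
  })
  scenario_config(species, modifiers,
                  contexts = lapply(obj$contexts, unlist),
                  times = unlist(obj$times),
                  replicates = obj$replicates, noise_sd = obj$noise_sd,
                  detection_limit = obj$detection_limit, seed = obj$seed)
}
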