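#' Compare a species between two community contexts
#'
#' Quantifies how a target species differs between two cultivation
#' contexts (e.g. mono-culture vs the four-species community, or the
#' full community vs an omission): fold changes of each fitted growth
#' parameter plus the endpoint abundance with a Mann-Whitney p value.
#' Fold changes are `context_b / context_a` for multiplicative
#' parameters (`x0`, `mu`, `K`, endpoint abundance) and the difference
#' `b - a` in hours for `tau`. For curves without apparent growth
#' (status `no_growth`) only the mean population level `K` is compared.
#' Swapping `context_a` and `context_b` inverts every fold change and
#' negates the `tau` difference while preserving the p value.
#'
#' @param fits Data.frame from [fit_all_contexts()], or `NULL` to
#'   compare endpoint abundance only.
#' @param table A [count_table()] containing both contexts.
#' @param target Species name (present in both contexts).
#' @param context_a,context_b Context labels.
#' @param endpoint_time Endpoint (h); default the largest time present
#'   in both contexts.
#' @return A data.frame of class `context_effect` with one row per
#'   compared parameter: `target`, `context_a`, `context_b`,
#'   `parameter`, `value_a`, `value_b`, `fold_change`, `p_value`.
#' @export
compare_contexts <- function(fits, table, target, context_a, context_b,
                             endpoint_time = NULL) {
  table <- validate_count_table(table)
  for (ctx in c(context_a, context_b)) {
    if (!any(table$context == ctx & table$species == target)) {
      stop("target '", target, "' absent from context '", ctx, "'",
           call. = FALSE)
    }
  }
  sub_a <- table[table$context == context_a & table$species == target, ]
  sub_b <- table[table$context == context_b & table$species == target, ]
  if (is.null(endpoint_time)) {
    endpoint_time <- max(intersect(sub_a$time_h, sub_b$time_h))
  }
  end_a <- sub_a$cfu_per_cm2[sub_a$time_h == endpoint_time]
  end_b <- sub_b$cfu_per_cm2[sub_b$time_h == endpoint_time]
  if (length(end_a) < 3L || length(end_b) < 3L) {
    stop("need >= 3 endpoint replicates per context", call. = FALSE)
  }
  gm <- function(x) 10^mean(log10(x))
  mw <- mann_whitney_compare(log10(end_a), log10(end_b))
  rows <- list(data.frame(
    target = target, context_a = context_a, context_b = context_b,
    parameter = "endpoint_abundance", value_a = gm(end_a),
    value_b = gm(end_b), fold_change = gm(end_b) / gm(end_a),
    p_value = mw$p_retained, stringsAsFactors = FALSE))

  if (!is.null(fits)) {
    fa <- fits[fits$species == target & fits$context == context_a, ]
    fb <- fits[fits$species == target & fits$context == context_b, ]
    if (nrow(fa) == 1L && nrow(fb) == 1L) {
      both_fitted <- fa$status == "fitted" && fb$status == "fitted"
      usable <- c("fitted", "no_growth")
      pars <- if (both_fitted) c("x0", "mu", "K", "tau")
              else if (fa$status %in% usable && fb$status %in% usable) "K"
              else character()
      for (pn in pars) {
        va <- fa[[pn]]; vb <- fb[[pn]]
        rows[[length(rows) + 1L]] <- data.frame(
          target = target, context_a = context_a, context_b = context_b,
          parameter = pn, value_a = va, value_b = vb,
          fold_change = if (pn == "tau") vb - va else vb / va,
          p_value = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("context_effect", class(out))
  out
}

# label of the context holding exactly these species, or NA
context_label_for <- function(table, species_set) {
  by_ctx <- split(table$species, table$context)
  for (nm in names(by_ctx)) {
    if (setequal(unique(by_ctx[[nm]]), species_set)) return(nm)
  }
  NA_character_
}

#' Endpoint effects of the single-species omission design
#'
#' For every target species of the full community, compares the full
#' community against each omission context that still contains the
#' target, using [compare_contexts()] endpoint rows; annotates each
#' effect with the omitted species.
#'
#' @param table A [count_table()] containing the full community context
#'   and its single-species omissions.
#' @param full_context Label of the full community context; by default
#'   the context with the largest species set.
#' @param endpoint_time Endpoint (h); default the latest common time.
#' @return A `context_effect` data.frame with an extra `omitted` column.
#' @export
omission_effects <- function(table, full_context = NULL,
                             endpoint_time = NULL) {
  table <- validate_count_table(table)
  sets <- lapply(split(table$species, table$context), unique)
  if (is.null(full_context)) {
    full_context <- names(sets)[which.max(lengths(sets))]
  }
  full <- sets[[full_context]]
  missing_ctx <- character()
  rows <- list()
  for (om in full) {
    ctx_b <- context_label_for(table, setdiff(full, om))
    if (is.na(ctx_b)) {
      missing_ctx <- c(missing_ctx, paste0("omission of ", om))
      next
    }
    for (target in setdiff(full, om)) {
      eff <- compare_contexts(NULL, table, target, full_context, ctx_b,
                              endpoint_time = endpoint_time)
      eff$omitted <- om
      rows[[length(rows) + 1L]] <- eff
    }
  }
  if (length(missing_ctx)) {
    stop("incomplete omission design; missing context(s): ",
         paste(missing_ctx, collapse = ", "), call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Classify signed interaction edges from omission effects
#'
#' Applies the omission-design logic: omitting species X significantly
#' *increases* target Y (endpoint fold change at least `fold_floor` and
#' Mann-Whitney p below `alpha`) gives a negative edge X -> Y; the edge
#' is labelled `amensalism` when the reciprocal check shows X itself
#' unaffected by the presence of Y, `competition` otherwise. Omitting Z
#' significantly *decreases* Y gives a positive edge Z -> Y, labelled
#' `mitigation` when a negative edge onto Y exists (the conditioning
#' edge is recorded), `facilitation` otherwise. Effects failing either
#' the significance or the effect-size floor yield no edge. The output
#' is invariant under permutation of the input rows.
#'
#' @param effects Output of [omission_effects()] (endpoint rows with an
#'   `omitted` column).
#' @param alpha Significance level (default 0.05).
#' @param fold_floor Minimal endpoint fold change to call an edge
#'   (default 3, i.e. 0.5 log10), preventing significance-without-
#'   magnitude calls.
#' @return A data.frame of class `interaction_edges`: `source`,
#'   `target`, `sign`, `type`, `parameter`, `magnitude` (release /
#'   suppression fold, always > 1), `p_value`, `conditioning`.
#' @export
classify_edges <- function(effects, alpha = 0.05, fold_floor = 3) {
  stopifnot(all(c("target", "omitted", "fold_change", "p_value") %in%
                names(effects)))
  eff <- effects[effects$parameter == "endpoint_abundance", ]
  eff <- eff[order(eff$omitted, eff$target), ]
  hit <- eff$p_value < alpha &
    (eff$fold_change >= fold_floor | eff$fold_change <= 1 / fold_floor)
  up <- hit & eff$fold_change >= fold_floor      # omission releases target
  down <- hit & eff$fold_change <= 1 / fold_floor

  edges <- list()
  neg_targets <- unique(eff$target[up])
  for (i in base::which(up)) {
    x <- eff$omitted[i]; y <- eff$target[i]
    recip <- eff[eff$target == x & eff$omitted == y, ]
    recip_affected <- nrow(recip) == 1L && recip$p_value < alpha &&
      (recip$fold_change >= fold_floor || recip$fold_change <= 1 / fold_floor)
    edges[[length(edges) + 1L]] <- data.frame(
      source = x, target = y, sign = "negative",
      type = if (recip_affected) "competition" else "amensalism",
      parameter = "endpoint_abundance", magnitude = eff$fold_change[i],
      p_value = eff$p_value[i], conditioning = NA_character_,
      stringsAsFactors = FALSE)
  }
  for (i in base::which(down)) {
    z <- eff$omitted[i]; y <- eff$target[i]
    neg_on_y <- vapply(edges, function(e) {
      e$target == y && e$sign == "negative"
    }, logical(1))
    cond <- if (any(neg_on_y)) {
      e <- edges[[base::which(neg_on_y)[1L]]]
      paste0(e$source, "->", e$target)
    } else NA_character_
    edges[[length(edges) + 1L]] <- data.frame(
      source = z, target = y, sign = "positive",
      type = if (!is.na(cond)) "mitigation" else "facilitation",
      parameter = "endpoint_abundance", magnitude = 1 / eff$fold_change[i],
      p_value = eff$p_value[i], conditioning = cond,
      stringsAsFactors = FALSE)
  }
  out <- if (length(edges)) do.call(rbind, edges) else data.frame(
    source = character(), target = character(), sign = character(),
    type = character(), parameter = character(), magnitude = numeric(),
    p_value = numeric(), conditioning = character(),
    stringsAsFactors = FALSE)
  out <- out[order(out$source, out$target, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_edges", class(out))
  out
}

#' Edges from growth-parameter comparisons (mono vs community)
#'
#' Complements the endpoint-based omission logic with the dynamic
#' effects visible in the fitted growth parameters: a community-imposed
#' lag extension of at least `tau_delay_min` hours yields a negative
#' `delay` edge onto the delayed species, and an increase of the
#' post-adhesion density `x0` (at least `fold_floor`, or a mono-culture
#' start below the detection limit rising above it in the community)
#' yields a positive `facilitation` edge. The source of these collective
#' effects is the set of other community members, joined with `+`.
#'
#' @param fits Data.frame from [fit_all_contexts()].
#' @param table The [count_table()] the fits came from (used for the
#'   earliest-non-censored `x0` comparison).
#' @param community Label of the full community context.
#' @param mono_prefix Prefix of mono-culture context labels.
#' @param tau_delay_min Minimal lag extension (h) to call a delay edge.
#' @param fold_floor Minimal `x0` fold change for facilitation.
#' @return An `interaction_edges` data.frame (possibly empty).
#' @export
growth_parameter_edges <- function(fits, table, community = "four_species",
                                   mono_prefix = "mono_",
                                   tau_delay_min = 8, fold_floor = 3) {
  table <- validate_count_table(table)
  comm_species <- unique(table$species[table$context == community])
  edges <- list()
  for (sp in comm_species) {
    mono <- paste0(mono_prefix, sp)
    if (!any(table$context == mono)) next
    others <- paste(sort(setdiff(comm_species, sp)), collapse = "+")
    fm <- fits[fits$species == sp & fits$context == mono, ]
    fc <- fits[fits$species == sp & fits$context == community, ]
    if (nrow(fm) == 1L && nrow(fc) == 1L &&
        fm$status == "fitted" && fc$status == "fitted" &&
        (fc$tau - fm$tau) >= tau_delay_min) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = others, target = sp, sign = "negative", type = "delay",
        parameter = "tau", magnitude = fc$tau - fm$tau,
        p_value = NA_real_, conditioning = NA_character_,
        stringsAsFactors = FALSE)
    }
    # earliest-time density comparison; censored mono starts are bounded
    # from above by the detection limit
    t0m <- table[table$context == mono & table$species == sp &
                 table$time_h == min(table$time_h), ]
    t0c <- table[table$context == community & table$species == sp &
                 table$time_h == min(table$time_h), ]
    if (!nrow(t0m) || !nrow(t0c)) next
    mono_censored <- all(t0m$censored)
    x0m <- if (mono_censored) t0m$detection_limit[1L]
           else 10^mean(log10(t0m$cfu_per_cm2[!t0m$censored]))
    x0c <- 10^mean(log10(t0c$cfu_per_cm2))
    fold <- x0c / x0m
    if ((fold >= fold_floor) ||
        (mono_censored && !any(t0c$censored) && fold > 1)) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = others, target = sp, sign = "positive",
        type = "facilitation", parameter = "x0", magnitude = fold,
        p_value = NA_real_, conditioning = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(edges)) do.call(rbind, edges) else data.frame(
    source = character(), target = character(), sign = character(),
    type = character(), parameter = character(), magnitude = numeric(),
    p_value = numeric(), conditioning = character(),
    stringsAsFactors = FALSE)
  class(out) <- c("interaction_edges", class(out))
  out
}

#' Assemble and validate the interaction network
#'
#' Deterministically ordered edge list (source, target, parameter
#' lexicographic); duplicate (source, target, parameter) edges are an
#' error.
#'
#' @param edges An `interaction_edges` data.frame (e.g. from
#'   [classify_edges()], possibly rbound with
#'   [growth_parameter_edges()]).
#' @return The sorted, validated edge table.
#' @export
build_network <- function(edges) {
  key <- paste(edges$source, edges$target, edges$parameter, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (source, target, parameter) edge: ",
         gsub("\r", " -> ", key[duplicated(key)][1L]), call. = FALSE)
  }
  out <- edges[order(edges$source, edges$target, edges$parameter), ,
               drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_edges", class(out))
  out
}

#' End-to-end interaction inference from a count table
#'
#' Runs the omission-design endpoint comparisons, classifies signed
#' edges, optionally adds growth-parameter (delay / adhesion
#' facilitation) edges from mono-culture fits, and assembles the
#' network.
#'
#' @param table A [count_table()] with the full community and its
#'   single-species omissions (mono contexts optional).
#' @param fits Optional [fit_all_contexts()] output; computed on demand
#'   when `include_parameter_edges = TRUE` and not supplied.
#' @param alpha,fold_floor Passed to [classify_edges()].
#' @param endpoint_time Endpoint (h).
#' @param include_parameter_edges Add delay / facilitation edges from
#'   mono-vs-community fits (default `FALSE`).
#' @return An `interaction_edges` data.frame.
#' @export
#' @examples
#' tab <- simulate_counts(default_scenario(seed = 1))
#' infer_interactions(tab)
infer_interactions <- function(table, fits = NULL, alpha = 0.05,
                               fold_floor = 3, endpoint_time = 72,
                               include_parameter_edges = FALSE) {
  eff <- omission_effects(table, endpoint_time = endpoint_time)
  edges <- classify_edges(eff, alpha = alpha, fold_floor = fold_floor)
  if (include_parameter_edges) {
    if (is.null(fits)) {
      fits <- fit_all_contexts(table, fit_bounds(mu_max = 2.5))
    }
    edges <- rbind(edges, growth_parameter_edges(fits, table,
                                                 fold_floor = fold_floor))
  }
  build_network(edges)
}

#' Write a network edge list
#'
#' `write_network_tsv()` writes the plain edge table;
#' `write_network_dot()` writes Graphviz DOT with solid/dashed styling
#' for negative/positive edges.
#'
#' @param edges An `interaction_edges` data.frame.
#' @param path File path.
#' @export
write_network_tsv <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
write_network_dot <- function(edges, path) {
  lines <- c("digraph interactions {")
  nodes <- unique(unlist(strsplit(c(edges$source, edges$target), "+",
                                  fixed = TRUE)))
  lines <- c(lines, sprintf("  \"%s\";", nodes))
  for (i in seq_len(nrow(edges))) {
    style <- if (edges$sign[i] == "negative") "solid" else "dashed"
    arrow <- if (edges$sign[i] == "negative") "tee" else "normal"
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [style=%s, arrowhead=%s, label=\"%s (%.3g)\"];",
      edges$source[i], edges$target[i], style, arrow, edges$type[i],
      edges$magnitude[i]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
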