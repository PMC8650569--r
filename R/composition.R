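#' Community composition at one time point
#'
#' Per-species proportions of the total count in one context at one
#' sampling time. Means are taken across replicates first, and the
#' proportions are the replicate means divided by the summed means, in
#' percent. Species below the detection limit contribute zero by default
#' (with an explicit flag); with `impute_midpoint = TRUE` censored
#' observations contribute the log-scale midpoint of the imputation
#' range (the detection limit itself) instead.
#'
#' @param table A [count_table()].
#' @param context Context label.
#' @param time Sampling time (h).
#' @param impute_midpoint Replace censored observations by the detection
#'   limit instead of zero (default `FALSE`).
#' @return An object of class `composition_snapshot`: list with
#'   `context`, `time`, `total` (summed mean cfu) and `proportions`, a
#'   data.frame with `species`, `mean_cfu`, `proportion_pct`,
#'   `censored`.
#' @export
#' @examples
#' tab <- simulate_counts(default_scenario(seed = 1))
#' proportions(tab, "four_species", 72)
proportions <- function(table, context, time, impute_midpoint = FALSE) {
  table <- validate_count_table(table)
  sub <- table[table$context == context & table$time_h == time, ]
  if (!nrow(sub)) stop("no rows at (", context, ", ", time, " h)", call. = FALSE)
  if (all(sub$censored)) {
    stop("all species censored at (", context, ", ", time,
         " h): zero total", call. = FALSE)
  }
  vals <- ifelse(sub$censored,
                 if (impute_midpoint) sub$detection_limit else 0,
                 sub$cfu_per_cm2)
  mean_cfu <- tapply(vals, sub$species, mean)
  flagged <- tapply(sub$censored, sub$species, any)
  total <- sum(mean_cfu)
  if (total <= 0) stop("zero total count", call. = FALSE)
  df <- data.frame(species = names(mean_cfu),
                   mean_cfu = as.numeric(mean_cfu),
                   proportion_pct = 100 * as.numeric(mean_cfu) / total,
                   censored = as.logical(flagged),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$proportion_pct), ]
  rownames(df) <- NULL
  structure(list(context = context, time = time, total = total,
                 proportions = df), class = "composition_snapshot")
}

#' @export
print.composition_snapshot <- function(x, ...) {
  cat(sprintf("<composition_snapshot> %s at %g h, total %.3g cfu\n",
              x$context, x$time, x$total))
  print(x$proportions, digits = 3)
  invisible(x)
}

# Tukey HSD p values for same-species contrasts between pairs of times
# within one context; returns data.frame(species, t1, t2, p)
time_tukey_contrasts <- function(sub) {
  f_sp <- factor(sub$species)
  f_t <- factor(sub$time_h)
  y <- log10(sub$cfu_per_cm2)
  tt <- sort(unique(sub$time_h))
  out <- list()
  if (nlevels(f_sp) > 1L) {
    fit <- stats::aov(y ~ f_sp * f_t)
    tk <- stats::TukeyHSD(fit, "f_sp:f_t")[["f_sp:f_t"]]
    for (sp in levels(f_sp)) {
      for (i in seq_along(tt)) {
        for (j in seq_len(i - 1L)) {
          nm1 <- paste0(sp, ":", tt[i], "-", sp, ":", tt[j])
          nm2 <- paste0(sp, ":", tt[j], "-", sp, ":", tt[i])
          hit <- if (nm1 %in% rownames(tk)) nm1 else nm2
          out[[length(out) + 1L]] <- data.frame(
            species = sp, t1 = tt[j], t2 = tt[i],
            p = unname(tk[hit, "p adj"]), stringsAsFactors = FALSE)
        }
      }
    }
  } else {
    fit <- stats::aov(y ~ f_t)
    tk <- stats::TukeyHSD(fit, "f_t")[["f_t"]]
    sp <- levels(f_sp)
    for (i in seq_along(tt)) {
      for (j in seq_len(i - 1L)) {
        nm1 <- paste0(tt[i], "-", tt[j])
        nm2 <- paste0(tt[j], "-", tt[i])
        hit <- if (nm1 %in% rownames(tk)) nm1 else nm2
        out[[length(out) + 1L]] <- data.frame(
          species = sp, t1 = tt[j], t2 = tt[i],
          p = unname(tk[hit, "p adj"]), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Earliest steady-state (equilibrium) time of a community
#'
#' Operationalizes "the community stopped changing": the earliest
#' sampling time T from which onwards no species' log10 abundance
#' changes significantly (Tukey HSD at `alpha` within a
#' species-by-time ANOVA).
#' * `mode = "all_later"` (default, stricter): every contrast between T
#'   and each later time must be non-significant for every species.
#' * `mode = "consecutive"`: every contrast between consecutive
#'   readings from T onwards must be non-significant — the comparison
#'   made between successive readings of the time course.
#' Returns the first sampling time for data flat from the start and
#' `NA` when change is still significant across the final interval.
#'
#' @param table A [count_table()].
#' @param context Context label (default `"four_species"`).
#' @param alpha Significance level.
#' @param mode `"all_later"` or `"consecutive"`.
#' @return The equilibrium time (h), or `NA_real_` if none.
#' @export
#' @examples
#' tab <- simulate_counts(default_scenario(seed = 1))
#' steady_state_time(tab, "four_species", mode = "consecutive")
steady_state_time <- function(table, context = "four_species", alpha = 0.05,
                              mode = c("all_later", "consecutive")) {
  mode <- match.arg(mode)
  table <- validate_count_table(table)
  sub <- table[table$context == context, ]
  if (!nrow(sub)) stop("context '", context, "' not in table", call. = FALSE)
  tt <- sort(unique(sub$time_h))
  if (length(tt) < 2L) stop("need >= 2 time points", call. = FALSE)
  if (length(tt) < 3L) warning("only two time points; equilibrium call is weak")
  ct <- time_tukey_contrasts(sub)
  sig_pair <- function(a, b) any(ct$p[ct$t1 == a & ct$t2 == b] < alpha)
  m <- length(tt)
  if (mode == "consecutive") {
    interval_sig <- vapply(seq_len(m - 1L),
                           function(i) sig_pair(tt[i], tt[i + 1L]), logical(1))
    for (j in seq_len(m - 1L)) {
      if (!any(interval_sig[j:(m - 1L)])) return(tt[j])
    }
  } else {
    for (j in seq_len(m - 1L)) {
      later <- tt[(j + 1L):m]
      if (!any(vapply(later, function(b) sig_pair(tt[j], b), logical(1)))) {
        return(tt[j])
      }
    }
  }
  NA_real_
}

#' Response of the community to a perturbation
#'
#' Compares an endpoint community grown under a perturbed condition with
#' the standard condition: per-species endpoint fold change plus
#' significance from a two-way (species x condition) ANOVA with Tukey's
#' HSD post-test on log10 counts. When either table contains censored
#' rows at the endpoint the test is routed through
#' [repeated_imputation_test()]. The community is called `altered` when
#' at least one species differs significantly at `alpha`, `robust`
#' otherwise.
#'
#' @param standard,perturbed [count_table()]s sharing species and the
#'   endpoint time (contexts may differ in label).
#' @param alpha Significance level.
#' @param endpoint_time Endpoint (h); default the latest shared time.
#' @param spec [imputation_spec()] for censored endpoints.
#' @param seed Seed for the imputation draws.
#' @return An object of class `robustness_report`: list with `verdict`
#'   (`"robust"` or `"altered"`), `endpoint_time`, and `species`, a
#'   data.frame with `species`, `fold_change`, `p_retained`, `stars`.
#' @export
perturbation_response <- function(standard, perturbed, alpha = 0.05,
                                  endpoint_time = NULL,
                                  spec = imputation_spec(), seed = NULL) {
  standard <- validate_count_table(standard)
  perturbed <- validate_count_table(perturbed)
  sp <- sort(unique(standard$species))
  if (!setequal(sp, unique(perturbed$species))) {
    stop("species mismatch between the two tables", call. = FALSE)
  }
  if (is.null(endpoint_time)) {
    endpoint_time <- max(intersect(standard$time_h, perturbed$time_h))
  }
  a <- standard[standard$time_h == endpoint_time, ]
  b <- perturbed[perturbed$time_h == endpoint_time, ]
  a$condition <- "standard"
  b$condition <- "perturbed"
  comb <- rbind(
    a[, c("species", "condition", "cfu_per_cm2", "censored",
          "detection_limit")],
    b[, c("species", "condition", "cfu_per_cm2", "censored",
          "detection_limit")])
  test_fun <- function(tab) {
    two_way_anova_tukey(tab, factors = c("species", "condition"),
                        alpha = alpha)
  }
  res <- if (any(comb$censored)) {
    repeated_imputation_test(comb, spec, test_fun, seed = seed,
                             alpha = alpha)
  } else {
    test_fun(comb)
  }
  gm <- function(x) 10^mean(log10(x))
  rows <- lapply(sp, function(s) {
    fa <- gm(a$cfu_per_cm2[a$species == s])
    fb <- gm(b$cfu_per_cm2[b$species == s])
    hit <- grepl(paste0("^", s, ":"), res$contrast)
    p <- if (any(hit)) max(res$p_retained[hit]) else NA_real_
    data.frame(species = s, fold_change = fb / fa, p_retained = p,
               stars = significance_stars(p), stringsAsFactors = FALSE)
  })
  species_df <- do.call(rbind, rows)
  verdict <- if (any(species_df$p_retained < alpha, na.rm = TRUE)) {
    "altered"
  } else {
    "robust"
  }
  structure(list(verdict = verdict, endpoint_time = endpoint_time,
                 alpha = alpha, species = species_df),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("<robustness_report> verdict: %s (endpoint %g h, alpha %g)\n",
              x$verdict, x$endpoint_time, x$alpha))
  print(x$species, digits = 3)
  invisible(x)
}

#' Write composition / robustness summaries as TSV
#'
#' @param x A `composition_snapshot` or `robustness_report`.
#' @param path File path.
#' @export
write_report_tsv <- function(x, path) {
  df <- if (inherits(x, "composition_snapshot")) x$proportions
        else if (inherits(x, "robustness_report")) x$species
        else as.data.frame(x)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stacked-bar composition plot
#'
#' Mean per-species abundances over time for one context, stacked on the
#' linear cfu scale. Requires ggplot2.
#'
#' @param table A [count_table()].
#' @param context Context label.
#' @return A ggplot object.
#' @export
plot_composition <- function(table, context = "four_species") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_composition() needs the ggplot2 package", call. = FALSE)
  }
  table <- validate_count_table(table)
  sub <- table[table$context == context, ]
  agg <- stats::aggregate(
    cfu_per_cm2 ~ species + time_h,
    data = transform(sub, cfu_per_cm2 = ifelse(sub$censored, 0,
                                               sub$cfu_per_cm2)),
    FUN = mean)
  ggplot2::ggplot(agg, ggplot2::aes(x = factor(time_h), y = cfu_per_cm2,
                                    fill = species)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "time (h)", y = "mean cfu per cm2",
                  title = paste("Community composition:", context)) +
    ggplot2::theme_minimal()
}
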