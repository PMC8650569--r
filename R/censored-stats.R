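#' Randomized-imputation settings for below-detection counts
#'
#' Below-detection observations are replaced by random values spanning
#' the detection limit plus or minus one on a log scale: uniform in log10
#' between `low` (default 1e2) and `high` (default 1e4 cfu cm^-2). The
#' imputation-plus-test procedure is repeated `n_repeats` times (default
#' 20). `scale_factor` is the multiplier used by sensitivity re-runs that
#' widen or shift the range tenfold.
#'
#' @param low,high Range bounds (cfu cm^-2), `0 < low < high`.
#' @param n_repeats Number of imputation repeats, >= 1.
#' @param scale_factor Sensitivity multiplier (default 10).
#' @return An object of class `imputation_spec`.
#' @export
imputation_spec <- function(low = 1e2, high = 1e4, n_repeats = 20L,
                            scale_factor = 10) {
  if (!(low > 0 && high > low)) stop("need 0 < low < high", call. = FALSE)
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  structure(list(low = as.numeric(low), high = as.numeric(high),
                 n_repeats = as.integer(n_repeats),
                 scale_factor = as.numeric(scale_factor)),
            class = "imputation_spec")
}

#' Impute below-detection counts
#'
#' Replaces the count of every censored row by `10^u` with
#' `u ~ Uniform(log10(low), log10(high))`; non-censored rows are
#' untouched and the censoring flags are preserved for audit (the
#' returned table is marked as imputed so the flag no longer implies
#' that the stored value equals the detection limit).
#'
#' @param table A [count_table()].
#' @param spec An [imputation_spec()].
#' @param seed Optional seed for the draw.
#' @return The table with imputed counts; attribute `imputed = TRUE`.
#' @export
impute_censored <- function(table, spec = imputation_spec(), seed = NULL) {
  stopifnot(is.data.frame(table))
  if (!is.null(seed)) set.seed(seed)
  idx <- which(table$censored)
  if (length(idx)) {
    u <- stats::runif(length(idx), log10(spec$low), log10(spec$high))
    table$cfu_per_cm2[idx] <- 10^u
  }
  attr(table, "imputed") <- TRUE
  table
}

#' Significance stars
#'
#' Deterministic star coding of a p value at the conventional levels:
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, otherwise `ns`.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Character vector of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
significance_stars <- function(p) {
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out
}

test_summary_row <- function(contrast, statistic, p, n_repeats_used = 1L,
                             alpha = 0.05) {
  data.frame(contrast = contrast, statistic = statistic,
             p_retained = p, n_repeats_used = as.integer(n_repeats_used),
             significant = p < alpha, stars = significance_stars(p),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two count groups
#'
#' Two-sided rank-sum test, used for the species-omission comparisons
#' against the full four-species community. The exact null distribution
#' is used for combined sample sizes up to 12 (when no ties are present);
#' larger or tied samples use the normal approximation with tie
#' correction.
#'
#' @param group_a,group_b Numeric vectors of counts, each of length >= 3.
#' @param alpha Significance level for the `significant` flag.
#' @return A one-row `TestSummary` data.frame: `contrast`, `statistic`
#'   (the rank-sum statistic W), `p_retained`, `n_repeats_used`,
#'   `significant`, `stars`.
#' @export
#' @examples
#' mann_whitney_compare(1:5, 6:10)  # p = 2/252
mann_whitney_compare <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 3L || length(group_b) < 3L) {
    stop("each group needs >= 3 values", call. = FALSE)
  }
  if (length(unique(c(group_a, group_b))) == 1L) {
    warning("all values tied across both groups; p = 1")
    return(test_summary_row("A vs B", length(group_a) * length(group_b) / 2,
                            1, alpha = alpha))
  }
  n_tot <- length(group_a) + length(group_b)
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0L
  wt <- if (n_tot <= 12L && !has_ties) {
    stats::wilcox.test(group_a, group_b, exact = TRUE)
  } else {
    stats::wilcox.test(group_a, group_b, exact = FALSE, correct = TRUE)
  }
  test_summary_row("A vs B", unname(wt$statistic), wt$p.value, alpha = alpha)
}

#' Two-way ANOVA with Tukey's HSD post-test on log10 counts
#'
#' Fits `log10(cfu) ~ factor1 * factor2` by [stats::aov()] and extracts
#' Tukey honestly-significant-difference contrasts between the
#' interaction cells. By default only the contrasts of interest for the
#' figures are returned: comparisons between levels of the second factor
#' within each level of the first (e.g. the same species across two
#' conditions or times); `which = "all"` returns every pairwise cell
#' contrast. Adjusted p values are Tukey's, over the full cell family.
#'
#' @param table A [count_table()] (possibly imputed).
#' @param factors Character vector of two column names, default
#'   `c("species", "time_h")`.
#' @param contrasts `"within_first"` (default) or `"all"`.
#' @param alpha Significance level for the `significant` flag.
#' @return A `TestSummary` data.frame, one row per contrast, with
#'   `contrast` formatted as `"A:x vs A:y"`.
#' @export
two_way_anova_tukey <- function(table, factors = c("species", "time_h"),
                                contrasts = c("within_first", "all"),
                                alpha = 0.05) {
  contrasts <- match.arg(contrasts)
  stopifnot(length(factors) == 2L, all(factors %in% names(table)))
  f1 <- factor(table[[factors[1L]]])
  f2 <- factor(table[[factors[2L]]])
  if (nlevels(f1) < 2L || nlevels(f2) < 2L) {
    stop("each factor needs >= 2 levels", call. = FALSE)
  }
  counts <- base::table(f1, f2)
  empty <- counts == 0L
  if (any(empty)) {
    i <- base::which(empty, arr.ind = TRUE)[1L, ]
    stop("empty cell: ", factors[1L], " = ", rownames(counts)[i[1L]], ", ",
         factors[2L], " = ", colnames(counts)[i[2L]], call. = FALSE)
  }
  if (any(counts < 2L)) {
    i <- base::which(counts < 2L, arr.ind = TRUE)[1L, ]
    stop("cell with a single replicate (no residual df): ",
         factors[1L], " = ", rownames(counts)[i[1L]], ", ",
         factors[2L], " = ", colnames(counts)[i[2L]], call. = FALSE)
  }
  y <- log10(table$cfu_per_cm2)
  fit <- stats::aov(y ~ f1 * f2)
  tk <- stats::TukeyHSD(fit, "f1:f2")[["f1:f2"]]
  # map rownames "a:x-b:y" back to cell pairs without string surgery on
  # user labels: build the expected names from the interaction levels
  cells <- levels(interaction(f1, f2, sep = ":", lex.order = TRUE))
  keep <- data.frame(a = character(), b = character())
  for (i in seq_along(cells)) {
    for (j in seq_len(i - 1L)) {
      la <- sub(":.*$", "", cells[i]); lb <- sub(":.*$", "", cells[j])
      if (contrasts == "all" || la == lb) {
        keep <- rbind(keep, data.frame(a = cells[i], b = cells[j]))
      }
    }
  }
  rows <- lapply(seq_len(nrow(keep)), function(r) {
    nm1 <- paste0(keep$a[r], "-", keep$b[r])
    nm2 <- paste0(keep$b[r], "-", keep$a[r])
    hit <- if (nm1 %in% rownames(tk)) nm1 else nm2
    if (!hit %in% rownames(tk)) return(NULL)
    test_summary_row(paste(keep$a[r], "vs", keep$b[r]),
                     unname(tk[hit, "diff"]), unname(tk[hit, "p adj"]),
                     alpha = alpha)
  })
  do.call(rbind, rows)
}

#' Repeated randomized-imputation testing
#'
#' Runs [impute_censored()] followed by the supplied test `n_repeats`
#' times with independent draws and retains, per contrast, a
#' conservative p value. The default retention rule is the upper limit
#' of the 95% confidence interval of the mean p across repeats,
#' `mean(p) + t[0.975, n-1] * sd(p) / sqrt(n)`, truncated to `[0, 1]`;
#' `method = "percentile"` retains the empirical 95th percentile of the
#' p sample instead. Tables without censored rows are tested once and
#' returned unchanged (`n_repeats_used = 1`).
#'
#' @param table A [count_table()].
#' @param spec An [imputation_spec()].
#' @param test A function mapping an (imputed) table to a `TestSummary`
#'   data.frame, e.g. `function(x) two_way_anova_tukey(x, c("species",
#'   "condition"))`.
#' @param seed Seed controlling all imputation draws.
#' @param method `"ci_upper"` (default) or `"percentile"`.
#' @param alpha Significance level for the `significant` flag.
#' @return A `TestSummary` data.frame; `statistic` is the mean statistic
#'   across repeats.
#' @export
repeated_imputation_test <- function(table, spec = imputation_spec(), test,
                                     seed = NULL,
                                     method = c("ci_upper", "percentile"),
                                     alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(is.function(test))
  if (!any(table$censored)) {
    res <- test(table)
    res$n_repeats_used <- 1L
    return(res)
  }
  n <- spec$n_repeats
  runs <- lapply(seq_len(n), function(i) {
    imp <- impute_censored(table, spec,
                           seed = if (is.null(seed)) NULL else seed + i)
    test(imp)
  })
  contrasts <- runs[[1L]]$contrast
  rows <- lapply(seq_along(contrasts), function(k) {
    p <- vapply(runs, function(r) r$p_retained[k], numeric(1))
    stat <- mean(vapply(runs, function(r) r$statistic[k], numeric(1)))
    p_ret <- if (n == 1L) {
      p
    } else if (method == "ci_upper") {
      min(1, max(0, mean(p) + stats::qt(0.975, n - 1L) * stats::sd(p) / sqrt(n)))
    } else {
      unname(stats::quantile(p, 0.95, type = 7))
    }
    test_summary_row(contrasts[k], stat, p_ret, n_repeats_used = n,
                     alpha = alpha)
  })
  do.call(rbind, rows)
}

#' Write test summaries as TSV
#'
#' @param summaries A `TestSummary` data.frame.
#' @param path File path.
#' @export
write_test_summaries <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
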