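test_that("context comparison reports printed-value fold changes", {
  set.seed(2)
  # endpoint means as measured for K. varians: 5.4e4 (community) vs
  # 1.1e7 (no-Bc omission) -> ~204-fold release
  tab <- rbind(
    make_table("four_species", "Kv", 5.4e4 * 10^rnorm(5, 0, 0.05)),
    make_table("no_Bc", "Kv", 1.1e7 * 10^rnorm(5, 0, 0.05)))
  eff <- compare_contexts(NULL, tab, "Kv", "four_species", "no_Bc")
  ep <- eff[eff$parameter == "endpoint_abundance", ]
  expect_equal(ep$fold_change, 1.1e7 / 5.4e4, tolerance = 0.25)
  expect_lt(ep$p_value, 0.01)
  expect_error(compare_contexts(NULL, tab, "Pf", "four_species", "no_Bc"),
               "absent")
})

test_that("identical contexts give unit fold change and p = 1", {
  tab <- rbind(make_table("a", "Kv", c(1e5, 2e5, 3e5, 4e5, 5e5)),
               make_table("b", "Kv", c(1e5, 2e5, 3e5, 4e5, 5e5)))
  eff <- compare_contexts(NULL, tab, "Kv", "a", "b")
  expect_equal(eff$fold_change[eff$parameter == "endpoint_abundance"], 1)
  expect_equal(eff$p_value[eff$parameter == "endpoint_abundance"], 1)
})

test_that("context comparison is antisymmetric", {
  set.seed(14)
  tab <- rbind(make_table("a", "Kv", 10^rnorm(5, 5, 0.1)),
               make_table("b", "Kv", 10^rnorm(5, 6, 0.1)))
  fits <- data.frame(
    species = "Kv", context = c("a", "b"), x0 = c(7.7e4, 7.7e4),
    mu = c(1.93, 0.9), K = c(2.1e7, 1e5), tau = c(3, 10),
    status = "fitted", sse = 0.1, n_points = 20,
    stringsAsFactors = FALSE)
  ab <- compare_contexts(fits, tab, "Kv", "a", "b")
  ba <- compare_contexts(fits, tab, "Kv", "b", "a")
  for (pn in c("x0", "mu", "K", "endpoint_abundance")) {
    expect_equal(ab$fold_change[ab$parameter == pn],
                 1 / ba$fold_change[ba$parameter == pn])
  }
  expect_equal(ab$fold_change[ab$parameter == "tau"],
               -ba$fold_change[ba$parameter == "tau"])
  expect_equal(ab$p_value[ab$parameter == "endpoint_abundance"],
               ba$p_value[ba$parameter == "endpoint_abundance"])
})

test_that("mono vs community fits expose the P. fluorescens delay", {
  fits <- data.frame(
    species = "Pf", context = c("mono_Pf", "four_species"),
    x0 = 2.7e4, mu = c(0.25, 0.94), K = c(1.7e7, 5.8e6), tau = c(0, 33),
    status = "fitted", sse = 0.1, n_points = 20, stringsAsFactors = FALSE)
  tab <- rbind(make_table("mono_Pf", "Pf", rep(c(1e7, 2e7), c(3, 2))),
               make_table("four_species", "Pf", rep(c(5e6, 6e6), c(3, 2))))
  eff <- compare_contexts(fits, tab, "Pf", "mono_Pf", "four_species")
  expect_equal(eff$fold_change[eff$parameter == "tau"], 33)
  k_fold <- eff$fold_change[eff$parameter == "K"]
  mu_fold <- eff$fold_change[eff$parameter == "mu"]
  expect_true(k_fold > 1 / 3 && k_fold < 3)
  expect_true(mu_fold > 1 / 3 && mu_fold < 4)
})

make_omission_effects <- function(p_upB = 0.008, p_dnP = 0.03, p_dnR = 0.008,
                                  p_null = 0.6) {
  row <- function(target, omitted, fold, p) data.frame(
    target = target, context_a = "four_species",
    context_b = paste0("no_", omitted), parameter = "endpoint_abundance",
    value_a = 1, value_b = fold, fold_change = fold, p_value = p,
    omitted = omitted, stringsAsFactors = FALSE)
  rbind(
    row("Kv", "Bc", 204, p_upB), row("Kv", "Pf", 1 / 4.5, p_dnP),
    row("Kv", "Rh", 1 / 15, p_dnR),
    row("Bc", "Kv", 1.1, p_null), row("Bc", "Pf", 0.9, p_null),
    row("Bc", "Rh", 1.2, p_null),
    row("Pf", "Kv", 1.05, p_null), row("Pf", "Bc", 0.95, p_null),
    row("Pf", "Rh", 1.1, p_null),
    row("Rh", "Kv", 0.9, p_null), row("Rh", "Bc", 1.08, p_null),
    row("Rh", "Pf", 1.15, p_null))
}

test_that("edge classification reproduces the omission-design logic", {
  eff <- make_omission_effects()
  edges <- classify_edges(eff)
  neg <- edges[edges$sign == "negative", ]
  expect_identical(nrow(neg), 1L)
  expect_identical(neg$source, "Bc")
  expect_identical(neg$target, "Kv")
  expect_identical(neg$type, "amensalism")
  mit <- edges[edges$type == "mitigation", ]
  expect_setequal(mit$source, c("Pf", "Rh"))
  expect_setequal(mit$target, "Kv")
  expect_setequal(mit$conditioning, "Bc->Kv")
  # nonsignificant effects produce no edges
  expect_identical(nrow(classify_edges(make_omission_effects(
    p_upB = 0.5, p_dnP = 0.5, p_dnR = 0.5))), 0L)
  # significance without magnitude is filtered by the fold floor
  eff2 <- make_omission_effects()
  eff2$fold_change[eff2$target == "Kv" & eff2$omitted == "Bc"] <- 2
  expect_false(any(classify_edges(eff2)$sign == "negative"))
})

test_that("edge classification ignores input row order", {
  eff <- make_omission_effects()
  set.seed(5)
  shuffled <- eff[sample(nrow(eff)), ]
  expect_identical(classify_edges(eff), classify_edges(shuffled))
})

test_that("a reciprocally affected pair is not amensalism", {
  eff <- make_omission_effects()
  eff$fold_change[eff$target == "Bc" & eff$omitted == "Kv"] <- 10
  eff$p_value[eff$target == "Bc" & eff$omitted == "Kv"] <- 0.01
  edges <- classify_edges(eff)
  e <- edges[edges$source == "Bc" & edges$target == "Kv", ]
  expect_identical(e$type, "competition")
})

test_that("network assembly orders edges and rejects duplicates", {
  edges <- classify_edges(make_omission_effects())
  net <- build_network(edges)
  expect_identical(net$source, sort(net$source))
  expect_error(build_network(rbind(net, net[1, ])), "duplicate")
  empty <- classify_edges(make_omission_effects(p_upB = 0.9, p_dnP = 0.9,
                                                p_dnR = 0.9))
  expect_identical(nrow(build_network(empty)), 0L)
})

test_that("end-to-end inference recovers the planted network", {
  tab <- simulate_counts(default_scenario(seed = 101))
  net <- infer_interactions(tab, include_parameter_edges = TRUE,
                            fits = fit_all_contexts(tab, fit_bounds(2.5)))
  expect_true(any(net$source == "Bc" & net$target == "Kv" &
                  net$sign == "negative" & net$type == "amensalism"))
  expect_true(any(net$type == "mitigation" & net$source == "Pf"))
  expect_true(any(net$type == "mitigation" & net$source == "Rh"))
  # Rhodocyclus adhesion facilitation shows up on the x0 comparison
  expect_true(any(net$type == "facilitation" & net$target == "Rh" &
                  net$parameter == "x0"))
  # P. fluorescens community delay
  expect_true(any(net$type == "delay" & net$target == "Pf"))
  # thiocillin-null preset: no negative edge onto K. varians
  tab_mut <- simulate_counts(default_scenario(amensalism = FALSE, seed = 101))
  net_mut <- infer_interactions(tab_mut)
  expect_false(any(net_mut$source == "Bc" & net_mut$target == "Kv" &
                   net_mut$sign == "negative"))
  # incomplete design errors with the missing context named
  expect_error(infer_interactions(tab[tab$context != "no_Pf", ]),
               "omission of Pf")
})

test_that("network files are written in edge-list and DOT form", {
  net <- classify_edges(make_omission_effects())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  dot <- withr::local_tempfile(fileext = ".dot")
  write_network_tsv(net, tsv)
  expect_identical(nrow(utils::read.delim(tsv)), nrow(net))
  write_network_dot(net, dot)
  txt <- readLines(dot)
  expect_true(any(grepl("\"Bc\" -> \"Kv\"", txt)))
})
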