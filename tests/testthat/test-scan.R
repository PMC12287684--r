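test_that("expected counts are exact, with 1-decimal display rounding", {
  expect_equal(expected_count(1951, 0.05), 97.55)
  expect_equal(expected_count(525, 0.05), 26.25)
  expect_equal(expected_count(525, 0.01), 5.25)
  expect_equal(expected_count(0, 0.05), 0)
  expect_error(expected_count(10, 0))
})

test_that("the enrichment statistic matches hand arithmetic and flags two-sided", {
  expect_equal(enrichment_statistic(97.55, 97.55), 0)
  expect_equal(enrichment_statistic(122, 97.55), (122 - 97.55)^2 / 97.55)
  # a deficit row short of the critical value stays unflagged
  stat <- enrichment_statistic(21, 31.8)
  expect_equal(stat, (21 - 31.8)^2 / 31.8)
  expect_lt(stat, enrichment_critical_value())
  expect_error(enrichment_statistic(5, 0), "positive")
})

test_that("the flag threshold is the chi-square(1) 0.95 quantile", {
  cv <- enrichment_critical_value()
  expect_equal(cv, qchisq(0.95, 1))
  expect_gt(cv, 3.84)   # comparisons use full precision, display rounds down
})

test_that("run_scan yields one paired result per item and is deterministic", {
  cfg <- sim_config(n_subjects = 400, seed = 17)
  co <- simulate_cohort(cfg)
  res <- run_scan(co$phenotypes, co$items, co$genotypes)
  expect_equal(nrow(res), 2 * 1951)
  expect_setequal(unique(res$method), c("binary_split", "linear_trend"))
  res2 <- run_scan(co$phenotypes, co$items, co$genotypes)
  expect_identical(res, res2)
  # every item yields a numeric result or a machine-readable reason
  expect_true(all(res$estimable | !is.na(res$reason)))
  expect_true(all(is.na(res$p_value[!res$estimable])))
  expect_true(all(res$p_value[res$estimable] >= 0 &
                    res$p_value[res$estimable] <= 1))
})

test_that("a constant item produces a not-estimable pair, not an error", {
  g <- genotypes_from_counts(c(rep(15, 50), rep(30, 10)))
  items <- meta_row("binary", 2, "I1")
  X <- matrix(1, 60, 1, dimnames = list(g$subject_id, "I1"))
  res <- run_scan(X, items, g)
  expect_equal(nrow(res), 2)
  expect_true(all(!res$estimable))
  expect_true(all(!is.na(res$reason)))
})

test_that("mismatched matrix and metadata raise a validation error naming ids", {
  g <- genotypes_from_counts(rep(c(15, 30), 10))
  items <- meta_row("binary", 2, "I1")
  X <- matrix(0, 20, 1, dimnames = list(g$subject_id, "OTHER"))
  expect_error(run_scan(X, items, g), "I1")
})

test_that("observed counts are additive across scopes and monotone in alpha", {
  cfg <- sim_config(n_subjects = 500, seed = 23,
                    effects = list(effect_spec(target_domain = "Addictions",
                                               magnitude = 0.15)))
  co <- simulate_cohort(cfg)
  res <- run_scan(co$phenotypes, co$items, co$genotypes)
  for (sc in c("all", "domain", "topic")) assign(paste0("e_", sc),
    tabulate_enrichment(res, scope = sc))
  for (a in c(0.05, 0.01, 0.001)) for (m in c("binary_split", "linear_trend")) {
    tot <- e_all$observed[e_all$alpha == a & e_all$method == m]
    dom <- e_domain[e_domain$alpha == a & e_domain$method == m, ]
    top <- e_topic[e_topic$alpha == a & e_topic$method == m, ]
    expect_equal(sum(dom$observed), tot)
    expect_equal(sum(top$observed), tot)
    expect_equal(sum(dom$n_items), e_all$n_items[e_all$alpha == a &
                                                   e_all$method == m])
    # topics within each domain sum to the domain count
    agg <- tapply(top$observed, top$domain, sum)
    expect_equal(as.numeric(agg[dom$scope_name]), as.numeric(dom$observed))
  }
  # monotone in alpha
  for (m in c("binary_split", "linear_trend")) {
    o <- sapply(c(0.001, 0.01, 0.05), function(a)
      e_all$observed[e_all$alpha == a & e_all$method == m])
    expect_true(all(diff(o) >= 0))
  }
  expect_true(all(e_domain$observed <= e_domain$n_items))
  expect_equal(e_domain$expected, e_domain$n_items * e_domain$alpha)
})

test_that("a fully significant domain is flagged as an excess", {
  res <- tibble::tibble(
    item_id = sprintf("I%02d", 1:40),
    domain = rep(c("A", "B"), each = 20),
    topic = rep(c("ta", "tb"), each = 20),
    method = "linear_trend",
    n_used = 100L, effect = 1, ci_low = 0.5, ci_high = 1.5,
    p_value = c(rep(0.001, 20), runif(20, 0.3, 0.9)),
    direction = 1L, estimable = TRUE, reason = NA_character_)
  cells <- tabulate_enrichment(res, alphas = 0.05, scope = "domain")
  a <- cells[cells$scope_name == "A", ]
  expect_equal(a$observed, 20)
  expect_equal(a$n_items, 20)
  expect_true(a$flagged)
  expect_equal(a$direction, "excess")
})

test_that("concordance filtering respects both significance and direction", {
  mk <- function(pb, pt, db = 1L, dt = 1L) tibble::tibble(
    item_id = "I1", domain = "D", topic = "T",
    method = c("binary_split", "linear_trend"),
    n_used = 10L, effect = 1, ci_low = 0, ci_high = 2,
    p_value = c(pb, pt), direction = c(db, dt),
    estimable = TRUE, reason = NA_character_)
  expect_equal(nrow(concordant_items(mk(0.004, 0.03), 0.05)), 1)
  expect_equal(nrow(concordant_items(mk(0.004, 0.03), 0.01)), 0)
  expect_equal(nrow(concordant_items(mk(0.004, 0.2), 0.05)), 0)
  expect_equal(nrow(concordant_items(mk(0.01, 0.01, 1L, -1L), 0.05)), 0)
  empty <- concordant_items(mk(0.5, 0.5)[0, ], 0.05)
  expect_equal(nrow(empty), 0)
})

test_that("drill-down targets flagged excesses and refuses everything else", {
  cfg <- sim_config(n_subjects = 1200, seed = 29, battery = two_domain_battery(),
                    effects = list(effect_spec(target_domain = "D2",
                                               magnitude = 0.25)))
  co <- simulate_cohort(cfg)
  res <- run_scan(co$phenotypes, co$items, co$genotypes)
  cells <- tabulate_enrichment(res, alphas = 0.05, scope = "domain")
  hot <- cells[cells$scope_name == "D2" & cells$method == "linear_trend", ]
  expect_true(hot$flagged)
  dd <- drill_down(hot, res, co$phenotypes, co$items, co$genotypes)
  expect_equal(dd$status, "ok")
  expect_gt(nrow(dd$item_list), 0)
  expect_true(all(dd$item_list$p_value < 0.05))
  expect_false(is.unsorted(dd$item_list$p_value))
  # one topic row per topic in the domain
  expect_equal(nrow(dd$topics), 1)
  expect_true(length(dd$summaries) > 0)
  cold <- cells[cells$scope_name == "D1" & cells$method == "linear_trend", ]
  if (!cold$flagged) {
    refused <- drill_down(cold, res, co$phenotypes, co$items, co$genotypes)
    expect_match(refused$status, "not flagged")
    expect_null(refused$item_list)
  }
})
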