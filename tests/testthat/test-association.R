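test_that("dichotomize splits strictly above the threshold and keeps missingness", {
  g <- genotypes_from_counts(c(15, 24, 25, 30))
  expect_identical(dichotomize(g)$high, c(FALSE, FALSE, TRUE, TRUE))
  g2 <- genotypes_from_counts(c(10, 12, 24))
  expect_equal(sum(dichotomize(g2)$high), 0)
  g3 <- g; g3$repeat_count[2] <- NA
  s <- dichotomize(g3)
  expect_true(is.na(s$high[2]))
  expect_equal(sum(s$high, na.rm = TRUE) + sum(!s$high, na.rm = TRUE) +
                 sum(is.na(s$high)), nrow(g3))
})

test_that("binary-split odds ratio matches the closed-form 2x2 oracle", {
  # high group: 10 yes / 90 no; low group: 30 yes / 870 no
  a <- 10; b <- 90; c <- 30; d <- 870
  values <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  counts <- c(rep(30, a + b), rep(15, c + d))   # 30 > 24 = high, 15 = low
  g <- genotypes_from_counts(counts)
  res <- test_binary_split(values, meta_row("binary", 2), dichotomize(g))
  or_oracle <- (a * d) / (b * c)                           # 3.22
  se_woolf <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- log(or_oracle) / se_woolf
  p_oracle <- 2 * stats::pnorm(-abs(z))
  expect_true(res$estimable)
  expect_equal(res$effect, or_oracle, tolerance = 1e-5)
  expect_equal(res$ci_low, exp(log(or_oracle) - 1.959964 * se_woolf), tolerance = 1e-5)
  expect_equal(res$ci_high, exp(log(or_oracle) + 1.959964 * se_woolf), tolerance = 1e-5)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-4)
  expect_equal(res$direction, 1L)
  expect_true(res$ci_low <= res$effect && res$effect <= res$ci_high)
})

test_that("a continuous item identical across groups gives effect 0, p near 1", {
  # exactly balanced: the same value pattern in both groups
  v2 <- c(rep(c(-1, 0, 1), 10), rep(c(-1, 0, 1), 30))
  g2 <- genotypes_from_counts(c(rep(30, 30), rep(15, 90)))
  res2 <- test_binary_split(v2, meta_row("continuous"), dichotomize(g2))
  expect_equal(res2$effect, 0, tolerance = 1e-12)
  expect_gt(res2$p_value, 0.999)
})

test_that("degenerate items are flagged not-estimable, never p of 0 or 1", {
  g <- genotypes_from_counts(c(rep(15, 30), rep(30, 10)))
  s <- dichotomize(g)
  res <- test_binary_split(rep(1, 40), meta_row("binary", 2), s)
  expect_false(res$estimable)
  expect_match(res$reason, "zero-variance")
  res2 <- test_linear_trend(rep(2, 40), meta_row("ordinal"), g)
  expect_false(res2$estimable)
  # all subjects low: empty high group
  g3 <- genotypes_from_counts(rep(15, 40))
  res3 <- test_binary_split(rep(c(0, 1), 20), meta_row("binary", 2),
                            dichotomize(g3))
  expect_false(res3$estimable)
  expect_match(res3$reason, "empty group")
})

test_that("complete separation is flagged rather than reported as a p-value", {
  # every high-repeat subject answers 1, every low subject answers 0
  g <- genotypes_from_counts(c(rep(30, 15), rep(15, 45)))
  v <- c(rep(1, 15), rep(0, 45))
  res <- test_binary_split(v, meta_row("binary", 2), dichotomize(g))
  expect_false(res$estimable)
  expect_match(res$reason, "separation")
})

test_that("linear-trend p equals the pooled two-sample t-test on 2-level items", {
  set.seed(404)
  for (i in 1:20) {
    n <- sample(30:200, 1)
    counts <- sample(5:40, n, replace = TRUE)
    v <- rbinom(n, 1, 0.4)
    if (length(unique(v)) < 2) next
    g <- genotypes_from_counts(counts)
    res <- test_linear_trend(v, meta_row("binary", 2), g)
    tt <- t.test(counts[v == 1], counts[v == 0], var.equal = TRUE)
    expect_lt(abs(res$p_value - tt$p.value), 1e-10)
    expect_lt(abs(res$effect - (mean(counts[v == 1]) - mean(counts[v == 0]))),
              1e-10)
  }
})

test_that("an ordered increase in mean repeats gives a positive trend direction", {
  v <- rep(c(0, 1, 2), each = 60)
  set.seed(5)
  counts <- round(15 + 2 * v + rnorm(180, 0, 2))
  res <- test_linear_trend(v, meta_row("ordinal"), genotypes_from_counts(counts))
  expect_gt(res$effect, 0)
  expect_equal(res$direction, 1L)
  expect_lt(res$p_value, 0.001)
})

test_that("run_item applies the two-method concordance rule", {
  set.seed(8)
  n <- 2000
  counts <- sample_repeats(n, seed = 88)$repeat_count
  g <- genotypes_from_counts(counts)
  s <- dichotomize(g)
  # item strongly linked to repeats: both methods significant, same direction
  v <- as.numeric(counts + rnorm(n, 0, 4) > 20)
  it <- run_item(v, meta_row("binary", 2), g, s)
  expect_true(it$concordant_at(0.05))
  expect_equal(it$binary$direction, it$trend$direction)
  expect_equal(nrow(it$results), 2)
  # null item: not concordant at stringent alpha
  v0 <- rbinom(n, 1, 0.5)
  it0 <- run_item(v0, meta_row("binary", 2), g, s)
  expect_false(it0$concordant_at(1e-6))
})

test_that("category summaries reproduce direct percentage arithmetic", {
  # per-category high counts (83, 76, 8) of (1660, 1041, 93)
  ns <- c(1660, 1041, 93); highs <- c(83, 76, 8)
  v <- rep(0:2, ns)
  counts <- unlist(lapply(1:3, function(i)
    c(rep(30, highs[i]), rep(15, ns[i] - highs[i]))))
  g <- genotypes_from_counts(counts)
  cs <- summarize_categories(v, meta_row("ordinal"), g, dichotomize(g))
  expect_equal(cs$table$n, ns)
  expect_equal(cs$table$n_high, highs)
  expect_equal(round(cs$table$pct_high, 1), c(5.0, 7.3, 8.6))
  expect_equal(sum(cs$table$n), cs$n_used)
  expect_equal(cs$table$mean_repeats,
               (30 * highs + 15 * (ns - highs)) / ns)
  expect_true(is.finite(cs$p_binary) && is.finite(cs$p_mean))
})

test_that("single-category items give non-estimable trend p-values", {
  g <- genotypes_from_counts(c(rep(15, 20), rep(30, 5)))
  cs <- summarize_categories(rep(1, 25), meta_row("ordinal"), g, dichotomize(g))
  expect_true(is.na(cs$p_binary))
  expect_true(is.na(cs$p_mean))
  expect_equal(nrow(cs$table), 1)
})

test_that("batched scan engines agree with per-item lm/glm fits", {
  cfg <- sim_config(n_subjects = 600, battery = small_battery(),
                    missing_rate = 0.05, seed = 55,
                    effects = list(effect_spec(target_topic = "T2",
                                               magnitude = 0.15)))
  co <- simulate_cohort(cfg)
  res <- run_scan(co$phenotypes, co$items, co$genotypes)
  split <- dichotomize(co$genotypes)
  for (id in co$items$item_id) {
    meta <- co$items[co$items$item_id == id, ]
    v <- co$phenotypes[co$genotypes$subject_id, id]
    b <- test_binary_split(v, meta, split)
    t <- test_linear_trend(v, meta, co$genotypes)
    rb <- res[res$item_id == id & res$method == "binary_split", ]
    rt <- res[res$item_id == id & res$method == "linear_trend", ]
    expect_equal(rb$estimable, b$estimable)
    expect_equal(rt$estimable, t$estimable)
    if (b$estimable) {
      # same estimator; differences reflect IRLS stopping points only
      expect_equal(rb$p_value, b$p_value, tolerance = 1e-4)
      expect_equal(rb$effect, b$effect, tolerance = 1e-4)
      expect_equal(rb$n_used, b$n_used)
    }
    if (t$estimable) {
      expect_equal(rt$p_value, t$p_value, tolerance = 1e-10)
      expect_equal(rt$effect, t$effect, tolerance = 1e-10)
    }
  }
})
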