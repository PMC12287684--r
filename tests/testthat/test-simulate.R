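test_that("identical configs reproduce identical cohorts; seeds differentiate", {
  cfg <- sim_config(n_subjects = 120, battery = small_battery(),
                    missing_rate = 0.1, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$genotypes, b$genotypes)
  cfg2 <- sim_config(n_subjects = 120, battery = small_battery(),
                     missing_rate = 0.1, seed = 6)
  expect_false(identical(simulate_cohort(cfg2)$phenotypes, a$phenotypes))
})

test_that("a zero-magnitude effect is byte-identical to no effect at all", {
  base <- sim_config(n_subjects = 200, battery = small_battery(), seed = 9)
  null_eff <- sim_config(n_subjects = 200, battery = small_battery(), seed = 9,
                         effects = list(effect_spec(target_domain = "D1",
                                                    magnitude = 0)))
  expect_identical(simulate_cohort(base)$phenotypes,
                   simulate_cohort(null_eff)$phenotypes)
})

test_that("a positive trend effect induces a positive repeat-item correlation", {
  spec <- battery_spec(data.frame(domain = "D", topic = "T", n_items = 1),
                       type_cycle = "continuous")
  cfg <- sim_config(n_subjects = 4000, battery = spec, seed = 21,
                    effects = list(effect_spec(target_items = "I0001",
                                               mechanism = "trend",
                                               magnitude = 0.3)))
  co <- simulate_cohort(cfg)
  expect_gt(cor(co$genotypes$repeat_count, co$phenotypes[, 1]), 0.1)
})

test_that("effects targeting unknown items or domains are configuration errors", {
  g <- genotypes_from_counts(rep(c(15, 25), 20))
  items <- build_battery(small_battery())
  expect_error(simulate_phenotypes(g, items,
                 effects = list(effect_spec(target_domain = "Nope"))),
               "unknown domain")
  expect_error(simulate_phenotypes(g, items,
                 effects = list(effect_spec(target_items = "Z9"))),
               "unknown items")
})

test_that("missingness is applied completely at random at the requested rate", {
  cfg <- sim_config(n_subjects = 500, battery = small_battery(24, 24),
                    missing_rate = 0.2, seed = 31)
  co <- simulate_cohort(cfg)
  rate <- mean(is.na(co$phenotypes))
  expect_lt(abs(rate - 0.2), 0.02)
  # missingness unrelated to genotype
  by_high <- tapply(rowMeans(is.na(co$phenotypes)),
                    co$genotypes$repeat_count > 24, mean)
  expect_lt(abs(diff(by_high)), 0.05)
})

test_that("simulated item-level power matches the analytic approximation", {
  # standardized trend slope 0.1 on 30 psychiatric-style items, n = 5000:
  # analytic two-sided power for a simple-regression slope at alpha 0.05
  beta <- 0.1; n <- 5000; alpha <- 0.05
  rho <- beta / sqrt(1 + beta^2)
  power_analytic <- stats::pnorm(sqrt(n) * rho - stats::qnorm(1 - alpha / 2)) +
    stats::pnorm(-sqrt(n) * rho - stats::qnorm(1 - alpha / 2))
  spec <- battery_spec(data.frame(domain = "Psychiatric", topic = "Psychosis",
                                  n_items = 30), type_cycle = "continuous")
  items <- build_battery(spec)
  eff <- list(effect_spec(target_domain = "Psychiatric", mechanism = "trend",
                          magnitude = beta))
  reps <- 500
  rej <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- sample_repeats(n, seed = 9000 + r)
    X <- simulate_phenotypes(g, items, effects = eff, seed = 19000 + r)
    res <- run_scan(X, items, g)
    p <- res$p_value[res$method == "linear_trend"]
    rej[r] <- mean(p < alpha)
  }
  expect_lt(abs(mean(rej) - power_analytic), 0.05)
})

test_that("block correlation induces within-block phenotype correlation", {
  spec <- battery_spec(data.frame(domain = "D", topic = "T", n_items = 40),
                       type_cycle = "continuous")
  cfg <- sim_config(n_subjects = 1500, battery = spec, seed = 77,
                    correlation = list(block_size = 20, loading = 0.5))
  co <- simulate_cohort(cfg)
  C <- cor(co$phenotypes)
  within <- C[1:20, 1:20][upper.tri(matrix(0, 20, 20))]
  between <- C[1:20, 21:40]
  expect_gt(mean(within), 0.2)            # loading^2 = 0.25
  expect_lt(abs(mean(between)), 0.05)
})
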