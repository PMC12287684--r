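#' Split subjects into high- and low-repeat groups
#'
#' Dichotomizes the repeat count at a threshold: subjects with
#' `repeat_count > threshold` form the high group, those at or below it the
#' low group (so with the default threshold of 24 — the mode of the second
#' peak of the repeat distribution — a count of 24 is low and 25 is high).
#' Missing genotypes give missing indicators.
#'
#' @param genotypes Genotype table with columns `subject_id`, `repeat_count`.
#' @param threshold Integer repeat-count threshold (>= 1), default 24.
#' @return An object of class `group_split`: list with `threshold`,
#'   `subject_id`, and `high` (logical indicator, `NA` where the genotype is
#'   missing).
#' @export
#' @examples
#' g <- data.frame(subject_id = letters[1:4], repeat_count = c(15, 24, 25, 30))
#' dichotomize(g)$high   # FALSE FALSE TRUE TRUE
dichotomize <- function(genotypes, threshold = 24L) {
  if (threshold < 1) stop("threshold must be >= 1", call. = FALSE)
  structure(list(threshold = as.integer(threshold),
                 subject_id = genotypes$subject_id,
                 high = genotypes$repeat_count > threshold),
            class = "group_split")
}

# One row of the per-item results table.
.assoc_result <- function(item_id, method, n_used = NA_integer_,
                          effect = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_,
                          direction = NA_integer_, estimable = TRUE,
                          reason = NA_character_) {
  tibble::tibble(item_id = item_id, method = method,
                 n_used = as.integer(n_used), effect = effect,
                 ci_low = ci_low, ci_high = ci_high, p_value = p_value,
                 direction = as.integer(direction), estimable = estimable,
                 reason = reason)
}

.not_estimable <- function(item_id, method, n_used, reason) {
  .assoc_result(item_id, method, n_used = n_used, estimable = FALSE,
                reason = reason)
}

#' Binary high-repeat-group comparison for one item
#'
#' Tests whether the item differs between subjects with repeat counts above
#' the threshold and the rest.  For a continuous item the comparison is a
#' two-group mean-difference linear model of the item on the group indicator
#' (two-sided Wald/t).  For a binary or ordinal item, high-group status is the
#' logistic response with the item's integer category score as predictor; the
#' effect is the odds ratio per category step with a Wald 95% CI.
#' Zero-variance items, empty groups and separated logistic fits are flagged
#' not-estimable rather than raising an error.
#'
#' @param values Numeric vector of item values (category scores for
#'   binary/ordinal items), aligned with `split`.
#' @param meta One row of item metadata (`item_id`, `type`, ...).
#' @param split A [dichotomize()] result.
#' @return A one-row tibble (see [run_scan()] for the column contract).
#' @export
test_binary_split <- function(values, meta, split) {
  id <- meta$item_id
  high <- split$high
  ok <- !is.na(values) & !is.na(high)
  n <- sum(ok)
  v <- values[ok]; h <- high[ok]
  if (meta$type == "continuous") {
    if (sum(h) < 2 || sum(!h) < 2)
      return(.not_estimable(id, "binary_split", n, "fewer than 2 complete cases in a group"))
    if (stats::sd(v) == 0)
      return(.not_estimable(id, "binary_split", n, "zero-variance item"))
    fit <- stats::lm(v ~ h)
    sm <- summary(fit)$coefficients
    if (nrow(sm) < 2 || is.na(sm[2, 2]) || sm[2, 2] == 0)
      return(.not_estimable(id, "binary_split", n, "degenerate fit"))
    b <- sm[2, 1]; se <- sm[2, 2]
    tcrit <- stats::qt(0.975, fit$df.residual)
    return(.assoc_result(id, "binary_split", n, effect = b,
                         ci_low = b - tcrit * se, ci_high = b + tcrit * se,
                         p_value = sm[2, 4], direction = sign(b)))
  }
  # categorical item: logistic model of high-group status on the score
  if (length(unique(v)) < 2)
    return(.not_estimable(id, "binary_split", n, "zero-variance item"))
  if (sum(h) == 0 || sum(!h) == 0)
    return(.not_estimable(id, "binary_split", n, "empty group"))
  fit <- suppressWarnings(stats::glm(h ~ v, family = stats::binomial(),
                                     control = stats::glm.control(epsilon = 1e-10,
                                                                  maxit = 50)))
  sm <- summary(fit)$coefficients
  sep <- !fit$converged || max(abs(fit$linear.predictors)) > 30
  if (sep || nrow(sm) < 2 || is.na(sm[2, 2]))
    return(.not_estimable(id, "binary_split", n, "separation or non-convergence"))
  b <- sm[2, 1]; se <- sm[2, 2]
  z <- stats::qnorm(0.975)
  .assoc_result(id, "binary_split", n, effect = exp(b),
                ci_low = exp(b - z * se), ci_high = exp(b + z * se),
                p_value = sm[2, 4], direction = sign(b))
}

#' Linear trend in mean repeat count for one item
#'
#' Regresses the repeat count on the item's numeric score (category scores
#' for binary/ordinal items) and reports the slope in repeat units per score
#' step, a t-based 95% CI and the two-sided p-value.  For a two-category item
#' this is identical to the pooled two-sample t-test comparing mean repeats
#' between categories.
#'
#' @inheritParams test_binary_split
#' @param genotypes Genotype table aligned with `values`.
#' @return A one-row tibble.
#' @export
test_linear_trend <- function(values, meta, genotypes) {
  id <- meta$item_id
  r <- genotypes$repeat_count
  ok <- !is.na(values) & !is.na(r)
  n <- sum(ok)
  v <- values[ok]; y <- r[ok]
  if (n < 3)
    return(.not_estimable(id, "linear_trend", n, "fewer than 3 complete cases"))
  if (stats::sd(v) == 0)
    return(.not_estimable(id, "linear_trend", n, "zero-variance item"))
  if (stats::sd(y) == 0)
    return(.not_estimable(id, "linear_trend", n, "zero-variance repeat counts"))
  fit <- stats::lm(y ~ v)
  sm <- summary(fit)$coefficients
  if (nrow(sm) < 2 || is.na(sm[2, 2]) || sm[2, 2] == 0)
    return(.not_estimable(id, "linear_trend", n, "degenerate fit"))
  b <- sm[2, 1]; se <- sm[2, 2]
  tcrit <- stats::qt(0.975, fit$df.residual)
  .assoc_result(id, "linear_trend", n, effect = b,
                ci_low = b - tcrit * se, ci_high = b + tcrit * se,
                p_value = sm[2, 4], direction = sign(b))
}

#' Run both association tests on one item
#'
#' Pairs the binary high-repeat comparison with the linear repeat trend.  An
#' item is treated as showing evidence of association at level `alpha` only
#' when the two methods agree: both p-values below `alpha` and both effects in
#' the same direction.
#'
#' @inheritParams test_linear_trend
#' @param split A [dichotomize()] result.
#' @return A list of class `item_result` with elements `binary`, `trend`
#'   (one-row tibbles), `results` (both rows bound), and `concordant_at`, a
#'   function of `alpha`.
#' @export
run_item <- function(values, meta, genotypes, split) {
  b <- test_binary_split(values, meta, split)
  t <- test_linear_trend(values, meta, genotypes)
  structure(list(
    binary = b, trend = t, results = dplyr::bind_rows(b, t),
    concordant_at = function(alpha) {
      isTRUE(b$estimable) && isTRUE(t$estimable) &&
        !is.na(b$p_value) && !is.na(t$p_value) &&
        b$p_value < alpha && t$p_value < alpha &&
        !is.na(b$direction) && !is.na(t$direction) &&
        b$direction != 0 && b$direction == t$direction
    }), class = "item_result")
}

#' Category-level summary of repeat counts for one categorical item
#'
#' For each response category of the item: the number of respondents, the
#' percentage (and count) with repeat counts above the threshold, and the
#' mean and SD of the repeat count.  Two trend p-values accompany the table:
#' `p_binary` from the logistic trend in the high-repeat proportion across
#' categories and `p_mean` from the linear trend in mean repeats.
#' Computation always uses true counts; counts below the suppression floor
#' are masked only at render time (see [render_category_summary()]).
#'
#' @inheritParams test_linear_trend
#' @param split A [dichotomize()] result.
#' @return An object of class `category_summary`: list with `item_id`,
#'   `table` (tibble: `category`, `n`, `n_high`, `pct_high`, `mean_repeats`,
#'   `sd_repeats`), `n_used`, `p_binary`, `p_mean`.
#' @export
summarize_categories <- function(values, meta, genotypes, split) {
  if (meta$type == "continuous")
    stop("summarize_categories requires a categorical item", call. = FALSE)
  r <- genotypes$repeat_count
  high <- split$high
  ok <- !is.na(values) & !is.na(r)
  v <- values[ok]; y <- r[ok]; h <- high[ok]
  cats <- if (length(v)) sort(unique(v)) else numeric(0)
  tab <- dplyr::bind_rows(lapply(cats, function(cc) {
    sel <- v == cc
    nn <- sum(sel)
    tibble::tibble(category = cc, n = nn, n_high = sum(h[sel]),
                   pct_high = 100 * sum(h[sel]) / nn,
                   mean_repeats = mean(y[sel]),
                   sd_repeats = if (nn > 1) stats::sd(y[sel]) else NA_real_)
  }))
  pb <- test_binary_split(values, meta, split)
  pm <- test_linear_trend(values, meta, genotypes)
  structure(list(item_id = meta$item_id, table = tab, n_used = sum(ok),
                 p_binary = if (pb$estimable) pb$p_value else NA_real_,
                 p_mean = if (pm$estimable) pm$p_value else NA_real_),
            class = "category_summary")
}
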