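#' Run the full dual-method phenome scan
#'
#' Tests every item of the battery twice against the repeat genotypes: the
#' binary comparison of subjects above the repeat threshold with the rest,
#' and the linear trend in mean repeat count across item scores.  Internally
#' the scan uses vectorized sufficient-statistic engines that reproduce the
#' per-item [test_binary_split()]/[test_linear_trend()] results exactly.
#'
#' @param phenotypes Numeric matrix, subjects in rows (rownames = subject
#'   ids), items in columns (colnames = item ids).
#' @param items Item metadata tibble (`item_id`, `domain`, `topic`, `type`,
#'   `n_categories`).
#' @param genotypes Genotype table (`subject_id`, `repeat_count`).
#' @param threshold Repeat-count threshold for the binary split (default 24).
#' @return A tibble of per-item paired results: columns `item_id`, `domain`,
#'   `topic`, `method` (`binary_split` / `linear_trend`), `n_used`, `effect`
#'   (odds ratio per category step, mean difference, or slope), `ci_low`,
#'   `ci_high`, `p_value`, `direction`, `estimable`, `reason`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 300, seed = 2,
#'   battery = battery_spec(data.frame(domain = "D", topic = "T", n_items = 10))))
#' run_scan(cohort$phenotypes, cohort$items, cohort$genotypes)
run_scan <- function(phenotypes, items, genotypes, threshold = 24L) {
  bad <- setdiff(items$item_id, colnames(phenotypes))
  bad2 <- setdiff(colnames(phenotypes), items$item_id)
  if (length(bad) || length(bad2))
    stop("phenotype matrix and item metadata do not match; unmatched ids: ",
         paste(c(bad, bad2), collapse = ", "), call. = FALSE)
  if (!setequal(rownames(phenotypes), genotypes$subject_id) ||
      nrow(phenotypes) != nrow(genotypes))
    stop("phenotype matrix subjects do not match genotype table", call. = FALSE)
  X <- phenotypes[genotypes$subject_id, items$item_id, drop = FALSE]
  split <- dichotomize(genotypes, threshold)
  res <- dplyr::bind_rows(
    .batch_binary_split(X, items, split$high),
    .batch_linear_trend(X, items, genotypes$repeat_count))
  res <- dplyr::left_join(res, items[, c("item_id", "domain", "topic")],
                          by = "item_id")
  res[, c("item_id", "domain", "topic", "method", "n_used", "effect",
          "ci_low", "ci_high", "p_value", "direction", "estimable", "reason")]
}

#' Number of significant tests expected by chance
#'
#' Exactly `n_items * alpha`; any rounding (to 1 decimal, as printed in
#' enrichment tables) happens only at render time.
#'
#' @param n_items Number of estimable items tested.
#' @param alpha Significance level in (0, 1).
#' @export
#' @examples
#' expected_count(1951, 0.05)   # 97.55
expected_count <- function(n_items, alpha) {
  stopifnot(n_items >= 0, alpha > 0, alpha < 1)
  n_items * alpha
}

#' Observed-vs-expected enrichment statistic
#'
#' The chi-square goodness-of-fit quantity `(observed - expected)^2 /
#' expected` for the count of tests significant at a level, referred to the
#' chi-square(1 df) 0.95 quantile (3.84).
#'
#' @param observed Observed count of significant tests.
#' @param expected Expected count (`n_items * alpha`), must be positive.
#' @export
#' @examples
#' enrichment_statistic(122, 97.55)   # 6.13
enrichment_statistic <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected must be positive", call. = FALSE)
  (observed - expected)^2 / expected
}

#' Critical value for the enrichment flag
#'
#' The full-precision chi-square(1 df) 0.95 quantile (3.8415); displayed as
#' 3.84 but compared at full precision.
#' @export
enrichment_critical_value <- function() stats::qchisq(0.95, df = 1)

#' Tabulate observed vs expected significant associations
#'
#' Builds the enrichment table at one scope: per domain, per topic, or the
#' single all-items row.  For each method and significance level, the number
#' of estimable items, the expected count `n_items * alpha`, the observed
#' count of tests with `p < alpha` (strict), the enrichment statistic and a
#' two-sided flag (statistic above the chi-square critical value) with the
#' direction of the departure.
#'
#' @param results Per-item results from [run_scan()].
#' @param alphas Significance levels (default `c(0.05, 0.01, 0.001)`).
#' @param scope `"all"`, `"domain"` or `"topic"`.
#' @param critical_value Flag threshold; default the full-precision
#'   chi-square(1) 0.95 quantile.
#' @return A tibble of enrichment cells: `scope`, `scope_name`, `domain`,
#'   `alpha`, `method`, `n_items`, `expected`, `observed`, `statistic`,
#'   `flagged`, `direction`.
#' @export
tabulate_enrichment <- function(results, alphas = c(0.05, 0.01, 0.001),
                                scope = c("domain", "topic", "all"),
                                critical_value = enrichment_critical_value()) {
  scope <- match.arg(scope)
  res <- results[results$estimable, ]
  key <- switch(scope, all = rep("ALL", nrow(res)),
                domain = res$domain, topic = res$topic)
  res$scope_name <- key
  cells <- dplyr::bind_rows(lapply(alphas, function(a) {
    g <- dplyr::summarise(
      dplyr::group_by(res, .data$scope_name, .data$method),
      domain = .data$domain[1],
      n_items = dplyr::n(),
      observed = sum(.data$p_value < a),
      .groups = "drop")
    g$alpha <- a
    g
  }))
  cells$domain <- if (scope == "domain") cells$scope_name
                  else if (scope == "all") NA_character_ else cells$domain
  cells$expected <- expected_count(cells$n_items, cells$alpha)
  cells$statistic <- enrichment_statistic(cells$observed, cells$expected)
  cells$flagged <- cells$statistic > critical_value
  cells$direction <- ifelse(cells$observed > cells$expected, "excess",
                     ifelse(cells$observed < cells$expected, "deficit", "none"))
  cells$scope <- scope
  out <- cells[, c("scope", "scope_name", "domain", "alpha", "method",
                   "n_items", "expected", "observed", "statistic",
                   "flagged", "direction")]
  out[order(out$method, out$alpha, out$scope_name), ]
}

#' Items significant and direction-concordant under both methods
#'
#' The scan's evidence rule: an item counts as associated at level `alpha`
#' only when the binary-split and linear-trend tests are both significant
#' (strictly below `alpha`) and agree in direction.
#'
#' @param results Per-item results from [run_scan()].
#' @param alpha Significance level.
#' @return A tibble of concordant items with both p-values and the shared
#'   direction, ordered by the larger of the two p-values.
#' @export
concordant_items <- function(results, alpha) {
  empty <- tibble::tibble(item_id = character(), domain = character(),
                          topic = character(), p_binary = numeric(),
                          p_trend = numeric(), direction = integer())
  if (sum(results$estimable) == 0) return(empty)
  w <- stats::reshape(
    as.data.frame(results[results$estimable,
                          c("item_id", "domain", "topic", "method",
                            "p_value", "direction")]),
    idvar = c("item_id", "domain", "topic"), timevar = "method",
    direction = "wide")
  pb <- w$p_value.binary_split; pt_ <- w$p_value.linear_trend
  db <- w$direction.binary_split; dt <- w$direction.linear_trend
  keep <- !is.na(pb) & !is.na(pt_) & pb < alpha & pt_ < alpha &
    !is.na(db) & !is.na(dt) & db != 0 & db == dt
  out <- tibble::tibble(item_id = w$item_id[keep], domain = w$domain[keep],
                        topic = w$topic[keep], p_binary = pb[keep],
                        p_trend = pt_[keep], direction = db[keep])
  out[order(pmax(out$p_binary, out$p_trend)), ]
}

#' Drill into a flagged enrichment cell
#'
#' For a domain (or topic) flagged for an excess of associations, returns the
#' per-topic observed/expected breakdown and a category-level summary for
#' every significant categorical item, ordered by p-value.  Cells that are
#' not flagged, or flagged for a deficit, are refused with an explanatory
#' status (drill-down targets excesses only).
#'
#' @param cell One row of a [tabulate_enrichment()] table.
#' @param results Per-item results from [run_scan()].
#' @param phenotypes,items,genotypes The scanned cohort.
#' @param threshold Repeat threshold used for the scan.
#' @return A list of class `drill_down`: `status` (`"ok"` or a refusal
#'   message), `topics` (per-topic enrichment at the cell's alpha/method),
#'   `item_list` (significant items under either method, ordered by p) and
#'   `summaries` (named list of [summarize_categories()] payloads).
#' @export
drill_down <- function(cell, results, phenotypes, items, genotypes,
                       threshold = 24L) {
  if (nrow(cell) != 1) stop("cell must be a single enrichment row", call. = FALSE)
  if (!isTRUE(cell$flagged))
    return(structure(list(status = "not flagged: no excess to investigate",
                          topics = NULL, item_list = NULL, summaries = NULL),
                     class = "drill_down"))
  if (cell$direction != "excess")
    return(structure(list(status = "flagged for a deficit: drill-down targets excesses",
                          topics = NULL, item_list = NULL, summaries = NULL),
                     class = "drill_down"))
  in_scope <- switch(cell$scope,
                     all = rep(TRUE, nrow(results)),
                     domain = results$domain == cell$scope_name,
                     topic = results$topic == cell$scope_name)
  sub <- results[in_scope, ]
  topics <- tabulate_enrichment(sub, alphas = cell$alpha, scope = "topic")
  topics <- topics[topics$method == cell$method, ]
  hits <- sub[sub$estimable & sub$p_value < cell$alpha, ]
  hits <- hits[order(hits$p_value), ]
  ids <- unique(hits$item_id)
  split <- dichotomize(genotypes, threshold)
  summaries <- list()
  for (id in ids) {
    meta <- items[items$item_id == id, ]
    if (meta$type == "continuous") next
    summaries[[id]] <- summarize_categories(
      phenotypes[genotypes$subject_id, id], meta, genotypes, split)
  }
  structure(list(status = "ok", topics = topics,
                 item_list = hits[, c("item_id", "domain", "topic", "method",
                                      "p_value", "direction")],
                 summaries = summaries),
            class = "drill_down")
}
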