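#' Specify an injected pleiotropic effect
#'
#' Describes how the repeat count should influence a set of phenotype items in
#' a simulated cohort.  Two mechanisms are supported, mirroring the two
#' association tests: `"trend"` adds `magnitude` times the standardized repeat
#' count to each targeted item's latent scale (a standardized slope per SD of
#' repeat count), and `"high_shift"` adds a `magnitude`-SD shift to subjects
#' above `threshold` repeats.  `magnitude = 0` reduces every targeted item to
#' the null model exactly.
#'
#' @param target_domain,target_topic,target_items Exactly one of these selects
#'   the items the effect applies to: all items of a domain, all items of a
#'   topic, or explicit item ids.
#' @param mechanism `"trend"` or `"high_shift"`.
#' @param magnitude Standardized effect size (latent-SD units); non-negative.
#' @param direction `+1` or `-1`; sign of the association between higher
#'   repeat counts and higher item scores.
#' @param threshold Repeat-count threshold for the `"high_shift"` mechanism.
#' @return An object of class `scan_effect`.
#' @export
effect_spec <- function(target_domain = NULL, target_topic = NULL,
                        target_items = NULL,
                        mechanism = c("trend", "high_shift"),
                        magnitude = 0.1, direction = 1L, threshold = 24L) {
  mechanism <- match.arg(mechanism)
  sel <- !vapply(list(target_domain, target_topic, target_items), is.null, TRUE)
  if (sum(sel) != 1)
    stop("specify exactly one of target_domain, target_topic, target_items",
         call. = FALSE)
  if (!is.numeric(magnitude) || magnitude < 0)
    stop("magnitude must be a non-negative number", call. = FALSE)
  if (!direction %in% c(-1, 1))
    stop("direction must be +1 or -1", call. = FALSE)
  structure(list(target_domain = target_domain, target_topic = target_topic,
                 target_items = target_items, mechanism = mechanism,
                 magnitude = magnitude, direction = as.integer(direction),
                 threshold = as.integer(threshold)),
            class = "scan_effect")
}

# Resolve an effect's targeted item ids against the metadata table.
.resolve_effect_items <- function(effect, items) {
  if (!is.null(effect$target_domain)) {
    if (!effect$target_domain %in% items$domain)
      stop("effect targets unknown domain: ", effect$target_domain, call. = FALSE)
    return(items$item_id[items$domain == effect$target_domain])
  }
  if (!is.null(effect$target_topic)) {
    if (!effect$target_topic %in% items$topic)
      stop("effect targets unknown topic: ", effect$target_topic, call. = FALSE)
    return(items$item_id[items$topic == effect$target_topic])
  }
  miss <- setdiff(effect$target_items, items$item_id)
  if (length(miss))
    stop("effect targets unknown items: ", paste(miss, collapse = ", "),
         call. = FALSE)
  effect$target_items
}

#' Full recipe for one synthetic cohort
#'
#' @param n_subjects Number of subjects.
#' @param mixture A [repeat_mixture()] for the repeat-count distribution.
#' @param battery A [battery_spec()] for the phenotype battery.
#' @param effects A list of [effect_spec()] objects (possibly empty).
#' @param correlation `NULL` for mutually independent items, or
#'   `list(block_size =, loading =)`: consecutive items share one latent
#'   factor per block with the given loading, quantifying the departure from
#'   the scan's item-independence assumption.
#' @param missing_rate Per-item probability of a missing value, completely at
#'   random; in `[0, 0.95)`.
#' @param seed Master integer seed.  Per-stage substreams (repeat sampling,
#'   phenotype generation, missingness) are derived deterministically from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 5000L, mixture = repeat_mixture(),
                       battery = battery_spec(), effects = list(),
                       correlation = NULL, missing_rate = 0, seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (inherits(effects, "scan_effect")) effects <- list(effects)
  if (!all(vapply(effects, inherits, TRUE, "scan_effect")))
    stop("effects must be a list of effect_spec() objects", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 0.95)
    stop("missing_rate must be in [0, 0.95)", call. = FALSE)
  if (!is.null(correlation)) {
    if (!is.list(correlation) ||
        !all(c("block_size", "loading") %in% names(correlation)))
      stop("correlation must be NULL or list(block_size=, loading=)", call. = FALSE)
    if (correlation$loading < 0 || correlation$loading >= 1)
      stop("correlation loading must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), mixture = mixture,
                 battery = battery, effects = effects,
                 correlation = correlation, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a phenotype matrix conditional on genotypes
#'
#' Each item is generated from a unit-variance latent normal variable.  Items
#' not targeted by any effect are independent of the repeat count (conditional
#' on any shared block factors); targeted items receive the effect's
#' contribution on the latent scale.  Continuous items report the latent value
#' itself; binary and ordinal items threshold it at fixed standard-normal
#' quantile cutoffs (binary: 70/30; ordinal-3: 50/30/20; `k` categories use
#' equal upper-tail splits of the remaining mass), coded as integer scores
#' `0..k-1`.  Missingness is applied completely at random.
#'
#' @param genotypes Genotype table (`subject_id`, `repeat_count`).
#' @param items Item metadata from [build_battery()].
#' @param effects List of [effect_spec()] objects.
#' @param correlation See [sim_config()].
#' @param missing_rate Per-cell missingness probability.
#' @param seed Integer seed for this stage (or `NULL` to use the current RNG).
#' @return A numeric matrix, subjects in rows (rownames = subject ids), items
#'   in columns (colnames = item ids); `NA` marks missing cells.
#' @export
simulate_phenotypes <- function(genotypes, items, effects = list(),
                                correlation = NULL, missing_rate = 0,
                                seed = NULL) {
  if (nrow(genotypes) == 0) stop("genotypes must be non-empty", call. = FALSE)
  if (nrow(items) == 0) stop("items must be non-empty", call. = FALSE)
  if (inherits(effects, "scan_effect")) effects <- list(effects)
  n <- nrow(genotypes)
  m <- nrow(items)
  # resolve targets first so configuration errors precede any RNG use
  eff_items <- lapply(effects, .resolve_effect_items, items = items)

  Z <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n * m), n, m)
    if (!is.null(correlation) && correlation$loading > 0) {
      bs <- as.integer(correlation$block_size)
      lam <- correlation$loading
      block <- rep(seq_len(ceiling(m / bs)), each = bs)[seq_len(m)]
      Fmat <- matrix(stats::rnorm(n * max(block)), n, max(block))
      Z <- sqrt(1 - lam^2) * Z + lam * Fmat[, block, drop = FALSE]
    }
    Z
  })

  r <- genotypes$repeat_count
  if (length(effects)) {
    ok <- !is.na(r)
    r_std <- rep(0, n)
    if (sum(ok) > 1 && stats::sd(r[ok]) > 0)
      r_std[ok] <- (r[ok] - mean(r[ok])) / stats::sd(r[ok])
    for (i in seq_along(effects)) {
      e <- effects[[i]]
      cols <- match(eff_items[[i]], items$item_id)
      contrib <- switch(e$mechanism,
        trend = e$direction * e$magnitude * r_std,
        high_shift = e$direction * e$magnitude *
          as.numeric(!is.na(r) & r > e$threshold))
      Z[, cols] <- Z[, cols] + contrib
    }
  }

  # observed scales; thresholding vectorized over items sharing a cutoff set
  X <- Z
  cat_idx <- which(items$type %in% c("binary", "ordinal"))
  if (length(cat_idx)) {
    cut_for <- function(k) {
      if (k == 2) stats::qnorm(0.7)
      else if (k == 3) stats::qnorm(c(0.5, 0.8))
      else stats::qnorm(0.5 + 0.5 * seq_len(k - 1) / (k - 1) - 1e-9)
    }
    for (k in unique(items$n_categories[cat_idx])) {
      idx <- cat_idx[items$n_categories[cat_idx] == k]
      cuts <- cut_for(k)
      S <- matrix(0, n, length(idx))
      for (cc in cuts) S <- S + (Z[, idx, drop = FALSE] > cc)
      X[, idx] <- S
    }
  }
  dimnames(X) <- list(genotypes$subject_id, items$item_id)

  if (missing_rate > 0) {
    drop <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                      stats::runif(n * m) < missing_rate)
    X[matrix(drop, n, m)] <- NA
  }
  X
}

#' Simulate a complete synthetic cohort
#'
#' Runs the full generator described by a [sim_config()]: samples repeat
#' genotypes from the bimodal mixture, builds the battery metadata, and
#' simulates the phenotype matrix with any injected effects, block
#' correlation and missingness.  Identical configs (including seed) produce
#' identical cohorts.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `genotypes`, `items`,
#'   `phenotypes` (matrix) and `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 200, seed = 7))
#' dim(cohort$phenotypes)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genotypes <- sample_repeats(config$n_subjects, config$mixture,
                              seed = stage_seed(config$seed, "repeats"))
  items <- build_battery(config$battery)
  phenotypes <- simulate_phenotypes(
    genotypes, items, effects = config$effects,
    correlation = config$correlation, missing_rate = config$missing_rate,
    seed = stage_seed(config$seed, "phenotypes"))
  structure(list(genotypes = genotypes, items = items,
                 phenotypes = phenotypes, config = config),
            class = "sim_cohort")
}
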