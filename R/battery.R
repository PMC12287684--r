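#' Default domain/topic layout of the phenotype battery
#'
#' The default battery reproduces the published layout of a six-domain,
#' 1951-item neurocognitive battery: Cognition (525 items), Temperament and
#' behaviour (636), Personality (271), Motor (102), Psychiatric (248) and
#' Addictions (169), each subdivided into the topics used for drill-down
#' reporting.
#'
#' @return A tibble with columns `domain`, `topic`, `n_items`.
#' @export
default_battery_layout <- function() {
  L <- list(
    Cognition = c(
      "Early child development" = 46, "IQ" = 24, "Memory" = 28,
      "Speech and language" = 185, "Reading ability" = 77,
      "Other test results" = 71, "Executive function" = 29,
      "Reasoning" = 10, "Non-verbal communication" = 41, "Musicality" = 14),
    `Temperament and behaviour` = c(
      "Temperament" = 62, "Sleep behaviours" = 127, "Feeding behaviours" = 100,
      "Temper tantrums" = 14, "SDQ behaviours" = 84, "DAWBA behaviours" = 129,
      "DAWBA diagnoses" = 45, "Selective attention" = 28,
      "Unusual behaviour observed" = 38, "Gender behaviour" = 9),
    Personality = c(
      "Locus of control" = 21, "Self-esteem" = 78,
      "Perception of ability" = 50, "Cognitive style" = 24,
      "Personality" = 10, "Borderline personality disorder" = 12,
      "Antisocial behaviour" = 38, "Sensation seeking" = 5,
      "Friendships and bullying" = 33),
    Motor = c("Laterality" = 25, "Balance" = 59, "Manual abilities" = 18),
    Psychiatric = c("Depression" = 77, "Psychosis" = 30,
                    "Eating disorders" = 84, "Self-harm" = 57),
    Addictions = c("Alcohol" = 55, "Cigarette smoking" = 20, "Cannabis" = 33,
                   "Other illicit drugs" = 39, "Gambling" = 22)
  )
  tibble::tibble(
    domain = rep(names(L), vapply(L, length, 1L)),
    topic = unlist(lapply(L, names), use.names = FALSE),
    n_items = as.integer(unlist(L, use.names = FALSE))
  )
}

#' Specify a phenotype battery
#'
#' @param layout A data frame with columns `domain`, `topic`, `n_items`
#'   (positive integers).  Defaults to [default_battery_layout()].
#' @param type_cycle Character vector over `"binary"`, `"ordinal"`,
#'   `"continuous"`; measurement types are assigned by cycling this pattern
#'   within each topic, so the assignment is deterministic.  The default
#'   20-item cycle gives 30% binary, 45% ordinal and 25% continuous items,
#'   reflecting a questionnaire-dominated battery with a minority of
#'   continuous test scores.
#' @param n_categories Number of categories for ordinal items (default 3,
#'   the typical "No / A little / A lot" coding).  Binary items always have
#'   2 categories; continuous items have `NA`.
#'
#' @return An object of class `battery_spec`.
#' @export
battery_spec <- function(layout = default_battery_layout(),
                         type_cycle = rep(c("binary", "ordinal", "ordinal",
                                            "continuous", "ordinal", "binary",
                                            "ordinal", "binary", "continuous",
                                            "ordinal", "binary", "ordinal",
                                            "continuous", "ordinal", "binary",
                                            "continuous", "ordinal", "binary",
                                            "ordinal", "continuous"), 1),
                         n_categories = 3L) {
  layout <- as.data.frame(layout)
  req <- c("domain", "topic", "n_items")
  if (!all(req %in% names(layout)))
    stop("layout must have columns domain, topic, n_items", call. = FALSE)
  if (any(layout$n_items < 1) || any(layout$n_items != round(layout$n_items)))
    stop("n_items must be positive integers", call. = FALSE)
  if (anyDuplicated(layout[, c("domain", "topic")]))
    stop("duplicated domain/topic rows in layout", call. = FALSE)
  if (!all(type_cycle %in% c("binary", "ordinal", "continuous")))
    stop("type_cycle entries must be binary|ordinal|continuous", call. = FALSE)
  if (n_categories < 2) stop("n_categories must be >= 2", call. = FALSE)
  structure(list(layout = layout, type_cycle = type_cycle,
                 n_categories = as.integer(n_categories)),
            class = "battery_spec")
}

#' Build the per-item metadata table for a battery
#'
#' Expands a [battery_spec()] into one row of metadata per phenotype item.
#' Every item belongs to exactly one domain and one topic; measurement types
#' follow the spec's deterministic cycle.
#'
#' @param spec A [battery_spec()].
#' @return A tibble with columns `item_id`, `domain`, `topic`, `type`
#'   (`binary`, `ordinal` or `continuous`) and `n_categories` (`NA` for
#'   continuous items).
#' @export
#' @examples
#' items <- build_battery(battery_spec())
#' nrow(items)                 # 1951
#' table(items$domain)["Cognition"]  # 525
build_battery <- function(spec = battery_spec()) {
  stopifnot(inherits(spec, "battery_spec"))
  lay <- spec$layout
  n_total <- sum(lay$n_items)
  rows <- lapply(seq_len(nrow(lay)), function(i) {
    n <- lay$n_items[i]
    type <- rep_len(spec$type_cycle, n)
    tibble::tibble(domain = lay$domain[i], topic = lay$topic[i], type = type)
  })
  items <- dplyr::bind_rows(rows)
  items$item_id <- sprintf("I%04d", seq_len(n_total))
  items$n_categories <- ifelse(items$type == "binary", 2L,
                        ifelse(items$type == "ordinal", spec$n_categories, NA_integer_))
  items[, c("item_id", "domain", "topic", "type", "n_categories")]
}
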