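#' Configure a full scan run
#'
#' Bundles everything one reproducible pipeline run needs: either a cohort
#' directory on disk or a [sim_config()] to generate one, the repeat
#' threshold, the significance grid, the flag critical value, the
#' suppression floor and the output directory.
#'
#' @param input Either a directory path containing a cohort TSV bundle (see
#'   [read_cohort()]) or a [sim_config()].
#' @param out_dir Output directory for the result bundle.
#' @param threshold Repeat-count threshold (default 24).
#' @param alphas Significance levels (default `c(0.05, 0.01, 0.001)`).
#' @param critical_value Enrichment flag threshold (default the
#'   full-precision chi-square(1) 0.95 quantile).
#' @param floor Small-cell suppression floor for rendering (default 5).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, out_dir, threshold = 24L,
                       alphas = c(0.05, 0.01, 0.001),
                       critical_value = enrichment_critical_value(),
                       floor = 5L) {
  if (!inherits(input, "sim_config") && !is.character(input))
    stop("input must be a cohort directory or a sim_config", call. = FALSE)
  structure(list(input = input, out_dir = out_dir,
                 threshold = as.integer(threshold), alphas = alphas,
                 critical_value = critical_value, floor = as.integer(floor)),
            class = "run_config")
}

.write_tsv_out <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Run the complete phenome-scan pipeline
#'
#' Loads (or simulates) the cohort, runs the dual-method scan, tabulates
#' enrichment at all scopes, extracts concordant items, drills into flagged
#' excess domains, and writes the output bundle: `items_results.tsv`,
#' `enrichment_domains.tsv`, `enrichment_topics.tsv`, `enrichment_all.tsv`,
#' `concordant_items.tsv`, `summary.json` and `run_record.json` (config plus
#' content digests of the inputs; identical run records imply identical
#' outputs).
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with `results`, `enrichment` (all/domain/topic),
#'   `concordant` (per alpha), `drill_downs`, and the paths written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]

  if (inherits(config$input, "sim_config")) {
    cohort <- simulate_cohort(config$input)
    cohort_digest <- list(source = "simulated",
                          seed = config$input$seed,
                          n_subjects = config$input$n_subjects)
  } else {
    cohort <- read_cohort(config$input)
    f <- .cohort_files(config$input)
    cohort_digest <- list(source = "files",
                          md5 = as.list(tools::md5sum(unlist(f)[file.exists(unlist(f))])))
  }
  n_sub <- nrow(cohort$genotypes)
  n_items <- nrow(cohort$items)
  log("loaded cohort: %d subjects, %d items [%.1fs]",
      n_sub, n_items, proc.time()[["elapsed"]] - t0)

  results <- run_scan(cohort$phenotypes, cohort$items, cohort$genotypes,
                      threshold = config$threshold)
  log("scan complete: %d paired tests [%.1fs]", n_items,
      proc.time()[["elapsed"]] - t0)

  enr <- list(
    all = tabulate_enrichment(results, config$alphas, scope = "all",
                              critical_value = config$critical_value),
    domain = tabulate_enrichment(results, config$alphas, scope = "domain",
                                 critical_value = config$critical_value),
    topic = tabulate_enrichment(results, config$alphas, scope = "topic",
                                critical_value = config$critical_value))
  conc <- lapply(stats::setNames(config$alphas, paste0("alpha_", config$alphas)),
                 function(a) concordant_items(results, a))

  # drill into every domain flagged for an excess, at each alpha/method
  flagged <- enr$domain[enr$domain$flagged & enr$domain$direction == "excess", ]
  drills <- lapply(seq_len(nrow(flagged)), function(i)
    drill_down(flagged[i, ], results, cohort$phenotypes, cohort$items,
               cohort$genotypes, threshold = config$threshold))
  names(drills) <- if (nrow(flagged)) paste(flagged$scope_name, flagged$method,
                                            flagged$alpha, sep = "|")
  log("enrichment: %d flagged domain cells [%.1fs]", nrow(flagged),
      proc.time()[["elapsed"]] - t0)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    items_results = file.path(config$out_dir, "items_results.tsv"),
    enrichment_all = file.path(config$out_dir, "enrichment_all.tsv"),
    enrichment_domains = file.path(config$out_dir, "enrichment_domains.tsv"),
    enrichment_topics = file.path(config$out_dir, "enrichment_topics.tsv"),
    concordant = file.path(config$out_dir, "concordant_items.tsv"),
    summary = file.path(config$out_dir, "summary.json"),
    run_record = file.path(config$out_dir, "run_record.json"))
  .write_tsv_out(results, paths$items_results)
  .write_tsv_out(enr$all, paths$enrichment_all)
  .write_tsv_out(enr$domain, paths$enrichment_domains)
  .write_tsv_out(enr$topic, paths$enrichment_topics)
  conc_flat <- dplyr::bind_rows(lapply(names(conc), function(nm) {
    x <- conc[[nm]]
    if (nrow(x)) cbind(alpha = sub("alpha_", "", nm), x) else NULL
  }))
  if (is.null(conc_flat) || nrow(conc_flat) == 0)
    conc_flat <- data.frame(alpha = character(), item_id = character())
  .write_tsv_out(conc_flat, paths$concordant)

  summary_json <- list(
    n_subjects = n_sub, n_items = n_items,
    threshold = config$threshold, alphas = config$alphas,
    critical_value = config$critical_value,
    cells = enr$domain, all = enr$all,
    n_concordant = lapply(conc, nrow),
    flagged_domains = flagged[, c("scope_name", "method", "alpha")])
  jsonlite::write_json(summary_json, paths$summary, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")

  run_record <- list(
    config = list(threshold = config$threshold, alphas = config$alphas,
                  critical_value = config$critical_value,
                  floor = config$floor),
    input = cohort_digest,
    output_digests = {
      d <- tools::md5sum(unlist(paths[names(paths) != "run_record"]))
      names(d) <- basename(names(d))
      as.list(d)
    })
  jsonlite::write_json(run_record, paths$run_record, auto_unbox = TRUE,
                       digits = NA)
  log("bundle written to %s [%.1fs]", config$out_dir,
      proc.time()[["elapsed"]] - t0)

  invisible(list(cohort = cohort, results = results, enrichment = enr,
                 concordant = conc, drill_downs = drills, paths = paths))
}
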