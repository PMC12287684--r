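# Plain-TSV cohort interchange.  Column names are part of the public
# contract: phenotypes.tsv (subject_id + one column per item, empty cell =
# missing), items.tsv (item_id, domain, topic, type, n_categories),
# genotypes.tsv (subject_id, repeat_count; blank = missing), config.json.

.cohort_files <- function(dir) {
  list(phenotypes = file.path(dir, "phenotypes.tsv"),
       items = file.path(dir, "items.tsv"),
       genotypes = file.path(dir, "genotypes.tsv"),
       config = file.path(dir, "config.json"))
}

#' Write a cohort to a directory of TSV files
#'
#' Writes the phenotype matrix, item metadata and genotypes as tab-separated
#' text (missing values as empty fields) plus, when available, the simulation
#' config as JSON.  The files round-trip losslessly through [read_cohort()].
#'
#' @param genotypes Genotype table (`subject_id`, `repeat_count`).
#' @param phenotypes Numeric phenotype matrix (subjects x items).
#' @param items Item metadata tibble.
#' @param dir Output directory (created if needed).
#' @param config Optional [sim_config()] written alongside as JSON.
#' @return Invisibly, the list of file paths written.
#' @export
write_cohort <- function(genotypes, phenotypes, items, dir, config = NULL) {
  if (nrow(phenotypes) != nrow(genotypes) ||
      ncol(phenotypes) != nrow(items))
    stop("inconsistent shapes between genotypes, phenotypes and items",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  f <- .cohort_files(dir)
  # full-precision text so the matrix round-trips losslessly
  chr <- matrix(ifelse(is.na(phenotypes), "",
                       formatC(phenotypes, digits = 17, format = "g")),
                nrow(phenotypes), ncol(phenotypes),
                dimnames = dimnames(phenotypes))
  pheno_df <- data.frame(subject_id = rownames(phenotypes),
                         chr, check.names = FALSE,
                         stringsAsFactors = FALSE)
  utils::write.table(pheno_df, f$phenotypes, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(as.data.frame(items), f$items, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(genotypes, f$genotypes, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(config)) write_sim_config(config, f$config)
  invisible(f)
}

#' @rdname write_cohort
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @export
write_sim_cohort <- function(cohort, dir) {
  write_cohort(cohort$genotypes, cohort$phenotypes, cohort$items, dir,
               config = cohort$config)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE, na.strings = NULL,
                    stringsAsFactors = FALSE)
}

# Convert character column to numeric, reporting offending data lines
# (1-based, counting the header as line 1).
.as_num <- function(x, what, file, integer = FALSE) {
  x[x == ""] <- NA
  suppress <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(suppress))
  if (integer)
    bad <- sort(unique(c(bad, which(!is.na(suppress) &
                                      suppress != round(suppress)))))
  if (length(bad))
    stop("invalid ", what, " in ", basename(file), " at line(s) ",
         paste(bad + 1, collapse = ", "), ": ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  if (integer) as.integer(suppress) else suppress
}

#' Read and validate a cohort directory
#'
#' Reads the TSV bundle written by [write_cohort()], cross-validates it
#' (unique ids, known measurement types, integer repeat counts, matrix and
#' metadata item sets equal) and returns typed structures.  Subjects present
#' in the phenotype matrix but absent from the genotype file are retained
#' with a missing genotype.
#'
#' @param dir Directory containing `phenotypes.tsv`, `items.tsv`,
#'   `genotypes.tsv`.
#' @return List with `genotypes`, `items` (tibble), `phenotypes` (numeric
#'   matrix) and `config` (a [sim_config()] or `NULL`).
#' @export
read_cohort <- function(dir) {
  f <- .cohort_files(dir)
  gen <- .read_tsv(f$genotypes)
  if (!all(c("subject_id", "repeat_count") %in% names(gen)))
    stop("genotypes.tsv must have columns subject_id, repeat_count", call. = FALSE)
  if (anyDuplicated(gen$subject_id))
    stop("duplicate subject_id in genotypes.tsv at line(s) ",
         paste(which(duplicated(gen$subject_id)) + 1, collapse = ", "),
         call. = FALSE)
  gen$repeat_count <- .as_num(gen$repeat_count, "repeat_count (must be integer)",
                              f$genotypes, integer = TRUE)
  bad_range <- which(!is.na(gen$repeat_count) &
                       (gen$repeat_count < 1 | gen$repeat_count > 199))
  if (length(bad_range))
    stop("repeat_count outside [1, 199] in genotypes.tsv at line(s) ",
         paste(bad_range + 1, collapse = ", "), call. = FALSE)

  items <- .read_tsv(f$items)
  req <- c("item_id", "domain", "topic", "type", "n_categories")
  if (!all(req %in% names(items)))
    stop("items.tsv must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (anyDuplicated(items$item_id))
    stop("duplicate item_id in items.tsv at line(s) ",
         paste(which(duplicated(items$item_id)) + 1, collapse = ", "),
         call. = FALSE)
  bad_type <- which(!items$type %in% c("binary", "ordinal", "continuous"))
  if (length(bad_type))
    stop("unknown measurement type in items.tsv at line(s) ",
         paste(bad_type + 1, collapse = ", "), ": ",
         paste(unique(items$type[bad_type]), collapse = ", "), call. = FALSE)
  items$n_categories <- .as_num(items$n_categories, "n_categories",
                                f$items, integer = TRUE)
  items <- tibble::as_tibble(items)

  ph <- .read_tsv(f$phenotypes)
  if (names(ph)[1] != "subject_id")
    stop("phenotypes.tsv must start with a subject_id column", call. = FALSE)
  if (anyDuplicated(ph$subject_id))
    stop("duplicate subject_id in phenotypes.tsv at line(s) ",
         paste(which(duplicated(ph$subject_id)) + 1, collapse = ", "),
         call. = FALSE)
  item_cols <- names(ph)[-1]
  missing_in_matrix <- setdiff(items$item_id, item_cols)
  extra_in_matrix <- setdiff(item_cols, items$item_id)
  if (length(missing_in_matrix) || length(extra_in_matrix))
    stop("item metadata and phenotype matrix do not match; ",
         if (length(missing_in_matrix))
           paste0("missing from matrix: ",
                  paste(missing_in_matrix, collapse = ", "), "; ") else "",
         if (length(extra_in_matrix))
           paste0("not in metadata: ",
                  paste(extra_in_matrix, collapse = ", ")) else "",
         call. = FALSE)
  M <- sapply(item_cols, function(cn) .as_num(ph[[cn]], paste0("value for ", cn),
                                              f$phenotypes))
  M <- matrix(as.numeric(M), nrow = nrow(ph),
              dimnames = list(ph$subject_id, item_cols))

  # retain matrix subjects absent from the genotype file, genotype missing
  extra_subj <- setdiff(ph$subject_id, gen$subject_id)
  if (length(extra_subj))
    gen <- rbind(gen, data.frame(subject_id = extra_subj,
                                 repeat_count = NA_integer_,
                                 stringsAsFactors = FALSE))
  gen <- gen[match(ph$subject_id, gen$subject_id), , drop = FALSE]
  rownames(gen) <- NULL

  config <- if (file.exists(f$config)) read_sim_config(f$config) else NULL
  list(genotypes = gen, items = items, phenotypes = M, config = config)
}

#' Serialize / restore a simulation config as JSON
#'
#' @param config A [sim_config()].
#' @param path JSON file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- list(
    n_subjects = config$n_subjects,
    mixture = unclass(config$mixture),
    battery = list(layout = config$battery$layout,
                   type_cycle = config$battery$type_cycle,
                   n_categories = config$battery$n_categories),
    effects = lapply(config$effects, unclass),
    correlation = config$correlation,
    missing_rate = config$missing_rate,
    seed = config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mix <- do.call(repeat_mixture, as.list(x$mixture))
  bat <- battery_spec(layout = as.data.frame(x$battery$layout),
                      type_cycle = x$battery$type_cycle,
                      n_categories = x$battery$n_categories)
  effects <- lapply(seq_len(NROW(x$effects)), function(i) {
    e <- if (is.data.frame(x$effects)) as.list(x$effects[i, ]) else x$effects[[i]]
    e <- e[!vapply(e, function(v) is.null(v) || all(is.na(v)), TRUE)]
    do.call(effect_spec, e)
  })
  corr <- if (is.null(x$correlation) || !length(x$correlation)) NULL
          else as.list(x$correlation)
  sim_config(n_subjects = x$n_subjects, mixture = mix, battery = bat,
             effects = effects, correlation = corr,
             missing_rate = x$missing_rate, seed = x$seed)
}
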