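# Report rendering.  Display conventions follow the field's tables: expected
# counts to 1 decimal, percentages to 1 decimal, means/SDs to 2 decimals,
# counts below the suppression floor rendered "<floor", flagged cells marked
# with an asterisk.  Rendering never alters stored full-precision values.

#' Percentage retained, as printed in cohort descriptions
#'
#' @param n_used Number of subjects analysed.
#' @param n_total Number enrolled.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage, e.g. `percent_retained(5060, 7573)` is 66.8.
#' @export
percent_retained <- function(n_used, n_total, digits = 1) {
  round_half_up(100 * n_used / n_total, digits)
}

#' Render a count under a small-cell suppression floor
#'
#' Counts below `floor` (but above zero-or-equal-to-zero: zero renders as
#' "0") are disclosive in small categories and are rendered `"<floor"`.
#' Suppression applies to rendering only; computations always use true
#' counts.
#'
#' @param n Integer count(s).
#' @param floor Suppression floor (default 5).
#' @return Character vector.
#' @export
#' @examples
#' suppress_count(c(0, 3, 5, 12))   # "0" "<5" "5" "12"
suppress_count <- function(n, floor = 5L) {
  ifelse(is.na(n), "", ifelse(n > 0 & n < floor, paste0("<", floor),
                              as.character(n)))
}

.fmt <- function(x, digits) {
  ifelse(is.na(x), "", formatC(round_half_up(x, digits), format = "f",
                               digits = digits))
}

#' Render an enrichment table as aligned text
#'
#' One row per scope, columns for each significance level: observed and
#' expected (1 decimal) counts, with an asterisk marking cells whose
#' enrichment statistic exceeds the critical value (observed differing from
#' expected at the chi-square(1) 0.05 level).
#'
#' @param cells A [tabulate_enrichment()] table (one method, one scope level;
#'   multiple alphas welcome).
#' @return A character vector of aligned lines (printed with `cat`).
#' @export
render_enrichment_table <- function(cells) {
  alphas <- sort(unique(cells$alpha), decreasing = TRUE)
  scopes <- unique(cells$scope_name)
  header <- c("Scope", "Items",
              unlist(lapply(alphas, function(a)
                c(sprintf("P<%g obs", a), "exp"))))
  rows <- lapply(scopes, function(s) {
    sub <- cells[cells$scope_name == s, ]
    c(s, as.character(sub$n_items[1]),
      unlist(lapply(alphas, function(a) {
        r <- sub[sub$alpha == a, ]
        if (nrow(r) == 0) return(c("", ""))
        c(paste0(r$observed, if (r$flagged) "*" else ""),
          .fmt(r$expected, 1))
      })))
  })
  tab <- do.call(rbind, c(list(header), rows))
  widths <- apply(nchar(tab), 2, max)
  lines <- apply(tab, 1, function(r)
    paste(mapply(formatC, r, width = widths,
                 flag = c("-", rep("", length(widths) - 1))), collapse = "  "))
  unname(lines)
}

#' Render a category-level drill-down summary
#'
#' The per-category repeat summary for one item — category n, percentage and
#' count with repeats above the threshold, mean [SD] repeats — with counts
#' below the suppression floor rendered `"<floor"`, percentages to 1 decimal
#' and means/SDs to 2 decimals, followed by the two trend p-values.
#'
#' @param summary A [summarize_categories()] payload.
#' @param floor Suppression floor for the high-repeat counts (default 5).
#' @return Character vector of aligned lines.
#' @export
render_category_summary <- function(summary, floor = 5L) {
  tab <- summary$table
  header <- c("Category", "n", "%(n) high", "Mean [SD] repeats")
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    if (r$n == 0) return(c(as.character(r$category), "0", "", ""))
    c(as.character(r$category), as.character(r$n),
      sprintf("%s (%s)", .fmt(r$pct_high, 1), suppress_count(r$n_high, floor)),
      sprintf("%s [%s]", .fmt(r$mean_repeats, 2), .fmt(r$sd_repeats, 2)))
  })
  ptxt <- sprintf("P (binary) = %s   P (trend) = %s",
                  ifelse(is.na(summary$p_binary), "not estimable",
                         .fmt(summary$p_binary, 3)),
                  ifelse(is.na(summary$p_mean), "not estimable",
                         .fmt(summary$p_mean, 3)))
  tabm <- do.call(rbind, c(list(header), rows))
  widths <- apply(nchar(tabm), 2, max)
  lines <- apply(tabm, 1, function(r)
    paste(mapply(formatC, r, width = widths,
                 flag = c("-", rep("", length(widths) - 1))), collapse = "  "))
  c(paste0("Item ", summary$item_id, " (n = ", summary$n_used, ")"),
    unname(lines), ptxt)
}
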