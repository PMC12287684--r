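# Shared fixtures, built in code.

# A small battery: one domain, two topics, mixed measurement types.
small_battery <- function(n1 = 12, n2 = 12) {
  battery_spec(data.frame(domain = c("D1", "D1"), topic = c("T1", "T2"),
                          n_items = c(n1, n2)))
}

# A two-domain battery for enrichment/recovery tests.
two_domain_battery <- function(n1 = 30, n2 = 30) {
  battery_spec(data.frame(domain = c("D1", "D2"), topic = c("T1", "T2"),
                          n_items = c(n1, n2)))
}

# Genotype table straight from counts.
genotypes_from_counts <- function(counts) {
  data.frame(subject_id = sprintf("S%04d", seq_along(counts)),
             repeat_count = as.integer(counts), stringsAsFactors = FALSE)
}

# One-item metadata row.
meta_row <- function(type = "ordinal", k = 3L, id = "X1") {
  tibble::tibble(item_id = id, domain = "D", topic = "T", type = type,
                 n_categories = if (type == "continuous") NA_integer_ else as.integer(k))
}
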