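Package: repeatscan
Title: Phenome Scans of Trinucleotide-Repeat Genotypes Against Large
    Phenotype Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenome-wide association scans of a hemizygous
    trinucleotide-repeat count (such as the FRAXE GCC repeat in AFF2/FMR2)
    against a large multi-domain battery of binary, ordinal and continuous
    phenotype items.  Each item is tested twice: a binary comparison of
    subjects above a repeat-count threshold with the rest, and a linear
    trend in mean repeat count across item categories.  Domain- and
    topic-level enrichment is assessed by comparing observed counts of
    significant tests with the counts expected by chance using a
    chi-square criterion, with concordance filtering and category-level
    drill-down summaries.  A synthetic-cohort generator reproduces the
    statistical structure such scans assume (bimodal repeat distribution,
    multi-domain battery, injected pleiotropic effects, inter-item
    correlation, missingness) so every stage is testable without
    access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
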