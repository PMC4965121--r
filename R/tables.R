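# Published summary counts bundled with the package, and the small
# arithmetic helpers the summary code uses to reproduce the printed
# percentages and per-family averages from raw counts.

#' Load a bundled published-count table
#'
#' The package ships the printed summary counts of the peach-fruit sRNA
#' study (read-filter accounting, annotation-category counts, genome-mapping
#' counts, target counts and degradome per-family counts) as TSV fixtures,
#' so the accounting arithmetic can be exercised against the printed values.
#'
#' @param name one of `"table1_filter_counts"`, `"table3_category_counts"`,
#'   `"genome_mapping_counts"`, `"target_counts"`,
#'   `"degradome_family_counts"`.
#' @return data.frame of the requested table.
#' @export
published_counts <- function(name = c("table1_filter_counts",
                                      "table3_category_counts",
                                      "genome_mapping_counts",
                                      "target_counts",
                                      "degradome_family_counts")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "fruitmir",
                      mustWork = TRUE)
  read_tsv(path)
}

#' Average cleaved targets per miRNA family
#'
#' @param n_targets number of cleaved target genes.
#' @param n_families number of miRNA families cleaving them.
#' @param digits decimal places (half-up, 2 as printed).
#' @return numeric average.
#' @export
per_family_average <- function(n_targets, n_families, digits = 2) {
  round_half_up(n_targets / n_families, digits)
}
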