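#' Reference validation tables
#'
#' Two small tables from the original global 0.5-degree application of the
#' fire-property GLMs are bundled as plain CSV so the package's arithmetic
#' can be validated against published numbers:
#'
#' \itemize{
#'   \item `reference_tss_table()`: True Skill Statistic of the ignition
#'     threshold at candidate percentiles of the zero-cell fitted
#'     distribution (columns `percentile`, `threshold`, `TSS`,
#'     `sensitivity`, `specificity`, `maxTSS`). The identities
#'     `TSS = sensitivity + specificity - 1` and `maxTSS = TSS + 1` hold in
#'     every row.
#'   \item `reference_biome_table()`: total burnt area per biome (km^2) and
#'     its global percentage under modern conditions and the two
#'     end-of-century mitigation scenarios. Each percentage equals the row's
#'     km^2 divided by the column sum of the printed rows; the separately
#'     printed modern global total (4,059,702 km^2) differs slightly from
#'     that row sum (4,060,759 km^2) and is reported via
#'     `printed_global_totals` for the record.
#' }
#'
#' These are validation inputs only -- nothing in the modelling pipeline
#' depends on them.
#'
#' @return A data.frame; `reference_biome_table()` additionally carries a
#'   `printed_global_totals` attribute (named vector, km^2).
#' @export
reference_tss_table <- function() {
  utils::read.csv(system.file("extdata", "tss_reference.csv",
                              package = "fireglm"))
}

#' @rdname reference_tss_table
#' @export
reference_biome_table <- function() {
  tab <- utils::read.csv(system.file("extdata",
                                     "biome_burnt_area_reference.csv",
                                     package = "fireglm"),
                         check.names = FALSE)
  attr(tab, "printed_global_totals") <- c(modern = 4059702,
                                          high_mitigation = 3481953,
                                          low_mitigation = 6114430)
  tab
}
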