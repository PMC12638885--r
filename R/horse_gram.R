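#' Published horse gram MET summary tables
#'
#' The package ships the published summary tables of a six-environment
#' horse gram (*Macrotyloma uniflorum*) mutant trial — 30 genotypes, 6
#' environments, 6 replicates — whose raw plot data were not deposited.
#' Three tables are bundled as plain CSV:
#'
#' * `"genotype_means"` — genotype means over environments for six traits:
#'   DM (days to maturity), NC (clusters/plant), NP (pods/plant),
#'   NPC (pods/cluster), NS (seeds/pod), YD (yield, kg/ha).
#' * `"variance_components"` — REML variance components (genotypic,
#'   genotype-by-environment, error) per trait, with the design constants.
#' * `"selection_response"` — per-trait population mean `XO`, selected-set
#'   mean `XS`, selection differential `SD_PCT` and gain `SG_PCT`.
#'
#' These are worked-example inputs: feeding the variance components through
#' [genetic_parameters()] reproduces the published heritability, accuracy
#' and correlation summaries, and the genotype-mean table reproduces the
#' published footer statistics and trait correlations.
#'
#' @param table One of `"genotype_means"`, `"variance_components"`,
#'   `"selection_response"`.
#' @return A tibble.
#' @export
horse_gram_table <- function(table = c("genotype_means",
                                       "variance_components",
                                       "selection_response")) {
  table <- match.arg(table)
  file <- system.file("extdata",
                      paste0("horse_gram_", table, ".csv"),
                      package = "metstab", mustWork = TRUE)
  readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
}
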