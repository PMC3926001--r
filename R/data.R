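#' Reference per-cohort summary statistics for nine pain-sensitivity DMRs
#'
#' Published per-cohort regression estimates (twin mixed-model and unrelated
#' linear-model slope, standard error and p) for nine whole-blood
#' differentially methylated regions associated with heat-pain sensitivity,
#' together with the printed fixed-effect meta-analysis values. The table is
#' the canonical worked example for [fixed_effect()]: combining the
#' per-cohort (beta, se) pairs reproduces the printed meta-analysis beta at
#' two decimals for seven of the nine rows; the remaining two (TRPA1 and the
#' second ST6GALNAC3 bin) miss by one unit in the second decimal, which is
#' the expected footprint of combining inputs that were themselves rounded
#' to two decimals.
#'
#' @return A tibble with one row per DMR: coordinates, nearest gene,
#'   per-cohort `beta`/`se`/`p`, the within-pair methylation-trait
#'   correlation, and the printed meta-analysis columns.
#' @export
#' @examples
#' d <- map_dmr_summary()
#' fixed_effect(c(d$beta_twin[2], d$beta_unrel[2]),
#'              c(d$se_twin[2], d$se_unrel[2]))
map_dmr_summary <- function() {
  path <- system.file("extdata", "map_dmr_summary.tsv",
                      package = "medipewas", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  na = "NA")
}
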