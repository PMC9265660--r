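# Bundled reference values: efficiency and productivity summaries reported
# by a published three-stage analysis of grain production in China's 13
# major grain-producing provinces (2000-2019).  They are used as numeric
# inputs for the derived-statistic checks (ranges, promotional effects,
# growth rates, before/after productivity gaps) — the underlying
# provincial yearbook inputs are not public, so only these printed
# summaries can be reproduced exactly.

#' Bundled provincial reference tables
#'
#' Returns the reference summary tables shipped with the package:
#' \describe{
#'   \item{stage1}{per-province mean comprehensive technical efficiency
#'     (cte), pure technical efficiency (pte) and scale efficiency (se)
#'     of the unadjusted first stage.}
#'   \item{stage3}{the same after environmental adjustment.}
#'   \item{annual}{output-weighted annual means of the three efficiency
#'     measures, stage 1 and stage 3, 2000-2019.}
#'   \item{gml}{mean global Malmquist-Luenberger index and its
#'     decomposition per province/region, before (plain columns) and
#'     after (`_adj`) adjustment.}
#' }
#'
#' @return named list of data frames.
#' @export
reference_tables <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "ebmgml", mustWork = TRUE),
    stringsAsFactors = FALSE)
  list(stage1 = rd("reference_stage1_efficiency.csv"),
       stage3 = rd("reference_stage3_efficiency.csv"),
       annual = rd("reference_annual_efficiency.csv"),
       gml = rd("reference_gml_summary.csv"))
}
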