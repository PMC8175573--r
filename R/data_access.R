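#' Published hit table of the enucleation screen
#'
#' The 40 hit rows (compound name, tested concentration, enucleation-frequency
#' fold change and cell-number fold change, both plate-normalized against
#' in-plate DMSO controls) reported by the published HDAC-inhibitor
#' enucleation screen. Used as a fixture for the hit-calling rule and as the
#' source of true effect sizes for simulated screens.
#'
#' @return Data.frame with columns `name`, `concentration_uM`,
#'   `enucleation_fold`, `cellnum_fold`.
#' @export
reference_hit_table <- function() {
  utils::read.csv(system.file("extdata", "reference_hit_table.csv",
                              package = "enucleoscreen"),
                  stringsAsFactors = FALSE)
}
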