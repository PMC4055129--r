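# Curated printed tables from the DHFR-inhibitor study the package's
# validation targets derive from, stored verbatim as TSV under extdata.

.fixtureRegistry <- list(
  table1 = list(file = "table1_activity.tsv",
                caption = "Experimental pIC50 values for 45 DHFR inhibitors with train/test split"),
  table2 = list(file = "table2_dock.tsv",
                caption = "DHFR and TS docking scores of TCM candidates plus MTX/MTX-PGs controls"),
  table3 = list(file = "table3_admet.tsv",
                caption = "Predicted ADMET levels (absorption, solubility, hepatotoxicity, PPB)"),
  table4 = list(file = "table4_pls.tsv",
                caption = "PLS statistics of the CoMFA/CoMSIA field models"),
  table5 = list(file = "table5_predictions.tsv",
                caption = "Experimental and CoMFA/CoMSIA-predicted pIC50 with residuals"),
  table6 = list(file = "table6_candidate_predictions.tsv",
                caption = "Per-model predicted pIC50 of the TCM candidates"),
  reference_mlr = list(file = "reference_mlr.tsv",
                       caption = "Printed MLR model: intercept and 11 descriptor coefficients")
)

#' Load a bundled fixture table
#'
#' The printed tables of the underlying DHFR inhibitor study, transcribed
#' verbatim (printed minus signs parsed as negation; absent dock scores as
#' NA). Provenance metadata (source table number and caption) is attached
#' as attributes.
#'
#' @param id one of `names(fixtureIds())`.
#' @return data.frame with attributes "fixture" and "caption".
#' @examples
#' nrow(loadFixture("table1"))  # 45
#' @export
loadFixture <- function(id) {
  if (!id %in% names(.fixtureRegistry)) {
    stop(sprintf("unknown fixture '%s'; available: %s", id,
                 paste(names(.fixtureRegistry), collapse = ", ")), call. = FALSE)
  }
  entry <- .fixtureRegistry[[id]]
  path <- system.file("extdata", entry$file, package = "qsarforge")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (id == "table6") attr(tab, "mtx_experimental") <- 8.5229
  attr(tab, "fixture") <- id
  attr(tab, "caption") <- entry$caption
  tab
}

#' @describeIn loadFixture registered fixture ids with captions.
#' @export
fixtureIds <- function() {
  vapply(.fixtureRegistry, function(e) e$caption, "")
}
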