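#' Build a prediction-vs-experiment validation report
#'
#' Residuals are experimental - predicted; R^2 is the squared Pearson
#' correlation of predicted and experimental activity, computed per subset
#' and overall (the coefficient of determination 1 - SSres/SStot is also
#' carried, under `r2Determination`). Subsets with zero variance in either
#' vector get an NA R^2.
#'
#' @param predictions predicted pIC50 values.
#' @param actuals experimental pIC50 values, aligned.
#' @param subsets subset labels (e.g. "train"/"test"); a single label is
#'   recycled.
#' @param ids optional compound ids.
#' @return a [ValidationReport-class].
#' @examples
#' validationReport(c(1, 2, 3.1), c(1, 2, 3), "train")
#' @export
validationReport <- function(predictions, actuals, subsets = "all", ids = NULL) {
  n <- length(predictions)
  if (length(actuals) != n) stop("predictions and actuals must align", call. = FALSE)
  subsets <- rep_len(as.character(subsets), n)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  tab <- data.frame(id = ids, subset = subsets, experimental = actuals,
                    predicted = predictions,
                    residual = actuals - predictions,
                    stringsAsFactors = FALSE)
  groups <- c(split(seq_len(n), subsets), list(overall = seq_len(n)))
  pearson2 <- vapply(groups, function(ix) {
    if (length(ix) < 3L) return(NA_real_)
    p <- predictions[ix]; a <- actuals[ix]
    if (stats::sd(p) == 0 || stats::sd(a) == 0) return(NA_real_)
    stats::cor(p, a)^2
  }, numeric(1))
  r2det <- vapply(groups, function(ix) {
    a <- actuals[ix]
    sst <- sum((a - mean(a))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((a - predictions[ix])^2) / sst
  }, numeric(1))
  new("ValidationReport", table = tab, r2 = pearson2, r2Determination = r2det)
}

#' @describeIn validationReport residual table accessor.
#' @param report a [ValidationReport-class].
#' @export
residualTable <- function(report) report@table

#' @describeIn validationReport squared Pearson correlations per subset.
#' @param convention "pearson" (default) or "determination".
#' @export
r2Values <- function(report, convention = c("pearson", "determination")) {
  switch(match.arg(convention), pearson = report@r2,
         determination = report@r2Determination)
}
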