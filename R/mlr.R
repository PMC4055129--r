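#' Fit a multiple linear regression QSAR model
#'
#' Ordinary least squares of activity on the named descriptor columns,
#' pIC50 = a0 + sum(a_i x_i). Rank-deficient designs are an error (no
#' silent regularization); remove collinear columns instead.
#'
#' @param X a [DescriptorTable-class] or numeric matrix.
#' @param y activity vector (pIC50), aligned with the rows of X.
#' @return an [MLRModel-class] with fitted coefficients and training r^2.
#' @examples
#' X <- DescriptorTable(matrix(rnorm(30), 10, 3,
#'                      dimnames = list(NULL, c("a", "b", "c"))))
#' fitMLR(X, as.matrix(X) %*% c(1, 2, 3) + 0.5)
#' @export
fitMLR <- function(X, y) {
  Xm <- as.matrix(X)
  if (nrow(Xm) != length(y)) stop("X rows must align with y", call. = FALSE)
  if (nrow(Xm) < ncol(Xm) + 1L) {
    stop("need at least one more sample than descriptors", call. = FALSE)
  }
  Xd <- cbind(`(Intercept)` = 1, Xm)
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrd$pivot[(qrd$rank + 1L):ncol(Xd)]]
    stop(sprintf("design matrix is rank deficient; remove collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cf <- qr.coef(qrd, y)
  fitted <- as.vector(Xd %*% cf)
  r2 <- if (stats::sd(fitted) > 0) as.numeric(stats::cor(fitted, y)^2) else NA_real_
  MLRModel(cf, r2 = r2)
}

#' Predict activity with a linear model
#'
#' @param object an [MLRModel-class].
#' @param newdata a [DescriptorTable-class], matrix or named numeric
#'   vector containing every descriptor the model uses.
#' @param ... ignored.
#' @return numeric vector of predicted pIC50 values.
#' @export
setMethod("predict", "MLRModel", function(object, newdata, ...) {
  cf <- object@coefficients
  terms <- names(cf)[-1]
  v <- resolveDescriptors(newdata, terms)
  as.vector(cf[1] + v %*% cf[-1])
})

# map a vector/matrix/DescriptorTable onto required descriptor names,
# honouring registered aliases; errors name missing descriptors
resolveDescriptors <- function(newdata, terms) {
  if (inherits(newdata, "DescriptorTable")) newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  if (!length(terms)) return(matrix(numeric(0), nrow(newdata), 0))
  avail <- colnames(newdata)
  for (al in names(.descriptorAliases)) {
    if (al %in% avail && !(.descriptorAliases[[al]] %in% avail)) {
      avail[avail == al] <- .descriptorAliases[[al]]
    }
  }
  colnames(newdata) <- avail
  missing <- setdiff(terms, avail)
  if (length(missing)) {
    stop(sprintf("missing descriptor(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  newdata[, terms, drop = FALSE]
}

#' The published DHFR-inhibitor MLR model
#'
#' The fully printed GFA-selected multiple linear regression model from the
#' DHFR inhibitor study this package's fixtures derive from: intercept
#' 31.623 and eleven named descriptor coefficients. Shipped as a fixture
#' so predictions with the literature model are reproducible exactly.
#'
#' @return an [MLRModel-class] carrying the printed coefficients.
#' @examples
#' coef(referenceMLRModel())["(Intercept)"]  # 31.623
#' @export
referenceMLRModel <- function() {
  tab <- utils::read.delim(system.file("extdata", "reference_mlr.tsv",
                                       package = "qsarforge"))
  cf <- stats::setNames(tab$coefficient, tab$term)
  MLRModel(cf)
}

#' Evaluate the published MLR model on a descriptor vector
#'
#' Returns a0 + sum(a_i x_i) with the printed coefficients, exactly.
#' "BD_Count" is accepted as an alias for "HBD_Count".
#'
#' @param v named numeric vector (or one-row table) with all eleven
#'   descriptors.
#' @return predicted pIC50.
#' @examples
#' z <- setNames(numeric(11), setdiff(names(coef(referenceMLRModel())), "(Intercept)"))
#' evaluateReferenceMLR(z)  # 31.623
#' @export
evaluateReferenceMLR <- function(v) {
  predict(referenceMLRModel(), v)
}
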