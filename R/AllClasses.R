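#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Molecule: atoms, bonds and derived per-atom properties
#'
#' The substrate of all descriptor and field computation. Atoms carry an
#' element symbol, optional 3D coordinates (Angstrom), an optional
#' Gasteiger partial charge (elementary charge units), an implicit hydrogen
#' count and a formal charge. Bonds are index pairs with order 1, 2, 3 or
#' 4 (aromatic, SDF convention).
#'
#' @slot name single compound identifier.
#' @slot atoms data.frame with columns element, x, y, z, charge, hcount,
#'   formal. Coordinates and charges are NA until assigned.
#' @slot bonds data.frame with columns a1, a2, order.
#' @export
setClass("Molecule", representation(
  name = "character",
  atoms = "data.frame",
  bonds = "data.frame"
))

setValidity("Molecule", function(object) {
  a <- object@atoms; b <- object@bonds
  msgs <- character()
  need <- c("element", "x", "y", "z", "charge", "hcount", "formal")
  if (!all(need %in% names(a))) {
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(b) > 0L) {
    if (!all(c("a1", "a2", "order") %in% names(b))) {
      return("bonds must have columns a1, a2, order")
    }
    idx <- c(b$a1, b$a2)
    if (any(idx < 1L | idx > nrow(a))) msgs <- c(msgs, "bond atom index out of range")
    if (any(b$a1 == b$a2)) msgs <- c(msgs, "self-bond")
    if (!all(b$order %in% c(1, 2, 3, 4))) msgs <- c(msgs, "bond order must be 1, 2, 3 or 4 (aromatic)")
  }
  if (any(a$hcount < 0, na.rm = TRUE)) msgs <- c(msgs, "implicit hydrogen counts must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a Molecule from atom and bond specifications
#'
#' @param elements character vector of element symbols.
#' @param bonds matrix/data.frame with columns a1, a2, order (may be empty).
#' @param coords optional n x 3 matrix of coordinates (Angstrom).
#' @param charges optional numeric vector of partial charges.
#' @param hcounts optional implicit hydrogen counts; computed from standard
#'   valences when omitted.
#' @param formal optional formal charges (default 0).
#' @param name compound identifier.
#' @return A [Molecule-class] object.
#' @examples
#' water <- Molecule(c("O", "H", "H"),
#'                   bonds = cbind(a1 = c(1, 1), a2 = c(2, 3), order = 1),
#'                   coords = rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' @export
Molecule <- function(elements, bonds = NULL, coords = NULL, charges = NULL,
                     hcounts = NULL, formal = NULL, name = "mol") {
  n <- length(elements)
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = numeric())
  } else {
    bonds <- as.data.frame(bonds)
    names(bonds)[1:3] <- c("a1", "a2", "order")
    bonds$a1 <- as.integer(bonds$a1); bonds$a2 <- as.integer(bonds$a2)
  }
  if (is.null(formal)) formal <- rep(0, n)
  if (is.null(hcounts)) hcounts <- impliedHydrogens(elements, bonds, formal)
  if (is.null(coords)) coords <- matrix(NA_real_, n, 3)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (is.null(charges)) charges <- rep(NA_real_, n)
  atoms <- data.frame(element = as.character(elements),
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      charge = charges, hcount = as.integer(hcounts),
                      formal = as.numeric(formal),
                      stringsAsFactors = FALSE)
  new("Molecule", name = name, atoms = atoms, bonds = bonds)
}

#' @describeIn Molecule number of explicit atoms.
#' @param x,object a Molecule.
#' @export
setMethod("length", "Molecule", function(x) nrow(x@atoms))

setMethod("show", "Molecule", function(object) {
  a <- object@atoms
  cat(sprintf("Molecule '%s': %d atoms (%d implicit H), %d bonds\n",
              object@name, nrow(a), sum(a$hcount), nrow(object@bonds)))
  cat(sprintf("  coordinates: %s; charges: %s\n",
              if (hasCoordinates(object)) "present" else "absent",
              if (hasCharges(object)) "assigned" else "unassigned"))
})

#' @describeIn Molecule TRUE if every atom has finite coordinates.
#' @export
hasCoordinates <- function(object) {
  all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")])))
}

#' @describeIn Molecule TRUE if partial charges are assigned.
#' @export
hasCharges <- function(object) all(is.finite(object@atoms$charge))

#' @describeIn Molecule atom coordinate matrix (n x 3).
#' @export
atomCoords <- function(object) {
  m <- as.matrix(object@atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' @describeIn Molecule element symbols.
#' @export
atomElements <- function(object) object@atoms$element

#' @describeIn Molecule partial charges.
#' @export
partialCharges <- function(object) object@atoms$charge

#' DescriptorTable: compounds by named molecular descriptors
#'
#' A rectangular, fully populated numeric matrix of descriptor values with
#' unique compound ids as rows. This is the design matrix consumed by the
#' 2D regressors and by GFA subset selection.
#'
#' @slot values numeric matrix, rownames = compound ids, colnames =
#'   descriptor names.
#' @export
setClass("DescriptorTable", representation(values = "matrix"))

setValidity("DescriptorTable", function(object) {
  v <- object@values
  if (nrow(v) > 0L) {
    if (is.null(rownames(v)) || anyDuplicated(rownames(v))) {
      return("row ids must be present and unique")
    }
    if (any(!is.finite(v))) return("all descriptor values must be finite")
  }
  if (ncol(v) > 0L && (is.null(colnames(v)) || anyDuplicated(colnames(v)))) {
    return("descriptor names must be present and unique")
  }
  TRUE
})

#' @describeIn DescriptorTable-class construct from a matrix or data.frame.
#' @param values numeric matrix-like, rows = compounds, cols = descriptors.
#' @export
DescriptorTable <- function(values) {
  v <- as.matrix(values)
  storage.mode(v) <- "double"
  if (is.null(rownames(v)) && nrow(v) > 0L) rownames(v) <- as.character(seq_len(nrow(v)))
  new("DescriptorTable", values = v)
}

#' @describeIn DescriptorTable-class underlying numeric matrix.
#' @param x a DescriptorTable.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "DescriptorTable", function(x, ...) x@values)

#' @describeIn DescriptorTable-class dimensions.
#' @export
setMethod("dim", "DescriptorTable", function(x) dim(x@values))

#' @describeIn DescriptorTable-class descriptor (column) names.
#' @export
descriptorNames <- function(x) colnames(x@values)

#' @describeIn DescriptorTable-class compound (row) ids.
#' @export
compoundIds <- function(x) rownames(x@values)

#' @describeIn DescriptorTable-class subset rows/columns, keeping the class.
#' @param i,j,drop as for matrix subsetting (drop is ignored).
#' @export
setMethod("[", "DescriptorTable", function(x, i, j, ..., drop = FALSE) {
  DescriptorTable(x@values[i, j, drop = FALSE])
})

setMethod("show", "DescriptorTable", function(object) {
  cat(sprintf("DescriptorTable: %d compounds x %d descriptors\n",
              nrow(object@values), ncol(object@values)))
  if (ncol(object@values)) {
    cat("  ", paste(utils::head(colnames(object@values), 8), collapse = ", "),
        if (ncol(object@values) > 8) ", ..." else "", "\n", sep = "")
  }
})

#' Linear QSAR model (intercept plus named descriptor terms)
#'
#' Shared representation for ordinary multiple linear regression models and
#' for the linear-term genomes evolved by GFA. Coefficients are stored with
#' the intercept first under "(Intercept)".
#'
#' @slot coefficients named numeric vector, intercept first.
#' @slot lof Friedman lack-of-fit score (NA when not scored).
#' @slot r2 squared Pearson correlation of fitted vs observed on the
#'   training data (NA when unknown).
#' @export
setClass("MLRModel", representation(
  coefficients = "numeric", lof = "numeric", r2 = "numeric"
))

setValidity("MLRModel", function(object) {
  cf <- object@coefficients
  if (is.null(names(cf)) || names(cf)[1] != "(Intercept)") {
    return("coefficients must be named with '(Intercept)' first")
  }
  if (anyDuplicated(names(cf))) return("descriptor names must be unique")
  if (any(!is.finite(cf))) return("coefficients must be finite")
  TRUE
})

MLRModel <- function(coefficients, lof = NA_real_, r2 = NA_real_) {
  new("MLRModel", coefficients = coefficients, lof = lof, r2 = r2)
}

setMethod("show", "MLRModel", function(object) {
  cf <- object@coefficients
  terms <- names(cf)[-1]
  cat(sprintf("MLRModel: intercept %.4g + %d term(s)%s\n", cf[1], length(terms),
              if (!is.na(object@lof)) sprintf(" (LOF %.4g)", object@lof) else ""))
  if (length(terms)) {
    cat("  ", paste(sprintf("%+.4g*%s", cf[-1], terms), collapse = " "), "\n", sep = "")
  }
})

#' @describeIn MLRModel-class model coefficients (intercept first).
#' @param object an MLRModel.
#' @param ... ignored.
#' @export
setMethod("coef", "MLRModel", function(object, ...) object@coefficients)

#' Epsilon-SVR model with Gaussian radial basis kernel
#'
#' @slot sv support-vector descriptor matrix (rows = support vectors).
#' @slot beta dual coefficients alpha - alpha* for the support vectors,
#'   each bounded by the box constraint C in absolute value.
#' @slot b bias term.
#' @slot sigma Gaussian kernel width (the kernel is
#'   exp(-||x - x'||^2 / (2 sigma^2))).
#' @slot C box constraint; @slot epsilon tube half-width.
#' @slot columns descriptor names the model was trained on.
#' @export
setClass("SVRModel", representation(
  sv = "matrix", beta = "numeric", b = "numeric", sigma = "numeric",
  cost = "numeric", epsilon = "numeric", columns = "character"
))

setValidity("SVRModel", function(object) {
  if (object@sigma <= 0) return("sigma must be > 0")
  if (any(abs(object@beta) > object@cost * (1 + 1e-8))) {
    return("|dual coefficient| must not exceed C")
  }
  TRUE
})

setMethod("show", "SVRModel", function(object) {
  cat(sprintf("SVRModel: %d support vectors, sigma %.4g, C %.4g, epsilon %.4g\n",
              nrow(object@sv), object@sigma, object@cost, object@epsilon))
})

#' Bayesian-network category regression model
#'
#' Discretizes activity into ordered categories, fits a per-category
#' ordinary least squares model, learns a discrete Bayesian network over
#' binned descriptors plus the category node, and predicts by evaluating
#' the argmax-posterior category's regression.
#'
#' @slot binEdges strictly increasing activity bin edges (inner edges).
#' @slot betas list of per-category coefficient vectors (intercept first).
#' @slot columns descriptor names used in the regressions/network.
#' @slot descEdges list of per-descriptor discretization inner edges.
#' @slot dag adjacency matrix over network nodes (1 = edge parent->child).
#' @slot cpts list of conditional probability tables per node.
#' @slot catNode name of the category node.
#' @export
setClass("BNCRModel", representation(
  binEdges = "numeric", betas = "list", columns = "character",
  descEdges = "list", dag = "matrix", cpts = "list", catNode = "character"
))

setValidity("BNCRModel", function(object) {
  if (length(object@binEdges) > 1L && any(diff(object@binEdges) <= 0)) {
    return("activity bin edges must be strictly increasing")
  }
  if (nrow(object@dag) > 0L && !.dagIsAcyclic(object@dag)) return("graph must be acyclic")
  for (ct in object@cpts) {
    s <- apply(ct, seq_len(max(1L, length(dim(ct)) - 1L)), sum)
    if (any(abs(s - 1) > 1e-9)) return("each CPT row must sum to 1")
  }
  TRUE
})

setMethod("show", "BNCRModel", function(object) {
  cat(sprintf("BNCRModel: %d categories, %d descriptors, %d network edges\n",
              length(object@betas), length(object@columns), sum(object@dag)))
})

#' Axis-aligned rectangular field lattice
#'
#' @slot origin lattice origin (Angstrom). @slot spacing point spacing.
#' @slot counts number of points per axis.
#' @export
setClass("GridSpec", representation(
  origin = "numeric", spacing = "numeric", counts = "integer"
))

setValidity("GridSpec", function(object) {
  if (object@spacing <= 0) return("spacing must be > 0")
  if (length(object@counts) != 3L || any(object@counts < 2L)) {
    return("need >= 2 points per axis")
  }
  TRUE
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d x %d points, spacing %.3g A, origin (%.3g, %.3g, %.3g)\n",
              object@counts[1], object@counts[2], object@counts[3],
              object@spacing, object@origin[1], object@origin[2], object@origin[3]))
})

#' Molecular interaction field block
#'
#' One field type evaluated for a set of aligned molecules over a common
#' lattice; rows are molecules, columns grid points in GridSpec enumeration
#' order (x fastest).
#'
#' @slot type one of "S", "E", "H", "D", "A".
#' @slot values molecules x grid-points matrix (kcal/mol for CoMFA S/E,
#'   dimensionless similarity indices for CoMSIA).
#' @slot grid the [GridSpec-class] the columns refer to.
#' @slot keptColumns indices into the full lattice (after column filtering).
#' @export
setClass("FieldBlock", representation(
  type = "character", values = "matrix", grid = "GridSpec",
  keptColumns = "integer"
))

setValidity("FieldBlock", function(object) {
  if (!object@type %in% c("S", "E", "H", "D", "A")) return("unknown field type")
  if (any(!is.finite(object@values))) return("field values must be finite")
  TRUE
})

setMethod("show", "FieldBlock", function(object) {
  cat(sprintf("FieldBlock '%s': %d molecules x %d grid points\n",
              object@type, nrow(object@values), ncol(object@values)))
})

#' Partial least squares (PLS1) field model
#'
#' @slot coefficients regression vector on the original (uncentered) columns.
#' @slot intercept scalar intercept.
#' @slot ncomp number of latent components.
#' @slot r2 coefficient of determination on the training fit.
#' @slot see standard error of estimate. @slot f F statistic.
#' @slot blockIndex integer vector assigning columns to field blocks.
#' @slot blockTypes field-type letter per block.
#' @export
setClass("PLSModel", representation(
  coefficients = "numeric", intercept = "numeric", ncomp = "integer",
  r2 = "numeric", see = "numeric", f = "numeric",
  blockIndex = "integer", blockTypes = "character"
))

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d component(s), r2 %.4f, SEE %.4f, F %.2f\n",
              object@ncomp, object@r2, object@see, object@f))
})

#' Prediction-vs-experiment validation report
#'
#' Per-compound residuals (experimental - predicted) together with squared
#' Pearson correlations per subset. The squared Pearson convention is the
#' reported default; the coefficient of determination 1 - SSres/SStot is
#' also carried for reference.
#'
#' @slot table data.frame with columns id, subset, experimental, predicted,
#'   residual.
#' @slot r2 named numeric: squared Pearson correlation per subset plus
#'   "overall" (NA where undefined).
#' @slot r2Determination same layout, 1 - SSres/SStot convention.
#' @export
setClass("ValidationReport", representation(
  table = "data.frame", r2 = "numeric", r2Determination = "numeric"
))

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %d compounds\n", nrow(object@table)))
  for (nm in names(object@r2)) {
    cat(sprintf("  R2[%s] = %s\n", nm,
                if (is.na(object@r2[nm])) "undefined" else sprintf("%.4f", object@r2[nm])))
  }
})
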