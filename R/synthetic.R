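# Seeded synthetic-data generators emulating the statistical structure
# each model class assumes: sparse linear activity for MLR/GFA/SVR,
# piecewise-linear category structure for BNCR, and aligned pseudo-atom
# series with field-linear activity for the 3D models.

#' Generate a linear-model descriptor dataset
#'
#' Descriptor columns are standard normal draws; activity is
#' a0 + sum(a_i x_i) + Gaussian noise. The planted truth is returned for
#' recovery tests.
#'
#' @param n samples; @param p descriptors (n > p required).
#' @param terms named coefficient vector over a subset of columns
#'   ("x1".."xp"); default plants 2*x3 - 1*x7.
#' @param intercept a0.
#' @param noiseSD activity noise standard deviation (pIC50 units).
#' @param seed RNG seed (mandatory).
#' @return list: `table` ([DescriptorTable-class]), `y`, `truth`.
#' @export
genLinearDataset <- function(n = 60L, p = 20L, terms = c(x3 = 2, x7 = -1),
                             intercept = 5, noiseSD = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n <= p) stop("need n > p", call. = FALSE)
  bad <- setdiff(names(terms), paste0("x", seq_len(p)))
  if (length(bad)) {
    stop(sprintf("planted term(s) outside the descriptor set: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  withSeed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(sprintf("cmp%03d", seq_len(n)),
                                paste0("x", seq_len(p))))
    y <- intercept + as.vector(X[, names(terms), drop = FALSE] %*% terms) +
      stats::rnorm(n, sd = noiseSD)
    list(table = DescriptorTable(X), y = y,
         truth = list(terms = terms, intercept = intercept, noiseSD = noiseSD))
  })
}

#' Generate a category-structured (piecewise-linear) dataset
#'
#' A latent ordered category is marked by a designated discrete driver
#' descriptor (x1 carries the category value exactly, so any quantile
#' binning separates the regimes and a Bayesian network can learn the
#' dependence); within each category the activity follows its own linear
#' model on x2 plus noise. Categories are separated on the activity scale
#' so that, at zero noise, the regimes are disjoint.
#'
#' @param n samples; @param p descriptors.
#' @param nCategories number of activity regimes.
#' @param slopes per-category slope on the effect descriptor; defaults to
#'   distinct values per category.
#' @param separation activity offset between consecutive categories.
#' @param noiseSD within-category noise.
#' @param shuffle if TRUE the category labels are permuted after the
#'   driver is written, decoupling descriptors from activity regime (null
#'   structure for negative controls).
#' @param seed RNG seed (mandatory).
#' @return list: `table`, `y`, `truth` (labels, slopes, offsets, driver).
#' @export
genCategoryDataset <- function(n = 150L, p = 4L, nCategories = 2L,
                               slopes = NULL, separation = 8, noiseSD = 0.2,
                               shuffle = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(slopes)) slopes <- seq(2, by = -3, length.out = nCategories)
  withSeed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(sprintf("cmp%03d", seq_len(n)),
                                paste0("x", seq_len(p))))
    labels <- sample(rep_len(seq_len(nCategories), n))
    X[, 1] <- labels  # discrete category marker
    if (shuffle) labels <- sample(labels)
    offsets <- separation * (seq_len(nCategories) - 1L)
    y <- offsets[labels] + slopes[labels] * X[, 2] + stats::rnorm(n, sd = noiseSD)
    list(table = DescriptorTable(X), y = y,
         truth = list(labels = labels, slopes = slopes, offsets = offsets,
                      driver = "x1", effect = "x2"))
  })
}

#' Generate an aligned congeneric series for field models
#'
#' A rigid scaffold of pseudo-atoms shared by every molecule, plus a fixed
#' substituent position whose atom varies in element (and hence field
#' contribution) across the series. Activity is a known linear function of
#' a designated field block's values at designated lattice points, plus
#' noise. Molecules are perfectly aligned by construction.
#'
#' @param nMolecules series size.
#' @param fieldType field letter whose values drive activity ("S", "E",
#'   "H", "D" or "A" under [comsiaFields()]).
#' @param nDriverPoints lattice points entering the activity function.
#' @param weightSD spread of the random activity weights.
#' @param noiseSD activity noise.
#' @param spacing,margin lattice parameters used for the driving field.
#' @param seed RNG seed (mandatory).
#' @return list: `mols` (prepared, aligned), `y`, `grid`, `truth`
#'   (driver points and weights).
#' @export
genAlignedSeries <- function(nMolecules = 12L, fieldType = "H",
                             nDriverPoints = 5L, weightSD = 1,
                             noiseSD = 0, spacing = 2.0, margin = 3.0, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  withSeed(seed, {
    # rigid T-shaped scaffold; substituent position at the tip
    scaffold <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0),
                      c(1.5, 1.5, 0), c(4.2, 0.9, 0.6))
    subElements <- c("C", "N", "O", "S", "F", "Cl")
    mols <- lapply(seq_len(nMolecules), function(i) {
      el <- c("C", "C", "C", "O", sample(subElements, 1))
      jitter <- matrix(stats::rnorm(3, sd = 0.05), nrow = 1)  # substituent wobble
      coords <- scaffold
      coords[5, ] <- coords[5, ] + jitter
      m <- Molecule(el, bonds = cbind(a1 = c(1, 2, 2, 3), a2 = c(2, 3, 4, 5),
                                      order = 1),
                    coords = coords, hcounts = rep(0L, 5),
                    name = sprintf("syn%02d", i))
      assignPartialCharges(m)
    })
    grid <- buildGrid(mols, spacing = spacing, margin = margin)
    block <- comsiaFields(mols, grid, types = fieldType)[[fieldType]]
    V <- block@values
    driver <- sample.int(ncol(V), nDriverPoints)
    w <- stats::rnorm(nDriverPoints, sd = weightSD)
    y <- as.vector(V[, driver, drop = FALSE] %*% w) +
      stats::rnorm(nMolecules, sd = noiseSD)
    list(mols = mols, y = y, grid = grid,
         truth = list(driverPoints = driver, weights = w,
                      fieldType = fieldType))
  })
}
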