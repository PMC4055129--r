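# NIPALS PLS1 on centered data; returns regression vector for the
# requested number of components.
.plsCore <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); qv <- numeric(ncomp)
  E <- Xc; f <- yc
  used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    p_a <- crossprod(E, t) / tt
    q_a <- sum(f * t) / tt
    E <- E - t %*% t(p_a)
    f <- f - t * q_a
    W[, a] <- w; P[, a] <- p_a; qv[a] <- q_a
    used <- a
  }
  if (used == 0L) {
    return(list(coef = numeric(p), intercept = ym, ncomp = 0L,
                xmean = xm, ymean = ym))
  }
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  qv <- qv[seq_len(used)]
  B <- W %*% solve(t(P) %*% W, qv)
  list(coef = as.vector(B), intercept = ym - sum(xm * B), ncomp = used,
       xmean = xm, ymean = ym)
}

#' Fit a PLS1 field model
#'
#' NIPALS partial least squares of activity on concatenated field columns.
#' Training statistics follow the CoMFA reporting conventions:
#' r^2 = 1 - SSres/SStot, SEE = sqrt(SSres / (m - c - 1)) and
#' F = (r^2 / c) / ((1 - r^2) / (m - c - 1)), with m molecules and c
#' latent components.
#'
#' @param X numeric matrix (molecules x field columns), e.g. from
#'   [concatBlocks()].
#' @param y activity vector (pIC50).
#' @param ncomp number of latent components
#'   (<= min(rows - 1, columns)).
#' @param blockIndex optional integer vector assigning each column to a
#'   field block (for fraction reporting).
#' @param blockTypes optional field-type letters per block.
#' @return a [PLSModel-class].
#' @export
fitPLS <- function(X, y, ncomp, blockIndex = NULL, blockTypes = NULL) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (stats::sd(y) == 0) stop("activity has zero variance", call. = FALSE)
  if (ncomp > min(m - 1L, ncol(X))) {
    stop("ncomp must be <= min(rows - 1, columns)", call. = FALSE)
  }
  core <- .plsCore(X, y, ncomp)
  fitted <- as.vector(X %*% core$coef + core$intercept)
  ssres <- sum((y - fitted)^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- 1 - ssres / sstot
  c_ <- core$ncomp
  see <- if (m - c_ - 1L > 0L) sqrt(ssres / (m - c_ - 1L)) else NA_real_
  f <- if (m - c_ - 1L > 0L && r2 < 1) (r2 / c_) / ((1 - r2) / (m - c_ - 1L)) else Inf
  new("PLSModel", coefficients = core$coef, intercept = core$intercept,
      ncomp = as.integer(core$ncomp), r2 = r2, see = see, f = f,
      blockIndex = as.integer(blockIndex %||% rep(1L, ncol(X))),
      blockTypes = blockTypes %||% "S")
}

#' @describeIn fitPLS predict activity for new field rows.
#' @param object a [PLSModel-class].
#' @param newdata matrix of field values with matching columns.
#' @param ... ignored.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  nd <- as.matrix(newdata)
  as.vector(nd %*% object@coefficients + object@intercept)
})

#' Leave-one-out cross-validated q^2
#'
#' q^2 = 1 - PRESS / SStot, where PRESS accumulates squared errors of
#' models refitted with each molecule left out and SStot is about the
#' overall activity mean. Zero components corresponds to predicting the
#' mean, hence q^2 = 0 by convention.
#'
#' @inheritParams fitPLS
#' @return scalar q^2 (at most 1; can be negative for models worse than
#'   the mean).
#' @export
looQ2 <- function(X, y, ncomp) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (ncomp == 0L) return(0)
  if (ncomp > min(m - 2L, ncol(X))) {
    stop("ncomp too large for leave-one-out refits", call. = FALSE)
  }
  press <- 0
  for (i in seq_len(m)) {
    core <- .plsCore(X[-i, , drop = FALSE], y[-i], ncomp)
    pred <- sum(X[i, ] * core$coef) + core$intercept
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Concatenate field blocks into one design matrix
#'
#' @param blocks list of [FieldBlock-class] with equal molecule counts.
#' @return list: `X` (molecules x total columns), `blockIndex`,
#'   `blockTypes`.
#' @export
concatBlocks <- function(blocks) {
  X <- do.call(cbind, lapply(blocks, function(b) b@values))
  blockIndex <- rep(seq_along(blocks),
                    vapply(blocks, function(b) ncol(b@values), integer(1)))
  list(X = X, blockIndex = blockIndex,
       blockTypes = vapply(blocks, function(b) b@type, ""))
}

#' Per-field fraction contributions
#'
#' Share of the summed absolute PLS coefficient mass (coefficient x column
#' standard deviation) falling on each field block; fractions are
#' non-negative and sum to 1.
#'
#' @param model a [PLSModel-class].
#' @param X the design matrix the model was fitted on.
#' @return named numeric vector of fractions per field type.
#' @export
fieldFractions <- function(model, X) {
  sds <- apply(as.matrix(X), 2, stats::sd)
  mass <- abs(model@coefficients) * sds
  total <- sum(mass)
  if (total == 0) total <- 1
  out <- vapply(seq_along(model@blockTypes), function(b) {
    sum(mass[model@blockIndex == b]) / total
  }, numeric(1))
  stats::setNames(out, model@blockTypes)
}

#' Scan field-type combinations and report PLS statistics
#'
#' For each combination string (e.g. "SE", "EHA", "EHDA"): concatenate the
#' named blocks (already column-filtered), scan component counts 1..max,
#' select the optimal number of components (ONC) as the argmax of
#' leave-one-out q^2 (ties resolve to fewer components), and report q^2,
#' r^2, SEE, F and per-field fractions at the ONC.
#'
#' @param blocks named list of filtered [FieldBlock-class] objects keyed
#'   by field letter.
#' @param y activity vector.
#' @param combinations character vector of type-strings.
#' @param maxComponents largest component count scanned.
#' @return data.frame, one row per combination, in the given order, with
#'   columns model, onc, q2, r2, see, f and frac_<letter>.
#' @export
runFieldCombinations <- function(blocks, y, combinations,
                                 maxComponents = 10L) {
  rows <- lapply(combinations, function(combo) {
    letters_ <- strsplit(combo, "")[[1]]
    if (anyDuplicated(letters_)) {
      stop(sprintf("duplicate field letters in combination '%s'", combo),
           call. = FALSE)
    }
    missing <- setdiff(letters_, names(blocks))
    if (length(missing)) {
      stop(sprintf("no field block for letter(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    cc <- concatBlocks(blocks[letters_])
    kmax <- min(maxComponents, nrow(cc$X) - 2L, ncol(cc$X))
    q2s <- vapply(seq_len(kmax), function(k) looQ2(cc$X, y, k), numeric(1))
    onc <- which.max(q2s)  # ties: which.max takes the first = fewest
    model <- fitPLS(cc$X, y, onc, cc$blockIndex, cc$blockTypes)
    fr <- fieldFractions(model, cc$X)
    frac <- stats::setNames(rep(0, 5), c("S", "E", "H", "D", "A"))
    frac[names(fr)] <- fr
    data.frame(model = combo, onc = onc, q2 = q2s[onc], r2 = model@r2,
               see = model@see, f = model@f,
               frac_s = frac["S"], frac_e = frac["E"], frac_h = frac["H"],
               frac_d = frac["D"], frac_a = frac["A"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Export favored/disfavored contour point sets
#'
#' Back-projects the PLS coefficient x column-standard-deviation products
#' onto the lattice and returns, per field, the grid points above the
#' favored percentile and below the disfavored percentile of the signed
#' product distribution (standard CoMFA contour levels, defaults 80/20).
#'
#' @param model a [PLSModel-class] fitted on concatenated filtered blocks.
#' @param X the design matrix used for the fit.
#' @param blocks the filtered [FieldBlock-class] list (for the kept-index
#'   maps and the grid).
#' @param favored,disfavored percentiles in [0, 100], favored > disfavored.
#' @return data.frame with columns field, set ("favored"/"disfavored"),
#'   x, y, z, value.
#' @export
exportContours <- function(model, X, blocks, favored = 80, disfavored = 20) {
  if (favored <= disfavored) {
    stop("favored percentile must exceed disfavored percentile", call. = FALSE)
  }
  sds <- apply(as.matrix(X), 2, stats::sd)
  prod <- model@coefficients * sds
  out <- list()
  for (b in seq_along(blocks)) {
    sel <- model@blockIndex == b
    v <- prod[sel]
    pts <- gridPoints(blocks[[b]]@grid)[blocks[[b]]@keptColumns, , drop = FALSE]
    hi <- stats::quantile(v, favored / 100, names = FALSE)
    lo <- stats::quantile(v, disfavored / 100, names = FALSE)
    fav <- which(v >= hi); dis <- which(v <= lo)
    if (favored == 100) fav <- seq_along(v)
    if (disfavored == 0) dis <- setdiff(seq_along(v), fav)
    mk <- function(ix, set) if (length(ix)) {
      data.frame(field = blocks[[b]]@type, set = set,
                 x = pts[ix, 1], y = pts[ix, 2], z = pts[ix, 3],
                 value = v[ix], stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- mk(fav, "favored")
    out[[length(out) + 1L]] <- mk(setdiff(dis, fav), "disfavored")
  }
  do.call(rbind, out)
}
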