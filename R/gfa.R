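#' Activity-correlation descriptor prefilter
#'
#' Retains descriptor columns whose squared Pearson correlation with the
#' activity reaches the threshold. A threshold of 0 keeps every column.
#' Zero-variance columns (correlation undefined) are dropped with a
#' warning.
#'
#' @param table a [DescriptorTable-class].
#' @param y activity vector aligned with the table rows.
#' @param threshold minimum r^2 in [0, 1].
#' @return the filtered [DescriptorTable-class].
#' @export
prefilterDescriptors <- function(table, y, threshold = 0.8) {
  X <- as.matrix(table)
  if (nrow(X) != length(y)) stop("table rows must align with y", call. = FALSE)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding zero-variance column(s): %s",
                    paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  ok <- sds > 0
  if (threshold > 0) {
    r2 <- rep(0, ncol(X))
    r2[ok] <- as.vector(stats::cor(X[, ok, drop = FALSE], y))^2
    ok <- ok & r2 >= threshold
  }
  table[, which(ok)]
}

# OLS fit of a descriptor subset; returns coefficients + residual sum of squares
.fitSubset <- function(X, y, terms) {
  Xd <- cbind(`(Intercept)` = 1, X[, terms, drop = FALSE])
  fit <- stats::lm.fit(Xd, y)
  rss <- sum(fit$residuals^2)
  list(coef = fit$coefficients, rss = rss, rank = fit$rank)
}

#' Friedman lack-of-fit score
#'
#' LOF = LSE / (1 - (c + d p) / m)^2, where LSE is the residual sum of
#' squares, c the number of coefficients including the intercept, p the
#' number of (non-intercept) terms, m the sample count and d the smoothing
#' factor penalizing model size. Lower is better; a non-positive
#' denominator yields +Inf (model rejected).
#'
#' @param lse residual sum of squares of the fitted linear model.
#' @param nCoefficients c (terms + intercept).
#' @param nTerms p.
#' @param m number of samples.
#' @param d smoothing factor (default 1).
#' @return the scalar LOF score.
#' @examples
#' lofScore(2.5, nCoefficients = 3, nTerms = 2, m = 10, d = 1)  # 10
#' @export
lofScore <- function(lse, nCoefficients, nTerms, m, d = 1) {
  den <- 1 - (nCoefficients + d * nTerms) / m
  if (den <= 0) return(Inf)
  lse / den^2
}

# score one genome (an integer vector of column indices)
.scoreGenome <- function(genome, X, y, d) {
  if (!length(genome)) {
    rss <- sum((y - mean(y))^2)
    return(list(lof = lofScore(rss, 1, 0, length(y), d),
                coef = c(`(Intercept)` = mean(y)), rss = rss))
  }
  fit <- .fitSubset(X, y, genome)
  if (fit$rank < length(genome) + 1L || anyNA(fit$coef)) {
    return(list(lof = Inf, coef = fit$coef, rss = fit$rss))
  }
  list(lof = lofScore(fit$rss, length(genome) + 1L, length(genome), length(y), d),
       coef = fit$coef, rss = fit$rss)
}

#' Genetic function approximation over descriptor subsets
#'
#' Evolves a population of linear-model term sets: random initial subsets
#' within the term cap, tournament selection (size 2), single-point
#' crossover on sorted term lists, and a mutation that adds, removes or
#' swaps one term. Every genome is fitted by ordinary least squares and
#' scored by the Friedman lack-of-fit criterion ([lofScore()]); the single
#' best genome survives each generation unchanged (elitism), so the best
#' LOF is non-increasing across generations. Deterministic given the seed.
#'
#' @param table a [DescriptorTable-class] (optionally prefiltered with
#'   [prefilterDescriptors()]; the r^2 > 0.8 activity-correlation filter is
#'   deliberately not applied by default).
#' @param y activity vector aligned with the table rows.
#' @param populationSize,generations GA size controls.
#' @param crossoverProb,mutationProb operator probabilities in [0, 1].
#' @param maxTerms largest allowed number of descriptor terms per model.
#' @param d LOF smoothing factor.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list of [MLRModel-class] objects, deduplicated by term set and
#'   sorted by ascending LOF; each carries fitted coefficients, its LOF
#'   and training r^2.
#' @export
runGFA <- function(table, y, populationSize = 50L, generations = 50L,
                   crossoverProb = 0.9, mutationProb = 0.3, maxTerms = 3L,
                   d = 1, seed = 1L) {
  X <- as.matrix(table)
  p <- ncol(X)
  if (p < 1L) stop("need at least one descriptor", call. = FALSE)
  if (nrow(X) != length(y)) stop("table rows must align with y", call. = FALSE)
  if (populationSize < 2L) stop("population must be >= 2", call. = FALSE)
  stopifnot(crossoverProb >= 0, crossoverProb <= 1,
            mutationProb >= 0, mutationProb <= 1)
  maxTerms <- min(maxTerms, p, nrow(X) - 2L)

  withSeed(seed, {
    newGenome <- function() sort(sample.int(p, sample.int(maxTerms, 1)))
    pop <- replicate(populationSize, newGenome(), simplify = FALSE)
    scores <- vapply(pop, function(g) .scoreGenome(g, X, y, d)$lof, numeric(1))

    tournament <- function() {
      ij <- sample.int(populationSize, 2L)
      pop[[ij[which.min(scores[ij])]]]
    }
    crossover <- function(g1, g2) {
      if (!length(g1) || !length(g2)) return(g1)
      cut <- sample.int(length(g1), 1L)
      child <- unique(c(g1[seq_len(cut)], g2))
      sort(child[seq_len(min(length(child), maxTerms))])
    }
    mutate <- function(g) {
      move <- sample(c("add", "remove", "swap"), 1L)
      free <- setdiff(seq_len(p), g)
      if (move == "add" && length(free) && length(g) < maxTerms) {
        g <- c(g, sample(free, 1L))
      } else if (move == "remove" && length(g) > 1L) {
        g <- g[-sample.int(length(g), 1L)]
      } else if (length(free) && length(g)) {
        g[sample.int(length(g), 1L)] <- sample(free, 1L)
      }
      sort(unique(g))
    }

    for (gen in seq_len(generations)) {
      elite <- pop[[which.min(scores)]]
      nxt <- list(elite)
      while (length(nxt) < populationSize) {
        child <- tournament()
        if (stats::runif(1) < crossoverProb) child <- crossover(child, tournament())
        if (stats::runif(1) < mutationProb) child <- mutate(child)
        nxt[[length(nxt) + 1L]] <- child
      }
      pop <- nxt
      scores <- vapply(pop, function(g) .scoreGenome(g, X, y, d)$lof, numeric(1))
    }

    keys <- vapply(pop, paste, "", collapse = ",")
    keep <- !duplicated(keys)
    pop <- pop[keep]; scores <- scores[keep]
    ord <- order(scores)
    lapply(ord, function(i) {
      sc <- .scoreGenome(pop[[i]], X, y, d)
      names(sc$coef) <- c("(Intercept)", colnames(X)[pop[[i]]])
      fitted <- cbind(1, X[, pop[[i]], drop = FALSE]) %*% sc$coef
      r2 <- if (stats::sd(fitted) > 0) stats::cor(fitted, y)^2 else NA_real_
      MLRModel(sc$coef, lof = sc$lof, r2 = as.numeric(r2))
    })
  })
}

#' Exhaustive descriptor-subset search (reference implementation)
#'
#' Enumerates every descriptor subset up to `maxTerms` and returns the one
#' with the lowest Friedman LOF. Exponential in the descriptor count; used
#' as the ground-truth oracle for [runGFA()] on small problems.
#'
#' @inheritParams runGFA
#' @return an [MLRModel-class] with the optimal term set.
#' @export
exhaustiveSubsetSearch <- function(table, y, maxTerms = 3L, d = 1) {
  X <- as.matrix(table)
  best <- NULL; bestLof <- Inf
  for (k in seq_len(min(maxTerms, ncol(X)))) {
    idx <- utils::combn(ncol(X), k)
    for (cix in seq_len(ncol(idx))) {
      sc <- .scoreGenome(idx[, cix], X, y, d)
      if (sc$lof < bestLof) {
        bestLof <- sc$lof
        best <- idx[, cix]
      }
    }
  }
  sc <- .scoreGenome(best, X, y, d)
  names(sc$coef) <- c("(Intercept)", colnames(X)[best])
  MLRModel(sc$coef, lof = sc$lof)
}
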