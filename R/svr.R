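#' Gaussian radial basis kernel matrix
#'
#' K(x, x') = exp(-||x - x'||^2 / (2 sigma^2)); symmetric positive
#' semi-definite for any sample set.
#'
#' @param X,X2 sample matrices (rows = samples); X2 defaults to X.
#' @param sigma kernel width (> 0).
#' @return kernel matrix of dimension nrow(X) x nrow(X2).
#' @export
rbfKernel <- function(X, X2 = X, sigma) {
  stopifnot(sigma > 0)
  d2 <- outer(rowSums(X^2), rowSums(X2^2), `+`) - 2 * X %*% t(X2)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

# epsilon-SVR dual objective in the beta = alpha - alpha* parametrization:
# W(beta) = 1/2 beta' K beta - y' beta + eps * sum|beta|,
# subject to sum(beta) = 0, |beta_i| <= C.
.svrDualObjective <- function(beta, K, y, epsilon) {
  0.5 * sum(beta * (K %*% beta)) - sum(y * beta) + epsilon * sum(abs(beta))
}

# Pairwise (SMO-style) coordinate descent on the dual. Each step optimizes
# beta_i + t, beta_j - t exactly over the piecewise quadratic in t (kinks
# where either coefficient crosses zero), preserving the equality
# constraint. Deterministic sweep order.
.solveSVRDual <- function(K, y, C, epsilon, tol = 1e-3, maxSweeps = 500L) {
  n <- length(y)
  beta <- numeric(n)
  Kb <- numeric(n)  # K %*% beta, maintained incrementally

  pairStep <- function(i, j) {
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta < 1e-12) return(FALSE)
    g <- (Kb[i] - y[i]) - (Kb[j] - y[j])
    L <- max(-C - beta[i], beta[j] - C)
    H <- min(C - beta[i], beta[j] + C)
    if (H <= L) return(FALSE)
    cand <- c(L, H,
              pmin(pmax(-beta[i], L), H),   # kink: beta_i crosses 0
              pmin(pmax(beta[j], L), H))    # kink: beta_j crosses 0
    for (si in c(-1, 1)) for (sj in c(-1, 1)) {
      t0 <- -(g + epsilon * (si + sj)) / eta
      cand <- c(cand, pmin(pmax(t0, L), H))
    }
    dW <- function(t) {
      0.5 * eta * t^2 + g * t +
        epsilon * (abs(beta[i] + t) - abs(beta[i]) +
                     abs(beta[j] - t) - abs(beta[j]))
    }
    vals <- vapply(cand, dW, numeric(1))
    t <- cand[which.min(vals)]
    if (min(vals) > -1e-14 || abs(t) < 1e-14) return(FALSE)
    beta[i] <<- beta[i] + t
    beta[j] <<- beta[j] - t
    Kb <<- Kb + t * (K[, i] - K[, j])
    TRUE
  }

  kkt <- function() {
    # multiplier interval implied by each coefficient's KKT condition
    F <- y - Kb
    lo <- -Inf; hi <- Inf; viol <- 0
    zeroBand <- 1e-8 * C
    for (i in seq_len(n)) {
      b <- beta[i]
      if (b > zeroBand && b < C * (1 - 1e-9)) {          # on upper tube
        lo <- max(lo, F[i] - epsilon); hi <- min(hi, F[i] - epsilon)
      } else if (b < -zeroBand && b > -C * (1 - 1e-9)) { # on lower tube
        lo <- max(lo, F[i] + epsilon); hi <- min(hi, F[i] + epsilon)
      } else if (abs(b) <= zeroBand) {
        lo <- max(lo, F[i] - epsilon); hi <- min(hi, F[i] + epsilon)
      } else if (b >= C * (1 - 1e-9)) {   # at +C: residual >= epsilon
        hi <- min(hi, F[i] - epsilon)
      } else {                            # at -C: residual <= -epsilon
        lo <- max(lo, F[i] + epsilon)
      }
    }
    if (lo <= hi) list(gap = 0, b = (lo + hi) / 2) else
      list(gap = lo - hi, b = (lo + hi) / 2)
  }

  for (sweep in seq_len(maxSweeps)) {
    changed <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (pairStep(i, j)) changed <- TRUE
    }
    k <- kkt()
    if (k$gap < tol) return(list(beta = beta, b = k$b, gap = k$gap))
    if (!changed) break
  }
  k <- kkt()
  if (k$gap >= tol) {
    stop(sprintf("SVR solver did not converge: KKT gap %.3g (tolerance %.3g)",
                 k$gap, tol), call. = FALSE)
  }
  list(beta = beta, b = k$b, gap = k$gap)
}

#' Fit an epsilon-insensitive support vector regression
#'
#' Minimizes the standard epsilon-SVR dual with the Gaussian kernel of
#' [rbfKernel()] using a pairwise coordinate (SMO-style) solver; the
#' equality constraint and box constraints are maintained exactly and the
#' solution satisfies the Karush-Kuhn-Tucker conditions to the stated
#' tolerance.
#'
#' @param X a [DescriptorTable-class] or numeric matrix.
#' @param y activity vector.
#' @param C box constraint (> 0).
#' @param epsilon tube half-width (> 0).
#' @param sigma kernel width; default is the median pairwise Euclidean
#'   distance heuristic.
#' @param tol KKT tolerance.
#' @return an [SVRModel-class].
#' @export
fitSVR <- function(X, y, C = 10, epsilon = 0.1, sigma = NULL, tol = 1e-3) {
  Xm <- as.matrix(X)
  stopifnot(C > 0, epsilon > 0)
  if (is.null(sigma)) {
    d <- stats::dist(Xm)
    sigma <- stats::median(d[d > 0])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  K <- rbfKernel(Xm, sigma = sigma)
  sol <- .solveSVRDual(K, y, C, epsilon, tol = tol)
  sv <- which(abs(sol$beta) > 1e-10)
  new("SVRModel", sv = Xm[sv, , drop = FALSE], beta = sol$beta[sv],
      b = sol$b, sigma = sigma, cost = C, epsilon = epsilon,
      columns = colnames(Xm) %||% character())
}

#' @describeIn fitSVR predict activity for new descriptor rows.
#' @param object an [SVRModel-class].
#' @param newdata descriptor matrix/table/vector.
#' @param ... ignored.
#' @export
setMethod("predict", "SVRModel", function(object, newdata, ...) {
  nd <- if (length(object@columns)) resolveDescriptors(newdata, object@columns)
        else { if (is.null(dim(newdata))) t(as.matrix(newdata)) else as.matrix(newdata) }
  if (nrow(object@sv) == 0L) return(rep(object@b, nrow(nd)))
  as.vector(rbfKernel(nd, object@sv, object@sigma) %*% object@beta + object@b)
})

# dual objective of a fitted model on its training kernel (for oracles/tests)
svrDualObjective <- function(model, X, y) {
  Xm <- as.matrix(X)
  beta <- numeric(nrow(Xm))
  if (nrow(model@sv)) {
    key <- apply(round(Xm, 10), 1, paste, collapse = ",")
    skey <- apply(round(model@sv, 10), 1, paste, collapse = ",")
    beta[match(skey, key)] <- model@beta
  }
  .svrDualObjective(beta, rbfKernel(Xm, sigma = model@sigma), y, model@epsilon)
}

#' Seeded k-fold grid search for SVR hyperparameters
#'
#' Cross-validation over a (C, sigma, epsilon) grid; fold assignment is
#' seeded and the minimising combination by mean squared error is refitted
#' on the full data.
#'
#' @inheritParams fitSVR
#' @param Cs,sigmas,epsilons candidate values.
#' @param folds number of cross-validation folds.
#' @param seed fold-assignment seed.
#' @return list: `model` (the refitted [SVRModel-class]), `grid`
#'   (data.frame of mean CV errors), `best` (chosen row).
#' @export
tuneSVR <- function(X, y, Cs = c(1, 10, 100), sigmas = NULL,
                    epsilons = c(0.05, 0.1, 0.2), folds = 3L, seed = 1L) {
  Xm <- as.matrix(X)
  if (is.null(sigmas)) {
    d <- stats::dist(Xm); s0 <- stats::median(d[d > 0])
    sigmas <- s0 * c(0.5, 1, 2)
  }
  fold <- withSeed(seed, sample(rep_len(seq_len(folds), nrow(Xm))))
  grid <- expand.grid(C = Cs, sigma = sigmas, epsilon = epsilons)
  grid$mse <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- fitSVR(Xm[tr, , drop = FALSE], y[tr], C = grid$C[g],
                  epsilon = grid$epsilon[g], sigma = grid$sigma[g])
      mean((predict(m, Xm[!tr, , drop = FALSE]) - y[!tr])^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- grid[which.min(grid$mse), ]
  model <- fitSVR(Xm, y, C = best$C, epsilon = best$epsilon, sigma = best$sigma)
  list(model = model, grid = grid, best = best)
}
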