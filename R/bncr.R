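#' Discretize activities into ordered categories
#'
#' Equal-width bins partition the activity range evenly; equal-frequency
#' bins place the inner edges at midpoints between the relevant order
#' statistics, so each category receives (up to ties) the same number of
#' compounds.
#'
#' @param y activity vector.
#' @param nCategories number of categories (>= 2).
#' @param strategy "frequency" or "width".
#' @param minPerCategory smallest admissible category size (downstream OLS
#'   needs terms + 2 members); violation is an error suggesting fewer
#'   categories. Set to 0 to disable.
#' @return list: `labels` (integer categories 1..n), `edges` (strictly
#'   increasing inner edges, length n - 1).
#' @examples
#' discretizeActivity(1:10, 2, "width")$labels
#' @export
discretizeActivity <- function(y, nCategories, strategy = c("frequency", "width"),
                               minPerCategory = 2L) {
  strategy <- match.arg(strategy)
  if (nCategories < 2L) stop("need at least 2 categories", call. = FALSE)
  if (length(unique(y)) < nCategories) {
    stop("fewer distinct activity values than categories", call. = FALSE)
  }
  if (strategy == "width") {
    edges <- min(y) + diff(range(y)) * seq_len(nCategories - 1L) / nCategories
  } else {
    ys <- sort(y)
    cut <- round(length(y) * seq_len(nCategories - 1L) / nCategories)
    edges <- (ys[cut] + ys[cut + 1L]) / 2
  }
  if (any(diff(edges) <= 0) || anyDuplicated(edges)) {
    stop("could not place strictly increasing bin edges (too many ties); use fewer categories",
         call. = FALSE)
  }
  labels <- findInterval(y, edges) + 1L
  counts <- tabulate(labels, nCategories)
  if (minPerCategory > 0L && any(counts < minPerCategory)) {
    stop(sprintf("category size(s) %s below %d; use fewer categories",
                 paste(counts, collapse = "/"), minPerCategory), call. = FALSE)
  }
  list(labels = labels, edges = edges)
}

#' Per-category ordinary least squares
#'
#' Fits, for every activity category i, the regression y_i = X_i beta_i
#' by OLS (beta_i = (X_i' X_i)^-1 X_i' y_i, intercept included). A single
#' category reduces to [fitMLR()] on the full data.
#'
#' Columns that are constant within a category (e.g. a category marker)
#' carry no within-category information and are dropped from that
#' category's design; each coefficient vector records its own column set.
#' Genuine collinearity among the remaining columns is an error naming the
#' category.
#'
#' @param X a [DescriptorTable-class] or matrix.
#' @param y activity vector.
#' @param labels integer category labels (1..n).
#' @return list of per-category coefficient vectors (intercept first).
#' @export
fitCategoryRegressions <- function(X, y, labels) {
  Xm <- as.matrix(X)
  lapply(seq_len(max(labels)), function(i) {
    sel <- labels == i
    Xi <- Xm[sel, , drop = FALSE]
    keep <- apply(Xi, 2, function(col) stats::sd(col) > 0)
    tryCatch(coef(fitMLR(Xi[, keep, drop = FALSE], y[sel])),
             error = function(e) {
               stop(sprintf("category %d: %s", i, conditionMessage(e)),
                    call. = FALSE)
             })
  })
}

# ---- discrete Bayesian network: BDeu hill-climbing --------------------------

# log BDeu family score of `node` given `parents` on a data.frame of factors
.bdeuFamily <- function(data, node, parents, ess) {
  r <- nlevels(data[[node]])
  if (length(parents)) {
    conf <- interaction(data[parents], drop = FALSE)
    q <- prod(vapply(data[parents], nlevels, integer(1)))
    counts <- table(conf, data[[node]])
  } else {
    q <- 1L
    counts <- matrix(table(data[[node]]), nrow = 1)
  }
  aj <- ess / q; ajk <- ess / (q * r)
  nj <- rowSums(counts)
  sum(lgamma(aj) - lgamma(aj + nj)) +
    sum(lgamma(ajk + counts) - lgamma(ajk))
}

.bdeuScore <- function(data, adj, ess, cache = NULL) {
  nodes <- colnames(adj)
  sum(vapply(seq_along(nodes), function(i) {
    .bdeuFamily(data, nodes[i], nodes[adj[, i] == 1], ess)
  }, numeric(1)))
}

#' Learn a discrete Bayesian-network structure by hill climbing
#'
#' Greedy search over single-edge additions, deletions and reversals
#' maximizing the BDeu (Bayesian-Dirichlet equivalent uniform) score, with
#' seeded random restarts; conditional probability tables are
#' Dirichlet-smoothed empirical counts. Deterministic given the seed.
#' Columns with a single observed level are excluded with a warning.
#'
#' @param data data.frame of discrete (factor) columns, including the
#'   category column.
#' @param maxParents in-degree cap.
#' @param ess equivalent sample size of the BDeu prior.
#' @param restarts number of random restarts (the empty graph is always
#'   one of the starts).
#' @param seed RNG seed.
#' @return list: `dag` (adjacency matrix, parent -> child), `cpts` (named
#'   list of conditional probability arrays; last dimension = node states),
#'   `score` (BDeu of the returned DAG), `nodes`.
#' @export
learnBNStructure <- function(data, maxParents = 3L, ess = 1, restarts = 5L,
                             seed = 1L) {
  data <- as.data.frame(lapply(data, function(col) {
    if (!is.factor(col)) factor(col) else droplevels(col)
  }))
  single <- vapply(data, nlevels, integer(1)) < 2L
  if (any(single)) {
    warning(sprintf("excluding single-level column(s): %s",
                    paste(names(data)[single], collapse = ", ")))
    data <- data[!single]
  }
  nodes <- names(data)
  n <- length(nodes)
  if (n < 1L) stop("no usable discrete columns", call. = FALSE)

  climb <- function(adj) {
    repeat {
      cur <- .bdeuScore(data, adj, ess)
      bestGain <- 0; bestAdj <- NULL
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        if (adj[i, j] == 0) {                       # try add i -> j
          if (sum(adj[, j]) >= maxParents) next
          cand <- adj; cand[i, j] <- 1
          if (!.dagIsAcyclic(cand)) next
        } else {                                    # try delete, then reverse
          cand <- adj; cand[i, j] <- 0
          gain <- .bdeuScore(data, cand, ess) - cur
          if (gain > bestGain + 1e-9) { bestGain <- gain; bestAdj <- cand }
          cand[j, i] <- 1                           # reversal
          if (sum(cand[, i]) > maxParents || !.dagIsAcyclic(cand)) next
        }
        gain <- .bdeuScore(data, cand, ess) - cur
        if (gain > bestGain + 1e-9) { bestGain <- gain; bestAdj <- cand }
      }
      if (is.null(bestAdj)) return(list(adj = adj, score = cur))
      adj <- bestAdj
    }
  }

  empty <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  best <- climb(empty)
  if (restarts > 1L && n > 1L) {
    withSeed(seed, {
      for (r in seq_len(restarts - 1L)) {
        adj <- empty
        nEdges <- sample.int(max(1L, n), 1L)
        for (k in seq_len(nEdges)) {
          ij <- sample.int(n, 2L)
          cand <- adj; cand[ij[1], ij[2]] <- 1L
          if (sum(cand[, ij[2]]) <= maxParents && .dagIsAcyclic(cand)) adj <- cand
        }
        res <- climb(adj)
        if (res$score > best$score + 1e-9) best <- res
      }
    })
  }

  cpts <- lapply(seq_len(n), function(j) {
    parents <- nodes[best$adj[, j] == 1]
    r <- nlevels(data[[j]])
    if (length(parents)) {
      q <- prod(vapply(data[parents], nlevels, integer(1)))
      counts <- table(interaction(data[parents], drop = FALSE), data[[j]])
      probs <- (counts + ess / (q * r))
      probs <- probs / rowSums(probs)
      arr <- array(as.numeric(probs), dim = dim(probs),
                   dimnames = list(rownames(counts), levels(data[[j]])))
    } else {
      counts <- table(data[[j]])
      probs <- (counts + ess / r) / (sum(counts) + ess)
      arr <- array(as.numeric(probs), dim = r, dimnames = list(levels(data[[j]])))
      dim(arr) <- c(1L, r)
      dimnames(arr) <- list("", levels(data[[j]]))
    }
    attr(arr, "parents") <- parents
    attr(arr, "levels") <- levels(data[[j]])
    arr
  })
  names(cpts) <- nodes
  list(dag = best$adj, cpts = cpts, score = best$score, nodes = nodes,
       levels = lapply(data, levels))
}

# joint probability of one complete assignment (named list of level strings)
.bnJoint <- function(bn, assign) {
  p <- 1
  for (node in bn$nodes) {
    ct <- bn$cpts[[node]]
    parents <- attr(ct, "parents")
    row <- if (length(parents)) {
      paste(vapply(parents, function(pa) assign[[pa]], ""), collapse = ".")
    } else ""
    pr <- ct[match(row, rownames(ct)), match(assign[[node]], attr(ct, "levels"))]
    if (is.na(pr)) return(0)
    p <- p * pr
  }
  p
}

# exact inference by enumeration: P(query = each level | evidence)
.bnPosterior <- function(bn, query, evidence) {
  free <- setdiff(bn$nodes, c(query, names(evidence)))
  qlev <- bn$levels[[query]]
  joint <- vapply(qlev, function(qv) {
    assigns <- c(evidence, stats::setNames(list(qv), query))
    if (!length(free)) return(.bnJoint(bn, assigns))
    grids <- expand.grid(bn$levels[free], stringsAsFactors = FALSE)
    sum(vapply(seq_len(nrow(grids)), function(r) {
      .bnJoint(bn, c(assigns, as.list(grids[r, , drop = FALSE])))
    }, numeric(1)))
  }, numeric(1))
  if (sum(joint) == 0) return(stats::setNames(rep(1 / length(qlev), length(qlev)), qlev))
  joint / sum(joint)
}

# ---- the combined category-regression model --------------------------------

.binLabel <- function(values, edges) findInterval(values, edges) + 1L

#' Fit the Bayesian-network category regression (BNCR)
#'
#' The category-structured regressor: activity is discretized into ordered
#' categories, each category gets its own OLS model, descriptors are
#' quantile-binned, and a discrete Bayesian network over binned descriptors
#' plus the category node is learned by BDeu hill climbing. Prediction
#' picks the argmax-posterior category given the (binned) descriptor
#' evidence and evaluates that category's regression.
#'
#' With `nCategories = 1` no discretization or network is used and the
#' model reduces exactly to [fitMLR()].
#'
#' @param X a [DescriptorTable-class] or matrix.
#' @param y activity vector.
#' @param nCategories number of activity categories (default 5).
#' @param strategy activity binning strategy (see [discretizeActivity()]).
#' @param descriptorBins quantile bins per descriptor for the network.
#' @param maxParents,ess,restarts,seed forwarded to [learnBNStructure()].
#' @return a [BNCRModel-class].
#' @export
fitBNCR <- function(X, y, nCategories = 5L, strategy = "frequency",
                    descriptorBins = 3L, maxParents = 3L, ess = 1,
                    restarts = 5L, seed = 1L) {
  Xm <- as.matrix(X)
  cols <- colnames(Xm)
  if (nCategories == 1L) {
    cf <- coef(fitMLR(Xm, y))
    return(new("BNCRModel", binEdges = numeric(), betas = list(cf),
               columns = cols, descEdges = list(), dag = matrix(0, 0, 0),
               cpts = list(), catNode = "pIC50_category"))
  }
  disc <- discretizeActivity(y, nCategories, strategy,
                             minPerCategory = ncol(Xm) + 2L)
  betas <- fitCategoryRegressions(Xm, y, disc$labels)
  descEdges <- lapply(cols, function(cn) {
    qs <- unique(stats::quantile(Xm[, cn],
                                 probs = seq_len(descriptorBins - 1L) / descriptorBins,
                                 names = FALSE))
    qs[!duplicated(qs)]
  })
  names(descEdges) <- cols
  dd <- as.data.frame(lapply(cols, function(cn) {
    factor(.binLabel(Xm[, cn], descEdges[[cn]]),
           levels = seq_len(length(descEdges[[cn]]) + 1L))
  }))
  names(dd) <- cols
  dd$pIC50_category <- factor(disc$labels, levels = seq_len(nCategories))
  bn <- suppressWarnings(
    learnBNStructure(dd, maxParents = maxParents, ess = ess,
                     restarts = restarts, seed = seed))
  new("BNCRModel", binEdges = disc$edges, betas = betas, columns = cols,
      descEdges = descEdges, dag = bn$dag,
      cpts = lapply(bn$cpts, identity), catNode = "pIC50_category")
}

# rebuild the learnBNStructure-shaped list from the model slots
.bnFromModel <- function(model) {
  nodes <- colnames(model@dag)
  list(dag = model@dag, cpts = model@cpts, nodes = nodes,
       levels = lapply(model@cpts, attr, "levels"))
}

#' Posterior category probabilities for a descriptor vector
#'
#' Exact inference by enumeration over the learned network. Evidence
#' values outside the descriptor bins are clamped to the nearest bin (a
#' message notes this).
#'
#' @param model a fitted [BNCRModel-class].
#' @param v named descriptor vector (or one-row table).
#' @return named probability vector over categories, summing to 1.
#' @export
posteriorCategory <- function(model, v) {
  if (!length(model@binEdges)) return(c(`1` = 1))
  x <- resolveDescriptors(v, model@columns)[1, ]
  bn <- .bnFromModel(model)
  evidence <- list()
  for (cn in model@columns) {
    if (!cn %in% bn$nodes) next
    lab <- .binLabel(x[[cn]], model@descEdges[[cn]])
    lvls <- bn$levels[[cn]]
    if (!as.character(lab) %in% lvls) {
      lab <- as.integer(lvls[which.min(abs(as.integer(lvls) - lab))])
      qfLog("evidence for %s outside observed bins; clamped to bin %d", cn, lab)
    }
    evidence[[cn]] <- as.character(lab)
  }
  .bnPosterior(bn, model@catNode, evidence)
}

#' Predict activity with a BNCR model
#'
#' k = argmax_i P(i | descriptors); posterior ties resolve to the lower
#' category index (a message notes the tie); the prediction is the chosen
#' category's OLS model evaluated on the continuous descriptor values.
#'
#' @param object a [BNCRModel-class].
#' @param newdata descriptor table/matrix/vector.
#' @param ... ignored.
#' @return numeric vector of predicted pIC50 values.
#' @export
setMethod("predict", "BNCRModel", function(object, newdata, ...) {
  nd <- resolveDescriptors(newdata, object@columns)
  vapply(seq_len(nrow(nd)), function(r) {
    post <- posteriorCategory(object, nd[r, , drop = FALSE])
    top <- which(post >= max(post) - 1e-12)
    if (length(top) > 1L) qfLog("posterior tie between categories %s; using %d",
                                paste(top, collapse = ","), min(top))
    k <- min(top)
    cf <- object@betas[[k]]
    terms <- names(cf)[-1]
    if (!length(terms)) return(as.numeric(cf[1]))
    as.numeric(cf[1] + nd[r, terms] %*% cf[-1])
  }, numeric(1))
})
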