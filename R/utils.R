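# Internal helpers shared across modules.

# Evaluate expr under a private RNG stream; the caller's .Random.seed is
# untouched. All stochastic operations in the package route through this.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

.dagIsAcyclic <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  queue <- which(indeg == 0)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    ch <- which(adj[v, ] == 1)
    for (c in ch) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  seen == n
}

# igraph view of the heavy-atom (hydrogen-suppressed) or full graph.
.moleculeGraph <- function(mol, suppressH = TRUE, weights = NULL) {
  el <- atomElements(mol)
  keep <- if (suppressH) which(el != "H") else seq_along(el)
  remap <- match(seq_along(el), keep)
  b <- mol@bonds
  if (nrow(b)) {
    ok <- !is.na(remap[b$a1]) & !is.na(remap[b$a2])
    edges <- cbind(remap[b$a1[ok]], remap[b$a2[ok]])
  } else {
    edges <- matrix(integer(), 0, 2)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(keep) - igraph::vcount(g)))
  list(graph = g, atoms = keep,
       orders = if (nrow(b)) b$order[if (suppressH) ok else TRUE] else numeric())
}

# message-level logging with a package prefix; suppressible via suppressMessages
qfLog <- function(fmt, ...) message(sprintf(paste0("[qsarforge] ", fmt), ...))

.assertFile <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path), call. = FALSE)
  invisible(path)
}
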