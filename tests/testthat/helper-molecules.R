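# Molecules built in code, shared across test files.

mkMethane <- function() Molecule("C", name = "methane")

mkEthane <- function() Molecule(c("C", "C"), bonds = cbind(1, 2, 1), name = "ethane")

mkEthanol <- function() {
  Molecule(c("C", "C", "O"), bonds = cbind(c(1, 2), c(2, 3), 1), name = "ethanol")
}

mkWater <- function() {
  Molecule(c("O", "H", "H"), bonds = cbind(c(1, 1), c(2, 3), 1),
           coords = rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.24, 0.9266, 0)),
           name = "water")
}

mkButane <- function() {
  Molecule(rep("C", 4), bonds = cbind(1:3, 2:4, 1), name = "n-butane")
}

mkNeopentane <- function() {
  Molecule(rep("C", 5), bonds = cbind(rep(1, 4), 2:5, 1), name = "neopentane")
}

mkFormate <- function() {
  Molecule(c("C", "O", "O", "H"),
           bonds = cbind(c(1, 1, 1), c(2, 3, 4), c(2, 1, 1)),
           formal = c(0, 0, -1, 0), hcounts = rep(0L, 4), name = "formate")
}

# linear alkane / cycloalkane graphs for brute-force descriptor checks
mkPath <- function(n) {
  Molecule(rep("C", n), bonds = if (n > 1) cbind(seq_len(n - 1), 2:n, 1),
           name = sprintf("path%d", n))
}

mkCycle <- function(n) {
  Molecule(rep("C", n), bonds = cbind(seq_len(n), c(2:n, 1), 1),
           name = sprintf("cycle%d", n))
}

# random chemically plausible tree molecules over C/N/O/S with random formal
# charge, for property tests (connected by construction)
randomMolecule <- function(nAtoms, seed) {
  withr::with_seed(seed, {
    el <- sample(c("C", "C", "C", "N", "O", "S"), nAtoms, replace = TRUE)
    bonds <- if (nAtoms > 1) {
      cbind(a1 = vapply(2:nAtoms, function(i) sample.int(i - 1L, 1), integer(1)),
            a2 = 2:nAtoms, order = 1)
    }
    formal <- numeric(nAtoms)
    if (stats::runif(1) < 0.3) formal[sample.int(nAtoms, 1)] <- sample(c(-1, 1), 1)
    Molecule(el, bonds = bonds, formal = formal, name = sprintf("rand%d", seed))
  })
}

# independent brute-force graph descriptors: hand-built adjacency,
# Floyd-Warshall distances, explicit subgraph enumeration (no igraph)
bruteGraphDescriptors <- function(mol) {
  el <- atomElements(mol)
  heavy <- which(el != "H")
  idx <- match(seq_along(el), heavy)
  n <- length(heavy)
  A <- matrix(0, n, n)
  b <- mol@bonds
  for (k in seq_len(nrow(b))) {
    i <- idx[b$a1[k]]; j <- idx[b$a2[k]]
    if (!is.na(i) && !is.na(j)) A[i, j] <- A[j, i] <- 1
  }
  deg <- rowSums(A)
  tab <- atomParameterTable()
  h <- mol@atoms$hcount[heavy]
  for (k in seq_len(nrow(b))) {
    if (el[b$a1[k]] == "H" && !is.na(idx[b$a2[k]])) h[idx[b$a2[k]]] <- h[idx[b$a2[k]]] + 1
    if (el[b$a2[k]] == "H" && !is.na(idx[b$a1[k]])) h[idx[b$a1[k]]] <- h[idx[b$a1[k]]] + 1
  }
  dv <- tab[el[heavy], "Zv"] - h
  chi <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (A[i, j]) chi <- chi + 1 / sqrt(dv[i] * dv[j])
  }
  sc3 <- 0
  for (c0 in seq_len(n)) {
    nb <- which(A[c0, ] == 1)
    if (length(nb) >= 3) sc3 <- sc3 + ncol(utils::combn(length(nb), 3))
  }
  balaban <- function(w) {
    D <- matrix(Inf, n, n); diag(D) <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (A[i, j]) D[i, j] <- 1 / (w[i] * w[j])
    }
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
      if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
    }
    s <- rowSums(D)
    M <- sum(A) / 2; mu <- M - n + 1
    tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (A[i, j]) tot <- tot + 1 / sqrt(s[i] * s[j])
    }
    M / (mu + 1) * tot
  }
  jx <- balaban(tab[el[heavy], "sanderson"] / tab["C", "sanderson"])
  jy <- balaban(tab[el[heavy], "covalent"] / tab["C", "covalent"])
  c(CHI_V_1 = chi, SC_3_C = sc3, JX = jx, JY = jy)
}
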