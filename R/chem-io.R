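#' Implicit hydrogen counts from standard valences
#'
#' Fills the valence of each atom up to the smallest standard valence
#' consistent with its explicit bond-order sum (aromatic bonds count 1.5),
#' adjusted by the formal charge (e.g. quaternary N+, O-).
#'
#' @param elements element symbols.
#' @param bonds bond data.frame (a1, a2, order).
#' @param formal formal charges.
#' @return integer vector of implicit hydrogen counts.
#' @export
impliedHydrogens <- function(elements, bonds, formal = rep(0, length(elements))) {
  bosum <- rep(0, length(elements))
  if (NROW(bonds)) {
    ord <- ifelse(bonds$order == 4, 1.5, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      bosum[bonds$a1[k]] <- bosum[bonds$a1[k]] + ord[k]
      bosum[bonds$a2[k]] <- bosum[bonds$a2[k]] + ord[k]
    }
  }
  bosum <- ceiling(bosum - 1e-9)
  vapply(seq_along(elements), function(i) {
    vals <- .standard_valences[[elements[i]]]
    if (is.null(vals)) return(0L)  # metals etc: no implicit H
    vals <- vals + formal[i]
    fit <- vals[vals >= bosum[i]]
    as.integer(max(0, if (length(fit)) min(fit) - bosum[i] else 0))
  }, integer(1))
}

# ---- reading ---------------------------------------------------------------

.sdfChargeCode <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                    `6` = -2, `7` = -3)

.sdfToMolecule <- function(sdf, name, dropCoords = FALSE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- ab[, 1:3, drop = FALSE]
  formal <- .sdfChargeCode[as.character(ab[, 4])]
  formal[is.na(formal)] <- 0
  bonds <- if (NROW(bb)) {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.numeric(bb[, 3]))
  } else NULL
  if (dropCoords) coords <- matrix(NA_real_, length(elements), 3)
  Molecule(elements, bonds = bonds, coords = coords, formal = formal, name = name)
}

# Apply "M  CHG" property lines, which supersede atom-block charge codes.
.applyChgLines <- function(mol, lines) {
  chg <- grep("^M  CHG", lines, value = TRUE)
  if (!length(chg)) return(mol)
  mol@atoms$formal[] <- 0
  for (ln in chg) {
    f <- as.numeric(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", ln)), "\\s+")[[1]])
    idx <- f[seq(1, length(f), 2)]; val <- f[seq(2, length(f), 2)]
    mol@atoms$formal[idx] <- val
  }
  mol@atoms$hcount <- impliedHydrogens(atomElements(mol), mol@bonds, mol@atoms$formal)
  mol
}

#' Read molecules from a SMILES or SDF file
#'
#' SMILES files carry one record per line: the SMILES string, optionally
#' followed by whitespace and a name. SDF input is MDL V2000; 3D
#' coordinates and formal charges (atom-block codes and M CHG lines) are
#' preserved verbatim. SMILES-derived molecules have no coordinates until
#' [embedCoordinates()] is called.
#'
#' @param path input file.
#' @param format "smiles" or "sdf".
#' @return list of [Molecule-class] objects in file order.
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines("CCO ethanol", f)
#' mols <- readMolecules(f, "smiles")
#' @export
readMolecules <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  .assertFile(path)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) return(list())
  if (format == "smiles") {
    if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
      stop("SMILES input requires the ChemmineOB package", call. = FALSE)
    }
    recs <- lines[nzchar(trimws(lines))]
    out <- vector("list", length(recs))
    for (i in seq_along(recs)) {
      parts <- strsplit(trimws(recs[i]), "\\s+")[[1]]
      nm <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else sprintf("mol_%d", i)
      sdfset <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(parts[1])),
                         error = function(e) e)
      if (inherits(sdfset, "error") || length(sdfset) == 0L) {
        stop(sprintf("record %d ('%s') could not be parsed as SMILES", i, parts[1]),
             call. = FALSE)
      }
      out[[i]] <- .sdfToMolecule(sdfset[[1]], nm, dropCoords = TRUE)
    }
    return(out)
  }
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                     error = function(e) stop("SDF file could not be parsed: ",
                                              conditionMessage(e), call. = FALSE))
  ok <- ChemmineR::validSDF(sdfset)
  if (any(!ok)) {
    stop(sprintf("unparseable SDF record(s) at index: %s",
                 paste(which(!ok), collapse = ", ")), call. = FALSE)
  }
  # raw record text, for M CHG lines that ChemmineR's atom block omits
  recBounds <- c(0L, grep("^\\$\\$\\$\\$", lines))
  out <- vector("list", length(sdfset))
  for (i in seq_along(sdfset)) {
    sdf <- sdfset[[i]]
    hdr <- ChemmineR::header(sdf)[1]
    nm <- if (nzchar(trimws(hdr))) trimws(hdr) else sprintf("mol_%d", i)
    mol <- .sdfToMolecule(sdf, nm)
    if (i < length(recBounds)) {
      rec <- lines[(recBounds[i] + 1L):recBounds[i + 1L]]
      mol <- .applyChgLines(mol, rec)
    }
    out[[i]] <- mol
  }
  out
}

#' Write molecules to an SDF file
#'
#' V2000 output via ChemmineR; assigned partial charges are carried in an
#' `ATOM_PARTIAL_CHARGES` data field (one value per atom, atom order).
#'
#' @param mols list of [Molecule-class] objects (coordinates required).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeMoleculesSDF <- function(mols, path) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  sdfs <- lapply(mols, function(mol) {
    if (!hasCoordinates(mol)) {
      stop(sprintf("molecule '%s' has no coordinates", mol@name), call. = FALSE)
    }
    a <- mol@atoms
    ab <- cbind(as.matrix(a[, c("x", "y", "z")]), matrix(0, nrow(a), 13))
    # V2000 charge codes: 1..7 = +3..-3 (4 unused)
    codeFor <- c(`3` = 1, `2` = 2, `1` = 3, `0` = 0, `-1` = 5, `-2` = 6, `-3` = 7)
    ab[, 4] <- codeFor[as.character(a$formal)]
    rownames(ab) <- paste(a$element, seq_len(nrow(a)), sep = "_")
    colnames(ab) <- paste0("C", seq_len(ncol(ab)))
    b <- mol@bonds
    bb <- if (nrow(b)) cbind(b$a1, b$a2, b$order, matrix(0, nrow(b), 4)) else
      matrix(0, 0, 7)
    colnames(bb) <- paste0("C", seq_len(7))
    db <- character()
    if (hasCharges(mol)) {
      db <- c(ATOM_PARTIAL_CHARGES = paste(sprintf("%.6f", a$charge), collapse = " "))
    }
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      nrow(a), nrow(b))
    new("SDF", header = c(Molecule_Name = mol@name, Source = "qsarforge",
                          Comment = "", Counts_Line = counts),
        atomblock = ab, bondblock = bb, datablock = db)
  })
  sdfset <- new("SDFset", SDF = sdfs, ID = vapply(mols, function(m) m@name, ""))
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}

# ---- explicit hydrogens ----------------------------------------------------

#' Expand implicit hydrogens into explicit atoms
#'
#' New hydrogen atoms are appended after the existing atoms, bonded by a
#' single bond to their parent, without coordinates or charges.
#'
#' @param mol a [Molecule-class].
#' @return a Molecule with hcount 0 everywhere.
#' @export
addExplicitHydrogens <- function(mol) {
  a <- mol@atoms
  nH <- sum(a$hcount)
  if (nH == 0L) return(mol)
  parents <- rep(seq_len(nrow(a)), a$hcount)
  elements <- c(a$element, rep("H", nH))
  coords <- rbind(as.matrix(a[, c("x", "y", "z")]), matrix(NA_real_, nH, 3))
  formal <- c(a$formal, rep(0, nH))
  charges <- c(a$charge, rep(NA_real_, nH))
  bonds <- rbind(mol@bonds,
                 data.frame(a1 = parents, a2 = nrow(a) + seq_len(nH), order = 1))
  Molecule(elements, bonds = bonds, coords = coords, charges = charges,
           hcounts = rep(0L, length(elements)), formal = formal, name = mol@name)
}

# ---- seeded 3D embedding ---------------------------------------------------

.hybridization <- function(mol) {
  n <- length(mol)
  maxOrder <- rep(1, n); nDouble <- rep(0L, n)
  b <- mol@bonds
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    o <- b$order[k]
    for (i in c(b$a1[k], b$a2[k])) {
      maxOrder[i] <- max(maxOrder[i], o)
      if (o == 2) nDouble[i] <- nDouble[i] + 1L
    }
  }
  ifelse(maxOrder >= 3 | nDouble >= 2, "sp",
         ifelse(maxOrder == 2 | maxOrder == 4, "sp2", "sp3"))
}

# distance targets: bonds (1-2), angles as 1-3 distances, and soft lower
# bounds for topologically distant pairs
.embedTargets <- function(mol) {
  el <- atomElements(mol)
  rcov <- .elementParam(el, "covalent", "covalent-radius")
  rvdw <- .elementParam(el, "vdw", "van der Waals")
  b <- mol@bonds
  shrink <- c(`1` = 1, `2` = 0.87, `3` = 0.78, `4` = 0.92)
  d12 <- (rcov[b$a1] + rcov[b$a2]) * shrink[as.character(b$order)]
  hyb <- .hybridization(mol)
  deg <- tabulate(c(b$a1, b$a2), nbins = length(el))
  # 1-3 targets via ideal angle at the central atom
  nb <- lapply(seq_along(el), function(i) {
    c(b$a2[b$a1 == i], b$a1[b$a2 == i])
  })
  p13 <- list(); d13 <- numeric()
  for (k in seq_along(el)) {
    nbk <- nb[[k]]
    if (length(nbk) < 2) next
    theta <- if (deg[k] >= 4) 109.47 else if (deg[k] == 3) 120 else
      switch(hyb[k], sp = 180, sp2 = 120, 109.47)
    ct <- cos(theta * pi / 180)
    dk <- vapply(nbk, function(j) {
      e <- which((b$a1 == k & b$a2 == j) | (b$a2 == k & b$a1 == j))[1]
      d12[e]
    }, numeric(1))
    cmb <- utils::combn(seq_along(nbk), 2)
    for (cix in seq_len(ncol(cmb))) {
      i <- nbk[cmb[1, cix]]; j <- nbk[cmb[2, cix]]
      di <- dk[cmb[1, cix]]; dj <- dk[cmb[2, cix]]
      p13[[length(p13) + 1L]] <- c(i, j)
      d13 <- c(d13, sqrt(di^2 + dj^2 - 2 * di * dj * ct))
    }
  }
  p13 <- if (length(p13)) do.call(rbind, p13) else matrix(integer(), 0, 2)
  # nonbonded lower bounds: pairs at graph distance >= 3
  g <- .moleculeGraph(mol, suppressH = FALSE)
  gd <- igraph::distances(g$graph)
  far <- which(upper.tri(gd) & gd >= 3, arr.ind = TRUE)
  dmin <- 0.8 * (rvdw[far[, 1]] + rvdw[far[, 2]])
  list(bonds = cbind(b$a1, b$a2), d12 = d12, p13 = p13, d13 = d13,
       far = far, dmin = dmin)
}

.embedEnergy <- function(xv, tg, n) {
  X <- matrix(xv, n, 3)
  E <- 0
  G <- matrix(0, n, 3)
  addPairs <- function(idx, f) {
    if (!NROW(idx)) return(invisible())
    i <- idx[, 1]; j <- idx[, 2]
    d <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    r <- sqrt(rowSums(d * d)) + 1e-12
    fg <- f(r)
    E <<- E + sum(fg$e)
    gi <- d * (fg$g / r)
    for (col in 1:3) {
      gcol <- G[, col]
      acc <- rowsum(c(gi[, col], -gi[, col]), group = c(i, j))
      at <- as.integer(rownames(acc))
      gcol[at] <- gcol[at] + acc[, 1]
      G[, col] <<- gcol
    }
    invisible()
  }
  addPairs(tg$bonds, function(r) list(e = 100 * (r - tg$d12)^2,
                                      g = 200 * (r - tg$d12)))
  addPairs(tg$p13, function(r) list(e = 30 * (r - tg$d13)^2,
                                    g = 60 * (r - tg$d13)))
  addPairs(tg$far, function(r) {
    v <- pmax(tg$dmin - r, 0)
    list(e = 10 * v^2, g = -20 * v)
  })
  list(E = E, G = as.vector(G))
}

#' Seeded distance-geometry-style 3D embedding
#'
#' Implicit hydrogens are made explicit, atoms get random seeded starting
#' positions, and a pseudo-energy of harmonic bond-length terms, 1-3
#' angle-distance terms and soft nonbonded lower bounds is minimized by
#' BFGS. The result is a single relaxed conformer; identical
#' (molecule, seed) pairs give identical coordinates.
#'
#' @param mol a [Molecule-class] with a valid connectivity graph.
#' @param seed integer seed controlling the starting positions.
#' @param maxAttempts random restarts before giving up.
#' @return the Molecule with coordinates on every (now explicit) atom.
#' @examples
#' m <- embedCoordinates(Molecule("C", name = "methane"), seed = 7)
#' @export
embedCoordinates <- function(mol, seed, maxAttempts = 5L) {
  mol <- addExplicitHydrogens(mol)
  n <- length(mol)
  if (n == 1L) {
    mol@atoms[, c("x", "y", "z")] <- 0
    return(mol)
  }
  g <- .moleculeGraph(mol, suppressH = FALSE)
  comp <- igraph::components(g$graph)
  if (comp$no > 1L) {
    stop(sprintf("molecule '%s' has %d disconnected fragments; embedding requires a connected graph",
                 mol@name, comp$no), call. = FALSE)
  }
  tg <- .embedTargets(mol)
  scale <- max(2, n^(1 / 3) * 1.5)
  for (attempt in seq_len(maxAttempts)) {
    x0 <- withSeed(seed + (attempt - 1L) * 1000003,
                   stats::rnorm(3 * n, sd = scale))
    fit <- stats::optim(x0, fn = function(v) .embedEnergy(v, tg, n)$E,
                        gr = function(v) .embedEnergy(v, tg, n)$G,
                        method = "BFGS",
                        control = list(maxit = 800, reltol = 1e-12))
    X <- matrix(fit$par, n, 3)
    d <- sqrt(rowSums((X[tg$bonds[, 1], , drop = FALSE] -
                         X[tg$bonds[, 2], , drop = FALSE])^2))
    if (all(abs(d - tg$d12) < 0.2 * tg$d12)) {
      X <- sweep(X, 2, colMeans(X))
      mol@atoms[, c("x", "y", "z")] <- round(X, 6)
      return(mol)
    }
  }
  stop(sprintf("embedding failed for '%s' after %d attempts", mol@name,
               maxAttempts), call. = FALSE)
}

# ---- Gasteiger-Marsili partial charges -------------------------------------

#' Gasteiger-Marsili partial charges
#'
#' Iterative partial equalization of orbital electronegativity: atom
#' electronegativity is the polynomial chi(q) = a + b q + c q^2 with
#' hybridisation-specific parameters; each iteration transfers charge along
#' every bond proportional to the electronegativity difference, scaled by
#' the cation electronegativity of the donor atom and a geometric damping
#' factor. Total charge is conserved exactly, so the sum of partial charges
#' equals the net formal charge. Implicit hydrogens are made explicit first.
#'
#' @param mol a [Molecule-class] with known connectivity.
#' @param iterations number of damped iterations.
#' @param damping per-iteration damping base (transfer is damping^k).
#' @return the Molecule with the `charge` atom column filled.
#' @examples
#' m <- assignPartialCharges(Molecule("C", name = "methane"))
#' sum(partialCharges(m))
#' @export
assignPartialCharges <- function(mol, iterations = 6L, damping = 0.5) {
  mol <- addExplicitHydrogens(mol)
  el <- atomElements(mol)
  hyb <- .hybridization(mol)
  par <- lapply(seq_along(el), function(i) {
    p <- .gasteiger_params[[el[i]]]
    if (is.null(p)) {
      stop(sprintf("no Gasteiger parameters for element '%s'", el[i]), call. = FALSE)
    }
    p[[hyb[i]]] %||% p[["sp2"]] %||% p[["sp3"]]
  })
  a <- vapply(par, `[`, numeric(1), 1)
  bq <- vapply(par, `[`, numeric(1), 2)
  cq <- vapply(par, `[`, numeric(1), 3)
  chiPlus <- ifelse(el == "H", 20.02, a + bq + cq)
  q <- mol@atoms$formal
  b <- mol@bonds
  if (nrow(b)) {
    for (k in seq_len(iterations)) {
      chi <- a + bq * q + cq * q^2
      dk <- damping^k
      delta <- numeric(length(q))
      for (e in seq_len(nrow(b))) {
        i <- b$a1[e]; j <- b$a2[e]
        # electrons flow toward the more electronegative atom: the donor
        # (lower chi) goes positive, scaled by its cation electronegativity
        if (chi[j] > chi[i]) {
          tr <- (chi[j] - chi[i]) / chiPlus[i] * dk
        } else {
          tr <- -(chi[i] - chi[j]) / chiPlus[j] * dk
        }
        delta[i] <- delta[i] + tr
        delta[j] <- delta[j] - tr
      }
      q <- q + delta
    }
  }
  mol@atoms$charge <- q
  mol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Shrake-Rupley SASA ----------------------------------------------------

# deterministic, nearly uniform sphere points (golden-spiral construction)
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA with a rolling probe: each atom's solvent-accessible
#' sphere (van der Waals radius + probe) is sampled with a deterministic
#' quasi-uniform point set, and points buried inside any neighbouring
#' atom's accessible sphere are discarded.
#'
#' @param mol a [Molecule-class] with coordinates (explicit hydrogens
#'   included if present).
#' @param probeRadius probe radius in Angstrom (water: 1.4).
#' @param nSpherePoints sample points per atom.
#' @return numeric vector of per-atom areas (Angstrom^2); total SASA is the
#'   sum, also attached as attribute "total".
#' @examples
#' m <- embedCoordinates(Molecule("C", name = "methane"), seed = 1)
#' sum(computeSASA(m))
#' @export
computeSASA <- function(mol, probeRadius = 1.4, nSpherePoints = 960L) {
  if (!hasCoordinates(mol)) {
    stop(sprintf("molecule '%s' has no coordinates; embed first", mol@name),
         call. = FALSE)
  }
  X <- atomCoords(mol)
  R <- .elementParam(atomElements(mol), "vdw", "van der Waals") + probeRadius
  n <- nrow(X)
  pts <- .spherePoints(nSpherePoints)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(X, 2, X[i, ])^2)
    nbr <- which(d2 < (R + R[i])^2 & seq_len(n) != i)
    p <- sweep(pts * R[i], 2, X[i, ], `+`)
    keep <- rep(TRUE, nSpherePoints)
    for (j in nbr) {
      dj <- sweep(p, 2, X[j, ])
      keep <- keep & rowSums(dj * dj) > R[j]^2
      if (!any(keep)) break
    }
    areas[i] <- 4 * pi * R[i]^2 * mean(keep)
  }
  attr(areas, "total") <- sum(areas)
  areas
}

#' Prepare a molecule for descriptor and field computation
#'
#' Convenience chain: explicit hydrogens, seeded embedding (skipped when
#' coordinates are already present), Gasteiger charges.
#'
#' @param mol a [Molecule-class].
#' @param seed embedding seed.
#' @return a fully prepared Molecule.
#' @export
prepareMolecule <- function(mol, seed = 1L) {
  mol <- addExplicitHydrogens(mol)
  if (!hasCoordinates(mol)) mol <- embedCoordinates(mol, seed = seed)
  if (!hasCharges(mol)) mol <- assignPartialCharges(mol)
  mol
}
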