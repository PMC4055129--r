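# CoMFA/CoMSIA field generation over a rectangular lattice.
# Molecules must arrive pre-aligned; alignment is the caller's concern.

#' Build a lattice covering aligned molecules
#'
#' Axis-aligned rectangular grid over the union bounding box of the atom
#' coordinates, extended by a margin on every side. Point counts are the
#' smallest that cover box + margin at the given spacing.
#'
#' @param mols list of aligned [Molecule-class] objects with coordinates.
#' @param spacing lattice spacing in Angstrom (CoMFA convention: 2.0).
#' @param margin extension beyond the bounding box (Angstrom).
#' @return a [GridSpec-class].
#' @export
buildGrid <- function(mols, spacing = 2.0, margin = 4.0) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  if (!length(mols)) stop("no molecules supplied", call. = FALSE)
  coords <- do.call(rbind, lapply(mols, function(m) {
    if (!hasCoordinates(m)) stop(sprintf("molecule '%s' has no coordinates", m@name),
                                 call. = FALSE)
    atomCoords(m)
  }))
  lo <- apply(coords, 2, min) - margin
  hi <- apply(coords, 2, max) + margin
  counts <- pmax(2L, as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L)
  new("GridSpec", origin = lo, spacing = spacing, counts = counts)
}

#' @describeIn buildGrid coordinates of every lattice point (x fastest).
#' @param grid a [GridSpec-class].
#' @export
gridPoints <- function(grid) {
  ax <- lapply(1:3, function(k) {
    grid@origin[k] + grid@spacing * (seq_len(grid@counts[k]) - 1L)
  })
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  pts
}

# Coulomb constant, kcal*Angstrom/(mol*e^2)
.kCoulomb <- 332.0637

#' CoMFA steric and electrostatic fields
#'
#' Probe-atom interaction energies at every lattice point:
#' steric via the Lennard-Jones 6-12 form eps*[(rmin/r)^12 - 2 (rmin/r)^6]
#' (rmin = atom vdW radius + probe radius, eps by geometric mean, minimum
#' exactly -eps at r = rmin), electrostatic via Coulomb with a
#' distance-dependent dielectric D(r) = r,
#' E = 332.0637 q_probe q_atom / r^2. Both fields are truncated at
#' +/- cutoff; a lattice point coinciding with an atom is set to +cutoff
#' (steric) and the truncation is logged. The default probe is an
#' sp3-carbon-like atom (radius 1.9 A, well depth 0.1 kcal/mol, charge +1).
#'
#' @param mols list of aligned, prepared [Molecule-class] objects.
#' @param grid a [GridSpec-class] shared by all molecules.
#' @param probeRadius,probeEps,probeCharge probe parameters.
#' @param cutoff truncation bound in kcal/mol.
#' @return list of two [FieldBlock-class] objects, named "S" and "E".
#' @export
comfaFields <- function(mols, grid, probeRadius = 1.9, probeEps = 0.1,
                        probeCharge = 1, cutoff = 30) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  pts <- gridPoints(grid)
  nPts <- nrow(pts)
  S <- matrix(0, length(mols), nPts)
  E <- matrix(0, length(mols), nPts)
  nClash <- 0L
  for (m in seq_along(mols)) {
    mol <- mols[[m]]
    if (!hasCharges(mol)) {
      stop(sprintf("molecule '%s' needs partial charges for the electrostatic field",
                   mol@name), call. = FALSE)
    }
    X <- atomCoords(mol)
    el <- atomElements(mol)
    rmin <- .elementParam(el, "vdw", "Lennard-Jones") + probeRadius
    epsPair <- sqrt(.elementParam(el, "lj_eps", "Lennard-Jones") * probeEps)
    q <- partialCharges(mol)
    for (a in seq_len(nrow(X))) {
      d2 <- (pts[, 1] - X[a, 1])^2 + (pts[, 2] - X[a, 2])^2 + (pts[, 3] - X[a, 3])^2
      r <- sqrt(d2)
      clash <- r < 1e-6
      nClash <- nClash + sum(clash)
      r[clash] <- 1e-6
      sr6 <- (rmin[a] / r)^6
      S[m, ] <- S[m, ] + epsPair[a] * (sr6^2 - 2 * sr6)
      E[m, ] <- E[m, ] + .kCoulomb * probeCharge * q[a] / (r * r)
    }
  }
  if (nClash > 0L) qfLog("%d grid point/atom coincidences truncated to +cutoff", nClash)
  clip <- function(v) pmin(pmax(v, -cutoff), cutoff)
  list(S = new("FieldBlock", type = "S", values = clip(S), grid = grid,
               keptColumns = seq_len(nPts)),
       E = new("FieldBlock", type = "E", values = clip(E), grid = grid,
               keptColumns = seq_len(nPts)))
}

# rule-based donor/acceptor flags and per-atom CoMSIA property values
.comsiaProperty <- function(mol, type) {
  el <- atomElements(mol)
  switch(type,
    S = .elementParam(el, "vdw", "CoMSIA steric")^3,
    E = {
      if (!hasCharges(mol)) stop(sprintf("molecule '%s' needs charges", mol@name),
                                 call. = FALSE)
      partialCharges(mol)
    },
    H = .elementParam(el, "hydrophobicity", "CoMSIA hydrophobic"),
    D = as.numeric(el %in% c("N", "O", "S") & .attachedHydrogens(mol) >= 1),
    A = as.numeric(el %in% c("N", "O")),
    stop(sprintf("unknown CoMSIA field type '%s'", type), call. = FALSE))
}

#' CoMSIA similarity-index fields
#'
#' Gaussian-attenuated similarity index at lattice point j:
#' A_j = -sum_atoms w_probe w_atom exp(-alpha r^2), with probe weight +1
#' and attenuation alpha (default 0.3 A^-2). Atom properties by type:
#' S = vdW volume proxy (r^3), E = partial charge, H = atomic
#' hydrophobicity increment, D/A = 1 for rule-flagged hydrogen-bond
#' donor/acceptor atoms (donor: N/O/S bearing H; acceptor: N/O), else 0.
#'
#' @param mols list of aligned, prepared [Molecule-class] objects.
#' @param grid a [GridSpec-class].
#' @param types subset of c("S", "E", "H", "D", "A").
#' @param alpha Gaussian attenuation factor (A^-2).
#' @return named list of [FieldBlock-class] objects, one per type.
#' @export
comsiaFields <- function(mols, grid, types = c("S", "E", "H", "D", "A"),
                         alpha = 0.3) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  bad <- setdiff(types, c("S", "E", "H", "D", "A"))
  if (length(bad)) stop(sprintf("unknown field type(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  pts <- gridPoints(grid)
  out <- lapply(types, function(tp) {
    V <- matrix(0, length(mols), nrow(pts))
    for (m in seq_along(mols)) {
      w <- .comsiaProperty(mols[[m]], tp)
      X <- atomCoords(mols[[m]])
      for (a in seq_len(nrow(X))) {
        if (w[a] == 0) next
        d2 <- (pts[, 1] - X[a, 1])^2 + (pts[, 2] - X[a, 2])^2 +
          (pts[, 3] - X[a, 3])^2
        V[m, ] <- V[m, ] - w[a] * exp(-alpha * d2)
      }
    }
    new("FieldBlock", type = tp, values = V, grid = grid,
        keptColumns = seq_len(nrow(pts)))
  })
  names(out) <- types
  out
}

#' Drop low-variance lattice columns
#'
#' Standard CoMFA column filtering: lattice columns whose standard
#' deviation across molecules is below the threshold carry no contrast and
#' are removed; the kept-index map supports contour back-projection.
#'
#' @param blocks list of [FieldBlock-class] sharing one grid.
#' @param sigmaMin minimum column standard deviation (default 2.0 for
#'   energy fields; use smaller values for CoMSIA indices).
#' @return list of reduced [FieldBlock-class] objects (keptColumns updated).
#' @export
filterColumns <- function(blocks, sigmaMin = 2.0) {
  if (inherits(blocks, "FieldBlock")) blocks <- list(blocks)
  out <- lapply(blocks, function(b) {
    sds <- apply(b@values, 2, stats::sd)
    keep <- which(sds >= sigmaMin)
    if (!length(keep)) {
      stop(sprintf("all columns of field '%s' dropped at sigma_min = %g; lower the threshold",
                   b@type, sigmaMin), call. = FALSE)
    }
    new("FieldBlock", type = b@type, values = b@values[, keep, drop = FALSE],
        grid = b@grid, keptColumns = b@keptColumns[keep])
  })
  names(out) <- vapply(out, function(b) b@type, "")
  out
}
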