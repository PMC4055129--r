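#' The registered descriptor set
#'
#' The eleven named molecular descriptors computed by this package:
#' seven topological (connectivity-derived, hydrogen-suppressed graph),
#' three charged-partial-surface-area (Jurs CPSA family) and one shadow
#' descriptor. "BD_Count" is a registered alias of "HBD_Count" (hydrogen
#' bond donor count).
#'
#' @return character vector of descriptor names.
#' @export
descriptorSet <- function() {
  c("HBD_Count", "Num_RotatableBonds", "CHI_V_1", "IAC_Mean", "JX", "JY",
    "SC_3_C", "Jurs_FNSA_1", "Jurs_RPCS", "Jurs_SASA", "Shadow_Xlength")
}

.descriptorAliases <- c(BD_Count = "HBD_Count")

# total hydrogens on each atom: implicit count plus explicit H neighbours
.attachedHydrogens <- function(mol) {
  el <- atomElements(mol)
  h <- as.numeric(mol@atoms$hcount)
  b <- mol@bonds
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    if (el[b$a1[k]] == "H") h[b$a2[k]] <- h[b$a2[k]] + 1
    if (el[b$a2[k]] == "H") h[b$a1[k]] <- h[b$a1[k]] + 1
  }
  h
}

# Balaban-type distance-connectivity index on the hydrogen-suppressed graph
# with multiplicative vertex weights applied to edge lengths of the
# distance matrix (weights relative to carbon).
.balabanWeighted <- function(mol, vertexWeight) {
  el <- atomElements(mol)
  heavy <- which(el != "H")
  if (length(heavy) < 2L) return(0)
  g <- .moleculeGraph(mol, suppressH = TRUE)
  w <- vertexWeight(el[heavy])
  ends <- igraph::as_edgelist(g$graph)
  ew <- 1 / (w[ends[, 1]] * w[ends[, 2]])
  D <- igraph::distances(g$graph, weights = ew)
  if (any(!is.finite(D))) {
    stop("Balaban index requires a connected heavy-atom graph", call. = FALSE)
  }
  s <- rowSums(D)
  M <- nrow(ends)
  mu <- M - length(heavy) + 1
  M / (mu + 1) * sum(1 / sqrt(s[ends[, 1]] * s[ends[, 2]]))
}

#' Topological descriptors
#'
#' Connectivity-only descriptors; coordinates are not required. Computed on
#' the hydrogen-suppressed graph except IAC_Mean, which is the Shannon
#' entropy (bits) of the element-type distribution over all atoms including
#' hydrogens.
#'
#' \describe{
#'   \item{HBD_Count}{N/O/S atoms bearing at least one hydrogen.}
#'   \item{Num_RotatableBonds}{non-ring single bonds between two
#'     non-terminal heavy atoms, amide C-N excluded.}
#'   \item{CHI_V_1}{Kier-Hall first-order valence connectivity: the sum
#'     over heavy-atom bonds of (delta_v_i * delta_v_j)^(-1/2), with
#'     delta_v = (Zv - h) / (Z - Zv - 1).}
#'   \item{JX, JY}{Balaban-type distance-connectivity index J on a weighted
#'     distance matrix; JX weights edges by inverse Sanderson
#'     electronegativity products, JY by inverse covalent-radius products,
#'     both relative to carbon.}
#'   \item{SC_3_C}{third-order cluster subgraph count: K_{1,3} stars, i.e.
#'     sum over heavy atoms of choose(degree, 3).}
#' }
#'
#' @param mol a [Molecule-class] with known connectivity.
#' @return named numeric vector of the seven topological descriptors.
#' @examples
#' ethane <- Molecule(c("C", "C"), bonds = cbind(1, 2, 1))
#' topologicalDescriptors(ethane)["CHI_V_1"]  # 1.0
#' @export
topologicalDescriptors <- function(mol) {
  el <- atomElements(mol)
  tab <- atomParameterTable()
  h <- .attachedHydrogens(mol)
  heavy <- which(el != "H")

  hbd <- sum(el %in% c("N", "O", "S") & h >= 1)

  # heavy-atom graph bookkeeping
  g <- .moleculeGraph(mol, suppressH = TRUE)
  deg <- igraph::degree(g$graph)
  bridgeEdges <- igraph::bridges(g$graph)
  ends <- igraph::as_edgelist(g$graph)
  inRing <- rep(TRUE, nrow(ends))
  inRing[as.integer(bridgeEdges)] <- FALSE

  # rotatable: acyclic single bonds between non-terminal heavy atoms,
  # excluding amide C-N
  isAmide <- function(i, j) {
    hi <- g$atoms[i]; hj <- g$atoms[j]
    ci <- if (el[hi] == "C" && el[hj] == "N") hi else
      if (el[hj] == "C" && el[hi] == "N") hj else return(FALSE)
    b <- mol@bonds
    any(b$order == 2 &
          ((b$a1 == ci & el[b$a2] == "O") | (b$a2 == ci & el[b$a1] == "O")))
  }
  nrot <- 0L
  if (nrow(ends)) for (e in seq_len(nrow(ends))) {
    i <- ends[e, 1]; j <- ends[e, 2]
    if (g$orders[e] == 1 && !inRing[e] && deg[i] >= 2 && deg[j] >= 2 &&
        !isAmide(i, j)) {
      nrot <- nrot + 1L
    }
  }

  # Kier-Hall valence delta; reduces to Zv - h for second-row elements
  dv <- (tab[el, "Zv"] - h) / pmax(tab[el, "Z"] - tab[el, "Zv"] - 1, 1)
  chi <- 0
  if (nrow(ends)) {
    dvi <- dv[g$atoms[ends[, 1]]]; dvj <- dv[g$atoms[ends[, 2]]]
    if (any(dvi <= 0 | dvj <= 0)) {
      stop("non-positive valence delta; element parameters unsupported", call. = FALSE)
    }
    chi <- sum(1 / sqrt(dvi * dvj))
  }

  counts <- c(table(el), H = sum(mol@atoms$hcount))
  counts <- tapply(as.numeric(counts), names(counts), sum)
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  iac <- -sum(p * log2(p))

  enC <- tab["C", "sanderson"]; rC <- tab["C", "covalent"]
  jx <- .balabanWeighted(mol, function(e) .elementParam(e, "sanderson", "JX electronegativity") / enC)
  jy <- .balabanWeighted(mol, function(e) .elementParam(e, "covalent", "JY covalent-radius") / rC)

  sc3 <- sum(choose(deg, 3))

  c(HBD_Count = hbd, Num_RotatableBonds = nrot, CHI_V_1 = chi,
    IAC_Mean = iac, JX = jx, JY = jy, SC_3_C = sc3)
}

#' Charged-partial-surface-area (Jurs) descriptors
#'
#' \describe{
#'   \item{Jurs_SASA}{total solvent-accessible surface area (Angstrom^2).}
#'   \item{Jurs_FNSA_1}{fraction of SASA on negatively charged atoms.}
#'   \item{Jurs_RPCS}{relative positive charged surface: SASA of the most
#'     positively charged atom times its charge divided by the sum of all
#'     positive charges; 0 when no atom carries positive charge.}
#' }
#'
#' @param mol a prepared [Molecule-class] (coordinates + charges).
#' @param sasa optional precomputed per-atom SASA from [computeSASA()].
#' @param probeRadius,nSpherePoints forwarded to [computeSASA()].
#' @return named numeric vector of the three surface descriptors.
#' @export
surfaceDescriptors <- function(mol, sasa = NULL, probeRadius = 1.4,
                               nSpherePoints = 960L) {
  if (!hasCharges(mol)) {
    stop(sprintf("molecule '%s' has no partial charges", mol@name), call. = FALSE)
  }
  if (is.null(sasa)) {
    sasa <- computeSASA(mol, probeRadius = probeRadius,
                        nSpherePoints = nSpherePoints)
  }
  q <- partialCharges(mol)
  total <- sum(sasa)
  fnsa <- if (total > 0) sum(sasa[q < 0]) / total else 0
  pos <- which(q > 0)
  rpcs <- if (length(pos)) {
    imax <- pos[which.max(q[pos])]
    sasa[imax] * q[imax] / sum(q[pos])
  } else 0
  c(Jurs_FNSA_1 = fnsa, Jurs_RPCS = rpcs, Jurs_SASA = total)
}

#' Shadow descriptors
#'
#' The molecule is rotated onto the principal axes of its atomic-coordinate
#' covariance (largest variance along X); Shadow_Xlength is the extent of
#' the van der Waals envelope along that axis:
#' max(x_i + r_i) - min(x_i - r_i), in Angstrom. Invariant to rigid
#' rotation of the input.
#'
#' @param mol a [Molecule-class] with coordinates.
#' @return named numeric vector (Shadow_Xlength).
#' @export
shadowDescriptors <- function(mol) {
  if (length(mol) < 1L) stop("empty molecule", call. = FALSE)
  if (!hasCoordinates(mol)) {
    stop(sprintf("molecule '%s' has no coordinates", mol@name), call. = FALSE)
  }
  X <- atomCoords(mol)
  r <- .elementParam(atomElements(mol), "vdw", "van der Waals")
  Xc <- sweep(X, 2, colMeans(X))
  if (nrow(X) > 1L) {
    ev <- eigen(stats::cov(Xc), symmetric = TRUE)
    Xc <- Xc %*% ev$vectors
  }
  x <- Xc[, 1]
  c(Shadow_Xlength = max(x + r) - min(x - r))
}

#' Assemble the full descriptor table
#'
#' Computes all eleven registered descriptors for each prepared molecule
#' and binds them into a [DescriptorTable-class]. Deterministic given the
#' input molecules.
#'
#' @param mols list of prepared [Molecule-class] objects.
#' @param probeRadius,nSpherePoints forwarded to [computeSASA()].
#' @return a [DescriptorTable-class] with one row per molecule.
#' @export
computeDescriptorTable <- function(mols, probeRadius = 1.4, nSpherePoints = 960L) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  if (!length(mols)) {
    return(DescriptorTable(matrix(numeric(), 0, length(descriptorSet()),
                                  dimnames = list(NULL, descriptorSet()))))
  }
  rows <- lapply(seq_along(mols), function(i) {
    mol <- mols[[i]]
    tryCatch(
      c(topologicalDescriptors(mol),
        surfaceDescriptors(mol, probeRadius = probeRadius,
                           nSpherePoints = nSpherePoints),
        shadowDescriptors(mol))[descriptorSet()],
      error = function(e) {
        stop(sprintf("descriptor computation failed for molecule %d ('%s'): %s",
                     i, mol@name, conditionMessage(e)), call. = FALSE)
      })
  })
  m <- do.call(rbind, rows)
  rownames(m) <- make.unique(vapply(mols, function(m) m@name, ""), sep = "#")
  DescriptorTable(m)
}
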