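# The eleven registered descriptors.

test_that("topological descriptors match hand computations", {
  expect_equal(topologicalDescriptors(mkEthane())[["CHI_V_1"]], 1.0)
  # methane: one C, four H -> -(0.2 log2 0.2 + 0.8 log2 0.8)
  expect_equal(topologicalDescriptors(mkMethane())[["IAC_Mean"]],
               -(0.2 * log2(0.2) + 0.8 * log2(0.8)), tolerance = 1e-9)
  expect_equal(topologicalDescriptors(mkButane())[["SC_3_C"]], 0)
  expect_equal(topologicalDescriptors(mkNeopentane())[["SC_3_C"]], 4)
  expect_equal(topologicalDescriptors(mkEthanol())[["HBD_Count"]], 1)
  expect_equal(topologicalDescriptors(mkMethane())[["Num_RotatableBonds"]], 0)
  # butane: only the central C-C bond is rotatable
  expect_equal(topologicalDescriptors(mkButane())[["Num_RotatableBonds"]], 1)
})

test_that("amide C-N bonds are not counted as rotatable", {
  # N-methylacetamide: CH3-C(=O)-N(H)-CH3
  nma <- Molecule(c("C", "C", "O", "N", "C"),
                  bonds = cbind(a1 = c(1, 2, 2, 4), a2 = c(2, 3, 4, 5),
                                order = c(1, 2, 1, 1)),
                  name = "NMA")
  expect_equal(topologicalDescriptors(nma)[["Num_RotatableBonds"]], 0)
})

test_that("graph descriptors agree with a brute-force implementation", {
  mols <- c(lapply(2:8, mkPath), lapply(3:8, mkCycle),
            list(mkNeopentane(), mkEthanol()))
  for (mol in mols) {
    got <- topologicalDescriptors(mol)
    ref <- bruteGraphDescriptors(mol)
    expect_equal(got[["CHI_V_1"]], ref[["CHI_V_1"]], tolerance = 1e-9,
                 label = mol@name)
    expect_equal(got[["SC_3_C"]], ref[["SC_3_C"]], label = mol@name)
    expect_equal(got[["JX"]], ref[["JX"]], tolerance = 1e-9, label = mol@name)
    expect_equal(got[["JY"]], ref[["JY"]], tolerance = 1e-9, label = mol@name)
  }
})

test_that("topological descriptors are invariant to atom re-indexing", {
  base <- Molecule(c("C", "N", "C", "O", "C", "S"),
                   bonds = cbind(a1 = c(1, 2, 3, 4, 3), a2 = c(2, 3, 4, 5, 6),
                                 order = c(1, 1, 1, 1, 1)), name = "mixed")
  ref <- topologicalDescriptors(base)
  for (s in 1:20) {
    perm <- withr::with_seed(s, sample(length(base)))
    inv <- order(perm)
    b <- base@bonds
    permuted <- Molecule(atomElements(base)[perm],
                         bonds = cbind(inv[b$a1], inv[b$a2], b$order),
                         name = "permuted")
    expect_equal(topologicalDescriptors(permuted), ref, tolerance = 1e-9)
  }
})

test_that("composition entropy is extremal where expected", {
  expect_equal(topologicalDescriptors(mkPath(5))[["IAC_Mean"]],
               -sum(c(5, 12) / 17 * log2(c(5, 12) / 17)), tolerance = 1e-9)
  onlyC <- Molecule(c("C", "C"), bonds = cbind(1, 2, 3), hcounts = c(1L, 1L))
  # ethyne has equal C and H counts: entropy is maximal (1 bit)
  expect_equal(topologicalDescriptors(onlyC)[["IAC_Mean"]], 1)
  bareC <- Molecule("C", hcounts = 0L)
  expect_equal(topologicalDescriptors(bareC)[["IAC_Mean"]], 0)
})

test_that("surface descriptors follow the CPSA definitions", {
  # synthetic diatomic with prescribed charges and coordinates
  dia <- Molecule(c("C", "O"), coords = rbind(c(0, 0, 0), c(2.0, 0, 0)),
                  charges = c(0.3, -0.3), hcounts = c(0L, 0L))
  sasa <- computeSASA(dia)
  got <- surfaceDescriptors(dia, sasa = sasa)
  expect_equal(got[["Jurs_SASA"]], sum(sasa))
  expect_equal(got[["Jurs_FNSA_1"]], sasa[2] / sum(sasa))
  expect_equal(got[["Jurs_RPCS"]], sasa[1] * 0.3 / 0.3)

  zero <- Molecule(c("C", "C"), coords = rbind(c(0, 0, 0), c(1.5, 0, 0)),
                   charges = c(0, 0), hcounts = c(0L, 0L))
  gz <- surfaceDescriptors(zero)
  expect_equal(gz[["Jurs_FNSA_1"]], 0)
  expect_equal(gz[["Jurs_RPCS"]], 0)

  for (s in 1:5) {
    mol <- prepareMolecule(randomMolecule(5, seed = s), seed = s)
    v <- surfaceDescriptors(mol)
    expect_gte(v[["Jurs_FNSA_1"]], 0)
    expect_lte(v[["Jurs_FNSA_1"]], 1)
  }
  expect_error(surfaceDescriptors(mkEthane()), "charges")
})

test_that("shadow length matches geometry and is rotation invariant", {
  one <- Molecule("C", coords = matrix(0, 1, 3), hcounts = 0L)
  expect_equal(shadowDescriptors(one)[["Shadow_Xlength"]], 2 * 1.7)

  d <- 1.54
  dia <- Molecule(c("C", "C"), coords = rbind(c(0, 0, 0), c(d, 0, 0)),
                  hcounts = c(0L, 0L))
  expect_equal(shadowDescriptors(dia)[["Shadow_Xlength"]], d + 2 * 1.7,
               tolerance = 1e-9)

  mol <- prepareMolecule(mkEthanol(), seed = 5)
  ref <- shadowDescriptors(mol)[["Shadow_Xlength"]]
  th <- 0.7; R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- mol
  rot@atoms[, c("x", "y", "z")] <- atomCoords(mol) %*% R
  expect_lt(abs(shadowDescriptors(rot)[["Shadow_Xlength"]] - ref), 1e-6)
})

test_that("the descriptor table composes the three descriptor families", {
  empty <- computeDescriptorTable(list())
  expect_identical(dim(empty), c(0L, 11L))

  mols <- lapply(1:3, function(i) prepareMolecule(mkEthanol(), seed = 9))
  tab <- computeDescriptorTable(mols)
  expect_identical(dim(tab), c(3L, 11L))
  expect_identical(descriptorNames(tab), descriptorSet())
  m <- as.matrix(tab)
  expect_equal(m[1, ], m[2, ])  # duplicates give identical rows
  byHand <- c(topologicalDescriptors(mols[[1]]),
              surfaceDescriptors(mols[[1]]),
              shadowDescriptors(mols[[1]]))[descriptorSet()]
  expect_equal(m[1, ], byHand)

  bad <- list(mkEthane())  # unprepared: no coordinates/charges
  expect_error(computeDescriptorTable(bad), "molecule 1")
})
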