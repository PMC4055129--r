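# Lattice construction, CoMFA/CoMSIA fields, PLS and contour export.

mkPointAtom <- function(element = "C", xyz = c(0, 0, 0), charge = NULL) {
  Molecule(element, coords = matrix(xyz, 1, 3), hcounts = 0L, charges = charge)
}

test_that("grid construction covers molecules with the documented margins", {
  g <- buildGrid(list(mkPointAtom()), spacing = 2, margin = 4)
  expect_identical(g@counts, rep(5L, 3))  # -4..4 by 2
  pts <- gridPoints(g)
  expect_equal(range(pts[, 1]), c(-4, 4))

  g2 <- buildGrid(list(mkPointAtom()), spacing = 2, margin = 6)
  expect_true(all(g2@counts >= g@counts))  # larger margin never loses points

  a <- mkPointAtom(xyz = c(0, 0, 0)); b <- mkPointAtom(xyz = c(3, 1, 0))
  gu <- buildGrid(list(a, b), spacing = 2, margin = 4)
  both <- rbind(atomCoords(a), atomCoords(b))
  expect_true(all(apply(gridPoints(gu), 2, min) <= apply(both, 2, min) - 4 + 1e-9))
  expect_error(buildGrid(list()), "no molecules")
})

test_that("CoMFA fields evaluate the stated potentials", {
  # neutral atom: electrostatic field identically zero
  cf0 <- comfaFields(list(mkPointAtom(charge = 0)),
                     buildGrid(list(mkPointAtom()), 2, 4))
  expect_true(all(cf0$E@values == 0))

  # steric minimum: probe at r = rmin gives exactly -eps_pair
  rmin <- 1.7 + 1.9
  grid <- new("GridSpec", origin = c(rmin, 0, 0), spacing = 50, counts = c(2L, 2L, 2L))
  cf <- comfaFields(list(mkPointAtom(charge = 0)), grid)
  epsPair <- sqrt(0.1094 * 0.1)
  expect_equal(cf$S@values[1, 1], -epsPair, tolerance = 1e-9)

  # +1 point charge, probe +1 at 2 A with D(r) = r: 332.0637 / 4
  grid2 <- new("GridSpec", origin = c(2, 0, 0), spacing = 50, counts = c(2L, 2L, 2L))
  cf2 <- comfaFields(list(mkPointAtom(charge = 1)), grid2, cutoff = 1000)
  expect_equal(cf2$E@values[1, 1], 332.0637 / 4, tolerance = 1e-9)

  # truncation bound respected
  cf3 <- suppressMessages(
    comfaFields(list(mkPointAtom(charge = 1)),
                buildGrid(list(mkPointAtom()), 2, 4), cutoff = 30))
  expect_true(all(abs(cf3$S@values) <= 30 + 1e-12))
  expect_true(all(abs(cf3$E@values) <= 30 + 1e-12))
})

test_that("CoMSIA fields follow the Gaussian similarity form", {
  g <- buildGrid(list(mkPointAtom()), 2, 4)
  # no donor atoms: D field identically zero
  cs <- comsiaFields(list(mkPointAtom(charge = 0)), g, types = "D")
  expect_true(all(cs$D@values == 0))

  # single atom, property w, point at distance r: -w exp(-alpha r^2)
  csS <- comsiaFields(list(mkPointAtom(charge = 0)), g, types = "S", alpha = 0.3)
  pts <- gridPoints(g)
  r2 <- rowSums(pts^2)
  expect_equal(as.vector(csS$S@values), -1.7^3 * exp(-0.3 * r2), tolerance = 1e-12)

  # strong attenuation kills all off-atom points
  csA <- comsiaFields(list(mkPointAtom(charge = 0)), g, types = "S", alpha = 1e3)
  far <- r2 >= 0.25
  expect_true(all(abs(csA$S@values[1, far]) < 1e-12))

  expect_error(comsiaFields(list(mkPointAtom()), g, types = "Q"), "unknown field type")
})

test_that("fields are equivariant under joint translation", {
  s <- genAlignedSeries(nMolecules = 4, seed = 3)
  shift <- c(5, -2, 1)
  shifted <- lapply(s$mols, function(m) {
    m@atoms[, c("x", "y", "z")] <- sweep(atomCoords(m), 2, shift, `+`)
    m
  })
  g2 <- new("GridSpec", origin = s$grid@origin + shift,
            spacing = s$grid@spacing, counts = s$grid@counts)
  f1 <- comsiaFields(s$mols, s$grid, types = "H")
  f2 <- comsiaFields(shifted, g2, types = "H")
  expect_equal(f1$H@values, f2$H@values, tolerance = 1e-9)
  e1 <- comfaFields(s$mols, s$grid)
  e2 <- comfaFields(shifted, g2)
  expect_equal(e1$S@values, e2$S@values, tolerance = 1e-9)
})

test_that("column filtering drops exactly the low-variance lattice columns", {
  v <- rbind(c(0, 5, 1), c(0, -5, 1.2), c(0, 5, 0.8), c(0, -5, 1.1))
  g <- new("GridSpec", origin = c(0, 0, 0), spacing = 1, counts = c(3L, 2L, 2L))
  blk <- new("FieldBlock", type = "S", values = cbind(v, matrix(0, 4, 9)),
             grid = g, keptColumns = 1:12)
  kept <- filterColumns(list(blk), sigmaMin = 1)[[1]]
  expect_identical(kept@keptColumns, 2L)
  kept0 <- filterColumns(list(blk), sigmaMin = 0)[[1]]
  expect_identical(kept0@keptColumns, 1:12)  # sigma_min 0 is the identity
  expect_error(filterColumns(list(blk), sigmaMin = 100), "lower the threshold")
})

test_that("PLS statistics are internally consistent and exact fits reach r2 = 1", {
  withr::with_seed(31, {
    X <- matrix(rnorm(12 * 6), 12, 6)
    beta <- rnorm(6)
    y <- as.vector(X %*% beta) + 2
  })
  m <- fitPLS(X, y, ncomp = 6)
  expect_equal(m@r2, 1, tolerance = 1e-9)

  yn <- y + withr::with_seed(32, rnorm(12, sd = 0.5))
  m2 <- fitPLS(X, yn, ncomp = 3)
  ssres <- sum((yn - predict(m2, X))^2)
  c_ <- m2@ncomp; mrows <- 12
  expect_equal(m2@see, sqrt(ssres / (mrows - c_ - 1)), tolerance = 1e-9)
  expect_equal(m2@f, (m2@r2 / c_) / ((1 - m2@r2) / (mrows - c_ - 1)),
               tolerance = 1e-9)
})

test_that("full-component PLS equals minimum-norm least squares", {
  withr::with_seed(41, {
    X <- matrix(rnorm(8 * 20), 8, 20)
    y <- rnorm(8)
  })
  m <- fitPLS(X, y, ncomp = 7)
  # minimum-norm LS on centered data via the pseudoinverse
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  sv <- svd(Xc)
  pos <- sv$d > 1e-10
  bmn <- sv$v[, pos] %*% ((t(sv$u[, pos]) %*% yc) / sv$d[pos])
  predMN <- as.vector(Xc %*% bmn) + mean(y)
  expect_lt(max(abs(predict(m, X) - predMN)), 1e-6)
})

test_that("leave-one-out q2 conventions hold", {
  s <- genAlignedSeries(nMolecules = 10, seed = 11)
  blocks <- filterColumns(comsiaFields(s$mols, s$grid, types = "H"),
                          sigmaMin = 1e-6)
  X <- blocks$H@values
  expect_identical(looQ2(X, s$y, 0L), 0)  # mean predictor baseline
  q2 <- looQ2(X, s$y, 2L)
  r2 <- fitPLS(X, s$y, 2L)@r2
  expect_lte(q2, r2 + 1e-9)
})

test_that("q2 never exceeds r2 across random datasets", {
  for (s in 1:5) {
    withr::with_seed(s, {
      X <- matrix(rnorm(10 * 15), 10, 15)
      y <- rnorm(10)
    })
    k <- 3L
    expect_lte(looQ2(X, y, k), fitPLS(X, y, k)@r2 + 1e-9)
  }
})

test_that("noiseless field-linear activities are recovered by PLS", {
  s <- genAlignedSeries(nMolecules = 12, noiseSD = 0, seed = 11)
  blocks <- filterColumns(comsiaFields(s$mols, s$grid, types = "H"),
                          sigmaMin = 1e-6)
  m <- fitPLS(blocks$H@values, s$y, ncomp = 3)
  expect_gte(m@r2, 0.99)
})

test_that("permuted activities give near-null q2", {
  nulls <- 0L
  for (s in 1:5) {
    ser <- genAlignedSeries(nMolecules = 12, noiseSD = 0, seed = 20 + s)
    blocks <- filterColumns(comsiaFields(ser$mols, ser$grid, types = "H"),
                            sigmaMin = 1e-6)
    yPerm <- withr::with_seed(s, sample(ser$y))
    if (looQ2(blocks$H@values, yPerm, 2L) <= 0.2) nulls <- nulls + 1L
  }
  expect_gte(nulls, 4L)
})

test_that("field-combination reports have coherent fractions", {
  s <- genAlignedSeries(nMolecules = 12, fieldType = "H", noiseSD = 0, seed = 11)
  blocks <- filterColumns(
    comsiaFields(s$mols, s$grid, types = c("E", "H", "A")), sigmaMin = 1e-6)
  rep_ <- runFieldCombinations(blocks, s$y, c("H", "EHA"), maxComponents = 4L)
  expect_identical(rep_$model, c("H", "EHA"))
  expect_equal(rep_$frac_h[1], 1)  # single-field fraction is 1
  expect_gt(rep_$frac_h[2], rep_$frac_e[2])  # planted H dependence dominates E
  fr <- rowSums(rep_[, c("frac_s", "frac_e", "frac_h", "frac_d", "frac_a")])
  expect_equal(fr, rep(1, 2), tolerance = 1e-6)
  expect_error(runFieldCombinations(blocks, s$y, "HH"), "duplicate")
  expect_error(runFieldCombinations(blocks, s$y, "SD"), "no field block")

  # identical blocks under two letters split the mass evenly
  twin <- blocks[c("H", "H")]
  names(twin) <- c("H", "D")
  twin$D@type <- "D"
  rep2 <- runFieldCombinations(twin, s$y, "HD", maxComponents = 3L)
  expect_lt(abs(rep2$frac_h - 0.5), 0.05)
  expect_lt(abs(rep2$frac_d - 0.5), 0.05)
})

test_that("contour export returns disjoint favored/disfavored point sets", {
  s <- genAlignedSeries(nMolecules = 12, fieldType = "H", noiseSD = 0, seed = 11)
  blocks <- filterColumns(comsiaFields(s$mols, s$grid, types = "H"),
                          sigmaMin = 1e-6)
  cc <- concatBlocks(blocks)
  m <- fitPLS(cc$X, s$y, 3L, cc$blockIndex, cc$blockTypes)
  ct <- exportContours(m, cc$X, blocks, favored = 80, disfavored = 20)
  fav <- ct[ct$set == "favored", c("x", "y", "z")]
  dis <- ct[ct$set == "disfavored", c("x", "y", "z")]
  expect_identical(nrow(merge(fav, dis)), 0L)

  all_ <- exportContours(m, cc$X, blocks, favored = 100, disfavored = 0)
  expect_identical(nrow(all_), ncol(cc$X))  # every kept point exported
  expect_error(exportContours(m, cc$X, blocks, 20, 80), "exceed")
})

test_that("a single influential column lands in the favored contour set", {
  withr::with_seed(51, {
    X <- matrix(rnorm(10 * 8, sd = 1), 10, 8)
    y <- 3 * X[, 4] + rnorm(10, sd = 0.05)
  })
  g <- new("GridSpec", origin = c(0, 0, 0), spacing = 1, counts = c(8L, 2L, 2L))
  blk <- new("FieldBlock", type = "S",
             values = cbind(X, matrix(0, 10, 24)), grid = g, keptColumns = 1:32)
  fb <- filterColumns(list(blk), sigmaMin = 1e-6)
  cc <- concatBlocks(fb)
  m <- fitPLS(cc$X, y, 2L, cc$blockIndex, cc$blockTypes)
  ct <- exportContours(m, cc$X, fb, favored = 80, disfavored = 20)
  target <- gridPoints(g)[4, ]
  fav <- ct[ct$set == "favored", ]
  expect_true(any(fav$x == target[1] & fav$y == target[2] & fav$z == target[3]))
})
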