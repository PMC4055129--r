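# MLR, the published reference model, SVR and the validation report.

test_that("OLS recovers exact and closed-form solutions", {
  x <- matrix(seq(-2, 2, length.out = 10), ncol = 1,
              dimnames = list(NULL, "x1"))
  y <- 3 * x[, 1] + 1
  m <- fitMLR(x, y)
  expect_lt(abs(coef(m)[["(Intercept)"]] - 1), 1e-9)
  expect_lt(abs(coef(m)[["x1"]] - 3), 1e-9)

  withr::with_seed(11, {
    x2 <- matrix(rnorm(25), 25, 1, dimnames = list(NULL, "x1"))
    y2 <- 0.7 * x2[, 1] + rnorm(25, sd = 0.3)
  })
  m2 <- fitMLR(x2, y2)
  expect_equal(coef(m2)[["x1"]], cov(x2[, 1], y2) / var(x2[, 1]),
               tolerance = 1e-9)
})

test_that("OLS residuals are orthogonal to the design", {
  d <- genLinearDataset(n = 50, p = 5, terms = c(x2 = 1), noiseSD = 0.5, seed = 9)
  m <- fitMLR(d$table, d$y)
  r <- d$y - predict(m, d$table)
  Xd <- cbind(1, as.matrix(d$table))
  expect_lt(max(abs(crossprod(Xd, r))) / length(r), 1e-8)
})

test_that("noisy planted coefficients are estimated within 3 standard errors", {
  withr::with_seed(13, {
    X <- matrix(rnorm(200 * 4), 200, 4,
                dimnames = list(NULL, paste0("x", 1:4)))
    beta <- c(1.5, -0.8, 0, 2)
    y <- 2 + as.vector(X %*% beta) + rnorm(200, sd = 0.1)
  })
  m <- fitMLR(X, y)
  fit <- lm(y ~ X)  # reference standard errors
  se <- summary(fit)$coefficients[, 2]
  est <- coef(m)
  expect_true(all(abs(est - c(2, beta)) <= 3 * se))
})

test_that("rank-deficient designs are rejected with advice", {
  X <- cbind(x1 = 1:10, x2 = 2 * (1:10))
  expect_error(fitMLR(X, rnorm(10)), "rank deficient.*x2")
  expect_error(fitMLR(matrix(rnorm(4), 2, 2), rnorm(2)), "more sample")
})

test_that("the published reference model evaluates the printed coefficients", {
  cf <- coef(referenceMLRModel())
  terms <- names(cf)[-1]
  zero <- setNames(numeric(11), terms)
  expect_identical(evaluateReferenceMLR(zero), 31.623)

  hbd1 <- zero; hbd1["HBD_Count"] <- 1
  expect_identical(evaluateReferenceMLR(hbd1), 31.623 + 2.5173)

  # all-ones vector: independently summed printed values
  printedSum <- sum(c(31.623, 2.5173, -0.47471, -1.7664, -12.997, -45.669,
                      36.62, 0.11612, 18.941, -4.8012, 0.029451, -0.084377))
  ones <- setNames(rep(1, 11), terms)
  expect_equal(evaluateReferenceMLR(ones), printedSum, tolerance = 1e-12)

  # BD_Count alias resolves to HBD_Count
  alias <- setNames(numeric(11), sub("^HBD_Count$", "BD_Count", terms))
  alias["BD_Count"] <- 1
  expect_identical(evaluateReferenceMLR(alias), 31.623 + 2.5173)

  expect_error(evaluateReferenceMLR(zero[-1]), "missing descriptor.*HBD_Count")
})

test_that("SVR training points stay within the epsilon tube when feasible", {
  X <- matrix(seq(0, 2, length.out = 5), 5, 1)
  y <- X[, 1]
  m <- fitSVR(X, y, C = 100, epsilon = 0.5, sigma = 1)
  expect_true(all(abs(predict(m, X) - y) <= 0.5 + 1e-6))
})

test_that("the RBF kernel matrix is symmetric positive semi-definite", {
  withr::with_seed(21, X <- matrix(rnorm(30), 10, 3))
  K <- rbfKernel(X, sigma = 1.3)
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values >= -1e-8))
})

test_that("the SVR dual solution matches an independent solver on a tiny instance", {
  withr::with_seed(2, {
    X <- matrix(rnorm(8), 4, 2)
    y <- rnorm(4)
  })
  m <- fitSVR(X, y, C = 5, epsilon = 0.1, sigma = 1.2, tol = 1e-6)
  ref <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                    gamma = 1 / (2 * 1.2^2), cost = 5, epsilon = 0.1,
                    scale = FALSE, tolerance = 1e-8)
  objGot <- qsarforge:::svrDualObjective(m, X, y)
  betaRef <- numeric(4); betaRef[ref$index] <- ref$coefs
  objRef <- qsarforge:::.svrDualObjective(betaRef, rbfKernel(X, sigma = 1.2),
                                          y, 0.1)
  expect_lt(abs(objGot - objRef), 1e-6)
  expect_lt(max(abs(predict(m, X) - as.vector(predict(ref, X)))), 1e-4)
})

test_that("SVR predictions are invariant to sample reordering", {
  withr::with_seed(5, {
    X <- matrix(rnorm(40), 20, 2)
    y <- X[, 1]^2 + rnorm(20, sd = 0.1)
  })
  m1 <- fitSVR(X, y, C = 10, epsilon = 0.1, sigma = 1.5, tol = 1e-6)
  perm <- withr::with_seed(6, sample(20))
  m2 <- fitSVR(X[perm, ], y[perm], C = 10, epsilon = 0.1, sigma = 1.5, tol = 1e-6)
  probe <- matrix(c(0.3, -0.2, 1.1, 0.5), 2, 2)
  expect_lt(max(abs(predict(m1, probe) - predict(m2, probe))), 1e-4)
})

test_that("seeded SVR grid search is reproducible and improves fit", {
  d <- genLinearDataset(n = 30, p = 2, terms = c(x1 = 1), noiseSD = 0.2, seed = 31)
  t1 <- tuneSVR(d$table, d$y, Cs = c(1, 10), epsilons = 0.1, folds = 3, seed = 4)
  t2 <- tuneSVR(d$table, d$y, Cs = c(1, 10), epsilons = 0.1, folds = 3, seed = 4)
  expect_identical(t1$grid, t2$grid)
  expect_lte(min(t1$grid$mse), max(t1$grid$mse))
})

test_that("validation reports reproduce printed residuals and R2 conventions", {
  t5 <- loadFixture("table5")
  t1 <- loadFixture("table1")
  exper <- t1$pic50[match(t5$id, t1$id)]
  rep_ <- validationReport(t5$comfa_pred, exper, subsets = t5$set, ids = t5$id)
  tab <- residualTable(rep_)
  expect_equal(round(tab$residual[tab$id == 22], 4), 0.5720)

  perfect <- validationReport(1:10, 1:10, "train")
  expect_equal(unname(r2Values(perfect)["overall"]), 1)
  expect_true(all(residualTable(perfect)$residual == 0))

  affine <- validationReport(2 * (1:10) + 3, 1:10, "train")
  expect_equal(unname(r2Values(affine)["overall"]), 1)     # Pearson convention
  expect_lt(r2Values(affine, "determination")[["overall"]], 0)

  flat <- validationReport(rep(1, 5), rnorm(5), "x")
  expect_true(is.na(r2Values(flat)[["x"]]))
})

test_that("MLR training R2 is invariant to affine descriptor rescaling", {
  d <- genLinearDataset(n = 40, p = 3, terms = c(x1 = 1, x2 = -2),
                        noiseSD = 0.3, seed = 17)
  X <- as.matrix(d$table)
  m1 <- fitMLR(X, d$y)
  X2 <- X; X2[, 1] <- 10 * X2[, 1] + 7
  m2 <- fitMLR(X2, d$y)
  expect_equal(m1@r2, m2@r2, tolerance = 1e-9)
})
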