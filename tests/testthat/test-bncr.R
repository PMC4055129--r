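# Activity discretization, per-category OLS, structure learning, inference.

test_that("activity discretization places edges as specified", {
  d <- discretizeActivity(1:10, 2, "width")
  expect_identical(d$labels, rep(1:2, each = 5L))
  expect_equal(d$edges, 5.5)

  expect_error(discretizeActivity(1:10, 1), "at least 2")
  expect_error(discretizeActivity(rep(1:2, 5), 4), "distinct")

  t1 <- loadFixture("table1")
  d3 <- discretizeActivity(t1$pic50, 3, "frequency")
  expect_identical(as.integer(table(d3$labels)), rep(15L, 3))
})

test_that("per-category OLS reduces to global OLS and recovers planted slopes", {
  d <- genLinearDataset(n = 30, p = 3, terms = c(x1 = 2), noiseSD = 0.2, seed = 3)
  one <- fitCategoryRegressions(d$table, d$y, rep(1L, 30))
  expect_equal(one[[1]], coef(fitMLR(d$table, d$y)), tolerance = 1e-12)

  withr::with_seed(8, {
    x <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "x1"))
    labels <- rep(1:2, each = 20L)
    y <- ifelse(labels == 1, 2 * x[, 1], -1 * x[, 1] + 5)
  })
  betas <- fitCategoryRegressions(x, y, labels)
  expect_lt(abs(betas[[1]][["x1"]] - 2), 1e-9)
  expect_lt(abs(betas[[2]][["x1"]] - (-1)), 1e-9)
  expect_lt(abs(betas[[2]][["(Intercept)"]] - 5), 1e-9)

  dup <- cbind(x1 = x[, 1], x2 = x[, 1])
  expect_error(fitCategoryRegressions(dup, y, labels), "category 1")
})

test_that("structure learning separates independence from dependence", {
  withr::with_seed(1, {
    A <- sample(1:2, 500, replace = TRUE)
    B <- sample(1:2, 500, replace = TRUE)
    Bdep <- ifelse(runif(500) < 0.9, A, 3 - A)
  })
  indep <- learnBNStructure(data.frame(A = A, B = B), seed = 1)
  expect_equal(sum(indep$dag), 0)

  dep <- learnBNStructure(data.frame(A = A, B = Bdep), seed = 1)
  expect_equal(sum(dep$dag), 1)  # one edge in the skeleton

  again <- learnBNStructure(data.frame(A = A, B = Bdep), seed = 1)
  expect_identical(dep$dag, again$dag)

  expect_warning(learnBNStructure(data.frame(A = A, C = rep(1, 500)), seed = 1),
                 "single-level")
})

test_that("posterior inference matches hand-computed Bayes inversion", {
  # 2-category model with an empty graph: posterior = marginal frequencies
  freq <- c(0.3, 0.7)
  dag0 <- matrix(0L, 1, 1, dimnames = list("pIC50_category", "pIC50_category"))
  cpt0 <- array(freq, dim = c(1L, 2L), dimnames = list("", c("1", "2")))
  attr(cpt0, "parents") <- character(); attr(cpt0, "levels") <- c("1", "2")
  m0 <- new("BNCRModel", binEdges = 5, betas = list(c(`(Intercept)` = 0),
                                                    c(`(Intercept)` = 1)),
            columns = character(), descEdges = list(),
            dag = dag0, cpts = list(pIC50_category = cpt0),
            catNode = "pIC50_category")
  post <- posteriorCategory(m0, setNames(numeric(0), character(0)))
  expect_equal(unname(post), freq, tolerance = 1e-12)

  # hand-built 2-node network: category -> evidence with known CPTs
  dag <- matrix(0L, 2, 2, dimnames = list(c("pIC50_category", "x1"),
                                          c("pIC50_category", "x1")))
  dag["pIC50_category", "x1"] <- 1L
  prior <- array(c(0.4, 0.6), dim = c(1L, 2L),
                 dimnames = list("", c("1", "2")))
  attr(prior, "parents") <- character(); attr(prior, "levels") <- c("1", "2")
  lik <- array(c(0.9, 0.2, 0.1, 0.8), dim = c(2L, 2L),
               dimnames = list(c("1", "2"), c("1", "2")))
  attr(lik, "parents") <- "pIC50_category"; attr(lik, "levels") <- c("1", "2")
  model <- new("BNCRModel", binEdges = 5,
               betas = list(c(`(Intercept)` = 0, x1 = 1),
                            c(`(Intercept)` = 10, x1 = 1)),
               columns = "x1", descEdges = list(x1 = 0.5),
               dag = dag, cpts = list(pIC50_category = prior, x1 = lik),
               catNode = "pIC50_category")
  # evidence x1 = bin 1: P(cat|x1=1) proportional to (0.4*0.9, 0.6*0.2)
  post1 <- posteriorCategory(model, c(x1 = 0))
  expect_equal(unname(post1), c(0.36, 0.12) / 0.48, tolerance = 1e-9)
  expect_equal(sum(post1), 1, tolerance = 1e-9)
})

test_that("deterministic evidence pins the posterior on one category", {
  dag <- matrix(0L, 2, 2, dimnames = list(c("pIC50_category", "x1"),
                                          c("pIC50_category", "x1")))
  dag["pIC50_category", "x1"] <- 1L
  prior <- array(c(0.5, 0.5), dim = c(1L, 2L), dimnames = list("", c("1", "2")))
  attr(prior, "parents") <- character(); attr(prior, "levels") <- c("1", "2")
  lik <- array(c(1, 0, 0, 1), dim = c(2L, 2L),
               dimnames = list(c("1", "2"), c("1", "2")))
  attr(lik, "parents") <- "pIC50_category"; attr(lik, "levels") <- c("1", "2")
  m <- new("BNCRModel", binEdges = 5,
           betas = list(c(`(Intercept)` = 0), c(`(Intercept)` = 1)),
           columns = "x1", descEdges = list(x1 = 0.5),
           dag = dag, cpts = list(pIC50_category = prior, x1 = lik),
           catNode = "pIC50_category")
  expect_equal(unname(posteriorCategory(m, c(x1 = 2))), c(0, 1))
})

test_that("posterior ties resolve to the lower category", {
  dag0 <- matrix(0L, 1, 1, dimnames = list("pIC50_category", "pIC50_category"))
  cpt0 <- array(c(0.5, 0.5), dim = c(1L, 2L), dimnames = list("", c("1", "2")))
  attr(cpt0, "parents") <- character(); attr(cpt0, "levels") <- c("1", "2")
  m <- new("BNCRModel", binEdges = 5,
           betas = list(c(`(Intercept)` = 100), c(`(Intercept)` = 200)),
           columns = character(), descEdges = list(),
           dag = dag0, cpts = list(pIC50_category = cpt0),
           catNode = "pIC50_category")
  expect_message(p <- predict(m, matrix(numeric(0), 1, 0)), "tie")
  expect_identical(p, 100)
})

test_that("BNCR with one category equals MLR on random datasets", {
  for (s in 1:20) {
    d <- genLinearDataset(n = 25, p = 3, terms = c(x1 = 1, x3 = -1),
                          noiseSD = 0.5, seed = s)
    b <- fitBNCR(d$table, d$y, nCategories = 1)
    m <- fitMLR(d$table, d$y)
    expect_lt(max(abs(predict(b, d$table) - predict(m, d$table))), 1e-9)
  }
})

test_that("BNCR recovers noiseless piecewise regimes exactly", {
  d <- genCategoryDataset(n = 200, p = 4, nCategories = 2, noiseSD = 0, seed = 5)
  m <- suppressMessages(fitBNCR(d$table, d$y, nCategories = 2, seed = 1))
  te <- genCategoryDataset(n = 50, p = 4, nCategories = 2, noiseSD = 0, seed = 6)
  pred <- suppressMessages(predict(m, te$table))
  expect_lt(max(abs(pred - te$y)), 1e-6)
  acc <- vapply(seq_len(50), function(i) {
    post <- suppressMessages(
      posteriorCategory(m, as.matrix(te$table)[i, , drop = FALSE]))
    which.max(post) == te$truth$labels[i]
  }, logical(1))
  expect_identical(mean(acc), 1)  # 100% category recovery
})

test_that("shuffled category links leave the category node unconnected", {
  isolated <- 0L
  for (s in 1:5) {
    d <- genCategoryDataset(n = 150, p = 4, nCategories = 2, noiseSD = 0.2,
                            shuffle = TRUE, seed = 100 + s)
    m <- suppressMessages(fitBNCR(d$table, d$y, nCategories = 2, seed = s))
    ci <- which(colnames(m@dag) == "pIC50_category")
    if (sum(m@dag[, ci]) + sum(m@dag[ci, ]) == 0) isolated <- isolated + 1L
  }
  expect_gte(isolated, 4L)
})
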