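# MARS, GLM, cross-validation and (partial) correlation screening.

test_that("MARS recovers a planted hinge exactly", {
  set.seed(1)
  x <- matrix(runif(200, 0, 4), ncol = 1, dimnames = list(NULL, "x"))
  y <- pmax(0, x[, 1] - 2)
  fit <- fitMars(x, y)
  expect_gte(fit$r2, 0.99)
  expect_true(any(abs(fit$terms$knot - 2) < 0.1))
  # prediction at new points follows the hinge
  newx <- matrix(c(0, 1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(predict(fit, newx), pmax(0, newx[, 1] - 2), tolerance = 0.05)
})

test_that("MARS nests linear fits and handles degenerate responses", {
  set.seed(2)
  x <- matrix(rnorm(100), ncol = 1, dimnames = list(NULL, "x"))
  y <- 2 * x[, 1] + 1
  mars <- fitMars(x, y)
  glmF <- fitGlmModel(x, y)
  expect_gte(mars$r2, glmF$r2 - 1e-6)
  # constant response: intercept-only model with R^2 = 0
  fit0 <- fitMars(x, rep(3, 100))
  expect_equal(nrow(fit0$terms), 0L)
  expect_equal(fit0$r2, 0)
  expect_error(fitMars(x, rnorm(5)), "sizes differ")
  expect_error(fitMars(x[1:5, , drop = FALSE], rnorm(5), maxTerms = 10),
               "smaller than the sample size")
})

test_that("the GCV penalty prunes noise terms", {
  set.seed(3)
  x <- matrix(rnorm(300 * 5), 300, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- x[, 1] + rnorm(300, 0, 0.5)   # only x1 matters
  fit <- fitMars(x, y)
  used <- unique(fit$terms$var)
  expect_true("x1" %in% used)
  expect_lte(length(used), 3L)
  expect_gte(fit$gcv, 0)
})

test_that("the Gaussian identity GLM is ordinary least squares", {
  set.seed(4)
  x <- matrix(rnorm(60), ncol = 1, dimnames = list(NULL, "x"))
  y <- 2 * x[, 1] + 1
  fit <- fitGlmModel(x, y)
  expect_equal(unname(fit$coef), c(1, 2), tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # response as its own predictor
  fit2 <- fitGlmModel(matrix(y, dimnames = list(NULL, "y")), y)
  expect_equal(fit2$r2, 1, tolerance = 1e-12)
  # collinear design drops a column with a warning
  xx <- cbind(a = x[, 1], b = 2 * x[, 1])
  expect_warning(fit3 <- fitGlmModel(xx, y), "collinear")
  expect_equal(fit3$r2, 1, tolerance = 1e-9)
  # null model: R^2 stays small for independent noise
  set.seed(5)
  xN <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("a", "b")))
  expect_lt(fitGlmModel(xN, rnorm(1000))$r2, 0.02)
})

test_that("cross-validation is seeded, honest and stratified", {
  set.seed(6)
  x <- matrix(runif(300, 0, 4), ncol = 1, dimnames = list(NULL, "x"))
  y <- pmax(0, x[, 1] - 2) + rnorm(300, 0, 0.01)
  cv1 <- crossValidate(x, y, fitMars, folds = 10, seed = 9)
  cv2 <- crossValidate(x, y, fitMars, folds = 10, seed = 9)
  expect_identical(cv1$fold, cv2$fold)
  expect_equal(cv1$r2cv, cv2$r2cv)
  expect_gte(cv1$r2cv, 0.95)   # strong signal generalizes
  # pure noise does not generalize
  cvN <- crossValidate(x, rnorm(300), fitMars, folds = 10, seed = 9)
  expect_lte(cvN$r2cv, 0.1)
  expect_error(crossValidate(x, y, fitMars, folds = 1), "at least 2")
})

test_that("resubstitution beats cross-validation on average", {
  set.seed(7)
  diffs <- vapply(1:5, function(i) {
    x <- matrix(rnorm(120 * 3), 120, 3,
                dimnames = list(NULL, paste0("x", 1:3)))
    y <- x[, 1] - 0.5 * pmax(0, x[, 2]) + rnorm(120, 0, 0.4)
    fit <- fitMars(x, y)
    cv <- crossValidate(x, y, fitMars, folds = 6, seed = i)
    fit$r2 - cv$r2cv
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("partial correlations match the formula and residual oracle", {
  # closed form: r_fp = r_fm = r_pm = 0.5 -> partial = 1/3
  expect_equal(dielomix:::partialFromPairwise(0.5, 0.5, 0.5), 1 / 3)
  # residual-correlation oracle on random data
  set.seed(8)
  for (i in 1:10) {
    m <- rnorm(40); f <- 0.5 * m + rnorm(40); p <- 0.3 * m + rnorm(40)
    expect_equal(
      dielomix:::partialFromPairwise(cor(f, p), cor(f, m), cor(p, m)),
      partialOracle(f, p, m), tolerance = 1e-10)
  }
})

test_that("feature-protein partials detect planted and null effects", {
  set.seed(9)
  n <- 120
  genes <- paste0("g", 1:n)
  m <- matrix(rnorm(n * 4, 5), n, 4, dimnames = list(genes, paste0("T", 1:4)))
  feat <- rnorm(n)
  p <- 0.8 * m + feat + rnorm(n * 4, 0, 0.3)
  nullFeat <- rnorm(n)
  fv <- cbind(planted = feat, null = nullFeat)
  rownames(fv) <- genes
  pc <- featureProteinPartialCorrelations(fv, m, p, nBoot = 200, seed = 3)
  expect_true(all(pc$partial["planted", ] > 0.5))
  expect_true(all(pc$p["planted", ] < 0.05))
  expect_true(all(abs(pc$partial["null", ]) < 0.3))
  # feature identical to mRNA is collinear
  fv2 <- cbind(clone = m[, 1])
  rownames(fv2) <- genes
  expect_error(featureProteinPartialCorrelations(fv2, m, p, nBoot = 0),
               "collinear")
  # feature equal to protein with independent mRNA: partial near 1
  mInd <- matrix(rnorm(n * 4, 5), n, 4, dimnames = dimnames(m))
  pv <- matrix(rnorm(n * 4), n, 4, dimnames = dimnames(m))
  fv3 <- cbind(self = pv[, 1])
  rownames(fv3) <- genes
  pc3 <- featureProteinPartialCorrelations(fv3, mInd, pv, nBoot = 0,
                                           method = "pearson")
  expect_gt(pc3$partial["self", 1], 0.99)
})

test_that("feature-mRNA Spearman correlations behave at the extremes", {
  set.seed(10)
  n <- 1000
  genes <- paste0("g", 1:n)
  m <- matrix(rnorm(n * 4), n, 4, dimnames = list(genes, paste0("T", 1:4)))
  ft <- new("FeatureTable",
            values = cbind(same = m[, 1], inv = -m[, 1], indep = rnorm(n),
                           const = rep(1, n)),
            info = S4Vectors::DataFrame(feature = c("same", "inv", "indep",
                                                    "const"),
                                        region = "cds", category = "test"),
            incomplete = setNames(rep(FALSE, n), genes))
  rownames(ft@values) <- genes
  expect_warning(rho <- featureMrnaCorrelations(ft, m), "constant")
  expect_equal(unname(rho["same", "T1"]), 1)
  expect_equal(unname(rho["inv", "T1"]), -1)
  expect_lt(abs(rho["indep", "T1"]), 0.1)
  expect_true(all(is.na(rho["const", ])))
})

test_that("constrained model subsets never beat the full model materially", {
  cfg <- smallConfig(nGenes = 250, seed = 35)
  gen <- generateSequences(cfg)
  expr <- generateExpression(gen$truth, cfg)
  mt <- timepointMeans(expr$mrna)
  pt <- timepointMeans(expr$protein)
  ft <- assembleFeatureTable(gen$sequences, mrna = mt)
  full <- fitAbundanceModels(ft, mt, pt, subset = "full", seed = 1)
  cai <- fitAbundanceModels(ft, mt, pt, subset = "mrnaCai", seed = 1)
  mrna <- fitAbundanceModels(ft, mt, pt, subset = "mrnaOnly", seed = 1)
  expect_true(all(cai$r2 <= full$r2 + 1e-6))
  expect_true(all(mrna$r2 <= full$r2 + 1e-6))
  expect_true(all(mrna$r2 <= cai$r2 + 1e-6))
})
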