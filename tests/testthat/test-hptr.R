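# HPTR identification, refit evaluation, feature tests, CSD balancing and
# elastic-net classifiers.

test_that("residual-quantile flags follow the stated construction", {
  set.seed(1)
  n <- 1060
  res <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(paste0("g", 1:n), paste0("T", 1:4)))
  # a gene above q95 in 3 models is HPTR+
  res["g1", 1:3] <- 10
  # a gene extreme in exactly 1 model is not HPTR
  res["g2", 1] <- -10
  hp <- identifyHptr(res)
  expect_true("g1" %in% hptrPlus(hp))
  expect_false("g2" %in% hptrGenes(hp))
  # ~5% of genes per tail per model (floor/ceil of quantile arithmetic)
  nHigh <- sum(res[, 1] > hp@quantiles$upper[1])
  expect_true(abs(nHigh - 0.05 * n) <= ceiling(0.002 * n) + 2)
  expect_error(identifyHptr(res, minModels = 9), "exceeds")
  expect_error(identifyHptr(res[, 1, drop = FALSE]), ">= 2 models")
})

test_that("HPTR membership is monotone in minModels and tails disjoint", {
  set.seed(2)
  res <- matrix(rnorm(400 * 4), 400, 4,
                dimnames = list(paste0("g", 1:400), paste0("T", 1:4)))
  sets <- lapply(1:4, function(k) hptrGenes(identifyHptr(res, minModels = k)))
  for (k in 2:4) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  hp <- identifyHptr(res)
  expect_equal(length(intersect(hptrPlus(hp), hptrMinus(hp))), 0L)
  # dominant-tail ties are excluded
  res2 <- res
  res2["g9", ] <- c(10, 10, -10, -10)
  expect_false("g9" %in% hptrGenes(identifyHptr(res2, minModels = 2)))
})

test_that("planted HPTR genes are recovered with high precision", {
  cfg <- smallConfig(nGenes = 400, seed = 45)
  gen <- generateSequences(cfg)
  expr <- generateExpression(gen$truth, cfg)
  mt <- timepointMeans(expr$mrna)
  pt <- timepointMeans(expr$protein)
  ft <- assembleFeatureTable(gen$sequences, mrna = mt)
  mod <- fitAbundanceModels(ft, mt, pt, seed = 1)
  hp <- identifyHptr(mod$residuals)
  truth <- gen$truth
  planted <- intersect(truth$gene[truth$hptr], mod$genes)
  det <- hptrGenes(hp)
  sens <- length(intersect(det, planted)) / length(planted)
  prec <- length(intersect(det, planted)) / length(det)
  expect_gte(sens, 0.6)
  expect_gte(prec, 0.6)
  # planted tails match the dominant-tail partition for detected genes
  plus <- intersect(hptrPlus(hp), planted)
  signs <- truth[plus, "hptrSign"]
  expect_gt(mean(signs == "+"), 0.8)
})

test_that("excluding HPTR genes improves cross-validated accuracy", {
  cfg <- smallConfig(nGenes = 350, seed = 47)
  gen <- generateSequences(cfg)
  expr <- generateExpression(gen$truth, cfg)
  mt <- timepointMeans(expr$mrna)
  pt <- timepointMeans(expr$protein)
  ft <- assembleFeatureTable(gen$sequences, mrna = mt)
  mod <- fitAbundanceModels(ft, mt, pt, seed = 1, maxTerms = 13)
  hp <- identifyHptr(mod$residuals)
  complete <- setdiff(rownames(featureValues(ft)), incompleteGenes(ft))
  heldout <- tail(sort(complete), 25)
  refit <- refitExcludingHptr(ft, mt, pt, hp, heldoutGenes = heldout,
                              folds = 5, seed = 2, nBootP = 200,
                              maxTerms = 13)
  expect_true(all(refit$delta > 0))
  expect_lt(refit$pImprovement, 0.05)
  expect_gt(refit$meanRelativeImprovement, 0)
  # held-out genes: refit models predict at least as well on average
  expect_gt(mean(refit$heldout$r2Refit - refit$heldout$r2Original), -0.05)
  # held-out genes are excluded from training by construction, so the
  # evaluation set never overlaps the training set
  expect_equal(length(intersect(refit$heldout$genes,
                                refit$original$genes)), 0L)
  # holding out the whole universe leaves nothing to train on
  expect_error(refitExcludingHptr(ft, mt, pt, hp, heldoutGenes = complete,
                                  folds = 5, seed = 2, nBootP = 0,
                                  maxTerms = 13),
               "30")
})

test_that("an empty HPTR set leaves the refit unchanged", {
  cfg <- smallConfig(nGenes = 200, seed = 49)
  gen <- generateSequences(cfg)
  expr <- generateExpression(gen$truth, cfg)
  mt <- timepointMeans(expr$mrna)
  pt <- timepointMeans(expr$protein)
  ft <- assembleFeatureTable(gen$sequences, mrna = mt)
  mod <- fitAbundanceModels(ft, mt, pt, seed = 1, maxTerms = 9)
  hp <- identifyHptr(mod$residuals, minModels = 4L)
  hp@plus <- character()
  hp@minus <- character()
  refit <- refitExcludingHptr(ft, mt, pt, hp, folds = 4, seed = 2,
                              nBootP = 0, maxTerms = 9)
  expect_equal(refit$delta, setNames(rep(0, 4), paste0("T", 1:4)))
  expect_equal(refit$r2cvOriginal, refit$r2cvRefit)
})

test_that("Wilcoxon feature screening is calibrated and powerful", {
  set.seed(3)
  n <- 1000
  fv <- matrix(rnorm(n * 6), n, 6,
               dimnames = list(paste0("g", 1:n), paste0("f", 1:6)))
  lab <- setNames(rep(FALSE, n), rownames(fv))
  lab[1:50] <- TRUE
  # null labels: Bonferroni keeps everything insignificant almost always
  res0 <- featureDistributionTests(fv, lab)
  expect_true(all(res0$padj > 0.05))
  # a 3 SD shift in the HPTR group is detected after correction
  fv2 <- fv
  fv2[lab, 1] <- fv2[lab, 1] + 3
  res1 <- featureDistributionTests(fv2, lab)
  expect_lt(res1$padj[res1$feature == "f1"], 0.01)
  # identical samples give p = 1
  fv3 <- cbind(flat = rep(c(1, 2), length.out = n))
  rownames(fv3) <- rownames(fv)
  res3 <- featureDistributionTests(fv3, lab)
  expect_equal(res3$p[1], 1, tolerance = 0.05)
  expect_error(featureDistributionTests(fv, rep(TRUE, n)), "non-empty")
})

test_that("convex pseudo-data stays inside the minority hull", {
  x <- rbind(a = c(0, 0), b = c(2, 2), c = c(0, 2))
  out <- balanceWithCsd(x, targetN = 10, seed = 5)
  expect_equal(nrow(out), 10L)
  pseudo <- out[-(1:3), ]
  expect_true(all(pseudo >= 0 & pseudo <= 2))
  # midpoint example: lambda = 0.5 of (0,0) and (2,2) is (1,1)
  expect_equal(0.5 * x["a", ] + 0.5 * x["b", ], c(1, 1))
  # balancing 10 vs 4 emits 6 pseudo-samples
  x4 <- matrix(rnorm(8), 4, 2)
  expect_equal(nrow(balanceWithCsd(x4, 10, seed = 1)) - 4, 6)
  expect_warning(balanceWithCsd(x4, 2, seed = 1), "below current")
  expect_error(balanceWithCsd(x4[1, , drop = FALSE], 5), ">= 2 samples")
})

test_that("the balanced success rate follows its definition", {
  expect_equal(balancedSuccessRate(8, 2, 6, 4), 0.7)
  expect_equal(balancedSuccessRate(5, 0, 9, 0), 1)
  expect_equal(balancedSuccessRate(3, 1, 1, 3), 0.5)
  expect_error(balancedSuccessRate(0, 0, 1, 1), "empty class")
  # invariant to duplicating one class's samples
  expect_equal(balancedSuccessRate(16, 4, 6, 4),
               balancedSuccessRate(8, 2, 6, 4))
})

test_that("elastic-net classifiers separate signal and stay at chance on noise", {
  set.seed(6)
  n <- 60
  x <- rbind(matrix(rnorm(n * 5, 0), n, 5),
             matrix(rnorm(20 * 5, 3), 20, 5))
  colnames(x) <- paste0("f", 1:5)
  labels <- c(rep("non-HPTR", n), rep("HPTR+", 20))
  fit <- trainHptrClassifiers(x, labels, seed = 2, nPerm = 30)
  expect_gte(fit$bsr, 0.95)
  expect_lt(fit$pBsr, 0.05)
  # features carrying no signal: BSR near chance, permutation p large
  xN <- matrix(rnorm(80 * 5), 80, 5, dimnames = list(NULL, paste0("f", 1:5)))
  fitN <- trainHptrClassifiers(xN, labels, seed = 3, nPerm = 30)
  expect_lt(abs(fitN$bsr - 0.5), 0.2)
  expect_gt(fitN$pBsr, 0.05)
  expect_error(trainHptrClassifiers(x, rep("one", nrow(x))), "two classes")
})
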