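# Synthetic-data generator: determinism, planted structure, sequence
# validity and peptide sampling.

test_that("generators are deterministic under a fixed seed", {
  cfg <- smallConfig(nGenes = 50, seed = 7)
  g1 <- generateSequences(cfg)
  g2 <- generateSequences(cfg)
  expect_identical(as.character(cds(g1$sequences)),
                   as.character(cds(g2$sequences)))
  expect_identical(as.data.frame(g1$truth), as.data.frame(g2$truth))
  e1 <- generateExpression(g1$truth, cfg)
  e2 <- generateExpression(g2$truth, cfg)
  expect_identical(assay(e1$mrna), assay(e2$mrna))
  p1 <- generatePeptides(e1$protein, cfg)
  p2 <- generatePeptides(e2$protein, cfg)
  expect_identical(assay(p1), assay(p2))
  # a different seed changes the sequences
  g3 <- generateSequences(smallConfig(nGenes = 50, seed = 8))
  expect_false(identical(as.character(cds(g1$sequences)),
                         as.character(cds(g3$sequences))))
})

test_that("generated CDS are valid ORFs translating to the protein", {
  gen <- generateSequences(smallConfig(nGenes = 40, seed = 3))
  sq <- gen$sequences
  expect_true(all(Biostrings::width(cds(sq)) %% 3 == 0))
  expect_true(all(startsWith(as.character(cds(sq)), "ATG")))
  tr <- Biostrings::translate(cds(sq))
  trChr <- as.character(tr)
  expect_true(all(endsWith(trChr, "*")))
  # no internal stops; body matches the protein record
  expect_identical(sub("\\*$", "", trChr), as.character(proteinSeqs(sq)))
  expect_false(any(grepl("\\*", sub("\\*$", "", trChr), fixed = FALSE)))
})

test_that("utrMissingRate = 0 gives complete UTRs and features", {
  gen <- generateSequences(smallConfig(nGenes = 30, seed = 5,
                                       utrMissingRate = 0))
  expect_true(all(gen$sequences@utr5Complete))
  expect_true(all(gen$sequences@utr3Complete))
  expect_true(all(Biostrings::width(utr5(gen$sequences)) > 0))
  expect_true(all(Biostrings::width(utr3(gen$sequences)) > 0))
})

test_that("a codon bias of 1 yields CAI = 1 against the gene's own usage", {
  cfg <- smallConfig(nGenes = 10, seed = 11)
  truth <- generateGroundTruth(cfg)
  truth$codonBias <- rep(1, 10)
  gen <- generateSequences(cfg, truth = truth)
  ref <- referenceCodonCounts(gen$sequences)
  cai <- computeCai(cds(gen$sequences), ref)
  expect_equal(unname(cai), rep(1, 10), tolerance = 1e-12)
})

test_that("realized delay-class proportions match the sampling mixture", {
  cfg <- simConfig(nGenes = 2000, seed = 19)
  truth <- generateGroundTruth(cfg)
  probs <- cfg@delayClassProbs
  freq <- table(factor(truth$delayClass, levels = names(probs))) / 2000
  se <- sqrt(probs * (1 - probs) / 2000)
  expect_true(all(abs(freq - probs) <= 3 * se + 1e-9))
})

test_that("zero noise, delay-0, no feature effects gives exact coupling", {
  cfg <- smallConfig(nGenes = 25, seed = 2,
                     delayClassProbs = c(delay0 = 1),
                     hptrFraction = 0,
                     featureEffects = c(cai = 0, utr5Structure = 0,
                                        mrnaHinge = 0),
                     noiseSdMrna = 0, noiseSdProtein = 0)
  truth <- generateGroundTruth(cfg)
  expr <- generateExpression(truth, cfg)
  r <- vapply(seq_len(25), function(g) {
    cor(expr$trueMrna[g, ], expr$trueProtein[g, ])
  }, numeric(1))
  expect_equal(r, rep(1, 25), tolerance = 1e-12)
})

test_that("planted delays are exact circular shifts in the clean matrices", {
  cfg <- smallConfig(nGenes = 30, seed = 13,
                     delayClassProbs = c(delay1 = 1), hptrFraction = 0,
                     featureEffects = c(cai = 0, utr5Structure = 0,
                                        mrnaHinge = 0),
                     noiseSdMrna = 0, noiseSdProtein = 0)
  truth <- generateGroundTruth(cfg)
  expr <- generateExpression(truth, cfg)
  shifted <- expr$trueMrna[, c(4, 1, 2, 3)]
  # protein is an affine map of the shifted mRNA profile
  expect_equal(cor(as.vector(shifted), as.vector(expr$trueProtein)), 1,
               tolerance = 1e-12)
})

test_that("peptide sampling respects missingness and sharing rates", {
  cfg <- smallConfig(nGenes = 60, seed = 23, missingRate = 0)
  truth <- generateGroundTruth(cfg)
  expr <- generateExpression(truth, cfg)
  pep <- generatePeptides(expr$protein, cfg)
  expect_false(anyNA(assay(pep)))
  expect_equal(ncol(pep), 4 * 3 * 4)  # timepoints x bioreps x techreps

  cfg2 <- simConfig(nGenes = 300, seed = 31, sharedPeptideRate = 0.1)
  truth2 <- generateGroundTruth(cfg2)
  expr2 <- generateExpression(truth2, cfg2)
  pep2 <- generatePeptides(expr2$protein, cfg2)
  nShared <- sum(!rowData(pep2)$unique)
  nPep <- nrow(pep2)
  se <- sqrt(0.1 * 0.9 * nPep)
  expect_lt(abs(nShared - 0.1 * nPep), 3 * se)
  expect_true(all(rowData(pep2)$unique ==
                    (lengths(strsplit(as.character(rowData(pep2)$proteinIds),
                                      ";")) == 1)))
})

test_that("zero-noise peptides with no offsets reproduce the protein row", {
  cfg <- smallConfig(nGenes = 5, seed = 3, missingRate = 0,
                     noiseSdPeptide = 0)
  truth <- generateGroundTruth(cfg)
  expr <- generateExpression(truth, cfg)
  pep <- generatePeptides(expr$protein, cfg)
  # within a dataset group, technical replicates carry the protein value
  # plus the fixed peptide offset: subtracting the per-peptide mean must
  # recover the protein's replicate profile shape exactly
  a <- assay(pep)
  prot <- assay(expr$protein)
  protOf <- sub(";.*$", "", as.character(rowData(pep)$proteinIds))
  tpbr <- paste(colData(pep)$timepoint, colData(pep)$biorep, sep = "_")
  protCols <- paste(colData(expr$protein)$timepoint,
                    colData(expr$protein)$biorep, sep = "_")
  idx <- match(tpbr, protCols)
  for (i in seq_len(nrow(a))) {
    pr <- prot[protOf[i], idx]
    expect_equal(a[i, ] - mean(a[i, ]), pr - mean(pr), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(nGenes = 0), "counts")
  expect_error(simConfig(nGenes = 10,
                         delayClassProbs = c(delay0 = 0.5, anti = 0.4)),
               "sum to 1")
  expect_error(simConfig(nGenes = 10, missingRate = 1.5), "proportions")
  expect_error(simConfig(nGenes = 10,
                         delayClassProbs = c(delay9 = 1)), "names")
})

test_that("noise-free, HPTR-free simulations recover all planted classes", {
  cfg <- simConfig(nGenes = 300, seed = 17, hptrFraction = 0,
                   noiseSdMrna = 0, noiseSdProtein = 0)
  truth <- generateGroundTruth(cfg)
  expr <- generateExpression(truth, cfg)
  jp <- zscoreProfiles(timepointMeans(expr$mrna),
                       timepointMeans(expr$protein))
  cl <- assignCorrelationClasses(jp)
  sel <- truth$delayClass != "independent"
  expected <- ifelse(truth$delayClass[sel] == "anti", "anti-correlated",
                     ifelse(truth$delay[sel] == 0, "correlated",
                            sprintf("delayed-%d-correlated",
                                    truth$delay[sel])))
  got <- as.character(cl[truth$gene[sel], "class"])
  expect_equal(mean(got == expected), 1)
})
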