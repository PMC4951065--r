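# Peptide filtering, quantile normalization, rollup, presence/absence and
# progressive differential testing.

test_that("occurrence and single-peptide filters follow the stated rules", {
  pep <- handPeptideSet()
  filt <- filterPeptides(pep, minDatasetFraction = 0.5,
                         varianceQuantile = 0)
  ids <- rowData(filt)$peptideId
  # protA peptides observed in 8/8 datasets survive
  expect_true(all(c("pep01", "pep02") %in% ids))
  # protB peptides observed in 4/8 datasets (exactly 50%) survive
  expect_true(all(c("pep03", "pep04") %in% ids))
  # protC peptides in 1/8 datasets fail the occurrence rule
  expect_false(any(c("pep05", "pep06", "pep07") %in% ids))
  # non-unique peptide removed; protD then has a single peptide -> dropped
  expect_false("pep09" %in% ids)
  expect_false("pep08" %in% ids)
  # protE only ever had one peptide -> dropped
  expect_false("pep10" %in% ids)
})

test_that("a peptide in half the datasets is retained at threshold 0.5", {
  a <- matrix(NA_real_, 2, 12,
              dimnames = list(c("p1", "p2"), paste0("d", 1:12)))
  a[1, 1:6] <- 1:6   # 6 of 12
  a[2, ] <- 2
  pep <- PeptideSet(a, S4Vectors::DataFrame(
    peptideId = c("p1", "p2"), proteinIds = c("A", "A"),
    unique = c(TRUE, TRUE)),
    S4Vectors::DataFrame(timepoint = rep("T1", 12),
                         biorep = rep("b1", 12),
                         techrep = paste0("t", 1:12)))
  filt <- filterPeptides(pep, varianceQuantile = 0)
  expect_setequal(rowData(filt)$peptideId, c("p1", "p2"))
})

test_that("the variance screen removes only the top residual fraction", {
  cfg <- smallConfig(nGenes = 50, seed = 9)
  truth <- generateGroundTruth(cfg)
  expr <- generateExpression(truth, cfg)
  pep <- generatePeptides(expr$protein, cfg)
  f0 <- filterPeptides(pep, varianceQuantile = 0)
  f5 <- filterPeptides(pep, varianceQuantile = 0.05)
  expect_equal(nrow(f0) - nrow(f5) >= floor(0.05 * nrow(f0)) - 2, TRUE)
  expect_true(all(rowData(f5)$peptideId %in% rowData(f0)$peptideId))
  # everything filtered away is an explicit error
  expect_error(filterPeptides(pep, minDatasetFraction = 1.01),
               "no peptides survive")
})

test_that("quantile normalization equalizes column distributions", {
  # closed form: columns [1,2,3] and [4,5,6] both become [2.5,3.5,4.5]
  m <- cbind(c(1, 2, 3), c(4, 5, 6))
  qn <- limma::normalizeQuantiles(m)
  expect_equal(qn[, 1], c(2.5, 3.5, 4.5))
  expect_equal(qn[, 2], c(2.5, 3.5, 4.5))

  # property: after normalization all columns share sorted values
  cfg <- smallConfig(nGenes = 40, seed = 21, missingRate = 0)
  truth <- generateGroundTruth(cfg)
  expr <- generateExpression(truth, cfg)
  pep <- generatePeptides(expr$protein, cfg)
  qn2 <- limma::normalizeQuantiles(assay(pep))
  sorted <- apply(qn2, 2L, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-9))
})

test_that("rollup removes constant peptide offsets", {
  base <- c(3, 4, 5, 4.5)
  a <- rbind(p1 = base, p2 = base + 0.3)
  colnames(a) <- paste0("T", 1:4)
  ru <- rollupMatrix(a, c("A", "A"))
  # offset peptide adds no information: profile equals the reference
  # peptide's profile (p2, the higher-median peptide at tied coverage)
  expect_equal(ru$values["A", ], base + 0.3, ignore_attr = TRUE)
  expect_equal(ru$nPeptides, 2L)

  # invariance: a constant added to the non-reference peptide's row is
  # absorbed by the median-difference shift (reference unchanged)
  a2 <- a
  a2["p1", ] <- a2["p1", ] + 0.1
  ru2 <- rollupMatrix(a2, c("A", "A"))
  expect_equal(ru2$values, ru$values)

  # missing overlap with the reference excludes the peptide with warning
  a3 <- rbind(p1 = c(1, 2, NA, NA), p2 = c(NA, NA, 3, 4))
  colnames(a3) <- paste0("T", 1:4)
  expect_warning(ru3 <- rollupMatrix(a3, c("A", "A")),
                 "no observations")
  expect_equal(ru3$nPeptides, 1L)
})

test_that("identical peptide rows roll up to the peptide row itself", {
  tp <- c("T1", "T2", "T3", "T4")
  base <- c(2, 3, 2.5, 4)
  a <- rbind(p1 = base, p2 = base)
  colnames(a) <- paste(tp, "b1", "t1", sep = "_")
  pep <- PeptideSet(a, S4Vectors::DataFrame(
    peptideId = c("p1", "p2"), proteinIds = c("A", "A"),
    unique = c(TRUE, TRUE)),
    S4Vectors::DataFrame(timepoint = tp, biorep = "b1", techrep = "t1"))
  # quantile normalization is a no-op for identical columns? not in
  # general -- check against the normalized peptide row instead
  qn <- limma::normalizeQuantiles(a)
  expect_equal(assay(normalizeAndRollup(pep))["A", ], qn[1, ],
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("presence calls follow the >=2-unique-peptide and 50% rules", {
  pep <- handPeptideSet()
  pres <- presenceAbsence(pep)
  p <- pres$presence
  expect_true(p["protA", "T1"] && p["protA", "T2"])
  expect_true(p["protB", "T1"])
  expect_false("protB" %in% rownames(p) && p["protB", "T2"])
  if ("protC" %in% rownames(p)) expect_false(any(p["protC", ]))
  if ("protD" %in% rownames(p)) expect_false(any(p["protD", ]))
  expect_equal(pres$presentAll, 1L)  # only protA spans both time points

  # monotonicity: lowering the occurrence threshold never removes calls
  loose <- presenceAbsence(pep, minDatasetFraction = 0.25)$presence
  common <- intersect(rownames(p), rownames(loose))
  expect_true(all(loose[common, ] >= p[common, ]))
})

test_that("no missingness means every simulated protein is present", {
  cfg <- smallConfig(nGenes = 40, seed = 33, missingRate = 0)
  truth <- generateGroundTruth(cfg)
  expr <- generateExpression(truth, cfg)
  pep <- generatePeptides(expr$protein, cfg)
  # restrict to proteins with >= 2 unique peptides (1-peptide proteins
  # can never satisfy the identification rule)
  protOf <- sub(";.*", "", as.character(rowData(pep)$proteinIds))
  eligible <- names(which(table(protOf[rowData(pep)$unique]) >= 2))
  pres <- presenceAbsence(pep)
  expect_true(all(eligible %in% rownames(pres$presence)))
  expect_true(all(pres$presence[eligible, ]))
})

test_that("progressive differential testing flags planted shifts", {
  # planted 1 log10 unit shift at T4 with tight replicates
  set.seed(4)
  tp <- rep(c("T1", "T2", "T3", "T4"), each = 3)
  br <- rep(paste0("b", 1:3), 4)
  m <- matrix(rnorm(2 * 12, 5, 0.05), 2, 12,
              dimnames = list(c("shifted", "flat"),
                              paste(tp, br, sep = "_")))
  m["shifted", tp == "T4"] <- m["shifted", tp == "T4"] + 1
  se <- dielExperiment(m, timepoint = tp, biorep = br)
  diff <- progressiveDifferential(se)
  hit <- diff[diff$protein == "shifted" & diff$comparison == "T3 vs T4", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$direction, "up")
  expect_lt(hit$p, 0.05)

  # identical replicate values: no significance, no crash
  m2 <- matrix(5, 1, 12, dimnames = list("const", colnames(m)))
  se2 <- dielExperiment(m2, timepoint = tp, biorep = br)
  expect_equal(nrow(progressiveDifferential(se2)), 0L)

  # alpha = 1 reports every testable protein-comparison
  diffAll <- progressiveDifferential(se, alpha = 1)
  expect_equal(nrow(diffAll), 2 * 4)

  # fewer than 2 replicates is an error
  se3 <- dielExperiment(m[, c(1, 4, 7, 10), drop = FALSE],
                        timepoint = c("T1", "T2", "T3", "T4"),
                        biorep = rep("b1", 4))
  expect_error(progressiveDifferential(se3), "2 biological replicates")
})
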