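# End-to-end orchestration of the synthetic-study analysis: simulate ->
# proteome prep -> correlation classes -> pathway concordance -> consensus
# clustering -> sequence features -> abundance models -> HPTR.

# Co-expression "pathways" from the planted structure: genes sharing a
# delay class and a phase quadrant rise and fall together.
truthGeneSets <- function(truth, minSize = 3L, maxSets = 40L) {
  bin <- paste(truth$delayClass,
               cut(truth$phase, breaks = seq(0, 2 * pi, length.out = 5L),
                   include.lowest = TRUE, labels = FALSE), sep = "_q")
  sets <- split(truth$gene, bin)
  sets <- sets[lengths(sets) >= minSize]
  head(sets, maxSets)
}

#' Run the full diel multi-omics pipeline on a simulated study
#'
#' Generates a synthetic study from `config`, then runs every analysis
#' stage in dependency order with seeds fanned out from the configuration
#' seed, returning a consolidated summary plus the per-stage objects.
#'
#' @param config A [SimulationConfig-class].
#' @param stages Character subset of
#'   `c("prep", "classes", "concordance", "cluster", "features", "model",
#'   "hptr")`; earlier stages a later stage depends on are added
#'   automatically.
#' @param nPerm Permutations for the class-count null (default 1000).
#' @param nBoot Re-shuffles for partial-correlation p-values (default 200).
#' @param kRange,k Consensus-clustering controls.
#' @param clusterGenes Number of most-variable genes clustered (default
#'   200).
#' @param folds Cross-validation folds (default 5 at pipeline scale).
#' @param maxTerms Forward-pass limit passed to [fitMars()].
#' @param doRefit Run the HPTR refit evaluation (default TRUE).
#' @param outdir Optional directory for TSV/JSON outputs.
#' @return A list with `summary` (plain scalars/vectors) and the stage
#'   objects (`sim`, `prep`, `classes`, `concordance`, `clustering`,
#'   `features`, `model`, `hptr`).
#' @export
runPipeline <- function(config,
                        stages = c("prep", "classes", "concordance",
                                   "cluster", "features", "model", "hptr"),
                        nPerm = 1000, nBoot = 200, kRange = 2:6, k = NULL,
                        clusterGenes = 200, folds = 5, maxTerms = NULL,
                        doRefit = TRUE, outdir = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  known <- c("prep", "classes", "concordance", "cluster", "features",
             "model", "hptr")
  badStage <- setdiff(stages, known)
  if (length(badStage))
    stop("unknown stage(s): ", paste(badStage, collapse = ", "))
  need <- function(s) s %in% stages
  if (need("hptr")) stages <- union(stages, c("model"))
  if (need("model")) stages <- union(stages, c("features"))
  seed <- config@seed
  summary <- list(seed = seed, nGenes = config@nGenes)
  out <- list(config = config)

  gen <- generateSequences(config)
  expr <- generateExpression(gen$truth, config)
  pep <- generatePeptides(expr$protein, config)
  out$sim <- list(sequences = gen$sequences, truth = gen$truth,
                  expression = expr, peptides = pep)
  truth <- gen$truth

  mrnaTp <- timepointMeans(expr$mrna)
  protTpDirect <- timepointMeans(expr$protein)

  if (need("prep")) {
    filt <- filterPeptides(pep)
    protTp <- normalizeAndRollup(filt, level = "timepoint")
    protReps <- normalizeAndRollup(filt, level = "biorep")
    pres <- presenceAbsence(pep)
    diff <- progressiveDifferential(protReps)
    out$prep <- list(filtered = filt, proteinTimepoint = protTp,
                     proteinReps = protReps, presence = pres,
                     differential = diff)
    summary$nProteinsQuantified <- nrow(protTp)
    summary$nPresentAllTimepoints <- pres$presentAll
    summary$nDifferential <- nrow(diff)
    protForAnalysis <- protTp
  } else {
    protForAnalysis <- protTpDirect
  }

  if (need("classes")) {
    jp <- zscoreProfiles(mrnaTp, protForAnalysis)
    classes <- assignCorrelationClasses(jp)
    pooled <- pooledCorrelations(mrnaTp, protForAnalysis,
                                 referenceTimepoint = "T3")
    permTest <- permutationClassTest(jp, nPerm = nPerm, seed = seed + 11L)
    out$classes <- list(profiles = jp, assignments = classes,
                        pooled = pooled, permutation = permTest)
    frac <- as.numeric(table(classes$class)) / nrow(classes)
    names(frac) <- levels(classes$class)
    summary$pooledSpearman <- pooled$pooled
    summary$logRatioSpearman <- pooled$logRatio
    summary$classFractions <- frac
    summary$classP <- permTest$p
  }

  if (need("concordance")) {
    sets <- truthGeneSets(truth)
    genes <- intersect(rownames(mrnaTp), rownames(protForAnalysis))
    sets <- lapply(sets, intersect, genes)
    sets <- sets[lengths(sets) >= 3L]
    conc <- pathwayConcordance(mrnaTp[genes, ], protForAnalysis[genes, ],
                               sets)
    out$concordance <- conc
    summary$nPathways <- nrow(conc)
    summary$nConcordantPositive <- sum(conc$esMrna > 0 & conc$esProt > 0)
    summary$meanConcordance <- mean(conc$cs)
  }

  if (need("cluster")) {
    genes <- intersect(rownames(mrnaTp), rownames(protForAnalysis))
    joint <- buildJointMatrix(mrnaTp[genes, ], protForAnalysis[genes, ])
    keep <- head(order(-apply(joint, 1L, var)), clusterGenes)
    cc <- consensusCluster(joint[sort(keep), , drop = FALSE],
                           kRange = kRange, seed = seed + 13L, k = k)
    out$clustering <- cc
    summary$chosenK <- cc@k
    summary$nTightClusters <- sum(cc@withinCor >= 0.75, na.rm = TRUE)
  }

  if (need("features")) {
    ft <- assembleFeatureTable(gen$sequences, mrna = mrnaTp)
    out$features <- ft
    summary$nIncompleteFeatureGenes <- sum(ft@incomplete)
  }

  if (need("model")) {
    ft <- out$features
    model <- fitAbundanceModels(ft, mrnaTp, protTpDirect, doCv = TRUE,
                                folds = folds, seed = seed + 17L,
                                maxTerms = maxTerms)
    mrnaOnly <- fitAbundanceModels(ft, mrnaTp, protTpDirect,
                                   subset = "mrnaOnly", doCv = FALSE,
                                   maxTerms = maxTerms)
    pc <- featureProteinPartialCorrelations(
      featureValues(ft)[, c("cds_CAI", "utr5_MFE"), drop = FALSE],
      mrnaTp, protTpDirect, nBoot = nBoot, seed = seed + 19L)
    out$model <- list(full = model, mrnaOnly = mrnaOnly,
                      partialCorrelations = pc)
    summary$r2Resub <- model$r2
    summary$r2Cv <- model$r2cv
    summary$r2ResubMrnaOnly <- mrnaOnly$r2
    summary$partialCorCai <- pc$partial["cds_CAI", ]
    summary$partialCorUtr5Mfe <- pc$partial["utr5_MFE", ]
  }

  if (need("hptr")) {
    model <- out$model$full
    hptr <- identifyHptr(model$residuals)
    detected <- hptrGenes(hptr)
    planted <- truth$gene[truth$hptr]
    plantedInModel <- intersect(planted, model$genes)
    sens <- if (length(plantedInModel))
      length(intersect(detected, plantedInModel)) / length(plantedInModel)
    else NA_real_
    prec <- if (length(detected))
      length(intersect(detected, plantedInModel)) / length(detected)
    else NA_real_
    out$hptr <- list(result = hptr, sensitivity = sens, precision = prec)
    summary$nHptr <- length(detected)
    summary$hptrSensitivity <- sens
    summary$hptrPrecision <- prec
    if (doRefit && length(detected)) {
      refit <- refitExcludingHptr(out$features, mrnaTp, protTpDirect, hptr,
                                  folds = folds, seed = seed + 23L,
                                  nBootP = 200, maxTerms = maxTerms)
      out$hptr$refit <- refit
      summary$refitDeltaR2cv <- refit$delta
      summary$refitMeanRelativeImprovement <- refit$meanRelativeImprovement
      summary$refitPImprovement <- refit$pImprovement
    }
  }

  out$summary <- summary
  if (!is.null(outdir)) writePipelineOutputs(out, outdir)
  out
}

writePipelineOutputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(out$classes)) {
    write.table(as.data.frame(out$classes$assignments),
                file.path(outdir, "correlation_classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$concordance)) {
    write.table(out$concordance, file.path(outdir, "concordance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(out$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
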