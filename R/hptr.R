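# HPTR gene identification from cross-model residual quantiles, refit
# evaluation, feature distribution tests, convex pseudo-data balancing and
# elastic-net classifiers scored by the balanced success rate.

#' Identify hypothetically post-transcriptionally regulated genes
#'
#' Per per-time-point model, flags genes whose residual
#' (predicted - observed) lies above the `upperQ` quantile (over-estimated)
#' or below the `lowerQ` quantile (under-estimated). Genes flagged in at
#' least `minModels` models are HPTR, partitioned by the dominant tail
#' (ties excluded): above the upper quantile means the models over-estimate
#' the protein, giving HPTR+.
#'
#' @param residuals Gene x model matrix of residuals (`predicted -
#'   observed`), e.g. from [fitAbundanceModels()].
#' @param lowerQ,upperQ Residual quantiles (defaults 0.05, 0.95).
#' @param minModels Minimum number of flagging models (default 2).
#' @return An [HptrResult-class].
#' @export
identifyHptr <- function(residuals, lowerQ = 0.05, upperQ = 0.95,
                         minModels = 2L) {
  residuals <- as.matrix(residuals)
  nm <- ncol(residuals)
  if (nm < 2L) stop("residuals from >= 2 models are required")
  if (minModels > nm) stop("minModels exceeds the number of models")
  qs <- apply(residuals, 2L, quantile, probs = c(lowerQ, upperQ),
              na.rm = TRUE)
  high <- sweep(residuals, 2L, qs[2L, ], ">")
  low <- sweep(residuals, 2L, qs[1L, ], "<")
  high[is.na(high)] <- FALSE
  low[is.na(low)] <- FALSE
  nHigh <- rowSums(high)
  nLow <- rowSums(low)
  flagged <- (nHigh + nLow) >= minModels
  dom <- sign(nHigh - nLow)
  plus <- rownames(residuals)[flagged & dom > 0]
  minus <- rownames(residuals)[flagged & dom < 0]
  new("HptrResult",
      quantiles = DataFrame(model = colnames(residuals),
                            lower = qs[1L, ], upper = qs[2L, ]),
      nHigh = setNames(as.integer(nHigh), rownames(residuals)),
      nLow = setNames(as.integer(nLow), rownames(residuals)),
      plus = plus, minus = minus, minModels = as.integer(minModels))
}

#' Refit abundance models excluding HPTR genes
#'
#' Refits the per-time-point models on non-HPTR genes and quantifies the
#' cross-validation improvement: per-time-point delta R-squared, the mean
#' relative improvement, and a gene-resampling p-value for the mean delta
#' (bootstrap over the shared non-HPTR genes' pooled out-of-fold
#' predictions). Optionally evaluates both model sets on held-out genes
#' never used in training.
#'
#' @param features,mrna,protein As in [fitAbundanceModels()].
#' @param hptr An [HptrResult-class].
#' @param heldoutGenes Optional character vector of genes excluded from
#'   training (must not overlap the training set of the original models).
#' @param folds,seed Cross-validation controls.
#' @param nBootP Resamples for the improvement p-value (default 1000).
#' @param ... Passed to [fitAbundanceModels()] (e.g. `maxTerms`).
#' @return A list: `r2cvOriginal`, `r2cvRefit`, `delta`,
#'   `meanRelativeImprovement`, `pImprovement`, and (when `heldoutGenes`
#'   given) `heldout` with per-time-point R-squared of both model sets.
#' @export
refitExcludingHptr <- function(features, mrna, protein, hptr,
                               heldoutGenes = NULL, folds = 10, seed = 1L,
                               nBootP = 1000, ...) {
  stopifnot(is(hptr, "HptrResult"))
  hptrSet <- hptrGenes(hptr)
  fv <- featureValues(features)
  complete <- rownames(fv)[!features@incomplete]
  m <- asAbundanceMatrix(mrna)
  p <- asAbundanceMatrix(protein)
  universe <- Reduce(intersect, list(complete, rownames(m), rownames(p)))
  if (!is.null(heldoutGenes)) {
    trainGenes <- setdiff(universe, heldoutGenes)
  } else trainGenes <- universe
  keepTrain <- function(genes) {
    ft <- features
    ft@incomplete <- ft@incomplete | !(names(ft@incomplete) %in% genes)
    ft
  }
  orig <- fitAbundanceModels(keepTrain(trainGenes), mrna, protein,
                             doCv = TRUE, folds = folds, seed = seed, ...)
  nonHptr <- setdiff(trainGenes, hptrSet)
  if (length(nonHptr) < 30L)
    stop("removing HPTR genes leaves fewer than 30 training genes")
  if (length(hptrSet) == 0L) {
    refit <- orig
  } else {
    refit <- fitAbundanceModels(keepTrain(nonHptr), mrna, protein,
                                doCv = TRUE, folds = folds, seed = seed, ...)
  }
  delta <- refit$r2cv - orig$r2cv
  rel <- mean(delta / pmax(abs(orig$r2cv), 1e-8))

  # gene-resampling p for the mean CV improvement, via pooled OOF errors
  tp <- names(orig$r2cv)
  shared <- intersect(orig$genes, refit$genes)
  oofErr <- function(fit) {
    err <- matrix(NA_real_, length(shared), length(tp),
                  dimnames = list(shared, tp))
    for (t in seq_along(tp)) {
      X <- cbind(mrna = m[fit$genes, t],
                 fv[fit$genes, setdiff(fit$predictors, "mrna"),
                    drop = FALSE])
      y <- p[fit$genes, t]
      cv <- crossValidate(X, y, if (fit$engine == "mars")
        function(x, yy) fitMars(x, yy, ...) else fitGlmModel,
        folds = folds, seed = seed + t)
      err[intersect(shared, fit$genes), t] <-
        (cv$pred - y)[match(intersect(shared, fit$genes), fit$genes)]
    }
    err
  }
  pImp <- NA_real_
  if (length(hptrSet) > 0L && nBootP > 0) {
    eO <- oofErr(orig)
    eR <- oofErr(refit)
    yShared <- p[shared, tp, drop = FALSE]
    bootDelta <- withSeed(seed + 99L, {
      vapply(seq_len(nBootP), function(b) {
        idx <- sample.int(length(shared), replace = TRUE)
        d <- 0
        for (t in seq_along(tp)) {
          tss <- sum((yShared[idx, t] - mean(yShared[idx, t]))^2)
          if (tss <= 0) next
          d <- d + (sum(eO[idx, t]^2, na.rm = TRUE) -
                      sum(eR[idx, t]^2, na.rm = TRUE)) / tss
        }
        d / length(tp)
      }, numeric(1))
    })
    pImp <- (1 + sum(bootDelta <= 0)) / (1 + nBootP)
  }

  out <- list(r2cvOriginal = orig$r2cv, r2cvRefit = refit$r2cv,
              delta = delta, meanRelativeImprovement = rel,
              pImprovement = pImp, original = orig, refit = refit)
  if (!is.null(heldoutGenes)) {
    if (length(intersect(heldoutGenes, orig$genes)))
      stop("held-out genes overlap the training set")
    hg <- Reduce(intersect, list(heldoutGenes, complete, rownames(m),
                                 rownames(p)))
    if (length(hg) >= 3L) {
      evalOn <- function(fit) {
        vapply(seq_along(tp), function(t) {
          X <- cbind(mrna = m[hg, t],
                     fv[hg, setdiff(fit$predictors, "mrna"), drop = FALSE])
          y <- p[hg, t]
          pred <- predict(fit$models[[t]], X)
          tss <- sum((y - mean(y))^2)
          if (tss > 0) 1 - sum((y - pred)^2) / tss else NA_real_
        }, numeric(1))
      }
      out$heldout <- list(genes = hg,
                          r2Original = setNames(evalOn(orig), tp),
                          r2Refit = setNames(evalOn(refit), tp))
    }
  }
  out
}

#' Wilcoxon tests of feature distributions, HPTR vs non-HPTR
#'
#' Two-sided rank-sum test per feature with Bonferroni adjustment;
#' all-missing or constant features are skipped with a warning.
#'
#' @param features A [FeatureTable-class] or numeric matrix.
#' @param hptrLabels Logical (or two-level factor) per gene, `TRUE` = HPTR.
#' @return data.frame: feature, p, padj.
#' @export
featureDistributionTests <- function(features, hptrLabels) {
  fv <- if (is(features, "FeatureTable")) featureValues(features)
        else as.matrix(features)
  lab <- as.logical(hptrLabels)
  if (!is.null(names(hptrLabels))) {
    fv <- fv[names(hptrLabels), , drop = FALSE]
  }
  if (!any(lab) || all(lab)) stop("both groups must be non-empty")
  ps <- rep(NA_real_, ncol(fv))
  for (f in seq_len(ncol(fv))) {
    a <- fv[lab, f]
    b <- fv[!lab, f]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b) || sd(c(a, b)) < 1e-12) {
      warning("skipping feature with no usable values: ", colnames(fv)[f])
      next
    }
    ps[f] <- suppressWarnings(wilcox.test(a, b)$p.value)
  }
  data.frame(feature = colnames(fv), p = ps,
             padj = pmin(1, ps * sum(!is.na(ps))))
}

#' Balance a minority class with convex pseudo-data
#'
#' Repeatedly draws two distinct minority samples `a`, `b` and a mixing
#' coefficient `lambda ~ Uniform(0, 1)`, emitting `lambda a +
#' (1 - lambda) b` until `targetN` rows are reached.
#'
#' @param x Numeric matrix of minority-class samples (>= 2 rows).
#' @param targetN Desired total number of rows.
#' @param seed Integer seed.
#' @return `x` with pseudo-samples appended (rownames `csd1`, `csd2`, ...).
#' @export
balanceWithCsd <- function(x, targetN, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("minority class needs >= 2 samples")
  if (targetN < nrow(x)) {
    warning("targetN below current size; returning input unchanged")
    return(x)
  }
  nNew <- targetN - nrow(x)
  if (nNew == 0L) return(x)
  withSeed(seed, {
    pseudo <- t(vapply(seq_len(nNew), function(i) {
      ab <- sample.int(nrow(x), 2L)
      lam <- runif(1)
      lam * x[ab[1L], ] + (1 - lam) * x[ab[2L], ]
    }, numeric(ncol(x))))
    rownames(pseudo) <- paste0("csd", seq_len(nNew))
    rbind(x, pseudo)
  })
}

#' Balanced success rate
#'
#' `SR_c = TP_c / (TP_c + FN_c)` per class; `BSR = (SR_1 + SR_2) / 2`
#' (chance level 0.5 for two classes, regardless of class imbalance).
#'
#' @param tp1,fn1,tp2,fn2 Per-class true-positive and false-negative
#'   counts.
#' @return The BSR, a real in `[0, 1]`.
#' @export
#' @examples
#' balancedSuccessRate(8, 2, 6, 4)  # (0.8 + 0.6) / 2 = 0.7
balancedSuccessRate <- function(tp1, fn1, tp2, fn2) {
  if (tp1 + fn1 == 0 || tp2 + fn2 == 0) stop("empty class")
  (tp1 / (tp1 + fn1) + tp2 / (tp2 + fn2)) / 2
}

#' Elastic-net HPTR classifier with CSD balancing
#'
#' Balances the minority class with convex pseudo-data, fits a binomial
#' elastic-net linear classifier (regularization strength by 10-fold
#' cross-validated deviance), evaluates the balanced success rate on
#' out-of-fold predictions, and estimates a permutation p-value for the
#' BSR by label shuffling with full refits.
#'
#' @param x Gene x feature numeric matrix (complete cases).
#' @param labels Two-level factor/character per row (e.g. `"non-HPTR"` vs
#'   `"HPTR+"`).
#' @param seed Integer seed.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param nfolds Folds for `cv.glmnet` (default 10).
#' @param nPerm Label shufflings for the BSR p-value (default 100; 0
#'   disables).
#' @return A list: `bsr`, `sr` (per class), `confusion`, `pBsr`,
#'   `coefficients`, `lambda`.
#' @export
trainHptrClassifiers <- function(x, labels, seed = 1L, alpha = 0.5,
                                 nfolds = 10, nPerm = 100) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly two classes are required")
  n1 <- sum(labels == lev[1L])
  n2 <- sum(labels == lev[2L])
  minority <- if (n1 < n2) lev[1L] else lev[2L]
  target <- max(n1, n2)

  fitOnce <- function(lab, sd) {
    xm <- x[lab == minority, , drop = FALSE]
    xb <- rbind(x[lab != minority, , drop = FALSE],
                balanceWithCsd(xm, target, seed = sd))
    yb <- c(rep(0, target), rep(1, target))
    cv <- withSeed(sd, glmnet::cv.glmnet(xb, yb, family = "binomial",
                                         alpha = alpha, nfolds = nfolds,
                                         type.measure = "deviance",
                                         keep = TRUE))
    iLam <- match(cv$lambda.min, cv$lambda)
    oof <- cv$fit.preval[, iLam] > 0
    tpNeg <- sum(!oof & yb == 0); fnNeg <- sum(oof & yb == 0)
    tpPos <- sum(oof & yb == 1); fnPos <- sum(!oof & yb == 1)
    list(bsr = balancedSuccessRate(tpNeg, fnNeg, tpPos, fnPos),
         sr = c(tpNeg / (tpNeg + fnNeg), tpPos / (tpPos + fnPos)),
         confusion = c(TP1 = tpNeg, FN1 = fnNeg, TP2 = tpPos, FN2 = fnPos),
         cv = cv)
  }
  obs <- fitOnce(labels, seed)
  pBsr <- NA_real_
  if (nPerm > 0) {
    nullBsr <- withSeed(seed + 1L, {
      vapply(seq_len(nPerm), function(i) {
        fitOnce(sample(labels), seed + 1L + i)$bsr
      }, numeric(1))
    })
    pBsr <- (1 + sum(nullBsr >= obs$bsr)) / (1 + nPerm)
  }
  list(bsr = obs$bsr,
       sr = setNames(obs$sr, c("class0", "class1")),
       classes = c(class0 = setdiff(lev, minority), class1 = minority),
       confusion = obs$confusion, pBsr = pBsr,
       coefficients = as.matrix(coef(obs$cv, s = "lambda.min")),
       lambda = obs$cv$lambda.min)
}
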