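# Feature screening by (partial) correlation with bootstrap significance,
# and per-time-point protein abundance models (MARS and GLM) with
# resubstitution and cross-validated R-squared.

#' Feature-mRNA Spearman correlations per time point
#'
#' @param features A [FeatureTable-class].
#' @param mrna Time-point-level mRNA expression.
#' @return Matrix feature x time point of pairwise-complete Spearman rho;
#'   constant features give `NA` with a warning.
#' @export
featureMrnaCorrelations <- function(features, mrna) {
  fv <- featureValues(features)
  m <- asAbundanceMatrix(mrna)
  genes <- intersect(rownames(fv), rownames(m))
  if (length(genes) < 10L) stop("need >= 10 genes with matched values")
  fv <- fv[genes, , drop = FALSE]
  m <- m[genes, , drop = FALSE]
  constant <- apply(fv, 2L, function(v) sd(v, na.rm = TRUE) < 1e-12 ||
                      all(is.na(v)))
  if (any(constant))
    warning("constant feature(s) give NA correlations: ",
            paste(head(colnames(fv)[constant], 5L), collapse = ", "))
  out <- suppressWarnings(cor(fv, m, use = "pairwise.complete.obs",
                              method = "spearman"))
  out[constant, ] <- NA_real_
  out
}

# First-order partial correlation from the three pairwise correlations.
partialFromPairwise <- function(rfp, rfm, rpm) {
  (rfp - rfm * rpm) / sqrt((1 - rfm^2) * (1 - rpm^2))
}

#' Feature-protein partial correlations given mRNA
#'
#' First-order partial correlation on rank-transformed values
#' (Spearman-flavoured; `method = "pearson"` uses raw values):
#' `r_fp.m = (r_fp - r_fm r_pm) / sqrt((1 - r_fm^2)(1 - r_pm^2))`.
#' The bootstrap null re-shuffles the gene labels of the feature vector
#' while keeping the (mRNA, protein) tuples intact; the two-sided
#' empirical p uses the add-one estimator.
#'
#' @param features A [FeatureTable-class] (or numeric gene x feature
#'   matrix).
#' @param mrna,protein Time-point-level expression with matched genes.
#' @param nBoot Number of re-shuffles (default 10000).
#' @param seed Integer seed.
#' @param method `"spearman"` (ranks, default) or `"pearson"`.
#' @return A list of matrices (feature x time point): `partial`, `p`,
#'   plus `nBoot`.
#' @export
featureProteinPartialCorrelations <- function(features, mrna, protein,
                                              nBoot = 10000, seed = 1L,
                                              method = c("spearman",
                                                         "pearson")) {
  method <- match.arg(method)
  fv <- if (is(features, "FeatureTable")) featureValues(features)
        else as.matrix(features)
  m <- asAbundanceMatrix(mrna)
  p <- asAbundanceMatrix(protein)
  genes <- Reduce(intersect, list(rownames(fv), rownames(m), rownames(p)))
  fv <- fv[genes, , drop = FALSE]
  m <- m[genes, , drop = FALSE]
  p <- p[genes, , drop = FALSE]
  tp <- colnames(m)
  partial <- pval <- matrix(NA_real_, ncol(fv), ncol(m),
                            dimnames = list(colnames(fv), tp))
  withSeed(seed, {
    for (t in seq_along(tp)) {
      for (f in seq_len(ncol(fv))) {
        ok <- !is.na(fv[, f]) & !is.na(m[, t]) & !is.na(p[, t])
        if (sum(ok) < 5L) next
        fx <- fv[ok, f]; mx <- m[ok, t]; px <- p[ok, t]
        if (method == "spearman") {
          fx <- rank(fx); mx <- rank(mx); px <- rank(px)
        }
        rfm <- cor(fx, mx)
        rpm <- cor(px, mx)
        if (abs(rfm) >= 1 - 1e-12 || abs(rpm) >= 1 - 1e-12)
          stop("collinear with mRNA: ",
               if (abs(rfm) >= 1 - 1e-12) colnames(fv)[f] else "protein")
        obs <- partialFromPairwise(cor(fx, px), rfm, rpm)
        partial[f, t] <- obs
        if (nBoot > 0) {
          nullv <- vapply(seq_len(nBoot), function(b) {
            fs <- fx[sample.int(length(fx))]
            partialFromPairwise(cor(fs, px), cor(fs, mx), rpm)
          }, numeric(1))
          pval[f, t] <- (1 + sum(abs(nullv) >= abs(obs))) / (1 + nBoot)
        }
      }
    }
  })
  list(partial = partial, p = pval, nBoot = nBoot)
}

#' Fit per-time-point protein abundance models
#'
#' For each time point, fits a model of (time-point-averaged) protein
#' log10 abundance on the same-time-point mRNA abundance plus sequence
#' features, over complete-feature genes. `subset` reproduces the
#' constrained variants: `"full"` (mRNA + all features), `"mrnaCai"`
#' (mRNA + CAI) and `"mrnaOnly"`.
#'
#' @param features A [FeatureTable-class].
#' @param mrna,protein Time-point-level expression with matched genes.
#' @param subset Predictor subset (see above).
#' @param engine `"mars"` (default) or `"glm"`.
#' @param doCv Also compute 10-fold cross-validated R-squared.
#' @param folds,seed Cross-validation controls.
#' @param ... Passed to [fitMars()].
#' @return A list of class `abundanceModelSet`: per-time-point `models`,
#'   `residuals` (predicted - observed; genes x time points), `r2`
#'   (resubstitution), `r2cv` (if requested), `genes` used, `predictors`.
#' @export
fitAbundanceModels <- function(features, mrna, protein,
                               subset = c("full", "mrnaCai", "mrnaOnly"),
                               engine = c("mars", "glm"), doCv = FALSE,
                               folds = 10, seed = 1L, ...) {
  subset <- match.arg(subset)
  engine <- match.arg(engine)
  fv <- featureValues(features)
  m <- asAbundanceMatrix(mrna)
  p <- asAbundanceMatrix(protein)
  complete <- rownames(fv)[!features@incomplete]
  genes <- Reduce(intersect, list(complete, rownames(m), rownames(p)))
  if (length(genes) < 30L) stop("need >= 30 complete-case genes")
  fv <- fv[genes, , drop = FALSE]
  keepF <- switch(subset,
                  full = colnames(fv),
                  mrnaCai = "cds_CAI",
                  mrnaOnly = character())
  # guard against residual missingness in the retained columns
  fv <- fv[, keepF, drop = FALSE]
  tp <- colnames(m)
  models <- vector("list", length(tp))
  names(models) <- tp
  resid <- matrix(NA_real_, length(genes), length(tp),
                  dimnames = list(genes, tp))
  r2 <- r2cv <- setNames(rep(NA_real_, length(tp)), tp)
  fitFun <- if (engine == "mars") function(x, y) fitMars(x, y, ...)
            else function(x, y) fitGlmModel(x, y)
  for (t in seq_along(tp)) {
    X <- cbind(mrna = m[genes, t], fv)
    y <- p[genes, t]
    ok <- complete.cases(X, y)
    fit <- fitFun(X[ok, , drop = FALSE], y[ok])
    pred <- predict(fit, X[ok, , drop = FALSE])
    resid[ok, t] <- pred - y[ok]
    r2[t] <- fit$r2
    models[[t]] <- fit
    if (doCv)
      r2cv[t] <- crossValidate(X[ok, , drop = FALSE], y[ok], fitFun,
                               folds = folds, seed = seed + t)$r2cv
  }
  structure(list(models = models, residuals = resid, r2 = r2,
                 r2cv = if (doCv) r2cv else NULL, genes = genes,
                 predictors = c("mrna", keepF), engine = engine,
                 subset = subset),
            class = "abundanceModelSet")
}

#' @export
print.abundanceModelSet <- function(x, ...) {
  cat("Protein abundance models (", x$engine, ", subset=", x$subset, ") over ",
      length(x$genes), " genes\n", sep = "")
  cat("  resubstitution R^2:",
      paste(names(x$r2), round(x$r2, 3), sep = "=", collapse = " "), "\n")
  if (!is.null(x$r2cv))
    cat("  cross-validated R^2:",
        paste(names(x$r2cv), round(x$r2cv, 3), sep = "=", collapse = " "),
        "\n")
  invisible(x)
}
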