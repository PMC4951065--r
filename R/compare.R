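# z-scored joint profiles, pooled correlations, delay-aware correlation
# classes and the permutation null on class counts.

#' z-score matched mRNA and protein profiles
#'
#' Standardizes each gene's across-time-point profile to mean 0, SD 1
#' (sample SD), independently per data type. Constant profiles are flagged
#' and excluded from class assignment.
#'
#' @param mrna,protein Time-point-level expression (`SummarizedExperiment`
#'   or matrix) sharing a gene set and time-point columns.
#' @return A `SummarizedExperiment` with assays `mrna` and `protein`
#'   (z-profiles; `NA` rows where constant) and a logical `constant` flag
#'   in `rowData`.
#' @export
zscoreProfiles <- function(mrna, protein) {
  m <- asAbundanceMatrix(mrna)
  p <- asAbundanceMatrix(protein)
  genes <- intersect(rownames(m), rownames(p))
  if (!length(genes)) stop("mrna and protein share no genes")
  if (ncol(m) != ncol(p)) stop("time-point columns do not match")
  m <- m[genes, , drop = FALSE]
  p <- p[genes, , drop = FALSE]
  zm <- rowZscore(m)
  zp <- rowZscore(p)
  constant <- attr(zm, "constant") | attr(zp, "constant")
  se <- SummarizedExperiment(assays = list(mrna = unclass(zm)[, , drop = FALSE],
                                           protein = unclass(zp)[, , drop = FALSE]),
                             rowData = DataFrame(constant = constant))
  rownames(se) <- genes
  colnames(se) <- colnames(m)
  metadata(se)$timepoints <- timepointLabels(mrna)
  se
}

#' Pooled and log-ratio mRNA-protein correlations
#'
#' Spearman correlation over all (gene, time point) pairs pooled, per time
#' point, and on log10 ratios of each non-reference time point to a
#' reference time point (the matrices are log10 scale, so ratios are
#' column differences).
#'
#' @param mrna,protein Time-point-level expression with matching genes.
#' @param referenceTimepoint Column used as the ratio reference.
#' @return A list: `pooled`, `perTimepoint`, `logRatio` (all Spearman).
#' @export
pooledCorrelations <- function(mrna, protein, referenceTimepoint = "T3") {
  m <- asAbundanceMatrix(mrna)
  p <- asAbundanceMatrix(protein)
  genes <- intersect(rownames(m), rownames(p))
  m <- m[genes, , drop = FALSE]
  p <- p[genes, , drop = FALSE]
  ok <- !is.na(m) & !is.na(p)
  if (sum(ok) < 3L) stop("fewer than 3 pooled (gene, time point) pairs")
  pooled <- cor(m[ok], p[ok], method = "spearman")
  perTp <- vapply(seq_len(ncol(m)), function(j) {
    cor(m[, j], p[, j], use = "pairwise.complete.obs", method = "spearman")
  }, numeric(1))
  names(perTp) <- colnames(m)
  if (!referenceTimepoint %in% colnames(m))
    stop("reference time point not present: ", referenceTimepoint)
  others <- setdiff(colnames(m), referenceTimepoint)
  lm_ <- m[, others, drop = FALSE] - m[, referenceTimepoint]
  lp_ <- p[, others, drop = FALSE] - p[, referenceTimepoint]
  ok2 <- !is.na(lm_) & !is.na(lp_)
  logRatio <- cor(lm_[ok2], lp_[ok2], method = "spearman")
  list(pooled = pooled, perTimepoint = perTp, logRatio = logRatio)
}

# Delay-resolved Pearson correlations between z-profiles: column k + 1
# holds R between the mRNA profile and the protein profile circularly
# shifted back by k time points.
delayCorrelations <- function(zm, zp) {
  T <- ncol(zm)
  R <- vapply(0:(T - 1L), function(k) {
    rowSums(zm * rotateCols(zp, k)) / (T - 1L)
  }, numeric(nrow(zm)))
  if (!is.matrix(R)) R <- matrix(R, nrow = nrow(zm))
  colnames(R) <- paste0("delay", 0:(T - 1L))
  rownames(R) <- rownames(zm)
  R
}

classifyFromR <- function(R, high, low) {
  n <- nrow(R)
  T <- ncol(R)
  hits <- abs(R) > high
  anyHit <- rowSums(hits) > 0L
  k <- max.col(hits, ties.method = "first")        # first qualifying delay
  kBest <- max.col(abs(R), ties.method = "first")  # fallback: largest |R|
  sel <- ifelse(anyHit, k, kBest)
  bestR <- R[cbind(seq_len(n), sel)]
  pos <- bestR > 0
  cls <- ifelse(anyHit,
                ifelse(sel == 1L,
                       ifelse(pos, "correlated", "anti-correlated"),
                       sprintf("delayed-%d-%s", sel - 1L,
                               ifelse(pos, "correlated", "anticorrelated"))),
                ifelse(abs(R[, 1L]) <= low, "low", "unclassified"))
  list(class = cls, bestDelay = sel - 1L, R = bestR)
}

correlationClassLevels <- function(T) {
  c("correlated", "anti-correlated",
    as.vector(rbind(sprintf("delayed-%d-correlated", seq_len(T - 1L)),
                    sprintf("delayed-%d-anticorrelated", seq_len(T - 1L)))),
    "low", "unclassified")
}

#' Assign mRNA-protein correlation classes
#'
#' For each delay k in `0..T-1`, computes the Pearson correlation between a
#' gene's mRNA z-profile and its protein z-profile circularly shifted back
#' by k. The exclusive class is given by the smallest delay whose `|R|`
#' exceeds `high` (the sign separating correlated from anti-correlated);
#' genes with no qualifying delay are `low` when `|R|` at delay 0 is at
#' most `low`, otherwise `unclassified`.
#'
#' @param profiles Joint z-profiles from [zscoreProfiles()].
#' @param high Magnitude threshold for (anti-)correlation (default 0.75).
#' @param low Magnitude threshold at delay 0 below which a gene is `low`
#'   (default 0.1).
#' @return A [S4Vectors::DataFrame] (gene, bestDelay, R, class);
#'   `metadata()$R` holds the full gene x delay correlation matrix.
#' @export
assignCorrelationClasses <- function(profiles, high = 0.75, low = 0.1) {
  T <- ncol(profiles)
  if (T < 3L) stop("at least 3 time points are required")
  keep <- !rowData(profiles)$constant
  zm <- assays(profiles)$mrna[keep, , drop = FALSE]
  zp <- assays(profiles)$protein[keep, , drop = FALSE]
  R <- delayCorrelations(zm, zp)
  cl <- classifyFromR(R, high, low)
  out <- DataFrame(gene = rownames(zm), bestDelay = cl$bestDelay,
                   R = cl$R,
                   class = factor(cl$class,
                                  levels = correlationClassLevels(T)),
                   row.names = rownames(zm))
  metadata(out)$R <- R
  metadata(out)$thresholds <- c(high = high, low = low)
  out
}

#' Permutation null for correlation-class counts
#'
#' Shuffles the gene labels of the protein z-profiles relative to the mRNA
#' z-profiles, reassigns classes, and records class counts per permutation.
#' The empirical p per class is the add-one two-sided estimator
#' `(1 + #(|count - null mean| >= |observed - null mean|)) / (1 + nPerm)`.
#'
#' @param profiles Joint z-profiles from [zscoreProfiles()].
#' @param nPerm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param high,low Class thresholds as in [assignCorrelationClasses()].
#' @return A list: `observed` (named counts), `p` (named empirical
#'   p-values), `null` (permutation x class count matrix), `nPerm`.
#' @export
permutationClassTest <- function(profiles, nPerm = 10000, seed = 1L,
                                 high = 0.75, low = 0.1) {
  keep <- !rowData(profiles)$constant
  zm <- assays(profiles)$mrna[keep, , drop = FALSE]
  zp <- assays(profiles)$protein[keep, , drop = FALSE]
  n <- nrow(zm)
  if (n < 2L) stop("at least 2 genes are required")
  if (nPerm < 100L) warning("fewer than 100 permutations is unreliable")
  T <- ncol(zm)
  lev <- correlationClassLevels(T)
  countClasses <- function(zpx) {
    cl <- classifyFromR(delayCorrelations(zm, zpx), high, low)$class
    table(factor(cl, levels = lev))
  }
  observed <- countClasses(zp)
  nullCounts <- withSeed(seed, {
    t(vapply(seq_len(nPerm), function(i) {
      as.integer(countClasses(zp[sample.int(n), , drop = FALSE]))
    }, integer(length(lev))))
  })
  colnames(nullCounts) <- lev
  center <- colMeans(nullCounts)
  p <- vapply(seq_along(lev), function(j) {
    (1 + sum(abs(nullCounts[, j] - center[j]) >=
               abs(observed[j] - center[j]))) / (1 + nPerm)
  }, numeric(1))
  names(p) <- lev
  list(observed = observed, p = p, null = nullCounts, nPerm = nPerm)
}
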