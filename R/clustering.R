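# Consensus co-expression clustering of the concatenated z-scored
# mRNA+protein matrix and hypergeometric cluster enrichment.

#' Concatenate row-standardized mRNA and protein matrices
#'
#' Rows (genes) of each molecular expression matrix are z-transformed
#' independently (sample SD), then the two matrices are concatenated
#' column-wise, giving one row of length `2 * nTimepoints` per gene.
#' Constant rows are flagged via the `"constant"` attribute.
#'
#' @param mrna,protein Time-point-level expression with a shared gene set.
#' @return A numeric matrix, genes x (mRNA time points, protein time
#'   points).
#' @export
buildJointMatrix <- function(mrna, protein) {
  m <- asAbundanceMatrix(mrna)
  p <- asAbundanceMatrix(protein)
  genes <- intersect(rownames(m), rownames(p))
  zm <- rowZscore(m[genes, , drop = FALSE])
  zp <- rowZscore(p[genes, , drop = FALSE])
  constant <- attr(zm, "constant") | attr(zp, "constant")
  joint <- cbind(unclass(zm), unclass(zp))
  colnames(joint) <- c(paste0("mrna_", colnames(m)),
                       paste0("protein_", colnames(p)))
  attr(joint, "constant") <- constant
  joint
}

# Area under the empirical CDF of the upper-triangle consensus values.
consensusCdfArea <- function(cons) {
  v <- sort(cons[upper.tri(cons)])
  if (!length(v)) return(0)
  grid <- seq(0, 1, length.out = 101L)
  cdf <- vapply(grid, function(g) mean(v <= g), numeric(1))
  sum(diff(grid) * cdf[-1L])
}

#' Consensus clustering with a PAM base learner
#'
#' For each candidate k, runs `nIter` PAM (partitioning around medoids,
#' Euclidean distance) clusterings on random gene subsamples; the
#' consensus entry for a gene pair is its co-clustering count divided by
#' its co-sampling count. Final labels come from average-linkage
#' hierarchical clustering of `1 - consensus` cut at k. Unless fixed by
#' the user, k is chosen by the consensus-CDF delta-area criterion. Also
#' reports each cluster's mean within-cluster pairwise Pearson
#' correlation (the >= 0.75 quality screen used downstream).
#'
#' @param joint Gene x feature matrix from [buildJointMatrix()].
#' @param kRange Candidate cluster numbers (default `2:6`).
#' @param nIter Subsampled PAM runs per k (default 100).
#' @param subsample Gene fraction per run (default 0.8).
#' @param seed Integer seed.
#' @param k Optional fixed number of clusters (skips selection).
#' @return A [ConsensusClusteringResult-class].
#' @export
consensusCluster <- function(joint, kRange = 2:6, nIter = 100,
                             subsample = 0.8, seed = 1L, k = NULL) {
  const <- attr(joint, "constant")
  if (!is.null(const) && any(const, na.rm = TRUE))
    joint <- joint[!const, , drop = FALSE]
  n <- nrow(joint)
  ks <- if (is.null(k)) sort(unique(as.integer(kRange))) else as.integer(k)
  if (any(ks < 2L) || any(ks > n - 1L))
    stop("kRange must lie within [2, nGenes - 1]")
  if (n < max(ks) * 3L)
    stop("need at least 3 genes per candidate cluster")
  nSub <- max(2L, round(subsample * n))
  consOf <- withSeed(seed, {
    lapply(ks, function(kk) {
      co <- matrix(0, n, n)
      both <- matrix(0, n, n)
      for (it in seq_len(nIter)) {
        idx <- sort(sample.int(n, nSub))
        lab <- cluster::pam(joint[idx, , drop = FALSE], k = kk,
                            metric = "euclidean",
                            cluster.only = TRUE, pamonce = 5)
        both[idx, idx] <- both[idx, idx] + 1
        same <- outer(lab, lab, "==")
        co[idx, idx] <- co[idx, idx] + same
      }
      cons <- ifelse(both > 0, co / both, 0)
      diag(cons) <- 1
      cons
    })
  })
  areas <- vapply(consOf, consensusCdfArea, numeric(1))
  delta <- numeric(length(ks))
  if (length(ks)) {
    delta[1L] <- areas[1L]
    if (length(ks) > 1L)
      delta[-1L] <- diff(areas) / pmax(areas[-length(areas)], 1e-12)
  }
  pick <- if (!is.null(k)) 1L else which.max(delta)
  cons <- consOf[[pick]]
  kSel <- ks[pick]
  rownames(cons) <- colnames(cons) <- rownames(joint)
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  labels <- stats::cutree(hc, k = kSel)
  withinCor <- vapply(seq_len(kSel), function(cl) {
    rows <- which(labels == cl)
    if (length(rows) < 2L) return(NA_real_)
    C <- cor(t(joint[rows, , drop = FALSE]))
    mean(C[upper.tri(C)])
  }, numeric(1))
  new("ConsensusClusteringResult", consensus = cons,
      labels = setNames(as.integer(labels), rownames(joint)),
      k = kSel,
      kTrace = DataFrame(k = ks, cdfArea = areas, deltaArea = delta),
      withinCor = withinCor)
}

#' Hypergeometric cluster enrichment
#'
#' One-sided upper-tail hypergeometric test of the overlap between every
#' cluster and every gene set (both intersected with the universe), with
#' Bonferroni correction over all tests performed.
#'
#' @param labels Named cluster labels (e.g. [clusterLabels()]).
#' @param sets Named list of gene sets.
#' @param universe Gene universe; defaults to the labelled genes.
#' @return A data.frame: cluster, set, overlap, clusterSize, setSize, p,
#'   padj.
#' @export
clusterEnrichment <- function(labels, sets, universe = names(labels)) {
  if (!length(universe)) stop("empty universe")
  labels <- labels[names(labels) %in% universe]
  sets <- lapply(sets, intersect, universe)
  N <- length(universe)
  res <- list()
  for (cl in sort(unique(labels))) {
    inCl <- names(labels)[labels == cl]
    for (s in names(sets)) {
      gs <- sets[[s]]
      ov <- length(intersect(inCl, gs))
      p <- phyper(ov - 1L, length(gs), N - length(gs), length(inCl),
                  lower.tail = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        cluster = cl, set = s, overlap = ov,
        clusterSize = length(inCl), setSize = length(gs), p = p)
    }
  }
  out <- do.call(rbind, res)
  out$padj <- pmin(1, out$p * nrow(out))
  out
}
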