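# Gene-pair correlation ranking, pathway pair sets, the GSEA running-sum
# enrichment score and the mRNA/protein concordance score.

pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Pairwise gene-gene expression correlations
#'
#' Pearson correlation of the across-time profiles of every unordered gene
#' pair, ranked descending. Constant profiles are excluded with a warning.
#'
#' @param expr Time-point-level expression (`SummarizedExperiment` or
#'   matrix) with at least 3 time points.
#' @return A data.frame (`pair`, `gene1`, `gene2`, `score`) sorted by
#'   decreasing correlation.
#' @export
pairwiseGeneCorrelations <- function(expr) {
  m <- asAbundanceMatrix(expr)
  if (ncol(m) < 3L) stop("at least 3 time points are required")
  sds <- apply(m, 1L, sd)
  if (any(sds < 1e-12)) {
    warning(sum(sds < 1e-12), " constant profile(s) excluded")
    m <- m[sds >= 1e-12, , drop = FALSE]
  }
  C <- cor(t(m))
  idx <- which(upper.tri(C), arr.ind = TRUE)
  out <- data.frame(gene1 = rownames(C)[idx[, 1]],
                    gene2 = rownames(C)[idx[, 2]],
                    score = C[idx])
  out$pair <- pairKey(out$gene1, out$gene2)
  out[order(-out$score), c("pair", "gene1", "gene2", "score")]
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set id, description, then gene ids.
#'
#' @param path Path to the GMT file.
#' @return A named list of character gene-id vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": expected at least 3 tab-separated ",
           "fields, found ", length(f))
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  sets
}

#' Expand pathway gene sets to gene-pair sets
#'
#' Each pathway is intersected with the analyzed gene universe and
#' converted to all unordered pairs of its remaining genes; pathways with
#' fewer than 2 analyzed genes are dropped with a warning.
#'
#' @param sets Named list of gene-id vectors (e.g. from [readGmt()]).
#' @param universe Character vector of analyzed gene ids.
#' @return A named list of pair-key character vectors.
#' @export
expandPathwaysToPairs <- function(sets, universe) {
  out <- lapply(sets, function(g) {
    g <- sort(intersect(g, universe))
    if (length(g) < 2L) return(NULL)
    idx <- utils::combn(g, 2L)
    pairKey(idx[1L, ], idx[2L, ])
  })
  dropped <- vapply(out, is.null, logical(1))
  if (any(dropped))
    warning("dropped ", sum(dropped),
            " pathway(s) with fewer than 2 analyzed genes: ",
            paste(head(names(out)[dropped], 5L), collapse = ", "))
  out[!dropped]
}

#' GSEA running-sum enrichment score
#'
#' Walks the ranked list; at a hit the running sum increases by
#' `|score|^p` normalized by the sum of `|score|^p` over hits, at a miss it
#' decreases by `1/(N - Nhits)`. The enrichment score is the signed maximum
#' deviation from zero. `p = 1` is the weighted statistic (the default of
#' the original GSEA application); `p = 0` is the classic Kolmogorov-
#' Smirnov-style statistic.
#'
#' @param ranked data.frame from [pairwiseGeneCorrelations()] (columns
#'   `pair` and `score`, sorted by decreasing score).
#' @param pairset Character vector of pair keys (a member of the output of
#'   [expandPathwaysToPairs()]); must be a subset of `ranked$pair`.
#' @param p Weight exponent (default 1).
#' @return The enrichment score, a real in `[-1, 1]`.
#' @export
gseaEnrichmentScore <- function(ranked, pairset, p = 1) {
  if (!length(pairset)) stop("empty pair set")
  hit <- ranked$pair %in% pairset
  N <- nrow(ranked)
  Nh <- sum(hit)
  if (Nh == 0L) stop("pair set has no overlap with the ranked list")
  if (Nh == N) stop("pair set equals the whole ranked universe")
  w <- abs(ranked$score)^p
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (N - Nh)
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Pathway concordance score
#'
#' `CS_p = sign(ES_mRNA) * sign(ES_prot) * |ES_mRNA| * |ES_prot|`, the
#' signed product of a pathway's enrichment scores in the two data types
#' (`sign(0) = 0`, so the score is 0 whenever either enrichment is 0).
#'
#' @param esMrna,esProt Enrichment scores in `[-1, 1]`.
#' @return The concordance score in `[-1, 1]`.
#' @export
#' @examples
#' concordanceScore(0.5, 0.5)   #  0.25
#' concordanceScore(-0.5, 0.5)  # -0.25
concordanceScore <- function(esMrna, esProt) {
  if (any(abs(c(esMrna, esProt)) > 1))
    stop("enrichment scores must lie in [-1, 1]")
  sign(esMrna) * sign(esProt) * abs(esMrna) * abs(esProt)
}

#' Pathway-level mRNA/protein concordance
#'
#' Ranks gene pairs by expression correlation separately for mRNA and
#' protein, scores every pathway pair set in both rankings, and reports the
#' concordance score per pathway.
#'
#' @param mrna,protein Time-point-level expression with matching genes.
#' @param sets Named list of pathway gene sets.
#' @param p Weight exponent passed to [gseaEnrichmentScore()].
#' @return A data.frame: pathway, nPairs, esMrna, esProt, cs.
#' @export
pathwayConcordance <- function(mrna, protein, sets, p = 1) {
  genes <- intersect(rownames(asAbundanceMatrix(mrna)),
                     rownames(asAbundanceMatrix(protein)))
  rankedM <- pairwiseGeneCorrelations(asAbundanceMatrix(mrna)[genes, ])
  rankedP <- pairwiseGeneCorrelations(asAbundanceMatrix(protein)[genes, ])
  pairSets <- expandPathwaysToPairs(sets, genes)
  res <- lapply(names(pairSets), function(pw) {
    esM <- gseaEnrichmentScore(rankedM, pairSets[[pw]], p = p)
    esP <- gseaEnrichmentScore(rankedP, pairSets[[pw]], p = p)
    data.frame(pathway = pw, nPairs = length(pairSets[[pw]]),
               esMrna = esM, esProt = esP,
               cs = concordanceScore(esM, esP))
  })
  do.call(rbind, res)
}
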