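# Sequence-derived features: codon adaptation index, minimum free energy of
# folding, composition, lengths, amino-acid classes and isoelectric point.

# Sense codons excluded from CAI: single-codon amino acids and stops.
caiExcludedCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc %in% c("M", "W", "*")]
}

#' Relative codon adaptiveness from reference counts
#'
#' `w(codon) = freq / max freq` among synonymous codons in the reference
#' set; zero counts receive a 0.5 pseudocount before normalization.
#'
#' @param referenceCodonCounts Named numeric vector of codon counts over
#'   the 64 codons (missing codons count 0).
#' @return Named numeric vector of `w` values over the 64 codons.
#' @export
codonAdaptiveness <- function(referenceCodonCounts) {
  gc <- Biostrings::GENETIC_CODE
  cnt <- setNames(numeric(length(gc)), names(gc))
  common <- intersect(names(referenceCodonCounts), names(cnt))
  cnt[common] <- referenceCodonCounts[common]
  cnt[cnt == 0] <- 0.5
  w <- cnt
  for (aa in unique(gc)) {
    fam <- names(gc)[gc == aa]
    w[fam] <- cnt[fam] / max(cnt[fam])
  }
  w
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness `w` of a gene's codons,
#' excluding Met, Trp and stop codons. A gene with no remaining codons
#' (e.g. a bare start codon) yields `NA`.
#'
#' @param cds A [Biostrings::DNAStringSet], character vector of coding
#'   sequences, or a [GeneSequenceSet-class].
#' @param referenceCodonCounts Reference codon counts (see
#'   [codonAdaptiveness()]).
#' @return Numeric CAI per gene, in `(0, 1]`.
#' @export
computeCai <- function(cds, referenceCodonCounts) {
  if (is(cds, "GeneSequenceSet")) cds <- cds(cds)
  if (!is(cds, "DNAStringSet")) cds <- DNAStringSet(cds)
  if (any(width(cds) %% 3L != 0L))
    stop("CDS length not divisible by 3")
  counts <- oligonucleotideFrequency(cds, width = 3L, step = 3L)
  aaPerCodon <- Biostrings::GENETIC_CODE[colnames(counts)]
  internalStops <- counts[, aaPerCodon == "*", drop = FALSE]
  # one terminal stop is expected; more indicates an internal stop
  if (any(rowSums(internalStops) > 1L))
    stop("internal stop codon in CDS")
  w <- codonAdaptiveness(referenceCodonCounts)[colnames(counts)]
  usable <- !(colnames(counts) %in% caiExcludedCodons())
  cu <- counts[, usable, drop = FALSE]
  nCodons <- rowSums(cu)
  cai <- exp(as.vector(cu %*% log(w[usable])) / nCodons)
  cai[nCodons == 0] <- NA_real_
  setNames(cai, names(cds))
}

#' Codon counts of a reference gene set
#'
#' Sums codon usage over the given genes; the conventional reference set is
#' the top expression decile when no curated set is available.
#'
#' @param cds Coding sequences ([Biostrings::DNAStringSet] or
#'   [GeneSequenceSet-class]).
#' @param genes Optional gene ids to restrict to.
#' @return Named codon count vector.
#' @export
referenceCodonCounts <- function(cds, genes = NULL) {
  if (is(cds, "GeneSequenceSet")) cds <- cds(cds)
  if (!is.null(genes)) cds <- cds[genes]
  colSums(oligonucleotideFrequency(cds, width = 3L, step = 3L))
}

#' Minimum free energy of RNA folding
#'
#' Default engine: dynamic-programming minimum-energy folding with per-pair
#' energies GC = -3, AU = -2, GU = -1, hairpin loops of at least 3 unpaired
#' bases, and no pseudoknots. T is mapped to U before folding; the energy
#' of the empty structure is 0, so results are always `<= 0`. An external
#' thermodynamic folder can be plugged in via `engine` (a function mapping
#' a character vector of RNA sequences to energies).
#'
#' @param seq Character vector (DNA or RNA) or an `XStringSet`.
#' @param engine Optional replacement folding function.
#' @return Numeric energy per sequence (kcal/mol-like score).
#' @export
#' @examples
#' computeMfe("AAAAAAAAAA")  # 0: no pairs possible
#' computeMfe("GGGAAAACCC")  # -9: three GC pairs around the loop
computeMfe <- function(seq, engine = NULL) {
  s <- as.character(seq)
  if (!is.null(engine)) return(engine(s))
  bad <- grepl("[^ACGTUacgtu]", s)
  if (any(bad, na.rm = TRUE))
    stop("non-ACGTU characters in sequence(s): ",
         paste(head(which(bad), 5L), collapse = ", "))
  .nussinovEnergy(s)
}

aaClassMembers <- function() {
  list(acidic = c("D", "E"),
       basic = c("K", "R", "H"),
       polar = c("S", "T", "N", "Q", "Y", "C"),
       nonpolar = c("A", "V", "L", "I", "P", "M", "F", "W", "G"),
       aromatic = c("F", "W", "Y"),
       aliphatic = c("A", "V", "L", "I"))
}

# pKa values (Lehninger-style) used by the isoelectric-point bisection.
pkaTable <- function() {
  c(Nterm = 9.6, Cterm = 2.34,
    D = 3.65, E = 4.25, C = 8.3, Y = 10.07,
    H = 6.0, K = 10.53, R = 12.48)
}

#' Hypothetical isoelectric point
#'
#' Solves net charge = 0 by bisection on the Henderson-Hasselbalch charge
#' function with the package's fixed pKa table ([pkaTable()]): positive
#' groups N-terminus, H, K, R; negative groups C-terminus, D, E, C, Y.
#'
#' @param protein Character vector or `AAStringSet` of protein sequences.
#' @param tol Bisection tolerance in pH units (default 1e-4).
#' @return Numeric pI per sequence.
#' @export
#' @examples
#' isoelectricPoint("GG")  # ~ (9.6 + 2.34) / 2 = 5.97
isoelectricPoint <- function(protein, tol = 1e-4) {
  if (!is(protein, "AAStringSet")) protein <- AAStringSet(as.character(protein))
  af <- alphabetFrequency(protein)
  pka <- pkaTable()
  posNames <- c("H", "K", "R")
  negNames <- c("D", "E", "C", "Y")
  nPos <- cbind(Nterm = rep(1, length(protein)),
                af[, posNames, drop = FALSE])
  nNeg <- cbind(Cterm = rep(1, length(protein)),
                af[, negNames, drop = FALSE])
  pkPos <- pka[c("Nterm", posNames)]
  pkNeg <- pka[c("Cterm", negNames)]
  charge <- function(ph) {
    pos <- rowSums(nPos / (1 + 10^(outer(ph, pkPos, "-"))))
    neg <- rowSums(nNeg / (1 + 10^(outer(ph, pkNeg, function(p, k) k - p))))
    pos - neg
  }
  lo <- rep(0, length(protein))
  hi <- rep(14, length(protein))
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    up <- charge(mid) > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  setNames((lo + hi) / 2, names(protein))
}

# Proportion features of one DNA region for a whole set; zero-width
# entries give NA (absent region), not zero.
regionComposition <- function(dna, prefix) {
  mono <- alphabetFrequency(dna)[, c("A", "C", "G", "T"), drop = FALSE]
  tot <- rowSums(mono)
  prop <- mono / tot
  gc <- (mono[, "G"] + mono[, "C"]) / tot
  di <- oligonucleotideFrequency(dna, width = 2L, step = 1L)
  diTot <- rowSums(di)
  diProp <- di / diTot
  colnames(diProp) <- paste0("di", colnames(diProp))
  out <- cbind(prop, GC = gc, diProp, length = width(dna))
  out[tot == 0, setdiff(colnames(out), "length")] <- NA_real_
  out[width(dna) == 0, "length"] <- NA_real_
  colnames(out) <- paste(prefix, colnames(out), sep = "_")
  out
}

#' Composition, length and physicochemical features
#'
#' Per gene computes, for each applicable region (CDS, 5' UTR, 3' UTR and
#' the full transcript 5'UTR+CDS+3'UTR): mononucleotide proportions, GC,
#' the 16 overlapping dinucleotide proportions, and lengths; plus GC3 over
#' CDS third codon positions, relative CDS length, the 20 amino-acid
#' proportions, amino-acid class proportions (acidic, basic, polar,
#' non-polar, aromatic, aliphatic) and the hypothetical isoelectric point.
#' Features of an absent UTR are missing, not zero.
#'
#' @param seqs A [GeneSequenceSet-class].
#' @return A list: `values` (gene x feature matrix) and `info`
#'   (feature/region/category metadata `DataFrame`).
#' @export
computeCompositionFeatures <- function(seqs) {
  stopifnot(is(seqs, "GeneSequenceSet"))
  n <- length(seqs)
  cdsChr <- as.character(cds(seqs))
  u5 <- utr5(seqs)
  u3 <- utr3(seqs)
  u5[!seqs@utr5Complete] <- DNAStringSet("")[rep(1, sum(!seqs@utr5Complete))]
  mrna <- DNAStringSet(paste0(as.character(u5), cdsChr, as.character(u3)))
  names(mrna) <- names(seqs)

  blocks <- list(cds = regionComposition(cds(seqs), "cds"),
                 utr5 = regionComposition(u5, "utr5"),
                 utr3 = regionComposition(u3, "utr3"),
                 mrna = regionComposition(mrna, "mrna"))

  gc3 <- vapply(cdsChr, function(s) {
    third <- substring(s, seq(3L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    mean(third %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
  relCds <- width(cds(seqs)) / width(mrna)

  aaFreq <- alphabetFrequency(proteinSeqs(seqs))
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
  aaProp <- aaFreq[, aa20, drop = FALSE] / rowSums(aaFreq[, aa20, drop = FALSE])
  colnames(aaProp) <- paste0("aa_", aa20)
  cls <- aaClassMembers()
  clsProp <- vapply(cls, function(members) {
    rowSums(aaProp[, paste0("aa_", members), drop = FALSE])
  }, numeric(n))
  if (!is.matrix(clsProp)) clsProp <- matrix(clsProp, nrow = n)
  colnames(clsProp) <- paste0("aaclass_", names(cls))

  values <- cbind(do.call(cbind, unname(blocks)),
                  cds_GC3 = gc3, cds_relLength = relCds,
                  aaProp, clsProp,
                  protein_pI = isoelectricPoint(proteinSeqs(seqs)))
  rownames(values) <- names(seqs)

  feat <- colnames(values)
  region <- sub("_.*$", "", feat)
  region[feat %in% c("cds_GC3", "cds_relLength")] <- "cds"
  region[startsWith(feat, "aa")] <- "protein"
  region[feat == "protein_pI"] <- "protein"
  category <- rep("nucleotide/dinucleotide composition", length(feat))
  category[grepl("_length$|_relLength$", feat)] <- "length"
  category[startsWith(feat, "aa_")] <- "amino-acid proportion"
  category[startsWith(feat, "aaclass_")] <- "amino-acid class proportion"
  category[feat == "protein_pI"] <- "physicochemical"
  category[feat == "cds_GC3"] <- "codon usage"
  list(values = values,
       info = DataFrame(feature = feat, region = region, category = category))
}

#' Assemble the full sequence-feature table
#'
#' Combines composition/length/physicochemical features with folding
#' energies (5' UTR, 3' UTR and the first 50 CDS nucleotides), the codon
#' adaptation index (reference set: codon counts of the top expression
#' decile unless `refCounts` is supplied), and optional user binary
#' annotations (e.g. predicted chloroplast localization, introner-element
#' status). Genes missing any required feature - typically because a UTR
#' is absent - are flagged incomplete and excluded later from model
#' training.
#'
#' @param seqs A [GeneSequenceSet-class].
#' @param annotations Optional data.frame/DataFrame of per-gene flags
#'   (rownames = gene ids).
#' @param mrna Optional expression used to pick the CAI reference decile.
#' @param refCounts Optional explicit reference codon counts (overrides
#'   `mrna`).
#' @param mfeEngine Optional replacement folding engine for [computeMfe()].
#' @return A [FeatureTable-class].
#' @export
assembleFeatureTable <- function(seqs, annotations = NULL, mrna = NULL,
                                 refCounts = NULL, mfeEngine = NULL) {
  stopifnot(is(seqs, "GeneSequenceSet"))
  genes <- names(seqs)
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  comp <- computeCompositionFeatures(seqs)

  u5c <- as.character(utr5(seqs))
  u3c <- as.character(utr3(seqs))
  cdsChr <- as.character(cds(seqs))
  mfe5 <- ifelse(seqs@utr5Complete & nchar(u5c) > 0,
                 computeMfe(ifelse(nchar(u5c) > 0, u5c, "A"),
                            engine = mfeEngine), NA_real_)
  mfe3 <- ifelse(seqs@utr3Complete & nchar(u3c) > 0,
                 computeMfe(ifelse(nchar(u3c) > 0, u3c, "A"),
                            engine = mfeEngine), NA_real_)
  mfeCds50 <- computeMfe(substr(cdsChr, 1L, 50L), engine = mfeEngine)

  if (is.null(refCounts)) {
    if (!is.null(mrna)) {
      expr <- rowMeans(asAbundanceMatrix(mrna), na.rm = TRUE)
      expr <- expr[intersect(names(expr), genes)]
      top <- names(expr)[expr >= quantile(expr, 0.9)]
      refCounts <- referenceCodonCounts(seqs, genes = top)
    } else {
      refCounts <- referenceCodonCounts(seqs)
    }
  }
  cai <- computeCai(cds(seqs), refCounts)

  values <- cbind(comp$values,
                  utr5_MFE = unname(mfe5), utr3_MFE = unname(mfe3),
                  cds_MFE50 = unname(mfeCds50), cds_CAI = unname(cai))
  info <- rbind(comp$info,
                DataFrame(feature = c("utr5_MFE", "utr3_MFE", "cds_MFE50",
                                      "cds_CAI"),
                          region = c("utr5", "utr3", "cds", "cds"),
                          category = c("structure (MFE)", "structure (MFE)",
                                       "structure (MFE)", "codon usage")))
  if (!is.null(annotations)) {
    ann <- as.matrix(as.data.frame(annotations))
    storage.mode(ann) <- "double"
    full <- matrix(NA_real_, length(genes), ncol(ann),
                   dimnames = list(genes, colnames(ann)))
    common <- intersect(rownames(ann), genes)
    full[common, ] <- ann[common, , drop = FALSE]
    values <- cbind(values, full)
    info <- rbind(info, DataFrame(feature = colnames(ann),
                                  region = "gene",
                                  category = "annotation flag"))
  }
  incomplete <- apply(values, 1L, anyNA)
  new("FeatureTable", values = values, info = info,
      incomplete = setNames(incomplete, genes))
}
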