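# Synthetic diel study generator: sequences, matched mRNA/protein expression
# and peptide-level proteomics with known ground truth.

#' Configure the synthetic diel study
#'
#' Defaults emulate the study design this package targets: 4 time points
#' (mid-day, dusk, pre-dawn, lights-on) x 3 biological replicates, protein
#' measured through 4 technical replicates at the peptide level, a planted
#' delay-class mixture matching the reported class fractions, 10% planted
#' HPTR genes, and planted codon-usage and 5' UTR structure effects on
#' protein abundance.
#'
#' @param nGenes Number of genes to simulate.
#' @param nTimepoints,nBioreps,nTechreps Study dimensions.
#' @param delayClassProbs Named probability vector over planted classes
#'   (`delay0..delay{T-1}`, `anti`, `independent`).
#' @param hptrFraction Proportion of genes planted as HPTR.
#' @param hptrDelta Log10 shift separating the HPTR+ / HPTR- tails.
#' @param featureEffects Planted coefficients: `cai` (codon bias ->
#'   protein), `utr5Structure` (5' UTR GC/structure -> protein; negative
#'   means more structure gives less protein) and `mrnaHinge` (hinge
#'   coefficient of the mRNA-protein coupling).
#' @param noiseSdMrna,noiseSdProtein,noiseSdPeptide Noise SDs, log10 units.
#' @param missingRate Peptide-level missingness probability per dataset.
#' @param utrMissingRate Probability that each UTR annotation is absent.
#' @param sharedPeptideRate Fraction of peptides mapping to two proteins.
#' @param seed Integer seed; the same seed reproduces all generator output.
#' @return A validated [SimulationConfig-class] object.
#' @export
#' @examples
#' cfg <- simConfig(nGenes = 50, seed = 7)
simConfig <- function(nGenes,
                      nTimepoints = 4L, nBioreps = 3L, nTechreps = 4L,
                      delayClassProbs = c(delay0 = 0.08, delay1 = 0.26,
                                          delay2 = 0.09, delay3 = 0.02,
                                          anti = 0.16, independent = 0.39),
                      hptrFraction = 0.1, hptrDelta = 3.0,
                      featureEffects = c(cai = 0.5, utr5Structure = -0.5,
                                         mrnaHinge = 0.5),
                      noiseSdMrna = 0.1, noiseSdProtein = 0.15,
                      noiseSdPeptide = 0.2, missingRate = 0.1,
                      utrMissingRate = 0.1, sharedPeptideRate = 0.05,
                      seed = 1L) {
  new("SimulationConfig",
      nGenes = as.integer(nGenes), nTimepoints = as.integer(nTimepoints),
      nBioreps = as.integer(nBioreps), nTechreps = as.integer(nTechreps),
      delayClassProbs = delayClassProbs, hptrFraction = hptrFraction,
      hptrDelta = hptrDelta, featureEffects = featureEffects,
      noiseSdMrna = noiseSdMrna, noiseSdProtein = noiseSdProtein,
      noiseSdPeptide = noiseSdPeptide, missingRate = missingRate,
      utrMissingRate = utrMissingRate, sharedPeptideRate = sharedPeptideRate,
      seed = as.integer(seed))
}

#' Draw the per-gene ground truth of a simulation
#'
#' Samples planted delay classes, HPTR membership (tail sign and mode:
#' independent expression program or coupling with inverted feature
#' effects), codon-bias and 5' UTR structure parameters, sequence lengths,
#' and the diel profile parameters (baseline, fundamental and Nyquist
#' harmonic amplitudes, phase).
#'
#' @param config A [SimulationConfig-class].
#' @return A [S4Vectors::DataFrame] with one row per gene;
#'   `metadata()` carries the planted effect sizes.
#' @export
generateGroundTruth <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@nGenes
  withSeed(config@seed, {
    gene <- sprintf("g%05d", seq_len(n))
    probs <- config@delayClassProbs
    cls <- sample(names(probs), n, replace = TRUE, prob = probs)
    delay <- rep(NA_integer_, n)
    isDelay <- grepl("^delay", cls)
    delay[isDelay] <- as.integer(sub("delay", "", cls[isDelay]))
    nH <- floor(config@hptrFraction * n)
    hptr <- logical(n)
    hptr[sample.int(n, nH)] <- TRUE
    idx <- which(hptr)
    hptrSign <- character(n)
    hptrMode <- character(n)
    if (nH > 0) {
      # both tails and both mechanisms, split evenly
      hptrSign[idx] <- rep_len(c("+", "-"), nH)
      hptrMode[idx] <- rep_len(c("independent", "independent",
                                 "inverted", "inverted"), nH)
    }
    truth <- DataFrame(
      gene = gene, delayClass = cls, delay = delay,
      hptr = hptr, hptrSign = hptrSign, hptrMode = hptrMode,
      codonBias = runif(n, 0.2, 1),
      utr5GC = runif(n, 0.2, 0.8),
      protLen = pmin(pmax(round(rlnorm(n, log(150), 0.35)), 50L), 400L),
      utr5Len = pmin(pmax(round(rlnorm(n, log(50), 0.4)), 10L), 150L),
      utr3Len = pmin(pmax(round(rlnorm(n, log(70), 0.4)), 10L), 150L),
      utr5Present = runif(n) >= config@utrMissingRate,
      utr3Present = runif(n) >= config@utrMissingRate,
      mu = rnorm(n, 2.5, 1.0),
      amp1 = runif(n, 0.4, 0.7),
      amp2 = sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.2, 0.3),
      phase = runif(n, 0, 2 * pi),
      indepAmp1 = runif(n, 0.4, 0.7),
      indepAmp2 = sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.2, 0.3),
      indepPhase = runif(n, 0, 2 * pi),
      row.names = gene)
    metadata(truth) <- list(featureEffects = config@featureEffects,
                            hptrDelta = config@hptrDelta,
                            hingeKnot = 2.5, seed = config@seed)
    truth
  })
}

# Codon machinery shared by the generator and the CAI computation ----------

geneticCodeTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# Deterministic "optimal" codon per amino acid (alphabetically first).
optimalCodons <- function() {
  tab <- geneticCodeTable()
  tab <- tab[names(tab) != "*"]
  vapply(tab, function(x) sort(x)[1], character(1))
}

#' Generate gene sequence records with planted feature structure
#'
#' Coding sequences start with ATG and end in a single stop codon; interior
#' codons are drawn from a gene-specific bias mixture: with probability
#' equal to the gene's planted codon-bias parameter the amino acid's
#' "optimal" codon is used, otherwise a synonymous codon uniformly at
#' random. 5' UTR base composition follows the gene's planted GC/structure
#' parameter (more GC folds to lower minimum free energy); 3' UTRs are
#' T-rich. A configurable fraction of genes lack one or both UTRs.
#'
#' @param config A [SimulationConfig-class].
#' @param truth Optional ground truth from [generateGroundTruth()]; drawn
#'   fresh from `config` when `NULL`.
#' @return A list with elements `sequences` ([GeneSequenceSet-class]) and
#'   `truth`.
#' @export
generateSequences <- function(config, truth = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (is.null(truth)) truth <- generateGroundTruth(config)
  n <- nrow(truth)
  withSeed(config@seed + 1L, {
    synTab <- geneticCodeTable()
    synTab <- synTab[names(synTab) != "*"]
    opt <- optimalCodons()
    aaNames <- names(synTab)

    lens <- truth$protLen - 1L  # interior residues beyond the start Met
    tot <- sum(lens)
    geneOf <- rep.int(seq_len(n), lens)
    aas <- sample(aaNames, tot, replace = TRUE)
    useOpt <- runif(tot) < truth$codonBias[geneOf]
    codon <- opt[aas]
    for (aa in aaNames) {
      i <- which(aas == aa & !useOpt)
      if (length(i))
        codon[i] <- sample(synTab[[aa]], length(i), replace = TRUE)
    }
    stopCodon <- ifelse(runif(n) < truth$codonBias, "TAA",
                        sample(c("TAA", "TAG", "TGA"), n, replace = TRUE))
    body <- vapply(split(codon, factor(geneOf, levels = seq_len(n))),
                   paste, character(1), collapse = "")
    cdsChr <- paste0("ATG", body, stopCodon)
    protChr <- paste0("M", vapply(split(aas, factor(geneOf, levels = seq_len(n))),
                                  paste, character(1), collapse = ""))

    sampleUtr <- function(len, gc, tRich) {
      tot <- sum(len)
      if (tot == 0) return(character(length(len)))
      gOf <- rep.int(seq_along(len), len)
      if (tRich) {
        base <- sample(c("A", "T", "G", "C"), tot, replace = TRUE,
                       prob = c(0.25, 0.40, 0.15, 0.20))
      } else {
        isGC <- runif(tot) < gc[gOf]
        pick <- runif(tot) < 0.5
        base <- ifelse(isGC, ifelse(pick, "G", "C"), ifelse(pick, "A", "T"))
      }
      out <- character(length(len))
      out[len > 0] <- vapply(split(base, factor(gOf, levels = seq_along(len))),
                             paste, character(1), collapse = "")[len > 0]
      out
    }
    u5len <- ifelse(truth$utr5Present, truth$utr5Len, 0L)
    u3len <- ifelse(truth$utr3Present, truth$utr3Len, 0L)
    utr5Chr <- sampleUtr(u5len, truth$utr5GC, tRich = FALSE)
    utr3Chr <- sampleUtr(u3len, NULL, tRich = TRUE)

    gene <- truth$gene
    seqs <- new("GeneSequenceSet",
                cds = DNAStringSet(setNames(cdsChr, gene)),
                utr5 = DNAStringSet(setNames(utr5Chr, gene)),
                utr3 = DNAStringSet(setNames(utr3Chr, gene)),
                protein = AAStringSet(setNames(protChr, gene)),
                utr5Complete = setNames(truth$utr5Present, gene),
                utr3Complete = setNames(truth$utr3Present, gene))
    # realized per-gene scores the planted expression effects act through
    truth$caiScore <- unname(computeCai(seqs@cds, referenceCodonCounts(seqs@cds)))
    truth$utr5Mfe <- ifelse(truth$utr5Present,
                            computeMfe(ifelse(nzchar(utr5Chr), utr5Chr, "A")),
                            NA_real_)
    list(sequences = seqs, truth = truth)
  })
}

# Piecewise-linear mRNA -> protein coupling shared with the documentation.
coupleMrna <- function(m, hinge, knot) 0.2 + 0.8 * m + hinge * pmax(0, m - knot)

#' Generate matched mRNA and protein expression
#'
#' mRNA profiles are diel-periodic: a gene-specific fundamental harmonic
#' plus a Nyquist (twice-daily) component, sampled at the study's time
#' points, with replicate-level Gaussian noise. For non-HPTR genes protein
#' is a linear-plus-hinge function of the (circularly delayed, or
#' mean-reflected for anti-correlated genes) mRNA profile plus the planted
#' sequence-feature offsets; HPTR genes follow an alternate program (an
#' independent profile, or coupling with inverted feature effects) shifted
#' into the tail given by their planted sign.
#'
#' @param truth Ground truth from [generateGroundTruth()].
#' @param config The matching [SimulationConfig-class].
#' @return A list: `mrna` and `protein` (replicate-level
#'   `SummarizedExperiment`s, genes x timepoint/biorep), `trueMrna` and
#'   `trueProtein` (noiseless gene x time point matrices).
#' @export
generateExpression <- function(truth, config) {
  stopifnot(is(config, "SimulationConfig"))
  n <- nrow(truth)
  if (n != config@nGenes) stop("truth and config disagree on the gene count")
  T <- config@nTimepoints
  B <- config@nBioreps
  fe <- config@featureEffects
  feGet <- function(nm) if (nm %in% names(fe)) unname(fe[nm]) else 0
  knot <- metadata(truth)$hingeKnot
  withSeed(config@seed + 2L, {
    theta <- 2 * pi * (0:(T - 1)) / T
    nyq <- if (T %% 2L == 0L) (-1)^(0:(T - 1)) else rep(0, T)
    harmonics <- function(a1, a2, phase) {
      outer(a1, theta, function(a, th) a) * sin(outer(phase, theta, "+")) +
        outer(a2, nyq)
    }
    cleanM <- truth$mu + harmonics(truth$amp1, truth$amp2, truth$phase)
    indep <- truth$mu + harmonics(truth$indepAmp1, truth$indepAmp2,
                                  truth$indepPhase)

    baseP <- cleanM
    for (g in seq_len(n)) {
      cl <- truth$delayClass[g]
      if (cl == "anti") {
        baseP[g, ] <- 2 * truth$mu[g] - cleanM[g, ]
      } else if (cl == "independent") {
        baseP[g, ] <- indep[g, ]
      } else {
        d <- truth$delay[g]
        if (d > 0)
          baseP[g, ] <- cleanM[g, ((seq_len(T) - 1L - d) %% T) + 1L]
      }
    }
    # planted effects act through the realized sequence scores when the
    # truth comes from generateSequences(); latent parameters otherwise
    zscale <- function(v) {
      out <- (v - mean(v, na.rm = TRUE)) / max(sd(v, na.rm = TRUE), 1e-12)
      out[is.na(out)] <- 0
      out
    }
    caiTerm <- if (!is.null(truth$caiScore)) zscale(truth$caiScore)
               else zscale(truth$codonBias)
    structTerm <- if (!is.null(truth$utr5Mfe)) zscale(-truth$utr5Mfe)
                  else zscale(truth$utr5GC)
    featOffset <- feGet("cai") * caiTerm +
      feGet("utr5Structure") * structTerm
    cleanP <- coupleMrna(baseP, feGet("mrnaHinge"), knot) + featOffset

    isH <- truth$hptr
    if (any(isH)) {
      shift <- ifelse(truth$hptrSign == "+", -1, 1) *
        metadata(truth)$hptrDelta
      ind <- isH & truth$hptrMode == "independent"
      inv <- isH & truth$hptrMode == "inverted"
      if (any(ind))
        cleanP[ind, ] <- coupleMrna(indep[ind, , drop = FALSE],
                                    feGet("mrnaHinge"), knot) + shift[ind]
      if (any(inv))
        cleanP[inv, ] <- coupleMrna(baseP[inv, , drop = FALSE],
                                    feGet("mrnaHinge"), knot) -
          featOffset[inv] + shift[inv]
    }

    tp <- paste0("T", seq_len(T))
    colTp <- rep(tp, each = B)
    colBr <- rep(paste0("b", seq_len(B)), times = T)
    expand <- function(clean, sdNoise) {
      m <- clean[, rep(seq_len(T), each = B), drop = FALSE] +
        matrix(rnorm(n * T * B, 0, sdNoise), n, T * B)
      dimnames(m) <- list(truth$gene, paste(colTp, colBr, sep = "_"))
      m
    }
    dimnames(cleanM) <- dimnames(cleanP) <- list(truth$gene, tp)
    list(
      mrna = dielExperiment(expand(cleanM, config@noiseSdMrna),
                            timepoint = colTp, biorep = colBr,
                            datatype = "mrna"),
      protein = dielExperiment(expand(cleanP, config@noiseSdProtein),
                               timepoint = colTp, biorep = colBr,
                               datatype = "protein"),
      trueMrna = cleanM, trueProtein = cleanP)
  })
}

#' Sample a peptide-level table from protein abundances
#'
#' Each protein yields 1-6 peptides; a peptide's log10 abundance is the
#' protein's replicate-level value plus a fixed peptide-specific ionization
#' offset plus technical noise, observed in each instrument dataset
#' (time point x biological replicate x technical replicate) with
#' probability `1 - missingRate`. A configurable fraction of peptides map
#' to a second protein and are flagged non-unique.
#'
#' @param protein Replicate-level protein `SummarizedExperiment` from
#'   [generateExpression()].
#' @param config The matching [SimulationConfig-class].
#' @return A [PeptideSet-class].
#' @export
generatePeptides <- function(protein, config) {
  stopifnot(is(config, "SimulationConfig"))
  cd <- colData(protein)
  if (!all(c("timepoint", "biorep") %in% colnames(cd)))
    stop("protein matrix must have replicate structure (timepoint, biorep)")
  pm <- assay(protein)
  n <- nrow(pm)
  K <- config@nTechreps
  withSeed(config@seed + 3L, {
    nPep <- sample.int(6L, n, replace = TRUE)
    pepOf <- rep.int(seq_len(n), nPep)
    nP <- length(pepOf)
    offset <- rnorm(nP, 0, 0.3)
    shared <- runif(nP) < config@sharedPeptideRate & n > 1L
    other <- vapply(which(shared), function(i) {
      sample(setdiff(seq_len(n), pepOf[i]), 1L)
    }, integer(1))
    proteinIds <- rownames(pm)[pepOf]
    proteinIds[shared] <- paste(proteinIds[shared], rownames(pm)[other],
                                sep = ";")
    nCols <- ncol(pm) * K
    abund <- pm[pepOf, rep(seq_len(ncol(pm)), each = K), drop = FALSE] +
      offset +
      matrix(rnorm(nP * nCols, 0, config@noiseSdPeptide), nP, nCols)
    if (config@missingRate > 0)
      abund[matrix(runif(nP * nCols) < config@missingRate, nP, nCols)] <- NA
    tpC <- rep(as.character(cd$timepoint), each = K)
    brC <- rep(as.character(cd$biorep), each = K)
    tkC <- rep(paste0("t", seq_len(K)), times = ncol(pm))
    pepId <- sprintf("pep%06d", seq_len(nP))
    dimnames(abund) <- list(pepId, paste(tpC, brC, tkC, sep = "_"))
    PeptideSet(abund,
               peptideInfo = DataFrame(peptideId = pepId,
                                       proteinIds = proteinIds,
                                       unique = !shared),
               sampleInfo = DataFrame(timepoint = tpC, biorep = brC,
                                      techrep = tkC))
  })
}

#' Construct a PeptideSet
#'
#' @param abundance Peptide x dataset matrix of log10 abundances (NA where
#'   not observed).
#' @param peptideInfo `DataFrame` with `peptideId`, `proteinIds`
#'   (semicolon-separated) and `unique` columns.
#' @param sampleInfo `DataFrame` with `timepoint`, `biorep`, `techrep`.
#' @return A validated [PeptideSet-class].
#' @export
PeptideSet <- function(abundance, peptideInfo, sampleInfo) {
  se <- SummarizedExperiment(assays = list(abundance = abundance),
                             rowData = peptideInfo, colData = sampleInfo)
  new("PeptideSet", se)
}
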