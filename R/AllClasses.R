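# S4 class definitions for the central data containers.

#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Simulation configuration for the synthetic diel study
#'
#' Holds every knob of the synthetic-data generator: study dimensions
#' (genes, time points, biological and technical replicates), the planted
#' mRNA-protein delay-class mixture, the HPTR (hypothetically
#' post-transcriptionally regulated) fraction, planted sequence-feature
#' effect sizes, log10-scale noise levels, and missingness rates.
#' Construct with [simConfig()].
#'
#' @slot nGenes,nTimepoints,nBioreps,nTechreps Study dimensions.
#' @slot delayClassProbs Named probability vector over the planted classes
#'   `delay0..delay{T-1}`, `anti`, `independent`; sums to 1.
#' @slot hptrFraction Proportion of genes planted as HPTR.
#' @slot hptrDelta Log10 abundance shift separating HPTR tails.
#' @slot featureEffects Named coefficients of the planted effects
#'   (`cai`, `utr5Structure`, `mrnaHinge`).
#' @slot noiseSdMrna,noiseSdProtein,noiseSdPeptide Noise SDs (log10 units).
#' @slot missingRate Per-observation peptide missingness probability.
#' @slot utrMissingRate Probability that a UTR annotation is absent.
#' @slot sharedPeptideRate Fraction of peptides mapping to two proteins.
#' @slot seed Integer seed driving all three generators.
#' @export
setClass("SimulationConfig", representation(
  nGenes = "integer", nTimepoints = "integer", nBioreps = "integer",
  nTechreps = "integer", delayClassProbs = "numeric", hptrFraction = "numeric",
  hptrDelta = "numeric", featureEffects = "numeric", noiseSdMrna = "numeric",
  noiseSdProtein = "numeric", noiseSdPeptide = "numeric",
  missingRate = "numeric", utrMissingRate = "numeric",
  sharedPeptideRate = "numeric", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  cnt <- c(nGenes = object@nGenes, nTimepoints = object@nTimepoints,
           nBioreps = object@nBioreps, nTechreps = object@nTechreps)
  if (any(is.na(cnt)) || any(cnt < 1L))
    msg <- c(msg, "all counts must be >= 1")
  p <- object@delayClassProbs
  allowed <- c(paste0("delay", 0:(max(1L, object@nTimepoints) - 1L)),
               "anti", "independent")
  if (is.null(names(p)) || !all(names(p) %in% allowed))
    msg <- c(msg, paste("delayClassProbs names must be among:",
                        paste(allowed, collapse = ", ")))
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, "delayClassProbs must be non-negative and sum to 1 (tol 1e-9)")
  props <- c(object@hptrFraction, object@missingRate, object@utrMissingRate,
             object@sharedPeptideRate)
  if (any(props < 0 | props > 1))
    msg <- c(msg, "proportions must lie in [0, 1]")
  if (any(c(object@noiseSdMrna, object@noiseSdProtein,
            object@noiseSdPeptide) < 0))
    msg <- c(msg, "noise SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-gene sequence records
#'
#' Stores coding, UTR and protein sequences for a gene set. Absent UTRs are
#' zero-width entries with the corresponding completeness flag set to
#' `FALSE`. Every CDS starts with ATG, has length divisible by 3, and
#' translates (standard code) to the protein followed by a single stop.
#'
#' @slot cds,utr5,utr3 [Biostrings::DNAStringSet] objects, one entry per gene.
#' @slot protein [Biostrings::AAStringSet], one entry per gene.
#' @slot utr5Complete,utr3Complete Logical flags per gene.
#' @export
setClass("GeneSequenceSet", representation(
  cds = "DNAStringSet", utr5 = "DNAStringSet", utr3 = "DNAStringSet",
  protein = "AAStringSet", utr5Complete = "logical", utr3Complete = "logical"
))

setValidity("GeneSequenceSet", function(object) {
  n <- length(object@cds)
  msg <- character()
  if (length(object@utr5) != n || length(object@utr3) != n ||
      length(object@protein) != n || length(object@utr5Complete) != n ||
      length(object@utr3Complete) != n)
    msg <- c(msg, "all slots must have one entry per gene")
  if (n > 0) {
    if (any(width(object@cds) %% 3L != 0L))
      msg <- c(msg, "CDS lengths must be multiples of 3")
    if (any(width(object@cds) < 6L))
      msg <- c(msg, "CDS must contain at least a start and a stop codon")
  }
  if (length(msg)) msg else TRUE
})

#' Peptide-level proteomics table
#'
#' A [SummarizedExperiment::SummarizedExperiment] of peptide log10
#' abundances (assay `"abundance"`, peptides x instrument datasets) with a
#' peptide-to-protein map in `rowData` (`peptideId`, `proteinIds`
#' semicolon-separated, `unique`) and the dataset design in `colData`
#' (`timepoint`, `biorep`, `techrep`).
#'
#' @export
setClass("PeptideSet", contains = "SummarizedExperiment")

setValidity("PeptideSet", function(object) {
  msg <- character()
  rd <- rowData(object)
  need <- c("peptideId", "proteinIds", "unique")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  else {
    nProt <- lengths(strsplit(as.character(rd$proteinIds), ";", fixed = TRUE))
    if (!all(rd$unique == (nProt == 1L)))
      msg <- c(msg, "unique flag must be TRUE iff exactly one protein id")
  }
  cd <- colData(object)
  if (!all(c("timepoint", "biorep", "techrep") %in% colnames(cd)))
    msg <- c(msg, "colData must contain timepoint, biorep, techrep")
  a <- assay(object)
  if (any(!is.finite(a) & !is.na(a)))
    msg <- c(msg, "abundances must be finite where present")
  if (length(msg)) msg else TRUE
})

#' Gene-by-feature table of sequence-derived values
#'
#' Real-valued sequence features per gene plus per-feature metadata
#' (region and category) and a per-gene incompleteness flag (any required
#' feature missing, e.g. because a UTR is absent).
#'
#' @slot values Numeric matrix, genes x features (NA = missing).
#' @slot info `DataFrame` with columns `feature`, `region`, `category`.
#' @slot incomplete Named logical, per gene.
#' @export
setClass("FeatureTable", representation(
  values = "matrix", info = "DataFrame", incomplete = "logical"
))

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (nrow(object@info) != ncol(object@values))
    msg <- c(msg, "info must describe every feature column")
  if (length(object@incomplete) != nrow(object@values))
    msg <- c(msg, "incomplete flag must cover every gene")
  if (length(msg)) msg else TRUE
})

#' Consensus clustering result
#'
#' @slot consensus Symmetric gene-by-gene co-clustering frequency matrix for
#'   the chosen k (values in `[0, 1]`, unit diagonal).
#' @slot labels Named integer cluster labels at the chosen k.
#' @slot k Chosen number of clusters.
#' @slot kTrace `DataFrame` with the consensus-CDF area and delta-area per k.
#' @slot withinCor Mean within-cluster pairwise Pearson correlation per
#'   cluster.
#' @export
setClass("ConsensusClusteringResult", representation(
  consensus = "matrix", labels = "integer", k = "integer",
  kTrace = "DataFrame", withinCor = "numeric"
))

#' HPTR identification result
#'
#' Genes persistently over- or under-estimated by the per-time-point
#' abundance models: residual (predicted - observed) above the upper
#' quantile in `>= minModels` models marks HPTR+ (over-estimated), below the
#' lower quantile HPTR- (under-estimated); genes extreme in opposite tails
#' are assigned to the dominant tail and dropped on ties.
#'
#' @slot quantiles `DataFrame` of per-model lower/upper residual thresholds.
#' @slot nHigh,nLow Named integer counts of extreme-residual models per gene.
#' @slot plus,minus Character vectors of HPTR+ / HPTR- gene ids.
#' @slot minModels Minimum number of flagging models required.
#' @export
setClass("HptrResult", representation(
  quantiles = "DataFrame", nHigh = "integer", nLow = "integer",
  plus = "character", minus = "character", minModels = "integer"
))
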