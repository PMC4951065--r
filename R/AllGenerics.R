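# Generics, accessors and show methods.

#' @rdname GeneSequenceSet-class
#' @param x A `GeneSequenceSet`.
#' @export
setGeneric("cds", function(x) standardGeneric("cds"))
#' @rdname GeneSequenceSet-class
#' @export
setGeneric("utr5", function(x) standardGeneric("utr5"))
#' @rdname GeneSequenceSet-class
#' @export
setGeneric("utr3", function(x) standardGeneric("utr3"))
#' @rdname GeneSequenceSet-class
#' @export
setGeneric("proteinSeqs", function(x) standardGeneric("proteinSeqs"))

#' @rdname GeneSequenceSet-class
#' @export
setMethod("cds", "GeneSequenceSet", function(x) x@cds)
#' @rdname GeneSequenceSet-class
#' @export
setMethod("utr5", "GeneSequenceSet", function(x) x@utr5)
#' @rdname GeneSequenceSet-class
#' @export
setMethod("utr3", "GeneSequenceSet", function(x) x@utr3)
#' @rdname GeneSequenceSet-class
#' @export
setMethod("proteinSeqs", "GeneSequenceSet", function(x) x@protein)

#' @rdname GeneSequenceSet-class
#' @export
setMethod("length", "GeneSequenceSet", function(x) length(x@cds))

#' @rdname GeneSequenceSet-class
#' @export
setMethod("names", "GeneSequenceSet", function(x) names(x@cds))

setMethod("show", "GeneSequenceSet", function(object) {
  cat("GeneSequenceSet with", length(object), "genes\n")
  cat("  5' UTR present:", sum(object@utr5Complete),
      "| 3' UTR present:", sum(object@utr3Complete), "\n")
  cat("  CDS width range:", paste(range(width(object@cds)), collapse = "-"), "\n")
})

#' @rdname FeatureTable-class
#' @param x A `FeatureTable`.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname FeatureTable-class
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))
#' @rdname FeatureTable-class
#' @export
setGeneric("incompleteGenes", function(x) standardGeneric("incompleteGenes"))

#' @rdname FeatureTable-class
#' @export
setMethod("featureValues", "FeatureTable", function(x) x@values)
#' @rdname FeatureTable-class
#' @export
setMethod("featureInfo", "FeatureTable", function(x) x@info)
#' @rdname FeatureTable-class
#' @export
setMethod("incompleteGenes", "FeatureTable",
          function(x) names(x@incomplete)[x@incomplete])

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object@values), "genes x",
      ncol(object@values), "features\n")
  cat("  incomplete genes:", sum(object@incomplete), "\n")
  cat("  categories:",
      paste(unique(object@info$category), collapse = ", "), "\n")
})

#' @rdname ConsensusClusteringResult-class
#' @param x A `ConsensusClusteringResult`.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname ConsensusClusteringResult-class
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))

#' @rdname ConsensusClusteringResult-class
#' @export
setMethod("clusterLabels", "ConsensusClusteringResult", function(x) x@labels)
#' @rdname ConsensusClusteringResult-class
#' @export
setMethod("consensusMatrix", "ConsensusClusteringResult",
          function(x) x@consensus)

setMethod("show", "ConsensusClusteringResult", function(object) {
  cat("ConsensusClusteringResult: k =", object@k, "over",
      length(object@labels), "genes\n")
  cat("  cluster sizes:", paste(tabulate(object@labels), collapse = ", "), "\n")
  cat("  mean within-cluster correlation:",
      paste(round(object@withinCor, 3), collapse = ", "), "\n")
})

#' @rdname HptrResult-class
#' @param x An `HptrResult`.
#' @export
setGeneric("hptrPlus", function(x) standardGeneric("hptrPlus"))
#' @rdname HptrResult-class
#' @export
setGeneric("hptrMinus", function(x) standardGeneric("hptrMinus"))
#' @rdname HptrResult-class
#' @export
setGeneric("hptrGenes", function(x) standardGeneric("hptrGenes"))

#' @rdname HptrResult-class
#' @export
setMethod("hptrPlus", "HptrResult", function(x) x@plus)
#' @rdname HptrResult-class
#' @export
setMethod("hptrMinus", "HptrResult", function(x) x@minus)
#' @rdname HptrResult-class
#' @export
setMethod("hptrGenes", "HptrResult", function(x) c(x@plus, x@minus))

setMethod("show", "HptrResult", function(object) {
  cat("HptrResult:", length(object@plus), "HPTR+ (over-estimated),",
      length(object@minus), "HPTR- (under-estimated)\n")
  cat("  flagged in >=", object@minModels, "per-time-point models\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes,",
      object@nTimepoints, "time points x", object@nBioreps, "bioreps x",
      object@nTechreps, "techreps (seed", paste0(object@seed, ")\n"))
  cat("  delay classes:",
      paste(names(object@delayClassProbs), object@delayClassProbs,
            sep = "=", collapse = " "), "\n")
  cat("  HPTR fraction:", object@hptrFraction,
      "| noise (mRNA/protein/peptide):",
      paste(c(object@noiseSdMrna, object@noiseSdProtein,
              object@noiseSdPeptide), collapse = "/"), "\n")
})
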