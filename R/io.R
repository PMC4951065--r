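# Plain-text readers/writers for the package's standard inputs and outputs.

#' Read a peptide abundance table
#'
#' Expects a TSV with columns `peptide_id`, `protein_ids`
#' (semicolon-separated) followed by one log10-abundance column per
#' instrument dataset (empty/NA = not observed), and a sample sheet TSV
#' with columns `sample_id`, `timepoint`, `biorep`, `techrep`.
#'
#' @param peptidePath,samplePath File paths.
#' @return A [PeptideSet-class].
#' @export
readPeptideTable <- function(peptidePath, samplePath) {
  tab <- read.delim(peptidePath, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!all(c("peptide_id", "protein_ids") %in% colnames(tab)))
    stop("peptide table needs peptide_id and protein_ids columns")
  ss <- read.delim(samplePath, stringsAsFactors = FALSE)
  needed <- c("sample_id", "timepoint", "biorep", "techrep")
  if (!all(needed %in% colnames(ss)))
    stop("sample sheet needs columns: ", paste(needed, collapse = ", "))
  datasets <- as.character(ss$sample_id)
  if (!all(datasets %in% colnames(tab)))
    stop("sample sheet datasets missing from the peptide table: ",
         paste(setdiff(datasets, colnames(tab)), collapse = ", "))
  a <- as.matrix(tab[, datasets, drop = FALSE])
  storage.mode(a) <- "double"
  rownames(a) <- tab$peptide_id
  nProt <- lengths(strsplit(tab$protein_ids, ";", fixed = TRUE))
  PeptideSet(a,
             peptideInfo = DataFrame(peptideId = tab$peptide_id,
                                     proteinIds = tab$protein_ids,
                                     unique = nProt == 1L),
             sampleInfo = DataFrame(timepoint = as.character(ss$timepoint),
                                    biorep = as.character(ss$biorep),
                                    techrep = as.character(ss$techrep)))
}

#' Read a gene-by-sample expression TSV
#'
#' First column gene ids, remaining columns samples; an optional sample
#' sheet (`sample_id`, `timepoint`, optionally `biorep`) attaches the
#' design. Without a sample sheet, column names are used as time points.
#'
#' @param path Expression TSV path.
#' @param samplePath Optional sample sheet path.
#' @param datatype Label stored in the metadata.
#' @return A `SummarizedExperiment` (see [dielExperiment()]).
#' @export
readExpressionMatrix <- function(path, samplePath = NULL,
                                 datatype = "abundance") {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1L]]
  if (!is.null(samplePath)) {
    ss <- read.delim(samplePath, stringsAsFactors = FALSE)
    ord <- match(colnames(m), as.character(ss$sample_id))
    if (anyNA(ord)) stop("sample sheet does not cover all columns")
    dielExperiment(m, timepoint = ss$timepoint[ord],
                   biorep = if ("biorep" %in% colnames(ss))
                     ss$biorep[ord], datatype = datatype)
  } else {
    dielExperiment(m, timepoint = colnames(m), datatype = datatype)
  }
}

#' Write an expression object as TSV
#'
#' @param se `SummarizedExperiment` or matrix.
#' @param path Output path.
#' @export
writeExpressionMatrix <- function(se, path) {
  m <- asAbundanceMatrix(se)
  write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated study to disk
#'
#' Emits FASTA sequence files (`cds.fa`, `utr5.fa`, `utr3.fa`,
#' `protein.fa`), expression TSVs, the peptide table with its sample
#' sheet, and the ground truth as JSON.
#'
#' @param sim Output of the generators: a list with `sequences`, `truth`,
#'   `expression` and `peptides` components (see [runPipeline()]'s `sim`).
#' @param dir Output directory (created if needed).
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sq <- sim$sequences
  writeXStringSet(cds(sq), file.path(dir, "cds.fa"))
  writeXStringSet(utr5(sq)[sq@utr5Complete], file.path(dir, "utr5.fa"))
  writeXStringSet(utr3(sq)[sq@utr3Complete], file.path(dir, "utr3.fa"))
  writeXStringSet(proteinSeqs(sq), file.path(dir, "protein.fa"))
  writeExpressionMatrix(sim$expression$mrna, file.path(dir, "mrna.tsv"))
  writeExpressionMatrix(sim$expression$protein,
                        file.path(dir, "protein.tsv"))
  pep <- sim$peptides
  a <- assay(pep)
  write.table(data.frame(peptide_id = rowData(pep)$peptideId,
                         protein_ids = rowData(pep)$proteinIds,
                         a, check.names = FALSE),
              file.path(dir, "peptides.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cd <- as.data.frame(colData(pep))
  write.table(data.frame(sample_id = colnames(a), cd,
                         datatype = "protein"),
              file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(as.data.frame(sim$truth),
                       file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Write gene sets as GMT
#'
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}
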