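# Peptide filtering, quantile normalization, reference-peptide rollup and
# the presence/absence and progressive differential summaries.

peptideProteinList <- function(pep) {
  strsplit(as.character(rowData(pep)$proteinIds), ";", fixed = TRUE)
}

#' Filter a peptide table for abundance analysis
#'
#' Applies, in order: (1) removal of peptides shared by several proteins
#' (only unique peptides are used for abundance); (2) the occurrence rule -
#' a peptide must be measured in at least `ceiling(minDatasetFraction *
#' nDatasets)` instrument datasets; (3) removal of proteins left with a
#' single peptide; (4) a variance screen that fits a linear mean-variance
#' trend across peptides and removes the `varianceQuantile` fraction with
#' the largest residual variance (0 disables the screen); then re-applies
#' rule (3).
#'
#' @param pep A [PeptideSet-class].
#' @param minDatasetFraction Minimum fraction of datasets a peptide must be
#'   observed in (default 0.5).
#' @param varianceQuantile Fraction of highest-residual-variance peptides to
#'   remove (default 0.05).
#' @return The filtered [PeptideSet-class].
#' @export
filterPeptides <- function(pep, minDatasetFraction = 0.5,
                           varianceQuantile = 0.05) {
  stopifnot(is(pep, "PeptideSet"), nrow(pep) > 0)
  keep <- rowData(pep)$unique
  pep <- pep[keep, ]
  a <- assay(pep)
  nObs <- rowSums(!is.na(a))
  pep <- pep[nObs >= ceiling(minDatasetFraction * ncol(a)), ]

  dropSingletons <- function(p) {
    prot <- unlist(peptideProteinList(p))
    p[prot %in% names(which(table(prot) >= 2L)), ]
  }
  pep <- dropSingletons(pep)
  if (varianceQuantile > 0 && nrow(pep) > 2L) {
    a <- assay(pep)
    mu <- rowMeans(a, na.rm = TRUE)
    v <- apply(a, 1L, var, na.rm = TRUE)
    resid <- stats::residuals(lm(v ~ mu))
    nDrop <- floor(varianceQuantile * nrow(pep))
    if (nDrop > 0) {
      pep <- pep[rank(-resid, ties.method = "first") > nDrop, ]
      pep <- dropSingletons(pep)
    }
  }
  if (nrow(pep) == 0L) stop("no peptides survive filtering")
  pep
}

#' Quantile-normalize peptides and roll up to protein abundances
#'
#' Peptide columns are quantile normalized (each column's sorted values
#' replaced by the across-column means of the order statistics), technical
#' replicates and - for `level = "timepoint"` - biological replicates are
#' averaged, and peptides are summarized per protein by the
#' reference-peptide rollup: the peptide with the most observations (ties:
#' highest median) anchors the protein, every other peptide is shifted by
#' the median of its paired differences to the reference, and the protein
#' value per sample is the median across shifted peptides. Missing values
#' are excluded pairwise throughout, never imputed.
#'
#' @param pep A filtered [PeptideSet-class] (unique peptides, >= 2 per
#'   protein).
#' @param level `"timepoint"` (average technical then biological
#'   replicates) or `"biorep"` (average technical replicates only).
#' @return A `SummarizedExperiment` of protein abundances with the number
#'   of contributing peptides in `rowData`.
#' @export
normalizeAndRollup <- function(pep, level = c("timepoint", "biorep")) {
  level <- match.arg(level)
  stopifnot(is(pep, "PeptideSet"))
  qn <- limma::normalizeQuantiles(assay(pep), ties = TRUE)
  cd <- colData(pep)
  grp <- if (level == "timepoint") as.character(cd$timepoint)
         else paste(cd$timepoint, cd$biorep, sep = "_")
  lev <- unique(grp)
  avg <- vapply(lev, function(l) {
    rowMeans(qn[, grp == l, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(qn)))
  avg[is.nan(avg)] <- NA_real_
  if (nrow(qn) == 1L) avg <- matrix(avg, nrow = 1L, dimnames = list(rownames(qn), lev))

  protOf <- vapply(peptideProteinList(pep), `[`, character(1), 1L)
  ru <- rollupMatrix(avg, protOf)
  out <- ru$values
  nPeptides <- ru$nPeptides
  tpLev <- if (level == "timepoint") lev else sub("_.*$", "", lev)
  se <- dielExperiment(out, timepoint = tpLev,
                       biorep = if (level == "biorep") sub("^.*_", "", lev),
                       datatype = "protein")
  rowData(se)$nPeptides <- nPeptides
  se
}

#' Reference-peptide rollup of a peptide-by-sample matrix
#'
#' Summarizes peptides to proteins: per protein, the peptide with the most
#' observations (ties: highest median) is the reference; every other
#' peptide is shifted by the median of its paired differences to the
#' reference (removing constant ionization offsets); the protein value per
#' sample is the median across shifted peptides. A peptide with no
#' observations shared with the reference is excluded with a warning.
#'
#' @param m Peptide x sample numeric matrix (NA = missing).
#' @param protOf Protein id per peptide row.
#' @return A list: `values` (protein x sample matrix) and `nPeptides`.
#' @export
rollupMatrix <- function(m, protOf) {
  prots <- unique(protOf)
  out <- matrix(NA_real_, length(prots), ncol(m),
                dimnames = list(prots, colnames(m)))
  nPeptides <- integer(length(prots))
  for (i in seq_along(prots)) {
    rows <- which(protOf == prots[i])
    sub <- m[rows, , drop = FALSE]
    nObs <- rowSums(!is.na(sub))
    med <- apply(sub, 1L, median, na.rm = TRUE)
    ref <- order(-nObs, -med)[1L]
    shifted <- matrix(NA_real_, length(rows), ncol(sub))
    shifted[ref, ] <- sub[ref, ]
    used <- 1L
    for (r in seq_along(rows)) {
      if (r == ref) next
      d <- sub[ref, ] - sub[r, ]
      if (all(is.na(d))) {
        warning("peptide ", rownames(sub)[r], " shares no observations ",
                "with the reference peptide of ", prots[i], "; excluded")
        next
      }
      shifted[r, ] <- sub[r, ] + median(d, na.rm = TRUE)
      used <- used + 1L
    }
    out[i, ] <- apply(shifted, 2L, median, na.rm = TRUE)
    nPeptides[i] <- used
  }
  out[is.nan(out)] <- NA_real_
  list(values = out, nPeptides = nPeptides)
}

#' Presence/absence calls per time point
#'
#' A protein is "present" at a time point when at least two unique peptides
#' each satisfy the occurrence rule - measurement in at least
#' `ceiling(minDatasetFraction * nDatasets)` instrument datasets, evaluated
#' within that time point's datasets (`scope = "timepoint"`, default) or
#' across all datasets (`scope = "global"`, requiring additionally one
#' within-time-point observation).
#'
#' @param pep A [PeptideSet-class] (variance filtering not required).
#' @param minDatasetFraction Occurrence threshold (default 0.5).
#' @param scope Where the occurrence rule is evaluated.
#' @return A list: `presence` (protein x time point logical matrix),
#'   `countsPerTimepoint`, and `presentAll` (number present at every time
#'   point).
#' @export
presenceAbsence <- function(pep, minDatasetFraction = 0.5,
                            scope = c("timepoint", "global")) {
  scope <- match.arg(scope)
  stopifnot(is(pep, "PeptideSet"))
  pep <- pep[rowData(pep)$unique, ]
  a <- assay(pep)
  tp <- as.character(colData(pep)$timepoint)
  lev <- unique(tp)
  protOf <- vapply(peptideProteinList(pep), `[`, character(1), 1L)
  prots <- unique(protOf)
  presence <- matrix(FALSE, length(prots), length(lev),
                     dimnames = list(prots, lev))
  globalPass <- rowSums(!is.na(a)) >= ceiling(minDatasetFraction * ncol(a))
  for (l in lev) {
    cols <- tp == l
    nIn <- rowSums(!is.na(a[, cols, drop = FALSE]))
    pass <- if (scope == "timepoint")
      nIn >= ceiling(minDatasetFraction * sum(cols))
    else globalPass & nIn >= 1L
    cnt <- table(protOf[pass])
    presence[names(cnt)[cnt >= 2L], l] <- TRUE
  }
  list(presence = presence,
       countsPerTimepoint = colSums(presence),
       presentAll = sum(rowSums(presence) == ncol(presence)))
}

#' Progressive differential protein abundance
#'
#' Compares biological-replicate protein abundances between adjacent time
#' points in the progressive order T3 vs T4, T4 vs T1, T1 vs T2, T2 vs T3
#' (dark through light and back) with Welch's two-sample t-test, reporting
#' direction relative to the later member of each pair. Raw p-values are
#' thresholded at `alpha` without multiple-testing correction.
#'
#' @param proteinReps Replicate-level protein `SummarizedExperiment`
#'   (from `normalizeAndRollup(pep, level = "biorep")`).
#' @param alpha Significance threshold on the raw p-value.
#' @param pairs List of `c(from, to)` time-point pairs; the default is the
#'   progressive scan above.
#' @return A data.frame: protein, comparison, direction (`"up"` = higher at
#'   `to`), statistic, p (only proteins with `p < alpha`).
#' @export
progressiveDifferential <- function(proteinReps, alpha = 0.05,
                                    pairs = list(c("T3", "T4"), c("T4", "T1"),
                                                 c("T1", "T2"), c("T2", "T3"))) {
  a <- asAbundanceMatrix(proteinReps)
  tp <- timepointLabels(proteinReps)
  out <- list()
  for (pr in pairs) {
    x <- a[, tp == pr[1], drop = FALSE]
    y <- a[, tp == pr[2], drop = FALSE]
    if (ncol(x) < 2L || ncol(y) < 2L)
      stop("at least 2 biological replicates per time point are required")
    for (g in rownames(a)) {
      xv <- x[g, ][!is.na(x[g, ])]
      yv <- y[g, ][!is.na(y[g, ])]
      if (length(xv) < 2L || length(yv) < 2L) next
      if (sd(c(xv, yv)) < 1e-12) next  # identical values: t = 0, skip
      tt <- tryCatch(t.test(yv, xv), error = function(e) NULL)
      if (is.null(tt) || is.na(tt$p.value)) next
      if (tt$p.value < alpha)
        out[[length(out) + 1L]] <- data.frame(
          protein = g, comparison = paste(pr[1], "vs", pr[2]),
          direction = if (mean(yv) > mean(xv)) "up" else "down",
          statistic = unname(tt$statistic), p = tt$p.value)
    }
  }
  if (!length(out))
    return(data.frame(protein = character(), comparison = character(),
                      direction = character(), statistic = numeric(),
                      p = numeric()))
  do.call(rbind, out)
}
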