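# Shared helpers: seeded evaluation, circular shifts, expression containers.

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Rotate the columns of a matrix left by k (circular): column t becomes t+k.
rotateCols <- function(m, k) {
  n <- ncol(m)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(m)
  m[, c((k + 1L):n, seq_len(k)), drop = FALSE]
}

#' Build an expression container for one data type
#'
#' Wraps a gene-by-sample abundance matrix in a
#' [SummarizedExperiment::SummarizedExperiment] with the sample metadata used
#' throughout the package (time point and, optionally, biological replicate).
#'
#' @param mat Numeric matrix, genes in rows, samples in columns (log10 scale).
#' @param timepoint Character or factor of length `ncol(mat)`.
#' @param biorep Optional replicate labels of length `ncol(mat)`.
#' @param datatype Free-text label, e.g. `"mrna"` or `"protein"`.
#' @return A `SummarizedExperiment` with assay `"abundance"`.
#' @export
#' @examples
#' m <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), NULL))
#' se <- dielExperiment(m, timepoint = c("T1", "T2", "T3", "T4"))
dielExperiment <- function(mat, timepoint, biorep = NULL, datatype = "abundance") {
  stopifnot(is.matrix(mat), length(timepoint) == ncol(mat))
  cd <- DataFrame(timepoint = as.character(timepoint))
  if (!is.null(biorep)) cd$biorep <- as.character(biorep)
  se <- SummarizedExperiment(assays = list(abundance = mat), colData = cd)
  metadata(se)$datatype <- datatype
  se
}

#' Average replicate columns to time-point level
#'
#' @param se A `SummarizedExperiment` from [dielExperiment()] with replicate
#'   columns (`timepoint` in its `colData`).
#' @return A `SummarizedExperiment` with one column per time point, in first
#'   order of appearance; missing values are excluded from the means.
#' @export
timepointMeans <- function(se) {
  tp <- as.character(colData(se)$timepoint)
  lev <- unique(tp)
  m <- assay(se)
  out <- vapply(lev, function(l) {
    rowMeans(m[, tp == l, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m)))
  out[is.nan(out)] <- NA_real_
  dielExperiment(out, timepoint = lev, datatype = metadata(se)$datatype)
}

# Coerce a SummarizedExperiment or matrix to a plain matrix.
asAbundanceMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) assay(x) else as.matrix(x)
}

# Timepoint labels of an expression object (falls back to column names).
timepointLabels <- function(x) {
  if (is(x, "SummarizedExperiment")) as.character(colData(x)$timepoint)
  else colnames(x)
}

# Row-wise z-scores with the sample (n - 1) SD; constant rows become NA.
rowZscore <- function(m, tol = 1e-12) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  z <- (m - mu) / s
  z[s < tol, ] <- NA_real_
  attr(z, "constant") <- s < tol
  z
}
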