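# Independent oracles used to freeze expected values; these never call the
# implementation paths they check.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

# Exhaustive minimum-energy RNA folding for short sequences: enumerates
# every nested structure with hairpin loops >= 3 under the pair energies
# GC = -3, AU = -2, GU = -1.
mfeOracle <- function(seq) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  pairE <- function(a, b) {
    key <- paste0(a, b)
    switch(key, GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1, 0)
  }
  best <- function(i, j) {
    if (j - i < 4L) return(0)
    # j unpaired
    e <- best(i, j - 1L)
    for (k in i:(j - 4L)) {
      pe <- pairE(s[k], s[j])
      if (pe < 0) {
        left <- if (k > i) best(i, k - 1L) else 0
        e <- min(e, left + pe + best(k + 1L, j - 1L))
      }
    }
    e
  }
  if (length(s) < 5L) return(0)
  best(1L, length(s))
}

# Hypergeometric upper-tail p by complete enumeration over all subsets of
# the universe of the cluster's size (universes <= 20).
hyperOracle <- function(overlap, setSize, universeSize, clusterSize) {
  total <- choose(universeSize, clusterSize)
  hits <- 0
  for (k in overlap:min(setSize, clusterSize)) {
    hits <- hits + choose(setSize, k) *
      choose(universeSize - setSize, clusterSize - k)
  }
  hits / total
}

# Partial correlation via residual correlation: correlate the residuals of
# f ~ m and p ~ m.
partialOracle <- function(f, p, m) {
  rf <- residuals(lm(f ~ m))
  rp <- residuals(lm(p ~ m))
  cor(rf, rp)
}

# Pearson correlation of 4-point profiles under circular shift, direct form.
shiftCorOracle <- function(m, p, k) {
  T <- length(m)
  cor(m, p[((seq_len(T) - 1 + k) %% T) + 1])
}
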