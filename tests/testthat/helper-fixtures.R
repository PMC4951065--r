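# Small fixtures shared across test files, built in code.

smallConfig <- function(nGenes = 80, seed = 42L, ...) {
  simConfig(nGenes = nGenes, seed = seed, ...)
}

# A hand-written 10-peptide table over 2 time points x 2 bioreps x
# 2 techreps (8 datasets) for presence/absence and filtering checks.
handPeptideSet <- function() {
  tp <- rep(c("T1", "T2"), each = 4)
  br <- rep(rep(c("b1", "b2"), each = 2), 2)
  tk <- rep(c("t1", "t2"), 4)
  a <- matrix(NA_real_, 10, 8,
              dimnames = list(sprintf("pep%02d", 1:10),
                              paste(tp, br, tk, sep = "_")))
  # protA: two unique peptides observed everywhere -> present at both tps
  a[1, ] <- 5 + (1:8) / 10
  a[2, ] <- 6 + (1:8) / 10
  # protB: two unique peptides observed only in T1's 4 datasets
  a[3, 1:4] <- 4.2
  a[4, 1:4] <- 4.4
  # protC: 3 unique peptides, each in 1 dataset (< 50% anywhere)
  a[5, 1] <- 3; a[6, 2] <- 3.1; a[7, 3] <- 3.2
  # protD: a single unique peptide everywhere
  a[8, ] <- 7
  # shared peptide (protA;protD)
  a[9, ] <- 5.5
  # protE+protA: peptide 10 unique to protE, one peptide only
  a[10, ] <- 2.5
  info <- DataFrame(
    peptideId = rownames(a),
    proteinIds = c("protA", "protA", "protB", "protB", "protC", "protC",
                   "protC", "protD", "protA;protD", "protE"),
    unique = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  PeptideSet(a, info, DataFrame(timepoint = tp, biorep = br, techrep = tk))
}

# Noise-free joint profiles with known classes.
cleanProfiles <- function() {
  m <- rbind(g1 = c(1, 2, 3, 0),
             g2 = c(0, 1, 2, 3),
             g3 = c(2, 0, 1, 3))
  # g1 protein identical; g2 shifted forward 1; g3 inverted
  p <- rbind(g1 = m["g1", ],
             g2 = m["g2", c(4, 1, 2, 3)],
             g3 = -m["g3", ])
  zscoreProfiles(m, p)
}
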