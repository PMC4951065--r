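---
title: "Methods: joint diel mRNA-protein analysis with dielomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint diel mRNA-protein analysis with dielomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Phytoplankton synchronized by a light:dark (diel) cycle reorganize their
transcriptome and proteome on very different schedules: mRNA for a gene
may peak hours before - or after - the protein it encodes, and a large
fraction of proteins track their transcripts only weakly or not at all.
`dielomix` implements a complete analysis chain for matched mRNA and
protein time courses sampled at a small number of diel transition points
(the canonical design: 4 time points - mid-day, dusk, pre-dawn, lights-on
- with 3 biological replicates, protein measured by LC-MS through 4
technical replicates at the peptide level). Its goal is twofold: to
*classify* the temporal relationship between each gene's mRNA and protein
profiles, and to *explain* protein abundance from mRNA plus
sequence-derived features, flagging the genes whose protein levels the
sequence cannot explain - candidates for post-transcriptional regulation
(HPTR genes).

# Proteomics preparation

Peptide-level log10 ion intensities are filtered before quantification:

* only peptides unique to a single protein are used for abundance;
* a peptide must be observed in at least 50% of the instrument datasets
  (`minDatasetFraction = 0.5`; a dataset is one time point x biological
  replicate x technical replicate run);
* proteins left with a single peptide are removed - one peptide is not
  considered sufficient evidence for quantification;
* a variance screen fits a linear trend of per-peptide variance against
  mean and removes the fraction of peptides with the largest residual
  variance. The screen is parameterized by the *fraction removed*
  (`varianceQuantile`, default 0.05, i.e. the top 5% most erratic
  peptides; 0 disables it). This parameterization makes the degenerate
  setting (`0` = no-op) unambiguous.

Surviving peptides are quantile normalized (each column's sorted values
replaced by across-column means of the order statistics, via
`limma::normalizeQuantiles`), technical and biological replicates are
averaged, and peptides are rolled up to proteins by the reference-peptide
scheme: the peptide with the most observations (ties broken by the higher
median) anchors the protein, every other peptide is shifted by the median
of its paired differences to the reference, and the protein's value per
sample is the median across shifted peptides. The median-difference shift
absorbs constant ionization-efficiency offsets between peptides, which is
exactly the artifact peptide-level label-free data exhibit; missing
values are excluded pairwise and never imputed. Note the output is
anchored at the reference peptide's scale, so the rollup is invariant to
constant offsets on non-reference peptides (shifting the reference
itself shifts the protein by the same constant - log-scale abundances are
relative quantities).

Presence/absence calls use the identification rule (at least 2 unique
peptides, each satisfying the 50% occurrence rule) evaluated within each
time point's datasets by default; a `scope = "global"` variant evaluates
the occurrence rule across all datasets instead, since the design is
ambiguous about which was intended - per-time-point is the stricter and
default reading. Progressive differential calls compare adjacent time
points in the order T3 vs T4, T4 vs T1, T1 vs T2, T2 vs T3 (dark through
light and back) with Welch's t-test on biological replicates at raw
p < 0.05, deliberately without multiple-testing correction: the
comparisons are descriptive, mirroring how such progressive scans are
reported.

# Correlation classes

Each gene's mRNA and protein 4-point profiles are z-scored independently
(sample SD, the convention of R tooling; constant profiles are flagged
and excluded). For delays k = 0..3 the Pearson correlation R is computed
between the mRNA profile and the protein profile circularly shifted back
by k. Shifts are *circular* because the diel cycle is periodic: with 4
time points a truncated-overlap delay-3 correlation would rest on a
single shared point, so wrap-around is the only reading under which all
delay classes are estimable. The exclusive class is the smallest delay
with |R| > 0.75 (sign separating correlated from anti-correlated, with
the same 0.75 magnitude threshold for the delayed anti-correlated
classes); genes with no qualifying delay are "low" when |R| at delay 0
is at most 0.1 and "unclassified" otherwise. The low-correlation rule is
stated here as |R| <= 0.1 - a deliberate resolution of an ambiguous
convention ("R > 0.1" cannot itself define *low* correlation).

Significance of class counts uses a permutation null: protein profiles
are re-assigned to genes uniformly at random (10,000 permutations by
default), classes are re-derived, and each class's two-sided empirical p
is the add-one estimator `(1 + #extreme) / (1 + nPerm)`, where extreme
means at least as far from the null mean as the observed count. The
add-one form avoids p = 0 and makes p-values exact multiples of
1/(nPerm + 1). A useful calibration fact: at n = 4 points the null
density of Pearson r is uniform on [-1, 1], so 12.5% of random gene
pairs exceed R = 0.75 at any fixed delay - the acceptance suite checks
this analytic value by simulation.

# Pathway concordance

For each data type the Pearson correlation of every unordered gene pair's
profiles is ranked, pathways are expanded to all within-pathway gene
pairs (restricted to the analyzed universe; pathways with fewer than 2
analyzed genes are dropped), and a running-sum enrichment score is
computed: hits advance the sum by `|score|^p` normalized over hits,
misses retreat by `1/(N - Nhits)`, and ES is the signed maximum
deviation. The weight exponent defaults to p = 1, the long-standing
default of the reference GSEA implementation; p = 0 (the classic
Kolmogorov-Smirnov form) is supported and used for closed-form tests. A
pair set equal to the whole ranked universe is rejected (the miss
decrement would divide by zero). Pathway concordance between the data
types is `CS_p = sign(ES_mRNA) sign(ES_prot) |ES_mRNA| |ES_prot|`, with
`sign(0) = 0`, which equals the plain product and is bounded by [-1, 1].

# Consensus co-expression clustering

The two z-scored matrices are concatenated row-wise (genes x 8 columns)
and clustered by consensus: for each candidate k, `nIter = 100` PAM runs
(Euclidean distance, `cluster::pam` with its deterministic build step)
on random 80% gene subsamples; the consensus for a gene pair is its
co-clustering count divided by its co-sampling count, so pairs absent
from a subsample are not penalized. Final labels come from
average-linkage hierarchical clustering of `1 - consensus`. When k is
not fixed by the user it is chosen by the consensus-CDF delta-area
criterion (the k with the largest relative gain in CDF area); in
practice the cluster count of real data is a judgment call, and fixing k
is fully supported. Per-cluster mean pairwise correlation is reported so
tight modules (>= 0.75) can be screened. Cluster enrichment against gene
sets is a one-sided upper-tail hypergeometric test with Bonferroni
correction over all (cluster, set) tests performed.

# Sequence features

The feature table covers, per applicable region (CDS, 5' UTR, 3' UTR,
full transcript): mononucleotide and overlapping dinucleotide
proportions, GC, lengths, GC3 (third codon positions), relative CDS
length, 20 amino-acid proportions, amino-acid class proportions
(acidic DE; basic KRH; polar STNQYC; non-polar AVLIPMFWG; aromatic FWY;
aliphatic AVLI - one documented choice among several in circulation), a
hypothetical isoelectric point, folding energies, and the codon
adaptation index. Features of an absent UTR are missing, never zero, and
genes with any missing feature are flagged incomplete and excluded from
model training.

*CAI* is the geometric mean of codon relative adaptiveness
`w = freq / max synonymous freq` (0.5 pseudocount for unseen codons),
excluding Met, Trp and stops; the default reference set is the codon
usage of the top expression decile, the standard fallback when no
curated highly-expressed set exists. An explicit reference can be
supplied. *MFE* uses a self-contained Nussinov-style dynamic program
with per-pair energies GC = -3, AU = -2, GU = -1, hairpin loops of at
least 3 unpaired bases and no pseudoknots - a deliberately simple,
exactly testable energy model (the test suite checks it against
exhaustive structure enumeration on all sequences up to 12 nt); a
thermodynamic folder can be plugged in through the `engine` argument.
MFE is computed for the 5' UTR, the 3' UTR and the first 50 CDS
nucleotides. The pI bisection uses a fixed, documented pKa table
(N-term 9.6, C-term 2.34; D 3.65, E 4.25, C 8.3, Y 10.07, H 6.0,
K 10.53, R 12.48) to 1e-4 pH units. A protein half-life proxy is
deliberately not part of the default feature set (such proxies rest on
very small training sets and did not help in practice); user-supplied
annotation flags (e.g. plastid targeting, introner-element status) merge
into the table as extra columns.

# Abundance models

A distinct model is fitted per time point: response = time-point-averaged
protein log10 abundance, predictors = same-time-point mRNA abundance
plus all features, over complete-feature genes. The regression engine is
an additive (degree-1) MARS: a forward pass greedily adds the reflected
hinge pair `max(0, x - t)`, `max(0, t - x)` with the largest RSS
reduction, up to `maxTerms = min(21, 2p + 1)` basis columns; a backward
pass prunes terms minimizing `GCV = (RSS/n) / (1 - enp/n)^2` with
`enp = M + penalty (M - 1)/2` and penalty 2, the additive-model
convention. Numerical choices: candidate knots are the unique data
values, or a 101-point quantile grid above 300 observations (31 above
500 - wide enough that a hinge knot lands within the local data spacing
at the scales the package targets); knots must have at least
`max(3, min(7, n/20))` observations on each side (an endspan rule -
without it a hinge supported by one or two points produces wild
out-of-fold extrapolations); candidate pairs whose orthogonalized energy
falls below 1e-6 of their raw energy are rejected as collinear. A
Gaussian identity-link GLM (ordinary least squares) provides the linear
baseline, and both support the constrained variants (mRNA only;
mRNA + CAI) used to show that sequence features carry real explanatory
power. Cross-validation is 10-fold by default (5 at pipeline scale),
seeded, stratified by response decile, and scores pooled out-of-fold
predictions as `1 - RSS/TSS` - an honest generalization estimate that
can be negative.

Feature screening reports per-time-point Spearman correlations with mRNA
and first-order partial correlations with protein given mRNA, computed
on ranks by default (a Pearson variant is available by flag):
`r_fp.m = (r_fp - r_fm r_pm) / sqrt((1 - r_fm^2)(1 - r_pm^2))`.
Significance is a bootstrap re-shuffling null (10,000 by default) that
permutes the gene labels of the feature vector while keeping each gene's
(mRNA, protein) tuple intact, with the add-one two-sided estimator.

# HPTR identification

Residuals are defined as predicted minus observed, so a residual above
the 95% quantile means the models *over-estimate* the protein (HPTR+)
and below the 5% quantile *under-estimate* it (HPTR-). Quantiles are
taken per model (per time point) rather than pooled - each sample's
model has its own error scale. Genes extreme in at least `minModels = 2`
of the per-time-point models are HPTR, partitioned by the dominant tail;
genes with equally many flags in both tails are dropped rather than
arbitrarily assigned. The refit evaluation retrains the models without
HPTR genes and reports per-time-point cross-validated R-squared deltas,
the mean relative improvement, a gene-resampling p-value (bootstrap over
shared genes' pooled out-of-fold errors), and - when held-out genes are
supplied - the R-squared of both model sets on genes never used in
training. Held-out genes are excluded from training *by construction*,
which is how the no-overlap contract is enforced.

Feature-distribution differences between HPTR and non-HPTR genes are
screened by two-sided Wilcoxon rank-sum tests with Bonferroni
correction. HPTR classifiers are binomial elastic-net linear models
(`glmnet`, mixing parameter alpha = 0.5 as the conventional halfway
point, regularization chosen by 10-fold cross-validated deviance) after
balancing the minority class with convex pseudo-data: random pairs of
minority samples mixed with Uniform(0,1) weights until the classes
match. Accuracy is the balanced success rate
`BSR = (SR_1 + SR_2)/2`, `SR = TP/(TP + FN)` per class - chance level
0.5 regardless of imbalance - evaluated on out-of-fold predictions, with
a label-shuffling permutation p (full refits per shuffle).

# The synthetic-data generator

Every stage is testable without external data because the generator
plants known structure at the study's design scale (4 x 3 x 4, defaults
in `simConfig()`):

* *Diel profiles.* Each gene's mRNA profile is a gene-specific
  fundamental harmonic plus a Nyquist (twice-daily) component with
  random sign, sampled at the 4 points:
  `mu + a1 sin(theta + phase) + a2 (-1)^t`, with `mu ~ N(2.5, 1)`,
  `a1 ~ U(0.4, 0.7)`, `|a2| ~ U(0.2, 0.3)`. The Nyquist term is
  essential, not decorative: a pure sinusoid sampled at 4 points makes a
  circular shift by 2 *identical to negation*, so planted delay-2 and
  anti-correlated classes (and delay-1 vs delay-3) would be
  mathematically indistinguishable downstream. The chosen amplitude
  ratio keeps every planted class identifiable with margin while diel
  oscillation stays small relative to the between-gene dynamic range, as
  in real abundance data. The baseline spread (SD 1.0 log10 units) was
  chosen so the pooled mRNA-protein Spearman correlation lands in the
  weak-to-moderate regime reported for such designs.
* *Delay classes.* The default class mixture (delay0 8%, delay1 26%,
  delay2 9%, delay3 2%, anti 16%, independent 39%) mirrors the reported
  class fractions for this kind of diel study. Delays are realized as
  circular shifts of the clean mRNA profile; anti-correlated genes
  reflect the profile about its mean; independent genes get their own
  harmonic parameters.
* *Coupling.* For non-HPTR genes,
  `protein = 0.2 + 0.8 m + hinge * max(0, m - 2.5) + feature offsets` -
  linear-plus-hinge so the spline models have true non-linearity to
  find. The hinge coefficient is itself a planted effect
  (`featureEffects["mrnaHinge"]`, default 0.5), so setting all feature
  effects to zero gives an exactly affine coupling (and per-gene
  Pearson R of 1 at zero noise, a unit-test anchor).
* *Sequence features.* CDS codons are drawn from a bias mixture (the
  gene's planted codon-bias parameter is the probability of using the
  amino acid's optimal codon), 5' UTR base composition follows a planted
  GC parameter, 3' UTRs are T-rich, UTR lengths are log-normal and short
  (median 50-70 nt, capped at 150 - compact-genome scale). The planted
  expression effects act through the *realized* sequence scores (the
  computed CAI and computed 5' UTR MFE, z-scaled): +0.5 log10 per SD of
  CAI and -0.5 per SD of 5' UTR structure (-MFE), so the downstream
  feature table measures exactly the quantity that carries the effect.
* *HPTR genes.* 10% of genes, split evenly between tails (HPTR+
  over-estimated, HPTR- under-estimated; shift 3.0 log10 units) and
  between two mechanisms: an independent expression program, and
  coupling with inverted feature effects - giving the residual-quantile
  detector both tails and both failure modes. The shift is chosen well
  clear of the models' residual spread because the detector's stated
  operating point (sensitivity >= 0.8 at 5%/95% quantiles with 10%
  planted genes) leaves no tail capacity to spare: the planted fraction
  exactly fills the two tails.
* *Peptides.* 1-6 peptides per protein, each with a fixed N(0, 0.3)
  ionization offset (the artifact RRollup removes), N(0, 0.2) technical
  noise, 10% missingness, and 5% of peptides mapped to a second protein.
* *Noise defaults* (log10 SD): mRNA 0.1, protein 0.15, peptide 0.2.
  No quantitative LC-MS noise model is available for this design, so
  these are free parameters chosen at plausible label-free scales, not
  estimates of any study's variance components.

Everything is seeded: the same `simConfig(seed = s)` reproduces
sequences, expression and peptides byte-identically; the generators
fan out sub-seeds (seed + 1, + 2, + 3) so each can be called
independently, and `runPipeline()` derives per-stage seeds by fixed
offsets from the configuration seed.

What the generator does *not* emulate: read-level RNA-Seq noise, raw
spectra or chromatographic artifacts, realistic codon-usage phylogenies,
UTR secondary-structure motifs beyond composition, correlated
missingness, or pathway-structured co-regulation beyond shared phases.
Passing tests therefore demonstrate the *algorithms* recover known
structure under the stated noise model - not that any particular
biological dataset satisfies that model.

# Problem sizes and degenerate inputs

The test suite runs the recovery checks at 2,000 genes across 20 seeds
and the unit checks at 30-600 genes; the acceptance script analyses one
2,000-gene study plus a 10,000-gene null calibration. Degenerate inputs
are handled explicitly: constant profiles are flagged and excluded from
classification and pairwise ranking; empty filtered peptide tables,
empty pair sets, whole-universe pair sets, single-class classifier
inputs, and fold counts below 2 raise errors; collinear features raise
an error naming the offending pair in partial correlations and are
dropped with a warning in the GLM.

# Known limitations

* Four time points bound what "delay" can mean; the circular-shift
  classes are coarse phase bins, not continuous phase estimates, and
  rhythmicity itself is not tested.
* The default MFE engine is a base-pair-counting model: adequate as a
  relative structure score and exactly testable, but not a thermodynamic
  prediction; plug in an external folder where absolute energies matter.
* The MARS engine is additive by design; interaction effects between
  sequence features are out of scope (as are boosted trees and kinetic
  ODE models of translation).
* With 10% planted HPTR genes the 5%/95% residual quantiles are exactly
  saturated, so detection sensitivity is intrinsically capped near the
  planted fraction's fill rate; real studies with rarer HPTR genes sit
  in an easier regime.
* BSR permutation p-values refit the classifier per shuffle and are the
  slowest routine in the package; reduce `nPerm` for exploration.
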