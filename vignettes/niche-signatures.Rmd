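---
title: "Detecting environmental niche signatures in proteome sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting environmental niche signatures in proteome sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the approach

Prokaryotes adapt the composition of their proteins to their
environment. If those adaptations are systematic, a supervised
classifier should be able to read an organism's niche — its domain of
life, whether it is a halophile, whether it grows at high temperature —
from proteome-wide averages of simple physico-chemical descriptors, and
the features the classifier leans on should form an interpretable
signature of each adaptation.

`nichesig` implements that pipeline: descriptor extraction, redundancy
reduction, repeated-split classifier evaluation with ROC/AUC and
permutation controls, and permutation feature importance. Because public
proteome collections change and accession lists go stale, the package
pairs the pipeline with a synthetic proteome generator that plants the
adaptations with known ground truth; every stage is validated against
that ground truth and against independent numerical oracles.

## The feature model

Every descriptor is a function of a protein's residue *composition* (and
its length): residue frequencies, amino-acid index means, isoelectric
point, length, residue-class frequency ratios, and charged fraction.
None depends on residue order. That is deliberate — proteome-level means
of order-sensitive quantities would require structural modeling well
outside this scope — and it licenses the generator's i.i.d. residue
sampling: for these descriptors, sequence order carries no information,
so an order-free generator loses nothing.

Proteome vectors are *unweighted means over proteins*: each feature,
including the isoelectric point and the length, is computed per protein
and averaged. This is not the same as recomputing features on the pooled
residue bag — with unequal protein lengths the two differ, and the
per-protein mean is the one used throughout (a two-protein contrast case
in the test suite pins this down).

Choices the data cannot make for us, recorded here:

* **Amino-acid index table.** The default is 48 complete AAindex scales,
  pinned by accession (see `DEFAULT_INDEX_CODES`), including the scales
  that recur in niche-signature work: normalized frequency of extended
  structure (MAXF760102), beta-turn (CHOP780101), information measure
  for loop (ROBB760113), the Chou–Fasman coil parameter (CHAM830101),
  Hopp–Woods hydrophilicity (HOPT810101), Grantham polarity
  (GRAR740102). The exact membership of the remaining 42 is
  configuration, not a scientific claim: `aaindex_table()` accepts any
  replacement table (TSV or matrix) and the pipeline's behavior is
  defined relative to the configured table.
* **Residue classes.** Negative/acidic = {D, E}; positive/basic =
  {K, R}; His is treated as neutral at physiological pH so that His
  content stays an independent signal; charged = {D, E, K, R}; the
  polar/non-polar split follows the standard chemical classification and
  disorder-/order-promoting the Dunker convention. All sets live in one
  `residue_sets()` object and can be overridden together.
* **"Charge" means charged content.** The `charge` feature is
  f(D)+f(E)+f(K)+f(R), the total charged fraction, not a net charge; net
  balance is carried by the f(negative)/f(positive) ratio. The two are
  deliberately distinct: a proteome can grow more charged overall while
  its negative fraction falls.
* **Isoelectric point.** Henderson–Hasselbalch net charge over the
  ionizable groups (termini always included), EMBOSS pKa values by
  default (`pka_set()` is replaceable). Z(pH) is monotone non-increasing
  with Z(0) > 0 > Z(14), so bisection on [0, 14] to a width of 1e-3 pH
  finds the unique root; the suite checks 500 random sequences against a
  1e-4-step grid scan within 2e-3 pH.
* **Zero denominators.** A ratio with a zero denominator (e.g. a
  sequence with no positive residues) gets the pseudocount 1/(length+1)
  added to the denominator, so a zero numerator still reports 0 and the
  feature matrix stays complete for the classifiers.
* **Ambiguity codes** (B, J, O, U, X, Z, stops, gaps) are removed, not
  redistributed, and counted per file, so composition denominators are
  explicit. A sequence that vanishes under sanitization is dropped with
  a warning.

## Redundancy reduction

Rank correlations (Spearman, average ranks on ties; constant features
are flagged and set to zero correlation) are clustered by UPGMA on
d = 1 − |ρ|. The tree is cut at height 1 − threshold with the threshold
defaulting to 0.9; merges at exactly the cut height are kept, so a
cluster groups features whose *average* absolute rank correlation is at
least 0.9. Each cluster is represented by its medoid — the member with
the largest mean |ρ| to the rest; no coordinate centroid exists in
correlation space — with exact ties broken by the lexicographically
smallest code. Agglomeration order in `stats::hclust` is deterministic,
so the whole step is reproducible; a brute-force UPGMA oracle in the
test suite confirms the partitions on every matrix of up to six
features. Because rank correlation is invariant under monotone
transformations, it is irrelevant whether the input matrix is raw or
normalized.

One reduction is computed per run and every classification case consumes
the same representative set — `run_full()` enforces this
single-feature-set contract.

## Evaluation protocol

Each case runs `n_repeats` (default 10) independent stratified splits,
2/3 training and 1/3 test, proportions preserved within one organism per
class. Min-max normalization is **fitted on the training portion only**
and applied unchanged to the test portion (test values may leave
[0, 1]). Normalizing each class separately over the full dataset would
leak label information into the test features, so that variant is not
offered. A feature constant on a training split maps to zero and is
flagged.

The classifier adapters are thin contracts — fit on a matrix and factor,
return per-class probability scores — over `ranger` (probability
forest, 1000 trees, node size 1, seeded, single-threaded) and
`e1071::svm` (RBF kernel; cost and gamma tuned by grid search,
C ∈ 2^{−5..15}, γ ∈ 2^{−15..3} in steps of 2², scored by internal
10-fold cross-validation on the training split only). The learning
algorithms are third-party; the protocol around them is the package's
contribution. On planted-signal data the two adapters agree to within
0.1 AUC, which is part of the acceptance suite.

ROC curves sweep the distinct score values; the AUC is the trapezoid
area and equals the Mann–Whitney pair-count statistic (ties one half) —
the suite verifies the identity on 1000 random score/label sets, and
once against an independent ROC implementation. Per-repeat AUCs are
reported with their mean; curves are kept per repeat.

**Permutation controls.** Two negative controls run through the
unchanged protocol: independent within-column shuffles of the feature
matrix (destroying every feature–label association while preserving
marginals), and label permutation (decoy classification). A fresh
permutation is drawn for every repeat: under a single frozen
permutation all ten repeats share the same accidental associations and
the mean control AUC scatters widely across draws (values as low as
0.35 were observed); redrawing per repeat estimates the same chance
level with roughly √10 less variance.

## Feature importance and signatures

Importance is classifier-agnostic: permute one feature's held-out
values, measure the increase in prediction error, average over shuffles
and over the repeated splits. The error is the **Brier score** of the
positive-class probability. The rank-based 1 − AUC alternative (offered
as an option) turned out to be degenerate on well-separated data: when
several features each separate the classes on their own, permuting any
one of them leaves the AUC at exactly 1 and every importance at exactly
zero. The Brier score is a strictly proper scoring rule and registers
the loss of confidence even while the ranking survives. Importance is
computed on held-out data rather than out-of-bag samples so the same
procedure applies to the SVM adapter unchanged.

Top-10 lists from the three cases are combined into signatures: features
in all three lists are *shared* (general discriminators), and a case's
*unique* features are its top-10 minus the union of the other two
top-10s (a stricter variant excluding only the three-way intersection is
available). Per-class feature distributions are summarized as Tukey
box-and-whisker statistics (type-7 quartiles, whiskers at 1.5 IQR,
outliers beyond), optionally min-max normalized across classes for
side-by-side display.

## The synthetic generator

`generate_dataset()` emulates, per class of organism: class-conditional
residue usage (multiplicative tilts on a Swiss-Prot-like baseline,
renormalized), lognormal protein lengths truncated at 30 residues, a
fixed number of proteins per organism, and growth-temperature ranges
sampled uniformly inside the region consistent with the class label, so
the label-derivation code is exercised nontrivially. Default effect
directions follow the reported adaptations — halophiles roughly double
their acidic fraction (Glu tilted more than Asp) and lose Lys, Phe and
some Gln; thermophiles gain Val, Tyr and Glu and lose Gln;
mesothermophiles sit at the square root of the thermophile tilts;
archaea lose His and Gln, gain Glu, and have shorter proteins (median
240 vs 300 residues). Magnitudes are tunable parameters, not claims.

Two generator properties deserve emphasis:

* **Organism-level heterogeneity.** Organisms of a class do not share
  the target composition exactly; each gets a multiplicative log-normal
  jitter (default sd 0.05, about 5% relative per residue) and a jitter
  of 0.05 on the log length location. Without it, per-organism
  compositions differ from the class mean only by residue-sampling noise
  — about 0.1% relative at proteome scale — so *every* feature separates
  the classes almost perfectly, classification is trivially AUC = 1 and
  importance rankings are meaningless. Five percent is a realistic order
  of between-organism compositional variability; it leaves the planted
  tilts easily classifiable while restoring a sensible signal-to-noise
  ordering across features. Setting the sd to 0 recovers the pure
  i.i.d. core, which is what the distributional convergence tests use.
* **What it does not emulate.** No phylogenetic correlation between
  organisms (real archaea are not i.i.d. draws), no GC-content or
  codon-level structure, no within-proteome distribution shapes beyond
  the mean, no horizontal transfer, no annotation noise. Passing the
  recovery tests therefore shows the *pipeline* is correct and
  sensitive, not that real proteomes are this easy; on real data,
  phylogenetic confounding in particular can inflate apparent
  classification accuracy.

Default study shapes: 32 organisms per class for binary cases (32/16/16
for the three temperature classes), 300 proteins per organism, median
length 300. The heavier test-suite checks scale some of this down (16
organisms per class, 100–150 proteins) so the full suite stays in the
minutes range on one CPU; effect recovery is insensitive to this because
the planted effects act on means whose standard errors are already tiny
at 150 proteins per organism.

## Numerical and degenerate-input choices

* pI bisection width 1e-3 pH (verified to 2e-3 against the grid oracle).
* Spearman with average ranks; constant features get ρ = 0, flagged.
* UPGMA merge ties follow `hclust`'s deterministic order;
  representative ties break lexicographically.
* Stratified splits round the per-class training count and clamp it to
  [1, n−1], so both portions are always populated; classes with fewer
  than two members are an error.
* A training-constant feature normalizes to 0 everywhere.
* Single-class label vectors make AUC undefined and error out rather
  than returning a default.
* Generator truncation resamples lengths below 30 (no probability mass
  piles up at the boundary).
* All seeds derive deterministically from one configuration seed;
  reruns are bit-identical (forest and SVM included, both
  single-threaded).

## Known limitations

* Importance on strongly redundant feature sets is diluted by design;
  the reduction step mitigates but does not remove this, which is why
  recovery is asserted at the level of cluster representatives.
* The SVM adapter's probability outputs come from Platt scaling inside
  `e1071`; they are monotone in the decision values, so AUCs are
  unaffected, but the probabilities themselves are not calibrated.
* The one-against-one average AUC weights the three class pairs
  equally regardless of class sizes.
* The pipeline evaluates proteome-level means only; within-proteome
  distribution shape descriptors are out of scope.
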