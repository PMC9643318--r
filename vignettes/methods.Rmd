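---
title: "Methods: multiplexed drug repurposing for bone-metastatic CRPC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplexed drug repurposing for bone-metastatic CRPC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repurposeBM)
```

## The problem and the model

Castration-resistant prostate cancer that has metastasized to bone is shaped
by its immune microenvironment, in particular by pro-tumour (M2-polarized)
macrophages. The pipeline in this package scores candidate compounds by their
capacity to *reverse* two transcriptional signatures at once: the
bone-metastasis (BM) differential signature, and an M2-macrophage-associated
signature. Every stage is a small, explicit model; this vignette states each
one, its assumptions, and the choices made where the design was genuinely
open.

## Disease signature selection

A gene enters the signed disease set iff its adjusted p-value is strictly
below 0.05 **and** |log2 fold-change| strictly exceeds 1; its direction is
the sign of the fold-change. Both inequalities are strict: a gene at exactly
the boundary is excluded, and the boundary tests pin this. The filter is
idempotent and monotone in both thresholds.

The macrophage-association screen keeps genes whose Pearson correlation with
a per-sample macrophage-abundance estimate exceeds 0.3 and is significant
(two-sided t-transform of r on n − 2 df, p < 0.05). Whether the 0.3 threshold
applies to signed or absolute r is ambiguous in common usage; the default is
**signed** (the screen targets positively macrophage-associated genes), with
`mode = "absolute"` exposed. Evidence from several methods or datasets is
combined with `consensus_intersect()`, which defaults to requiring presence
in *all* supplied sets.

## Consensus rank aggregation and the composite score

Each signature-reversal source contributes an ordered drug list truncated to
its top 50 entries (the cap imposed by the most restrictive source's export
limit). The consensus prior weights the number of occurrences and the average
rank:

$$\mathrm{prior}(d) = \frac{k_d}{K}\left(1 - \frac{\bar r_d - 1}{\mathrm{cutoff}}\right)$$

with $k_d$ the number of sources listing $d$ and $\bar r_d$ its mean rank
among those. The form is multiplicative so that a prior of 1 is attainable
only by a drug ranked first by every source; it is monotone in both
arguments and permutation-invariant in the sources. The referenced consensus
method's exact expression is not published; this is the module's single
normative choice.

The composite score is the weighted sum $0.45\,aS + 0.45\,FS + 0.1\,StS$.
Only the weights are fixed by the study; the three components here are
explicit proxies, each pluggable: the activity score $aS$ is the consensus
prior; the functional score $FS$ is target-overlap precision
$|T_d \cap S_{\mathrm{disease}}|/|T_d|$; the structural score $StS$ is the
fraction of four classical drug-likeness rules satisfied (MW ≤ 500,
logP ≤ 5, H-bond donors ≤ 5, acceptors ≤ 10), so it always lies on the grid
$\{0, 0.25, 0.5, 0.75, 1\}$.

## Chemical redundancy clustering

Structures are canonicalized and fingerprinted with hashed circular
substructure (ECFP, radius 2) fingerprints folded to a configurable 2048
bits. Tanimoto similarity $|a \wedge b| / |a \vee b|$ is defined as 1 when
both fingerprints are empty (identical absence of features avoids 0/0).

Clustering is agglomerative with Ward's minimum-variance linkage applied to
the distance $d = 1 - s$ — a known formal impropriety (the Tanimoto distance
matrix is not Euclidean) retained deliberately because it mirrors the
standard chemoinformatics service procedure. The dendrogram is cut at the
merge height corresponding to $d = 1 - 0.80$; whether the upstream tool cuts
at raw distance or merge height is not recoverable, and merge height was
chosen and is documented here. The test suite proves the implementation
identical to a from-definition Lance–Williams agglomeration oracle on 200
random matrices ($n \le 8$). Cluster ids are ordered by each cluster's
lexicographically smallest member, which makes the assignment exactly
invariant to input order; representatives are the per-cluster composite-score
argmax with lexicographic tie-break.

Jointly clustering candidates with clinical-trial drugs yields the final
classification: `in_trial` (identical canonical structure), `trial_similar`
(shares a cluster with a trial drug), `structurally_specific` (shares none).

## Network criticality

For compound $i$ with signed target set $S_i$ and a reference signature $S$:

$$\mathrm{Score}_i \;=\; \frac{\mathrm{Degree}^{\mathrm{reverse}}_i - \mathrm{Degree}^{\mathrm{mimic}}_i}{|S_i \cap S|},$$

where a *reverse* edge is a shared gene driven opposite to the disease
direction and a *mimic* edge one driven the same way; degrees conserve
($\mathrm{rev} + \mathrm{mim} = |S_i \cap S|$) and the ratio is antisymmetric
under direction flip. Scores are normalized by dividing by the maximum
absolute score so the strongest compound sits at ±1 — the typeset source
formula reads as a multiplication, but only division lands in (−1, 1), so
division is implemented. Each axis (BM and M2) is normalized by **its own**
maximum by default, so both independently span the unit interval;
`normalize_m2_by = "bm_max"` switches to a shared denominator. An empty
intersection gives a raw score of 0 with a warning (the compound is
uninformative) rather than an error, keeping the weighted score total. The
final score is $DR_i = 0.3\,\mathrm{Score}_{BM,i} + 0.7\,\mathrm{Score}_{M2,i}$.

## Drug sensitivity

The response stage follows the contract of ridge expression-to-response
prediction, implemented directly rather than bit-matching any particular
package: drugs missing in strictly more than 20% of cell lines are discarded
*before* imputation; the remaining gaps are filled by KNN over cell lines
(k = 5 by default; neither orientation nor k is fixed by the study, and both
are exposed). Distances between lines are root-mean-square differences over
jointly observed drugs after scaling each drug by its observed mean — the
mean (rather than the raw Euclidean sum) keeps pairs with different numbers
of jointly observed drugs comparable. Neighbour ties break by line id, and
imputed values are clamped to the drug's observed range, preserving IC50
positivity.

The ridge model is closed-form (SVD of the centered design, intercept
unpenalized); the penalty defaults to the minimizer of leave-one-out GCV,
$n\,\mathrm{RSS}/(n - \mathrm{df})^2$, over a fixed grid
$10^{-4} \ldots 10^{4}$ (33 log-spaced points). IC50 is modelled on the
natural-log scale and predictions are back-transformed. At $\lambda = 0$ the
fit equals ordinary least squares, which the tests verify against `lm()`.

A drug is *sensitive* when its **mean** predicted IC50 over the BM group is
strictly below 10 μM — the study does not state whether the threshold applies
per sample or to the group mean; the mean was chosen and is documented here —
and the final set is the intersection across the two screens. Group contrasts
use the two-sided Wilcoxon rank-sum test (the study reports only "P < 0.05"
without naming a test); the suite checks it against an exhaustive permutation
oracle.

## Thermodynamics and trajectory statistics

Binding constants use $K_i = \exp(\Delta G / RT)$ with
$R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹ at $T = 298.15$ K. Published
docking tables print energies to one decimal, so round-trip agreement is
~0.3%; a 1% tolerance absorbs it.

The dynamic cross-correlation matrix uses the scalar-product convention with
equal frame weights:
$C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
\sqrt{\langle |\Delta r_i|^2\rangle \langle |\Delta r_j|^2\rangle}$,
displacements taken about per-particle time means. RMSD performs **no**
optimal superposition (inputs are assumed post-processed/aligned;
superposition is an explicit non-goal); RMSF is the per-particle fluctuation
about the time mean; Rg is mass-weighted with uniform masses by default. All
three are checked against their defining identities and the DCC against a
double-loop oracle at $10^{-10}$.

## What the synthetic data emulates — and what it does not

The generators are pure functions of `(spec, seed)` on an explicitly seeded
Mersenne-Twister stream that never touches the global RNG state. Defaults
describe the study conditions where stated (3 sources, 50 drugs per list,
sensitivity threshold geometry, 20% missingness rule) and otherwise a
realistic regime chosen once: 2000 genes with 10% differential at
|log2FC| ≥ 2; source lists drawn from a 150-drug universe with 60% overlap
and rank noise of 2 positions; 20 compounds × 50 shared signature genes; 100
cell lines × 30 drugs with 5% missingness; 100-frame, 20-particle
trajectories with amplitude 0.5 nm and noise 0.05 nm.

Design details worth knowing:

* Non-differential genes draw adjusted p uniformly on [0.05, 1], so the DEG
  filter recovers the planted truth set *exactly* — crisp truth sets beat
  realism here.
* Ranked-list overlap is realized on the head of the latent efficacy
  ordering, reflecting that reversal screens agree most on their top hits;
  with full overlap and zero noise the consensus prior provably recovers the
  latent order.
* The SMILES grammar enumerates chain–ring–substituent combinations; planted
  near-duplicate pairs extend a terminal tail by one carbon, and the
  pairable tails are restricted to those whose extension stays above the
  80% Tanimoto threshold for every grammar combination (exhaustively
  scanned), so the planted truth holds by construction.
* Trajectory blocks share a sinusoidal collective coordinate along x with
  ±1 block signs; at the default noise-to-amplitude ratio of 0.1 the
  within-block mean correlation exceeds 0.8 and the cross-block mean falls
  below −0.8.

What the generators do **not** emulate: expression covariance structure,
probe-level microarray artefacts, realistic chemical diversity, non-MCAR
missingness, or anharmonic protein dynamics. Passing tests therefore
demonstrate the *algorithmic* correctness and recovery behaviour of each
stage under its stated assumptions, not performance on real cohort data —
the published dataset-dependent candidate counts require the original
external retrievals and are deliberately out of scope.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately small problem sizes — 100
replicates for recovery rates, 200 random matrices for the clustering
oracle, 1000 random signatures for the conservation property, 200×10 ridge
designs, 25×12 imputation matrices — chosen as the smallest scales at which
the checked properties are statistically crisp. Degenerate inputs are
handled explicitly: empty DEG tables give empty sets with zero counts;
all-zero raw scores normalize to zero; both-empty fingerprints have
similarity 1; single-compound matrices form one singleton cluster; constant
responses give intercept-only ridge fits. All sorted outputs break ties
lexicographically by identifier, which makes every table byte-deterministic
for a given seed.
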