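---
title: "Topological discriminant screening for JAK inhibitors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological discriminant screening for JAK inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topojak)
library(dplyr)
```

`topojak` implements a ligand-based virtual-screening workflow built on
molecular topology: molecules are treated as graphs, numeric graph
invariants (topological indices) serve as QSAR features, linear
discriminant functions separate actives from decoys, and distribution
diagrams of the discriminant scores define the score windows used to
screen libraries. This vignette explains the model, the conventions
behind each computation, the choices made where the procedure was
genuinely open, and what the package's synthetic tests do and do not
demonstrate.

## The chemical graph

Molecules enter as SMILES and become hydrogen-suppressed graphs: vertices
are heavy atoms (element, formal charge, implicit hydrogen count,
aromatic flag), edges are bonds with a *conventional bond order* (single
1, double 2, triple 3, aromatic 1.5). The adjacency matrix **A** and the
topological distance matrix **D** (shortest-path edge counts, via
igraph) are precomputed once per molecule; every descriptor is a function
of these matrices and of per-atom property vectors. Salts and other
multi-fragment inputs are reduced to the largest fragment, since all
descriptor definitions assume a connected graph. Stereochemistry is
parsed and discarded — by construction the approach uses connectivity
only, never 3D geometry, which is what makes it cheap enough to screen
hundreds of thousands of catalog compounds.

Atomic property weights (atomic mass, Sanderson electronegativity, first
ionization potential, van der Waals surface area from Bondi radii, and a
Crippen-style atomic log P contribution) come from one fixed reference
table (`element_properties()`), carbon-scaled where the descriptor
family demands it so carbon is exactly 1. The table covers H, B, C, N,
O, F, Si, P, S, Cl, Br, I; an unknown element raises an error naming it
rather than guessing.

## Descriptor conventions

Where a published index family admits more than one convention, the
package fixes one and documents it here:

* **SRW05** is the raw trace of **A**⁵ — the number of closed walks of
  length 5. Odd closed walks exist only in the presence of odd rings, so
  for ordinary organic molecules (no 3-rings) SRW05 > 0 is effectively a
  five-membered-ring detector: cyclopentane scores 10, benzene 0. An
  `ln(1+x)` transform is available (`log_transform = TRUE`) but off by
  default.
* **ICk / CICk** operate on the *hydrogen-filled* graph with *n* total
  atoms. Atoms are partitioned by iterated neighborhood refinement
  (Weisfeiler–Lehman style): initial colors are (element, vertex
  degree), edges carry bond orders, and *k* rounds of refinement encode
  the order-*k* coordination sphere; at order 0 the partition is by
  element alone. Then `IC_k = −Σ p_c log2 p_c` over class probabilities
  and `CIC_k = log2(n) − IC_k`. The initial coloring was pinned down by
  a printed calibration value: tofacitinib's hydrogen-filled graph (43
  atoms) must give CIC2 = 0.500, which holds for (element, degree)
  initial colors with bond-labeled refinement and for no coarser
  variant.
* **GATSk / MATSk** follow the standard Geary / Moran forms over
  unordered (resp. ordered) atom pairs at topological distance *k*, with
  carbon-scaled weights. Two total-function conventions apply: an empty
  lag returns 0, and zero weight variance (homonuclear skeletons)
  returns 0. Both are asserted in tests and matched against
  literal-formula oracles.
* **JGIk** builds **M = A·Q** with `q_ij = 1/d_ij²`, takes charge terms
  `CT_ij = m_ij − m_ji`, sums |CT| over pairs at distance *k* and
  divides by *n* − 1.
* **Eig05_AEA(dm)** is the 5th largest eigenvalue of the edge-adjacency
  matrix with per-bond dipole moments (Debye) on the diagonal. The bond
  dipole table (`bond_dipole_table()`) is keyed by element pair and bond
  order class; pairs outside the table fall back to the absolute
  Sanderson electronegativity difference. Fewer than five bonds gives 0.
* **P_VSA_LogP_k** sums van der Waals surface increments of atoms whose
  atomic log P contribution falls in bin *k* of a SlogP_VSA-style edge
  set (`pvsa_logp_bins()`). The exact proprietary bin edges of the
  original descriptor software are not recoverable, so the edge set is
  shipped as data and can be recalibrated; the partition property (bins
  sum to the total surface area) is convention-independent and tested.
* **PCD** enumerates simple paths up to 10 edges; the multiple path
  count weights each path by the product of conventional bond orders, so
  saturated acyclic hydrocarbons score exactly 0.

All descriptors are total functions (degenerate inputs give 0 rather
than NA) because a screening pipeline must score every catalog molecule,
and all are invariant under atom relabeling, which the suite verifies
across random permutations.

## Discriminant models

The classifier is a two-group linear discriminant
`DF = a0 + Σ a_i λ_i`, fitted as the Fisher discriminant with pooled
covariance and equal priors. The intercept is placed so the decision
boundary sits at DF = 0 midway between class centroids — the sign rule
(DF > 0 ⇒ active) is part of the published model form. Separation
quality is summarized by Wilks' λ = det(W)/det(T) (0 = perfect, 1 =
none), converted to an F statistic by the exact two-group identity
`F = ((N − p − 1)/p) · ((1 − λ)/λ)` on (p, N − p − 1) degrees of
freedom.

Descriptor subsets are chosen by hybrid stepwise selection: each step
adds the candidate minimizing λ if its partial-F p-value is below 0.05,
then removes any included descriptor whose removal p-value exceeds 0.05,
up to 20 terms. Ties are broken lexicographically so runs are exactly
reproducible. The default candidate pool for refitting
(`retraining_descriptors()`) is the eleven descriptors of the published
models plus the complete walk, autocorrelation and charge-index families
at lags 1–8 — the families the original analysis drew from.

The published equations themselves are typeset as images in the source
document, so their numeric coefficients cannot be transcribed; the
shipped registry (`published_models()`) records each model's descriptor
set and training statistics (N, λ, F, p) with coefficients marked
unavailable, and screening of the published compound table works
directly from the printed per-compound DF values.

Internal validation follows the leave-some-out scheme: per fold, 20% of
each class (rounded up) is held out along a seeded stratified shuffle
with folds as disjoint as the fraction permits, coefficients are refitted
on the remainder over the fixed descriptor set, the holdout is scored,
and λ′ is recomputed. The published robustness yardstick — validation
accuracy within 7 points of training accuracy — is asserted on the
synthetic study design.

## Distribution diagrams and activity windows

For a DF histogram (default bin width 0.25, chosen because the published
window boundaries are multiples of 0.25), per-bin class fractions *a*
and *i* give the expectancies `E_a = a/(i+1)` and `E_i = i/(a+1)`. The
formulas are defined for arbitrary DF ranges, which matters for window
derivation: with class-*fraction* semantics, a single narrow bin can
rarely exceed any useful threshold, but a whole region can.

How the published diagrams were turned into numeric windows is not
stated, so the package fixes a two-step rule: candidate windows are
maximal runs of bins where actives are denser than inactives
(*a* > *i*, with zero-density bins treated as neutral so sparse tails do
not fragment runs), and a candidate is kept when its range-level E_a
exceeds the threshold (default 0.5) or when it contains no inactive
density at all. The second clause admits pure-active satellite regions —
the published general model has exactly such a narrow secondary window
— while the threshold keeps mixed regions honest. Windows are clipped to
the observed DF support, and values beyond the support are
non-classifiable (outside the applicability domain).

The screening windows shipped as defaults are the published ones:
general model active for DF in [0.5, 5] ∪ [−1, −0.75], non-classifiable
outside [−7, 5]; subtype windows JAK1 [−1.2, 8] (overlap zone below
2.5), JAK2 [−0.55, 6], JAK3 [0, 7.5], calibrated once against the
printed 47-compound decision table and stored as configuration, not
code. With closed boundaries these reproduce 45 of the 47 printed
verdict rows; the two exceptions are inconsistencies within the printed
table itself (a compound selected at DF_gen = −1.097, outside the stated
general window, and one unassigned at DF_2 = 0.956, inside the JAK2
window) and are asserted as the only failures.

## Fingerprints and diversity

Carhart atom-pair fingerprints hash (atom type, atom type, topological
distance) features — atom types are (element, heavy-atom degree, π
indicator) — into 1024 bits by default. The printed description of the
original fingerprints mentions 32-bit strings, which is implausibly
small for atom pairs and collides heavily; a 32-bit compatibility mode
is retained behind `n_bits = 32`, but 1024 is the default. Similarity is
the Tanimoto coefficient on bit sets (two empty fingerprints count as
identical); `1 − T` is the Soergel distance, a metric on bit sets,
verified by brute force over random triples.

Clustering is agglomerative with average linkage (the original work
names only its cut criterion, not the linkage). The flat cut minimizes
the Kelley–Gardner–Sutcliffe penalty: the mean within-cluster spread
(average pairwise distance over non-singleton clusters), normalized
across all dendrogram levels to [1, n − 1], plus the number of clusters.
Scoring every level from one cluster upward is essential — the
one-cluster level anchors the normalization, and omitting it makes the
penalty prefer near-singleton cuts. The criterion recovers planted
scaffold families when within-family variation is tight and homogeneous;
when a family contains real substructure (e.g. halogenated vs.
chain-extended members), the criterion legitimately reports the finer
granularity.

## The synthetic study design

No training compounds are deposited with the original work, so the
package generates libraries with the statistical structure the analysis
assumes, from a fragment grammar that guarantees chemical validity:

* **Actives** carry a five-membered (aza)ring scaffold with probability
  0.75 — echoing the reported 31/42 prevalence among inhibitors — and
  asymmetric, nitrogen-rich decoration (nitriles, amides, aminoazines);
  half of the five-ring actives are fused to a bicyclic aminopyrimidine
  motif. The fused core is restricted to five-ring scaffolds because it
  contains a five-ring itself and would otherwise inflate the designed
  prevalence.
* **Decoys** get five-ring scaffolds with probability 0.30 (the reported
  18/59), symmetric decoration from a broader substituent pool, and are
  matched to the actives on molecular weight and C/N/O/halogen counts by
  a best-of-25 greedy draw. Ring parity is decided per decoy before
  matching so the matching step cannot bias the designed rate.

On the seed-42, 100-per-class library, stepwise selection from the
retraining pool reaches ~94% training accuracy, keeps cross-validated
accuracy within the 7-point robustness band, and includes odd-order walk
counts (the five-ring channel) in the selected set. What this shows is
that the pipeline recovers a planted topological signal end to end; it
does not show real-world screening enrichment. Real inhibitor/decoy sets
are noisier (the original training data reached 77% accuracy), chemically
broader, and carry correlations the grammar does not emulate —
conclusions about actual JAK screening performance require the original
supplementary compound lists, which are not machine-readable.

## Numerical and degenerate-input choices

* Empty autocorrelation lags, zero weight variance, fewer than five
  bonds (Eig05), single atoms (JGI, IC) all return 0; these conventions
  are documented on each function and asserted in tests.
* Wilks' λ is clamped to [0, 1]; a singular total scatter raises an
  error naming the cause (collinear or constant descriptors) rather than
  returning NaN.
* λ = 0 maps to F = ∞ with p = 0; λ = 1 to F = 0 with p = 1.
* Stepwise ties (equal λ) break by descriptor name; all resampling is
  seeded; reruns of the pipeline with one config are byte-identical.
* Percentages in classification tables are rounded half-up to integers,
  matching the published table style (one printed cell, 24/33 shown as
  72, appears truncated rather than rounded; the package rounds).

## Known limitations

* The SMILES dialect covers the organic subset, brackets, rings and
  branches but not reaction SMILES, wildcard atoms, or explicit aromatic
  bond perception from Kekulé input — aromatic rings must be written in
  aromatic (lowercase) form, as all shipped structures are.
* Published model coefficients are unavailable (typeset as images), so
  `evaluate_df` on registry entries errors informatively; refit models
  or printed DF values are the working paths.
* The dipole-moment and log P atomic contribution tables are documented
  approximations at element/bond-class resolution, not the proprietary
  per-environment tables of the original descriptor software; absolute
  values of Eig05_AEA(dm) and P_VSA_LogP_5 can differ from that software
  even though orderings and the tested invariants hold.
* The subtype overlap zone is published only pictorially; the shipped
  threshold (JAK1 overlap below DF_1 = 2.5) is calibrated once against
  the printed decision table.
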