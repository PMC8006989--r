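---
title: "Methods: relationship networks over protein sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relationship networks over protein sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfnet)
```

## The question the pipeline answers

Given a set of protein sequences grouped into structural classes (such as
the mainly-alpha / mainly-beta / mixed top classes of CATH, or the four
top classes of SCOP), which *sequence features* are most strongly related
to the other features, and does that relational importance differ between
structural classes? Rather than classifying proteins from feature vectors,
the pipeline treats each feature as a node of a network: for a class of
N_s proteins and a feature scheme with K components, the N_s x K feature
matrix yields K feature *series* (its columns), pairwise relations between
series become weighted edges, and node centralities then rank the features
by how embedded they are in the web of relations.

## Feature schemes

Six schemes are extracted per protein, analyzed separately because their
value ranges (and hence relation magnitudes) differ:

* **N, mu, D** — the three 20-component blocks of the natural vector: per
  amino acid, its count, the mean of its positions, and the normalized
  second central moment of its positions, `D2_k = sum_i (s_ki - mu_k)^2 /
  (n_k n)`. Positions are `index - 1 + offset`. The "first residue as
  origin" convention is ambiguous between a distance of 0 and an index of
  1 for the first residue; the package defaults to `offset = 1` (the
  position-index convention of the natural-vector literature) and supports
  `offset = 0`. The choice shifts every mu by a constant and leaves D
  unchanged, so it does not move correlations at all and affects the other
  measures only through binning boundaries.
* **APF** — the 10 sequence-averaged physical property factors. The factor
  values are not part of this package's contribution; the bundled table
  carries the standard published factor set (see
  `inst/extdata/PROVENANCE.md`) and can be swapped by passing any 20 x M
  table to `load_property_table()`.
* **PseAAC0 / PseAAC10** — type-1 pseudo amino acid composition at
  lambda = 0 (plain frequencies) and lambda = 10. The correlation function
  Theta is the mean of squared differences of three properties
  (hydrophobicity, hydrophilicity, side-chain mass), each standardized to
  mean 0 and sample SD 1 over the 20 amino acids. The sequence-order
  weight is `w = 0.05`. Since lambda must be smaller than the sequence
  length, sequences shorter than 20 residues are dropped at input, along
  with any record containing a non-canonical letter — the feature
  formulas are defined only on the 20 canonical types, so such records
  are dropped whole rather than silently recoded.

All schemes output fixed-dimensional vectors; an amino acid absent from a
sequence contributes `(0, 0, 0)` to its N/mu/D entries, keeping the
60-dimensional layout intact and finite.

## Three connectivity measures

For every pair of feature series the pipeline computes three deliberately
independent relation estimates:

* **CR** — absolute Pearson correlation: symmetric *linear* dependence in
  [0, 1]. A constant series (e.g. an amino acid absent from every protein
  of a small class) has undefined correlation; its off-diagonal entries
  are set to 0 with a warning rather than propagating NaN.
* **nMIR** — plug-in mutual information on discretized series, normalized
  by the maximum Shannon entropy over all series of the matrix
  (`I'_ij = I(X_i; X_j) / H_max` off-diagonal, `H(X_i) / H_max` on the
  diagonal): symmetric *model-free* dependence in [0, 1]. Natural
  logarithms are used throughout; the normalization cancels the base.
* **TE** — transfer entropy, the conditional mutual information
  `I(X_i,t+1 ; X_j,t-embedding | X_i,t-embedding)`: *directed*,
  non-deterministic dependence in nats. A series copies nothing beyond
  its own past from a deterministic duplicate of itself, so TE vanishes
  on deterministic relations — the property that makes it complementary
  to CR/nMIR, and the reason a pair can show high CR/nMIR with zero TE
  (deterministic) or the reverse (noisy directed coupling).

A planted example of the complementarity (the values below are computed
by this vignette's code, not quoted):

```{r measures}
x <- simulate_feature_series(2000, 2, "nonlinear", seed = 8)
c(CR = correlation_matrix(x)$values[1, 2],
  nMIR = nmir_matrix(x)$values[1, 2])
```

The squared latent variable is almost uncorrelated with the original but
shares most of its information — low CR, high nMIR flags a nonlinear
symmetric relation.

### Discretization

The entropy/MI estimator is a plug-in over `bins = 10` equal-frequency
bins by default (`equal_width` available). Equal-frequency bins are cut
at the *unique empirical quantiles of the values*, so an observation's
state depends only on its value, never on its row index. This matters:
the permutation-robustness analysis below rests on CR and nMIR being
exactly invariant under joint row permutations, and a rank-based
tie-break would silently break that invariance on tied data — count
features are heavily tied. Ties that straddle a quantile boundary
collapse into one bin, slightly unbalancing bin occupancy, which is the
price of value-based (hence permutation-invariant) binning. Series with
fewer than two distinct values collapse to a single state with a warning.

### Transfer entropy estimation

The paper-level procedure prescribes a nearest-neighbour estimator with
embedding lengths `l = k = 5` (equal lengths being the basic requirement
for transfer detection on real-valued data). The package implements the
Kraskov–Stoegbauer–Grassberger / Frenzel–Pompe conditional-MI form in
C++: Chebyshev norm, `knn = 4` neighbours, counting marginal-space
neighbours strictly inside the k-th joint-space neighbour distance. The
raw estimate is bias-corrected per ordered pair (j -> i) by generating
`q = 10` surrogates of the *target* series, subtracting the surrogate
maximum, and clipping at zero:
`TE_C = max(0, TE - max_q TE^(q))`. Correcting against the surrogate
maximum means an exchangeable null pair survives with probability about
1/(q + 1), so roughly 10/11 of null entries are exactly zero — the
observed zero fraction on independent series sits at ~90%, by
construction, not by tuning.

Two conventions deserve flagging:

* The surrogate randomizes the *target* (the procedure is stated that
  way), although randomizing the source is the more common practice; both
  break the source-target alignment, and the implemented form follows the
  stated one. The default surrogate is a circular time shift by a random
  offset in [N/4, 3N/4] — the "time-shifted" technique, which preserves
  marginals and autocorrelation — with a full random `shuffle` also
  available.
* The matrix is laid out with `entry (i, j) = TE_C(j -> i)` (columns act
  as sources), the convention under which the network formulas for in-
  and out-degree are row and column sums respectively. The alternative
  (rows as sources) appears in one displayed matrix of the source
  procedure; the network-construction convention is the one fixed here.

Exact ties degenerate nearest-neighbour counts, so the matrix driver adds
a deterministic seeded jitter of relative amplitude 1e-10 before
estimation — ten orders of magnitude under the data scale, preserving the
estimates while making neighbour counts well-defined on count-valued
features.

## Networks and centralities

Relation matrices become weighted adjacency matrices with the diagonal
zeroed (edges only between distinct features). CR/nMIR networks are
undirected and get degree and eigenvector centralities (leading right
eigenvector by power iteration, tolerance 1e-12, non-negative
orientation). TE networks are directed and get in/out degree, Katz
`y = (I - alpha A)^{-1} 1`, and the out-strength-scaled PageRank
`y = D (D - alpha A)^{-1} 1` with `d_ii = max(1, out-degree_i)`.

The Katz attenuation prescription "slightly smaller than the leading
eigenvalue" cannot make `I - alpha A` invertible when the leading
eigenvalue k1 exceeds 1, so it is read as *alpha slightly below 1/k1*:
`alpha = 0.9 / k1` by default (attenuation factor configurable; alpha = 0
for an empty network, where Katz and PageRank correctly return the
uniform vector). PageRank damping defaults to 0.85. Eigenvector
centrality is restricted to undirected networks (directed networks have
distinct left/right leading eigenvectors and zero-in-degree pathologies).

Every centrality vector is max-normalized — divided by its maximum so the
most central feature scores 1 — making magnitudes comparable across
networks; an all-zero vector stays zero.

## Permutation ensemble and robustness

Because the feature series inherit the arbitrary ordering of proteins,
the entire analysis is repeated over P = 100 seeded joint row
permutations of the feature matrix (permutation 1 is the identity). CR
and nMIR are mathematically invariant under joint row permutations —
correlation is a symmetric function of the rows, and value-based binning
makes the MI plug-in one too — so their permutation spread measures
nothing but floating-point summation order, of magnitude 1e-15 or below.
The package exploits the invariance: by default CR/nMIR are computed once
per matrix and replicated, with `strict = TRUE` available to recompute
them literally per permutation (the tests assert the equivalence). TE is
genuinely order-dependent (its embeddings read the rows as a series), so
its centralities vary at the 1e-2 to 1e-1 scale across permutations.

The robustness table is the two-stage average of that spread: SD per
feature over permutations, averaged over the K features, then over the
structural classes.

## Ordering features by significance

Per network and centrality, each feature contributes P = 100 normalized
centrality samples. A Levene check (standard upper-tail form) first
diagnoses variance heterogeneity across features — the printed statistic
in the source procedure carries an extra sample-size factor in its
denominator and a two-sided acceptance region; the package implements the
textbook statistic, since the test's only pipeline role is to justify
unequal-variance comparisons. Features are then ordered by pairwise
one-sided Welch t-tests with Welch–Satterthwaite degrees of freedom
(v = 198 for two equal-variance samples of 100): feature i scores one
point for every feature whose centrality is significantly lower at level
theta, ties sharing a score. The sweep over
theta in {0.25, 0.1, 0.05, 0.025, 0.01, 0.005} is reported with its
monotonicity: smaller theta narrows the rejection regions, so the
resolved pairs at a smaller theta are a subset of those at a larger one.
No multiple-testing correction is applied across the K(K-1)/2 pairs; the
sweep over raw theta levels *is* the sensitivity analysis, and users who
need familywise control should apply it downstream.

Degenerate cases are decisions, not errors: two constant samples with
equal means compare as "no difference"; with unequal means the t statistic
is infinite and the decision follows its sign.

## What the synthetic data emulates — and what it does not

`simulate_sequences()` plants structure at the composition level:
per-class amino-acid profiles (Dirichlet-perturbed from uniform via
`class_compositions()`), i.i.d. residues or a first-order Markov
repetition bias for arrangement structure, and uniform lengths with a
floor of 20. This emulates exactly what the cross-protein feature series
respond to — composition and arrangement differences between classes —
and deliberately nothing else: no homology, no secondary-structure
grammar, no length-composition coupling, no database redundancy
filtering. Passing tests therefore certify the *statistical machinery*
(estimators, invariances, orderings), not any biological conclusion about
real CATH/SCOP classes; reproducing those requires the real 8321- and
4836-protein sequence sets, whose retrieval is out of scope (only their
deposited id-list format is supported, via the MAT reader).

`simulate_feature_series()` plants ground truth directly at the series
level — a correlation matrix, a squared-latent nonlinear pair, or a
stable first-order VAR with chosen directed edges — giving each
connectivity measure a target with a known answer: CR recovers planted
rho within sampling error (~3/sqrt(n)), nMIR flags the nonlinear pair,
and the bias-corrected TE matrix recovers a planted `1 -> 2` edge as a
positive `(2, 1)` entry with the reverse entry clipped to zero in >= 90%
of seeds at n = 1000.

## Problem sizes and numerical choices

The shipped analysis scripts and tests run at sizes chosen to exercise
every code path at desk scale: 3 classes x 60-100 proteins for
sequence-level runs, P = 100 permutations for undirected and Welch
analyses, P = 20 for directed TE ensembles on the K = 10 scheme, and
n = 500-2000 for ground-truth series. The estimators are all O(n^2) or
cheaper per pair; the TE estimator is the only compiled component, and a
full K = 20 bias-corrected TE matrix at N_s = 100 costs a few seconds.

Other numerical conventions, collected: natural logs everywhere; power
iteration tolerance 1e-12 with non-negative orientation; `max(raw) = 0`
centralities normalize to zero; a numerically singular `I - alpha A`
retries once with alpha halved before failing; RNG flows from a single
master seed through named sub-streams (`spawn_seeds`), so any single
permutation or surrogate batch is reproducible in isolation.

## Known limitations

* The plug-in MI estimator is biased upward at small N_s; nMIR values
  from classes of a few dozen proteins are comparable within a run but
  not across very different sample sizes.
* TE with l = k = 5 on feature series treats protein order as a time
  axis; the permutation ensemble quantifies exactly how much of the
  result is order noise, and the TE robustness SDs (1e-2 to 1e-1) should
  accompany any interpretation of individual TE edges.
* Bias correction by the surrogate maximum is conservative and leaves a
  ~1/(q+1) false-positive floor per entry; q = 10 trades that floor
  against runtime.
* The Levene diagnostic and Welch ordering assume approximately normal
  centrality samples, defensible at P = 100 by the CLT but not enforced.
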