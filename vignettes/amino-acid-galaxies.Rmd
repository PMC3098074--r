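---
title: "Amino acid galaxies: vector representations of substitution matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amino acid galaxies: vector representations of substitution matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aagalaxy)
```

## The model

A protein substitution matrix is a symmetric 20x20 table of log-odds scores
$s_{ab}$ for aligning residues $a$ and $b$. It quantifies pairwise
exchangeability but says nothing about residues individually. This package
derives a per-residue description from the matrix itself: a set of 20
Euclidean vectors whose dot products reproduce the scores.

Singular value decomposition writes any symmetric $S$ as
$S = \sum_{K} w_K\, U_K V_K^T$ with positive, decreasing singular values
$w_K$. For a symmetric matrix each component has $U_K = \pm V_K$; components
with $U_K = -V_K$ carry negative eigenvalues, which cannot be realized as
real dot products, and are omitted (`aa_embed()` records them in
`$dropped`). The retained coordinates

$$ x_{Ka} = U_{Ka} \sqrt{w_K} $$

define the residue vectors, and $\hat s_{ab} = \vec v_a \cdot \vec v_b$ is
the rank-$R$ reconstruction. Two diagnostics measure the agreement:

* the **quality index**
  $q = 100\,\bigl(1 - \lVert S - \hat S\rVert_F^2 / \lVert S\rVert_F^2\bigr)$
  in percent, and
* the **Pearson correlation** over the 210 upper-triangular entries
  (190 pairs + 20 diagonal cells), which is insensitive to systematic
  offsets.

Two algebraic forms of the quality ratio are plausible (squared or unsquared
Frobenius ratio); the squared form is the one that reproduces the published
quality sequence of the rounded PAM series (28.5% for PAM10, 70.6% for
PAM160, 94.7% for PAM500 — values this package recovers to the printed
digit), and is the form implemented.

## Shifts, centering and the galaxy

Adding a constant to every cell of $S$ (a *shift*) changes the decomposition
drastically, but not the underlying geometry: the vector set, re-centered on
its centroid, is invariant up to rigid motion. This centered 20-point cloud
is the **amino acid galaxy**; its radius $R_g$ is the mean distance of the
points from their centroid. Because score matrices carry a large negative
mean (they are "negatively shifted" versions of an approximately centered
table), the raw dot products systematically overestimate the scores, and the
overestimation worsens at short evolutionary distances — quality drops from
93% (BLOSUM30) to 58% (BLOSUM100) and to 28% for PAM10. Centering the matrix
before decomposing (`aa_embed(center = TRUE)`, the default) removes most of
the negative spectrum and lifts quality to 98–100% across the BLOSUM series.

The full correction fits, by least squares, a translation $\vec T$ applied
to every vector and a scalar shift:
$\hat s_{ab} = (\vec v_a + \vec T)\cdot(\vec v_b + \vec T) + \textit{shift}$.
At the optimum the shift is tied to the translation by
$\textit{shift} = \bar S - \lVert \vec t + \vec T \rVert^2$ ($\bar S$ the
400-cell matrix mean, $\vec t$ the vector centroid); substituting this
relation makes the objective exactly quadratic in $\vec T$, so
`fit_shift_translation()` solves a small linear system (with a
pseudo-inverse fallback for singular systems, flagged in the result). On
every one of the 65 bundled matrices the refined reconstruction exceeds
99.0% quality and 0.990 correlation.

Two distinct "centered reconstruction" conventions appear in this field and
both are exposed:

* decompose the centered matrix and compare with it (`aa_embed()` with
  `center = TRUE`); and
* re-center the *raw* decomposition's vectors and place their Gram back at
  the matrix mean, comparing against the original scores
  (`galaxy_reconstruction()`). For the rounded PAM series this second
  convention is the one that reproduces the published centered values
  (89.5% for PAM160, with correlations 0.985/0.943/0.923 for
  PAM500/PAM160/PAM10).

## Units along a series

The bundled rounded files use series-dependent score units (half-bit for
BLOSUM62, third-bit for BLOSUM50, $\ln 2/7$ for PAM500, ...). Quality,
correlation, clustering and property contributions are scale-invariant, but
the matrix mean and the galaxy radius are not, so cross-series statistics
must be computed in a common unit. `submat(name, bits = TRUE)` rescales
scores to bits using the per-file scale annotation. With that convention the
BLOSUM series shows a ~64% radius growth from index 30 to 100 and the
near-perfect anti-correlation (about $-0.999$ here) between matrix mean and
relative entropy; the published PAM series statistics (anti-correlation
$-0.978$, radius growth ~75%) correspond to the files in their native mixed
units, and `series_summary()` therefore takes whatever units the caller
loads.

## Clustering

`cluster_residues()` runs squared-Euclidean k-means on the galaxy in its
full retained dimensionality, keeping the best of 50 random restarts under a
fixed seed (base R provides no k-means++ initialization; with 20 points and
50 restarts the search recovers the same optimum across seeds). On the
BLOSUM62 galaxy the partitions for k = 2-4 are the classical ones: polar vs
non-polar, then aromatics {F, W, Y} split from the aliphatics {C, I, L, M,
V}, then small/neutral {A, G, P, S, T} from the charged-and-associated
group. At k = 5 the optimum found here isolates cysteine (inertia 76.4)
rather than histidine (inertia 78.8, the variant reported for non-rounded
score tables); both partitions are chemically sensible, and the discrepancy
is a reminder that integer rounding of the scores perturbs fine clustering
structure.

## Physicochemical properties

A scalar property (hydrophobicity, charge, ...) is a 20-vector $p_a$,
centered and normalized to unit Euclidean norm (`normalize_property()`), so
that the self-sum $\sum_a p_a^2 = 1$. The best **property axis** minimizes
the squared distances between the scaled property positions
$\lambda p_a \hat n$ on a line and the residue points; the optimum is
$\lambda \hat n = \sum_a p_a \vec v_a$. The **contribution** of the property
is the spread it explains,
$100\,\lambda^2 / \sum_a \lVert \vec v_a \rVert^2$ percent, bounded above by
the leading component's share $100\,w_1/\sum_K w_K$ (`max_contribution()`,
about 19% for BLOSUM62). A random centered unit pseudo-property has expected
contribution $100/19 \approx 5.3\%$ *for any galaxy* (its expected squared
cosine against any fixed axis of the 19-dimensional centered property space
is $1/19$); the seeded Monte-Carlo baseline
(`random_property_baseline()`) reproduces this, matching the published
$5.2 \pm 1.4$.

The bundled table of 17 scales (`property_scales()`) is a reconstruction:
charge and aromaticity are defined exactly (R, K = +1 / D, E = -1; F, W, Y
= 1), and the other slots carry canonical AAindex scales of the named
property family, transcribed from the AAindex distribution with their
accession recorded per row. The original study's exact source table is not
redistributed here, so individual contributions can differ by up to about a
percentage point from published values; computed values are reported as-is,
never adjusted toward the reference.

## Distances and the triangle inequality

Two classical similarity-to-distance conversions are provided:
$d_{ab} = s_{aa} + s_{bb} - 2 s_{ab}$ (`"linear"`) and its square root
(`"sqrt"`). On a true Gram matrix the sqrt form equals the exact Euclidean
inter-point distances. On real score matrices neither is guaranteed metric;
`triangle_violations()` audits all 1140 residue triplets and reports **two
counts**: flagged triplets (out of 1140) and violated inequality instances
(out of 3420). For the sqrt form the audit finds zero violations for every
BLOSUM matrix and every PAM matrix up to index 210. Above PAM210 the
violated-inequality fraction stays below 3% (the counting convention under
which the published "at most 3% of the distance triplets" holds on these
exact files), while the flagged-triplet fraction reaches about 7.5%.

Three ways of building vectors from distances are included for comparison:
classical Torgerson scaling (`torgerson_embed()`, via `stats::cmdscale`),
direct stress minimization (`stress_fit()`) and maximization of the
anti-correlation between scores and distances (`anticorrelation_fit()`),
both seeded multi-start quasi-Newton optimizations (20 restarts by
default). On BLOSUM62 the anti-correlation fit achieves a stronger negative
score-distance correlation than the Torgerson configuration, consistent
with the published ranking of the three approaches. Note that for a Gram
matrix of collinear points the optimum of the anti-correlation objective in
one dimension converges to about $-0.80$, not $-1$: the absolute-difference
distance cannot be an affine function of a product of coordinates.
`vector_metric()` gives pairwise Euclidean distances between galaxy points —
a true metric by construction, verified to produce zero violations on all
65 bundled matrices.

## Consensus residues

The consensus of an alignment column is the residue whose vector is nearest
to the centroid of the column's residue vectors (gaps ignored, duplicates
weighting the centroid; the "geometric mean" of a vector set is implemented
as the arithmetic centroid, since component-wise geometric means are
undefined for negative coordinates). This is equivalent to minimizing the
total squared vector distance to the column, which the tests verify against
a brute-force scan. With the bundled rounded-BLOSUM62 galaxy the example
column {H, R, V} resolves to R (distances R 2.06, H 2.29, V 2.43); the
published resolution of that column to T evidently relies on vectors from
the non-rounded score table, which is not redistributable here. Ties are
broken in canonical residue order and reported.

## Synthetic generators

`random_gram()` produces Gram matrices of known centered point sets
(optionally shifted) — the ground-truth oracle used throughout the tests for
rank recovery, shift recovery and shift invariance. `random_pseudo_matrix()`
draws a symmetric joint residue distribution $q_{ab}$ from a symmetric
Dirichlet model on the 210 unique cells, and derives the log-odds scores,
the marginals and the mutual information; independence gives zero scores and
zero information, perfect covariation saturates the information at the
marginal entropy, and over a seeded ensemble the matrix mean anti-correlates
with the mutual information, mirroring the behaviour of the real series.

## Numerical choices and limitations

* Canonical residue order: alphabetical one-letter
  (`r paste(amino_acids(), collapse = " ")`), used everywhere.
* Rank tolerance: components with $w_K \le 10^{-10} w_1$ are discarded as
  noise (not recorded as dropped).
* Axis signs: each retained component is oriented so its largest-magnitude
  coordinate is positive, making outputs reproducible across linear-algebra
  backends.
* Superposition allows improper (reflecting) orthogonal maps by default,
  since SVD axes carry arbitrary signs; galaxies of unequal dimensionality
  are zero-padded.
* The fixture registry bundles the standard *rounded* NCBI-format matrices:
  15 BLOSUM (30-90 by 5, 100, and 62; BLOSUM95 is not part of the bundled
  NCBI set) and 50 PAM (10-500 by 10), each with the relative entropy read
  from its header. Non-rounded BLOSUM score tables (published only via the
  BLOCKS database) are not redistributed; quantities that depend on them —
  the 75.7% raw BLOSUM62 quality, the four-decimal $-0.9999$ series
  anti-correlation, the k = 5 clustering variant and the {H, R, V}
  consensus — are reproduced here only up to rounding effects, as discussed
  above.
* Relative entropy is metadata from the matrix file headers; it is never
  recomputed from alignment counts.
* Problem sizes: every analysis operates on 20x20 tables; the test suite
  and the reproduction script run the full 65-matrix collection, a
  1000-draw property baseline and a 300-draw pseudo-matrix ensemble, which
  together complete in a few seconds on a single core.
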