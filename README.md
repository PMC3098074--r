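# aagalaxy

Euclidean amino acid vectors from substitution matrices.

Substitution matrices (BLOSUM, PAM) score the exchangeability of residue
*pairs* but provide no description of residues individually. **aagalaxy**
factorizes a 20x20 substitution matrix by singular value decomposition into
one vector per amino acid, so that scores become dot products:

```
S = sum_K w_K U_K V_K^T,   x_Ka = U_Ka * sqrt(w_K),   s_ab ~ v_a . v_b
```

Components whose left/right singular vectors are opposed (negative
eigenvalues) cannot be realized as real dot products and are omitted. The
agreement between the matrix and its reconstruction is measured by a quality
index `q = 100 * (1 - ||S - Shat||_F^2 / ||S||_F^2)` and by the Pearson
correlation over the 210 upper-triangular entries. A least-squares
translation-plus-shift refinement (`fit_shift_translation()`) pushes the
quality above 99% for every bundled matrix.

The centered vector set — the amino acid "galaxy" — is shift-invariant and
supports a family of downstream analyses:

* galaxy radius and multidimensional rigid-body superposition
  (`galaxy_radius()`, `superpose()`);
* k-means clustering of residues (`cluster_residues()`);
* series-wide statistics relating matrix mean, relative entropy and galaxy
  radius (`series_summary()`);
* best-fit physicochemical property axes and their percent contribution,
  with a random pseudo-property baseline (`fit_property_axis()`,
  `max_contribution()`, `random_property_baseline()`);
* similarity-to-distance conversions with triangle-inequality audits, plus
  a guaranteed-metric distance from the vectors
  (`similarity_to_distance()`, `triangle_violations()`, `vector_metric()`);
* vector-space consensus residues for alignment columns
  (`column_consensus()`, `consensus_sequence()`);
* synthetic generators with exact ground truth (`random_gram()`,
  `random_pseudo_matrix()`).

The package bundles the standard rounded NCBI-format matrix files
(15 BLOSUM, 50 PAM, each with its relative-entropy header) and a table of
17 physicochemical property scales keyed by AAindex accession.

## Worked example

```r
library(aagalaxy)

E <- aa_embed(submat("BLOSUM62"))
E
#> Amino acid vector embedding of BLOSUM62 (centered input)
#> Dimensionality R = 19 (1 component(s) dropped)
#> Dot-product reconstruction: quality 99.0%, correlation 0.9981
#> Shift/translation refinement: quality 99.9%, correlation 0.9997
```

Centering the matrix before decomposing is what makes the dot products
accurate: the raw (non-centered) decomposition of the same matrix reaches
only 77.8% quality (correlation 0.990), because score matrices are strongly
negatively shifted relative to a representable dot-product table.

```r
G <- aa_galaxy(E)
galaxy_radius(G)
#> [1] 2.602457

cluster_residues(G, k = 3)
#> k-means partition (k = 3, inertia 98.54):
#>   { A, D, E, G, H, K, N, P, Q, R, S, T }
#>   { C, I, L, M, V }
#>   { F, W, Y }
```

The k = 3 partition splits the aromatics from the aliphatics and from the
polar group — the classical chemistry of the genetic code, recovered from
scores alone. Property axes quantify how much any scalar scale explains:

```r
arom <- normalize_property(as.numeric(amino_acids() %in% c("F","W","Y")),
                           "aromaticity")
fit_property_axis(G, arom)
#> Property axis 'aromaticity': lambda = 4.353, contribution 13.7%

max_contribution(E)
#> [1] 19.13537
```

Aromaticity explains 13.7% of the spatial spread of the residues, close to
the ~19% ceiling set by the leading component — and far above the ~5.2%
expected of a random pseudo-property. A metric distance table for the same
matrix is one call away:

```r
D <- vector_metric(G)
triangle_violations(D)$count
#> [1] 0
```

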