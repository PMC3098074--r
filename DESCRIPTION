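Package: aagalaxy
Title: Euclidean Amino Acid Vectors from Substitution Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Factorizes 20x20 amino acid substitution matrices (BLOSUM, PAM)
    by singular value decomposition into per-residue Euclidean vectors whose
    dot products reproduce the matrix scores, with a least-squares shift and
    translation refinement. Provides the geometry of the centered vector set
    (the amino acid "galaxy"): radius, multidimensional rigid-body
    superposition, k-means residue clustering and series-wide summaries;
    projection of physicochemical property scales onto best-fit axes with
    contribution percentages and random-property baselines; similarity-to-
    distance conversions with triangle-inequality audits and metric distances
    from the vectors; vector-space consensus residues for alignment columns;
    and synthetic generators (low-rank Gram matrices, pseudo substitution
    matrices from random joint distributions) with known ground truth.
    Ships the standard rounded NCBI-format BLOSUM and PAM series as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
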