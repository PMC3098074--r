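test_that("decomposition recovers an exact low-rank Gram matrix", {
  sg <- random_gram(20, 5, shift = 0, seed = 11)
  E <- aa_embed(sg$gram, center = FALSE, refine = FALSE)
  expect_equal(E$dimensionality, 5)
  expect_identical(nrow(E$dropped), 0L)
  expect_equal(unclass(gram(E)), unclass(sg$gram), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(E$quality, 100, tolerance = 1e-9)
  # retained coordinates carry the singular values: sum_a x_Ka^2 = w_K
  expect_equal(colSums(E$vectors^2), E$singular_values,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the identity matrix yields an orthonormal 20-component frame", {
  I20 <- as_submat(matrix(diag(20), 20, 20, dimnames = list(aa, aa)))
  E <- aa_embed(I20, center = FALSE, refine = FALSE)
  expect_equal(E$dimensionality, 20)
  expect_equal(E$singular_values, rep(1, 20))
  expect_equal(unclass(gram(E)), unclass(I20), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("negative eigencomponents are dropped and raw dot products overestimate", {
  E <- aa_embed(submat("BLOSUM62"), center = FALSE, refine = FALSE)
  expect_gt(nrow(E$dropped), 0)
  expect_true(all(grepl("opposed", E$dropped$reason)))
  # systematic overestimation of the original entries by the raw dot products
  expect_gt(mean(unclass(gram(E)) - unclass(submat("BLOSUM62"))), 0)
})

test_that("quality index and upper-triangle correlation behave as designed", {
  S <- submat("BLOSUM45")
  expect_equal(quality_index(S, S), 100)
  # correlation is insensitive to affine (systematic) errors
  expect_equal(upper_tri_correlation(S, shift_matrix(S, 7)), 1)
  expect_equal(upper_tri_correlation(S, as_submat(unclass(S) * 2 + 7,
                                                  name = "affine")), 1)
  flat <- as_submat(matrix(1, 20, 20, dimnames = list(aa, aa)))
  expect_error(upper_tri_correlation(S, flat), "zero variance")
})

test_that("raw reconstruction quality degrades monotonically along the BLOSUM series", {
  am <- available_matrices()
  bl <- am[am$series == "BLOSUM", ]
  q <- vapply(bl$name[order(bl$index)], function(n)
    aa_embed(submat(n), center = FALSE, refine = FALSE)$quality, 0)
  expect_true(all(diff(q) < 0))
})

test_that("the galaxy is shift-invariant", {
  sg <- random_gram(20, 4, shift = 0, seed = 5)
  g0 <- aa_embed(sg$gram, center = FALSE, refine = FALSE)$galaxy
  for (c in c(0.5, 2, 10)) {
    Sc <- shift_matrix(sg$gram, c)   # diagonal stays positive
    gc <- aa_embed(Sc, center = FALSE, refine = FALSE)$galaxy
    expect_lt(superpose(gc, g0)$rmsd, 1e-6)
  }
})

test_that("decompose/gram round-trips and center_vectors zeroes the centroid", {
  E <- aa_embed(submat("PAM250"), refine = FALSE)
  E2 <- aa_embed(gram(E), center = FALSE, refine = FALSE)
  expect_equal(unclass(gram(E2)), unclass(gram(E)), tolerance = 1e-9,
               ignore_attr = TRUE)
  cv <- center_vectors(E)
  expect_equal(colMeans(unclass(cv$galaxy)), rep(0, ncol(cv$galaxy)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("shift/translation fit recovers a known applied shift", {
  sg <- random_gram(20, 6, shift = 2.5, seed = 21)
  # a positively shifted Gram is itself PSD, so decompose the centered matrix
  # (the true point set) and let the fit place it back
  E <- aa_embed(sg$gram, center = TRUE, refine = FALSE)
  f <- fit_shift_translation(sg$gram, E)
  expect_equal(f$shift, 2.5, tolerance = 1e-6)
  expect_lt(sqrt(sum(f$translation^2)), 1e-6)
  expect_equal(f$quality, 100, tolerance = 1e-6)
})

test_that("refinement never does worse than the raw reconstruction", {
  for (nm in c("BLOSUM30", "BLOSUM62", "PAM10", "PAM250", "PAM500")) {
    S <- submat(nm)
    E <- aa_embed(S, center = FALSE, refine = TRUE)
    expect_gte(E$refinement$quality, quality_index(S, gram(E)))
  }
})

test_that("strongly negative shifts break the dot-product representation", {
  sg <- random_gram(20, 4, shift = 0, seed = 8)
  shift_bad <- -(max(diag(unclass(sg$gram))) + 1)  # all diagonals negative
  Sb <- shift_matrix(sg$gram, shift_bad)
  E <- aa_embed(Sb, center = FALSE, refine = FALSE)
  expect_gt(nrow(E$dropped), 0)
  expect_lt(E$quality, 100 - 1e-3)
})

test_that("galaxy-based reconstruction matches the refined fit structure", {
  E <- aa_embed(submat("PAM160"), center = FALSE, refine = FALSE)
  g <- galaxy_reconstruction(E)
  # shift equals the matrix mean when the translation is pinned to -centroid
  expect_equal(g$shift, matrix_mean(submat("PAM160")))
  full <- fit_shift_translation(submat("PAM160"), E)
  expect_gte(full$quality, g$quality)   # free T can only do better
})
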