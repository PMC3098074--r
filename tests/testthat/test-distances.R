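test_that("similarity-to-distance conversions have zero diagonals and exact Gram limits", {
  S <- submat("BLOSUM62")
  for (form in c("linear", "sqrt")) {
    D <- similarity_to_distance(S, form)
    expect_equal(unname(diag(unclass(D))), rep(0, 20))
    expect_equal(unclass(D), t(unclass(D)))
  }
  # on a true Gram matrix the sqrt form is the exact Euclidean distance
  sg <- random_gram(20, 5, seed = 17)
  D <- similarity_to_distance(sg$gram, "sqrt")
  expect_equal(unclass(D), as.matrix(dist(sg$true_points)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("negative squared distances are refused with the offending pair", {
  M <- matrix(0, 20, 20, dimnames = list(aa, aa))
  M["A", "C"] <- M["C", "A"] <- 5   # s_AA + s_CC - 2 s_AC = -10
  expect_error(similarity_to_distance(as_submat(M), "linear"), "A/C")
})

test_that("triangle violations are counted per triplet and per inequality", {
  # exact Euclidean distances violate nothing
  sg <- random_gram(20, 5, seed = 23)
  D <- similarity_to_distance(sg$gram, "sqrt")
  v <- triangle_violations(D)
  expect_identical(v$count, 0L)
  expect_identical(v$inequality_count, 0L)

  # one constructed violating triplet: d(A,C)=1, d(C,D)=1, d(A,D)=5, rest 3
  M <- matrix(3, 20, 20, dimnames = list(aa, aa)); diag(M) <- 0
  M["A", "C"] <- M["C", "A"] <- 1
  M["C", "D"] <- M["D", "C"] <- 1
  M["A", "D"] <- M["D", "A"] <- 5
  v <- triangle_violations(structure(M, class = c("dist_matrix", "matrix")))
  expect_identical(v$count, 1L)
  expect_identical(v$inequality_count, 1L)
  expect_identical(unlist(v$triplets[1, ], use.names = FALSE), c("A", "C", "D"))
  expect_equal(v$fraction, 100 / 1140)
})

test_that("classical scaling round-trips exact distances", {
  sg <- random_gram(20, 4, seed = 29)
  D <- similarity_to_distance(sg$gram, "sqrt")
  X <- torgerson_embed(D, 4)
  fit <- superpose(aa_galaxy(X), aa_galaxy(sg$true_points))
  expect_lt(fit$rmsd, 1e-6)
  expect_warning(torgerson_embed(D, 19), "truncating")
})

test_that("an all-equal distance table embeds as a regular simplex", {
  cst <- 2
  M <- matrix(cst, 20, 20, dimnames = list(aa, aa)); diag(M) <- 0
  X <- torgerson_embed(structure(M, class = c("dist_matrix", "matrix")), 19)
  d <- as.matrix(dist(X))
  expect_equal(d[upper.tri(d)], rep(cst, 190), tolerance = 1e-9)
  # centered simplex vertex norm: c * sqrt((n-1)/(2n))
  expect_equal(sqrt(rowSums(X^2)), rep(cst * sqrt(19 / 40), 20),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("stress minimization reaches zero in the true dimension and is seeded", {
  sg <- random_gram(20, 2, seed = 31)
  D <- similarity_to_distance(sg$gram, "sqrt")
  X <- stress_fit(D, dims = 2, seed = 1, restarts = 5)
  expect_lt(attr(X, "stress"), 1e-8)
  X1 <- stress_fit(D, dims = 1, seed = 1, restarts = 5)
  expect_gt(attr(X1, "stress"), 1e-4)   # dimensional obstruction
  X2 <- stress_fit(D, dims = 2, seed = 1, restarts = 5)
  expect_identical(unclass(X), unclass(X2))
})

test_that("anticorrelation fitting is strong for collinear geometry and seeded", {
  sg <- random_gram(20, 1, seed = 37)
  X <- anticorrelation_fit(sg$gram, dims = 1, seed = 2, restarts = 5)
  # the converged optimum of cor(score, |distance|) for a 1-D Gram is ~ -0.80
  expect_lt(attr(X, "correlation"), -0.75)
  X2 <- anticorrelation_fit(sg$gram, dims = 1, seed = 2, restarts = 5)
  expect_identical(unclass(X), unclass(X2))
})

test_that("direct anti-correlation fitting beats classical scaling on BLOSUM62", {
  S <- submat("BLOSUM62")
  X <- anticorrelation_fit(S, dims = 3, seed = 1, restarts = 5)
  Xt <- torgerson_embed(similarity_to_distance(S, "sqrt"), 3)
  off <- upper.tri(unclass(S))
  ct <- cor(unclass(S)[off], as.matrix(dist(Xt))[off])
  expect_lt(attr(X, "correlation"), ct)
})

test_that("vector-derived distances are a true metric with sensible neighborhoods", {
  G <- aa_galaxy(blosum62)
  D <- vector_metric(G)
  v <- triangle_violations(D)
  expect_identical(v$count, 0L)
  # aliphatic residues sit closer to each other than to the acidic pair
  ali <- c("L", "I", "V", "M")
  within <- unclass(D)[ali, ali][upper.tri(diag(4))]
  across <- unclass(D)[ali, c("D", "E")]
  expect_lt(max(within), min(across))
})
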