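test_that("parsing normalizes residue order and drops extended codes", {
  # 4-residue toy written in two different orders plus extended columns
  base <- c("# toy", "   A  C  D  E",
            "A  4  0 -2 -1", "C  0  9 -3 -4", "D -2 -3  6  2", "E -1 -4  2  5")
  perm <- c("# toy permuted", "   E  A  D  C",
            "E  5 -1  2 -4", "A -1  4 -2  0", "D  2 -2  6 -3", "C -4  0 -3  9")
  # embed the toy block into a full 20x20 by padding with BLOSUM62 scores
  pad <- function(order4, rows4) {
    M <- unclass(blosum62)
    for (i in seq_along(order4)) for (j in seq_along(order4))
      M[order4[i], order4[j]] <- rows4[i, j]
    M
  }
  r1 <- matrix(c(4, 0, -2, -1, 0, 9, -3, -4, -2, -3, 6, 2, -1, -4, 2, 5),
               4, 4, byrow = TRUE)
  r2 <- matrix(c(5, -1, 2, -4, -1, 4, -2, 0, 2, -2, 6, -3, -4, 0, -3, 9),
               4, 4, byrow = TRUE)
  A <- as_submat(pad(c("A", "C", "D", "E"), r1))
  B <- as_submat(pad(c("E", "A", "D", "C"), r2))
  expect_identical(unclass(A), unclass(B))

  # bundled file carries B, Z, X, * columns; they must be gone
  S <- submat("BLOSUM62")
  expect_identical(dim(unclass(S)), c(20L, 20L))
  expect_identical(rownames(S), amino_acids())
  # tryptophan is the largest diagonal (and overall) element
  expect_identical(which.max(diag(unclass(S))), c(W = 19L))
})

test_that("parser errors on missing residues and asymmetry", {
  f <- write_matrix_fixture(c("   A  C", "A  1  0", "C  0  2"))
  expect_error(read_submat(f), "missing canonical residues")
  M <- unclass(blosum62)
  M["A", "C"] <- M["A", "C"] + 1
  expect_error(as_submat(M), "not symmetric.*A/C|C/A")
})

test_that("matrix mean, shift and centering obey their algebra", {
  Sc <- as_submat(matrix(3.5, 20, 20, dimnames = list(aa, aa)))
  expect_equal(matrix_mean(Sc), 3.5)
  expect_equal(unclass(center_matrix(Sc)), unclass(shift_matrix(Sc, -3.5)),
               ignore_attr = TRUE)
  expect_true(all(unclass(center_matrix(Sc)) == 0))

  S <- blosum62
  expect_equal(matrix_mean(center_matrix(S)), 0, tolerance = 1e-12)
  # shift composition and the mean-shift relation
  expect_equal(unclass(shift_matrix(shift_matrix(S, 1.25), -0.5)),
               unclass(shift_matrix(S, 0.75)), ignore_attr = TRUE)
  expect_equal(matrix_mean(shift_matrix(S, 2.5)), matrix_mean(S) + 2.5,
               tolerance = 1e-12)
  # centering is idempotent
  expect_equal(unclass(center_matrix(center_matrix(S))),
               unclass(center_matrix(S)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("Frobenius norm has its closed forms and spectral identity", {
  Z <- as_submat(matrix(0, 20, 20, dimnames = list(aa, aa)))
  expect_equal(frobenius_norm(Z), 0)
  D3 <- as_submat(matrix(diag(3, 20), 20, 20, dimnames = list(aa, aa)))
  expect_equal(frobenius_norm(D3), 3 * sqrt(20))
  # sum of squared singular values (all 20) equals the squared norm
  for (nm in c("BLOSUM62", "PAM250")) {
    S <- submat(nm)
    E <- aa_embed(S, center = FALSE, refine = FALSE)
    expect_equal(sum(E$all_singular_values^2), frobenius_norm(S)^2,
                 tolerance = 1e-9)
  }
})

test_that("write/parse round-trips a matrix", {
  S <- submat("PAM120")
  f <- tempfile()
  write_submat(S, f)
  S2 <- read_submat(f, name = "PAM120")
  expect_equal(unclass(S2), unclass(S), ignore_attr = TRUE)
  expect_equal(attr(S2, "entropy"), attr(S, "entropy"))
})

test_that("the registry serves the full bundled series with entropy metadata", {
  am <- available_matrices()
  expect_identical(sum(am$series == "BLOSUM"), 15L)
  expect_identical(sum(am$series == "PAM"), 50L)
  expect_identical(sort(am$index[am$series == "PAM"]), seq(10L, 500L, 10L))
  ent <- vapply(c("BLOSUM30", "BLOSUM100", "PAM10", "PAM500"),
                function(n) attr(submat(n), "entropy"), 0)
  expect_true(all(is.finite(ent) & ent > 0))
  expect_error(submat("BLOSUM9000"), "unknown matrix")
})

test_that("bit rescaling uses the per-file scale annotation", {
  S <- submat("BLOSUM62")
  Sb <- submat("BLOSUM62", bits = TRUE)
  expect_equal(attr(S, "scale"), 2)           # half-bit units
  expect_equal(unclass(Sb) * 2, unclass(S), ignore_attr = TRUE)
  # rounded BLOSUM means, in bits, grow more negative with the index
  m <- vapply(c("BLOSUM30", "BLOSUM62", "BLOSUM100"),
              function(n) matrix_mean(submat(n, bits = TRUE)), 0)
  expect_true(all(diff(m) < 0))
})
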