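# shared helpers for building exact-ground-truth fixtures in code

aa <- amino_acids()

# random orthogonal matrix (Haar-ish via QR)
random_rotation <- function(d, seed = 1) {
  Q <- with(list(), {
    set.seed(seed)
    qr.Q(qr(matrix(rnorm(d * d), d, d)))
  })
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# a centered 20-point set with unit distance from the origin:
# ten antipodal pairs of random unit directions
unit_sphere_galaxy <- function(d = 4, seed = 3) {
  set.seed(seed)
  U <- matrix(rnorm(10 * d), 10, d)
  U <- U / sqrt(rowSums(U^2))
  P <- rbind(U, -U)
  rownames(P) <- aa
  aa_galaxy(P)
}

# write a small NCBI-style matrix file and return its path
write_matrix_fixture <- function(lines) {
  f <- tempfile(fileext = ".mat")
  writeLines(lines, f)
  f
}

blosum62 <- submat("BLOSUM62")
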