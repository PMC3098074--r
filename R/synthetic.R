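#' Random Gram matrix with known generating points
#'
#' Samples `n` centered points in `d` dimensions and returns their labelled
#' Gram (dot-product) matrix, optionally with a constant shift added to
#' every cell. The true points are kept alongside, so every downstream stage
#' (decomposition, galaxy recovery, shift fitting, distance conversion) can
#' be checked against exact ground truth. With `n = 20` the rows are
#' labelled with the canonical residues so the result can be treated as a
#' pseudo substitution matrix.
#'
#' @param n Number of points (>= d).
#' @param d True dimensionality (>= 1).
#' @param shift Constant added to every Gram cell.
#' @param seed Integer RNG seed.
#' @return List with `true_points` (n x d, centered), `gram` (a `submat`
#'   when n = 20, otherwise a plain labelled matrix) and `applied_shift`.
#' @export
#' @examples
#' sg <- random_gram(20, 5, shift = 0, seed = 1)
#' E <- aa_embed(sg$gram, center = FALSE, refine = FALSE)
#' E$dimensionality
random_gram <- function(n, d, shift = 0, seed = 0) {
  if (n < d || d < 1) stop("need n >= d >= 1")
  P <- with_seed(seed, matrix(stats::rnorm(n * d), n, d))
  P <- sweep(P, 2, colMeans(P))
  G <- tcrossprod(P) + shift
  labels <- if (n == 20) AA_ORDER else paste0("p", seq_len(n))
  dimnames(G) <- list(labels, labels)
  rownames(P) <- labels
  gram <- if (n == 20)
    as_submat(G, name = sprintf("synthetic gram (d=%d, shift=%g)", d, shift),
              rounded = FALSE)
  else G
  list(true_points = P, gram = gram, applied_shift = shift)
}

#' Random pseudo substitution matrix from a joint residue distribution
#'
#' Draws a symmetric joint probability table `q_ab` from a symmetric
#' Dirichlet model over the 210 unique cells (concentration parameter
#' controlling the distance from independence), computes the marginal
#' background probabilities `p_a`, the log-odds scores
#' `s_ab = log2(q_ab / (p_a p_b))` and the mutual information
#' `M = sum q_ab log2(q_ab / (p_a p_b))` in bits. `M` is zero iff residues
#' are independent (`q_ab = p_a p_b`) and maximal, equal to the marginal
#' entropy, when residues always covary (diagonal q).
#'
#' @param seed Integer RNG seed.
#' @param concentration Dirichlet concentration (> 0); small values give
#'   rugged, high-information tables, large values approach uniformity.
#' @return A `pseudo_matrix`: list with `q` (20x20, sums to 1), `p`
#'   (marginals), `scores` (a `submat`), `mutual_information` (bits) and
#'   `expected_score` (`sum p_a p_b s_ab`).
#' @export
random_pseudo_matrix <- function(seed = 0, concentration = 1) {
  if (concentration <= 0) stop("concentration must be positive")
  iu <- upper.tri(diag(20), diag = TRUE)
  g <- with_seed(seed, stats::rgamma(sum(iu), shape = concentration))
  Q <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  Q[iu] <- g
  Q <- Q + t(Q) - diag(diag(Q))
  Q <- Q / sum(Q)
  pseudo_matrix(Q)
}

#' Pseudo substitution matrix from a given joint table
#'
#' Assembles the model quantities (marginals, log-odds scores, mutual
#' information, expected score) from an explicit symmetric joint probability
#' table, e.g. an independence table `outer(p, p)` or a purely diagonal one.
#'
#' @param Q Symmetric nonnegative 20x20 table summing to 1.
#' @return A `pseudo_matrix`, as for [random_pseudo_matrix()].
#' @export
pseudo_matrix <- function(Q) {
  stopifnot(all(dim(Q) == 20), isTRUE(all.equal(sum(Q), 1, tolerance = 1e-9)),
            all(Q >= 0), isTRUE(all.equal(Q, t(Q), tolerance = 1e-9)))
  dimnames(Q) <- list(AA_ORDER, AA_ORDER)
  p <- rowSums(Q)
  PP <- outer(p, p)
  ratio <- ifelse(Q > 0, Q / PP, 1)   # 0 log 0 = 0 convention
  S <- log2(ratio)
  mi <- sum(ifelse(Q > 0, Q * log2(Q / PP), 0))
  structure(list(
    q = Q, p = p,
    scores = as_submat(S, name = "pseudo matrix", units = "bits",
                       scale = 1, entropy = max(mi, 0), rounded = FALSE),
    mutual_information = mi,
    expected_score = sum(PP * S)), class = "pseudo_matrix")
}

#' @export
print.pseudo_matrix <- function(x, ...) {
  cat(sprintf(
    "Pseudo substitution matrix: M = %.4g bits, expected score %.4g, mean %.4g\n",
    x$mutual_information, x$expected_score, matrix_mean(x$scores)))
  invisible(x)
}
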