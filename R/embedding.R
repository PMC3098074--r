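#' Fit a Euclidean amino acid vector representation of a substitution matrix
#'
#' Decomposes a symmetric 20x20 substitution matrix `S` by singular value
#' decomposition into per-residue vectors whose pairwise dot products
#' reconstruct the matrix. Writing `S = sum_K w_K U_K V_K^T`, a component is
#' retained when its left and right singular vectors agree in sign
#' (`dot(U_K, V_K) > 0`); opposed components correspond to negative
#' eigenvalues, which cannot be represented as real dot products, and are
#' dropped. Retained coordinates are `U_Ka * sqrt(w_K)`, so residue `a`'s
#' vector reproduces `s_ab` as a dot product up to the dropped components.
#'
#' With `center = TRUE` (default) the matrix is first centered (its
#' 400-element mean subtracted), which empirically leaves the geometry of the
#' vector set unchanged but removes most of the negative spectrum and makes
#' the dot-product reconstruction far more accurate. With `refine = TRUE`
#' a least-squares translation vector and scalar shift are fitted on top
#' (see [fit_shift_translation()]), pushing reconstruction quality above 99%
#' for every bundled matrix.
#'
#' @param S A [as_submat()] object or symmetric named 20x20 matrix.
#' @param center Center the matrix before decomposing.
#' @param refine Fit the translation + shift refinement against the original
#'   (uncentered) matrix.
#' @param tol Relative rank tolerance: components with `w_K <= tol * w_1`
#'   are discarded as rank noise.
#' @return An object of class `aa_embed` with elements
#'   \describe{
#'     \item{vectors}{20 x R matrix of raw residue vectors (canonical order).}
#'     \item{singular_values}{retained `w_K`, decreasing.}
#'     \item{all_singular_values}{all 20 singular values.}
#'     \item{dropped}{data frame of omitted components (index, w, reason).}
#'     \item{galaxy}{the centered vector set, class `aa_galaxy`.}
#'     \item{centroid}{geometric center subtracted to form the galaxy.}
#'     \item{quality, correlation}{raw dot-product reconstruction quality (%)
#'       and upper-triangle Pearson correlation against the decomposed input.}
#'     \item{refinement}{a `shift_fit` (see [fit_shift_translation()]) or NULL.}
#'   }
#' @seealso [gram()], [quality_index()], [aa_galaxy()]
#' @export
#' @examples
#' E <- aa_embed(submat("BLOSUM62"))
#' E
#' head(coef(E)[, 1:3])
aa_embed <- function(S, center = TRUE, refine = TRUE, tol = 1e-10) {
  S <- as_submat(unclass(S), name = attr(S, "name") %||% "matrix",
                 units = attr(S, "units") %||% "unknown",
                 scale = attr(S, "scale") %||% NA_real_,
                 entropy = attr(S, "entropy") %||% NA_real_)
  input <- if (center) center_matrix(S) else S
  sv <- svd(unclass(input))
  agree <- vapply(1:20, function(k) sum(sv$u[, k] * sv$v[, k]) > 0, TRUE)
  above <- sv$d > tol * sv$d[1]
  keep <- agree & above
  # components below the rank tolerance are silently discarded as noise;
  # `dropped` records only genuine negative eigencomponents
  omitted <- !agree & above
  dropped <- data.frame(index = which(omitted), w = sv$d[omitted],
                        reason = rep("opposed singular vectors (negative eigenvalue)",
                                     sum(omitted)),
                        stringsAsFactors = FALSE)
  R <- sum(keep)
  V <- sv$u[, keep, drop = FALSE] %*% diag(sqrt(sv$d[keep]), R)
  # resolve the per-axis sign ambiguity: largest-|coordinate| positive
  if (R > 0) {
    sgn <- vapply(seq_len(R), function(k) {
      v <- V[, k]; s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
    }, 0)
    V <- sweep(V, 2, sgn, `*`)
  }
  rownames(V) <- AA_ORDER
  colnames(V) <- if (R > 0) paste0("x", seq_len(R)) else character()
  Shat <- tcrossprod(V)
  centroid <- colMeans(V)
  G <- sweep(V, 2, centroid)
  obj <- structure(list(
    vectors = V,
    singular_values = sv$d[keep],
    all_singular_values = sv$d,
    dimensionality = R,
    dropped = dropped,
    centered_input = center,
    source = attr(S, "name"),
    original = S,
    input = input,
    quality = quality_index(input, Shat),
    correlation = if (R > 0) upper_tri_correlation(input, Shat) else NA_real_,
    galaxy = structure(G, source = attr(S, "name"),
                       class = c("aa_galaxy", "matrix")),
    centroid = centroid,
    refinement = NULL), class = "aa_embed")
  if (refine) obj$refinement <- fit_shift_translation(S, obj)
  obj
}

#' Dot-product (Gram) reconstruction of an embedding
#'
#' Pairwise dot products of the raw embedding vectors: the rank-R
#' approximation of the decomposed matrix. A zero-dimensional embedding
#' yields the zero matrix.
#'
#' @param E An `aa_embed`.
#' @return A `submat` of dot products.
#' @export
gram <- function(E) {
  stopifnot(inherits(E, "aa_embed"))
  as_submat(structure(tcrossprod(E$vectors),
                      dimnames = list(AA_ORDER, AA_ORDER)),
            name = paste0(E$source, " (reconstructed)"), rounded = FALSE)
}

#' Reconstruction quality index
#'
#' Percent agreement between a matrix and its reconstruction, measured as
#' `100 * (1 - ||S - Shat||_F^2 / ||S||_F^2)`: 100% iff the reconstruction
#' is exact, decreasing as the squared Frobenius discrepancy grows relative
#' to the squared norm of the original.
#'
#' @param S,S_hat 20x20 matrices in the same residue order.
#' @return Quality in percent (can be negative for a very poor fit).
#' @export
quality_index <- function(S, S_hat) {
  S <- unclass(S); S_hat <- unclass(S_hat)
  denom <- sum(S^2)
  if (denom == 0) stop("zero matrix has no quality index")
  100 * (1 - sum((S - S_hat)^2) / denom)
}

#' Upper-triangle correlation between a matrix and its reconstruction
#'
#' Pearson correlation over the 210 upper-triangular entries (190
#' off-diagonal pairs plus the 20 diagonal cells). Insensitive to systematic
#' (affine) reconstruction errors, so it complements [quality_index()].
#'
#' @param S,S_hat 20x20 matrices in the same residue order.
#' @return Correlation in `[-1, 1]`.
#' @export
upper_tri_correlation <- function(S, S_hat) {
  S <- unclass(S); S_hat <- unclass(S_hat)
  iu <- upper.tri(S, diag = TRUE)
  x <- S[iu]; y <- S_hat[iu]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in upper-triangle entries; correlation undefined")
  stats::cor(x, y)
}

#' Least-squares shift and translation refinement
#'
#' Improves the dot-product reconstruction by an adjustable translation `T`
#' common to all residue vectors and a scalar `shift`:
#' `Shat_ab = (v_a + T) . (v_b + T) + shift`, with `T` and `shift` chosen to
#' minimize the squared reconstruction error against `S`. At the optimum the
#' shift is tied to the translation by
#' `shift = mean(S) - ||t + T||^2`, where `t` is the geometric center of the
#' vectors; substituting it makes the objective quadratic in `T`, which is
#' then obtained from a linear system (pseudo-inverse fallback when the
#' system is singular, flagged in the result).
#'
#' @param S The target substitution matrix (original, uncentered scores).
#' @param E An `aa_embed` decomposed from `S` or from centered `S`.
#' @return An object of class `shift_fit`: list with `translation`, `shift`,
#'   `quality` (%), `correlation`, `singular` (logical flag).
#' @export
fit_shift_translation <- function(S, E) {
  stopifnot(inherits(E, "aa_embed"))
  S <- unclass(S)
  V <- E$vectors
  N <- nrow(V)
  t0 <- colMeans(V)
  C <- sweep(V, 2, t0)
  mS <- mean(S)
  # per-residue residual row-sums of the T-independent part
  e_row <- rowSums(S) - N * drop(V %*% t0) - N * mS + N * sum(t0^2)
  A <- 2 * N * crossprod(C)
  b <- 2 * drop(crossprod(C, e_row))
  singular <- FALSE
  Tv <- tryCatch(solve(A, b), error = function(e) {
    singular <<- TRUE
    drop(MASS::ginv(A) %*% b)
  })
  shift <- mS - sum((t0 + Tv)^2)
  Vt <- sweep(V, 2, Tv, `+`)
  Shat <- tcrossprod(Vt) + shift
  structure(list(translation = Tv, shift = shift,
                 quality = quality_index(S, Shat),
                 correlation = upper_tri_correlation(S, Shat),
                 singular = singular),
            class = "shift_fit")
}

#' @export
print.shift_fit <- function(x, ...) {
  cat(sprintf("Shift/translation fit: shift = %.4g, |T| = %.4g%s\n",
              x$shift, sqrt(sum(x$translation^2)),
              if (x$singular) " (pseudo-inverse)" else ""))
  cat(sprintf("Refined quality %.2f%%, correlation %.4f\n",
              x$quality, x$correlation))
  invisible(x)
}

#' Center an embedding's vector set
#'
#' Subtracts the geometric mean from each raw vector, returning the centered
#' vector set (the "galaxy") and the subtracted centroid. The galaxy is
#' invariant, up to rigid motion, under any constant shift of the decomposed
#' matrix.
#'
#' @param E An `aa_embed`.
#' @return List with `galaxy` (an `aa_galaxy`) and `centroid`.
#' @export
center_vectors <- function(E) {
  stopifnot(inherits(E, "aa_embed"))
  list(galaxy = E$galaxy, centroid = E$centroid)
}

#' Reconstruction from the centered vector set
#'
#' Reconstructs the original matrix from the galaxy (centered vectors):
#' `Shat_ab = c_a . c_b + mean(S)`. This is the shift/translation form with
#' the translation pinned to minus the vector centroid and the shift at its
#' tied optimum; it measures how well the shift-invariant galaxy alone,
#' placed back at the matrix mean, accounts for the original scores.
#'
#' @param E An `aa_embed`.
#' @return A `shift_fit` with the pinned translation.
#' @export
galaxy_reconstruction <- function(E) {
  stopifnot(inherits(E, "aa_embed"))
  S <- unclass(E$original)
  G <- unclass(E$galaxy)
  shift <- mean(S)
  Shat <- tcrossprod(G) + shift
  structure(list(translation = -E$centroid, shift = shift,
                 quality = quality_index(S, Shat),
                 correlation = upper_tri_correlation(S, Shat),
                 singular = FALSE),
            class = "shift_fit")
}

#' @export
print.aa_embed <- function(x, ...) {
  cat(sprintf("Amino acid vector embedding of %s (%s input)\n", x$source,
              if (x$centered_input) "centered" else "raw"))
  cat(sprintf("Dimensionality R = %d (%d component(s) dropped)\n",
              x$dimensionality, nrow(x$dropped)))
  cat(sprintf("Dot-product reconstruction: quality %.1f%%, correlation %.4f\n",
              x$quality, x$correlation))
  if (!is.null(x$refinement))
    cat(sprintf("Shift/translation refinement: quality %.1f%%, correlation %.4f\n",
                x$refinement$quality, x$refinement$correlation))
  invisible(x)
}

#' @export
summary.aa_embed <- function(object, ...) {
  print(object)
  cat("\nSingular values (retained):\n")
  print(signif(object$singular_values, 4))
  if (nrow(object$dropped)) {
    cat("\nDropped components:\n")
    print(object$dropped)
  }
  cat(sprintf("\nGalaxy radius R_g = %.4g\n", galaxy_radius(object$galaxy)))
  invisible(object)
}

#' @export
coef.aa_embed <- function(object, ...) object$vectors

#' @export
fitted.aa_embed <- function(object, ...) gram(object)

#' Predict (reconstruct) substitution scores from an embedding
#'
#' @param object An `aa_embed`.
#' @param type `"gram"` for the plain dot-product reconstruction of the
#'   decomposed input, `"refined"` for the shift/translation-corrected
#'   reconstruction of the original matrix.
#' @param ... Unused.
#' @return A `submat` of reconstructed scores.
#' @export
predict.aa_embed <- function(object, type = c("gram", "refined"), ...) {
  type <- match.arg(type)
  if (type == "gram") return(gram(object))
  if (is.null(object$refinement))
    object$refinement <- fit_shift_translation(object$original, object)
  Vt <- sweep(object$vectors, 2, object$refinement$translation, `+`)
  as_submat(structure(tcrossprod(Vt) + object$refinement$shift,
                      dimnames = list(AA_ORDER, AA_ORDER)),
            name = paste0(object$source, " (refined)"), rounded = FALSE)
}

#' @export
residuals.aa_embed <- function(object, type = c("gram", "refined"), ...) {
  type <- match.arg(type)
  target <- if (type == "gram") object$input else object$original
  unclass(target) - unclass(predict(object, type = type))
}

#' @export
plot.aa_embed <- function(x, dims = c(1, 2), ...) {
  plot(x$galaxy, dims = dims, ...)
}
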