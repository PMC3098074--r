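#' The amino acid galaxy
#'
#' The centered vector set of an embedding: 20 labelled points whose
#' centroid is the origin. `aa_galaxy()` extracts it from an `aa_embed` (or
#' fits one from a matrix directly); `galaxy_radius()` is the mean Euclidean
#' distance of the points from the center.
#'
#' @param x An `aa_embed`, a `submat`, or a 20 x R numeric matrix of
#'   centered points with residue row names.
#' @param ... Passed to [aa_embed()] when `x` is a matrix of scores.
#' @return An `aa_galaxy`: 20 x R matrix, rows in canonical order, with a
#'   `source` attribute.
#' @export
#' @examples
#' G <- aa_galaxy(submat("BLOSUM62"))
#' galaxy_radius(G)
aa_galaxy <- function(x, ...) {
  if (inherits(x, "aa_galaxy")) return(x)
  if (inherits(x, "aa_embed")) return(x$galaxy)
  if (inherits(x, "submat")) return(aa_embed(x, refine = FALSE, ...)$galaxy)
  x <- as.matrix(x)
  if (is.null(rownames(x)) || !setequal(rownames(x), AA_ORDER))
    stop("point set must have the 20 canonical residue row names")
  x <- x[AA_ORDER, , drop = FALSE]
  x <- sweep(x, 2, colMeans(x))
  structure(x, source = "points", class = c("aa_galaxy", "matrix"))
}

#' @rdname aa_galaxy
#' @param G An `aa_galaxy` (or centered point matrix).
#' @export
galaxy_radius <- function(G) mean(sqrt(rowSums(unclass(G)^2)))

#' @export
print.aa_galaxy <- function(x, ...) {
  cat(sprintf("Amino acid galaxy from %s: %d dimensions, radius %.4g\n",
              attr(x, "source"), ncol(x), galaxy_radius(x)))
  print(signif(unclass(x)[1:5, seq_len(min(5, ncol(x))), drop = FALSE], 3))
  cat("...\n")
  invisible(x)
}

#' @export
plot.aa_galaxy <- function(x, dims = c(1, 2), ...) {
  G <- unclass(x)
  plot(G[, dims[1]], G[, dims[2]], type = "n",
       xlab = sprintf("component %d", dims[1]),
       ylab = sprintf("component %d", dims[2]),
       main = sprintf("Amino acid galaxy (%s)", attr(x, "source")), ...)
  graphics::text(G[, dims[1]], G[, dims[2]], labels = rownames(G))
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  invisible(x)
}

# zero-pad two point sets to a common dimensionality
pad_common <- function(A, B) {
  d <- max(ncol(A), ncol(B))
  padto <- function(M) cbind(M, matrix(0, nrow(M), d - ncol(M)))
  list(A = padto(unclass(A)), B = padto(unclass(B)))
}

#' Multidimensional rigid-body superposition of two galaxies
#'
#' Finds the orthogonal map `Q` (optionally with a scale factor) minimizing
#' the squared residual `||s * A Q - B||` over the 20 corresponding
#' residues, the multidimensional analogue of a rigid-body (Kabsch/
#' Procrustes) fit. Galaxies of unequal dimensionality are zero-padded to a
#' common space. Improper (reflecting) maps are allowed by default, since
#' the axes of an SVD carry arbitrary signs.
#'
#' @param A,B `aa_galaxy` objects (or centered point matrices with matching
#'   residue order).
#' @param allow_scaling Fit a global scale factor (otherwise fixed at 1).
#' @param allow_reflection Permit `det(Q) = -1` maps.
#' @return A `superposition`: list with `orthogonal_map`, `scale`, `rmsd`
#'   (root-mean-square residual distance over the 20 residues) and `mapped`
#'   (the transformed copy of `A`).
#' @export
superpose <- function(A, B, allow_scaling = FALSE, allow_reflection = TRUE) {
  p <- pad_common(A, B)
  A <- p$A; B <- p$B
  M <- crossprod(A, B)                        # R x R cross-covariance
  sv <- svd(M)
  d <- rep(1, length(sv$d))
  if (!allow_reflection) {
    detQ <- det(sv$u %*% t(sv$v))
    if (detQ < 0) d[length(d)] <- -1
  }
  Q <- sv$u %*% diag(d, length(d)) %*% t(sv$v)
  s <- if (allow_scaling) sum(sv$d * d) / sum(A^2) else 1
  mapped <- s * A %*% Q
  rmsd <- sqrt(mean(rowSums((mapped - B)^2)))
  structure(list(orthogonal_map = Q, scale = s, rmsd = rmsd,
                 mapped = mapped), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd %.4g, scale %.4g, det(Q) = %+.0f\n",
              x$rmsd, x$scale, det(x$orthogonal_map)))
  invisible(x)
}

#' Cluster amino acids in the galaxy by k-means
#'
#' Partitions the 20 residue points into `k` groups by squared-Euclidean
#' k-means in the full retained dimensionality, taking the best (lowest
#' within-cluster sum of squares) of `restarts` random initializations under
#' a fixed seed, so results are deterministic.
#'
#' @param G An `aa_galaxy` (or anything [aa_galaxy()] accepts).
#' @param k Number of clusters, between 2 and 20.
#' @param seed Integer RNG seed (default 0).
#' @param restarts Number of random restarts (default 50).
#' @return A `cluster_partition`: list with `k`, `assignment` (named integer
#'   vector, cluster ids 1..k), `inertia` (within-cluster sum of squares)
#'   and `groups` (list of residue character vectors, ordered by first
#'   member in canonical order).
#' @export
#' @examples
#' cluster_residues(aa_galaxy(submat("BLOSUM62")), k = 3)
cluster_residues <- function(G, k, seed = 0, restarts = 50) {
  G <- aa_galaxy(G)
  if (k < 2 || k > 20) stop("k must be between 2 and 20")
  if (k == nrow(G)) {
    # every residue its own cluster; stats::kmeans refuses k == n
    assignment <- stats::setNames(seq_len(nrow(G)), rownames(G))
    groups <- as.list(rownames(G))
    return(structure(list(k = k, assignment = assignment, inertia = 0,
                          groups = groups), class = "cluster_partition"))
  }
  km <- with_seed(seed,
    stats::kmeans(unclass(G), centers = k, nstart = restarts, iter.max = 100))
  assignment <- stats::setNames(km$cluster, rownames(G))
  groups <- split(names(assignment), assignment)
  groups <- groups[order(vapply(groups, `[`, "", 1L))]
  names(groups) <- NULL
  structure(list(k = k, assignment = assignment, inertia = km$tot.withinss,
                 groups = groups), class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("k-means partition (k = %d, inertia %.4g):\n", x$k, x$inertia))
  for (g in x$groups) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}

#' Series-wide summary of matrix mean, entropy and galaxy radius
#'
#' For a list of substitution matrices (e.g. a whole BLOSUM or PAM series),
#' computes per matrix the 400-element mean, the relative entropy from the
#' file metadata, and the centered-galaxy radius, and then the Pearson
#' correlations among the three statistics across the series. Matrices in a
#' series must be expressed in comparable units for the mean and radius to
#' be meaningful across the series (see `bits` in [submat()]).
#'
#' @param matrices List of `submat` objects, each carrying relative entropy
#'   metadata; at least 3.
#' @return A `series_summary`: list with `table` (data frame: name, index,
#'   mean, entropy, radius) and `correlations` (3x3 correlation matrix).
#' @export
#' @examples
#' blos <- lapply(c("BLOSUM45", "BLOSUM62", "BLOSUM80"), submat, bits = TRUE)
#' series_summary(blos)$correlations
series_summary <- function(matrices) {
  if (length(matrices) < 3) stop("need at least 3 matrices")
  ent <- vapply(matrices, function(S) attr(S, "entropy") %||% NA_real_, 0)
  if (anyNA(ent)) {
    nm <- vapply(matrices[is.na(ent)], function(S) attr(S, "name"), "")
    stop("missing relative entropy metadata for: ", paste(nm, collapse = ", "))
  }
  tab <- data.frame(
    name = vapply(matrices, function(S) attr(S, "name"), ""),
    index = vapply(matrices, function(S) as.integer(attr(S, "index")), 0L),
    mean = vapply(matrices, matrix_mean, 0),
    entropy = ent,
    radius = vapply(matrices, function(S)
      galaxy_radius(aa_embed(S, refine = FALSE)$galaxy), 0),
    stringsAsFactors = FALSE)
  if (stats::sd(tab$mean) == 0 || stats::sd(tab$entropy) == 0 ||
      stats::sd(tab$radius) == 0)
    stop("degenerate series: a statistic is constant, correlations undefined")
  cors <- stats::cor(tab[, c("mean", "entropy", "radius")])
  structure(list(table = tab, correlations = cors), class = "series_summary")
}

#' @export
print.series_summary <- function(x, ...) {
  cat(sprintf("Series summary over %d matrices\n", nrow(x$table)))
  print(x$table, digits = 4)
  cat("\nCorrelations:\n")
  print(round(x$correlations, 4))
  invisible(x)
}
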