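#' Convert a similarity matrix into a distance matrix
#'
#' Two classical conversions of substitution scores into inter-residue
#' "distances": the linear form `d_ab = s_aa + s_bb - 2 s_ab` and its square
#' root. Neither is guaranteed to be a metric -- the linear form very often
#' violates the triangle inequality (see [triangle_violations()]); the
#' square-root form is much better behaved. For a true Gram matrix the
#' square-root form equals the exact Euclidean distances between the
#' generating points. For a guaranteed metric derived from the vector
#' representation itself, see [vector_metric()].
#'
#' @param S A `submat`.
#' @param form `"linear"` or `"sqrt"`.
#' @return A `dist_matrix`: symmetric nonnegative 20x20 matrix with zero
#'   diagonal and attributes `formula` and `source`.
#' @export
similarity_to_distance <- function(S, form = c("linear", "sqrt")) {
  form <- match.arg(form)
  M <- unclass(S)
  L <- outer(diag(M), diag(M), `+`) - 2 * M
  L[abs(L) < 1e-12] <- 0
  if (any(L < 0)) {
    ij <- which(L < 0, arr.ind = TRUE)
    pairs <- unique(apply(ij, 1, function(r)
      paste(sort(AA_ORDER[r]), collapse = "/")))
    stop("negative squared distance for pair(s): ",
         paste(utils::head(pairs, 5), collapse = ", "))
  }
  D <- if (form == "sqrt") sqrt(L) else L
  structure(D, formula = toupper(form),
            source = attr(S, "name") %||% "matrix",
            class = c("dist_matrix", "matrix"))
}

#' Audit the triangle inequality over all residue triplets
#'
#' Checks, over all `C(20,3) = 1140` unordered residue triplets, the three
#' inequalities `d(a,c) <= d(a,b) + d(b,c)` with a strictness tolerance.
#' Both a triplet count (a triplet is flagged when any of its three
#' inequalities fails) and an inequality-instance count (out of 3 x 1140 =
#' 3420) are reported; the published violation rates for the rounded PAM
#' series above index 210 correspond to the inequality-instance counting.
#'
#' @param D A `dist_matrix` (or symmetric zero-diagonal matrix).
#' @param tol Tolerance: a violation must exceed `tol` to count.
#' @return List with `count` and `fraction` (percent of the 1140 triplets),
#'   `inequality_count` and `inequality_fraction` (percent of the 3420
#'   inequality instances), and `triplets` (data frame of flagged triplets).
#' @export
triangle_violations <- function(D, tol = 1e-9) {
  D <- unclass(D)
  n <- nrow(D)
  viol <- list()
  count <- 0L
  icount <- 0L
  total <- choose(n, 3)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    f <- c(D[i, k] > D[i, j] + D[j, k] + tol,
           D[i, j] > D[i, k] + D[j, k] + tol,
           D[j, k] > D[i, j] + D[i, k] + tol)
    if (any(f)) {
      count <- count + 1L
      icount <- icount + sum(f)
      viol[[length(viol) + 1L]] <- c(i, j, k)
    }
  }
  trip <- if (length(viol))
    stats::setNames(as.data.frame(do.call(rbind, lapply(viol, function(v)
      rownames(D)[v] %||% as.character(v)))), c("a", "b", "c"))
  else data.frame(a = character(), b = character(), c = character())
  list(count = count, fraction = 100 * count / total,
       inequality_count = icount,
       inequality_fraction = 100 * icount / (3 * total),
       triplets = trip)
}

#' Classical (Torgerson) multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distances, eigendecomposes the resulting
#' dot-product matrix and keeps the top `dims` components with positive
#' eigenvalues (truncating with a warning when fewer are available).
#'
#' @param D A `dist_matrix`.
#' @param dims Target dimensionality.
#' @return A 20 x dims matrix of coordinates (residue row names).
#' @export
torgerson_embed <- function(D, dims) {
  D <- unclass(D)
  n <- nrow(D)
  full <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1,
                                           eig = TRUE))
  npos <- sum(full$eig > 1e-9)
  if (dims > npos) {
    warning("only ", npos, " positive components available; truncating")
    dims <- npos
  }
  X <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = dims))
  rownames(X) <- rownames(D)
  X
}

stress_value <- function(x, D, dims) {
  X <- matrix(x, ncol = dims)
  sum((as.matrix(stats::dist(X)) - D)^2) / 2
}

#' Fit a point configuration by direct stress minimization
#'
#' Minimizes the squared differences between the target distances and the
#' configuration's Euclidean distances (raw metric stress), by quasi-Newton
#' descent from seeded random starts, keeping the best of `restarts` runs.
#' Deterministic for a given seed.
#'
#' @param D A `dist_matrix`.
#' @param dims Embedding dimensionality (>= 1).
#' @param seed Integer RNG seed.
#' @param restarts Number of random starts.
#' @return A 20 x dims coordinate matrix with attribute `stress`.
#' @export
stress_fit <- function(D, dims, seed = 0, restarts = 20) {
  D <- unclass(D)
  n <- nrow(D)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      x0 <- stats::rnorm(n * dims, sd = max(D) / 2)
      fit <- stats::optim(x0, stress_value, D = D, dims = dims,
                          method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  X <- matrix(best$par, ncol = dims)
  X <- sweep(X, 2, colMeans(X))
  rownames(X) <- rownames(D)
  structure(X, stress = best$value)
}

#' Fit a configuration maximizing anti-correlation with the scores
#'
#' Finds point coordinates whose pairwise Euclidean distances are maximally
#' negatively correlated with the substitution scores over the 190
#' off-diagonal pairs, by seeded multi-start quasi-Newton optimization.
#'
#' @param S A `submat`.
#' @param dims Embedding dimensionality (>= 1).
#' @param seed Integer RNG seed.
#' @param restarts Number of random starts.
#' @return A 20 x dims coordinate matrix with attribute `correlation` (the
#'   achieved correlation between scores and distances, expected negative).
#' @export
anticorrelation_fit <- function(S, dims, seed = 0, restarts = 20) {
  M <- unclass(S)
  n <- nrow(M)
  off <- upper.tri(M)
  s <- M[off]
  objective <- function(x) {
    X <- matrix(x, ncol = dims)
    d <- as.matrix(stats::dist(X))[off]
    if (stats::sd(d) == 0) return(1)
    stats::cor(s, d)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      x0 <- stats::rnorm(n * dims)
      fit <- stats::optim(x0, objective, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  X <- matrix(best$par, ncol = dims)
  X <- sweep(X, 2, colMeans(X))
  rownames(X) <- rownames(M)
  structure(X, correlation = best$value)
}

#' Metric distances from the amino acid vectors
#'
#' Pairwise Euclidean distances between the galaxy points: by construction a
#' true metric (positive, symmetric, triangle inequality), unlike the
#' score-derived conversions of [similarity_to_distance()].
#'
#' @param G An `aa_galaxy`.
#' @return A `dist_matrix` with formula `"VECTOR_METRIC"`.
#' @export
vector_metric <- function(G) {
  G <- aa_galaxy(G)
  D <- as.matrix(stats::dist(unclass(G)))
  structure(D, formula = "VECTOR_METRIC",
            source = attr(G, "source") %||% "galaxy",
            class = c("dist_matrix", "matrix"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix (%s) from %s\n",
              attr(x, "formula"), attr(x, "source")))
  print(signif(unclass(x)[1:5, 1:5], 3))
  cat("... (20 x 20)\n")
  invisible(x)
}
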