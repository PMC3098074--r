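#' Physicochemical property scales
#'
#' Loads the bundled table of 17 per-residue physicochemical property scales
#' (residue volume, charge, absolute charge, water-accessible surface,
#' aromaticity, several hydrophobicity scales, bulkiness, secondary
#' structure propensities, molecular mass). Charge (R, K = +1; D, E = -1;
#' others 0) and aromaticity (F, Y, W = 1; others 0) are defined exactly;
#' the remaining scales are transcribed from the AAindex database, with the
#' accession recorded per row. Values are raw (un-normalized).
#'
#' @param file Optional path to a CSV with columns `property`, then the 20
#'   residues in canonical order, then optional `accession`, `description`.
#' @return A data frame, one row per property, with a `property` column and
#'   the 20 residue columns.
#' @export
#' @examples
#' p <- property_scales()
#' p$property
property_scales <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "properties", "property_scales.csv",
                        package = "aagalaxy")
  d <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(AA_ORDER %in% names(d)), "property" %in% names(d))
  d
}

#' Center and normalize a property scale
#'
#' Property scales come in arbitrary units; they are centered to zero mean
#' and scaled to unit Euclidean norm, so that the self-sum `sum(p_a^2)` in
#' the property-axis equations equals 1.
#'
#' @param raw Numeric vector of 20 values, named by residue (canonical order
#'   assumed if unnamed).
#' @param name Property name.
#' @return A `property_scale`: named numeric vector with attributes `name`
#'   and `normalized = TRUE`.
#' @export
normalize_property <- function(raw, name = "property") {
  raw <- unclass(raw)
  if (length(raw) != 20 || anyNA(raw) || any(!is.finite(raw)))
    stop("need 20 finite values")
  if (!is.null(names(raw))) {
    if (!setequal(names(raw), AA_ORDER)) stop("names must be the canonical 20")
    raw <- raw[AA_ORDER]
  } else names(raw) <- AA_ORDER
  v <- raw - mean(raw)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("constant property has no direction")
  structure(v / n, name = name, normalized = TRUE,
            class = c("property_scale", "numeric"))
}

#' Best-fit property axis in the amino acid space
#'
#' Finds the line through the origin of the centered galaxy that best
#' represents a scalar property: the axis direction minimizing the squared
#' distances between the scaled property values `lambda * p_a` placed on
#' the axis and the corresponding residue points. At the optimum the axis is
#' proportional to the property-weighted sum of residue vectors
#' `sum_a p_a v_a` (the self-sum `sum p_a^2` being 1 for a normalized
#' scale), and `lambda` is the norm of that weighted sum.
#'
#' @param G An `aa_galaxy` (centered).
#' @param p A normalized [normalize_property()] scale (raw vectors are
#'   normalized on the fly).
#' @return A `property_projection`: list with `axis` (unit vector),
#'   `lambda` (scale factor), `contribution` (%), `projections`
#'   (`lambda * p_a`, positions along the axis) and `property`.
#' @export
#' @examples
#' G <- aa_galaxy(submat("BLOSUM62"))
#' arom <- normalize_property(
#'   as.numeric(amino_acids() %in% c("F", "W", "Y")), "aromaticity")
#' fit_property_axis(G, arom)
fit_property_axis <- function(G, p) {
  G <- aa_galaxy(G)
  if (!isTRUE(attr(p, "normalized")))
    p <- normalize_property(p, attr(p, "name") %||% "property")
  wsum <- drop(crossprod(unclass(G), unclass(p)))   # sum_a p_a v_a
  lambda <- sqrt(sum(wsum^2))
  if (lambda == 0) stop("degenerate property: weighted vector sum is zero")
  axis <- wsum / lambda
  structure(list(axis = axis, lambda = lambda,
                 contribution = 100 * lambda^2 / sum(unclass(G)^2),
                 projections = stats::setNames(lambda * unclass(p), AA_ORDER),
                 property = attr(p, "name") %||% "property"),
            class = "property_projection")
}

#' @export
print.property_projection <- function(x, ...) {
  cat(sprintf("Property axis '%s': lambda = %.4g, contribution %.1f%%\n",
              x$property, x$lambda, x$contribution))
  invisible(x)
}

#' Contribution of a property to the matrix
#'
#' The percent of the spatial spread of the residue points explained by the
#' property along its best axis: the ratio of the spread of the scaled
#' property values on the line (`sum_a (lambda p_a)^2 = lambda^2`) to the
#' spread of the points in space (`sum_a ||v_a||^2`). Bounded above by
#' [max_contribution()], the share of the leading component.
#'
#' @param proj A `property_projection` fitted on `G`.
#' @param G The `aa_galaxy` it was fitted on.
#' @return Contribution in percent, in `[0, 100]`.
#' @export
contribution <- function(proj, G) {
  stopifnot(inherits(proj, "property_projection"))
  G <- aa_galaxy(G)
  100 * proj$lambda^2 / sum(unclass(G)^2)
}

#' Upper limit of any property contribution
#'
#' The first retained component of the decomposition is the best
#' one-dimensional approximation of the amino acid spread, so its share of
#' the total squared spread, `100 * w_1 / sum(w_K)`, bounds the contribution
#' of every scalar property.
#'
#' @param x An `aa_embed`, or an `aa_galaxy` (the Gram spectrum of the
#'   points is then used).
#' @return Percent in `(0, 100]`.
#' @export
max_contribution <- function(x) {
  if (inherits(x, "aa_embed")) w <- x$singular_values
  else {
    G <- aa_galaxy(x)
    w <- eigen(crossprod(unclass(G)), symmetric = TRUE, only.values = TRUE)$values
    w <- w[w > 1e-12 * max(w)]
  }
  100 * w[1] / sum(w)
}

#' Random pseudo-property baseline
#'
#' Monte-Carlo null distribution for property contributions: draws `n`
#' standard-normal 20-vectors, centers and normalizes each, and computes its
#' contribution on the galaxy. Deterministic for a given seed.
#'
#' @param G An `aa_galaxy`.
#' @param n Number of draws (>= 100).
#' @param seed Integer RNG seed.
#' @return List with `mean`, `sd` (percent) and `contributions` (length-n
#'   vector).
#' @export
#' @examples
#' G <- aa_galaxy(submat("BLOSUM62"))
#' b <- random_property_baseline(G, n = 200, seed = 1)
#' c(b$mean, b$sd)
random_property_baseline <- function(G, n = 1000, seed = 0) {
  G <- aa_galaxy(G)
  if (n < 100) stop("n must be at least 100")
  total <- sum(unclass(G)^2)
  draws <- with_seed(seed, matrix(stats::rnorm(20 * n), nrow = 20))
  cc <- apply(draws, 2, function(r) {
    r <- r - mean(r); r <- r / sqrt(sum(r^2))
    100 * sum(drop(crossprod(unclass(G), r))^2) / total
  })
  list(mean = mean(cc), sd = stats::sd(cc), contributions = cc)
}
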