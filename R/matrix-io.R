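#' Substitution matrix objects
#'
#' A `submat` is a 20x20 symmetric numeric matrix of substitution scores,
#' rows and columns indexed by [amino_acids()], carrying metadata as
#' attributes: `name`, `series` (`"BLOSUM"`, `"PAM"` or `"OTHER"`), `index`
#' (series index or `NA`), `rounded`, `units` (free-text scale annotation,
#' e.g. `"half-bit"`), `scale` (numeric divisor converting scores to bits,
#' `NA` when unknown) and `entropy` (relative entropy in bits from the file
#' header, `NA` when absent).
#'
#' @param x A 20x20 numeric matrix (or coercible), rows/columns named with
#'   one-letter codes in any order covering the canonical 20.
#' @param name Text identifier, e.g. `"BLOSUM62"`.
#' @param units Free-text scale annotation.
#' @param scale Numeric divisor converting scores to bit units (`NA` unknown).
#' @param entropy Optional relative entropy (bits), nonnegative.
#' @param rounded Logical, whether entries are integer-rounded scores.
#' @param tol Symmetry tolerance for real-valued matrices.
#' @return An object of class `submat`.
#' @export
as_submat <- function(x, name = "matrix", units = "unknown", scale = NA_real_,
                      entropy = NA_real_, rounded = all(x == round(x)),
                      tol = 1e-9) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("matrix must have residue row and column names")
  missing <- setdiff(AA_ORDER, rownames(x))
  if (length(missing))
    stop("missing canonical residues: ", paste(missing, collapse = ", "))
  missing <- setdiff(AA_ORDER, colnames(x))
  if (length(missing))
    stop("missing canonical residue columns: ", paste(missing, collapse = ", "))
  dropped <- setdiff(union(rownames(x), colnames(x)), AA_ORDER)
  if (length(dropped))
    message("dropping non-canonical residue codes: ",
            paste(dropped, collapse = ", "))
  x <- x[AA_ORDER, AA_ORDER]
  asym <- abs(x - t(x))
  if (any(asym > tol)) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("matrix not symmetric: %s/%s differ by %g",
                 AA_ORDER[ij[1]], AA_ORDER[ij[2]], max(asym)))
  }
  x <- (x + t(x)) / 2
  if (!is.na(entropy) && entropy < 0)
    stop("relative entropy must be nonnegative")
  series <- if (grepl("^BLOSUM", name)) "BLOSUM"
            else if (grepl("^PAM", name)) "PAM" else "OTHER"
  idx <- suppressWarnings(as.integer(sub("^(BLOSUM|PAM)", "", name)))
  structure(x, name = name, series = series, index = idx, rounded = rounded,
            units = units, scale = scale, entropy = entropy,
            class = c("submat", "matrix"))
}

#' Parse an NCBI/EMBOSS-format substitution matrix file
#'
#' Reads a whitespace-separated scoring matrix with optional `#` comment
#' lines, a header row of residue letters and one labelled row per residue.
#' Rows and columns are reordered to the canonical order; extended codes
#' (B, Z, X, *, J, U, O) are dropped with a message. A header comment
#' `Entropy = <x>` is captured as relative entropy, and scale annotations
#' (`1/n Bit Units` for BLOSUM, `scale = ln(2)/n` for PAM) as the
#' bit-conversion divisor.
#'
#' @param file Path to the matrix file, or a character vector of lines via
#'   `text`.
#' @param name Matrix name; defaults to the file base name.
#' @param text Optional character vector of file content (overrides `file`).
#' @param bits If `TRUE`, divide all scores by the parsed scale so that the
#'   returned matrix is in bit units (error if the scale is unknown).
#' @return A [as_submat()] object.
#' @export
#' @examples
#' f <- system.file("extdata", "matrices", "BLOSUM62.mat", package = "aagalaxy")
#' S <- read_submat(f)
#' S["W", "W"]   # largest diagonal element
read_submat <- function(file, name = NULL, text = NULL, bits = FALSE) {
  lines <- if (!is.null(text)) text else readLines(file)
  if (is.null(name))
    name <- if (!is.null(text)) "matrix"
            else toupper(sub("\\.[^.]*$", "", basename(file)))
  comments <- grep("^\\s*#", lines, value = TRUE)
  entropy <- NA_real_
  h <- grep("Entropy\\s*=", comments, value = TRUE)
  if (length(h))
    entropy <- as.numeric(sub(".*Entropy\\s*=\\s*(-?[0-9.]+).*", "\\1", h[1]))
  scale <- NA_real_
  units <- "unknown"
  b <- grep("1/([0-9]+) Bit Units", comments, value = TRUE)
  if (length(b)) {
    scale <- as.numeric(sub(".*1/([0-9]+) Bit Units.*", "\\1", b[1]))
    units <- sprintf("1/%d bit", scale)
  }
  p <- grep("scale\\s*=\\s*ln\\(2\\)/([0-9]+)", comments, value = TRUE)
  if (length(p)) {
    scale <- as.numeric(sub(".*scale\\s*=\\s*ln\\(2\\)/([0-9]+).*", "\\1", p[1]))
    units <- sprintf("1/%d bit", scale)
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("no matrix body found in ", name)
  split_ws <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  header <- split_ws(body[1])
  rows <- lapply(body[-1], split_ws)
  bad <- which(lengths(rows) != length(header) + 1L)
  if (length(bad))
    stop("malformed row(s) at line ", paste(bad, collapse = ", "), " of ", name)
  rn <- vapply(rows, `[`, "", 1L)
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  if (anyNA(m)) stop("non-numeric entries in ", name)
  rownames(m) <- rn
  colnames(m) <- header
  if (bits) {
    if (is.na(scale)) stop("bit scale unknown for ", name)
    m <- m / scale
    units <- "bit"
  }
  rounded <- if (bits) FALSE else all(m == round(m))
  suppressMessages(
    as_submat(m, name = name, units = units,
              scale = if (bits) 1 else scale, entropy = entropy,
              rounded = rounded))
}

#' Write a substitution matrix in NCBI format
#'
#' @param S A `submat`.
#' @param file Output path (or `""` for stdout).
#' @param digits Significant digits for non-integer scores.
#' @return Invisibly, the lines written.
#' @export
write_submat <- function(S, file = "", digits = 10) {
  S <- as_submat(unclass(S), name = attr(S, "name") %||% "matrix",
                 units = attr(S, "units") %||% "unknown",
                 scale = attr(S, "scale") %||% NA_real_,
                 entropy = attr(S, "entropy") %||% NA_real_)
  hdr <- c(sprintf("# %s", attr(S, "name")),
           if (!is.na(attr(S, "entropy")))
             sprintf("# Entropy = %g", attr(S, "entropy")))
  fmt <- function(v) {
    if (all(v == round(v))) sprintf("%d", as.integer(v))
    else sprintf(paste0("%.", digits, "g"), v)
  }
  cells <- matrix(fmt(unclass(S)), 20, 20)
  wid <- max(nchar(cells), 2L)
  pad <- function(s) formatC(s, width = wid + 1L)
  lines <- c(hdr,
             paste0(" ", paste(pad(AA_ORDER), collapse = "")),
             vapply(seq_len(20), function(i)
               paste0(AA_ORDER[i], paste(pad(cells[i, ]), collapse = "")), ""))
  writeLines(lines, file)
  invisible(lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled matrix registry
#'
#' The package ships the standard rounded NCBI-format substitution matrices:
#' BLOSUM 30-90 in steps of 5, BLOSUM100 and BLOSUM62 (15 matrices; BLOSUM95
#' is not part of the standard NCBI set bundled here) and PAM10-PAM500 in
#' steps of 10 (50 matrices). `available_matrices()` lists them;
#' `submat()` loads one by name.
#'
#' @param name Matrix name, e.g. `"BLOSUM62"` or `"PAM250"`.
#' @param bits If `TRUE`, rescale scores to bit units using the scale
#'   annotation in the file header. The rounded files use series-dependent
#'   units (half-bit, third-bit, ...), so cross-matrix statistics such as
#'   the matrix mean or the galaxy radius are only comparable in bits.
#' @return `submat()`: a [as_submat()] object. `available_matrices()`: a
#'   data frame with columns `name`, `series`, `index`.
#' @export
#' @examples
#' S <- submat("BLOSUM62")
#' matrix_mean(S)
submat <- function(name, bits = FALSE) {
  f <- system.file("extdata", "matrices", paste0(name, ".mat"),
                   package = "aagalaxy")
  if (!nzchar(f)) {
    avail <- available_matrices()$name
    stop("unknown matrix '", name, "'; available: ",
         paste(utils::head(avail, 8), collapse = ", "), ", ...")
  }
  read_submat(f, name = name, bits = bits)
}

#' @rdname submat
#' @export
available_matrices <- function() {
  dir <- system.file("extdata", "matrices", package = "aagalaxy")
  names <- sort(sub("\\.mat$", "", list.files(dir, pattern = "\\.mat$")))
  series <- ifelse(grepl("^BLOSUM", names), "BLOSUM", "PAM")
  idx <- as.integer(sub("^(BLOSUM|PAM)", "", names))
  d <- data.frame(name = names, series = series, index = idx,
                  stringsAsFactors = FALSE)
  d[order(d$series, d$index), , drop = FALSE]
}

#' Matrix mean, shift, centering and Frobenius norm
#'
#' `matrix_mean()` is the arithmetic mean over all 400 cells of the square
#' table (each off-diagonal value counted twice, as it appears twice).
#' `shift_matrix()` adds a constant to every entry; `center_matrix()` shifts
#' by the negative mean so the result has mean zero. `frobenius_norm()` is
#' the square root of the sum of squared entries over all 400 cells.
#'
#' @param S A `submat` (or plain 20x20 matrix).
#' @param c Shift constant.
#' @return A scalar (`matrix_mean`, `frobenius_norm`) or a shifted `submat`.
#' @export
matrix_mean <- function(S) mean(unclass(S))

#' @rdname matrix_mean
#' @export
shift_matrix <- function(S, c) {
  out <- unclass(S) + c
  nm <- attr(S, "name") %||% "matrix"
  as_submat(out, name = if (c != 0) sprintf("%s%+g", nm, c) else nm,
            units = attr(S, "units") %||% "unknown",
            scale = attr(S, "scale") %||% NA_real_,
            entropy = attr(S, "entropy") %||% NA_real_,
            rounded = isTRUE(attr(S, "rounded")) && c == round(c))
}

#' @rdname matrix_mean
#' @export
center_matrix <- function(S) {
  out <- shift_matrix(S, -matrix_mean(S))
  attr(out, "name") <- paste0(attr(S, "name") %||% "matrix", " (centered)")
  out
}

#' @rdname matrix_mean
#' @export
frobenius_norm <- function(S) sqrt(sum(unclass(S)^2))

#' @export
print.submat <- function(x, ...) {
  cat(sprintf("Substitution matrix %s (%s series, %s, units: %s)\n",
              attr(x, "name"), attr(x, "series"),
              if (isTRUE(attr(x, "rounded"))) "rounded" else "non-rounded",
              attr(x, "units")))
  if (!is.na(attr(x, "entropy")))
    cat(sprintf("Relative entropy: %.4g bits\n", attr(x, "entropy")))
  cat(sprintf("Mean: %.4g  Frobenius norm: %.4g\n",
              matrix_mean(x), frobenius_norm(x)))
  print(unclass(x)[1:6, 1:6], ...)
  cat("... (20 x 20)\n")
  invisible(x)
}
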