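#' Vector-space consensus residue for an alignment column
#'
#' The consensus of a column is the amino acid whose vector lies closest (in
#' Euclidean distance) to the centroid of the vectors of the residues
#' observed in the column. Duplicate residues weight the centroid; gaps are
#' ignored. Equivalently, the consensus minimizes the sum of squared vector
#' distances to the column residues among the 20 candidates. Ties are broken
#' in canonical residue order and reported with a message.
#'
#' @param col Character vector of one-letter codes (gaps `"-"` allowed).
#' @param G An `aa_galaxy` (defaults expected from the caller; the centered
#'   BLOSUM62 galaxy is the natural choice).
#' @return Single residue character, with attributes `distances` (distance
#'   of every residue to the centroid) and `tie` (logical).
#' @export
#' @examples
#' G <- aa_galaxy(submat("BLOSUM62"))
#' column_consensus(c("H", "R", "V"), G)
column_consensus <- function(col, G) {
  G <- aa_galaxy(G)
  col <- toupper(col)
  col <- col[col != "-"]
  if (!length(col)) stop("all-gap column has no consensus")
  bad <- setdiff(col, AA_ORDER)
  if (length(bad)) stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  cen <- colMeans(unclass(G)[col, , drop = FALSE])
  d <- sqrt(rowSums(sweep(unclass(G), 2, cen)^2))
  best <- min(d)
  winners <- names(d)[d <= best + 1e-12]
  tie <- length(winners) > 1
  if (tie) message("consensus tie among {", paste(winners, collapse = ", "),
                   "}; canonical order breaks it")
  structure(winners[1], distances = d, tie = tie)
}

# read an aligned FASTA into a named character vector of equal-length strings
read_alignment <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(seqs, `[[`, "", 1L)), names(seqs))
}

#' Consensus sequence of a multiple alignment
#'
#' Applies [column_consensus()] column by column. Columns where gaps are in
#' the majority either emit a gap (`"majority_gap_emits_gap"`) or are called
#' from the non-gap residues alone (`"ignore_gaps"`).
#'
#' @param alignment Path to an aligned FASTA file, or a named character
#'   vector of equal-length aligned sequences.
#' @param G An `aa_galaxy`.
#' @param gap_rule `"majority_gap_emits_gap"` or `"ignore_gaps"`.
#' @return Single consensus string with attribute `per_column` (data frame:
#'   position, consensus, distance of winner to centroid, runner-up, margin).
#' @export
consensus_sequence <- function(alignment, G,
                               gap_rule = c("majority_gap_emits_gap",
                                            "ignore_gaps")) {
  gap_rule <- match.arg(gap_rule)
  G <- aa_galaxy(G)
  seqs <- if (is.character(alignment) && length(alignment) == 1 &&
              file.exists(alignment)) read_alignment(alignment)
          else toupper(alignment)
  if (length(unique(nchar(seqs))) != 1)
    stop("ragged alignment: sequences have unequal lengths")
  L <- nchar(seqs[1])
  mat <- do.call(rbind, strsplit(seqs, ""))
  out <- character(L)
  rows <- vector("list", L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    ngap <- sum(col == "-")
    if (gap_rule == "majority_gap_emits_gap" && ngap > length(col) / 2) {
      out[j] <- "-"
      rows[[j]] <- data.frame(position = j, consensus = "-",
                              distance = NA_real_, runner_up = NA_character_,
                              margin = NA_real_)
      next
    }
    if (all(col == "-")) stop("all-gap column at position ", j)
    cons <- suppressMessages(column_consensus(col, G))
    d <- sort(attr(cons, "distances"))
    out[j] <- as.character(cons)
    rows[[j]] <- data.frame(position = j, consensus = out[j],
                            distance = d[1], runner_up = names(d)[2],
                            margin = d[2] - d[1])
  }
  structure(paste(out, collapse = ""),
            per_column = do.call(rbind, rows))
}
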