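#' Read an aligned FASTA file
#'
#' Loads aligned sequences via Biostrings, validates that all records share
#' one alignment length, uppercases and maps T to U so DNA- and RNA-style
#' alignments behave identically downstream.
#'
#' @param path Aligned FASTA file.
#' @return Named character vector of aligned sequences (equal lengths).
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  aln <- toupper(as.character(set))
  aln <- chartr("T", "U", aln)
  if (length(unique(nchar(aln))) != 1) {
    ptc_abort("Alignment records do not share a common length",
              class = "ptcflex_invalid_alignment")
  }
  if (is.null(names(aln)) || anyNA(names(aln))) {
    ptc_abort("Alignment records must be named")
  }
  aln
}

## coerce alignment input (character vector or XStringSet) to a clean
## named character vector
as_alignment <- function(alignment) {
  if (inherits(alignment, "XStringSet")) alignment <- as.character(alignment)
  if (!is.character(alignment)) ptc_abort("Alignment must be a named character vector or XStringSet")
  aln <- chartr("T", "U", toupper(alignment))
  if (length(unique(nchar(aln))) != 1) {
    ptc_abort("Alignment records do not share a common length",
              class = "ptcflex_invalid_alignment")
  }
  aln
}

#' Map reference positions to alignment columns
#'
#' Walks the (possibly gapped) reference record and returns, for each
#' requested 1-based ungapped reference position, the 1-based alignment
#' column holding that residue. The reference character at the mapped
#' column always equals the reference's ungapped character, and the map is
#' strictly increasing in position.
#'
#' @param alignment Named character vector (or `XStringSet`) of aligned
#'   sequences.
#' @param reference_id Name of the reference record (e.g. the E. coli
#'   sequence used to define regions of interest).
#' @param positions Integer vector of ungapped reference positions.
#' @return Tibble `position`, `column` (1-based alignment column).
#' @export
map_reference_positions <- function(alignment, reference_id, positions) {
  aln <- as_alignment(alignment)
  if (!reference_id %in% names(aln)) {
    ptc_abort(sprintf("Reference record '%s' not found in alignment", reference_id),
              class = "ptcflex_missing_reference")
  }
  chars <- strsplit(aln[[reference_id]], "")[[1]]
  cols <- which(!chars %in% c("-", "."))
  if (any(positions < 1) || any(positions > length(cols))) {
    ptc_abort(sprintf(
      "Position(s) beyond ungapped reference length (%d): %s", length(cols),
      paste(positions[positions < 1 | positions > length(cols)], collapse = ", ")
    ), class = "ptcflex_position_out_of_range")
  }
  tibble::tibble(position = as.integer(positions), column = cols[positions])
}

#' Shannon entropy of an alignment column
#'
#' \eqn{H = -\sum_{i \in \{A,U,G,C\}} p_i \ln p_i}, where \eqn{p_i} is the
#' count of nucleotide *i* divided by the number of retained (non-excluded)
#' sequences at that column. H is reported in nats: 0 for a monomorphic
#' column, ln 4 (about 1.386) when all four bases are equally likely.
#'
#' @param counts Named numeric vector of per-base counts (names among
#'   A/C/G/U); excluded sequences are simply absent from the counts.
#' @return Entropy in nats.
#' @examples
#' column_entropy(c(A = 25, C = 25, G = 25, U = 25)) # ~1.386
#' @export
column_entropy <- function(counts) {
  if (length(counts) == 0 || !all(names(counts) %in% RNA_BASES)) {
    ptc_abort("counts must be named with bases among A, C, G, U")
  }
  if (any(counts < 0)) ptc_abort("counts must be non-negative")
  total <- sum(counts)
  if (total < 1) {
    ptc_abort("All sequences excluded at this column; entropy undefined",
              class = "ptcflex_undefined_entropy")
  }
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

## per-column base counts with the exclusion rule applied.
## exclude = "non_acgu" drops gaps and any ambiguity character;
## exclude = "gap_only" drops only '-' (and '.') and errors on other symbols.
column_counts <- function(seq_mat, column, exclude = c("non_acgu", "gap_only")) {
  exclude <- match.arg(exclude)
  chars <- seq_mat[, column]
  gap <- chars %in% c("-", ".")
  if (exclude == "gap_only") {
    keep <- !gap
    if (any(!chars[keep] %in% RNA_BASES)) {
      ptc_abort(sprintf("Non-ACGU character in column %d under gap-only exclusion", column))
    }
  } else {
    keep <- chars %in% RNA_BASES
  }
  counts <- vapply(RNA_BASES, function(b) sum(chars[keep] == b), integer(1))
  list(counts = counts, n_excluded = sum(!keep))
}

#' Per-position conservation profile of a region
#'
#' Maps each region position onto its alignment column and computes the
#' column's base counts, exclusion count and Shannon entropy (nats).
#' Sequences carrying a gap (or, by default, any non-ACGU symbol) at a
#' column are removed from that column before computing probabilities.
#'
#' @inheritParams map_reference_positions
#' @param positions Either an integer vector of reference positions or a
#'   tibble with a `position` column (e.g. from [region_positions()]).
#' @param exclude `"non_acgu"` (default) excludes gaps and ambiguity codes;
#'   `"gap_only"` reproduces a strict '-'-only rule.
#' @return Tibble `position`, `column`, `n_A`, `n_C`, `n_G`, `n_U`,
#'   `n_excluded`, `entropy` in region order.
#' @export
entropy_profile <- function(alignment, reference_id, positions,
                            exclude = c("non_acgu", "gap_only")) {
  exclude <- match.arg(exclude)
  aln <- as_alignment(alignment)
  if (is.data.frame(positions)) positions <- positions$position
  map <- map_reference_positions(aln, reference_id, positions)
  seq_mat <- do.call(rbind, strsplit(unname(aln), ""))
  purrr::map2_dfr(map$position, map$column, function(pos, col) {
    prof <- column_counts(seq_mat, col, exclude)
    h <- withCallingHandlers(
      tryCatch(column_entropy(prof$counts),
               ptcflex_undefined_entropy = function(e) {
                 ptc_abort(sprintf("All sequences excluded at position %d (column %d)", pos, col),
                           class = "ptcflex_undefined_entropy")
               })
    )
    tibble::tibble(
      position = pos, column = col,
      n_A = prof$counts[["A"]], n_C = prof$counts[["C"]],
      n_G = prof$counts[["G"]], n_U = prof$counts[["U"]],
      n_excluded = prof$n_excluded, entropy = h
    )
  })
}
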