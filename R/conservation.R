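#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal file into the character-matrix
#' representation used by the conservation functions (rows = sequences,
#' columns = alignment columns, gaps as `"-"`).
#'
#' @param path File path.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @return Character matrix with sequence ids as row names.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(Biostrings::unmasked(aln))
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned sequences have unequal lengths")
  }
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- if (!is.null(names(seqs))) names(seqs) else
    paste0("seq", seq_len(nrow(m)))
  m
}

#' Write an alignment as aligned FASTA
#'
#' @param alignment Character matrix (rows = sequences).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(alignment, path) {
  seqs <- apply(alignment, 1L, paste, collapse = "")
  ids <- rownames(alignment)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  writeLines(paste0(">", ids, "\n", seqs), path)
  invisible(path)
}

gap_chars <- c("-", ".")

#' Wu-Kabat variability of an alignment column
#'
#' `N * k / n`, where `N` is the number of sequences in the alignment, `k`
#' the number of distinct amino acids at the position, and `n` the count of
#' the most common amino acid there. A fully conserved, gap-free column
#' scores 1; variability grows with the number and evenness of observed
#' residues (a depth-20 column of 20 distinct residues scores 400). Gaps
#' are ignored when counting `k` and `n` while `N` stays the full alignment
#' depth (the classical convention); set `gap_as_symbol = TRUE` to count
#' gaps as a 21st symbol instead.
#'
#' @param column Character vector of aligned residues (one alignment
#'   column), possibly containing gap characters `-` or `.`.
#' @param gap_as_symbol Treat the gap as an ordinary 21st symbol.
#' @return The Wu-Kabat variability (>= 1 for any non-degenerate column).
#' @examples
#' wu_kabat(c("A", "A", "C", "G"))  # 4 * 3 / 2 = 6
#' @export
wu_kabat <- function(column, gap_as_symbol = FALSE) {
  stopifnot(length(column) > 0L)
  N <- length(column)
  obs <- if (gap_as_symbol) column else column[!column %in% gap_chars]
  if (length(obs) == 0L) stop("all-gap column has no Wu-Kabat variability")
  counts <- table(obs)
  N * length(counts) / max(counts)
}

#' Per-column Wu-Kabat profile mapped to reference coordinates
#'
#' @param alignment Character matrix (rows = sequences).
#' @param reference Row name (or index) of the reference sequence;
#'   alignment columns where the reference has a gap are skipped. `NULL`
#'   returns all columns on alignment coordinates.
#' @param gap_as_symbol Passed to [wu_kabat()].
#' @return Data frame with `position` (reference residue index, or
#'   alignment column if `reference` is `NULL`) and `variability`.
#' @export
wu_kabat_profile <- function(alignment, reference = NULL,
                             gap_as_symbol = FALSE) {
  cols <- seq_len(ncol(alignment))
  if (!is.null(reference)) {
    ref <- alignment_reference_row(alignment, reference)
    keep <- !alignment[ref, ] %in% gap_chars
    cols <- which(keep)
  }
  data.frame(
    position = seq_along(cols),
    column = cols,
    variability = vapply(cols, function(j)
      wu_kabat(alignment[, j], gap_as_symbol), numeric(1))
  )
}

alignment_reference_row <- function(alignment, reference) {
  if (is.numeric(reference)) return(as.integer(reference))
  ref <- match(reference, rownames(alignment))
  if (is.na(ref)) stop("reference sequence '", reference,
                       "' absent from the alignment")
  ref
}

#' Conserved positions of an alignment
#'
#' A column is conserved when all its non-gap characters are identical and
#' its gap fraction does not exceed `max_gap_fraction` (default 0: fully
#' ungapped and invariant, the strictest reading). Columns are mapped to
#' reference-sequence residue positions; columns where the reference has a
#' gap are never assigned a position.
#'
#' @param alignment Character matrix.
#' @param reference Reference row name or index.
#' @param max_gap_fraction Maximal tolerated gap fraction (default 0).
#' @return Integer vector of conserved reference positions.
#' @export
conserved_positions <- function(alignment, reference = 1L,
                                max_gap_fraction = 0) {
  ref <- alignment_reference_row(alignment, reference)
  ref_cols <- which(!alignment[ref, ] %in% gap_chars)
  conserved <- vapply(ref_cols, function(j) {
    col <- alignment[, j]
    gaps <- col %in% gap_chars
    mean(gaps) <= max_gap_fraction &&
      length(unique(col[!gaps])) == 1L
  }, TRUE)
  which(conserved)  # ref_cols are 1:1 with reference residue positions
}

#' Conserved positions per substructure segment
#'
#' Counts conserved alignment positions (see [conserved_positions()])
#' falling into each segment of a substructure map and divides by segment
#' length (conserved sites per residue, CSR/residue).
#'
#' @inheritParams conserved_positions
#' @param map A `substructure_map` on reference coordinates.
#' @return Data frame with `segment`, `class`, `length`, `conserved`,
#'   `csr_per_residue`.
#' @export
csr_per_segment <- function(alignment, map, reference = 1L,
                            max_gap_fraction = 0) {
  cons <- conserved_positions(alignment, reference, max_gap_fraction)
  seg <- residue_segments(map)
  cls <- residue_classes(map)
  lens <- segment_lengths(map)$segments
  segs <- names(lens)
  data.frame(
    segment = segs,
    class = vapply(segs, function(s) cls[which(seg == s)[1]], ""),
    length = as.integer(lens),
    conserved = vapply(segs, function(s)
      sum(cons %in% which(seg == s)), 0L),
    csr_per_residue = vapply(segs, function(s)
      sum(cons %in% which(seg == s)) / lens[[s]], numeric(1)),
    row.names = NULL
  )
}

#' Pairwise sequence identity matrix
#'
#' For each sequence pair: (i) positions are compared one at a time,
#' (ii) all gap characters are treated as gaps, (iii) columns where both
#' sequences have a gap are removed and do not contribute, (iv) a residue
#' against a gap counts as a mismatch, (v) the reported value is the number
#' of identities divided by the number of columns remaining after both-gap
#' removal.
#'
#' @param alignment Character matrix of aligned sequences (equal lengths).
#' @return Symmetric numeric matrix of identity fractions with unit
#'   diagonal.
#' @examples
#' aln <- rbind(a = strsplit("ACDE-", "")[[1]],
#'              b = strsplit("ACE--", "")[[1]])
#' identity_matrix(aln)["a", "b"]  # 0.5
#' @export
identity_matrix <- function(alignment) {
  n <- nrow(alignment)
  if (n < 2L) stop("need at least two aligned sequences")
  out <- diag(1, n)
  dimnames(out) <- list(rownames(alignment), rownames(alignment))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- alignment[i, ]
      b <- alignment[j, ]
      both_gap <- a %in% gap_chars & b %in% gap_chars
      a <- a[!both_gap]
      b <- b[!both_gap]
      if (length(a) == 0L) stop("sequence pair shares no columns")
      ident <- sum(a == b & !a %in% gap_chars)
      out[i, j] <- out[j, i] <- ident / length(a)
    }
  }
  out
}

#' Per-class amino-acid composition across an alignment
#'
#' For every sequence, computes the amino-acid percentage composition over
#' the alignment columns belonging to each mechanical class (S/U) of the
#' reference-coordinate substructure map, skipping that sequence's gaps;
#' reports the across-sequence mean and standard deviation. Per class and
#' sequence the percentages sum to 100.
#'
#' @param alignment Character matrix (a single sequence may be passed as a
#'   1-row matrix).
#' @param map A `substructure_map` on reference coordinates.
#' @param reference Reference row name or index (default 1).
#' @return Data frame with `class`, `aa`, `mean_pct`, `sd_pct`.
#' @export
composition_profile <- function(alignment, map, reference = 1L) {
  ref <- alignment_reference_row(alignment, reference)
  ref_cols <- which(!alignment[ref, ] %in% gap_chars)
  cls <- residue_classes(map)
  out <- NULL
  for (cl in c("U", "S")) {
    pos <- which(cls == cl)
    cols <- ref_cols[pos]   # alignment columns of this class
    pct <- t(apply(alignment[, cols, drop = FALSE], 1L, function(row) {
      obs <- row[!row %in% gap_chars]
      100 * tabulate(match(obs, AA_ALPHABET),
                     nbins = length(AA_ALPHABET)) / length(obs)
    }))
    colnames(pct) <- AA_ALPHABET
    sd_pct <- if (nrow(pct) > 1L) apply(pct, 2L, stats::sd) else
      rep(0, ncol(pct))
    out <- rbind(out, data.frame(
      class = cl, aa = AA_ALPHABET,
      mean_pct = colMeans(pct),
      sd_pct = sd_pct,
      row.names = NULL))
  }
  out
}
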