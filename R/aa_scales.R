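#' Load the amino-acid physico-chemical scale table
#'
#' Reads a table of 28 literature amino-acid scales (ids `A1`...`A28`), each
#' assigning one real value to each of the 20 standard amino acids. The
#' packaged default covers hydropathy/hydrophobicity scales (A1-A19, which
#' are subject to moving-average smoothing) and context-free descriptors
#' such as flexibility, polarity, refractivity, bulkiness and mutability
#' (A20-A28, used as raw per-residue values). Scale values were transcribed
#' from the cited publications; each scale carries its citation string.
#'
#' @param path Path to a TSV with an `aa` column (20 standard one-letter
#'   codes) and one numeric column per scale id. `NULL` loads the packaged
#'   default.
#' @param meta_path Path to a JSON sidecar mapping scale ids to
#'   `name`/`citation` strings. `NULL` loads the sidecar next to `path` (or
#'   the packaged default).
#' @param averaged_ids Character vector of scale ids smoothed by the moving
#'   average. Default `A1`-`A19`.
#' @return An object of class `scale_table`: a list with `values` (20 x 28
#'   numeric matrix, rows named by [AA_ALPHABET], columns by scale id),
#'   `info` (data frame of `id`, `name`, `citation`) and `averaged_ids`.
#' @examples
#' tab <- load_scales()
#' tab$info$name[tab$info$id == "A1"]   # "Hydropathicity"
#' tab$values["A", "A1"]               # Ala on the Kyte-Doolittle scale
#' @export
load_scales <- function(path = NULL, meta_path = NULL,
                        averaged_ids = paste0("A", 1:19)) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_scales.tsv", package = "seqstab",
                        mustWork = TRUE)
  }
  if (is.null(meta_path)) {
    candidate <- file.path(dirname(path), "aa_scales_meta.json")
    meta_path <- if (file.exists(candidate)) candidate else
      system.file("extdata", "aa_scales_meta.json", package = "seqstab",
                  mustWork = TRUE)
  }
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"aa" %in% names(raw)) stop("scale table needs an 'aa' column")
  ids <- setdiff(names(raw), "aa")
  expected <- paste0("A", 1:28)
  missing_ids <- setdiff(expected, ids)
  if (length(missing_ids) > 0L || length(ids) != 28L) {
    stop("scale table must provide exactly the 28 scales A1...A28; ",
         if (length(missing_ids) > 0L)
           paste0("missing: ", paste(missing_ids, collapse = ", "))
         else paste0("found ", length(ids), " scales"))
  }
  missing_aa <- setdiff(AA_ALPHABET, raw$aa)
  if (length(missing_aa) > 0L) {
    stop("scale table missing amino acid(s): ",
         paste(missing_aa, collapse = ", "))
  }
  if (anyDuplicated(raw$aa)) stop("duplicated amino-acid rows in scale table")
  values <- matrix(NA_real_, nrow = length(AA_ALPHABET),
                   ncol = length(expected),
                   dimnames = list(AA_ALPHABET, expected))
  ord <- match(AA_ALPHABET, raw$aa)
  for (id in expected) {
    col <- suppressWarnings(as.numeric(raw[[id]]))
    if (anyNA(col)) {
      stop("non-numeric or missing value in scale ", id, " for residue ",
           raw$aa[which(is.na(col))[1]])
    }
    if (length(unique(col)) < 2L) {
      stop("scale ", id, " is constant; Z-scoring would be undefined")
    }
    values[, id] <- col[ord]
  }
  meta <- jsonlite::read_json(meta_path)
  info <- data.frame(
    id = expected,
    name = vapply(expected, function(id)
      if (!is.null(meta[[id]]$name)) meta[[id]]$name else NA_character_, ""),
    citation = vapply(expected, function(id)
      if (!is.null(meta[[id]]$citation)) meta[[id]]$citation else
        NA_character_, ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!all(averaged_ids %in% expected)) {
    stop("averaged_ids must be a subset of the scale ids")
  }
  structure(list(values = values, info = info, averaged_ids = averaged_ids),
            class = "scale_table")
}

#' @export
print.scale_table <- function(x, ...) {
  cat("Amino-acid scale table: ", ncol(x$values), " scales x ",
      nrow(x$values), " residues\n", sep = "")
  cat("Smoothed by moving average: ", x$averaged_ids[1], "...",
      x$averaged_ids[length(x$averaged_ids)],
      " (", length(x$averaged_ids), " scales)\n", sep = "")
  invisible(x)
}

#' Write a scale table back to its TSV + JSON file format
#'
#' Inverse of [load_scales()]; the TSV/JSON pair round-trips bit-identically
#' through a reload.
#'
#' @param table A `scale_table`.
#' @param path Output TSV path; the JSON sidecar is written next to it as
#'   `aa_scales_meta.json` unless `meta_path` is given.
#' @param meta_path Optional JSON sidecar path.
#' @return Invisibly, `path`.
#' @export
write_scales <- function(table, path, meta_path = NULL) {
  stopifnot(inherits(table, "scale_table"))
  if (is.null(meta_path)) meta_path <- file.path(dirname(path),
                                                 "aa_scales_meta.json")
  df <- data.frame(aa = rownames(table$values), table$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- lapply(seq_len(nrow(table$info)), function(i)
    list(name = table$info$name[i], citation = table$info$citation[i]))
  names(meta) <- table$info$id
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' One-hot encode a protein sequence
#'
#' Represents each residue as a 20-column binary indicator row, one column
#' per standard amino acid in the fixed alphabetical order of
#' [AA_ALPHABET]. Used as the context-free baseline encoding, which carries
#' no notion of chemical similarity between amino acids.
#'
#' @param sequence Protein sequence (one-letter codes; standard residues
#'   only).
#' @return An integer matrix of dimension `nchar(sequence)` x 20 with
#'   `rownames` = 1-based positions and `colnames` = [AA_ALPHABET]. Each row
#'   sums to 1.
#' @examples
#' one_hot_encode("ACDY")
#' @export
one_hot_encode <- function(sequence) {
  chars <- split_residues(sequence)
  m <- matrix(0L, nrow = length(chars), ncol = length(AA_ALPHABET),
              dimnames = list(seq_along(chars), AA_ALPHABET))
  m[cbind(seq_along(chars), match(chars, AA_ALPHABET))] <- 1L
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' @param matrix A position x 20 binary matrix as produced by
#'   [one_hot_encode()].
#' @return The protein sequence as a single string.
#' @export
one_hot_decode <- function(matrix) {
  stopifnot(ncol(matrix) == length(AA_ALPHABET),
            all(rowSums(matrix) == 1))
  paste(AA_ALPHABET[apply(matrix, 1L, which.max)], collapse = "")
}

#' Shuffled-scale null: permute each scale's values across amino acids
#'
#' Negative control destroying the chemical grouping encoded in the scales:
#' within each scale, the 20 values are randomly reassigned to amino acids.
#' Values never cross scales, so each scale's value multiset (and hence mean
#' and standard deviation) is preserved exactly. Classifiers trained on
#' shuffled scales should lose their ability to separate stable from
#' unstable residues if chemical similarity is what they exploit.
#'
#' @param table A `scale_table`.
#' @param seed Integer seed; identical seeds yield identical shuffles. The
#'   caller's RNG state is not disturbed.
#' @return A `scale_table` with permuted values (names and citations kept).
#' @export
shuffle_scales <- function(table, seed) {
  stopifnot(inherits(table, "scale_table"))
  values <- with_seed(seed, {
    apply(table$values, 2L, sample)
  })
  rownames(values) <- rownames(table$values)
  out <- table
  out$values <- values
  out
}
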