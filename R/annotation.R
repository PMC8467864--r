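#' Construct a substructure map
#'
#' A substructure map partitions the analyzed part of a protein sequence
#' into named segments, each labeled mechanically stable (`S`) or unstable
#' (`U`). Segments may be discontinuous (several residue ranges). Residue
#' coordinates are 1-based inclusive throughout. Intervals listed in
#' `excluded` (e.g. a disordered tail) are outside the analysis.
#'
#' @param segments Data frame with columns `segment` (name), `class`
#'   (`"S"`/`"U"`) and 1-based inclusive `start`, `end`; a discontinuous
#'   segment contributes several rows under the same name.
#' @param excluded Optional data frame with `start`, `end` columns of
#'   excluded intervals (may be `NULL`).
#' @param sequence_length Total sequence length.
#' @return An object of class `substructure_map`.
#' @export
substructure_map <- function(segments, excluded = NULL, sequence_length) {
  stopifnot(is.data.frame(segments),
            all(c("segment", "class", "start", "end") %in% names(segments)))
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  if (!all(segments$class %in% c("S", "U"))) {
    stop("segment class must be 'S' or 'U'")
  }
  if (any(segments$start > segments$end)) stop("interval with start > end")
  if (any(segments$start < 1L) || any(segments$end > sequence_length)) {
    stop("segment range outside [1, sequence_length]")
  }
  if (is.null(excluded)) {
    excluded <- data.frame(start = integer(0), end = integer(0))
  }
  excluded$start <- as.integer(excluded$start)
  excluded$end <- as.integer(excluded$end)

  covered <- integer(0)
  for (i in seq_len(nrow(segments))) {
    iv <- segments$start[i]:segments$end[i]
    if (any(iv %in% covered)) {
      stop("overlapping segment ranges at residue ",
           intersect(iv, covered)[1])
    }
    covered <- c(covered, iv)
  }
  excl <- unlist(mapply(seq, excluded$start, excluded$end,
                        SIMPLIFY = FALSE))
  if (any(excl %in% covered)) stop("excluded interval overlaps a segment")
  uncovered <- setdiff(seq_len(sequence_length), c(covered, excl))
  if (length(uncovered) > 0L) {
    stop("residue ", uncovered[1],
         " belongs to no segment and is not excluded")
  }
  structure(list(segments = segments, excluded = excluded,
                 sequence_length = as.integer(sequence_length)),
            class = "substructure_map")
}

#' @export
print.substructure_map <- function(x, ...) {
  tot <- segment_lengths(x)
  cat("Substructure map: ", length(tot$segments), " segments (",
      sum(x$segments$class[!duplicated(x$segments$segment)] == "S"), " S, ",
      sum(x$segments$class[!duplicated(x$segments$segment)] == "U"), " U), ",
      x$sequence_length, " residues, ", sum(tot$class_totals),
      " analyzed\n", sep = "")
  invisible(x)
}

#' Default DnaK substructure map
#'
#' The mechanical substructure assignment of the 638-residue E. coli Hsp70
#' chaperone DnaK, established by single-molecule optical-tweezers
#' unfolding: three unstable substructures (U1 = lobe I 1-185, U2 = the
#' interdomain linker 372-392, U3 = helices A/B 506-533) and four stable
#' ones (S1 = lobe IIa, discontinuous 186-228 + 312-371; S2 = lobe IIb
#' 229-311; S3 = beta-core 393-505; S4 = helical lid 534-603). The
#' disordered C-terminal tail 604-638 is excluded from analysis. The
#' boundary residue 371, quoted in the source ranges of both S1 and the
#' linker, is assigned to S1 so that the linker has its documented length
#' of 21 residues.
#'
#' @return A `substructure_map` covering residues 1-603 of a 638-residue
#'   sequence.
#' @examples
#' map <- default_dnak_map()
#' segment_lengths(map)$class_totals  # U 234, S 369
#' @export
default_dnak_map <- function() {
  segments <- data.frame(
    segment = c("U1", "S1", "S1", "S2", "U2", "S3", "U3", "S4"),
    class   = c("U",  "S",  "S",  "S",  "U",  "S",  "U",  "S"),
    start   = c(1L, 186L, 312L, 229L, 372L, 393L, 506L, 534L),
    end     = c(185L, 228L, 371L, 311L, 392L, 505L, 533L, 603L),
    stringsAsFactors = FALSE
  )
  excluded <- data.frame(start = 604L, end = 638L)
  substructure_map(segments, excluded, sequence_length = 638L)
}

#' Per-residue class vector of a map
#'
#' @param map A `substructure_map`.
#' @return Character vector of length `sequence_length`: `"S"`/`"U"` for
#'   analyzed residues, `NA` for excluded ones.
#' @export
residue_classes <- function(map) {
  cls <- rep(NA_character_, map$sequence_length)
  for (i in seq_len(nrow(map$segments))) {
    cls[map$segments$start[i]:map$segments$end[i]] <- map$segments$class[i]
  }
  cls
}

residue_segments <- function(map) {
  seg <- rep(NA_character_, map$sequence_length)
  for (i in seq_len(nrow(map$segments))) {
    seg[map$segments$start[i]:map$segments$end[i]] <- map$segments$segment[i]
  }
  seg
}

#' Analyzed residue positions of a map
#'
#' @param map A `substructure_map`.
#' @return Sorted integer vector of all residue positions belonging to a
#'   segment (i.e. not excluded).
#' @export
analyzed_positions <- function(map) {
  which(!is.na(residue_classes(map)))
}

#' Label one or more residues with their segment and class
#'
#' @param map A `substructure_map`.
#' @param position Vector of 1-based residue positions.
#' @return Data frame with columns `position`, `segment`, `class`; excluded
#'   residues get segment `NA` and class `"excluded"`.
#' @examples
#' label_residue(default_dnak_map(), c(100, 250, 610))
#' @export
label_residue <- function(map, position) {
  stopifnot(inherits(map, "substructure_map"))
  position <- as.integer(position)
  if (any(position < 1L) || any(position > map$sequence_length)) {
    stop("position out of range 1..", map$sequence_length)
  }
  cls <- residue_classes(map)[position]
  seg <- residue_segments(map)[position]
  data.frame(position = position, segment = seg,
             class = ifelse(is.na(cls), "excluded", cls),
             stringsAsFactors = FALSE)
}

#' Segment lengths and class totals
#'
#' @param map A `substructure_map`.
#' @return A list with `segments` (named integer vector of residue counts
#'   per segment, summing discontinuous ranges) and `class_totals` (named
#'   integer vector over `U`, `S`).
#' @export
segment_lengths <- function(map) {
  stopifnot(inherits(map, "substructure_map"))
  widths <- map$segments$end - map$segments$start + 1L
  segs <- tapply(widths, map$segments$segment, sum)
  segs <- segs[unique(map$segments$segment)]   # keep map order
  segs <- stats::setNames(as.integer(segs), names(segs))
  cls_of <- map$segments$class[!duplicated(map$segments$segment)]
  names(cls_of) <- unique(map$segments$segment)
  totals <- c(U = sum(segs[cls_of == "U"]), S = sum(segs[cls_of == "S"]))
  list(segments = segs, class_totals = totals)
}

#' Distance of a residue to the nearest opposite-class residue
#'
#' For each analyzed residue, the minimal absolute sequence distance to any
#' analyzed residue of the other mechanical class. Residues adjacent to a
#' class border return 1. Used to characterize where misclassifications
#' fall: errors concentrate at S/U borders, where the moving-average window
#' mixes both classes.
#'
#' @param map A `substructure_map`.
#' @param position Vector of analyzed residue positions.
#' @return Integer vector of border distances.
#' @examples
#' border_distance(default_dnak_map(), c(185, 186, 100))
#' @export
border_distance <- function(map, position) {
  stopifnot(inherits(map, "substructure_map"))
  position <- as.integer(position)
  cls <- residue_classes(map)
  if (any(position < 1L) || any(position > map$sequence_length) ||
      anyNA(cls[position])) {
    stop("border_distance is defined for analyzed residues only")
  }
  vapply(position, function(p) {
    other <- which(!is.na(cls) & cls != cls[p])
    min(abs(other - p))
  }, integer(1))
}

#' Read and write substructure maps as TSV
#'
#' The format is a 4-column TSV `segment`, `class`, `start`, `end` with one
#' row per (possibly partial) range; discontinuous segments repeat the
#' segment name and excluded intervals carry class `"X"`.
#'
#' @param path File path.
#' @param sequence_length Total sequence length (required on read, since the
#'   TSV carries ranges only).
#' @return `read_substructure_map()` returns a `substructure_map`;
#'   `write_substructure_map()` invisibly returns `path`.
#' @export
read_substructure_map <- function(path, sequence_length) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("segment", "class", "start", "end") %in% names(df)))
  excl <- df[df$class == "X", c("start", "end"), drop = FALSE]
  segs <- df[df$class != "X", , drop = FALSE]
  substructure_map(segs, if (nrow(excl) > 0L) excl else NULL,
                   sequence_length = sequence_length)
}

#' @rdname read_substructure_map
#' @param map A `substructure_map` to write.
#' @export
write_substructure_map <- function(map, path) {
  stopifnot(inherits(map, "substructure_map"))
  df <- map$segments[, c("segment", "class", "start", "end")]
  if (nrow(map$excluded) > 0L) {
    df <- rbind(df, data.frame(segment = "excluded", class = "X",
                               start = map$excluded$start,
                               end = map$excluded$end))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign residues to protein domains for reporting
#'
#' Default domain split for DnaK-style reports: nucleotide-binding domain
#' (NBD) = residues 1-392 including the interdomain linker,
#' substrate-binding domain (SBD) = 393 onward.
#'
#' @param position Vector of residue positions.
#' @param nbd_end Last residue of the NBD (default 392).
#' @return Character vector `"NBD"`/`"SBD"`.
#' @export
domain_of <- function(position, nbd_end = 392L) {
  ifelse(position <= nbd_end, "NBD", "SBD")
}
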