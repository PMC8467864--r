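#' Default synthetic segment layout
#'
#' The DnaK-like layout used by the synthetic generator: the mechanical
#' class runs of the DnaK substructure map collapsed into contiguous
#' alternating blocks — U 185, S 186, U 21, S 113, U 28, S 70 residues
#' (603 analyzed residues in total, U 234 / S 369).
#'
#' @return Data frame with columns `class` and `length`.
#' @export
dnak_layout <- function() {
  data.frame(class = c("U", "S", "U", "S", "U", "S"),
             length = c(185L, 186L, 21L, 113L, 28L, 70L))
}

#' Average amino-acid background composition
#'
#' Database-average amino-acid frequencies (UniProtKB/Swiss-Prot style),
#' normalized to sum to 1, in [AA_ALPHABET] order. Used as the base
#' composition of the synthetic generator.
#'
#' @return Named numeric probability vector of length 20.
#' @export
average_aa_composition <- function() {
  p <- c(A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86, G = 7.07,
         H = 2.27, I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06,
         P = 4.70, Q = 3.93, R = 5.53, S = 6.56, T = 5.34, V = 6.87,
         W = 1.08, Y = 2.92)
  p[AA_ALPHABET] / sum(p)
}

#' Specify a synthetic labeled-sequence generator
#'
#' Defines the statistical structure of a synthetic protein: a layout of
#' alternating S/U class runs, residues drawn i.i.d. within each segment
#' from a class-specific composition
#' `p_class = (1 - delta) * base + delta * e_class`, where `e_class` puts
#' all mass on a class-preferred residue (default Ala for U, Thr for S,
#' mirroring the compositional contrast observed between unstable and
#' stable substructures). `delta = 0` makes the classes statistically
#' identical; `delta = 1` makes segments homopolymeric.
#'
#' @param layout Data frame with `class`, `length` columns (default
#'   [dnak_layout()]).
#' @param base_composition Probability vector over [AA_ALPHABET] (default
#'   [average_aa_composition()]).
#' @param delta Composition divergence in `[0, 1]`.
#' @param enrichment Named character vector with the preferred residue of
#'   each class, e.g. `c(U = "A", S = "T")`.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(layout = dnak_layout(),
                           base_composition = average_aa_composition(),
                           delta = 0.5,
                           enrichment = c(U = "A", S = "T"),
                           seed = 1L) {
  stopifnot(is.data.frame(layout),
            all(c("class", "length") %in% names(layout)),
            all(layout$class %in% c("S", "U")), all(layout$length >= 1L))
  base <- base_composition[AA_ALPHABET]
  if (anyNA(base) || any(base < 0) || abs(sum(base) - 1) > 1e-8) {
    stop("base_composition must be a probability vector over AA_ALPHABET")
  }
  stopifnot(delta >= 0, delta <= 1,
            all(c("U", "S") %in% names(enrichment)),
            all(enrichment %in% AA_ALPHABET))
  comp <- lapply(c(U = "U", S = "S"), function(cl) {
    e <- stats::setNames(numeric(length(AA_ALPHABET)), AA_ALPHABET)
    e[enrichment[[cl]]] <- 1
    (1 - delta) * base + delta * e
  })
  structure(list(layout = layout, base_composition = base, delta = delta,
                 enrichment = enrichment, class_compositions = comp,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labeled synthetic sequence
#'
#' Draws a protein sequence segment by segment from the class compositions
#' of a [synthetic_spec()] and returns it together with the ground-truth
#' substructure map (segments named U1, S1, ... in layout order, no
#' excluded intervals). Reproducible given the spec's seed.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `sequence` (string) and `map` (`substructure_map`).
#' @export
generate_labeled_sequence <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  layout <- spec$layout
  counts <- stats::setNames(c(0L, 0L), c("U", "S"))
  names <- character(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    cl <- layout$class[i]
    counts[cl] <- counts[cl] + 1L
    names[i] <- paste0(cl, counts[cl])
  }
  ends <- cumsum(layout$length)
  starts <- ends - layout$length + 1L
  chars <- with_seed(spec$seed, {
    unlist(lapply(seq_len(nrow(layout)), function(i) {
      sample(AA_ALPHABET, layout$length[i], replace = TRUE,
             prob = spec$class_compositions[[layout$class[i]]])
    }))
  })
  map <- substructure_map(
    data.frame(segment = names, class = layout$class,
               start = starts, end = ends),
    excluded = NULL, sequence_length = sum(layout$length))
  list(sequence = paste(chars, collapse = ""), map = map)
}

#' Generate a synthetic multiple sequence alignment
#'
#' Emulates an ungapped family alignment around a reference sequence: each
#' of `n_sequences - 1` additional rows mutates every column independently
#' with probability `rate` to a uniformly chosen different residue. No
#' indels are introduced, so alignment columns correspond 1:1 to reference
#' positions.
#'
#' @param reference Reference protein sequence (string).
#' @param n_sequences Total number of rows including the reference.
#' @param rate Per-column substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Character matrix with the reference as row `"reference"` and
#'   rows `"seq2"`, `"seq3"`, ...
#' @export
generate_msa <- function(reference, n_sequences, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1, n_sequences >= 1L)
  ref <- split_residues(reference)
  L <- length(ref)
  aln <- matrix(rep(ref, each = n_sequences), nrow = n_sequences)
  rownames(aln) <- c("reference",
                     if (n_sequences > 1L) paste0("seq", 2:n_sequences))
  if (n_sequences > 1L && rate > 0) {
    aln <- with_seed(seed, {
      for (i in 2:n_sequences) {
        mut <- which(stats::runif(L) < rate)
        if (length(mut) > 0L) {
          aln[i, mut] <- vapply(ref[mut], function(a)
            sample(setdiff(AA_ALPHABET, a), 1L), "")
        }
      }
      aln
    })
  }
  aln
}
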