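#' Centered Gaussian smoothing window
#'
#' Weights for a centered Gaussian moving average of odd window size `k`.
#' Index `i = 0 ... k-1` receives unnormalized weight
#' `exp(-0.5 * (i - mean)^2 / stdev^2)` with `mean = (k-1)/2` and
#' `stdev = (k-1)/4`; weights are normalized to sum to 1. The center residue
#' receives the maximal weight and the window is symmetric. `k = 1` is the
#' degenerate identity window with the single weight 1.
#'
#' @param k Odd positive window size in residues.
#' @return An object of class `gaussian_window`: list with `k`, `mean`,
#'   `stdev`, `weights` (length `k`, summing to 1).
#' @examples
#' gaussian_window(31)$stdev  # 7.5
#' gaussian_window(5)$weights
#' @export
gaussian_window <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1L || k %% 2L == 0L) {
    stop("window size k must be an odd positive integer")
  }
  k <- as.integer(k)
  if (k == 1L) {
    return(structure(list(k = 1L, mean = 0, stdev = 0, weights = 1),
                     class = "gaussian_window"))
  }
  m <- (k - 1) / 2
  s <- (k - 1) / 4
  w <- exp(-0.5 * ((0:(k - 1) - m) / s)^2)
  structure(list(k = k, mean = m, stdev = s, weights = w / sum(w)),
            class = "gaussian_window")
}

#' Gaussian-weighted moving average
#'
#' Smooths a numeric series with a centered [gaussian_window()]. Only full
#' windows are emitted: the output drops `(k-1)/2` values at each edge, so a
#' length-`L` input yields `L - k + 1` values, the `n`-th centered on input
#' position `n + (k-1)/2`.
#'
#' @param series Numeric vector of length `>= k`.
#' @param window A `gaussian_window` (or an odd integer, converted).
#' @return Numeric vector of length `length(series) - k + 1`.
#' @examples
#' moving_average(c(5, 5, 5, 5, 5), gaussian_window(3))  # 5 5 5
#' @export
moving_average <- function(series, window) {
  if (!inherits(window, "gaussian_window")) window <- gaussian_window(window)
  k <- window$k
  L <- length(series)
  if (L < k) stop("series of length ", L, " is shorter than the window (", k, ")")
  if (k == 1L) return(as.numeric(series))
  # weighted convolution; filter() keeps full windows, edges become NA
  out <- stats::filter(as.numeric(series), window$weights, sides = 2)
  half <- (k - 1L) / 2L
  as.numeric(out[(half + 1L):(L - half)])
}

#' Z-score normalization by column
#'
#' Standardizes each column to mean 0 and standard deviation 1 (sample
#' standard deviation, `n - 1` denominator), storing the per-column
#' parameters for reuse on new data.
#'
#' @param columns Numeric matrix (or data frame) with at least 2 rows.
#' @return List with `values` (standardized matrix), `mu` and `sigma`
#'   (named per-column parameters).
#' @examples
#' zscore(cbind(x = c(1, 2, 3)))$values  # -1 0 1
#' @export
zscore <- function(columns) {
  m <- as.matrix(columns)
  mu <- colMeans(m)
  sigma <- apply(m, 2L, stats::sd)
  zero <- sigma == 0 | is.na(sigma)
  if (any(zero)) {
    stop("constant column(s) cannot be Z-scored: ",
         paste(colnames(m)[zero], collapse = ", "))
  }
  values <- sweep(sweep(m, 2L, mu, "-"), 2L, sigma, "/")
  list(values = values, mu = mu, sigma = sigma)
}

#' Build a context-dependent feature matrix for a sequence
#'
#' Looks up the raw per-residue value of every scale, smooths the scales in
#' `table$averaged_ids` (by default the hydrophobicity scales A1-A19) with a
#' centered Gaussian moving average of window size `k`, and keeps the
#' remaining scales (A20-A28) as raw center-residue values. Rows are
#' restricted to positions of the analyzed region where a full window fits
#' (edge trimming): for an analyzed region of length `L` the matrix has
#' `L - k + 1` rows covering positions `start + (k-1)/2` to
#' `end - (k-1)/2`. Optionally Z-scores every column over the retained rows
#' (the normalization the classifiers expect).
#'
#' @param sequence Protein sequence string.
#' @param table A `scale_table` from [load_scales()].
#' @param k Odd window size (residues).
#' @param analyzed Length-2 integer vector `c(start, end)` delimiting the
#'   contiguous analyzed region (default the full sequence). Smoothing is
#'   computed within this region only, so excluded tails never leak into
#'   analyzed features.
#' @param normalize Z-score the columns (default `TRUE`).
#' @return An object of class `feature_matrix`: list with `positions`
#'   (1-based residue indices), `values` (positions x 28 matrix), `k`,
#'   `averaged_ids`, `normalized`, and `norm` (the Z-score parameters, or
#'   `NULL`).
#' @export
build_feature_matrix <- function(sequence, table, k, analyzed = NULL,
                                 normalize = TRUE) {
  stopifnot(inherits(table, "scale_table"))
  chars <- split_residues(sequence)
  L <- length(chars)
  if (is.null(analyzed)) analyzed <- c(1L, L)
  stopifnot(length(analyzed) == 2L, analyzed[1] >= 1L, analyzed[2] <= L,
            analyzed[1] <= analyzed[2])
  window <- gaussian_window(k)
  region <- analyzed[1]:analyzed[2]
  raw <- table$values[match(chars[region], rownames(table$values)), ,
                      drop = FALSE]
  half <- (window$k - 1L) / 2L
  if (length(region) < window$k) {
    stop("analyzed region shorter than the window")
  }
  positions <- region[(half + 1L):(length(region) - half)]
  ids <- colnames(table$values)
  values <- matrix(NA_real_, nrow = length(positions), ncol = length(ids),
                   dimnames = list(positions, ids))
  for (id in ids) {
    values[, id] <- if (id %in% table$averaged_ids) {
      moving_average(raw[, id], window)
    } else {
      raw[(half + 1L):(length(region) - half), id]
    }
  }
  norm <- NULL
  if (normalize) {
    z <- zscore(values)
    values <- z$values
    norm <- z[c("mu", "sigma")]
  }
  structure(list(positions = positions, values = values, k = window$k,
                 averaged_ids = table$averaged_ids, normalized = normalize,
                 norm = norm),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix: ", nrow(x$values), " positions (",
      min(x$positions), "-", max(x$positions), ") x ", ncol(x$values),
      " features, window ", x$k, " aa",
      if (x$normalized) ", Z-scored" else "", "\n", sep = "")
  invisible(x)
}

#' Write a feature matrix as TSV
#'
#' Emits a `position` column (1-based) plus one column per feature; window
#' size and averaging provenance go into `#`-prefixed header comment lines.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# window_size\t", fm$k),
    paste0("# averaged_ids\t", paste(fm$averaged_ids, collapse = ",")),
    paste0("# normalized\t", fm$normalized)
  ), con)
  df <- data.frame(position = fm$positions, fm$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Feature-feature Pearson correlation matrix
#'
#' @param matrix A `feature_matrix` or a plain numeric matrix with at least
#'   3 rows and no constant columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(matrix) {
  m <- if (inherits(matrix, "feature_matrix")) matrix$values else
    as.matrix(matrix)
  if (nrow(m) < 3L) stop("need at least 3 rows")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  stats::cor(m)
}

#' Mean absolute off-diagonal correlation
#'
#' Single-number summary of inter-feature redundancy: the mean of `|r|` over
#' all off-diagonal pairs. Smoothing only part of the feature set (A1-A19
#' but not A20-A28) lowers this summary as the window grows.
#'
#' @inheritParams correlation_matrix
#' @return A real in `[0, 1]`.
#' @export
average_abs_correlation <- function(matrix) {
  r <- correlation_matrix(matrix)
  mean(abs(r[upper.tri(r)]))
}

#' Greedy correlation filter
#'
#' Passes over features in column order; a feature is dropped when its
#' squared Pearson correlation with any already-retained feature exceeds
#' `r2_threshold`. Deterministic; on ties the earlier feature id wins.
#'
#' @inheritParams correlation_matrix
#' @param r2_threshold Squared-correlation threshold (default 0.95).
#' @return Character vector of retained feature ids.
#' @export
correlation_filter <- function(matrix, r2_threshold = 0.95) {
  r <- correlation_matrix(matrix)
  ids <- colnames(r)
  keep <- character(0)
  for (id in ids) {
    if (length(keep) == 0L || all(r[id, keep]^2 <= r2_threshold)) {
      keep <- c(keep, id)
    }
  }
  keep
}
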