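#' Leakage-aware train/test split over the analyzed positions
#'
#' The held-out test set is the first `block_size` and the last
#' `block_size` analyzed positions that survive edge trimming at window
#' size `k` (for the DnaK map the first block lies in U1 and the second in
#' S4, giving one pure-U and one pure-S block). Because a moving-average
#' window of size `k` mixes information across up to `k - 1` neighboring
#' residues, every training position must lie at distance greater than
#' `k - 1` from both test blocks; positions inside that guard zone are
#' discarded. This removes train/test information leakage through the
#' smoothing window.
#'
#' @param map A `substructure_map`.
#' @param k Odd window size used for the features.
#' @param block_size Test positions per class block (default 40).
#' @return An object of class `train_test_split`: list with
#'   `test_positions` (U block then S block), `train_positions`, `k`,
#'   `guard` (`k - 1`), and `test_classes`.
#' @examples
#' sp <- make_split(default_dnak_map(), k = 1)
#' range(sp$test_positions)  # 1 .. 603
#' @export
make_split <- function(map, k, block_size = 40L) {
  stopifnot(inherits(map, "substructure_map"))
  window <- gaussian_window(k)
  half <- (window$k - 1L) / 2L
  pos <- analyzed_positions(map)
  if (any(diff(pos) != 1L)) {
    stop("analyzed region must be contiguous for splitting")
  }
  trimmed <- pos[(half + 1L):(length(pos) - half)]
  if (length(trimmed) < 2L * block_size + 2L * window$k) {
    stop("analyzed region too short for two test blocks plus guards")
  }
  test_u <- trimmed[seq_len(block_size)]
  test_s <- trimmed[(length(trimmed) - block_size + 1L):length(trimmed)]
  cls <- residue_classes(map)
  if (length(unique(cls[test_u])) != 1L ||
      length(unique(cls[test_s])) != 1L ||
      cls[test_u[1]] == cls[test_s[1]]) {
    stop("test blocks are not class-pure U then S")
  }
  guard <- window$k - 1L
  test <- c(test_u, test_s)
  train <- trimmed[!trimmed %in% test]
  keep <- vapply(train, function(p) min(abs(p - test)) > guard, TRUE)
  train <- train[keep]
  structure(list(test_positions = test, train_positions = train,
                 k = window$k, guard = guard,
                 test_classes = cls[test]),
            class = "train_test_split")
}

#' @export
print.train_test_split <- function(x, ...) {
  cat("Train/test split: ", length(x$train_positions), " train, 2 x ",
      length(x$test_positions) / 2, " test positions, guard distance ",
      x$guard, "\n", sep = "")
  invisible(x)
}

# Fit on the training rows of `fm` and return accuracy on the test rows.
split_accuracy <- function(spec, fm, labels, split, feature_ids) {
  idx_tr <- match(split$train_positions, fm$positions)
  idx_te <- match(split$test_positions, fm$positions)
  if (anyNA(idx_tr) || anyNA(idx_te)) {
    stop("split positions missing from the feature matrix")
  }
  x <- fm$values[, feature_ids, drop = FALSE]
  fit <- train_model(spec, x[idx_tr, , drop = FALSE], labels[idx_tr])
  pred <- predict(fit, x[idx_te, , drop = FALSE])
  mean(pred == labels[idx_te])
}

#' Greedy forward feature selection
#'
#' Starts from the empty feature set; at each step every unused candidate
#' is tried and the one maximizing accuracy on the held-out test blocks is
#' added (ties resolved toward the earlier candidate id). The full
#' trajectory is recorded and the best subset is the prefix with maximal
#' accuracy.
#'
#' @param spec A [model_spec()].
#' @param split A [make_split()] result.
#' @param fm A `feature_matrix` covering all split positions.
#' @param labels Class label per row of `fm`.
#' @param candidates Feature ids to consider (default all columns, e.g.
#'   after [correlation_filter()]).
#' @return List with `trajectory` (data frame `step`, `feature`,
#'   `accuracy`), `best_features` (character vector) and `best_accuracy`.
#' @export
forward_feature_selection <- function(spec, split, fm, labels,
                                      candidates = colnames(fm$values)) {
  stopifnot(length(candidates) >= 1L)
  selected <- character(0)
  remaining <- candidates
  trajectory <- data.frame(step = integer(0), feature = character(0),
                           accuracy = numeric(0))
  while (length(remaining) > 0L) {
    accs <- vapply(remaining, function(f) {
      split_accuracy(spec, fm, labels, split, c(selected, f))
    }, numeric(1))
    best <- which.max(accs)   # first maximum = earliest candidate id
    selected <- c(selected, remaining[best])
    trajectory <- rbind(trajectory, data.frame(
      step = length(selected), feature = remaining[best],
      accuracy = accs[best]))
    remaining <- remaining[-best]
  }
  best_step <- which.max(trajectory$accuracy)
  list(trajectory = trajectory,
       best_features = trajectory$feature[seq_len(best_step)],
       best_accuracy = trajectory$accuracy[best_step])
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every combination of the supplied grid axes on the held-out
#' test blocks and returns the best specification. Combinations are
#' enumerated with the first axis varying fastest ([expand.grid()] order);
#' ties keep the earliest combination.
#'
#' @param kind Model kind (`"LR"`, `"RF"`, `"SVM"`).
#' @param grid Named list of hyperparameter vectors (axes).
#' @param split A [make_split()] result.
#' @param fm A `feature_matrix`.
#' @param labels Class label per row of `fm`.
#' @param feature_ids Features to train on (default all).
#' @param seed Seed passed to each [model_spec()].
#' @return List with `best_spec`, `best_accuracy`, and `results` (one row
#'   per combination, in evaluation order).
#' @export
grid_optimize <- function(kind, grid, split, fm, labels,
                          feature_ids = colnames(fm$values), seed = 1L) {
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    stop("empty hyperparameter grid")
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  accs <- vapply(seq_len(nrow(combos)), function(i) {
    spec <- do.call(model_spec,
                    c(list(kind = kind, seed = seed), as.list(combos[i, ,
                      drop = FALSE])))
    split_accuracy(spec, fm, labels, split, feature_ids)
  }, numeric(1))
  best <- which.max(accs)
  best_spec <- do.call(model_spec,
                       c(list(kind = kind, seed = seed),
                         as.list(combos[best, , drop = FALSE])))
  list(best_spec = best_spec, best_accuracy = accs[best],
       results = cbind(combos, accuracy = accs))
}
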