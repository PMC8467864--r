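#' Classification metrics from predictions or a confusion matrix
#'
#' Builds the 2x2 confusion matrix (rows = true U/S, columns = predicted
#' U/S) and derives accuracy, Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' marginals, and per-class recall, precision and F-measure (harmonic mean
#' of the class's precision and recall).
#'
#' @param truth True class labels, or a 2x2 confusion matrix (rows = true
#'   U/S, columns = predicted U/S) if `predicted` is missing.
#' @param predicted Predicted class labels.
#' @param positions Optional residue positions for the per-residue table.
#' @return An object of class `eval_report`: list with `confusion`,
#'   `accuracy`, `cohens_kappa`, `per_class` (data frame of recall,
#'   precision, f_measure for U and S), `n`, and optionally `per_residue`
#'   (data frame `position`, `true`, `predicted`, `correct`).
#' @examples
#' evaluate(matrix(c(34, 0, 6, 40), 2,
#'          dimnames = list(c("U", "S"), c("U", "S"))))$accuracy  # 0.925
#' @export
evaluate <- function(truth, predicted = NULL, positions = NULL) {
  per_residue <- NULL
  if (is.null(predicted)) {
    confusion <- as.matrix(truth)
    stopifnot(nrow(confusion) == 2L, ncol(confusion) == 2L,
              all(confusion >= 0))
    dimnames(confusion) <- list(true = c("U", "S"),
                                predicted = c("U", "S"))
  } else {
    t <- as_class_factor(truth)
    p <- as_class_factor(predicted)
    stopifnot(length(t) == length(p), !anyNA(t), !anyNA(p))
    confusion <- table(true = t, predicted = p)
    confusion <- unclass(confusion)
    if (!is.null(positions)) {
      per_residue <- data.frame(position = positions,
                                true = as.character(t),
                                predicted = as.character(p),
                                correct = t == p)
    }
  }
  n <- sum(confusion)
  if (n < 1L) stop("need at least one prediction")
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  per_class <- do.call(rbind, lapply(c("U", "S"), function(cl) {
    tp <- confusion[cl, cl]
    recall <- if (sum(confusion[cl, ]) > 0) tp / sum(confusion[cl, ]) else NA
    precision <- if (sum(confusion[, cl]) > 0) tp / sum(confusion[, cl]) else
      NA
    f <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0) {
      2 * precision * recall / (precision + recall)
    } else NA
    data.frame(class = cl, recall = recall, precision = precision,
               f_measure = f)
  }))
  structure(list(confusion = confusion, accuracy = po,
                 cohens_kappa = kappa, per_class = per_class, n = n,
                 per_residue = per_residue),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("Evaluation of", x$n, "predictions\n")
  print(x$confusion)
  cat("accuracy ", round(x$accuracy, digits), ", Cohen's kappa ",
      round(x$cohens_kappa, digits), "\n", sep = "")
  print(x$per_class, row.names = FALSE, digits = digits)
  invisible(x)
}

# Stratified fold assignment giving per-class sizes that differ by at most
# one; the U remainder is assigned to the first folds and the S remainder
# to the last, which balances total fold sizes (573 positions -> 57-58).
stratified_folds <- function(labels, folds, seed) {
  y <- as_class_factor(labels)
  fold_of <- integer(length(y))
  counts <- function(total, r_front) {
    base <- total %/% folds
    extra <- total %% folds
    sizes <- rep(base, folds)
    if (extra > 0L) {
      idx <- if (r_front) seq_len(extra) else (folds - extra + 1L):folds
      sizes[idx] <- sizes[idx] + 1L
    }
    sizes
  }
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      sizes <- counts(length(idx), r_front = cl == "U")
      fold_of[idx] <- rep(seq_len(folds), times = sizes)
    }
  })
  fold_of
}

#' Stratified k-fold cross-validation
#'
#' Randomly partitions the positions into `folds` class-stratified folds
#' (per-class fold sizes differ by at most one; the assignment convention
#' balances total fold sizes), trains on each complement and evaluates on
#' the fold. The pooled report sums the fold confusion matrices. Note that
#' consecutive positions share smoothing windows, so random-fold CV does
#' not enforce the window guard of [make_split()]; interpret accordingly.
#'
#' @param spec A [model_spec()].
#' @param fm A `feature_matrix`.
#' @param labels Class label per row of `fm`.
#' @param folds Number of folds (default 10); each class must have at
#'   least `folds` members.
#' @param seed Seed for the random partition.
#' @param feature_ids Features to train on (default all columns).
#' @return List with `fold_reports` (list of `eval_report`), `pooled`
#'   (`eval_report` over the summed confusion, plus the per-residue table),
#'   `fold_sizes`, `fold_error_sd` (standard deviation of fold error
#'   rates) and `fold_of` (fold id per position).
#' @export
cross_validate <- function(spec, fm, labels, folds = 10L, seed = 1L,
                           feature_ids = colnames(fm$values)) {
  y <- as_class_factor(labels)
  if (min(table(y)) < folds) stop("each class needs at least ", folds,
                                  " positions")
  fold_of <- stratified_folds(y, folds, seed)
  x <- fm$values[, feature_ids, drop = FALSE]
  fold_reports <- vector("list", folds)
  per_residue <- NULL
  for (f in seq_len(folds)) {
    te <- fold_of == f
    fit <- train_model(spec, x[!te, , drop = FALSE], y[!te])
    pred <- predict(fit, x[te, , drop = FALSE])
    fold_reports[[f]] <- evaluate(y[te], pred,
                                  positions = fm$positions[te])
    per_residue <- rbind(per_residue, fold_reports[[f]]$per_residue)
  }
  pooled_conf <- Reduce(`+`, lapply(fold_reports, `[[`, "confusion"))
  pooled <- evaluate(pooled_conf)
  per_residue <- per_residue[order(per_residue$position), ]
  rownames(per_residue) <- NULL
  pooled$per_residue <- per_residue
  err <- vapply(fold_reports, function(r) 1 - r$accuracy, numeric(1))
  list(fold_reports = fold_reports, pooled = pooled,
       fold_sizes = as.integer(table(fold_of)),
       fold_error_sd = stats::sd(err), fold_of = fold_of)
}

#' Summarize misclassified residues by class, domain and border distance
#'
#' Tabulates prediction errors against the substructure map: error counts
#' and percentages per mechanical class and per protein domain (NBD/SBD),
#' and the distribution of distances to the nearest opposite-class residue
#' among errors versus correct positions. Misclassifications concentrate at
#' the S/U borders, where the smoothing window averages over both classes.
#'
#' @param per_residue Data frame with `position`, `true`, `predicted`
#'   columns (e.g. `cross_validate()$pooled$per_residue`).
#' @param map The `substructure_map` the positions refer to.
#' @param nbd_end Last NBD residue for the domain split (default 392).
#' @return List with `per_residue` (input plus `border_distance`, `domain`,
#'   `correct`), `by_class`, `by_domain` (data frames of error counts, % of
#'   errors, % of class/domain positions) and `border` (median border
#'   distance of errors and of correct positions).
#' @export
misclassification_report <- function(per_residue, map, nbd_end = 392L) {
  stopifnot(all(c("position", "true", "predicted") %in% names(per_residue)))
  pr <- per_residue
  pr$correct <- pr$true == pr$predicted
  pr$border_distance <- border_distance(map, pr$position)
  pr$domain <- domain_of(pr$position, nbd_end)
  errors <- pr[!pr$correct, , drop = FALSE]
  n_err <- nrow(errors)
  tab <- function(group) {
    lv <- sort(unique(pr[[group]]))
    data.frame(
      group = lv,
      errors = vapply(lv, function(g) sum(errors[[group]] == g), 0L),
      pct_of_errors = vapply(lv, function(g)
        if (n_err == 0L) 0 else 100 * sum(errors[[group]] == g) / n_err,
        numeric(1)),
      pct_of_positions = vapply(lv, function(g)
        100 * sum(errors[[group]] == g) / sum(pr[[group]] == g),
        numeric(1)),
      row.names = NULL
    )
  }
  by_class <- tab("true")
  names(by_class)[1] <- "class"
  by_domain <- tab("domain")
  names(by_domain)[1] <- "domain"
  border <- data.frame(
    set = c("errors", "correct"),
    median_border_distance = c(
      if (n_err > 0L) stats::median(errors$border_distance) else NA_real_,
      stats::median(pr$border_distance[pr$correct]))
  )
  list(per_residue = pr, by_class = by_class, by_domain = by_domain,
       border = border)
}
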