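#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names = record ids with
#'   descriptions preserved).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (anyDuplicated(names(set))) stop("duplicate sequence ids in ", path)
  stats::setNames(as.character(set), names(set))
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  writeLines(paste0(">", names(sequences), "\n", unname(sequences)), path)
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' Collects everything a classification run needs. All residue coordinates
#' are 1-based inclusive; every stochastic step takes its seed from
#' `seed`.
#'
#' @param sequence Protein sequence string.
#' @param map A `substructure_map` for the sequence.
#' @param window_size Odd moving-average window size (default 31).
#' @param block_size Test positions per class block (default 40).
#' @param model_kind `"LR"`, `"RF"` or `"SVM"` (default `"LR"`).
#' @param folds Cross-validation folds (default 10).
#' @param seed Master seed (default 1).
#' @param r2_threshold Correlation-filter threshold (default 0.95).
#' @param select_features Run forward feature selection (default `TRUE`).
#' @param scales A `scale_table` (default the packaged scales).
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(sequence, map, window_size = 31L, block_size = 40L,
                       model_kind = "LR", folds = 10L, seed = 1L,
                       r2_threshold = 0.95, select_features = TRUE,
                       scales = load_scales()) {
  stopifnot(inherits(map, "substructure_map"),
            nchar(sequence) == map$sequence_length)
  structure(list(sequence = sequence, map = map,
                 window_size = as.integer(window_size),
                 block_size = as.integer(block_size),
                 model_kind = model_kind, folds = as.integer(folds),
                 seed = as.integer(seed), r2_threshold = r2_threshold,
                 select_features = isTRUE(select_features),
                 scales = scales),
            class = "run_config")
}

config_hash <- function(config) {
  semantic <- config[c("sequence", "window_size", "block_size",
                       "model_kind", "folds", "seed", "r2_threshold",
                       "select_features")]
  semantic$map <- config$map$segments
  semantic$scales <- config$scales$values
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(semantic, auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full classification pipeline
#'
#' Builds the context-dependent feature matrix for the configured window,
#' applies the correlation filter, forms the leakage-guarded train/test
#' split, optionally runs forward feature selection, trains and evaluates
#' the configured model on the held-out blocks, cross-validates over all
#' analyzed positions, and summarizes misclassifications. If `out_dir` is
#' given, writes the feature matrix, selection trajectory, per-residue
#' predictions, metric tables and a machine-readable JSON summary (stamped
#' with a configuration hash and the seed); reruns with the same config
#' reproduce identical TSV outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List with `features` (the `feature_matrix`), `retained`
#'   (features surviving the correlation filter), `split`, `selection`
#'   (or `NULL`), `holdout` (`eval_report` on the test blocks), `cv`
#'   (cross-validation result), `misclassification`, `summary` (named
#'   list of headline numbers) and `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  map <- config$map
  pos <- analyzed_positions(map)
  fm <- build_feature_matrix(config$sequence, config$scales,
                             config$window_size,
                             analyzed = range(pos), normalize = TRUE)
  labels <- residue_classes(map)[fm$positions]
  retained <- correlation_filter(fm, config$r2_threshold)
  split <- make_split(map, config$window_size, config$block_size)
  spec <- model_spec(config$model_kind, seed = config$seed)

  selection <- NULL
  feature_ids <- retained
  if (config$select_features) {
    selection <- forward_feature_selection(spec, split, fm, labels,
                                           candidates = retained)
    feature_ids <- selection$best_features
  }
  idx_tr <- match(split$train_positions, fm$positions)
  idx_te <- match(split$test_positions, fm$positions)
  x <- fm$values[, feature_ids, drop = FALSE]
  fit <- train_model(spec, x[idx_tr, , drop = FALSE], labels[idx_tr])
  pred <- predict(fit, x[idx_te, , drop = FALSE])
  holdout <- evaluate(labels[idx_te], pred,
                      positions = split$test_positions)
  cv <- cross_validate(spec, fm, labels, folds = config$folds,
                       seed = config$seed, feature_ids = feature_ids)
  mis <- misclassification_report(cv$pooled$per_residue, map)
  summary <- list(
    window_size = config$window_size,
    n_analyzed = length(pos),
    n_features_retained = length(retained),
    n_features_selected = length(feature_ids),
    holdout_accuracy = holdout$accuracy,
    holdout_kappa = holdout$cohens_kappa,
    cv_accuracy = cv$pooled$accuracy,
    cv_kappa = cv$pooled$cohens_kappa,
    cv_fold_error_sd = cv$fold_error_sd,
    seed = config$seed
  )
  hash <- config_hash(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_matrix(fm, file.path(out_dir, "features.tsv"))
    if (!is.null(selection)) {
      utils::write.table(selection$trajectory,
                         file.path(out_dir, "selection.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(mis$per_residue,
                       file.path(out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(cv$pooled$confusion),
                       file.path(out_dir, "cv_confusion.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(c(summary, config_hash = hash),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(features = fm, retained = retained, split = split,
       selection = selection, holdout = holdout, cv = cv,
       misclassification = mis, summary = summary, config_hash = hash)
}
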