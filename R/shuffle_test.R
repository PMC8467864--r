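#' Shuffled-scale negative control for a trained classification setup
#'
#' Validation experiment for a sequence/map/window configuration: features
#' are forward-selected and evaluated with the real amino-acid scales, then
#' the values of every scale are randomly permuted among amino acids
#' ([shuffle_scales()]), the features are rebuilt, and a model restricted
#' to the same selected feature subset is retrained and evaluated on the
#' identical leakage-guarded split. Because selection was tuned to the real
#' chemistry, a genuine physico-chemical signal shows up as an accuracy
#' drop under shuffling.
#'
#' @param sequence Protein sequence string.
#' @param map The `substructure_map` for the sequence.
#' @param table A `scale_table` (default packaged scales).
#' @param k Window size (default 31).
#' @param spec Model specification (default ridge logistic regression).
#' @param shuffle_seed Seed for the permutation.
#' @param block_size Test positions per class block (default 40).
#' @param r2_threshold Correlation-filter threshold (default 0.95).
#' @return List with `real_accuracy`, `shuffled_accuracy`,
#'   `selected_features`, and the forward-selection `trajectory`.
#' @export
shuffle_test <- function(sequence, map, table = load_scales(), k = 31L,
                         spec = model_spec("LR"), shuffle_seed = 1L,
                         block_size = 40L, r2_threshold = 0.95) {
  split <- make_split(map, k, block_size)
  region <- range(analyzed_positions(map))
  fm <- build_feature_matrix(sequence, table, k, analyzed = region)
  labels <- residue_classes(map)[fm$positions]
  ffs <- forward_feature_selection(spec, split, fm, labels,
                                   candidates = correlation_filter(fm,
                                                                   r2_threshold))
  shuffled <- shuffle_scales(table, shuffle_seed)
  fm_s <- build_feature_matrix(sequence, shuffled, k, analyzed = region)
  shuf_acc <- split_accuracy(spec, fm_s, labels, split,
                             ffs$best_features)
  list(real_accuracy = ffs$best_accuracy, shuffled_accuracy = shuf_acc,
       selected_features = ffs$best_features,
       trajectory = ffs$trajectory)
}
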