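# Shared fixtures, built in code at test time.

# A toy scale table with a single 2-valued scale, for permutation checks.
toy_two_value_table <- function() {
  values <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1,
                   dimnames = list(AA_ALPHABET, "A1"))
  structure(list(values = values,
                 info = data.frame(id = "A1", name = "toy", citation = "toy"),
                 averaged_ids = "A1"),
            class = "scale_table")
}

# Two well-separated Gaussian blobs in `p` dimensions with labels U/S.
make_blobs <- function(n_per_class = 50, p = 2, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * p), ncol = p),
             matrix(stats::rnorm(n_per_class * p, mean = sep), ncol = p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, labels = rep(c("U", "S"), each = n_per_class))
}

# A short alternating layout long enough for window-31 splits.
small_layout <- function() {
  data.frame(class = c("U", "S"), length = c(120L, 120L))
}

# Convenience: synthetic sequence + feature matrix + labels + split.
synthetic_case <- function(delta, seed, k = 31, table = load_scales()) {
  g <- generate_labeled_sequence(synthetic_spec(delta = delta, seed = seed))
  fm <- build_feature_matrix(g$sequence, table, k)
  list(g = g, fm = fm,
       labels = residue_classes(g$map)[fm$positions],
       split = make_split(g$map, k))
}

holdout_accuracy <- function(case, spec = model_spec("LR"),
                             feature_ids = NULL) {
  if (is.null(feature_ids)) feature_ids <- correlation_filter(case$fm)
  idx_tr <- match(case$split$train_positions, case$fm$positions)
  idx_te <- match(case$split$test_positions, case$fm$positions)
  x <- case$fm$values[, feature_ids, drop = FALSE]
  fit <- train_model(spec, x[idx_tr, , drop = FALSE], case$labels[idx_tr])
  mean(predict(fit, x[idx_te, , drop = FALSE]) == case$labels[idx_te])
}
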