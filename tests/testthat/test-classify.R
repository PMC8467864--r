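test_that("splits take end blocks and guard the training set", {
  map <- default_dnak_map()
  s1 <- make_split(map, 1)
  expect_identical(s1$test_positions, c(1:40, 564:603))
  expect_identical(s1$train_positions, 41:563)
  expect_identical(unname(s1$test_classes), rep(c("U", "S"), each = 40))

  s31 <- make_split(map, 31)
  expect_identical(s31$test_positions, c(16:55, 549:588))
  expect_identical(s31$guard, 30L)
  for (p in s31$train_positions) {
    expect_gt(min(abs(p - s31$test_positions)), s31$guard)
  }
  expect_length(intersect(s31$train_positions, s31$test_positions), 0)

  # class-impure blocks are rejected
  tiny <- substructure_map(
    data.frame(segment = c("U1", "S1"), class = c("U", "S"),
               start = c(1L, 21L), end = c(20L, 200L)),
    NULL, 200L)
  expect_error(make_split(tiny, 1, block_size = 40), "class-pure")
})

test_that("feature recomputation after mutating test residues leaves guarded training features unchanged", {
  tab <- load_scales()
  g <- generate_labeled_sequence(synthetic_spec(delta = 0.5, seed = 21))
  k <- 31
  split <- make_split(g$map, k)
  fm <- build_feature_matrix(g$sequence, tab, k, normalize = FALSE)
  chars <- strsplit(g$sequence, "")[[1]]
  set.seed(22)
  chars[split$test_positions] <- sample(AA_ALPHABET,
                                        length(split$test_positions),
                                        replace = TRUE)
  fm2 <- build_feature_matrix(paste(chars, collapse = ""), tab, k,
                              normalize = FALSE)
  idx <- match(split$train_positions, fm$positions)
  expect_equal(fm$values[idx, ], fm2$values[idx, ], tolerance = 1e-12)
})

test_that("the three model kinds learn separable data deterministically", {
  b <- make_blobs(n_per_class = 50, p = 5, sep = 8, seed = 14)
  for (kind in c("LR", "RF", "SVM")) {
    spec <- model_spec(kind, seed = 3)
    fit <- train_model(spec, b$x, b$labels)
    pred <- predict(fit, b$x)
    expect_equal(mean(pred == b$labels), 1,
                 info = paste(kind, "training accuracy"))
    fit2 <- train_model(spec, b$x, b$labels)
    expect_identical(predict(fit2, b$x), pred)
  }
  expect_error(train_model(model_spec("LR"), b$x, rep("S", nrow(b$x))),
               "single class")
})

test_that("label-independent features give chance-level test accuracy", {
  set.seed(15)
  x <- matrix(rnorm(400 * 5), ncol = 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  labels <- rep(c("U", "S"), 200)
  tr <- 1:200; te <- 201:400
  fit <- train_model(model_spec("LR"), x[tr, ], labels[tr])
  acc <- mean(predict(fit, x[te, ]) == labels[te])
  expect_gt(acc, 0.4)
  expect_lt(acc, 0.6)
})

test_that("forward selection finds a planted perfect feature first", {
  g <- generate_labeled_sequence(synthetic_spec(delta = 0.3, seed = 16))
  map <- g$map
  split <- make_split(map, 1)
  pos <- analyzed_positions(map)
  cls <- residue_classes(map)[pos]
  set.seed(17)
  x <- matrix(rnorm(length(pos) * 9), ncol = 9,
              dimnames = list(pos, paste0("noise", 1:9)))
  x <- cbind(x, signal = ifelse(cls == "S", 1, -1) + rnorm(length(pos), sd = .1))
  fm <- structure(list(positions = pos, values = x, k = 1L,
                       averaged_ids = character(0), normalized = TRUE),
                  class = "feature_matrix")
  ffs <- forward_feature_selection(model_spec("LR"), split, fm, cls)
  expect_identical(ffs$trajectory$feature[1], "signal")
  expect_identical(nrow(ffs$trajectory), 10L)
  expect_equal(ffs$best_accuracy, max(ffs$trajectory$accuracy))
  expect_identical(ffs$best_features,
                   ffs$trajectory$feature[seq_len(which.max(
                     ffs$trajectory$accuracy))])
})

test_that("grid optimization is exhaustive with deterministic ties", {
  case <- synthetic_case(delta = 0.6, seed = 18, k = 15)
  feats <- correlation_filter(case$fm)

  single <- grid_optimize("LR", list(lambda = 0.01), case$split, case$fm,
                          case$labels, feature_ids = feats)
  expect_equal(single$best_spec$params$lambda, 0.01)
  expect_identical(nrow(single$results), 1L)

  grid <- list(power = c(1, 2), bias = c(0, 1), gamma = c(0.1, 1))
  res <- grid_optimize("SVM", grid, case$split, case$fm, case$labels,
                       feature_ids = feats)
  expect_identical(nrow(res$results), 8L)      # product of axis sizes
  expect_equal(res$best_accuracy, max(res$results$accuracy))
  first_best <- which.max(res$results$accuracy)
  expect_equal(res$best_spec$params$power, res$results$power[first_best])

  expect_error(grid_optimize("LR", list(), case$split, case$fm,
                             case$labels), "empty")
})
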