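test_that("Gaussian windows follow the mean/stdev/weight definition", {
  w31 <- gaussian_window(31)
  expect_equal(w31$stdev, 7.5)
  expect_equal(w31$mean, 15)
  expect_equal(sum(w31$weights), 1, tolerance = 1e-12)

  expect_identical(gaussian_window(1)$weights, 1)

  w5 <- gaussian_window(5)
  raw <- exp(-0.5 * ((0:4 - 2) / 1)^2)   # e^-2, e^-.5, 1, e^-.5, e^-2
  expect_equal(w5$weights, raw / sum(raw), tolerance = 1e-12)

  # symmetric, center-peaked
  for (k in c(3L, 15L, 31L)) {
    w <- gaussian_window(k)$weights
    expect_equal(w, rev(w), tolerance = 1e-12)
    expect_identical(which.max(w), (k + 1L) %/% 2L)
  }
  expect_error(gaussian_window(4), "odd")
  expect_error(gaussian_window(0), "odd")
})

test_that("moving average matches a naive weighted-sum oracle", {
  expect_equal(moving_average(rep(5, 5), gaussian_window(3)), rep(5, 3))
  set.seed(3)
  x <- rnorm(50)
  expect_identical(moving_average(x, gaussian_window(1)), x)
  w <- gaussian_window(7)
  oracle <- vapply(4:47, function(n)
    sum(w$weights * x[(n - 3):(n + 3)]), numeric(1))
  expect_equal(moving_average(x, w), oracle, tolerance = 1e-10)
  expect_error(moving_average(x[1:5], w), "shorter")
})

test_that("moving average commutes with affine maps and only smooths", {
  set.seed(4)
  x <- rnorm(80)
  for (k in c(3, 15, 31)) {
    w <- gaussian_window(k)
    expect_equal(moving_average(2.5 * x - 1, w),
                 2.5 * moving_average(x, w) - 1, tolerance = 1e-10)
  }
  vars <- vapply(c(1, 3, 15, 31), function(k)
    var(moving_average(x, gaussian_window(k))), numeric(1))
  expect_true(all(diff(vars) <= 1e-12))
})

test_that("Z-scoring standardizes columns with the sample sd", {
  z <- zscore(cbind(a = c(1, 2, 3)))
  expect_equal(unname(z$values[, 1]), c(-1, 0, 1))
  expect_equal(unname(z$mu), 2)
  # idempotent on already-standardized data
  z2 <- zscore(z$values)
  expect_equal(z2$values, z$values, tolerance = 1e-12)
  expect_error(zscore(cbind(ok = 1:5, flat = rep(2, 5))), "flat")
})

test_that("feature matrices trim edges and only smooth A1-A19", {
  tab <- load_scales()
  set.seed(5)
  seq <- paste(sample(AA_ALPHABET, 638, replace = TRUE), collapse = "")

  fm1 <- build_feature_matrix(seq, tab, 1, analyzed = c(1, 603),
                              normalize = FALSE)
  chars <- strsplit(seq, "")[[1]][1:603]
  expect_equal(unname(fm1$values),
               unname(tab$values[match(chars, AA_ALPHABET), ]))

  fm31 <- build_feature_matrix(seq, tab, 31, analyzed = c(1, 603))
  expect_identical(nrow(fm31$values), 573L)
  expect_identical(range(fm31$positions), c(16L, 588L))
  expect_true(all(abs(colMeans(fm31$values)) < 1e-9))
  expect_true(all(abs(apply(fm31$values, 2, sd) - 1) < 1e-9))

  # A20-A28 keep raw center-residue values (before normalization)
  fm31r <- build_feature_matrix(seq, tab, 31, analyzed = c(1, 603),
                                normalize = FALSE)
  expect_equal(unname(fm31r$values[, "A22"]),
               unname(tab$values[match(chars[16:588], AA_ALPHABET), "A22"]))
  # ... while averaged columns differ from the raw lookup
  expect_gt(max(abs(fm31r$values[, "A1"] -
                    tab$values[match(chars[16:588], AA_ALPHABET), "A1"])), 0.1)

  expect_error(build_feature_matrix(strrep("A", 100), tab, 15),
               "constant")
})

test_that("correlations match the textbook formula and drive the filter", {
  set.seed(6)
  m <- matrix(rnorm(500), ncol = 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  r <- correlation_matrix(m)
  # direct covariance-formula oracle
  oracle <- outer(1:5, 1:5, Vectorize(function(i, j) {
    xi <- m[, i] - mean(m[, i]); xj <- m[, j] - mean(m[, j])
    sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }))
  expect_equal(unname(r), oracle, tolerance = 1e-12)
  expect_equal(unname(diag(r)), rep(1, 5))

  dup <- cbind(a = m[, 1], b = m[, 1], c = -m[, 1], d = m[, 2])
  rd <- correlation_matrix(dup)
  expect_equal(rd["a", "b"], 1)
  expect_equal(rd["a", "c"], -1)
  expect_identical(correlation_filter(dup), c("a", "d"))
  expect_identical(correlation_filter(m), colnames(m))

  # chain A~B~C all above threshold: only A kept
  base <- rnorm(200)
  chain <- cbind(A = base, B = base + rnorm(200, sd = 0.01),
                 C = base + rnorm(200, sd = 0.01))
  expect_identical(correlation_filter(chain, 0.95), "A")
})

test_that("smoothing part of the features lowers their overall correlation", {
  tab <- load_scales()
  g <- generate_labeled_sequence(synthetic_spec(delta = 0.4, seed = 2))
  r1 <- average_abs_correlation(build_feature_matrix(g$sequence, tab, 1))
  r31 <- average_abs_correlation(build_feature_matrix(g$sequence, tab, 31))
  expect_lt(r31, r1)
})
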