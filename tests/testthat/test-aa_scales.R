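test_that("packaged scale table loads with 28 validated scales", {
  tab <- load_scales()
  expect_s3_class(tab, "scale_table")
  expect_identical(colnames(tab$values), paste0("A", 1:28))
  expect_identical(rownames(tab$values), AA_ALPHABET)
  expect_false(anyNA(tab$values))
  expect_identical(tab$info$name[tab$info$id == "A1"], "Hydropathicity")
  expect_identical(tab$info$name[tab$info$id == "A20"],
                   "Average flexibility index")
  expect_identical(tab$averaged_ids, paste0("A", 1:19))
  expect_false("A20" %in% tab$averaged_ids)
  # no constant scale, so Z-scoring is defined everywhere
  expect_true(all(apply(tab$values, 2, function(v) length(unique(v))) >= 2))
})

test_that("malformed scale tables are rejected with informative errors", {
  tab <- load_scales()
  tsv <- tempfile(fileext = ".tsv")
  meta <- system.file("extdata", "aa_scales_meta.json", package = "seqstab")

  df <- data.frame(aa = rownames(tab$values), tab$values, check.names = FALSE)
  utils::write.table(df[, -2], tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)                    # 27 scales
  expect_error(load_scales(tsv, meta), "A1")

  utils::write.table(df[-1, ], tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)                    # missing Ala
  expect_error(load_scales(tsv, meta), "A")

  df2 <- df
  df2$A3[2] <- "not-a-number"
  utils::write.table(df2, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_scales(tsv, meta), "A3")
})

test_that("scale tables round-trip through the TSV + JSON format", {
  tab <- load_scales()
  tsv <- file.path(tempdir(), "scales_rt.tsv")
  write_scales(tab, tsv)
  back <- load_scales(tsv, file.path(tempdir(), "aa_scales_meta.json"))
  expect_identical(back$values, tab$values)
  expect_identical(back$info, tab$info)
})

test_that("one-hot encoding has indicator rows and counts residues", {
  m <- one_hot_encode("A")
  expect_identical(as.integer(m[1, ]),
                   as.integer(AA_ALPHABET == "A"))
  m2 <- one_hot_encode("AC")
  expect_identical(rowSums(m2), c(`1` = 1, `2` = 1))

  set.seed(11)
  seq <- paste(sample(AA_ALPHABET, 200, replace = TRUE), collapse = "")
  enc <- one_hot_encode(seq)
  expect_true(all(rowSums(enc) == 1))
  # column sums equal direct letter counts
  counts <- vapply(AA_ALPHABET, function(a)
    lengths(regmatches(seq, gregexpr(a, seq, fixed = TRUE))), 1L)
  expect_identical(as.integer(colSums(enc)), unname(counts))
  # invertible back to the sequence
  expect_identical(one_hot_decode(enc), seq)

  expect_error(one_hot_encode("ACXQ"), "position 3")
})

test_that("shuffling permutes each scale in place, reproducibly", {
  tab <- load_scales()
  s1 <- shuffle_scales(tab, 7)
  s2 <- shuffle_scales(tab, 7)
  expect_identical(s1$values, s2$values)
  for (id in colnames(tab$values)) {
    expect_identical(sort(unname(s1$values[, id])),
                     sort(unname(tab$values[, id])))
  }
  # means/sds preserved exactly, no cross-scale exchange
  expect_equal(colMeans(s1$values), colMeans(tab$values), tolerance = 0)
  expect_equal(apply(s1$values, 2, sd), apply(tab$values, 2, sd),
               tolerance = 0)
  expect_false(identical(s1$values, tab$values))
})

test_that("both orderings of a 2-valued scale occur across seeds", {
  toy <- toy_two_value_table()
  first_vals <- vapply(1:100, function(s)
    shuffle_scales(toy, s)$values[1, 1], numeric(1))
  expect_setequal(unique(first_vals), c(0, 1))
})
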