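test_that("Wu-Kabat variability follows N*k/n with gaps ignored", {
  expect_equal(wu_kabat(rep("A", 205)), 1)
  expect_equal(wu_kabat(c("A", "A", "C", "G")), 6)      # 4 * 3 / 2
  expect_equal(wu_kabat(AA_ALPHABET), 400)              # 20 * 20 / 1
  # gaps drop out of k and n but not N
  expect_equal(wu_kabat(c("A", "A", "-", "-")), 4 * 1 / 2)
  expect_error(wu_kabat(c("-", "-")), "all-gap")
  # gap-as-symbol variant
  expect_equal(wu_kabat(c("A", "A", "-", "-"), gap_as_symbol = TRUE),
               4 * 2 / 2)
})

test_that("Wu-Kabat matches a brute-force counter on random columns", {
  set.seed(23)
  for (i in 1:200) {
    col <- sample(c(AA_ALPHABET, "-"), sample(3:40, 1), replace = TRUE)
    if (all(col == "-")) next
    obs <- col[col != "-"]
    oracle <- length(col) * length(unique(obs)) /
      max(table(factor(obs, levels = unique(obs))))
    expect_equal(wu_kabat(col), oracle)
  }
})

test_that("mean Wu-Kabat grows with the substitution rate", {
  ref <- generate_labeled_sequence(synthetic_spec(seed = 24))$sequence
  means <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4), function(rate) {
    aln <- generate_msa(ref, 30, rate, seed = 25)
    mean(wu_kabat_profile(aln)$variability)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("conserved positions require invariant ungapped columns", {
  aln <- rbind(s1 = strsplit("ACDEFGHIKL", "")[[1]],
               s2 = strsplit("ACDEFGHIKL", "")[[1]],
               s3 = strsplit("ACWEFGHIKL", "")[[1]],
               s4 = strsplit("ACDEF-HIKL", "")[[1]])
  cons <- conserved_positions(aln, reference = "s1")
  expect_identical(cons, c(1L, 2L, 4L, 5L, 7L, 8L, 9L, 10L))
  # tolerate the gap at column 6 when the cap allows it
  cons_gap <- conserved_positions(aln, reference = "s1",
                                  max_gap_fraction = 0.25)
  expect_true(6L %in% cons_gap)

  ident <- matrix("A", 3, 5,
                  dimnames = list(paste0("s", 1:3), NULL))
  expect_identical(conserved_positions(ident, 1L), 1:5)
  expect_error(conserved_positions(aln, reference = "nope"), "absent")
})

test_that("conserved positions map onto substructure segments", {
  ref <- generate_labeled_sequence(synthetic_spec(seed = 26))
  aln0 <- generate_msa(ref$sequence, 10, rate = 0, seed = 27)
  csr <- csr_per_segment(aln0, ref$map)
  expect_equal(csr$conserved, csr$length)   # rate 0: everything conserved
  expect_equal(csr$csr_per_residue, rep(1, nrow(csr)))
})

test_that("pairwise identity implements the both-gap removal rules", {
  aln <- rbind(a = strsplit("ACDE-", "")[[1]],
               b = strsplit("ACE--", "")[[1]],
               c = strsplit("ACDE-", "")[[1]])
  m <- identity_matrix(aln)
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m["a", "b"], 0.5)     # 4 cols after both-gap removal, 2 match
  expect_equal(m["a", "c"], 1)
  expect_equal(m, t(m))

  disjoint <- rbind(x = c("A", "C"), y = c("D", "E"))
  expect_equal(identity_matrix(disjoint)["x", "y"], 0)
})

test_that("composition profiles recover planted class enrichment", {
  g <- generate_labeled_sequence(synthetic_spec(delta = 0.4, seed = 28))
  aln <- generate_msa(g$sequence, 25, rate = 0.05, seed = 29)
  comp <- composition_profile(aln, g$map)
  ala_u <- comp$mean_pct[comp$class == "U" & comp$aa == "A"]
  ala_s <- comp$mean_pct[comp$class == "S" & comp$aa == "A"]
  thr_u <- comp$mean_pct[comp$class == "U" & comp$aa == "T"]
  thr_s <- comp$mean_pct[comp$class == "S" & comp$aa == "T"]
  expect_gt(ala_u, ala_s)
  expect_gt(thr_s, thr_u)
  for (cl in c("U", "S")) {
    expect_equal(sum(comp$mean_pct[comp$class == cl]), 100,
                 tolerance = 1e-9)
  }

  # single sequence: defined composition, zero variability
  single <- matrix(strsplit(g$sequence, "")[[1]], nrow = 1,
                   dimnames = list("ref", NULL))
  comp1 <- composition_profile(single, g$map)
  expect_true(all(comp1$sd_pct == 0))
})

test_that("alignments round-trip through aligned FASTA", {
  ref <- generate_labeled_sequence(synthetic_spec(seed = 30))$sequence
  aln <- generate_msa(substr(ref, 1, 50), 5, rate = 0.2, seed = 31)
  path <- tempfile(fileext = ".fasta")
  write_alignment(aln, path)
  back <- read_alignment(path)
  expect_identical(unname(back), unname(aln))
  expect_identical(rownames(back), rownames(aln))
})
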