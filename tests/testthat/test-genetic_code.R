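# Codon-level combinatorics of the standard genetic code.

test_that("codon table invariants hold and codon sets match the standard code", {
  code <- codon_table()
  expect_length(code, 64L)
  expect_length(stop_codons(code), 3L)
  expect_setequal(stop_codons(code), c("UAA", "UAG", "UGA"))
  sets <- lapply(aa_symbols(), codons_for, code = code)
  expect_equal(sum(lengths(sets)), 61L)
  expect_setequal(codons_for("K"), c("AAA", "AAG"))
  expect_setequal(codons_for("W"), "UGG")
  expect_setequal(codons_for("L"),
                  c("UUA", "UUG", "CUU", "CUC", "CUA", "CUG"))
  # full agreement with Biostrings' table
  sense <- oracle_sense_codons()
  for (aa in aa_symbols())
    expect_setequal(codons_for(aa), names(sense)[sense == aa])
  expect_error(codons_for("B"), "canonical")
  expect_error(codons_for("*"), "canonical")
})

test_that("codon table accepts a DNA CSV override and validates it", {
  sense <- oracle_sense_codons()
  gc <- Biostrings::getGeneticCode("1")  # DNA codon names, T not U
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(codon = names(gc), symbol = unname(gc)), tmp,
            row.names = FALSE)
  code <- codon_table(tmp)
  expect_s3_class(code, "codon_table")
  expect_setequal(codons_for("W", code), "UGG")
  # a broken table (duplicate codon) is rejected
  bad <- data.frame(codon = c(names(gc)[-1], names(gc)[2]),
                    symbol = unname(gc))
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(codon_table(tmp), "64")
})

test_that("single-point counts match spec examples and enumeration oracle", {
  expect_identical(count_single_point("K", "N"), 4L)
  expect_identical(count_single_point("K", "N", 3), 4L)
  expect_identical(count_single_point("K", "N", 1), 0L)
  expect_identical(count_single_point("W", "M"), 0L)
  expect_identical(count_single_point("L", "F"), 6L)
  expect_identical(count_single_point("L", "F", 1), 2L)
  expect_identical(count_single_point("L", "F", 3), 4L)
  expect_error(count_single_point("K", "K"), "differ")
  for (p in 1:3) {
    S <- mutation_count_matrix(p)
    expect_equal(unname(S), unname(oracle_count_matrix(p)))
  }
})

test_that("counts are symmetric and bounded by capacity at every position", {
  for (p in list(1, 2, 3, "ALL")) {
    S <- mutation_count_matrix(p)
    expect_identical(S, t(S))
    expect_true(all(diag(S) == 0))
    caps <- vapply(aa_symbols(), mutation_capacity, numeric(1), position = p)
    expect_true(all(rowSums(S) <= caps))
  }
})

test_that("capacities and fractions follow M = 9n / 3n", {
  expect_identical(mutation_capacity("K"), 18L)
  expect_identical(mutation_capacity("W"), 9L)
  expect_identical(mutation_capacity("K", 3), 6L)
  expect_equal(mutation_fraction("L", "F"), 6 / 54)
  expect_equal(mutation_fraction("F", "L"), 6 / 18)
  expect_equal(mutation_fraction("W", "M"), 0)
  expect_equal(mutation_fraction("K", "N", 3), 4 / 6)
})

test_that("mutation_pairs flags zero-path pairs and is internally consistent", {
  mp <- mutation_pairs("ALL")
  expect_equal(nrow(mp), 380L)
  expect_equal(mp$fraction, mp$count / mp$capacity)
  expect_identical(mp$has_path, mp$count > 0L)
  wm <- mp[mp$source == "W" & mp$target == "M", ]
  expect_false(wm$has_path)
  # totals conserved across positions: 83 + 88 + 25 unordered pairs counts
  per_pos <- vapply(1:3, function(p) {
    S <- mutation_count_matrix(p)
    sum(S[upper.tri(S)])
  }, numeric(1))
  expect_equal(per_pos, c(83, 88, 25))
})

test_that("background per-pair means are the exact rationals; the literal
           per-aa formula is exposed but differs", {
  expect_equal(background_per_pair_mean(1), 83 / 190)
  expect_equal(background_per_pair_mean(2), 88 / 190)
  expect_equal(background_per_pair_mean(3), 25 / 190)
  expect_equal(background_per_pair_mean("ALL"), 196 / 190)
  expect_equal(round(sapply(1:3, background_per_pair_mean), 2),
               c(0.44, 0.46, 0.13))
  # diagnostic variant: the printed formula's reading, ~0.92 at position 1
  expect_gt(background_per_pair_mean(1, variant = "per_aa"), 0.85)
})

test_that("path-graph expectations are 19 x background mean", {
  expect_equal(path_graph_expectation("ALL"), 19 * 196 / 190)
  expect_equal(path_graph_expectation("ALL"), 19.6)
  expect_equal(path_graph_expectation(2), 8.8)
  expect_equal(path_graph_expectation(3), 2.5)
  expect_equal(path_graph_expectation(1), 8.3)
})
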