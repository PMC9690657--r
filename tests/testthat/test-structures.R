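test_that("rna_seq normalizes case, maps T to U and validates characters", {
  s <- rna_seq("acgt", id = "x")
  expect_equal(s$residues, "ACGU")
  expect_equal(s$n, 4L)
  expect_equal(s$id, "x")
})

test_that("rna_structure rejects malformed pair sets", {
  expect_error(rna_structure(10, pairs_mat(5, 3)), "i must be < j")
  expect_error(rna_structure(10, pairs_mat(1, 11)), "out of range")
  expect_error(rna_structure(10, pairs_mat(c(1, 1), c(6, 8))),
               "more than one pair")
  expect_error(rna_structure(10, pairs_mat(c(2, 3), c(6, 6))),
               "more than one pair")
})

test_that("rna_structure sorts pairs deterministically", {
  y <- rna_structure(12, pairs_mat(c(5, 1), c(10, 7)))
  expect_equal(y$pairs[, "i"], c(i = 1L, i = 5L), ignore_attr = TRUE)
})

test_that("crosses implements the interleaving relation", {
  expect_true(crosses(c(1, 6), c(3, 9)))
  expect_true(crosses(c(3, 9), c(1, 6)))
  expect_false(crosses(c(1, 9), c(3, 6)))   # nested
  expect_false(crosses(c(1, 4), c(5, 9)))   # disjoint
  expect_false(crosses(c(1, 6), c(1, 6)))   # identical
})

test_that("validate_decomposition enforces Eq 9-11", {
  # valid H-type: stem B crosses stem A
  d <- rna_levels(20, list(pairs_mat(c(1, 2), c(10, 9)),
                           pairs_mat(c(5, 6), c(15, 14))))
  expect_equal(nrow(validate_decomposition(d)), 0L)
  # Eq 9 violated: base 10 used on two levels
  d2 <- rna_levels(20, list(pairs_mat(1, 10), pairs_mat(c(5, 10), c(15, 16))))
  expect_true("one-partner" %in% validate_decomposition(d2)$constraint)
  # Eq 10 violated: crossing pairs within one level
  d3 <- rna_levels(20, list(pairs_mat(c(1, 3), c(6, 9))))
  expect_equal(validate_decomposition(d3)$constraint, "within-level-crossing")
  # Eq 11 violated: level-2 pair nested inside every level-1 pair
  d4 <- rna_levels(20, list(pairs_mat(1, 20), pairs_mat(5, 10)))
  expect_equal(validate_decomposition(d4)$constraint, "lower-level-crossing")
})

test_that("merge_levels flattens a decomposition and keeps all pairs", {
  d <- rna_levels(20, list(pairs_mat(c(1, 2), c(10, 9)),
                           pairs_mat(c(5, 6), c(15, 14))))
  y <- merge_levels(d)
  expect_s3_class(y, "rna_structure")
  expect_equal(nrow(y$pairs), 4L)
  expect_setequal(paste(y$pairs[, 1], y$pairs[, 2]),
                  c("1 10", "2 9", "5 15", "6 14"))
})

test_that("assign_levels produces a valid decomposition and round-trips", {
  y <- rna_structure(26, pairs_mat(c(1, 2, 3, 8, 9), c(14, 13, 12, 20, 19)))
  d <- assign_levels(y)
  expect_equal(nrow(validate_decomposition(d)), 0L)
  m <- merge_levels(d)$pairs
  expect_setequal(paste(m[, 1], m[, 2]), paste(y$pairs[, 1], y$pairs[, 2]))
  # a pseudoknot-free structure stays on one level
  y2 <- rna_structure(12, pairs_mat(c(1, 2), c(8, 7)))
  expect_equal(length(assign_levels(y2)$levels), 1L)
})

test_that("enumerate_pk_free_structures counts match the Motzkin-style DP", {
  # with min_sep = 1 the count over n positions is the Motzkin number M(n)
  motzkin <- c(1, 2, 4, 9, 21, 51, 127)  # M(1)..M(7)
  for (n in 1:7)
    expect_length(enumerate_pk_free_structures(n, min_sep = 1L), motzkin[n])
  # all enumerated structures are valid and unique
  st <- enumerate_pk_free_structures(8, min_sep = 4L)
  keys <- vapply(st, function(p) paste(p[, 1], p[, 2], collapse = ";"), "")
  expect_false(anyDuplicated(keys) > 0)
  for (p in st) {
    y <- rna_structure(8, p)  # validates one-partner-per-base
    if (nrow(p) > 0) expect_true(all(p[, 2] - p[, 1] >= 4))
  }
  expect_error(enumerate_pk_free_structures(15), "<= 14")
})
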