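test_that("pair_score and the candidate threshold are consistent", {
  expect_equal(pair_score(0.5, 1), 0)
  expect_equal(pair_score(1, 4), 4)
  expect_equal(pair_score(c(0, 1), 3), c(-1, 3))
  expect_error(pair_score(1.2, 1))
  expect_error(pair_score(0.5, 0))
})

test_that("nussinov_decode matches exhaustive enumeration on random instances", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(5:10, 1)
    gamma <- sample(c(0.5, 1, 4), 1)
    min_sep <- sample(c(1L, 4L), 1)
    P <- random_bpp(n)
    y <- nussinov_decode(P, gamma, min_sep)
    expect_equal(attr(y, "score"), score_structure(P, y, gamma))
    expect_equal(attr(y, "score"), best_pk_free(P, gamma, min_sep))
  }
})

test_that("nussinov_decode respects min_sep and never crosses", {
  set.seed(7)
  P <- random_bpp(20, density = 0.8)
  y <- nussinov_decode(P, gamma = 4, min_sep = 4L)
  p <- y$pairs
  expect_true(all(p[, 2] - p[, 1] >= 4))
  if (nrow(p) > 1)
    for (a in 1:(nrow(p) - 1)) for (b in (a + 1):nrow(p))
      expect_false(crosses(p[a, ], p[b, ]))
})

test_that("nussinov_decode is deterministic and prefers fewer pairs on ties", {
  # exact ties: all probabilities at the threshold give gain 0, so the
  # empty structure is optimal and must be returned
  n <- 10
  P <- matrix(0, n, n)
  P[upper.tri(P)] <- 0.2   # gain with gamma = 4 is exactly 0
  P <- P + t(P)
  y <- nussinov_decode(P, gamma = 4, min_sep = 1L)
  expect_equal(nrow(y$pairs), 0L)
  set.seed(1)
  Q <- random_bpp(15)
  expect_identical(nussinov_decode(Q, 2, 4L)$pairs, nussinov_decode(Q, 2, 4L)$pairs)
})

test_that("augmented decoding with zero deltas reduces to plain decoding", {
  set.seed(11)
  for (rep in 1:20) {
    P <- random_bpp(sample(6:14, 1))
    y_ref <- nussinov_decode(P, 1, 2L)
    y0 <- nussinov_decode(P, 4, 2L)
    ya <- nussinov_decode_augmented(P, 4, y_ref, 0, 0, 2L)
    expect_equal(attr(ya, "score"), attr(y0, "score"), tolerance = 1e-12)
  }
})

test_that("augmented decoding seeks margin violators, not the reference", {
  n <- 10
  # delta_fn penalizes predicting a borderline reference pair: a pair kept
  # by plain decoding is dropped once its gain minus delta_fn goes negative
  P <- matrix(0, n, n); P[1, 8] <- 0.25
  P <- P + t(P)
  ref <- rna_structure(n, pairs_mat(1, 8))
  plain <- nussinov_decode(P, 4, 4L)
  expect_equal(paste(plain$pairs[, 1], plain$pairs[, 2]), "1 8")
  aug <- nussinov_decode_augmented(P, 4, ref, delta_fn = 0.5, delta_fp = 0, min_sep = 4L)
  expect_equal(nrow(aug$pairs), 0L)
  # delta_fp rewards false positives: with an empty reference and an
  # all-zero matrix the violator fills up with would-be false positives
  Z <- matrix(0, n, n)
  aug2 <- nussinov_decode_augmented(Z, 4, rna_structure(n), 0, 5, 4L)
  expect_gt(nrow(aug2$pairs), 0L)
  expect_equal(nrow(nussinov_decode(Z, 4, 4L)$pairs), 0L)
})

test_that("decoders reject malformed probability matrices", {
  expect_error(nussinov_decode(matrix(2, 5, 5), 4, 1L), "lie in")
  expect_error(nussinov_decode(matrix(0.5, 3, 4), 4, 1L))
})
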