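test_that("candidate_pairs applies per-level strict thresholds and min_sep", {
  n <- 12
  P <- matrix(0, n, n)
  P[1, 8] <- 0.5; P[2, 7] <- 0.6; P[3, 12] <- 0.3; P[4, 6] <- 0.9
  P <- P + t(P)
  cand <- candidate_pairs(P, gammas = c(1, 3), min_sep = 4L)
  # level 1: p > 0.5 strictly, so (1,8) at exactly 0.5 is excluded
  expect_setequal(paste(cand[[1]]$i, cand[[1]]$j), "2 7")
  # level 2: p > 0.25, which admits (1,8) at 0.5; (4,6) violates min_sep
  expect_setequal(paste(cand[[2]]$i, cand[[2]]$j), c("1 8", "2 7", "3 12"))
})

test_that("with one level ipknot_decode equals nussinov_decode", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(6:18, 1)
    gamma <- sample(c(1, 4), 1)
    P <- random_bpp(n)
    dp <- nussinov_decode(P, gamma, 4L)
    ip <- ipknot_decode(P, gammas = gamma, min_sep = 4L)
    expect_lt(abs(ip$objective - attr(dp, "score")), 1e-9)
    expect_equal(ip$status, "optimal")
  }
})

test_that("m = 2 branch-and-bound matches the subset-enumeration oracle", {
  set.seed(9)
  done <- 0
  while (done < 12) {
    n <- sample(8:11, 1)
    P <- random_bpp(n, density = 0.4)
    # keep the 3^K oracle tractable
    if (length(candidate_pairs(P, c(1, 3), 2L)[[2]]$i) > 8) next
    sol <- ipknot_decode(P, c(1, 3), min_sep = 2L)
    expect_equal(sol$objective, best_ip_oracle(P, c(1, 3), 2L), tolerance = 1e-9)
    expect_equal(nrow(validate_decomposition(sol$decomposition)), 0L)
    done <- done + 1
  }
})

test_that("the solver recovers a constructed H-type pseudoknot exactly", {
  n <- 30
  P <- matrix(0, n, n)
  stemA <- pairs_mat(1:4, 16 - (1:4))
  stemB <- pairs_mat(5:8, 30 - (0:3))
  P[stemA] <- 0.9; P[stemB] <- 0.9
  P <- P + t(P)
  sol <- ipknot_decode(P, gammas = c(1, 3), min_sep = 4L)
  expect_equal(nrow(validate_decomposition(sol$decomposition)), 0L)
  got <- merge_levels(sol$decomposition)$pairs
  expect_equal(nrow(got), 8L)
  expect_setequal(paste(got[, 1], got[, 2]),
                  c(paste(stemA[, 1], stemA[, 2]), paste(stemB[, 1], stemB[, 2])))
  expect_equal(sol$objective, 4 * (2 * 0.9 - 1) + 4 * (4 * 0.9 - 1),
               tolerance = 1e-12)
})

test_that("every level-2 pair crosses some level-1 pair (Eq 11)", {
  set.seed(21)
  for (rep in 1:10) {
    P <- random_bpp(14, density = 0.6)
    sol <- ipknot_decode(P, c(1, 3), min_sep = 2L)
    l1 <- sol$decomposition$levels[[1]]
    l2 <- sol$decomposition$levels[[2]]
    if (nrow(l2) > 0) {
      expect_gt(nrow(l1), 0)
      for (a in seq_len(nrow(l2)))
        expect_true(any(vapply(seq_len(nrow(l1)),
                               function(b) crosses(l2[a, ], l1[b, ]), TRUE)))
    }
  }
})

test_that("an exhausted node budget returns a feasible incumbent with a warning", {
  set.seed(33)
  P <- random_bpp(20, density = 0.9)
  expect_warning(sol <- ipknot_decode(P, c(1, 3), min_sep = 1L, node_limit = 3),
                 "node limit")
  expect_equal(sol$status, "node_limit")
  expect_equal(nrow(validate_decomposition(sol$decomposition)), 0L)
  full <- ipknot_decode(P, c(1, 3), min_sep = 1L)
  expect_lte(sol$objective, full$objective + 1e-9)
})

test_that("augmented IP decoding with zero deltas matches plain decoding", {
  set.seed(13)
  for (rep in 1:10) {
    P <- random_bpp(sample(8:14, 1), density = 0.5)
    ref <- merge_levels(ipknot_decode(P, c(1, 3), 2L)$decomposition)
    plain <- ipknot_decode(P, c(1, 3), 2L)
    aug <- ipknot_decode_augmented(P, c(1, 3), ref, 0, 0, 2L)
    expect_equal(aug$objective, plain$objective, tolerance = 1e-9)
  }
})
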