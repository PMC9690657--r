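# gradient of sum_ij W_ij p_ij by central finite differences on the
# flattened parameter vector
fd_gradient <- function(model, x, W, eps = 1e-5) {
  flat <- bppnet:::flatten_params(model$params)
  obj <- function(v) {
    m <- model
    m$params <- bppnet:::unflatten_params(v, model$params)
    sum(W * bpp_matrix(m, x))
  }
  g <- numeric(length(flat))
  for (a in seq_along(flat)) {
    up <- flat; up[a] <- up[a] + eps
    dn <- flat; dn[a] <- dn[a] - eps
    g[a] <- (obj(up) - obj(dn)) / (2 * eps)
  }
  g
}

test_that("encode_pair_context one-hot encodes two k-windows with padding", {
  x <- rna_seq("ACGUA")
  F <- encode_pair_context(x, pairs_mat(2, 4), k = 3)
  expect_equal(dim(F), c(1L, 2L * 3L * 5L))
  expect_equal(sum(F), 6)             # every in-range slot is one-hot
  blocks <- matrix(F[1, ], nrow = 5)  # 5 channels x 6 window positions
  expect_equal(colSums(blocks), rep(1, 6))
  # A=1, C=2, G=3, U=4: window at i = 2 reads A C G, at j = 4 reads G U A
  expect_equal(apply(blocks, 2, which.max), c(1, 2, 3, 3, 4, 1))
  # off-sequence slots stay all-zero
  F2 <- encode_pair_context(x, pairs_mat(1, 5), k = 3)
  expect_equal(sum(F2), 4)
  expect_equal(sum(matrix(F2[1, ], nrow = 5)[, c(1, 6)]), 0)
})

test_that("fnn forward produces probabilities strictly inside (0, 1)", {
  m <- fnn_model(k = 5, hidden = c(8, 4), min_sep = 2L, seed = 3)
  x <- rna_seq("GGGAAACCCUUU")
  P <- bpp_matrix(m, x)
  expect_equal(dim(P), c(12L, 12L))
  ij <- bppnet:::candidate_ij(12L, 2L)
  expect_true(all(P[ij] > 0 & P[ij] < 1))
  # entries below min_sep stay at zero
  expect_equal(P[1, 2], 0)
  expect_equal(P[lower.tri(P)], rep(0, sum(lower.tri(P))))
})

test_that("bpp_matrix is independent of batch size", {
  m <- fnn_model(k = 5, hidden = c(8, 4), min_sep = 2L, seed = 3)
  x <- rna_seq(paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = ""))
  P1 <- bpp_matrix(m, x, batch_size = 1L)
  P2 <- bpp_matrix(m, x, batch_size = 4096L)
  expect_equal(P1, P2, tolerance = 1e-14)
})

test_that("fnn analytic gradient matches finite differences", {
  set.seed(8)
  m <- fnn_model(k = 3, hidden = c(4, 3), min_sep = 2L, seed = 8)
  # move parameters off the ReLU kinks left by zero bias initialization
  flat <- bppnet:::flatten_params(m$params)
  m$params <- bppnet:::unflatten_params(flat + rnorm(length(flat), sd = 0.05),
                                        m$params)
  x <- rna_seq("GCAUGGCAU")
  W <- matrix(rnorm(81), 9, 9)
  g <- bppnet:::flatten_params(bppnet:::model_gradient(m, x, W))
  g_fd <- fd_gradient(m, x, W)
  denom <- pmax(abs(g), abs(g_fd), 1e-8)
  expect_lt(max(abs(g - g_fd) / denom), 1e-4)
})

test_that("model initialization is reproducible from its seed", {
  a <- fnn_model(k = 5, hidden = c(8, 4), seed = 7)
  b <- fnn_model(k = 5, hidden = c(8, 4), seed = 7)
  c <- fnn_model(k = 5, hidden = c(8, 4), seed = 8)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
})
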