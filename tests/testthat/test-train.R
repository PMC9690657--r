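test_that("structured_loss counts false negatives and false positives", {
  y <- rna_structure(12, pairs_mat(c(1, 2, 3), c(10, 9, 8)))
  y_hat <- rna_structure(12, pairs_mat(c(1, 4), c(10, 12)))
  # tp = 1, fn = 2, fp = 1
  expect_equal(structured_loss(y, y_hat, 0.1, 0.2), 2 * 0.1 + 1 * 0.2)
  expect_equal(structured_loss(y, y, 0.1, 0.2), 0)
})

test_that("hinge is nonnegative on feasible references and zero deltas tie out", {
  set.seed(15)
  m <- fnn_model(k = 3, hidden = c(6, 4), min_sep = 2L, seed = 15)
  flat <- bppnet:::flatten_params(m$params)
  m$params <- bppnet:::unflatten_params(flat + rnorm(length(flat), sd = 0.3),
                                        m$params)
  for (rep in 1:10) {
    x <- rna_seq(paste(sample(c("A", "C", "G", "U"), 12, TRUE), collapse = ""))
    P <- bpp_matrix(m, x)
    # references decoded from the model's own matrix are feasible points
    ref_n <- nussinov_decode(P, 4, 2L)
    rec_n <- structure_record(x, ref_n)
    h <- example_hinge(m, rec_n, "nussinov", gamma = 4)
    expect_gte(h$hinge, -1e-9)
    # at the decode optimum with zero deltas the hinge is exactly zero
    h0 <- example_hinge(m, rec_n, "nussinov", gamma = 4,
                        delta_fn = 0, delta_fp = 0)
    expect_lt(abs(h0$hinge), 1e-9)
  }
})

test_that("the hinge subgradient has the paper's (gamma + 1)(yhat - y) form", {
  set.seed(16)
  m <- fnn_model(k = 3, hidden = c(6, 4), min_sep = 2L, seed = 16)
  x <- rna_seq("GCGCAUAUGCGC")
  ref <- rna_structure(12, pairs_mat(c(1, 2), c(12, 11)))
  h <- example_hinge(m, structure_record(x, ref), "nussinov", gamma = 4)
  W <- h$W
  expect_true(all(W %in% c(0, 5, -5)))
  expect_equal(W[pairs_mat(c(1, 2), c(12, 11))],
               ifelse(paste(c(1, 2), c(12, 11)) %in%
                        paste(h$y_hat$pairs[, 1], h$y_hat$pairs[, 2]), 0, -5))
})

test_that("ssvm training drives the structured loss down and is seeded", {
  spec <- rna_family_spec(n_stems = 1L, stem_len_range = c(4L, 4L),
                          loop_len_range = c(3L, 3L), pseudoknot_prob = 0,
                          mutation_rate = 0, pair_probs = c(1, 0, 0),
                          n_sequences = 8L, seq_len = 12L, seed = 3L)
  recs <- make_dataset(spec)
  fit1 <- bppnet(recs, model = "fnn", decoder = "nussinov", gamma = 4,
                 k = 5L, hidden = c(16L, 8L), eta = 0.05, epochs = 8L,
                 seed = 1L)
  expect_s3_class(fit1, "bppnet")
  expect_lt(tail(fit1$history$objective, 1), fit1$history$objective[1])
  fit2 <- bppnet(recs, model = "fnn", decoder = "nussinov", gamma = 4,
                 k = 5L, hidden = c(16L, 8L), eta = 0.05, epochs = 8L,
                 seed = 1L)
  expect_identical(coef(fit1), coef(fit2))
  # training reproduces the family on its own training set
  preds <- predict(fit1, recs, type = "structure")
  ev <- evaluate_dataset(preds, recs)
  expect_gt(ev$aggregate$f, 0.9)
})

test_that("iterate averaging changes the final parameters but stays finite", {
  spec <- rna_family_spec(n_stems = 1L, stem_len_range = c(4L, 4L),
                          loop_len_range = c(3L, 3L), pseudoknot_prob = 0,
                          mutation_rate = 0, pair_probs = c(1, 0, 0),
                          n_sequences = 6L, seq_len = 12L, seed = 3L)
  recs <- make_dataset(spec)
  base <- list(model = "fnn", decoder = "nussinov", gamma = 4, k = 5L,
               hidden = c(16L, 8L), eta = 0.05, epochs = 6L, seed = 1L)
  f1 <- do.call(bppnet, c(list(recs), base))
  f2 <- do.call(bppnet, c(list(recs), base, list(average = TRUE)))
  expect_false(identical(coef(f1), coef(f2)))
  expect_true(all(is.finite(coef(f2))))
})

test_that("bppnet returns a complete classed fit with working methods", {
  spec <- rna_family_spec(n_stems = 1L, stem_len_range = c(4L, 4L),
                          loop_len_range = c(3L, 3L), pseudoknot_prob = 0,
                          mutation_rate = 0, pair_probs = c(1, 0, 0),
                          n_sequences = 5L, seq_len = 12L, seed = 4L)
  recs <- make_dataset(spec)
  fit <- bppnet(recs, model = "fnn", decoder = "nussinov", gamma = 4,
                k = 5L, hidden = c(8L, 4L), eta = 0.05, epochs = 2L, seed = 1L)
  expect_output(print(fit), "structured-SVM")
  expect_s3_class(summary(fit), "summary.bppnet")
  expect_true(is.numeric(coef(fit)) && length(coef(fit)) > 100)
  P <- predict(fit, recs[[1]], type = "bpp")
  expect_equal(dim(P), c(12L, 12L))
  y <- predict(fit, recs[[1]], type = "structure")
  expect_s3_class(y, "rna_structure")
  expect_length(fitted(fit), length(recs))
  r <- residuals(fit)
  expect_length(r, length(recs))
  expect_true(is.numeric(r))
})
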