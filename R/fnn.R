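#' Feedforward base-pairing probability model
#'
#' Builds a (randomly initialized) feedforward network that maps the two
#' k-mer contexts around a candidate base pair (i, j) to its pairing
#' probability.  Each window position carries 5 input nodes: a one-hot
#' encoding of the nucleotide (all-zero for unknown residues and for
#' positions outside the sequence) plus an end-of-loop node that is active
#' in the left window for positions l >= j and in the right window for
#' positions l <= i, embedding loop length and helix opening/closing
#' context.  Two ReLU hidden layers feed a single sigmoid output.
#'
#' Weights are drawn uniformly scaled by fan-in; hidden biases start at 0;
#' the output bias starts at -2 so that an untrained model assigns low
#' pairing probability everywhere, reflecting the prior that most base
#' pairs are absent.
#'
#' @param k odd context length (default 81).
#' @param hidden sizes of the two hidden layers (default c(200, 50)).
#' @param min_sep minimum pair span enforced when building probability
#'   matrices (the network itself imposes no constraint).
#' @param seed integer seed for the parameter draw.
#' @return an object of classes `fnn_model`, `bpp_model`.
#' @export
fnn_model <- function(k = 81L, hidden = c(200L, 50L), min_sep = 4L, seed = 1L) {
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) stop("k must be odd and >= 3")
  stopifnot(length(hidden) == 2L, all(hidden >= 1L))
  d <- 2L * k * 5L
  params <- with_seed(seed, list(
    W1 = init_mat(d, hidden[1L]),
    b1 = numeric(hidden[1L]),
    W2 = init_mat(hidden[1L], hidden[2L]),
    b2 = numeric(hidden[2L]),
    w3 = init_mat(hidden[2L], 1L),
    b3 = -2
  ))
  structure(list(type = "fnn",
                 config = list(k = k, hidden = as.integer(hidden),
                               min_sep = as.integer(min_sep), seed = as.integer(seed)),
                 params = params),
            class = c("fnn_model", "bpp_model"))
}

#' @export
print.fnn_model <- function(x, ...) {
  cat(sprintf("Feedforward base-pairing model: k = %d (input %d), hidden %d/%d, %d parameters\n",
              x$config$k, 2L * x$config$k * 5L, x$config$hidden[1L], x$config$hidden[2L],
              length(flatten_params(x$params))))
  invisible(x)
}

#' Encode the two k-mer contexts of candidate pairs
#'
#' @param x an [rna_seq()] (or string).
#' @param ij a two-column matrix of candidate pairs (a single pair may be
#'   given as a length-2 vector).
#' @param k odd context length.
#' @return a numeric matrix with one row per pair and 2 * k * 5 columns:
#'   the k window positions centred at i (5 nodes each), then the k
#'   positions centred at j.
#' @export
encode_pair_context <- function(x, ij, k) {
  x <- as_rna_seq(x)
  if (!is.matrix(ij)) ij <- matrix(as.integer(ij), ncol = 2L)
  if (nrow(ij) > 0L && any(ij[, 1L] >= ij[, 2L])) stop("pairs must satisfy i < j")
  n <- x$n
  code <- match(seq_chars(x), c("A", "C", "G", "U"))  # NA for unknown
  h <- (k - 1L) %/% 2L
  m <- nrow(ij)
  F <- matrix(0, m, 2L * k * 5L)
  if (m == 0L) return(F)
  iv <- ij[, 1L]; jv <- ij[, 2L]
  for (t in seq_len(k)) {
    off <- t - 1L - h
    # left window, centred at i
    lp <- iv + off
    ok <- lp >= 1L & lp <= n
    cc <- code[lp[ok]]
    hasb <- !is.na(cc)
    F[cbind(which(ok)[hasb], (t - 1L) * 5L + cc[hasb])] <- 1
    eol <- ok & lp >= jv
    F[which(eol), (t - 1L) * 5L + 5L] <- 1
    # right window, centred at j
    rp <- jv + off
    ok <- rp >= 1L & rp <= n
    cc <- code[rp[ok]]
    hasb <- !is.na(cc)
    F[cbind(which(ok)[hasb], (k + t - 1L) * 5L + cc[hasb])] <- 1
    eol <- ok & rp <= iv
    F[which(eol), (k + t - 1L) * 5L + 5L] <- 1
  }
  F
}

# forward pass; returns probabilities and, if cache = TRUE, the
# intermediate activations needed for backpropagation
fnn_forward_full <- function(model, F, cache = FALSE) {
  d <- 2L * model$config$k * 5L
  if (!is.matrix(F)) F <- matrix(F, ncol = d)
  if (ncol(F) != d)
    stop(sprintf("feature width %d does not match 2*k*5 = %d", ncol(F), d))
  pr <- model$params
  z1 <- sweep(F %*% pr$W1, 2L, -pr$b1)
  a1 <- relu(z1)
  z2 <- sweep(a1 %*% pr$W2, 2L, -pr$b2)
  a2 <- relu(z2)
  z3 <- drop(a2 %*% pr$w3) + pr$b3
  p <- sigmoid(z3)
  if (!cache) return(p)
  list(p = p, F = F, z1 = z1, a1 = a1, z2 = z2, a2 = a2)
}

#' Forward pass of the feedforward model
#'
#' @param model an [fnn_model()].
#' @param features a feature vector of length 2 * k * 5 (or a matrix with
#'   one row per candidate pair) from [encode_pair_context()].
#' @return pairing probabilities, strictly inside (0, 1).
#' @export
fnn_forward <- function(model, features) {
  stopifnot(inherits(model, "fnn_model"))
  fnn_forward_full(model, features, cache = FALSE)
}

#' @rdname bpp_matrix
#' @param batch_size evaluate candidate pairs in chunks of this many rows
#'   (memory control; the result is independent of batching).
#' @export
bpp_matrix.fnn_model <- function(model, x, batch_size = 4096L, ...) {
  x <- as_rna_seq(x)
  n <- x$n
  P <- matrix(0, n, n)
  ij <- candidate_ij(n, model$config$min_sep)
  if (nrow(ij) == 0L) return(P)
  for (s in seq.int(1L, nrow(ij), by = batch_size)) {
    e <- min(s + batch_size - 1L, nrow(ij))
    blk <- ij[s:e, , drop = FALSE]
    P[blk] <- fnn_forward_full(model, encode_pair_context(x, blk, model$config$k))
  }
  P
}

# backprop of sum_r w_r p_r given cached activations; returns a gradient
# list shaped like model$params
fnn_backward <- function(model, cache, w) {
  pr <- model$params
  p <- cache$p
  dz3 <- w * p * (1 - p)
  g_w3 <- crossprod(cache$a2, dz3)
  g_b3 <- sum(dz3)
  da2 <- tcrossprod(dz3, drop(pr$w3))   # m x h2 outer product
  dz2 <- da2 * (cache$z2 > 0)
  g_W2 <- crossprod(cache$a1, dz2)
  g_b2 <- colSums(dz2)
  da1 <- dz2 %*% t(pr$W2)
  dz1 <- da1 * (cache$z1 > 0)
  g_W1 <- crossprod(cache$F, dz1)
  g_b1 <- colSums(dz1)
  list(W1 = g_W1, b1 = g_b1, W2 = g_W2, b2 = g_b2, w3 = g_w3, b3 = g_b3)
}

#' @export
model_gradient.fnn_model <- function(model, x, W, features = NULL, ij = NULL, ...) {
  x <- as_rna_seq(x)
  if (is.null(ij)) ij <- candidate_ij(x$n, model$config$min_sep)
  if (nrow(ij) == 0L)
    return(rapply(model$params, function(a) a * 0, how = "replace"))
  if (is.null(features)) features <- encode_pair_context(x, ij, model$config$k)
  w <- W[ij]
  cache <- fnn_forward_full(model, features, cache = TRUE)
  fnn_backward(model, cache, w)
}
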