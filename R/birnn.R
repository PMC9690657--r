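#' Bidirectional recursive base-pairing probability model
#'
#' A neural analogue of the inside-outside algorithm over the simple RNA
#' grammar S -> aS'a | aS | Sa | SS | empty.  Each span (i, j) of the
#' sequence carries an inside hidden state computed bottom-up from the
#' grammar's productions and an outside state computed top-down from the
#' enclosing contexts; ReLU is applied to each source state before it
#' enters a recursive transition, and the pairing probability of (i, j)
#' combines the inside state of the enclosed span (i+1, j-1), the outside
#' state of (i, j) and the one-hot encodings of the two bases through a
#' sigmoid head.  No normalization over derivations is computed: the
#' states are learned representations, not span probabilities.
#'
#' The recursion costs O(n^3) hidden-vector operations, so sequences
#' longer than `max_len` are refused.
#'
#' @param hidden hidden state width (default 80).
#' @param min_sep minimum pair span for probability matrices.
#' @param max_len refuse sequences longer than this (default 200).
#' @param seed integer seed for the parameter draw.
#' @return an object of classes `birnn_model`, `bpp_model`.
#' @export
birnn_model <- function(hidden = 80L, min_sep = 4L, max_len = 200L, seed = 1L) {
  h <- as.integer(hidden)
  stopifnot(h >= 1L)
  w <- function(nin) matrix(stats::runif(h * nin, -1 / sqrt(nin), 1 / sqrt(nin)), h, nin)
  params <- with_seed(seed, list(
    # inside: state(i,j) from pair / aS / Sa / SS-split sources
    c_in = stats::runif(h, -1 / sqrt(h), 1 / sqrt(h)),  # empty-span state
    b_in = numeric(h),
    A_p = w(h), E_p = w(8L),
    A_l = w(h), E_l = w(4L),
    A_r = w(h), E_r = w(4L),
    B_L = w(h), B_R = w(h),
    # outside: state(i,j) from enclosing pair / aS / Sa / SS contexts
    c_out = stats::runif(h, -1 / sqrt(h), 1 / sqrt(h)), # root-span state
    b_out = numeric(h),
    P_p = w(h), F_p = w(8L),
    P_l = w(h), F_l = w(4L),
    P_r = w(h), F_r = w(4L),
    QL_o = w(h), QL_i = w(h),
    QR_o = w(h), QR_i = w(h),
    # sigmoid output head
    u_in = stats::runif(h, -1 / sqrt(h), 1 / sqrt(h)),
    u_out = stats::runif(h, -1 / sqrt(h), 1 / sqrt(h)),
    u_e = stats::runif(8L, -1 / sqrt(8), 1 / sqrt(8)),
    b_head = -2
  ))
  structure(list(type = "birnn",
                 config = list(hidden = h, min_sep = as.integer(min_sep),
                               max_len = as.integer(max_len), seed = as.integer(seed)),
                 params = params),
            class = c("birnn_model", "bpp_model"))
}

#' @export
print.birnn_model <- function(x, ...) {
  cat(sprintf("Recursive (inside-outside) base-pairing model: hidden = %d, %d parameters\n",
              x$config$hidden, length(flatten_params(x$params))))
  invisible(x)
}

# 4-dim one-hot per base (all-zero for unknown), as columns of a 4 x n matrix
onehot_cols <- function(x) {
  code <- match(seq_chars(x), c("A", "C", "G", "U"))
  E <- matrix(0, 4L, x$n)
  ok <- !is.na(code)
  E[cbind(code[ok], which(ok))] <- 1
  E
}

#' Inside pass of the recursive model
#'
#' @param model a [birnn_model()].
#' @param x an [rna_seq()] (or string) no longer than the model's `max_len`.
#' @return an `n x n x hidden` array `I` with `I[i, j, ]` the (pre-ReLU)
#'   inside state of span i..j for i <= j; attribute `spans` counts the
#'   spans computed (each exactly once).
#' @export
inside_pass <- function(model, x) {
  stopifnot(inherits(model, "birnn_model"))
  x <- as_rna_seq(x)
  n <- x$n
  if (n > model$config$max_len)
    stop(sprintf("sequence length %d exceeds the model's max_len %d", n, model$config$max_len))
  pr <- model$params
  h <- model$config$hidden
  E <- onehot_cols(x)
  I <- array(0, dim = c(n, n, h))
  rc <- relu(pr$c_in)
  spans <- 0L
  getI <- function(i, j) if (i > j) rc else relu(I[i, j, ])
  for (len in 1:n) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      v <- pr$b_in +
        pr$A_l %*% getI(i + 1L, j) + pr$E_l %*% E[, i] +
        pr$A_r %*% getI(i, j - 1L) + pr$E_r %*% E[, j]
      if (len >= 2L)
        v <- v + pr$A_p %*% getI(i + 1L, j - 1L) + pr$E_p %*% c(E[, i], E[, j])
      if (len >= 2L)
        for (c in i:(j - 1L))
          v <- v + pr$B_L %*% getI(i, c) + pr$B_R %*% getI(c + 1L, j)
      I[i, j, ] <- v
      spans <- spans + 1L
    }
  }
  attr(I, "spans") <- spans
  I
}

#' Outside pass of the recursive model
#'
#' @inheritParams inside_pass
#' @param inside the array returned by [inside_pass()].
#' @return an `n x n x hidden` array of (pre-ReLU) outside states; the
#'   root span state equals the learned constant `c_out`.
#' @export
outside_pass <- function(model, x, inside) {
  stopifnot(inherits(model, "birnn_model"))
  x <- as_rna_seq(x)
  n <- x$n
  pr <- model$params
  h <- model$config$hidden
  E <- onehot_cols(x)
  O <- array(0, dim = c(n, n, h))
  O[1L, n, ] <- pr$c_out
  spans <- 1L
  if (n >= 2L) {
    for (len in (n - 1L):1L) {
      for (i in seq_len(n - len + 1L)) {
        j <- i + len - 1L
        v <- pr$b_out
        if (i >= 2L && j <= n - 1L)
          v <- v + pr$P_p %*% relu(O[i - 1L, j + 1L, ]) + pr$F_p %*% c(E[, i - 1L], E[, j + 1L])
        if (i >= 2L)
          v <- v + pr$P_l %*% relu(O[i - 1L, j, ]) + pr$F_l %*% E[, i - 1L]
        if (j <= n - 1L)
          v <- v + pr$P_r %*% relu(O[i, j + 1L, ]) + pr$F_r %*% E[, j + 1L]
        if (j + 1L <= n)
          for (jp in (j + 1L):n)
            v <- v + pr$QL_o %*% relu(O[i, jp, ]) + pr$QL_i %*% relu(inside[j + 1L, jp, ])
        if (i - 1L >= 1L)
          for (ip in 1L:(i - 1L))
            v <- v + pr$QR_o %*% relu(O[ip, j, ]) + pr$QR_i %*% relu(inside[ip, i - 1L, ])
        O[i, j, ] <- v
        spans <- spans + 1L
      }
    }
  }
  attr(O, "spans") <- spans
  O
}

# head pre-activation for candidate pairs; inner empty spans use c_in
birnn_heads <- function(model, x, ij, I, O) {
  pr <- model$params
  E <- onehot_cols(x)
  rc <- relu(pr$c_in)
  z <- vapply(seq_len(nrow(ij)), function(a) {
    i <- ij[a, 1L]; j <- ij[a, 2L]
    inner <- if (i + 1L > j - 1L) rc else relu(I[i + 1L, j - 1L, ])
    sum(pr$u_in * inner) + sum(pr$u_out * relu(O[i, j, ])) +
      sum(pr$u_e * c(E[, i], E[, j])) + pr$b_head
  }, numeric(1))
  z
}

#' @rdname bpp_matrix
#' @export
bpp_matrix.birnn_model <- function(model, x, ...) {
  x <- as_rna_seq(x)
  n <- x$n
  P <- matrix(0, n, n)
  ij <- candidate_ij(n, model$config$min_sep)
  if (nrow(ij) == 0L) return(P)
  I <- inside_pass(model, x)
  O <- outside_pass(model, x, I)
  P[ij] <- sigmoid(birnn_heads(model, x, ij, I, O))
  P
}

#' @export
model_gradient.birnn_model <- function(model, x, W, ...) {
  x <- as_rna_seq(x)
  n <- x$n
  pr <- model$params
  h <- model$config$hidden
  ij <- candidate_ij(n, model$config$min_sep)
  g <- rapply(pr, function(a) a * 0, how = "replace")
  if (nrow(ij) == 0L) return(g)
  E <- onehot_cols(x)
  I <- inside_pass(model, x)
  O <- outside_pass(model, x, I)
  z <- birnn_heads(model, x, ij, I, O)
  p <- sigmoid(z)
  w <- W[ij]
  dz <- w * p * (1 - p)

  dI <- array(0, dim = c(n, n, h))
  dO <- array(0, dim = c(n, n, h))
  dc_in <- numeric(h)
  rc <- relu(pr$c_in)
  mc <- as.numeric(pr$c_in > 0)

  # --- head ---
  for (a in seq_len(nrow(ij))) {
    i <- ij[a, 1L]; j <- ij[a, 2L]
    d <- dz[a]
    if (i + 1L > j - 1L) {
      g$u_in <- g$u_in + d * rc
      dc_in <- dc_in + d * pr$u_in * mc
    } else {
      s <- I[i + 1L, j - 1L, ]
      g$u_in <- g$u_in + d * relu(s)
      dI[i + 1L, j - 1L, ] <- dI[i + 1L, j - 1L, ] + d * pr$u_in * (s > 0)
    }
    s <- O[i, j, ]
    g$u_out <- g$u_out + d * relu(s)
    dO[i, j, ] <- dO[i, j, ] + d * pr$u_out * (s > 0)
    g$u_e <- g$u_e + d * c(E[, i], E[, j])
    g$b_head <- g$b_head + d
  }

  # helper: propagate adjoint `d` through transition `Wt %*% relu(src)`
  # where src is the raw state vector; returns relu-masked back signal
  back <- function(Wt, d, src) (crossprod(Wt, d)) * (src > 0)

  # --- outside backward: spans by increasing length (reverse of forward) ---
  if (n >= 2L) {
    for (len in 1L:(n - 1L)) {
      for (i in seq_len(n - len + 1L)) {
        j <- i + len - 1L
        d <- dO[i, j, ]
        if (all(d == 0)) next
        g$b_out <- g$b_out + d
        if (i >= 2L && j <= n - 1L) {
          s <- O[i - 1L, j + 1L, ]
          g$P_p <- g$P_p + tcrossprod(d, relu(s))
          g$F_p <- g$F_p + tcrossprod(d, c(E[, i - 1L], E[, j + 1L]))
          dO[i - 1L, j + 1L, ] <- dO[i - 1L, j + 1L, ] + back(pr$P_p, d, s)
        }
        if (i >= 2L) {
          s <- O[i - 1L, j, ]
          g$P_l <- g$P_l + tcrossprod(d, relu(s))
          g$F_l <- g$F_l + tcrossprod(d, E[, i - 1L])
          dO[i - 1L, j, ] <- dO[i - 1L, j, ] + back(pr$P_l, d, s)
        }
        if (j <= n - 1L) {
          s <- O[i, j + 1L, ]
          g$P_r <- g$P_r + tcrossprod(d, relu(s))
          g$F_r <- g$F_r + tcrossprod(d, E[, j + 1L])
          dO[i, j + 1L, ] <- dO[i, j + 1L, ] + back(pr$P_r, d, s)
        }
        if (j + 1L <= n) {
          for (jp in (j + 1L):n) {
            s <- O[i, jp, ]
            g$QL_o <- g$QL_o + tcrossprod(d, relu(s))
            dO[i, jp, ] <- dO[i, jp, ] + back(pr$QL_o, d, s)
            s <- I[j + 1L, jp, ]
            g$QL_i <- g$QL_i + tcrossprod(d, relu(s))
            dI[j + 1L, jp, ] <- dI[j + 1L, jp, ] + back(pr$QL_i, d, s)
          }
        }
        if (i - 1L >= 1L) {
          for (ip in 1L:(i - 1L)) {
            s <- O[ip, j, ]
            g$QR_o <- g$QR_o + tcrossprod(d, relu(s))
            dO[ip, j, ] <- dO[ip, j, ] + back(pr$QR_o, d, s)
            s <- I[ip, i - 1L, ]
            g$QR_i <- g$QR_i + tcrossprod(d, relu(s))
            dI[ip, i - 1L, ] <- dI[ip, i - 1L, ] + back(pr$QR_i, d, s)
          }
        }
      }
    }
  }
  # root span adjoint flows into the learned constant c_out
  g$c_out <- g$c_out + dO[1L, n, ]

  # --- inside backward: spans by decreasing length ---
  accI <- function(i, j, v) {
    if (i > j) dc_in <<- dc_in + v * mc
    else dI[i, j, ] <<- dI[i, j, ] + v * (I[i, j, ] > 0)
  }
  gsrc <- function(i, j) if (i > j) rc else relu(I[i, j, ])
  for (len in n:1L) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      d <- dI[i, j, ]
      if (all(d == 0)) next
      g$b_in <- g$b_in + d
      g$A_l <- g$A_l + tcrossprod(d, gsrc(i + 1L, j))
      g$E_l <- g$E_l + tcrossprod(d, E[, i])
      accI(i + 1L, j, crossprod(pr$A_l, d))
      g$A_r <- g$A_r + tcrossprod(d, gsrc(i, j - 1L))
      g$E_r <- g$E_r + tcrossprod(d, E[, j])
      accI(i, j - 1L, crossprod(pr$A_r, d))
      if (len >= 2L) {
        g$A_p <- g$A_p + tcrossprod(d, gsrc(i + 1L, j - 1L))
        g$E_p <- g$E_p + tcrossprod(d, c(E[, i], E[, j]))
        accI(i + 1L, j - 1L, crossprod(pr$A_p, d))
        for (c in i:(j - 1L)) {
          g$B_L <- g$B_L + tcrossprod(d, gsrc(i, c))
          accI(i, c, crossprod(pr$B_L, d))
          g$B_R <- g$B_R + tcrossprod(d, gsrc(c + 1L, j))
          accI(c + 1L, j, crossprod(pr$B_R, d))
        }
      }
    }
  }
  g$c_in <- g$c_in + dc_in
  g
}
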