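#' Expected-gain score of a single base pair
#'
#' Under the maximum-expected-accuracy (gamma-centroid) criterion a pair
#' with pairing probability p contributes (gamma + 1) p - 1 to the
#' expected gain, which is positive exactly when p exceeds the threshold
#' theta = 1 / (gamma + 1).
#'
#' @param p base-pairing probability (or vector of them) in \[0, 1\].
#' @param gamma positive base-pair weight; larger gamma favours
#'   sensitivity over precision.
#' @return numeric vector of per-pair gains.
#' @export
pair_score <- function(p, gamma) {
  stopifnot(all(gamma > 0), all(p >= 0 & p <= 1))
  (gamma + 1) * p - 1
}

#' Expected-gain score of a structure
#'
#' Sums [pair_score()] over all pairs of `y` against a base-pairing
#' probability matrix.
#'
#' @param P an n x n base-pairing probability matrix (upper triangle used).
#' @param y an [rna_structure()] with `y$n == nrow(P)`.
#' @param gamma positive base-pair weight.
#' @return a single number; 0 for the empty structure.
#' @export
score_structure <- function(P, y, gamma) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P), inherits(y, "rna_structure"),
            y$n == nrow(P))
  if (nrow(y$pairs) == 0L) return(0)
  sum(pair_score(P[y$pairs], gamma))
}

# gain matrix with non-candidates (j - i < min_sep) left at -Inf
gain_matrix <- function(P, gamma, min_sep) {
  n <- nrow(P)
  S <- matrix(-Inf, n, n)
  if (n >= min_sep + 1L) {
    ut <- which(upper.tri(S) & (col(S) - row(S) >= min_sep))
    S[ut] <- (gamma + 1) * P[ut] - 1
  }
  S
}

check_bpp <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  ut <- P[upper.tri(P)]
  if (any(ut < 0 | ut > 1 | is.na(ut)))
    stop("base-pairing probabilities must lie in [0, 1]")
  invisible(P)
}

#' Decode the pseudoknot-free MEA structure by dynamic programming
#'
#' Finds the non-crossing structure maximizing the expected gain
#' sum over pairs of ((gamma + 1) p_ij - 1) by a Nussinov-style recursion
#' with deterministic tie-breaking (unpaired-left, unpaired-right, pair,
#' bifurcation; ties resolve toward fewer pairs, so a pair of non-positive
#' gain is never reported).
#'
#' @inheritParams score_structure
#' @param gamma positive base-pair weight (default 4; the classic
#'   gamma-centroid grid is 2^n for n in -5..10).
#' @param min_sep minimum pair span: pairs require j - i >= min_sep
#'   (default 4, i.e. at least 3 unpaired bases in a hairpin loop).
#' @return an [rna_structure()] with attribute `score` (the DP optimum,
#'   equal to [score_structure()] of the result).
#' @export
nussinov_decode <- function(P, gamma = 4, min_sep = 4L) {
  check_bpp(P); stopifnot(gamma > 0)
  S <- gain_matrix(P, gamma, min_sep)
  res <- .nussinov_cpp(S, as.integer(min_sep))
  out <- rna_structure(nrow(P), res$pairs)
  attr(out, "score") <- res$score
  out
}

#' Loss-augmented Nussinov decoding
#'
#' Maximizes f(x, y-hat) + Delta(y_ref, y-hat) over non-crossing
#' structures, where Delta is the false-negative/false-positive loss of
#' structured-SVM training.  Up to the constant delta_fn * |y_ref| this is
#' the plain DP with per-pair gain shifted by -delta_fn on reference pairs
#' and +delta_fp elsewhere; with delta_fn = delta_fp = 0 it reduces
#' exactly to [nussinov_decode()].
#'
#' @inheritParams nussinov_decode
#' @param y_ref the reference [rna_structure()].
#' @param delta_fn,delta_fp nonnegative loss weights for false-negative
#'   and false-positive base pairs.
#' @return an [rna_structure()] with attributes `score` (plain expected
#'   gain of the result) and `aug_score` (the DP optimum of the augmented
#'   objective, without the constant term).
#' @export
nussinov_decode_augmented <- function(P, gamma = 4, y_ref, delta_fn = 0.1,
                                      delta_fp = 0.1, min_sep = 4L) {
  check_bpp(P)
  stopifnot(inherits(y_ref, "rna_structure"), y_ref$n == nrow(P),
            gamma > 0, delta_fn >= 0, delta_fp >= 0)
  S <- gain_matrix(P, gamma, min_sep)
  fin <- is.finite(S)
  S[fin] <- S[fin] + delta_fp
  if (nrow(y_ref$pairs) > 0L)
    S[y_ref$pairs] <- S[y_ref$pairs] - delta_fp - delta_fn
  res <- .nussinov_cpp(S, as.integer(min_sep))
  out <- rna_structure(nrow(P), res$pairs)
  attr(out, "score") <- score_structure(P, out, gamma)
  attr(out, "aug_score") <- res$score
  out
}
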