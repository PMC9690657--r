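#' Per-level candidate base pairs for IP decoding
#'
#' Level p of the hierarchical decoder only considers pairs whose pairing
#' probability strictly exceeds the level threshold
#' theta(p) = 1 / (gamma(p) + 1) (a pair at or below the threshold has
#' non-positive gain and can never be part of an optimal solution).
#'
#' @param P an n x n base-pairing probability matrix.
#' @param gammas vector of positive per-level weights (level 1 first).
#' @param min_sep minimum pair span.
#' @return a list with one data frame per level (columns `i`, `j`, `p`).
#' @export
candidate_pairs <- function(P, gammas = c(1, 3), min_sep = 4L) {
  check_bpp(P)
  stopifnot(all(gammas > 0))
  n <- nrow(P)
  ut <- which(upper.tri(P) & (col(P) - row(P) >= min_sep))
  ii <- row(P)[ut]; jj <- col(P)[ut]; pp <- P[ut]
  lapply(gammas, function(g) {
    keep <- pp > 1 / (g + 1)
    data.frame(i = ii[keep], j = jj[keep], p = pp[keep])
  })
}

ip_solution <- function(n, levels, objective, status, nodes) {
  structure(list(decomposition = rna_levels(n, levels), objective = objective,
                 status = status, nodes = nodes),
            class = "ip_solution")
}

#' @export
print.ip_solution <- function(x, ...) {
  cat(sprintf("IP decoding solution (%s): objective %.6g, %d pair(s) in %d level(s)\n",
              x$status, x$objective,
              sum(vapply(x$decomposition$levels, nrow, 1L)),
              length(x$decomposition$levels)))
  invisible(x)
}

ipknot_solve <- function(n, cand, scores, min_sep, node_limit) {
  res <- .ipknot_bb_cpp(n,
                        lapply(cand, function(d) as.integer(d$i)),
                        lapply(cand, function(d) as.integer(d$j)),
                        scores,
                        as.integer(min_sep), as.numeric(node_limit))
  if (!identical(res$status, "optimal"))
    warning(sprintf(paste0("IP branch-and-bound stopped at its node limit ",
                           "(%g nodes); returning the best feasible solution ",
                           "found (not proven optimal)"), node_limit))
  ip_solution(n, res$levels, res$objective, res$status, res$nodes)
}

#' Decode a pseudoknotted structure as a hierarchical integer program
#'
#' Maximizes the per-level expected gain
#' sum_p sum_\{i<j\} ((gamma(p) + 1) p_ij - 1) y^(p)_ij subject to one
#' partner per base across levels, no crossing within a level, and every
#' level-p pair crossing at least one selected pair at every lower level.
#' The program is solved exactly by a specialized branch-and-bound
#' algorithm (levels below the last are branched on; the last level is a
#' plain non-crossing matching solved by dynamic programming; bounds come
#' from per-level DP relaxations).  With a single level the result is
#' equivalent to [nussinov_decode()].
#'
#' @inheritParams candidate_pairs
#' @param node_limit stop branching after this many branch-and-bound nodes
#'   and return the best feasible solution found so far (with a warning and
#'   `status = "node_limit"`); within the limit the solution is exact and
#'   `status = "optimal"`.
#' @return an object of class `ip_solution`: a list with `decomposition`
#'   (an [rna_levels()] that always passes [validate_decomposition()]),
#'   `objective`, `status` and `nodes`.
#' @export
ipknot_decode <- function(P, gammas = c(1, 3), min_sep = 4L, node_limit = 5e5) {
  cand <- candidate_pairs(P, gammas, min_sep)
  scores <- mapply(function(d, g) pair_score(d$p, g), cand, gammas, SIMPLIFY = FALSE)
  ipknot_solve(nrow(P), cand, scores, min_sep, node_limit)
}

#' Loss-augmented IP decoding
#'
#' Same program as [ipknot_decode()] with every candidate's objective
#' coefficient shifted by -delta_fn when the pair belongs to the reference
#' structure (level-agnostic membership) and +delta_fp otherwise; with
#' delta_fn = delta_fp = 0 it reduces to the plain decoder.  Reference
#' pairs absent from every candidate list cannot be recovered by the
#' decoder (they contribute a constant delta_fn to the loss) and are
#' reported in the `missed_ref` element.
#'
#' @inheritParams ipknot_decode
#' @param y_ref the reference [rna_structure()].
#' @param delta_fn,delta_fp nonnegative loss weights.
#' @return an `ip_solution` with extra element `missed_ref` (two-column
#'   matrix of reference pairs outside all candidate lists).
#' @export
ipknot_decode_augmented <- function(P, gammas = c(1, 3), y_ref, delta_fn = 0.1,
                                    delta_fp = 0.1, min_sep = 4L, node_limit = 5e5) {
  stopifnot(inherits(y_ref, "rna_structure"), y_ref$n == nrow(P),
            delta_fn >= 0, delta_fp >= 0)
  cand <- candidate_pairs(P, gammas, min_sep)
  ref_key <- character(0)
  if (nrow(y_ref$pairs) > 0L)
    ref_key <- paste(y_ref$pairs[, 1L], y_ref$pairs[, 2L])
  covered <- character(0)
  scores <- mapply(function(d, g) {
    if (nrow(d) == 0L) return(numeric(0))
    key <- paste(d$i, d$j)
    in_ref <- key %in% ref_key
    covered <<- union(covered, key[in_ref])
    pair_score(d$p, g) + ifelse(in_ref, -delta_fn, delta_fp)
  }, cand, gammas, SIMPLIFY = FALSE)
  sol <- ipknot_solve(nrow(P), cand, scores, min_sep, node_limit)
  missed <- setdiff(ref_key, covered)
  sol$missed_ref <- if (length(missed) > 0L) {
    ij <- do.call(rbind, lapply(strsplit(missed, " "), as.integer))
    pairs_mat(ij[, 1L], ij[, 2L])
  } else pairs_mat()
  sol
}
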