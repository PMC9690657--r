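#' Structured loss between a reference and a predicted structure
#'
#' delta_fn * (# reference pairs missing from the prediction) +
#' delta_fp * (# predicted pairs absent from the reference).
#'
#' @param y reference [rna_structure()].
#' @param y_hat predicted [rna_structure()] over the same sequence length.
#' @param delta_fn,delta_fp nonnegative loss weights (defaults 0.1).
#' @return a single nonnegative number.
#' @export
structured_loss <- function(y, y_hat, delta_fn = 0.1, delta_fp = 0.1) {
  stopifnot(inherits(y, "rna_structure"), inherits(y_hat, "rna_structure"))
  if (y$n != y_hat$n) stop("structures have different sequence lengths")
  ky <- pair_keys(y); kh <- pair_keys(y_hat)
  delta_fn * sum(!ky %in% kh) + delta_fp * sum(!kh %in% ky)
}

pair_keys <- function(y) {
  if (nrow(y$pairs) == 0L) return(character(0))
  paste(y$pairs[, 1L], y$pairs[, 2L])
}

# Eq-8-style score of a (reference) structure under per-level gammas:
# pairs are assigned levels greedily; levels beyond length(gammas) reuse
# the last gamma.
score_by_levels <- function(P, y, gammas) {
  if (nrow(y$pairs) == 0L) return(list(score = 0, levels = assign_levels(y, 10L)))
  lv <- assign_levels(y, max_levels = 10L)
  s <- 0
  for (p in seq_along(lv$levels)) {
    pm <- lv$levels[[p]]
    if (nrow(pm) > 0L)
      s <- s + sum(pair_score(P[pm], gammas[min(p, length(gammas))]))
  }
  list(score = s, levels = lv)
}

#' Structured hinge loss of one training example
#'
#' Computes the base-pairing probability matrix under the current model,
#' runs the loss-augmented decoder, and returns the hinge
#' f(x, y-hat) + Delta(y, y-hat) - f(x, y) together with the per-pair
#' coefficient matrix W with W_ij = (gamma + 1)(y-hat_ij - y_ij) (for the
#' hierarchical decoder, the gamma of the level that selected the pair;
#' reference pairs use the level-1 gamma) that feeds the parameter
#' gradient of sum W_ij p_ij.  The hinge is nonnegative (up to solver
#' tolerance) whenever the reference is feasible for the decoder, i.e.
#' non-crossing (Nussinov) or above the candidate thresholds (IP).
#'
#' @param model an [fnn_model()] or [birnn_model()].
#' @param record an [structure_record()] with a reference structure.
#' @param decoder `"nussinov"` or `"ipknot"`.
#' @param gamma base-pair weight(s); a vector of per-level weights for the
#'   IP decoder.
#' @param delta_fn,delta_fp loss weights.
#' @param node_limit branch-and-bound node cap for the IP decoder.
#' @param bpp optionally, a precomputed probability matrix for `record`.
#' @return a list with `hinge`, `W` (n x n coefficient matrix), `y_hat`,
#'   and `P`.
#' @export
example_hinge <- function(model, record, decoder = c("nussinov", "ipknot"),
                          gamma = NULL, delta_fn = 0.1, delta_fp = 0.1,
                          node_limit = 5e5, bpp = NULL) {
  decoder <- match.arg(decoder)
  stopifnot(inherits(record, "rna_record"))
  if (is.null(record$structure)) stop("training record lacks a reference structure")
  if (is.null(gamma)) gamma <- if (decoder == "nussinov") 4 else c(1, 3)
  x <- record$sequence
  y <- record$structure
  min_sep <- model$config$min_sep
  P <- if (is.null(bpp)) bpp_matrix(model, x) else bpp
  n <- x$n
  W <- matrix(0, n, n)
  if (decoder == "nussinov") {
    y_hat <- nussinov_decode_augmented(P, gamma[1L], y, delta_fn, delta_fp, min_sep)
    f_hat <- attr(y_hat, "score")
    f_y <- score_structure(P, y, gamma[1L])
    if (nrow(y_hat$pairs) > 0L) W[y_hat$pairs] <- W[y_hat$pairs] + (gamma[1L] + 1)
    if (nrow(y$pairs) > 0L) W[y$pairs] <- W[y$pairs] - (gamma[1L] + 1)
  } else {
    sol <- ipknot_decode_augmented(P, gamma, y, delta_fn, delta_fp, min_sep,
                                   node_limit = node_limit)
    y_hat <- merge_levels(sol$decomposition)
    f_hat <- 0
    for (p in seq_along(sol$decomposition$levels)) {
      pm <- sol$decomposition$levels[[p]]
      if (nrow(pm) > 0L) {
        f_hat <- f_hat + sum(pair_score(P[pm], gamma[p]))
        W[pm] <- W[pm] + (gamma[p] + 1)
      }
    }
    f_y <- score_by_levels(P, y, gamma)$score
    if (nrow(y$pairs) > 0L) W[y$pairs] <- W[y$pairs] - (gamma[1L] + 1)
  }
  hinge <- f_hat + structured_loss(y, y_hat, delta_fn, delta_fp) - f_y
  list(hinge = hinge, W = W, y_hat = y_hat, P = P)
}

# stochastic subgradient descent over structured hinges; mutates nothing,
# returns the trained model and the per-epoch history
ssvm_train <- function(model, records, decoder, gamma, delta_fn, delta_fp,
                       eta, epochs, tol, seed, shuffle = TRUE, lr_decay = FALSE,
                       average = FALSE, node_limit = 5e5, verbose = FALSE) {
  stopifnot(length(records) > 0L)
  for (r in records)
    if (is.null(r$structure)) stop("every training record needs a reference structure")
  # k-mer features depend only on the sequence: encode once, reuse per epoch
  feat <- NULL
  if (inherits(model, "fnn_model")) {
    feat <- lapply(records, function(r) {
      ij <- candidate_ij(r$sequence$n, model$config$min_sep)
      list(ij = ij, F = encode_pair_context(r$sequence, ij, model$config$k))
    })
  }
  history <- data.frame(epoch = integer(0), objective = numeric(0),
                        mean_hinge = numeric(0))
  t_update <- 0L
  # Polyak-style iterate averaging over the last half of the epochs: the
  # returned parameters are the mean of the end-of-epoch snapshots, which
  # damps the oscillation of plain stochastic subgradient descent
  avg_from <- epochs %/% 2L + 1L
  avg_sum <- NULL
  avg_n <- 0L
  with_seed(seed, {
    prevL <- NA_real_
    for (ep in seq_len(epochs)) {
      ord <- if (shuffle) sample.int(length(records)) else seq_along(records)
      L <- 0
      for (r_id in ord) {
        rec <- records[[r_id]]
        P <- if (is.null(feat)) bpp_matrix(model, rec$sequence) else {
          n <- rec$sequence$n
          Pm <- matrix(0, n, n)
          if (nrow(feat[[r_id]]$ij) > 0L)
            Pm[feat[[r_id]]$ij] <- fnn_forward_full(model, feat[[r_id]]$F)
          Pm
        }
        eh <- example_hinge(model, rec, decoder, gamma, delta_fn, delta_fp,
                            node_limit = node_limit, bpp = P)
        L <- L + eh$hinge
        if (any(eh$W != 0)) {
          g <- if (is.null(feat))
            model_gradient(model, rec$sequence, eh$W)
          else
            model_gradient(model, rec$sequence, eh$W,
                           features = feat[[r_id]]$F, ij = feat[[r_id]]$ij)
          if (any(!is.finite(flatten_params(g))))
            stop("non-finite gradient on training example '", rec$sequence$id, "'")
          t_update <- t_update + 1L
          step <- if (lr_decay) eta / sqrt(t_update) else eta
          model$params <- params_axpy(model$params, g, step)
        }
      }
      history <- rbind(history, data.frame(epoch = ep, objective = L,
                                           mean_hinge = L / length(records)))
      if (average && ep >= avg_from) {
        v <- flatten_params(model$params)
        avg_sum <- if (is.null(avg_sum)) v else avg_sum + v
        avg_n <- avg_n + 1L
      }
      if (verbose)
        message(sprintf("epoch %3d: objective %.6f", ep, L))
      if (!is.na(prevL) && abs(L - prevL) <= tol * max(1, abs(prevL))) break
      prevL <- L
    }
  })
  if (average && avg_n > 0L)
    model$params <- unflatten_params(avg_sum / avg_n, model$params)
  list(model = model, history = history)
}
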