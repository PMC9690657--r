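#' Fit a neural base-pairing probability model by max-margin training
#'
#' Trains a feedforward (default) or recursive neural network to emit
#' base-pairing probabilities p_ij such that maximum-expected-accuracy
#' decoding of the resulting matrix reproduces the reference structures.
#' Training minimizes the structured-SVM objective
#' sum over examples of \[max over structures of f(x, y-hat) +
#' Delta(y, y-hat)\] - f(x, y) by stochastic subgradient descent, where f
#' is the expected-gain score of the decoder in use and Delta the
#' false-negative/false-positive loss; the inner maximization is the
#' decoder itself run on loss-augmented pair gains.
#'
#' @param records a list of [structure_record()] objects with reference
#'   structures (e.g. from [rna_family()] or [read_bpseq()]).
#' @param model `"fnn"` (k-mer context feedforward network) or `"birnn"`
#'   (inside-outside recursive network).
#' @param decoder decoder used for loss-augmented inference during
#'   training and as the default at prediction: `"nussinov"`
#'   (pseudoknot-free dynamic programming) or `"ipknot"` (hierarchical
#'   integer program allowing pseudoknots).
#' @param gamma base-pair weight(s): a single gamma for `"nussinov"`
#'   (default 4), a vector of per-level gammas for `"ipknot"` (default
#'   c(1, 3) with m = 2 levels).
#' @param k context length of the feedforward model (odd, default 81).
#' @param hidden hidden layer sizes of the feedforward model.
#' @param birnn_hidden hidden state width of the recursive model.
#' @param delta_fn,delta_fp structured-loss weights (defaults 0.1).
#' @param eta learning rate of the subgradient descent (default 0.01).
#' @param epochs maximum training epochs (default 100).
#' @param tol stop when the epoch objective changes by less than this
#'   relative amount (default 1e-4).
#' @param min_sep minimum pair span (default 4: at least 3 unpaired bases
#'   in a hairpin loop).
#' @param seed seed controlling initialization and example shuffling.
#' @param shuffle reshuffle example order each epoch.
#' @param lr_decay use a 1/sqrt(t) learning-rate decay.
#' @param average return the average of the end-of-epoch parameters over
#'   the last half of the epochs (Polyak-style iterate averaging) instead
#'   of the final iterate; damps the variance of the plain stochastic
#'   subgradient descent.
#' @param max_len length cap of the recursive model.
#' @param node_limit branch-and-bound node cap of the IP decoder.
#' @param verbose print the objective per epoch.
#' @return an object of class `bppnet` with components `model` (the
#'   trained network), `decoder`, `gamma`, `history` (per-epoch objective)
#'   and `records` (the training data).  Methods: [print()], [summary()],
#'   [coef()], [predict.bppnet()], [plot()], [fitted()], [residuals()].
#' @export
bppnet <- function(records, model = c("fnn", "birnn"),
                   decoder = c("nussinov", "ipknot"), gamma = NULL,
                   k = 81L, hidden = c(200L, 50L), birnn_hidden = 80L,
                   delta_fn = 0.1, delta_fp = 0.1, eta = 0.01,
                   epochs = 100L, tol = 1e-4, min_sep = 4L, seed = 1L,
                   shuffle = TRUE, lr_decay = FALSE, average = FALSE,
                   max_len = 200L, node_limit = 5e5, verbose = FALSE) {
  model <- match.arg(model)
  decoder <- match.arg(decoder)
  if (is.null(gamma)) gamma <- if (decoder == "nussinov") 4 else c(1, 3)
  stopifnot(all(gamma > 0), delta_fn >= 0, delta_fp >= 0, eta > 0, epochs >= 1)
  if (inherits(records, "rna_record")) records <- list(records)
  net <- if (model == "fnn")
    fnn_model(k = k, hidden = hidden, min_sep = min_sep, seed = seed)
  else
    birnn_model(hidden = birnn_hidden, min_sep = min_sep, max_len = max_len, seed = seed)
  fit <- ssvm_train(net, records, decoder, gamma, delta_fn, delta_fp,
                    eta, epochs, tol, seed = seed, shuffle = shuffle,
                    lr_decay = lr_decay, average = average,
                    node_limit = node_limit, verbose = verbose)
  structure(list(model = fit$model, decoder = decoder, gamma = gamma,
                 delta_fn = delta_fn, delta_fp = delta_fp,
                 history = fit$history, records = records,
                 node_limit = node_limit, call = match.call()),
            class = "bppnet")
}

#' @export
print.bppnet <- function(x, ...) {
  cat("Neural base-pairing probability model (structured-SVM trained)\n")
  cat(sprintf("  architecture: %s; decoder: %s; gamma: %s\n",
              x$model$type, x$decoder, paste(x$gamma, collapse = ", ")))
  cat(sprintf("  trained on %d sequence(s), %d epoch(s); final objective %.4f\n",
              length(x$records), nrow(x$history),
              x$history$objective[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.bppnet <- function(object, ...) {
  h <- object$history
  res <- residuals(object)
  out <- list(fit = object, final_objective = h$objective[nrow(h)],
              epochs = nrow(h), hinge = summary(res))
  class(out) <- "summary.bppnet"
  out
}

#' @export
print.summary.bppnet <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  per-example hinge at the final parameters:\n"))
  print(x$hinge)
  invisible(x)
}

#' @export
coef.bppnet <- function(object, ...) flatten_params(object$model$params)

#' Predict secondary structures or probability matrices
#'
#' @param object a fitted [bppnet()] model.
#' @param newdata sequences to predict for: a list of [rna_seq()] /
#'   [structure_record()] objects or strings, or a single one.
#' @param type `"structure"` (decoded structure, default) or `"bpp"`
#'   (the raw probability matrix).
#' @param gamma override the fitted gamma(s).
#' @param decoder override the fitted decoder.
#' @param levels number of pseudoknot levels m for the IP decoder
#'   (defaults to `length(gamma)`; `levels = 1` makes the IP decoder
#'   equivalent to the DP decoder).
#' @param ... unused.
#' @return a list (or, for single input, one element) of
#'   [rna_structure()] with attribute `score` — and, for the IP decoder,
#'   attribute `decomposition` — or of probability matrices.
#' @export
predict.bppnet <- function(object, newdata, type = c("structure", "bpp"),
                           gamma = NULL, decoder = NULL, levels = NULL, ...) {
  type <- match.arg(type)
  if (is.null(decoder)) decoder <- object$decoder
  if (is.null(gamma))
    gamma <- if (identical(decoder, object$decoder)) object$gamma
             else if (decoder == "nussinov") 4 else c(1, 3)
  single <- !is.null(newdata) && (inherits(newdata, "rna_seq") ||
              inherits(newdata, "rna_record") ||
              (is.character(newdata) && length(newdata) == 1L))
  if (single) newdata <- list(newdata)
  min_sep <- object$model$config$min_sep
  out <- lapply(newdata, function(s) {
    if (inherits(s, "rna_record")) s <- s$sequence
    s <- as_rna_seq(s)
    P <- bpp_matrix(object$model, s)
    if (type == "bpp") return(P)
    if (decoder == "nussinov") {
      nussinov_decode(P, gamma[1L], min_sep)
    } else {
      m <- if (is.null(levels)) length(gamma) else as.integer(levels)
      g <- rep_len(gamma, m)
      sol <- ipknot_decode(P, g, min_sep, node_limit = object$node_limit)
      y <- merge_levels(sol$decomposition)
      attr(y, "score") <- sol$objective
      attr(y, "decomposition") <- sol$decomposition
      y
    }
  })
  if (single) out[[1L]] else out
}

#' @export
fitted.bppnet <- function(object, ...) predict(object, object$records)

#' @export
residuals.bppnet <- function(object, ...) {
  vapply(object$records, function(r)
    example_hinge(object$model, r, object$decoder, object$gamma,
                  object$delta_fn, object$delta_fp,
                  node_limit = object$node_limit)$hinge,
    numeric(1))
}

#' @export
plot.bppnet <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$objective, type = "b",
                 xlab = "epoch", ylab = "structured-SVM objective",
                 main = "Training objective", ...)
  invisible(x)
}
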