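# Shared numerical helpers for the probability models.

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# uniform weight matrix scaled by fan-in (rows = inputs)
init_mat <- function(nin, nout) {
  a <- 1 / sqrt(nin)
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

# flatten a (possibly nested) list of numeric arrays into one named vector
flatten_params <- function(params) {
  flat <- unlist(params, use.names = TRUE)
  v <- as.numeric(flat)
  names(v) <- names(flat)
  v
}

# rebuild a parameter list with the shapes of `skeleton` from a flat vector
unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  rebuild <- function(x) {
    if (is.list(x)) return(lapply(x, rebuild))
    k <- length(x)
    out <- vec[(pos + 1L):(pos + k)]
    pos <<- pos + k
    dim(out) <- dim(x)
    out
  }
  out <- rebuild(skeleton)
  stopifnot(pos == length(vec))
  out
}

# elementwise a - eta * b over two parameter lists of identical shape
params_axpy <- function(a, b, eta) {
  mapply(function(x, g) x - eta * g, a, b, SIMPLIFY = FALSE)
}

#' Base-pairing probability matrix from a model
#'
#' Evaluates a trained (or freshly initialized) probability model on every
#' candidate pair (i, j) with j - i >= the model's minimum pair span, and
#' returns the full n x n matrix with non-candidate entries at 0.
#'
#' @param model a model built by [fnn_model()] or [birnn_model()].
#' @param x an [rna_seq()] (a plain string is accepted).
#' @param ... passed to methods (`batch_size` for the feedforward model).
#' @return an n x n numeric matrix of probabilities in (0, 1) on
#'   candidates, 0 elsewhere.
#' @export
bpp_matrix <- function(model, x, ...) UseMethod("bpp_matrix")

# gradient of sum_ij W[i,j] * p_ij with respect to the model parameters;
# W is an n x n coefficient matrix (only candidate entries are used).
model_gradient <- function(model, x, W, ...) UseMethod("model_gradient")

as_rna_seq <- function(x) if (inherits(x, "rna_seq")) x else rna_seq(x)

# candidate (i, j) index matrix for a sequence of length n
candidate_ij <- function(n, min_sep) {
  if (n < min_sep + 1L) return(pairs_mat())
  ij <- which(outer(seq_len(n), seq_len(n), function(i, j) j - i >= min_sep),
              arr.ind = TRUE)
  pairs_mat(ij[, 1L], ij[, 2L])
}
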