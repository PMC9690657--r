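#' Evaluate a predicted structure against a reference
#'
#' Base pairs are compared by exact (i, j) identity.  Sensitivity is
#' TP / (TP + FN), positive predictive value TP / (TP + FP), and F their
#' harmonic mean; empty denominators yield 0.
#'
#' @param pred predicted [rna_structure()].
#' @param ref reference [rna_structure()] over the same sequence length.
#' @return a one-row data frame with columns `tp`, `fp`, `fn`, `sen`,
#'   `ppv`, `f`.
#' @export
evaluate <- function(pred, ref) {
  stopifnot(inherits(pred, "rna_structure"), inherits(ref, "rna_structure"))
  if (pred$n != ref$n) stop("structures have different sequence lengths")
  kp <- pair_keys(pred); kr <- pair_keys(ref)
  tp <- sum(kp %in% kr)
  eval_from_counts(tp, length(kp) - tp, length(kr) - tp)
}

eval_from_counts <- function(tp, fp, fn) {
  sen <- if (tp + fn > 0) tp / (tp + fn) else 0
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (sen + ppv > 0) 2 * sen * ppv / (sen + ppv) else 0
  data.frame(tp = tp, fp = fp, fn = fn, sen = sen, ppv = ppv, f = f)
}

#' Evaluate predictions over a dataset
#'
#' @param preds list of predicted [rna_structure()] objects.
#' @param refs list of matching reference [rna_structure()] objects (or
#'   [structure_record()]s).
#' @param aggregate `"counts"` (default: sum TP/FP/FN over the dataset
#'   before computing the ratios) or `"mean"` (average the per-sequence
#'   SEN/PPV/F values).
#' @return a list with `per_record` (data frame, one row per pair of
#'   structures) and `aggregate` (one-row data frame).
#' @export
evaluate_dataset <- function(preds, refs, aggregate = c("counts", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(preds) == length(refs))
  refs <- lapply(refs, function(r) if (inherits(r, "rna_record")) r$structure else r)
  per <- do.call(rbind, mapply(evaluate, preds, refs, SIMPLIFY = FALSE))
  agg <- if (aggregate == "counts")
    eval_from_counts(sum(per$tp), sum(per$fp), sum(per$fn))
  else
    data.frame(tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn),
               sen = mean(per$sen), ppv = mean(per$ppv), f = mean(per$f))
  list(per_record = per, aggregate = agg)
}
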