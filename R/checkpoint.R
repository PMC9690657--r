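#' Save a probability model to a plain-text checkpoint
#'
#' The checkpoint embeds the architecture tag and all hyperparameters
#' (context length, hidden sizes, minimum pair span) so that prediction
#' cannot silently run with a mismatched encoding.  Parameter values are
#' written with 17 significant digits, which round-trips IEEE doubles
#' exactly: a loaded model reproduces identical probabilities bit for bit.
#'
#' @param model an [fnn_model()] or [birnn_model()].
#' @param path output path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "bpp_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("bppnet-checkpoint 1",
               jsonlite::toJSON(list(type = model$type, config = model$config),
                                auto_unbox = TRUE)), con)
  for (nm in names(model$params)) {
    v <- model$params[[nm]]
    d <- if (is.null(dim(v))) length(v) else dim(v)
    writeLines(paste(">", nm, paste(d, collapse = " ")), con)
    writeLines(paste(sprintf("%.17g", as.numeric(v)), collapse = " "), con)
  }
  invisible(path)
}

#' Load a probability model from a checkpoint
#'
#' @param path checkpoint path.
#' @param type if given (`"fnn"` or `"birnn"`), fail unless the checkpoint
#'   holds that architecture.
#' @param k if given, fail unless the checkpoint's context length matches
#'   (feedforward models only).
#' @return the reconstructed model.
#' @export
load_model <- function(path, type = NULL, k = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[1L], "bppnet-checkpoint"))
    stop(path, ": not a model checkpoint")
  hdr <- jsonlite::fromJSON(lines[2L])
  if (!is.null(type) && !identical(hdr$type, type))
    stop(sprintf("architecture mismatch: expected '%s' but checkpoint holds '%s'",
                 type, hdr$type))
  if (!is.null(k) && identical(hdr$type, "fnn") && hdr$config$k != k)
    stop(sprintf("hyperparameter mismatch: expected k = %d but checkpoint records k = %d",
                 as.integer(k), as.integer(hdr$config$k)))
  model <- switch(hdr$type,
    fnn = fnn_model(k = hdr$config$k, hidden = hdr$config$hidden,
                    min_sep = hdr$config$min_sep, seed = hdr$config$seed),
    birnn = birnn_model(hidden = hdr$config$hidden, min_sep = hdr$config$min_sep,
                        max_len = hdr$config$max_len, seed = hdr$config$seed),
    stop(path, ": unknown architecture tag '", hdr$type, "'"))
  at <- grep("^> ", lines)
  got <- character(0)
  for (a in at) {
    f <- strsplit(sub("^> ", "", lines[a]), " ")[[1L]]
    nm <- f[1L]
    d <- as.integer(f[-1L])
    if (!nm %in% names(model$params))
      stop(sprintf("%s: checkpoint parameter '%s' unknown to architecture '%s'",
                   path, nm, hdr$type))
    v <- as.numeric(strsplit(lines[a + 1L], " ", fixed = TRUE)[[1L]])
    tmpl <- model$params[[nm]]
    exp_d <- if (is.null(dim(tmpl))) length(tmpl) else dim(tmpl)
    if (!identical(as.integer(exp_d), d) || length(v) != prod(d))
      stop(sprintf("%s: parameter '%s' has shape [%s], expected [%s]",
                   path, nm, paste(d, collapse = "x"), paste(exp_d, collapse = "x")))
    if (!is.null(dim(tmpl))) dim(v) <- d
    model$params[[nm]] <- v
    got <- c(got, nm)
  }
  missing <- setdiff(names(model$params), got)
  if (length(missing) > 0L)
    stop(path, ": checkpoint lacks parameter(s): ", paste(missing, collapse = ", "))
  model
}
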