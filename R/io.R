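#' Structure record: a sequence with an optional reference structure
#'
#' @param sequence an [rna_seq()].
#' @param structure an [rna_structure()] of the same length, or `NULL` for
#'   prediction-only inputs.
#' @return an object of class `rna_record`.
#' @export
structure_record <- function(sequence, structure = NULL) {
  stopifnot(inherits(sequence, "rna_seq"))
  if (!is.null(structure)) {
    stopifnot(inherits(structure, "rna_structure"))
    if (structure$n != sequence$n)
      stop("structure length does not match sequence length")
  }
  structure(list(sequence = sequence, structure = structure), class = "rna_record")
}

#' @export
print.rna_record <- function(x, ...) {
  cat(sprintf("RNA record '%s': %d nt, %s\n", x$sequence$id, x$sequence$n,
              if (is.null(x$structure)) "no reference structure"
              else sprintf("%d reference pair(s)", nrow(x$structure$pairs))))
  invisible(x)
}

#' Read RNA sequences from a FASTA file
#'
#' Case-insensitive; `T` is mapped to `U` and other non-ACGU letters to
#' the unknown symbol.  Multi-line entries are concatenated.
#'
#' @param path file path.
#' @return a list of [rna_seq()] objects in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("FASTA parse error in '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  mapply(function(s, id) rna_seq(s, id = id), as.character(ss), ids,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs a list of [rna_seq()] (or [rna_record()]) objects.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  lines <- unlist(lapply(seqs, function(s) {
    if (inherits(s, "rna_record")) s <- s$sequence
    c(paste0(">", s$id), s$residues)
  }))
  writeLines(lines, path)
}

# tokenize non-comment lines of a whitespace-separated file
read_tokens <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

pairs_from_partner <- function(partner, path) {
  n <- length(partner)
  for (i in seq_len(n)) {
    p <- partner[i]
    if (p < 0L || p > n)
      stop(sprintf("%s: partner %d of base %d out of range", path, p, i))
    if (p == i) stop(sprintf("%s: base %d pairs with itself", path, i))
    if (p > 0L && partner[p] != i)
      stop(sprintf("%s: asymmetric partners: line %d says %d but line %d says %d",
                   path, i, p, p, partner[p]))
  }
  keep <- which(partner > seq_len(n))
  pairs_mat(keep, partner[keep])
}

#' Read a BPSEQ file
#'
#' One line per base: `index base partner` (1-based; partner 0 means
#' unpaired).  Partner claims must be symmetric; self-pairs and index gaps
#' are parse errors.
#'
#' @param path file path.
#' @return an [structure_record()].
#' @export
read_bpseq <- function(path) {
  tk <- read_tokens(path)
  if (length(tk$lines) == 0L) stop("empty BPSEQ file: ", path)
  f <- strsplit(trimws(tk$lines), "\\s+")
  bad <- which(lengths(f) != 3L)
  if (length(bad) > 0L)
    stop(sprintf("%s: line %d: expected 'index base partner'", path, tk$lineno[bad[1L]]))
  idx <- as.integer(vapply(f, `[`, "", 1L))
  base <- vapply(f, `[`, "", 2L)
  partner <- as.integer(vapply(f, `[`, "", 3L))
  if (anyNA(idx) || anyNA(partner))
    stop(path, ": non-numeric index or partner column")
  if (!identical(idx, seq_along(idx)))
    stop(path, ": base indices must run 1..n without gaps")
  seqobj <- rna_seq(paste(base, collapse = ""), id = sub("\\.[^.]*$", "", basename(path)))
  structure_record(seqobj, rna_structure(seqobj$n, pairs_from_partner(partner, path)))
}

#' Write a BPSEQ file
#'
#' @param record an [structure_record()] with a structure.
#' @param path output path.
#' @export
write_bpseq <- function(record, path) {
  stopifnot(inherits(record, "rna_record"), !is.null(record$structure))
  n <- record$sequence$n
  partner <- integer(n)
  p <- record$structure$pairs
  if (nrow(p) > 0L) { partner[p[, 1L]] <- p[, 2L]; partner[p[, 2L]] <- p[, 1L] }
  writeLines(paste(seq_len(n), seq_chars(record$sequence), partner), path)
}

#' Read a CT (connectivity table) file
#'
#' Standard 6-column CT: a header line starting with the base count, then
#' `index base index-1 index+1 partner index` per base.
#'
#' @param path file path.
#' @return an [structure_record()].
#' @export
read_ct <- function(path) {
  tk <- read_tokens(path)
  if (length(tk$lines) < 1L) stop("empty CT file: ", path)
  head_f <- strsplit(trimws(tk$lines[1L]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(head_f[1L]))
  if (is.na(n) || n < 1L) stop(path, ": CT header must start with the base count")
  body <- tk$lines[-1L]
  if (length(body) != n)
    stop(sprintf("%s: header declares %d bases but body has %d lines", path, n, length(body)))
  f <- strsplit(trimws(body), "\\s+")
  if (any(lengths(f) < 6L)) stop(path, ": CT body lines need 6 columns")
  idx <- as.integer(vapply(f, `[`, "", 1L))
  base <- vapply(f, `[`, "", 2L)
  partner <- as.integer(vapply(f, `[`, "", 5L))
  if (!identical(idx, seq_len(n))) stop(path, ": base indices must run 1..n")
  id <- if (length(head_f) > 1L) paste(head_f[-1L], collapse = " ") else basename(path)
  seqobj <- rna_seq(paste(base, collapse = ""), id = id)
  structure_record(seqobj, rna_structure(n, pairs_from_partner(partner, path)))
}

#' Write a CT file
#'
#' @inheritParams write_bpseq
#' @export
write_ct <- function(record, path) {
  stopifnot(inherits(record, "rna_record"), !is.null(record$structure))
  n <- record$sequence$n
  partner <- integer(n)
  p <- record$structure$pairs
  if (nrow(p) > 0L) { partner[p[, 1L]] <- p[, 2L]; partner[p[, 2L]] <- p[, 1L] }
  i <- seq_len(n)
  writeLines(c(paste(n, record$sequence$id),
               paste(i, seq_chars(record$sequence), i - 1L, i + 1L, partner, i)),
             path)
}

db_open <- c("(", "[", "{")
db_close <- c(")", "]", "}")

#' Parse extended dot-bracket notation
#'
#' `()` encodes level-1 pairs, `[]` level 2 and `{}` level 3, which is how
#' pseudoknots are written as crossing bracket alphabets.
#'
#' @param text a dot-bracket string.
#' @return an [rna_levels()] object (merge with [merge_levels()] for a
#'   flat structure); levels with no pairs are dropped from the end.
#' @export
parse_dotbracket <- function(text) {
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n == 0L) stop("empty dot-bracket string")
  bad <- !ch %in% c(".", db_open, db_close)
  if (any(bad))
    stop(sprintf("dot-bracket parse error: unexpected character '%s' at position %d",
                 ch[which(bad)[1L]], which(bad)[1L]))
  levels <- vector("list", 3L)
  stacks <- rep(list(integer(0)), 3L)
  for (pos in seq_len(n)) {
    l <- match(ch[pos], db_open)
    if (!is.na(l)) { stacks[[l]] <- c(stacks[[l]], pos); next }
    l <- match(ch[pos], db_close)
    if (!is.na(l)) {
      if (length(stacks[[l]]) == 0L)
        stop(sprintf("dot-bracket parse error: unmatched '%s' at position %d", ch[pos], pos))
      i <- stacks[[l]][length(stacks[[l]])]
      stacks[[l]] <- stacks[[l]][-length(stacks[[l]])]
      levels[[l]] <- rbind(levels[[l]], pairs_mat(i, pos))
    }
  }
  open_left <- which(lengths(stacks) > 0L)
  if (length(open_left) > 0L)
    stop(sprintf("dot-bracket parse error: unmatched '%s'", db_open[open_left[1L]]))
  used <- which(vapply(levels, function(x) !is.null(x) && nrow(x) > 0L, TRUE))
  top <- if (length(used) == 0L) 1L else max(used)
  levels <- lapply(levels[seq_len(top)], function(x) if (is.null(x)) pairs_mat() else x)
  rna_levels(n, levels)
}

#' Write extended dot-bracket notation
#'
#' A [rna_levels()] decomposition is written with one bracket alphabet per
#' level; a bare [rna_structure()] is first decomposed by greedy first-fit
#' level assignment ([assign_levels()]).  More than 3 levels is
#' unsupported.
#'
#' @param x an [rna_structure()] or [rna_levels()].
#' @return a dot-bracket string.
#' @export
write_dotbracket <- function(x) {
  if (inherits(x, "rna_structure")) x <- assign_levels(x, max_levels = 3L)
  stopifnot(inherits(x, "rna_levels"))
  if (length(x$levels) > 3L)
    stop(sprintf("dot-bracket supports at most 3 levels, got %d", length(x$levels)))
  out <- rep(".", x$n)
  for (l in seq_along(x$levels)) {
    p <- x$levels[[l]]
    if (nrow(p) > 0L) { out[p[, 1L]] <- db_open[l]; out[p[, 2L]] <- db_close[l] }
  }
  paste(out, collapse = "")
}

#' Read a plain-text base-pairing probability matrix
#'
#' Triplet lines `i j p` (1-based, i < j); unlisted entries are 0.
#'
#' @param path file path.
#' @param n sequence length.
#' @return an n x n probability matrix.
#' @export
read_bpp_matrix <- function(path, n) {
  tk <- read_tokens(path)
  P <- matrix(0, n, n)
  if (length(tk$lines) == 0L) return(P)
  f <- strsplit(trimws(tk$lines), "\\s+")
  if (any(lengths(f) != 3L)) stop(path, ": expected triplet lines 'i j p'")
  i <- as.integer(vapply(f, `[`, "", 1L))
  j <- as.integer(vapply(f, `[`, "", 2L))
  p <- as.numeric(vapply(f, `[`, "", 3L))
  if (anyNA(i) || anyNA(j) || anyNA(p)) stop(path, ": non-numeric entry")
  if (any(i >= j)) stop(path, ": entries must satisfy i < j")
  if (any(i < 1L) || any(j > n)) stop(path, ": index out of range 1..n")
  if (any(p < 0 | p > 1)) stop(path, ": probabilities must lie in [0, 1]")
  P[cbind(i, j)] <- p
  P
}

#' Write a base-pairing probability matrix as text triplets
#'
#' @param P an n x n probability matrix (upper triangle used).
#' @param path output path.
#' @param threshold entries below this are omitted (sparsity control).
#' @export
write_bpp_matrix <- function(P, path, threshold = 1e-5) {
  check_bpp(P)
  idx <- which(upper.tri(P) & P >= threshold, arr.ind = TRUE)
  lines <- if (nrow(idx) == 0L) character(0)
           else sprintf("%d %d %.10g", idx[, 1L], idx[, 2L], P[idx])
  writeLines(lines, path)
}
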