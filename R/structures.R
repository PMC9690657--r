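#' RNA sequence object
#'
#' Builds an RNA sequence over the alphabet \{A, C, G, U\}.  Lowercase
#' letters are accepted, `T` is mapped to `U` (DNA-style input), and any
#' other letter is mapped to the unknown symbol `N`.  Unknown residues are
#' legal everywhere: they receive an all-zero one-hot encoding in the
#' probability models and are not barred from pairing.
#'
#' @param residues a single string of residues (or a character vector of
#'   single letters, which is collapsed).
#' @param id a text label.
#' @return an object of class `rna_seq`: a list with elements `id`,
#'   `residues` (normalized string) and `n` (sequence length).
#' @export
rna_seq <- function(residues, id = "seq") {
  if (length(residues) > 1L) residues <- paste(residues, collapse = "")
  stopifnot(is.character(residues), length(residues) == 1L)
  r <- toupper(residues)
  r <- chartr("T", "U", r)
  ch <- strsplit(r, "", fixed = TRUE)[[1L]]
  if (length(ch) == 0L) stop("residues must be nonempty")
  ch[!ch %in% c("A", "C", "G", "U")] <- "N"
  structure(list(id = as.character(id), residues = paste(ch, collapse = ""), n = length(ch)),
            class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat(sprintf("RNA sequence '%s' (%d nt)\n", x$id, x$n))
  cat(substr(x$residues, 1L, 70L), if (x$n > 70L) "..." else "", "\n", sep = "")
  invisible(x)
}

seq_chars <- function(x) strsplit(x$residues, "", fixed = TRUE)[[1L]]

#' Base-pair matrix constructor
#'
#' @param i,j integer vectors of 5' and 3' partner positions (1-based).
#' @return an integer matrix with columns `i` and `j`, one row per pair.
#' @export
pairs_mat <- function(i = integer(0), j = integer(0)) {
  stopifnot(length(i) == length(j))
  m <- cbind(i = as.integer(i), j = as.integer(j))
  rownames(m) <- NULL
  m
}

#' Secondary structure object
#'
#' A set of base pairs (i, j), i < j, over a sequence of length `n`, with
#' each base in at most one pair.  Crossing pairs (pseudoknots) are
#' permitted in this container; decoders that cannot produce them enforce
#' non-crossing themselves.
#'
#' @param n sequence length.
#' @param pairs a two-column integer matrix as from [pairs_mat()].
#' @return an object of class `rna_structure`.
#' @export
rna_structure <- function(n, pairs = pairs_mat()) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (is.null(pairs) || length(pairs) == 0L) pairs <- pairs_mat()
  if (!is.matrix(pairs)) pairs <- matrix(as.integer(pairs), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  storage.mode(pairs) <- "integer"
  colnames(pairs) <- c("i", "j")
  if (nrow(pairs) > 0L) {
    if (any(pairs[, 1L] >= pairs[, 2L])) stop("malformed pair: i must be < j")
    if (any(pairs < 1L) || any(pairs > n)) stop("pair index out of range 1..n")
    idx <- c(pairs[, 1L], pairs[, 2L])
    if (anyDuplicated(idx)) stop("a base takes part in more than one pair")
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  structure(list(n = n, pairs = pairs), class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("RNA secondary structure: n = %d, %d base pair(s)\n", x$n, nrow(x$pairs)))
  if (nrow(x$pairs) > 0L && nrow(x$pairs) <= 25L)
    cat(paste(sprintf("(%d,%d)", x$pairs[, 1L], x$pairs[, 2L]), collapse = " "), "\n")
  invisible(x)
}

n_pairs <- function(y) nrow(y$pairs)

#' Do two base pairs cross (form a pseudoknot)?
#'
#' Two pairs written as (i, j) and (k, l) with i < k cross if and only if
#' i < k < j < l, i.e. their arcs intersect when drawn above the sequence.
#'
#' @param pair_a,pair_b length-2 integer vectors (i, j) with i < j.
#' @return `TRUE` iff the pairs cross.
#' @export
crosses <- function(pair_a, pair_b) {
  if (length(pair_a) != 2L || length(pair_b) != 2L ||
      pair_a[1L] >= pair_a[2L] || pair_b[1L] >= pair_b[2L])
    stop("malformed pair: expected (i, j) with i < j")
  if (pair_a[1L] > pair_b[1L]) { tmp <- pair_a; pair_a <- pair_b; pair_b <- tmp }
  pair_b[1L] > pair_a[1L] && pair_b[1L] < pair_a[2L] && pair_b[2L] > pair_a[2L]
}

# vectorized: which rows of `pairs` cross the single pair (k, l)?
crosses_which <- function(pairs, k, l) {
  if (nrow(pairs) == 0L) return(logical(0))
  i <- pairs[, 1L]; j <- pairs[, 2L]
  (i < k & k < j & j < l) | (k < i & i < l & l < j)
}

#' Hierarchical level decomposition of a pseudoknotted structure
#'
#' A list of m pseudoknot-free substructures ("levels").  A valid
#' decomposition satisfies: (i) base pairs across levels are mutually
#' exclusive and each base pairs at most once overall; (ii) within a level
#' no two pairs cross; (iii) every pair at level p >= 2 crosses at least
#' one pair at every lower level.  Validity is not enforced at
#' construction; use [validate_decomposition()].
#'
#' @param n sequence length.
#' @param levels a list of two-column pair matrices (level 1 first).
#' @return an object of class `rna_levels`.
#' @export
rna_levels <- function(n, levels) {
  n <- as.integer(n)
  stopifnot(n >= 1L, is.list(levels))
  levels <- lapply(levels, function(p) {
    if (inherits(p, "rna_structure")) p <- p$pairs
    if (is.null(p) || length(p) == 0L) return(pairs_mat())
    storage.mode(p) <- "integer"
    colnames(p) <- c("i", "j")
    p
  })
  structure(list(n = n, levels = levels), class = "rna_levels")
}

#' @export
print.rna_levels <- function(x, ...) {
  cat(sprintf("Level decomposition: n = %d, %d level(s), %d pair(s) total\n",
              x$n, length(x$levels), sum(vapply(x$levels, nrow, 1L))))
  invisible(x)
}

#' Validate a level decomposition
#'
#' Checks the three invariants of a hierarchical pseudoknot decomposition:
#' one partner per base across all levels, no crossing within a level, and
#' each pair at level p crossed by at least one pair at every level q < p.
#'
#' @param d an [rna_levels()] object.
#' @return a data frame of violations with columns `constraint` (one of
#'   `"one-partner"`, `"within-level-crossing"`, `"lower-level-crossing"`)
#'   and `detail`; zero rows iff the decomposition is valid.
#' @export
validate_decomposition <- function(d) {
  stopifnot(inherits(d, "rna_levels"))
  viol <- list()
  add <- function(constraint, detail) viol[[length(viol) + 1L]] <<- data.frame(
    constraint = constraint, detail = detail, stringsAsFactors = FALSE)

  all_pairs <- do.call(rbind, d$levels)
  if (!is.null(all_pairs) && nrow(all_pairs) > 0L) {
    if (any(all_pairs[, 1L] >= all_pairs[, 2L]))
      add("one-partner", "malformed pair with i >= j")
    idx <- c(all_pairs[, 1L], all_pairs[, 2L])
    dup <- unique(idx[duplicated(idx)])
    for (b in dup) add("one-partner", sprintf("base %d used by more than one pair", b))
  }
  for (p in seq_along(d$levels)) {
    lp <- d$levels[[p]]
    if (nrow(lp) >= 2L) {
      for (a in seq_len(nrow(lp) - 1L)) {
        cr <- crosses_which(lp[(a + 1L):nrow(lp), , drop = FALSE], lp[a, 1L], lp[a, 2L])
        if (any(cr)) {
          b <- which(cr)[1L] + a
          add("within-level-crossing",
              sprintf("level %d pairs (%d,%d) and (%d,%d) cross",
                      p, lp[a, 1L], lp[a, 2L], lp[b, 1L], lp[b, 2L]))
        }
      }
    }
    if (p >= 2L && nrow(lp) > 0L) {
      for (q in seq_len(p - 1L)) {
        lq <- d$levels[[q]]
        for (a in seq_len(nrow(lp))) {
          if (nrow(lq) == 0L || !any(crosses_which(lq, lp[a, 1L], lp[a, 2L])))
            add("lower-level-crossing",
                sprintf("level %d pair (%d,%d) crosses no pair at level %d",
                        p, lp[a, 1L], lp[a, 2L], q))
        }
      }
    }
  }
  if (length(viol) == 0L)
    data.frame(constraint = character(0), detail = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, viol)
}

#' Merge a level decomposition into a single structure
#'
#' @param d an [rna_levels()] object whose levels use disjoint bases.
#' @return an [rna_structure()] holding the union of pairs across levels
#'   (which may contain crossing pairs).
#' @export
merge_levels <- function(d) {
  stopifnot(inherits(d, "rna_levels"))
  all_pairs <- do.call(rbind, d$levels)
  if (is.null(all_pairs)) all_pairs <- pairs_mat()
  if (nrow(all_pairs) > 0L) {
    idx <- c(all_pairs[, 1L], all_pairs[, 2L])
    if (anyDuplicated(idx)) stop("levels overlap: a base is used by more than one pair")
  }
  rna_structure(d$n, all_pairs)
}

#' Greedy first-fit level assignment for a bare structure
#'
#' Assigns each pair (in (i, j) order) to the lowest level where it
#' crosses no already-placed pair.  The result always satisfies the
#' lower-level-crossing condition: a pair placed at level p crossed some
#' pair at every level below.
#'
#' @param y an [rna_structure()].
#' @param max_levels refuse assignments needing more than this many levels.
#' @return an [rna_levels()] object.
#' @export
assign_levels <- function(y, max_levels = 3L) {
  stopifnot(inherits(y, "rna_structure"))
  lv <- list()
  p <- y$pairs
  if (nrow(p) > 0L) {
    p <- p[order(p[, 1L], p[, 2L]), , drop = FALSE]
    for (a in seq_len(nrow(p))) {
      placed <- FALSE
      for (l in seq_along(lv)) {
        if (!any(crosses_which(lv[[l]], p[a, 1L], p[a, 2L]))) {
          lv[[l]] <- rbind(lv[[l]], p[a, , drop = FALSE]); placed <- TRUE; break
        }
      }
      if (!placed) {
        if (length(lv) + 1L > max_levels)
          stop(sprintf("structure needs more than %d levels", max_levels))
        lv[[length(lv) + 1L]] <- p[a, , drop = FALSE]
      }
    }
  }
  if (length(lv) == 0L) lv <- list(pairs_mat())
  rna_levels(y$n, lv)
}

#' Enumerate all pseudoknot-free structures (brute-force oracle)
#'
#' Exhaustively lists every non-crossing secondary structure of a sequence
#' of length `n` whose pairs all satisfy j - i >= `min_sep`, including the
#' empty structure.  Intended as a small-n oracle for validating decoders;
#' refuses n > 14.
#'
#' @param n sequence length (<= 14).
#' @param min_sep minimum pair span: a pair (i, j) requires j - i >= min_sep.
#' @return a list of two-column pair matrices, each structure exactly once.
#' @export
enumerate_pk_free_structures <- function(n, min_sep = 4L) {
  n <- as.integer(n)
  if (n > 14L)
    stop("enumerate_pk_free_structures is a brute-force oracle; n must be <= 14")
  stopifnot(n >= 1L, min_sep >= 1L)
  memo <- new.env(parent = emptyenv())
  span <- function(i, j) {
    if (i >= j) return(list(pairs_mat()))
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- span(i + 1L, j)                       # i unpaired
    if (i + min_sep <= j) {
      for (k in seq.int(i + min_sep, j)) {
        left <- span(i + 1L, k - 1L)
        right <- span(k + 1L, j)
        for (L in left) for (R in right)
          out[[length(out) + 1L]] <- rbind(pairs_mat(i, k), L, R)
      }
    }
    memo[[key]] <- out
    out
  }
  span(1L, n)
}
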