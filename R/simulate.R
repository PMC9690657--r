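#' Specification of a synthetic RNA family
#'
#' Describes a toy RNA family: a fixed structure template (stems and
#' loops, optionally an H-type pseudoknot) threaded with complementary
#' sequences under a mutation rate, so that training and decoding are
#' testable without external data.
#'
#' @param n_stems number of stems in a pseudoknot-free template (an H-type
#'   template always has exactly two, mutually crossing).
#' @param stem_len_range inclusive range of stem lengths (base pairs).
#' @param loop_len_range inclusive range of loop/spacer lengths (min 3, so
#'   hairpins respect the steric minimum of 3 unpaired bases).
#' @param pseudoknot_prob probability that the template is an H-type
#'   pseudoknot (two crossing stems on two levels).
#' @param mutation_rate per-base probability of substitution to a
#'   different random base after threading; must be < 0.5.
#' @param pair_probs probabilities of threading a pair as G-C, A-U and
#'   G-U respectively (default `c(0.4, 0.4, 0.2)`).  A-U/G-U-rich stems
#'   can slide by one position and still be fully complementary, which
#'   makes the reference register ambiguous; a G-C-heavy mixture keeps
#'   the stem register identifiable.
#' @param n_sequences number of sequences per dataset.
#' @param seq_len target sequence length (templates are centred by
#'   padding; an error is raised if the template cannot fit).
#' @param seed integer seed; all sampling is deterministic given it.
#' @return a list of class `rna_family_spec`.
#' @export
rna_family_spec <- function(n_stems = 2L, stem_len_range = c(4L, 5L),
                            loop_len_range = c(3L, 5L), pseudoknot_prob = 0,
                            mutation_rate = 0.1, pair_probs = c(0.4, 0.4, 0.2),
                            n_sequences = 50L, seq_len = 40L, seed = 1L) {
  stopifnot(n_stems >= 1L, stem_len_range[1L] >= 1L,
            stem_len_range[2L] >= stem_len_range[1L],
            loop_len_range[2L] >= loop_len_range[1L],
            pseudoknot_prob >= 0, pseudoknot_prob <= 1,
            length(pair_probs) == 3L, all(pair_probs >= 0), sum(pair_probs) > 0)
  if (loop_len_range[1L] < 3L) stop("loop lengths must be >= 3")
  if (mutation_rate < 0 || mutation_rate >= 0.5)
    stop("mutation_rate must lie in [0, 0.5)")
  structure(list(n_stems = as.integer(n_stems),
                 stem_len_range = as.integer(stem_len_range),
                 loop_len_range = as.integer(loop_len_range),
                 pseudoknot_prob = pseudoknot_prob,
                 mutation_rate = mutation_rate,
                 pair_probs = pair_probs / sum(pair_probs),
                 n_sequences = as.integer(n_sequences),
                 seq_len = as.integer(seq_len), seed = as.integer(seed)),
            class = "rna_family_spec")
}

rint <- function(range) if (range[1L] == range[2L]) range[1L] else
  sample(range[1L]:range[2L], 1L)

# template sampler using the current RNG state
template_impl <- function(spec) {
  pk <- stats::runif(1) < spec$pseudoknot_prob
  if (pk) {
    a <- rint(spec$stem_len_range); b <- rint(spec$stem_len_range)
    l1 <- rint(spec$loop_len_range); l2 <- rint(spec$loop_len_range)
    l3 <- rint(spec$loop_len_range)
    used <- 2L * (a + b) + l1 + l2 + l3
    if (used > spec$seq_len)
      stop(sprintf("template needs %d nt but seq_len is %d", used, spec$seq_len))
    lead <- (spec$seq_len - used) %/% 2L
    sA <- lead + 1L
    sB <- sA + a + l1
    sA3 <- sB + b + l2
    sB3 <- sA3 + a + l3
    t_a <- seq_len(a); t_b <- seq_len(b)
    rna_levels(spec$seq_len, list(
      pairs_mat(sA + t_a - 1L, sA3 + a - t_a),
      pairs_mat(sB + t_b - 1L, sB3 + b - t_b)))
  } else {
    lens <- vapply(seq_len(spec$n_stems), function(i) rint(spec$stem_len_range), 1L)
    loops <- vapply(seq_len(spec$n_stems), function(i) rint(spec$loop_len_range), 1L)
    spacers <- if (spec$n_stems > 1L)
      vapply(seq_len(spec$n_stems - 1L), function(i) rint(spec$loop_len_range), 1L)
    else integer(0)
    used <- sum(2L * lens + loops) + sum(spacers)
    if (used > spec$seq_len)
      stop(sprintf("template needs %d nt but seq_len is %d", used, spec$seq_len))
    lead <- (spec$seq_len - used) %/% 2L
    cur <- lead
    pr <- pairs_mat()
    for (s in seq_len(spec$n_stems)) {
      L <- lens[s]
      open <- cur + 1L
      close <- cur + L + loops[s]  # first base after the loop
      t <- seq_len(L)
      pr <- rbind(pr, pairs_mat(open + t - 1L, close + L - t + 1L))
      cur <- cur + 2L * L + loops[s]
      if (s < spec$n_stems) cur <- cur + spacers[s]
    }
    rna_levels(spec$seq_len, list(pr))
  }
}

#' Sample a structure template for a synthetic family
#'
#' With probability `pseudoknot_prob` the template is an H-type pseudoknot
#' (two mutually crossing stems, the second assigned to level 2);
#' otherwise it is a chain of hairpin stems on a single level.  The result
#' always passes [validate_decomposition()].
#'
#' @param spec an [rna_family_spec()].
#' @return an [rna_levels()] template; deterministic given `spec$seed`.
#' @export
sample_template <- function(spec) {
  stopifnot(inherits(spec, "rna_family_spec"))
  with_seed(spec$seed, template_impl(spec))
}

# threading using the current RNG state
thread_impl <- function(template, spec, id) {
  n <- template$n
  ch <- sample(c("A", "C", "G", "U"), n, replace = TRUE)  # loops and padding
  merged <- merge_levels(template)
  pm <- merged$pairs
  for (a in seq_len(nrow(pm))) {
    pp <- if (is.null(spec$pair_probs)) c(0.4, 0.4, 0.2) else spec$pair_probs
    type <- sample(c("GC", "AU", "GU"), 1L, prob = pp)
    duo <- strsplit(type, "")[[1L]]
    if (stats::runif(1) < 0.5) duo <- rev(duo)
    ch[pm[a, 1L]] <- duo[1L]; ch[pm[a, 2L]] <- duo[2L]
  }
  if (spec$mutation_rate > 0) {
    hit <- which(stats::runif(n) < spec$mutation_rate)
    for (b in hit) ch[b] <- sample(setdiff(c("A", "C", "G", "U"), ch[b]), 1L)
  }
  rec <- structure_record(rna_seq(paste(ch, collapse = ""), id = id), merged)
  attr(rec, "template") <- template
  rec
}

#' Thread a complementary sequence onto a template
#'
#' Paired positions receive complementary bases (G-C and A-U at 0.4 each,
#' G-U wobble at 0.2, random orientation), loops and padding receive
#' uniform random bases, and every base is then mutated independently with
#' the spec's mutation rate (to one of the three other bases).
#'
#' @param template an [rna_levels()] template.
#' @param spec the [rna_family_spec()].
#' @param id sequence label.
#' @param seed optional seed; if `NULL` the current RNG state is used.
#' @return an [structure_record()] whose reference structure is the merged
#'   template (attribute `template` keeps the level decomposition).
#' @export
thread_sequence <- function(template, spec, id = "seq", seed = NULL) {
  stopifnot(inherits(template, "rna_levels"), inherits(spec, "rna_family_spec"))
  if (is.null(seed)) thread_impl(template, spec, id)
  else with_seed(seed, thread_impl(template, spec, id))
}

#' Generate a synthetic RNA family dataset
#'
#' Samples one template and threads `n_sequences` sequences onto it.  If
#' `dir` is given, writes `family.fasta`, one BPSEQ file per sequence and
#' `spec.json`; reading the files back reproduces the in-memory records.
#'
#' @param spec an [rna_family_spec()].
#' @param dir optional output directory (created if needed).
#' @return a list of [structure_record()]s, deterministic given
#'   `spec$seed`.
#' @export
make_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "rna_family_spec"))
  records <- with_seed(spec$seed, {
    tpl <- template_impl(spec)
    lapply(seq_len(spec$n_sequences), function(i)
      thread_impl(tpl, spec, sprintf("seq%03d", i)))
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(records, file.path(dir, "family.fasta"))
    for (r in records)
      write_bpseq(r, file.path(dir, paste0(r$sequence$id, ".bpseq")))
    writeLines(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, pretty = TRUE),
               file.path(dir, "spec.json"))
  }
  records
}

#' Split records into disjoint train and test sets by a seeded shuffle
#'
#' @param records list of records.
#' @param n_test number of held-out records.
#' @param seed shuffle seed.
#' @return a list with elements `train` and `test`.
#' @export
split_records <- function(records, n_test, seed = 1L) {
  stopifnot(n_test >= 1L, n_test < length(records))
  ord <- with_seed(seed, sample.int(length(records)))
  list(train = records[ord[seq_len(length(records) - n_test)]],
       test = records[ord[(length(records) - n_test + 1L):length(records)]])
}
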