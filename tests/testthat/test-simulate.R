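test_that("rna_family_spec validates its arguments", {
  expect_error(rna_family_spec(mutation_rate = 0.5), "0.5")
  expect_error(rna_family_spec(loop_len_range = c(2L, 4L)), ">= 3")
  expect_error(rna_family_spec(pseudoknot_prob = 1.5))
  expect_error(rna_family_spec(pair_probs = c(1, 0)))
  expect_error(rna_family_spec(pair_probs = c(-1, 1, 1)))
})

test_that("templates fit the sequence and pass decomposition validation", {
  for (seed in 1:5) {
    spec <- rna_family_spec(pseudoknot_prob = 1, seq_len = 40L, seed = seed)
    tpl <- sample_template(spec)
    expect_length(tpl$levels, 2L)
    expect_equal(nrow(validate_decomposition(tpl)), 0L)
    # every level-2 pair crosses every level-1 pair in an H-type knot
    for (a in seq_len(nrow(tpl$levels[[2]])))
      for (b in seq_len(nrow(tpl$levels[[1]])))
        expect_true(crosses(tpl$levels[[2]][a, ], tpl$levels[[1]][b, ]))
  }
  spec0 <- rna_family_spec(n_stems = 3L, pseudoknot_prob = 0, seq_len = 60L,
                           seed = 2L)
  tpl0 <- sample_template(spec0)
  expect_length(tpl0$levels, 1L)
  expect_equal(nrow(validate_decomposition(tpl0)), 0L)
  expect_error(sample_template(rna_family_spec(seq_len = 10L)), "seq_len")
})

test_that("threading respects complementarity at mutation rate zero", {
  spec <- rna_family_spec(pseudoknot_prob = 0, mutation_rate = 0,
                          seq_len = 40L, seed = 4L)
  tpl <- sample_template(spec)
  rec <- thread_sequence(tpl, spec, seed = 9L)
  ch <- strsplit(rec$sequence$residues, "")[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  pm <- rec$structure$pairs
  for (a in seq_len(nrow(pm))) {
    duo <- paste0(ch[pm[a, 1]], ch[pm[a, 2]])
    expect_true(duo %in% c("GC", "CG", "AU", "UA", "GU", "UG"))
  }
})

test_that("pair_probs steers the threaded pair-type mixture", {
  spec <- rna_family_spec(pseudoknot_prob = 0, mutation_rate = 0,
                          pair_probs = c(1, 0, 0), seq_len = 30L,
                          n_sequences = 20L, seed = 5L)
  recs <- make_dataset(spec)
  for (r in recs) {
    ch <- strsplit(r$sequence$residues, "")[[1]]
    pm <- r$structure$pairs
    for (a in seq_len(nrow(pm)))
      expect_true(paste0(ch[pm[a, 1]], ch[pm[a, 2]]) %in% c("GC", "CG"))
  }
})

test_that("make_dataset is deterministic and file round-trips", {
  spec <- rna_family_spec(n_sequences = 5L, seq_len = 30L, seed = 6L)
  r1 <- make_dataset(spec)
  r2 <- make_dataset(spec)
  expect_equal(lapply(r1, function(r) r$sequence$residues),
               lapply(r2, function(r) r$sequence$residues))
  dir <- withr::local_tempdir()
  make_dataset(spec, dir = dir)
  seqs <- read_fasta(file.path(dir, "family.fasta"))
  expect_length(seqs, 5L)
  expect_equal(seqs[[1]]$residues, r1[[1]]$sequence$residues)
  back <- read_bpseq(file.path(dir, "seq001.bpseq"))
  expect_equal(back$structure$pairs, r1[[1]]$structure$pairs)
  expect_true(file.exists(file.path(dir, "spec.json")))
})

test_that("base composition of unpaired positions is roughly uniform", {
  spec <- rna_family_spec(n_stems = 1L, stem_len_range = c(4L, 4L),
                          pseudoknot_prob = 0, mutation_rate = 0,
                          n_sequences = 40L, seq_len = 40L, seed = 7L)
  recs <- make_dataset(spec)
  paired <- c(recs[[1]]$structure$pairs)
  free <- setdiff(seq_len(40L), paired)
  bases <- unlist(lapply(recs, function(r)
    strsplit(r$sequence$residues, "")[[1]][free]))
  counts <- table(factor(bases, levels = c("A", "C", "G", "U")))
  N <- length(bases)
  # each base should fall within 4 binomial sigmas of N/4
  sigma <- sqrt(N * 0.25 * 0.75)
  expect_true(all(abs(counts - N / 4) < 4 * sigma))
})

test_that("split_records is disjoint, exhaustive and reproducible", {
  spec <- rna_family_spec(n_sequences = 12L, seq_len = 40L, seed = 8L)
  recs <- make_dataset(spec)
  sp <- split_records(recs, n_test = 3L, seed = 2L)
  expect_length(sp$train, 9L)
  expect_length(sp$test, 3L)
  ids <- function(l) vapply(l, function(r) r$sequence$id, "")
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0L)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(recs))
  sp2 <- split_records(recs, n_test = 3L, seed = 2L)
  expect_identical(ids(sp2$test), ids(sp$test))
  expect_error(split_records(recs, n_test = 12L))
})
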