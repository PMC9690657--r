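# bppnet

Neural inference of RNA base-pairing probabilities, with
maximum-expected-accuracy decoding of pseudoknot-free structures and
exact integer-programming decoding of pseudoknots.

## What it does

RNA secondary structure prediction is usually split into two stages:
estimate a matrix of base-pairing probabilities `p_ij`, then decode a
structure from it. Classic tools obtain `p_ij` from a thermodynamic or
grammar partition function; `bppnet` instead learns them directly with
neural networks trained end-to-end against reference structures:

- **Probability models.** A feedforward network over one-hot `k`-mer
  contexts around each candidate pair (`model = "fnn"`), or a recursive
  network that computes inside and outside hidden states for every
  subsequence span (`model = "birnn"`).
- **Decoders.** Nussinov-style dynamic programming maximizing the
  expected gain `sum((gamma + 1) p_ij - 1)` over pseudoknot-free
  structures (`decoder = "nussinov"`), or an IPknot-style hierarchical
  integer program whose levels are pseudoknot-free sets that must
  mutually cross (`decoder = "ipknot"`), solved exactly by a specialized
  branch-and-bound.
- **Training.** A structured SVM: the decoder is run on loss-augmented
  gains to find the worst margin violator, and stochastic subgradient
  descent shrinks the hinge. Everything — forward passes, backprop,
  decoding, training — is implemented in base R plus a small C++ core.

The package also ships readers/writers for FASTA, BPSEQ, CT, extended
dot-bracket and plain-text probability matrices, a seeded generator of
synthetic RNA families, SEN/PPV/F evaluation, and a command-line
interface (`inst/cli/bppnet.R`).

## Worked example

Train on a small synthetic hairpin family and evaluate on held-out
sequences:

```r
library(bppnet)

spec <- rna_family_spec(n_stems = 1L, stem_len_range = c(5L, 5L),
                        loop_len_range = c(4L, 4L), pseudoknot_prob = 0,
                        mutation_rate = 0.05, pair_probs = c(0.9, 0.1, 0),
                        n_sequences = 50L, seq_len = 16L, seed = 1L)
records <- make_dataset(spec)
split <- split_records(records, n_test = 10L, seed = 2L)

fit <- bppnet(split$train, model = "fnn", decoder = "nussinov", gamma = 4,
              k = 11L, hidden = c(32L, 16L), eta = 0.05, epochs = 30L,
              seed = 1L, average = TRUE)
fit
#> Neural base-pairing probability model (structured-SVM trained)
#>   architecture: fnn; decoder: nussinov; gamma: 4
#>   trained on 40 sequence(s), 13 epoch(s); final objective 0.0000

preds <- predict(fit, split$test)
evaluate_dataset(preds, split$test)$aggregate
#>   tp fp fn sen ppv f
#> 1 50  0  0   1   1 1

cat(write_dotbracket(preds[[1]]))
#> .(((((....))))).
```

(Training stops early here because the hinge objective reaches zero on
every example; see the vignette for a full walk-through.)

Pseudoknots use the IP decoder; structures print in extended
dot-bracket, with one bracket alphabet per level:

```r
P <- matrix(0, 30, 30)
P[cbind(1:4, 15:12)] <- 0.9   # stem A
P[cbind(5:8, 30:27)] <- 0.9   # stem B, crossing stem A
P <- P + t(P)
sol <- ipknot_decode(P, gammas = c(1, 3), min_sep = 4L)
write_dotbracket(sol$decomposition)
#> [1] "[[[[((((...]]]]...........))))"
```

## Testing and acceptance checks

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "bppnet", load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The acceptance script re-runs the package's property checks (decoder
exactness against brute-force oracles, gradient checks against finite
differences, loss-augmented reductions, format round-trips, metric
arithmetic) and two seeded training experiments, and writes the measured
quantities as JSON. The training experiments are stochastic by nature;
their robustness across seeds is documented in the methods vignette.

## Layout

- `R/` — structures/containers, I/O, the two models, decoders, SSVM
  training, the `bppnet()` modelling interface, synthetic families,
  evaluation, checkpoints
- `src/decode.cpp` — Nussinov DP and the branch-and-bound IP solver
- `tests/testthat/` — unit and property tests, plus
  `test-acceptance.R` with the acceptance criteria
- `scripts/acceptance.R` — standalone acceptance run against the
  installed package
- `inst/cli/bppnet.R` — `train` / `predict` / `eval` / `fixtures`
  subcommands
- `vignettes/bppnet-methods.Rmd` — model, decoding and training details,
  design decisions and caveats
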