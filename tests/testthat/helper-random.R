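# shared generators for randomized tests

# random symmetric base-pairing probability matrix
random_bpp <- function(n, density = 0.4) {
  P <- matrix(0, n, n)
  ut <- which(upper.tri(P), arr.ind = TRUE)
  on <- runif(nrow(ut)) < density
  if (any(on)) P[ut[on, , drop = FALSE]] <- runif(sum(on))
  P + t(P)
}

# brute-force MEA optimum over all pseudoknot-free structures
best_pk_free <- function(P, gamma, min_sep) {
  best <- 0
  for (pr in enumerate_pk_free_structures(nrow(P), min_sep)) {
    s <- score_structure(P, rna_structure(nrow(P), pr), gamma)
    if (s > best) best <- s
  }
  best
}

# brute-force optimum of the hierarchical IP (Eq 8-11) by assigning every
# candidate pair to a level or dropping it (3^K enumeration for m = 2)
best_ip_oracle <- function(P, gammas, min_sep) {
  n <- nrow(P)
  # all pairs above the loosest level threshold (strict, as in the decoder)
  thr <- 1 / (max(gammas) + 1)
  cand <- list()
  for (i in seq_len(n)) {
    if (i + min_sep <= n) for (j in seq(i + min_sep, n))
      if (P[i, j] > thr) cand[[length(cand) + 1L]] <- c(i, j)
  }
  K <- length(cand)
  m <- length(gammas)
  if (K > 12) stop("oracle instance too large")
  best <- 0
  assign_next <- function(a, lv) {
    if (a > K) {
      sel <- lapply(seq_len(m), function(p) {
        idx <- which(lv == p)
        if (length(idx) == 0) return(pairs_mat())
        do.call(rbind, lapply(idx, function(q) pairs_mat(cand[[q]][1], cand[[q]][2])))
      })
      # Eq 9: one partner per base
      bases <- unlist(lapply(which(lv > 0), function(q) cand[[q]]))
      if (anyDuplicated(bases) > 0) return()
      sc <- 0
      for (p in seq_len(m)) {
        pm <- sel[[p]]
        if (nrow(pm) == 0) next
        # candidate must be above its level threshold
        if (any(P[pm] <= 1 / (gammas[p] + 1))) return()
        # Eq 10: no crossing within a level
        if (nrow(pm) > 1) {
          for (a2 in 1:(nrow(pm) - 1)) for (b2 in (a2 + 1):nrow(pm))
            if (crosses(pm[a2, ], pm[b2, ])) return()
        }
        # Eq 11: every pair crosses something at every lower level
        if (p > 1) {
          for (a2 in seq_len(nrow(pm))) for (q in seq_len(p - 1)) {
            lowers <- sel[[q]]
            ok <- nrow(lowers) > 0 &&
              any(vapply(seq_len(nrow(lowers)),
                         function(b2) crosses(pm[a2, ], lowers[b2, ]), TRUE))
            if (!ok) return()
          }
        }
        sc <- sc + sum(pair_score(P[pm], gammas[p]))
      }
      if (sc > best) best <<- sc
      return()
    }
    for (l in 0:m) { lv[a] <- l; assign_next(a + 1L, lv) }
  }
  assign_next(1L, integer(K))
  best
}
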