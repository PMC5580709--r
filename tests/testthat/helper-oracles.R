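# Independent brute-force oracles, kept free of the package's own code
# paths: plain-R recomputations used to cross-check the implementation.

# All-pairs Hamming scan: index of best hit, its distance, and tie count.
bf_best_hamming <- function(probe, refs) {
  p <- strsplit(probe, "")[[1]]
  d <- vapply(strsplit(refs, ""), function(r) sum(r != p), integer(1))
  best <- min(d)
  list(idx = which.min(d), dist = best, ties = sum(d == best))
}

bf_min_pairwise <- function(seqs) {
  n <- length(seqs)
  best <- nchar(seqs[1])
  sp <- strsplit(seqs, "")
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      best <- min(best, sum(sp[[i]] != sp[[j]]))
  best
}

# Spreadsheet-style recomputation of the scoring chain for one query:
# divide-by-average normalization, pseudocounted log2 GAL/GLU ratio,
# mean / (n-1)-sd standardisation, Poisson error propagation, corrected
# bounds. Deliberately written with explicit loops and base arithmetic.
bf_score <- function(counts, query, pc = 0.5) {
  gal <- counts[, paste0(query, "_GAL")]
  glu <- counts[, paste0(query, "_GLU")]
  m_gal <- sum(gal) / length(gal)
  m_glu <- sum(glu) / length(glu)
  n <- length(gal)
  lr <- numeric(n)
  for (i in seq_len(n))
    lr[i] <- log((gal[i] / m_gal + pc / m_gal) /
                   (glu[i] / m_glu + pc / m_glu)) / log(2)
  mu <- sum(lr) / n
  s <- sqrt(sum((lr - mu)^2) / (n - 1))
  z <- (lr - mu) / s
  delta <- er <- low <- high <- numeric(n)
  for (i in seq_len(n)) {
    delta[i] <- sqrt(1 / (gal[i] + pc) + 1 / (glu[i] + pc)) / log(2)
    er[i] <- if (z[i] == 0) 1 else (delta[i] / s) / abs(z[i])
    low[i] <- (1 - min(er[i], 1)) * z[i]
    high[i] <- (1 + er[i]) * z[i]
  }
  list(log_ratio = lr, z = z, error_rate = er, low = low, high = high,
       sd = s)
}

# Exhaustive enumeration of the hypergeometric upper tail: probability
# that a uniformly random draw of `drawn` genes from the universe hits the
# category at least `hits` times, by enumerating all draws with combn.
bf_enrich_p <- function(hits, category, universe, drawn) {
  draws <- combn(length(universe), drawn)
  in_cat <- universe %in% category
  sum(apply(draws, 2, function(ix) sum(in_cat[ix]) >= hits)) /
    ncol(draws)
}

# Small fixture: a deterministic catalog plus a design for the given
# queries, with FASTQs written under `dir`.
make_sim_fixture <- function(n_strains = 50, queries = "Q1", depth = 1000,
                             error = 0, seed = 11,
                             dir = tempfile("fixture"), ...) {
  cfg <- sim_config(n_strains = n_strains, n_suppressors = 5,
                    n_enhancers = 5, depth = depth,
                    seq_error_rate = error, seed = seed, ...)
  simulate_screen(cfg, queries = queries, outdir = dir)
}
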