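# Independent oracles used across test files. These deliberately use naive
# enumeration / closed forms, never the package's own code paths.

# Brute-force SNP grouping: enumerate every (offset, start) pair directly.
brute_groups <- function(n_snps, group_size = 100,
                         offsets = c(1, 21, 41, 61, 81), min_size = 80) {
  out <- list()
  for (o in offsets) {
    s <- o
    while (s <= n_snps) {
      e <- min(s + group_size - 1, n_snps)
      if (e - s + 1 >= min_size) {
        out[[length(out) + 1]] <- c(first = s, last = e)
      }
      s <- s + group_size
    }
  }
  do.call(rbind, out)
}

# Brute-force transitive merge of closed intervals: grow components by
# repeated pairwise checks until a fixed point.
brute_components <- function(lo, hi) {
  n <- length(lo)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (lo[i] <= hi[j] && lo[j] <= hi[i] && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Brute-force contiguous correlation blocks: maximal left-to-right runs in
# which every pair exceeds the threshold.
brute_blocks <- function(corr, threshold) {
  n <- nrow(corr)
  starts <- integer(0); ends <- integer(0)
  s <- 1
  while (s <= n) {
    e <- s
    while (e < n) {
      cand <- s:(e + 1)
      pairs <- utils::combn(cand, 2)
      if (all(corr[cbind(pairs[1, ], pairs[2, ])] > threshold)) e <- e + 1
      else break
    }
    starts <- c(starts, s); ends <- c(ends, e)
    s <- e + 1
  }
  data.frame(start = starts, end = ends)
}

# Batch-means Monte-Carlo standard error of a chain's mean.
mcse <- function(x, n_batch = 25) {
  n <- length(x)
  b <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch),
                  function(i) mean(x[((i - 1) * b + 1):(i * b)]), numeric(1))
  stats::sd(means) / sqrt(n_batch)
}

# Hand evaluation of the window-variance statistic on raw draws:
# per draw s and group J, var across cows of sum_{m in J} g_lm a_ms;
# percent = 100 * mean_s(num) / mean_s(var across cows of total gEBV).
brute_percent_varA <- function(Gc, A, J) {
  ndraw <- nrow(A); ncow <- nrow(Gc)
  num <- den <- numeric(ndraw)
  for (s in seq_len(ndraw)) {
    gg <- numeric(ncow); tt <- numeric(ncow)
    for (l in seq_len(ncow)) {
      for (m in J) gg[l] <- gg[l] + Gc[l, m] * A[s, m]
      for (m in seq_len(ncol(Gc))) tt[l] <- tt[l] + Gc[l, m] * A[s, m]
    }
    num[s] <- stats::var(gg); den[s] <- stats::var(tt)
  }
  100 * mean(num) / mean(den)
}

# Small posterior_samples stand-in built from explicit draw matrices.
fake_samples <- function(snp, cow_a, var, wavenumber = 1000) {
  structure(list(snp = snp, cow_a = cow_a, var = var,
                 wavenumber = wavenumber),
            class = "posterior_samples")
}

# Shared tiny simulation used by several files (cheap, deterministic).
tiny_sim <- function(seed = 11, n_cows = 120, ...) {
  cfg <- sim_config(n_cows = n_cows, n_herds = 8, n_chromosomes = 2,
                    snps_per_chromosome = 100,
                    records_per_cow_range = c(2, 4), seed = seed, ...)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_spectra(cfg, geno)
  list(cfg = cfg, geno = geno, spectra = sim$spectra, truth = sim$truth)
}
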