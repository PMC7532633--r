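# Shared fixtures and independent oracles, all built in code.

# Build a validated methylome tibble from bare site records.
make_methylome <- function(chrom, pos, level, coverage, chrom_sizes) {
  meth <- tibble::tibble(
    chrom = chrom, pos = as.numeric(pos), strand = "+", context = "CpG",
    level = level, coverage = as.numeric(coverage)
  )
  meth$level[meth$coverage == 0] <- 0
  meth$meth <- round(meth$level * meth$coverage)
  attr(meth, "chrom_sizes") <- chrom_sizes
  meth
}

# Build a bin tibble directly (bypasses bin_methylome) for HMM-level tests.
make_bins <- function(m, n, bin_size = 1000, chrom = "chr1", n_cpgs = NULL) {
  L <- length(m)
  bins <- tibble::tibble(
    chrom = chrom, start = (seq_len(L) - 1) * bin_size,
    end = seq_len(L) * bin_size, m = as.numeric(m), n = as.numeric(n),
    n_cpgs = if (is.null(n_cpgs)) as.integer(pmin(n, 1)) else n_cpgs
  )
  attr(bins, "bin_size") <- bin_size
  attr(bins, "chrom_sizes") <- stats::setNames(L * bin_size, chrom[1])
  bins
}

rbetabinom <- function(k, size, alpha, beta) {
  stats::rbinom(k, size, stats::rbeta(k, alpha, beta))
}

# Simulate a binned observation sequence directly from a known 2-state HMM:
# an independent generative route from the genome simulator.
sim_hmm_bins <- function(L, n_obs = 40, means = c(0.45, 0.85), precision = 10,
                         diag = 0.99, seed = 1) {
  set.seed(seed)
  A <- matrix(c(diag, 1 - diag, 1 - diag, diag), 2, 2, byrow = TRUE)
  st <- integer(L)
  st[1] <- sample(1:2, 1)
  for (t in 2:L) {
    st[t] <- if (stats::runif(1) < A[st[t - 1], st[t - 1]]) st[t - 1] else 3L - st[t - 1]
  }
  mu <- means[st]
  m <- rbetabinom(L, n_obs, mu * precision, (1 - mu) * precision)
  list(bins = make_bins(m, rep(n_obs, L)), states = st)
}

# Exact forward-backward oracle: enumerate all 2^L state paths.
enum_posterior <- function(logB, pi, A) {
  L <- nrow(logB)
  paths <- as.matrix(expand.grid(rep(list(1:2), L)))
  logp <- apply(paths, 1L, function(s) {
    lp <- log(pi[s[1]]) + logB[1, s[1]]
    if (L > 1) {
      for (t in 2:L) lp <- lp + log(A[s[t - 1], s[t]]) + logB[t, s[t]]
    }
    lp
  })
  mx <- max(logp)
  w <- exp(logp - mx)
  loglik <- mx + log(sum(w))
  w <- w / sum(w)
  post_pmd <- vapply(seq_len(L), function(t) sum(w[paths[, t] == 1L]), numeric(1))
  list(posterior_pmd = post_pmd, loglik = loglik)
}

# Distance from each called domain edge to the nearest true edge.
edge_errors <- function(called, truth) {
  e_called <- c(called$start, called$end)
  e_true <- c(truth$start, truth$end)
  vapply(e_called, function(x) min(abs(x - e_true)), numeric(1))
}
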