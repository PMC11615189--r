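# Independent oracles used across the suite. These enumerate or evaluate the
# target quantity directly and stay independent of the code paths they check.

# Two-sided binomial p, minimum-likelihood convention: sum of probabilities
# of all outcomes no more likely than the observed one. A (1 + 1e-7)
# relative tie tolerance collects outcomes whose probabilities are equal up
# to float rounding (dbinom(k) and dbinom(n - k) at p = 0.5 differ in the
# last bits).
oracle_binom_two_sided <- function(x, n, p = 0.5) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= dbinom(x, n, p) * (1 + 1e-7)])
}

# Upper-tail binomial p: P(X >= x).
oracle_binom_upper <- function(x, n, p) {
  if (x <= 0) return(1)
  sum(dbinom(x:n, n, p))
}

# One-sided (enrichment) Fisher p for the 2x2 table [[tp, fn], [fp, tn]]
# by direct enumeration of all tables with the same margins, probabilities
# computed from log binomial coefficients.
oracle_fisher_greater <- function(tp, fn, fp, tn) {
  K <- tp + fn          # experimental positives
  n <- tp + fp          # predicted positives
  N <- tp + fn + fp + tn
  ks <- max(0, n - (N - K)):min(K, n)
  pr <- exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n))
  sum(pr[ks >= tp])
}

# Step-up Benjamini-Hochberg reference: largest k with p_(k) <= k/m * alpha
# rejected; returns adjusted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Posterior crossing of a two-component Gaussian mixture on a brute-force
# grid (no bisection; resolution 1e-4).
oracle_posterior_crossing <- function(means, sds, weights, cut = 0.95) {
  grid <- seq(means[1] - 4 * sds[1], means[2] + 4 * sds[2], by = 1e-4)
  d1 <- weights[1] * dnorm(grid, means[1], sds[1])
  d2 <- weights[2] * dnorm(grid, means[2], sds[2])
  grid[which(d2 / (d1 + d2) >= cut)[1]]
}

# Brute-force re-application of the printed copy-number state rule list.
oracle_cn_state <- function(cn_major, cn_minor, ploidy) {
  tot <- cn_major + cn_minor
  rp <- round(ploidy)
  state <- "neutral"
  if (tot > rp) state <- "weak gain"
  if (tot > 1.5 * rp) state <- "medium gain"
  if (tot > 2.5 * rp) state <- "strong gain"
  if (tot < rp) state <- "shallow loss"
  if (tot < 0.5 * rp) state <- "loss"
  ratio <- cn_major / tot
  balance <- if (cn_minor > 0 && cn_major == cn_minor) "balance"
  else if (cn_major > cn_minor && ratio <= 2 / 3) "weak imbalance"
  else if (cn_major > cn_minor && ratio > 2 / 3) "strong imbalance"
  else "balance"
  list(state = state, balance = balance, loh = cn_minor == 0)
}

# Brute-force TMM label from the printed rules.
oracle_tmm_label <- function(mycn_amp, tert_re, z_above, tlr_above) {
  tert_high <- z_above && !mycn_amp && !tert_re
  ctm <- mycn_amp || tert_re || tert_high
  if (ctm && tlr_above) "Mix"
  else if (ctm) "CTM"
  else if (tlr_above) "ALT"
  else "None"
}

# Exact power of the two-sided minlike binomial AEI test at raw level alpha.
oracle_binom_power <- function(n, p_true, alpha = 0.05) {
  pv <- vapply(0:n, oracle_binom_two_sided, numeric(1), n = n)
  sum(dbinom(which(pv < alpha) - 1, n, p_true))
}

# Small default cohort used by several suites; moderate size so the whole
# file stays fast.
tiny_config <- function(seed = 1, n_samples = 8, n_chromosomes = 6, ...) {
  sim_config(n_samples = n_samples, n_chromosomes = n_chromosomes,
             snps_per_chrom = 120, genes_per_chrom = 8,
             reads_per_sample = 300, terra_fragments = 150,
             atrx_bins = 120, seed = seed, ...)
}
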