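#' Expected BAF and LogR under a purity/ploidy mixture model
#'
#' Forward model for the observed B-allele frequency and coverage log-ratio
#' of a tumor segment carrying `n_a` copies of the major (A) and `n_b` copies
#' of the minor (B) allele, in a sample of purity `purity` mixed with diploid
#' normal cells, relative to an average tumor ploidy `ploidy`:
#'
#' \deqn{BAF = \frac{(1-\rho) + \rho n_B}{2(1-\rho) + \rho(n_A+n_B)}}
#' \deqn{LogR = \gamma \log_2 \frac{2(1-\rho) + \rho(n_A+n_B)}
#'                                 {2(1-\rho) + \rho\psi}}
#'
#' This is the generative counterpart of the allele-specific copy-number
#' inversion performed by [estimate_allele_cn()].
#'
#' @param n_a,n_b Integer copy numbers of the major and minor allele
#'   (`n_a >= n_b >= 0`). Vectorized.
#' @param purity Tumor cell fraction `rho`, in (0, 1].
#' @param ploidy Average tumor copy number `psi` (> 0).
#' @param gamma Platform coverage-response coefficient; 1 for WGS.
#'
#' @return A tibble with columns `baf` (minor-allele frequency, <= 0.5) and
#'   `logr`.
#' @examples
#' forward_baf_logr(1, 1, purity = 1, ploidy = 2)   # (0.5, 0)
#' forward_baf_logr(2, 1, purity = 1, ploidy = 2)   # (1/3, log2(1.5))
#' @export
forward_baf_logr <- function(n_a, n_b, purity, ploidy, gamma = 1) {
  if (any(purity <= 0) || any(purity > 1)) {
    abort("`purity` must be in (0, 1]", class = "nbd_domain_error")
  }
  if (any(ploidy <= 0)) {
    abort("`ploidy` must be positive", class = "nbd_domain_error")
  }
  if (any(n_b > n_a) || any(n_b < 0)) {
    abort("require n_a >= n_b >= 0", class = "nbd_domain_error")
  }
  tot <- n_a + n_b
  denom <- 2 * (1 - purity) + purity * tot
  baf <- ((1 - purity) + purity * n_b) / denom
  logr <- gamma * log2(denom / (2 * (1 - purity) + purity * ploidy))
  tibble(baf = baf, logr = logr)
}

#' Posterior-probability threshold of a two-component Gaussian mixture
#'
#' Smallest value `z` at which the posterior probability of the higher-mean
#' component reaches `posterior_cut`, located on a fine grid between the
#' component means (extended by 4 SDs) and refined by bisection. Used to turn
#' a fitted TERT-expression mixture into a TERT-high cutoff.
#'
#' @param means,sds,weights Component parameters; components are sorted by
#'   mean internally, weights must sum to 1.
#' @param posterior_cut Required posterior of the high component.
#' @return The threshold z (scalar).
#' @examples
#' mixture_posterior_threshold(c(-0.5, 1.5), c(0.3, 0.3), c(0.7, 0.3))
#' @export
mixture_posterior_threshold <- function(means, sds, weights,
                                        posterior_cut = 0.95) {
  stopifnot(length(means) == 2, length(sds) == 2, length(weights) == 2,
            all(sds > 0), abs(sum(weights) - 1) < 1e-6)
  o <- order(means)
  means <- means[o]; sds <- sds[o]; weights <- weights[o]
  post_hi <- function(z) {
    d1 <- weights[1] * dnorm(z, means[1], sds[1])
    d2 <- weights[2] * dnorm(z, means[2], sds[2])
    d2 / (d1 + d2)
  }
  lo <- means[1] - 4 * sds[1]
  hi <- means[2] + 4 * sds[2]
  grid <- seq(lo, hi, length.out = 4096L)
  p <- post_hi(grid)
  idx <- which(p >= posterior_cut)
  if (length(idx) == 0L) {
    abort("posterior never reaches `posterior_cut` on the search grid",
          class = "nbd_numerical_error")
  }
  i <- idx[1]
  if (i == 1L) return(grid[1])
  # bisection between the last grid point below and the first at/above the cut
  a <- grid[i - 1]; b <- grid[i]
  for (k in 1:60) {
    m <- (a + b) / 2
    if (post_hi(m) >= posterior_cut) b <- m else a <- m
  }
  b
}
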