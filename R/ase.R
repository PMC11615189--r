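# Allele-specific expression: site filtering, bi-allelic testing, reference
# bias, haplotype aggregation, allelic expression imbalance (AEI) calling and
# cohort-level per-gene summaries.

#' Filter allelic RNA count sites
#'
#' Removes sites with fewer than `min_total` total allelic reads or fewer
#' than `min_allelic` reads on an allele. The default reads "less than 2
#' allelic reads" strictly: both alleles must reach `min_allelic`
#' (`rule = "each"`); `rule = "either"` requires it of one allele only.
#'
#' @param sites Data frame with integer columns `refCount`, `altCount`.
#' @param min_total Minimum `refCount + altCount`.
#' @param min_allelic Minimum per-allele read count.
#' @param rule Apply `min_allelic` to `"each"` allele or `"either"` allele.
#' @return The retained rows; attribute `dropped` holds the removed count.
#' @examples
#' filter_sites(tibble::tibble(refCount = c(6, 7), altCount = c(2, 1)))
#' @export
filter_sites <- function(sites, min_total = 8, min_allelic = 2,
                         rule = c("each", "either")) {
  rule <- match.arg(rule)
  s <- as_tibble(sites)
  if (!all(c("refCount", "altCount") %in% names(s))) {
    input_error("`sites` must have columns refCount, altCount")
  }
  tot <- s$refCount + s$altCount
  al <- if (rule == "each") pmin(s$refCount, s$altCount)
        else pmax(s$refCount, s$altCount)
  keep <- tot >= min_total & al >= min_allelic
  out <- s[keep, , drop = FALSE]
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Flag bi-allelic sites by an upper-tail binomial noise test
#'
#' The sample-level sequencing-noise rate is estimated as
#' `p0 = sum(otherBases) / sum(rawDepth)` over all sites of the sample. Each
#' site's minimum allele count is then tested against Binomial(ref + alt,
#' p0), upper tail: a minimum allele count incompatible with noise marks the
#' site as bi-allelic (heterozygous signal on both alleles). P-values are
#' Benjamini-Hochberg adjusted across sites; sites rejected at
#' `alpha_fdr` are flagged.
#'
#' @param sites Data frame of one sample's sites with columns `refCount`,
#'   `altCount`, `otherBases`, `rawDepth`.
#' @param alpha_fdr FDR level for the bi-allelic flag.
#' @param p0_floor Noise floor substituted (with a warning) when the
#'   estimated noise rate is 0.
#' @return Input tibble with `p_biallelic`, `q_biallelic` and logical
#'   `biallelic` appended; attribute `p0` holds the noise rate used.
#' @examples
#' s <- tibble::tibble(refCount = 20, altCount = 10, otherBases = 1,
#'                     rawDepth = 31)
#' biallelic_test(s)
#' @export
biallelic_test <- function(sites, alpha_fdr = 0.05, p0_floor = 1e-4) {
  s <- as_tibble(sites)
  need <- c("refCount", "altCount", "otherBases", "rawDepth")
  if (!all(need %in% names(s))) {
    input_error(paste("`sites` must have columns", paste(need, collapse = ", ")))
  }
  p0 <- sum(s$otherBases) / sum(s$rawDepth)
  if (!is.finite(p0) || p0 <= 0) {
    warn(sprintf("noise rate is 0; using floor %g", p0_floor))
    p0 <- p0_floor
  }
  m <- pmin(s$refCount, s$altCount)
  n <- s$refCount + s$altCount
  p <- pbinom(m - 1, n, p0, lower.tail = FALSE)   # P(X >= m)
  q <- p.adjust(p, method = "BH")
  out <- mutate(s, p_biallelic = p, q_biallelic = q,
                biallelic = q < alpha_fdr)
  attr(out, "p0") <- p0
  out
}

#' Reference-allele mapping bias
#'
#' Mean reference allele fraction `ref / (ref + alt)` over ASE sites lying
#' in copy-balanced segments of the sample, where the true allelic ratio is
#' 1:1 and any systematic departure from 0.5 measures reference mapping
#' bias. The estimate is reported for diagnostics; the AEI null stays at 0.5
#' unless the bias-corrected null is requested in [aei_test()].
#'
#' @param sites Data frame of qualifying sites (already restricted to
#'   balanced copy-number regions) with columns `refCount`, `altCount`.
#' @return Scalar mean reference fraction, or `NA` (with a warning) when no
#'   site qualifies.
#' @examples
#' estimate_ref_bias(tibble::tibble(refCount = c(50, 54),
#'                                  altCount = c(50, 46)))
#' @export
estimate_ref_bias <- function(sites) {
  s <- as_tibble(sites)
  if (nrow(s) == 0L) {
    warn("no qualifying sites; reference bias is NA")
    return(NA_real_)
  }
  mean(s$refCount / (s$refCount + s$altCount))
}

#' Aggregate phased site counts to gene haplotype counts
#'
#' Sums allelic counts of the allele phased to haplotype A (and B) across
#' the exonic heterozygous sites of each gene. The `haplotype` column uses
#' the phased-genotype convention: `"0|1"` puts the reference allele on
#' haplotype A, `"1|0"` the alternative allele. Unphased sites are excluded
#' with a warning; genes with fewer than `min_counts` total haplotype counts
#' are dropped.
#'
#' @param sites Data frame with columns `gene`, `refCount`, `altCount`,
#'   `haplotype` (and optionally `sample`, grouped over when present).
#' @param min_counts Minimum `A + B` per gene (and sample).
#' @return Tibble with columns (`sample`,) `gene`, `a`, `b`, `n_sites`,
#'   `ase_ratio = max(A, B) / (A + B)`.
#' @examples
#' s <- tibble::tibble(gene = "g1", refCount = c(10, 3), altCount = c(5, 12),
#'                     haplotype = c("0|1", "1|0"))
#' aggregate_haplotypes(s, min_counts = 10)
#' @export
aggregate_haplotypes <- function(sites, min_counts = 10) {
  s <- as_tibble(sites)
  need <- c("gene", "refCount", "altCount", "haplotype")
  if (!all(need %in% names(s))) {
    input_error(paste("`sites` must have columns", paste(need, collapse = ", ")))
  }
  phased <- s$haplotype %in% c("0|1", "1|0")
  if (any(!phased)) {
    warn(sprintf("%d unphased sites excluded", sum(!phased)))
    s <- s[phased, , drop = FALSE]
  }
  s$a_count <- ifelse(s$haplotype == "0|1", s$refCount, s$altCount)
  s$b_count <- ifelse(s$haplotype == "0|1", s$altCount, s$refCount)
  keys <- intersect(c("sample", "gene"), names(s))
  out <- s |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(a = sum(.data$a_count), b = sum(.data$b_count),
              n_sites = dplyr::n(), .groups = "drop") |>
    filter(.data$a + .data$b >= min_counts) |>
    mutate(ase_ratio = pmax(.data$a, .data$b) / (.data$a + .data$b))
  out
}

# Exact two-sided binomial p at null prob p0, minimum-likelihood convention:
# the sum of probabilities of all outcomes no more likely than the observed
# one (this is stats::binom.test's definition; kept as a thin wrapper so the
# convention is stated once).
binom_p_two_sided <- function(x, n, p0 = 0.5) {
  purrr::map2_dbl(x, n, function(xi, ni) {
    binom.test(xi, ni, p = p0, alternative = "two.sided")$p.value
  })
}

#' Test genes for allelic expression imbalance (AEI)
#'
#' Exact two-sided binomial test of the haplotype-A count against
#' Binomial(A + B, 0.5) per gene (and sample), with Benjamini-Hochberg
#' adjustment pooled across all observations; AEI is called at
#' `q < alpha_fdr`. The two-sided p-value is the minimum-likelihood
#' convention: the sum of probabilities of all outcomes at most as likely as
#' the observed count. Setting `null_prob` to a reference-bias estimate
#' re-centers the null.
#'
#' @param genes Data frame with integer columns `a`, `b` (haplotype counts,
#'   `a + b >= 10`).
#' @param alpha_fdr FDR level for the AEI flag.
#' @param null_prob Null success probability (0.5 unless bias-correcting).
#' @return Input tibble with `p_aei`, `q_aei` and logical `aei` appended.
#' @examples
#' aei_test(tibble::tibble(a = c(25, 22), b = c(25, 8)))
#' @export
aei_test <- function(genes, alpha_fdr = 0.05, null_prob = 0.5) {
  g <- as_tibble(genes)
  if (!all(c("a", "b") %in% names(g))) {
    input_error("`genes` must have columns a, b")
  }
  p <- binom_p_two_sided(g$a, g$a + g$b, null_prob)
  q <- p.adjust(p, method = "BH")
  mutate(g, p_aei = p, q_aei = q, aei = q < alpha_fdr)
}

#' Per-gene cohort summary of allelic expression imbalance
#'
#' Summarizes AEI calls across samples: per gene, the fraction of
#' informative samples with AEI and the mean ASE ratio. When an annotated
#' imprinted-gene set is supplied, enrichment of imprinted genes among high
#' AEI-frequency / high mean-ratio genes is tested by one-sided Wilcoxon
#' rank-sum tests.
#'
#' @param gene_ase Data frame of per gene x sample AEI results with columns
#'   `gene`, `ase_ratio`, `aei`.
#' @param imprinted Optional character vector of imprinted gene ids.
#' @return Tibble per gene: `gene`, `n_informative`, `aei_freq`,
#'   `mean_ratio`. With an annotation, attribute `enrichment` holds a tibble
#'   of one-sided rank-sum p-values for both statistics.
#' @examples
#' ga <- tibble::tibble(gene = "g1", ase_ratio = c(0.9, 0.95),
#'                      aei = c(TRUE, TRUE))
#' gene_ase_summary(ga)
#' @export
gene_ase_summary <- function(gene_ase, imprinted = NULL) {
  g <- as_tibble(gene_ase)
  need <- c("gene", "ase_ratio", "aei")
  if (!all(need %in% names(g))) {
    input_error(paste("`gene_ase` must have columns",
                      paste(need, collapse = ", ")))
  }
  out <- g |>
    group_by(.data$gene) |>
    summarise(n_informative = dplyr::n(),
              aei_freq = mean(.data$aei),
              mean_ratio = mean(.data$ase_ratio), .groups = "drop")
  if (!is.null(imprinted) && length(imprinted) > 0) {
    is_imp <- out$gene %in% imprinted
    if (any(is_imp) && any(!is_imp)) {
      enr <- purrr::map_dfr(c("aei_freq", "mean_ratio"), function(v) {
        tibble(statistic = v,
               p_enrichment = wilcox.test(out[[v]][is_imp], out[[v]][!is_imp],
                                          alternative = "greater",
                                          exact = FALSE)$p.value)
      })
      attr(out, "enrichment") <- enr
    }
  }
  out
}
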