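# Structural-event detection and region-level association scans: ATRX exon
# deletions from binned coverage, bootstrapped whole-genome-doubling calls,
# WGD enrichment across TMM groups, and the arm-level ALT / binned survival
# generalized-linear-model scans.

#' Detect ATRX exon deletions from binned coverage
#'
#' Fits a two-component Gaussian mixture to the per-bin coverage signal
#' `s_i = log2(n_iT / n_iN)` over the gene. A deletion is called when the
#' two cluster means differ by at least `mean_gap` signal units and the
#' smaller cluster's weight is at least `min_prop` of the larger cluster's
#' (deleted and intact exons each need visible support).
#'
#' @param bins Data frame with either a `signal` column or normalized count
#'   columns `norm_tumor`, `norm_normal` from which the signal is computed.
#' @param mean_gap Minimum cluster mean difference (log2 units).
#' @param min_prop Minimum small/large cluster weight ratio.
#' @param seed Seed for the EM initialization.
#' @return One-row tibble: `deleted`, `mean_lo`, `mean_hi`, `weight_lo`,
#'   `weight_hi`, `gap`, `note`.
#' @examples
#' s <- c(rnorm(60, 0), rnorm(40, -2, 0.2))
#' detect_atrx_deletion(tibble::tibble(signal = s))
#' @export
detect_atrx_deletion <- function(bins, mean_gap = 1.5, min_prop = 0.10,
                                 seed = 1L) {
  b <- as_tibble(bins)
  if (!"signal" %in% names(b)) {
    if (!all(c("norm_tumor", "norm_normal") %in% names(b))) {
      input_error("`bins` needs `signal` or `norm_tumor`/`norm_normal`")
    }
    b$signal <- log2(b$norm_tumor / b$norm_normal)
  }
  s <- b$signal[is.finite(b$signal)]
  if (length(s) < 50) input_error("need >= 50 bins with finite signal")
  if (sd(s) < 1e-10) {
    return(tibble(deleted = FALSE, mean_lo = mean(s), mean_hi = mean(s),
                  weight_lo = NA_real_, weight_hi = NA_real_, gap = 0,
                  note = "degenerate signal (zero variance)"))
  }
  fit <- with_seed(seed, mclust::Mclust(s, G = 2, verbose = FALSE))
  if (is.null(fit)) {
    fit <- with_seed(seed, mclust::Mclust(s, G = 2, modelNames = "E",
                                          verbose = FALSE))
  }
  if (is.null(fit)) {
    abort("mixture fit failed on coverage signal",
          class = "nbd_numerical_error")
  }
  means <- as.numeric(fit$parameters$mean)
  w <- as.numeric(fit$parameters$pro)
  o <- order(means)
  means <- means[o]; w <- w[o]
  gap <- diff(means)
  ratio <- min(w) / max(w)
  tibble(deleted = gap >= mean_gap & ratio >= min_prop,
         mean_lo = means[1], mean_hi = means[2],
         weight_lo = w[1], weight_hi = w[2], gap = gap, note = NA_character_)
}

#' Bootstrap a whole-genome-doubling caller over chromosomes
#'
#' Single-sample WGD callers that look for a doubling on the shortest
#' evolutionary path can be conservative, because a doubling followed by
#' losses is also explained by gains. The bootstrap resamples the 22
#' chromosomes with replacement `n_boot` times, applies the caller to each
#' resampled profile, and marks the sample WGD-positive when at least
#' `frac_cut` of the runs call a doubling.
#'
#' @param segments One sample's copy-number segments: `chrom`, `start`,
#'   `end`, `cn_major`, `cn_minor`.
#' @param caller Function `segments -> logical(1)`; defaults to
#'   [default_wgd_caller()].
#' @param n_boot Number of bootstrap profiles.
#' @param frac_cut Positive-call fraction required.
#' @param seed Integer seed (resampling is seed-deterministic).
#' @return One-row tibble: `wgd`, `frac_positive`, `n_boot`.
#' @examples
#' seg <- tibble::tibble(chrom = 1:22, start = 1, end = 1e6,
#'                       cn_major = 2, cn_minor = 2)
#' wgd_bootstrap(seg, seed = 1)
#' @export
wgd_bootstrap <- function(segments, caller = default_wgd_caller,
                          n_boot = 100, frac_cut = 0.05, seed = 1L) {
  seg <- as_tibble(segments)
  need <- c("chrom", "start", "end", "cn_major", "cn_minor")
  if (!all(need %in% names(seg))) {
    input_error(paste("`segments` must have columns",
                      paste(need, collapse = ", ")))
  }
  chroms <- sort(unique(seg$chrom))
  by_chrom <- split(seg, seg$chrom)
  pos <- with_seed(seed, {
    purrr::map_lgl(seq_len(n_boot), function(b) {
      draw <- sample(as.character(chroms), length(chroms), replace = TRUE)
      prof <- dplyr::bind_rows(by_chrom[draw], .id = "draw_id")
      res <- tryCatch(isTRUE(caller(prof)), error = function(e) {
        abort(sprintf("WGD caller failed on bootstrap %d: %s", b,
                      conditionMessage(e)),
              class = "nbd_numerical_error")
      })
      res
    })
  })
  tibble(wgd = mean(pos) >= frac_cut, frac_positive = mean(pos),
         n_boot = n_boot)
}

#' Default single-profile whole-genome-doubling caller
#'
#' Positive when at least half of the profile's genome length carries a
#' total copy number of 4 or more with a major allele count of at least 2.
#' This length-based criterion is a replaceable stand-in for
#' evolutionary-distance WGD callers; [wgd_bootstrap()] accepts any caller.
#'
#' @param segments Segments with `start`, `end`, `cn_major`, `cn_minor`.
#' @return Logical scalar.
#' @export
default_wgd_caller <- function(segments) {
  len <- segments$end - segments$start + 1
  hit <- (segments$cn_major + segments$cn_minor) >= 4 & segments$cn_major >= 2
  sum(len[hit]) / sum(len) >= 0.5
}

#' Fisher enrichment of whole-genome doubling across groups
#'
#' For each group (e.g. TMM label), compares the observed number of
#' WGD-positive samples with the expectation under the cohort-wide WGD rate,
#' `round(n_group * total_wgd / N)`, and tests the 2x2 table (WGD x group
#' membership) by Fisher's exact test.
#'
#' @param data Data frame with a group column and a logical `wgd` column.
#' @param group Name of the group column.
#' @param alternative Sidedness of the Fisher test.
#' @return Tibble per group: `group`, `n`, `observed`, `expected`, `p`.
#' @examples
#' d <- tibble::tibble(tmm = rep(c("ALT", "None"), c(20, 51)),
#'                     wgd = rep(c(TRUE, FALSE, TRUE, FALSE),
#'                               c(2, 18, 26, 25)))
#' fisher_wgd_enrichment(d, group = "tmm")
#' @export
fisher_wgd_enrichment <- function(data, group = "tmm_label",
                                  alternative = c("two.sided", "greater",
                                                  "less")) {
  alternative <- match.arg(alternative)
  d <- as_tibble(data)
  if (!all(c(group, "wgd") %in% names(d))) {
    input_error(sprintf("`data` must have columns `%s` and `wgd`", group))
  }
  n_tot <- nrow(d)
  wgd_tot <- sum(d$wgd)
  groups <- unique(d[[group]])
  if (length(groups) < 2) input_error("need >= 2 groups")
  purrr::map_dfr(groups, function(g) {
    ing <- d[[group]] == g
    n_g <- sum(ing)
    if (n_g == 0) return(NULL)
    obs <- sum(d$wgd[ing])
    tab <- matrix(c(obs, n_g - obs,
                    wgd_tot - obs, (n_tot - n_g) - (wgd_tot - obs)), 2)
    tibble(group = g, n = n_g, observed = obs,
           expected = round(n_g * wgd_tot / n_tot),
           p = fisher.test(tab, alternative = alternative)$p.value)
  })
}

# Nested-GLM chi-squared scan shared by the arm and bin associations; one
# test per region column of `region_values`. The Rao score statistic is used
# for its near-exact small-sample tail calibration in logistic models (the
# deviance LRT is mildly anti-conservative at a few dozen events).
glm_lrt_scan <- function(region_values, outcome, covariates, family) {
  covars <- names(covariates)
  df0 <- dplyr::bind_cols(tibble(.y = outcome), covariates)
  const <- covars[purrr::map_lgl(covars,
                                 ~ length(unique(df0[[.x]])) < 2)]
  if (length(const)) {
    warn(paste("dropping constant covariate(s):",
               paste(const, collapse = ", ")))
    covars <- setdiff(covars, const)
  }
  rhs0 <- if (length(covars)) paste(covars, collapse = " + ") else "1"
  purrr::map_dfr(names(region_values), function(rg) {
    df <- df0
    df$.x <- region_values[[rg]]
    df <- df[complete.cases(df), , drop = FALSE]
    if (nrow(df) < 10 || sd(df$.x) < 1e-12 ||
        length(unique(df$.y)) < 2) {
      return(tibble(region = rg, estimate = NA_real_, p = NA_real_,
                    separated = NA))
    }
    m0 <- suppressWarnings(glm(as.formula(paste(".y ~", rhs0)),
                               data = df, family = family))
    m1 <- suppressWarnings(glm(as.formula(paste(".y ~", rhs0, "+ .x")),
                               data = df, family = family))
    mu <- stats::fitted(m1)
    separated <- any(mu > 1 - 1e-8 | mu < 1e-8) || !m1$converged
    p <- anova(m0, m1, test = "Rao")$`Pr(>Chi)`[2]
    tibble(region = rg, estimate = coef(m1)[[".x"]], p = p,
           separated = separated)
  })
}

#' Arm-level association of copy-number LogR with ALT status
#'
#' Per chromosome arm, a nested-model chi-squared test (Rao score) between
#' logistic models of the binary ALT outcome with and without the arm's
#' length-weighted copy-number LogR, controlling for the supplied covariates
#' (MYCN amplification, ATRX alteration, age, sex, cohort, purity, ploidy).
#' P-values are Bonferroni-corrected across arms; arms below 0.05
#' family-wise error are significant. Samples of the Mix TMM group must be
#' excluded upstream. Arms with complete separation are flagged in the
#' `separated` column (the deviance-based p is still reported).
#'
#' @param arm_logr Data frame, one row per sample: a logical `alt` column
#'   plus one numeric column per arm (e.g. `"11q"`).
#' @param covariates Data frame of per-sample covariates, same row order.
#' @param alpha FWER level.
#' @return Tibble per arm: `region`, `estimate`, `direction`, `p`, `p_adj`,
#'   `significant`, `separated`.
#' @export
arm_alt_association <- function(arm_logr, covariates, alpha = 0.05) {
  d <- as_tibble(arm_logr)
  if (!"alt" %in% names(d)) input_error("`arm_logr` must have column `alt`")
  arms <- setdiff(names(d), c("alt", "sample"))
  res <- glm_lrt_scan(d[arms], d$alt, as_tibble(covariates),
                      family = stats::binomial())
  res |>
    mutate(p_adj = pmin(.data$p * sum(!is.na(.data$p)), 1),
           direction = if_else(.data$estimate > 0, "gain", "loss"),
           significant = !is.na(.data$p_adj) & .data$p_adj < alpha) |>
    select("region", "estimate", "direction", "p", "p_adj", "significant",
           "separated")
}

#' Binned-genome association of copy-number ratio with mortality
#'
#' Per 5 Mb bin, a nested-GLM chi-squared (Rao score) test of the binary outcome
#' "deceased from disease" on the bin's summarized copy-number ratio,
#' controlling for covariates (MYCN amplification, age, stage 4, sex,
#' purity, ploidy); Bonferroni across bins, significant below `alpha` FWER.
#' Runs of adjacent significant bins on the same chromosome are merged into
#' regions.
#'
#' @param bin_ratio Data frame, one row per sample: logical `deceased`
#'   column plus one numeric column per bin (named `chrom:start`, as
#'   produced by [genome_bins()] + [summarize_region()]).
#' @param covariates Data frame of per-sample covariates, same row order.
#' @param alpha FWER level.
#' @return List with `bins` (per-bin tibble: `region`, `estimate`, `p`,
#'   `p_adj`, `significant`) and `merged_regions` (tibble of merged
#'   significant runs: `chrom`, `start_bin`, `end_bin`, `n_bins`).
#' @export
bin_survival_association <- function(bin_ratio, covariates, alpha = 0.05) {
  d <- as_tibble(bin_ratio)
  if (!"deceased" %in% names(d)) {
    input_error("`bin_ratio` must have column `deceased`")
  }
  bins <- setdiff(names(d), c("deceased", "sample"))
  res <- glm_lrt_scan(d[bins], d$deceased, as_tibble(covariates),
                      family = stats::binomial())
  res <- res |>
    mutate(p_adj = pmin(.data$p * sum(!is.na(.data$p)), 1),
           significant = !is.na(.data$p_adj) & .data$p_adj < alpha)
  sig <- res[res$significant, "region", drop = FALSE]
  merged <- if (nrow(sig)) {
    parts <- stringr::str_match(sig$region, "^chr(\\d+):(\\d+)$")
    info <- tibble(chrom = as.integer(parts[, 2]),
                   start = as.numeric(parts[, 3])) |>
      arrange(.data$chrom, .data$start) |>
      group_by(.data$chrom) |>
      mutate(run = cumsum(c(1, diff(.data$start) > 5e6 + 1))) |>
      group_by(.data$chrom, .data$run) |>
      summarise(start_bin = min(.data$start), end_bin = max(.data$start),
                n_bins = dplyr::n(), .groups = "drop") |>
      select(-"run")
    info
  } else {
    tibble(chrom = integer(0), start_bin = numeric(0),
           end_bin = numeric(0), n_bins = integer(0))
  }
  list(bins = select(res, "region", "estimate", "p", "p_adj", "significant"),
       merged_regions = merged)
}
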