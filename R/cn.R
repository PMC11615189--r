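# Allele-specific copy-number profiling: BAF/LogR tracks, mirrored-BAF
# segmentation, inversion to integer allele counts, state classification and
# region-level summaries.

#' Per-SNP B-allele frequency and coverage log-ratio
#'
#' Computes, for every SNP with total depth of at least `min_depth` in both
#' the tumor and the matched normal, the tumor B-allele frequency
#' `BAF = altT / (refT + altT)` and the coverage log-ratio
#' `LogR = log2((d_t / d_n) / (mean_dt / mean_dn))`, where the mean depths
#' are taken over the retained SNPs. Sites below the depth cutoff are
#' dropped; the number dropped is recorded in the `dropped` attribute.
#'
#' @param sites Data frame with integer columns `refT`, `altT`, `refN`,
#'   `altN` (tumor/normal allelic depths); other columns are carried through.
#' @param min_depth Minimum total depth required in both tissues.
#' @return The retained rows as a tibble with `baf`, `baf_n` (normal BAF) and
#'   `logr` appended; attribute `dropped` holds the removed-site count.
#' @examples
#' sites <- tibble::tibble(refT = 15, altT = 15, refN = 15, altN = 15)
#' compute_baf_logr(sites)
#' @export
compute_baf_logr <- function(sites, min_depth = 10) {
  need <- c("refT", "altT", "refN", "altN")
  if (!all(need %in% names(sites))) {
    input_error(paste("`sites` must have columns", paste(need, collapse = ", ")))
  }
  d_t <- sites$refT + sites$altT
  d_n <- sites$refN + sites$altN
  keep <- d_t >= min_depth & d_n >= min_depth
  out <- as_tibble(sites[keep, , drop = FALSE])
  d_t <- d_t[keep]; d_n <- d_n[keep]
  if (nrow(out) == 0L) {
    warn("no sites pass the depth filter")
    out$baf <- numeric(0); out$baf_n <- numeric(0); out$logr <- numeric(0)
    attr(out, "dropped") <- sum(!keep)
    return(out)
  }
  mean_t <- mean(d_t); mean_n <- mean(d_n)
  out$baf <- out$altT / d_t
  out$baf_n <- out$altN / d_n
  out$logr <- log2((d_t / d_n) / (mean_t / mean_n))
  attr(out, "dropped") <- sum(!keep)
  out
}

# Residual-variance estimate from first differences (robust to level shifts).
mad_sigma2 <- function(x) {
  if (length(x) < 3) return(stats::var(x) %||% 0)
  s <- median(abs(diff(x))) / (sqrt(2) * 0.6745)
  max(s^2, 1e-8)
}

# Recursive binary segmentation on a numeric signal. Returns sorted indices i
# such that a breakpoint lies between sites i and i+1.
binseg <- function(x, threshold, min_sites) {
  n <- length(x)
  if (n < 2 * min_sites) return(integer(0))
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  tot_ss <- cs2[n] - cs[n]^2 / n
  ks <- min_sites:(n - min_sites)
  lh <- cs[ks]; nl <- ks
  ss_left <- cs2[ks] - lh^2 / nl
  rh <- cs[n] - lh; nr <- n - ks
  ss_right <- (cs2[n] - cs2[ks]) - rh^2 / nr
  gain <- tot_ss - (ss_left + ss_right)
  best <- which.max(gain)
  if (gain[best] <= threshold) return(integer(0))
  k <- ks[best]
  c(binseg(x[1:k], threshold, min_sites),
    k,
    k + binseg(x[(k + 1):n], threshold, min_sites))
}

#' Segment the genome on mirrored B-allele frequency
#'
#' Changepoint segmentation of heterozygous-SNP BAF tracks. Breakpoints are
#' determined from the mirrored signal `|BAF - 0.5|` only (coverage noise
#' does not drive segmentation); each segment's coverage is then summarized
#' as the mean LogR of its sites. Segmentation is recursive binary splitting
#' of the per-chromosome sum of squares, accepting a split when the cost
#' reduction exceeds `penalty * sigma^2 * log(n)`, with `sigma^2` estimated
#' robustly from first differences of the mirrored signal.
#'
#' @param het_sites Data frame of heterozygous sites with columns `chrom`,
#'   `pos`, `baf` and `logr`, ordered by position within chromosome.
#' @param penalty Split-acceptance penalty multiplier.
#' @param min_sites Minimum sites per segment.
#' @return A tibble with one row per segment: `chrom`, `start`, `end`
#'   (positions of the flanking sites, 1-based inclusive), `start_idx`,
#'   `end_idx` (site indices within the chromosome), `n_snps`, `baf_mirror`
#'   (mean mirrored BAF), `baf` (minor-allele BAF, `0.5 - baf_mirror`) and
#'   `logr` (mean LogR).
#' @examples
#' sites <- tibble::tibble(chrom = 1, pos = 1:100 * 1000,
#'                         baf = rep(c(0.5, 0.25), each = 50), logr = 0)
#' segment_baf(sites)
#' @export
segment_baf <- function(het_sites, penalty = 4, min_sites = 5) {
  need <- c("chrom", "pos", "baf", "logr")
  if (!all(need %in% names(het_sites))) {
    input_error(paste("`het_sites` must have columns",
                      paste(need, collapse = ", ")))
  }
  if (nrow(het_sites) == 0L) {
    warn("empty site table: empty segmentation")
    return(tibble(chrom = integer(0), start = numeric(0), end = numeric(0),
                  start_idx = integer(0), end_idx = integer(0),
                  n_snps = integer(0), baf_mirror = numeric(0),
                  baf = numeric(0), logr = numeric(0)))
  }
  purrr::map_dfr(split(as_tibble(het_sites), het_sites$chrom), function(sc) {
    sc <- arrange(sc, .data$pos)
    x <- abs(sc$baf - 0.5)
    n <- nrow(sc)
    if (n < 2) {
      warn(sprintf("chromosome %s has < 2 het sites", sc$chrom[1]))
      bps <- integer(0)
    } else {
      thr <- penalty * mad_sigma2(x) * log(n)
      bps <- binseg(x, thr, min_sites)
    }
    starts <- c(1L, bps + 1L)
    ends <- c(bps, n)
    tibble(chrom = sc$chrom[1],
           start = sc$pos[starts], end = sc$pos[ends],
           start_idx = starts, end_idx = ends,
           n_snps = ends - starts + 1L,
           baf_mirror = purrr::map2_dbl(starts, ends,
                                        ~ mean(x[.x:.y])),
           baf = 0.5 - purrr::map2_dbl(starts, ends, ~ mean(x[.x:.y])),
           logr = purrr::map2_dbl(starts, ends, ~ mean(sc$logr[.x:.y])))
  })
}

#' Invert segment BAF/LogR to integer allele-specific copy numbers
#'
#' For each segment, finds the integer pair `(cn_major >= cn_minor >= 0)`
#' minimizing the squared distance between the observed (minor-allele BAF,
#' LogR) and the values predicted by [forward_baf_logr()] at the sample's
#' purity and ploidy. Ties are broken toward the smaller total copy number,
#' then the larger minor allele count, making the inversion deterministic.
#' At zero noise this is an exact inverse of the forward model.
#'
#' @param segments Data frame with numeric columns `baf` (minor-allele BAF,
#'   in \[0, 0.5\]) and `logr`.
#' @param purity,ploidy Sample purity (0, 1\] and average tumor ploidy.
#' @param gamma Coverage-response coefficient of the platform.
#' @param max_cn Largest allele copy number considered.
#' @return The input tibble with integer columns `cn_major`, `cn_minor` and
#'   the achieved squared error `fit_err` appended.
#' @examples
#' estimate_allele_cn(tibble::tibble(baf = 1 / 3, logr = log2(1.5)),
#'                    purity = 1, ploidy = 2)
#' @export
estimate_allele_cn <- function(segments, purity, ploidy, gamma = 1,
                               max_cn = 12) {
  if (purity <= 0 || purity > 1) {
    abort("`purity` must be in (0, 1]", class = "nbd_domain_error")
  }
  grid <- tidyr::expand_grid(n_a = 0:max_cn, n_b = 0:max_cn) |>
    filter(.data$n_a >= .data$n_b)
  fwd <- forward_baf_logr_safe(grid$n_a, grid$n_b, purity, ploidy, gamma)
  ok <- is.finite(fwd$baf) & is.finite(fwd$logr)
  grid <- grid[ok, ]; fwd <- fwd[ok, ]
  if (nrow(grid) == 0L) {
    abort("no feasible copy-number pair", class = "nbd_numerical_error")
  }
  # order so that which.min's first-hit tie break = smaller total, larger minor
  o <- order(grid$n_a + grid$n_b, -grid$n_b)
  grid <- grid[o, ]; fwd <- fwd[o, ]
  res <- purrr::map2_dfr(segments$baf, segments$logr, function(b, r) {
    err <- (fwd$baf - b)^2 + (fwd$logr - r)^2
    i <- which.min(err)
    tibble(cn_major = as.integer(grid$n_a[i]),
           cn_minor = as.integer(grid$n_b[i]),
           fit_err = err[i])
  })
  dplyr::bind_cols(as_tibble(segments), res)
}

# forward model tolerating the rho=1, (0,0) corner by returning NaN there
forward_baf_logr_safe <- function(n_a, n_b, purity, ploidy, gamma) {
  tot <- n_a + n_b
  denom <- 2 * (1 - purity) + purity * tot
  tibble(baf = ifelse(denom > 0,
                      ((1 - purity) + purity * n_b) / denom, NaN),
         logr = ifelse(denom > 0,
                       gamma * log2(denom /
                                      (2 * (1 - purity) + purity * ploidy)),
                       NaN))
}

#' Classify copy-number and allelic-balance states of segments
#'
#' Applies the rule list for copy-number states in order, later matching
#' conditions winning: *weak gain* if `CN_total > round(ploidy)`, *medium
#' gain* if `> 1.5 * round(ploidy)`, *strong gain* if `> 2.5 *
#' round(ploidy)`, *shallow loss* if `< round(ploidy)`, *loss* if `< 0.5 *
#' round(ploidy)`, else *neutral*. *Amplification* overrides every state for
#' focal segments (< 10 Mb) with `cn_major >= 5` and `logr_seg - logr_contig
#' > 0.7`, where `logr_contig` is the mean LogR of the segment's chromosome.
#' The balance state is *balance* if `cn_minor > 0` and `cn_major ==
#' cn_minor`, *weak imbalance* if `cn_major > cn_minor` and `CN_ratio <=
#' 2/3`, *strong imbalance* if `CN_ratio > 2/3` (with `CN_ratio = cn_major /
#' CN_total`), again with the focal amplification override. Segments with
#' `cn_minor == 0` are flagged LOH. `round()` is R's round-half-to-even;
#' ploidy estimates near x.5 therefore resolve to the even integer.
#'
#' @param segments Data frame with columns `cn_major`, `cn_minor`, `start`,
#'   `end`, `logr_seg` and `chrom` (chrom/logr only needed for the
#'   amplification override; missing columns disable it).
#' @param ploidy Average tumor ploidy of the sample.
#' @param logr_contig Optional named/per-row chromosome mean LogR; computed
#'   as the length-weighted mean of `logr_seg` per chromosome when absent.
#' @return The input tibble with `cn_total`, `cn_ratio`, `state`, `balance`
#'   and `loh` appended.
#' @examples
#' classify_cn_state(tibble::tibble(cn_major = 3, cn_minor = 2), ploidy = 2)
#' @export
classify_cn_state <- function(segments, ploidy, logr_contig = NULL) {
  seg <- as_tibble(segments)
  if (!all(c("cn_major", "cn_minor") %in% names(seg))) {
    input_error("`segments` must have columns cn_major, cn_minor")
  }
  tot <- seg$cn_major + seg$cn_minor
  rp <- round(ploidy)
  state <- rep("neutral", nrow(seg))
  state[tot > rp] <- "weak gain"
  state[tot > 1.5 * rp] <- "medium gain"
  state[tot > 2.5 * rp] <- "strong gain"
  state[tot < rp] <- "shallow loss"
  state[tot < 0.5 * rp] <- "loss"
  cn_ratio <- ifelse(tot > 0, seg$cn_major / tot, NA_real_)
  balance <- dplyr::case_when(
    seg$cn_minor > 0 & seg$cn_major == seg$cn_minor ~ "balance",
    seg$cn_major > seg$cn_minor & cn_ratio <= 2 / 3 ~ "weak imbalance",
    seg$cn_major > seg$cn_minor & cn_ratio > 2 / 3 ~ "strong imbalance",
    TRUE ~ "balance")
  amp <- rep(FALSE, nrow(seg))
  if (all(c("start", "end", "logr_seg") %in% names(seg))) {
    if (is.null(logr_contig)) {
      if ("chrom" %in% names(seg)) {
        w <- seg$end - seg$start + 1
        lc <- tapply(seg$logr_seg * w, seg$chrom, sum) /
          tapply(w, seg$chrom, sum)
        logr_contig <- unname(lc[as.character(seg$chrom)])
      } else {
        logr_contig <- stats::weighted.mean(seg$logr_seg,
                                            seg$end - seg$start + 1)
      }
    }
    amp <- (seg$end - seg$start + 1) < 10e6 &
      seg$cn_major >= 5 &
      (seg$logr_seg - logr_contig) > 0.7
    amp[is.na(amp)] <- FALSE
  }
  state[amp] <- "amplification"
  balance[amp] <- "amplification"
  mutate(seg,
         cn_total = tot,
         cn_ratio = cn_ratio,
         state = factor(state, levels = CN_STATE_LEVELS),
         balance = factor(balance, levels = CN_BALANCE_LEVELS),
         loh = seg$cn_minor == 0)
}

CN_STATE_LEVELS <- c("loss", "shallow loss", "neutral", "weak gain",
                     "medium gain", "strong gain", "amplification")
CN_BALANCE_LEVELS <- c("balance", "weak imbalance", "strong imbalance",
                       "amplification")

#' Gene amplification call from state and gene-level LogR
#'
#' A gene is amplified when its copy-number state is *amplification* or its
#' mean LogR over the SNPs inside the gene exceeds 2.5.
#'
#' @param genes Data frame with columns `state` and `logr_gene`; rows with
#'   missing `logr_gene` (no SNPs in the gene) are flagged `NA` with a
#'   warning.
#' @return Input tibble with logical `amplified` appended.
#' @examples
#' gene_amplification(tibble::tibble(state = "neutral", logr_gene = 2.6))
#' @export
gene_amplification <- function(genes) {
  g <- as_tibble(genes)
  if (!all(c("state", "logr_gene") %in% names(g))) {
    input_error("`genes` must have columns state, logr_gene")
  }
  if (anyNA(g$logr_gene)) {
    warn(sprintf("%d genes without SNP coverage skipped (amplified = NA)",
                 sum(is.na(g$logr_gene))))
  }
  mutate(g, amplified = as.character(.data$state) == "amplification" |
           .data$logr_gene > 2.5)
}

#' Summarize copy-number segments over genomic regions
#'
#' Projects per-segment values onto regions (chromosome arms, cytobands,
#' genes or 5 Mb bins). `weighted_mean` returns, for each numeric column in
#' `values`, the overlap-length-weighted mean over all segments intersecting
#' the region; `dominant_state` returns the `state` with the largest total
#' overlap. When `amp_override = TRUE` (the 5 Mb-bin convention), a region
#' overlapping an *amplification* segment takes that segment's values
#' directly, discarding the other overlapping segments; with several
#' amplified segments the one with the largest overlap wins.
#'
#' @param segments Data frame with `chrom`, `start`, `end` plus the value
#'   columns (and `state` for `dominant_state` / the override).
#' @param regions Data frame with `region`, `chrom`, `start`, `end`.
#' @param values Character vector of numeric segment columns to summarize.
#' @param mode `"weighted_mean"` or `"dominant_state"`.
#' @param amp_override Apply the focal-amplification override.
#' @return Tibble with one row per region; regions without overlap get `NA`.
#' @examples
#' seg <- tibble::tibble(chrom = 1, start = c(1, 3e6), end = c(3e6, 5e6),
#'                       cn_ratio = c(1, 0.5), state = "neutral")
#' reg <- tibble::tibble(region = "bin1", chrom = 1, start = 1, end = 5e6)
#' summarize_region(seg, reg, values = "cn_ratio")
#' @export
summarize_region <- function(segments, regions, values = c("logr_seg",
                                                           "cn_ratio"),
                             mode = c("weighted_mean", "dominant_state"),
                             amp_override = FALSE) {
  mode <- match.arg(mode)
  seg <- as_tibble(segments)
  values <- intersect(values, names(seg))
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    s <- seg[seg$chrom == r$chrom & seg$start <= r$end & seg$end >= r$start, ]
    out <- tibble(region = r$region, chrom = r$chrom,
                  start = r$start, end = r$end)
    if (nrow(s) == 0L) {
      if (mode == "weighted_mean") {
        for (v in values) out[[v]] <- NA_real_
      } else out$state <- NA_character_
      return(out)
    }
    ov <- pmin(s$end, r$end) - pmax(s$start, r$start) + 1
    if (mode == "dominant_state") {
      tot <- tapply(ov, as.character(s$state), sum)
      out$state <- names(tot)[which.max(tot)]
      return(out)
    }
    if (amp_override && "state" %in% names(s) &&
        any(as.character(s$state) == "amplification")) {
      amp <- which(as.character(s$state) == "amplification")
      j <- amp[which.max(ov[amp])]
      for (v in values) out[[v]] <- s[[v]][j]
      return(out)
    }
    for (v in values) out[[v]] <- sum(s[[v]] * ov) / sum(ov)
    out
  })
}

#' Tile the simulated genome into fixed-width bins
#'
#' @param chrom_lengths Chromosome lengths (bp), in chromosome order.
#' @param width Bin width in bp (default 5 Mb).
#' @return Tibble of regions `region`, `chrom`, `start`, `end`.
#' @examples
#' genome_bins(c(12e6, 8e6))
#' @export
genome_bins <- function(chrom_lengths, width = 5e6) {
  purrr::map_dfr(seq_along(chrom_lengths), function(ch) {
    starts <- seq(1, chrom_lengths[ch], by = width)
    tibble(region = sprintf("chr%d:%d", ch, starts),
           chrom = ch, start = starts,
           end = pmin(starts + width - 1, chrom_lengths[ch]))
  })
}

#' Chromosome arms of the simulated genome
#'
#' Centromeres sit at 40% of each chromosome length.
#'
#' @inheritParams genome_bins
#' @return Tibble of regions `region` (e.g. `"3p"`), `chrom`, `start`, `end`.
#' @examples
#' genome_arms(c(12e6, 8e6))
#' @export
genome_arms <- function(chrom_lengths) {
  purrr::map_dfr(seq_along(chrom_lengths), function(ch) {
    cen <- round(0.4 * chrom_lengths[ch])
    tibble(region = paste0(ch, c("p", "q")), chrom = ch,
           start = c(1, cen + 1), end = c(cen, chrom_lengths[ch]))
  })
}
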