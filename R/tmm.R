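# Telomere maintenance mechanism calling: telomeric-repeat read counting,
# TERT-expression mixture threshold, rule-based labels, TERRA quantification
# and validation against experimental labels.

has_repeats <- function(seqs, motif, k) {
  stringr::str_detect(toupper(seqs), stringr::fixed(strrep(motif, k)))
}

#' Count telomeric reads and derive a telomere-length proxy
#'
#' A read is telomeric if it contains at least `k` exact consecutive copies
#' of the telomere repeat TTAGGG or (by default) of its reverse complement
#' CCCTAA. The length proxy is `counted / total * scale`; because the
#' tumor/normal telomere-length *ratio* is the quantity used downstream, the
#' scale constant cancels and stands in for the GC and genome-size
#' normalization of read-count-based telomere-length estimators.
#' Counting is invariant to read order and sequence case.
#'
#' @param reads Data frame with a character column `seq` (one row per read),
#'   or a character vector of sequences.
#' @param k Required number of consecutive repeat copies.
#' @param both_strands Also count the CCCTAA strand (set `FALSE` to count
#'   the G-strand motif only).
#' @param scale Scale constant of the length proxy.
#' @return A one-row tibble: `n_reads`, `n_telomeric`, `length_proxy`.
#' @examples
#' count_telomeric_reads(c(strrep("TTAGGG", 7), "ACGTACGT"))
#' @export
count_telomeric_reads <- function(reads, k = 7, both_strands = TRUE,
                                  scale = 100) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (length(seqs) == 0L) input_error("`reads` is empty")
  hit <- has_repeats(seqs, TEL_MOTIF, k)
  if (both_strands) hit <- hit | has_repeats(seqs, TEL_MOTIF_RC, k)
  tibble(n_reads = length(seqs), n_telomeric = sum(hit),
         length_proxy = sum(hit) / length(seqs) * scale)
}

#' Log telomere-length ratio
#'
#' `log(L_T / L_N)` (natural log) between tumor and matched-normal telomere
#' length estimates. Values above the ALT cutoff (0.5, about a 1.65-fold
#' elongation) are the length criterion for alternative lengthening of
#' telomeres.
#'
#' @param l_tumor,l_normal Positive length estimates (vectorized).
#' @return Numeric vector of log ratios.
#' @examples
#' telomere_length_ratio(2, 1)   # ln 2 > 0.5: ALT length criterion met
#' @export
telomere_length_ratio <- function(l_tumor, l_normal) {
  if (any(l_tumor <= 0) || any(l_normal <= 0)) {
    abort("telomere lengths must be positive", class = "nbd_domain_error")
  }
  log(l_tumor / l_normal)
}

#' Fit the TERT-high expression threshold
#'
#' Fits a two-component univariate Gaussian mixture to cohort TERT
#' expression Z-scores by EM and returns the smallest Z at which the
#' posterior probability of assignment to the stronger-expression component
#' reaches `posterior_cut` (default 95%).
#'
#' @param tert_z Numeric vector of cohort Z-scores (>= 10 samples).
#' @param posterior_cut Required posterior of the high component.
#' @param seed Seed for the EM initialization.
#' @return An object of class `nbd_mixture_fit`: list with `means`, `sds`,
#'   `weights` (low component first), `threshold`, `posterior_cut`,
#'   `loglik`, `n`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' z <- c(rnorm(80, -0.5, 0.3), rnorm(30, 1.5, 0.3))
#' fit_tert_threshold(z, seed = 1)
#' @export
fit_tert_threshold <- function(tert_z, posterior_cut = 0.95, seed = 1L) {
  z <- tert_z[is.finite(tert_z)]
  if (length(z) < 10) input_error("need >= 10 finite TERT Z-scores")
  if (sd(z) < 1e-10) {
    abort("degenerate input: all TERT Z-scores equal",
          class = "nbd_numerical_error")
  }
  # univariate G=2 fit; BIC chooses between equal/unequal variances
  fit <- with_seed(seed, mclust::Mclust(z, G = 2, verbose = FALSE))
  if (is.null(fit)) {
    fit <- with_seed(seed,
                     mclust::Mclust(z, G = 2, modelNames = "E",
                                    verbose = FALSE))
  }
  if (is.null(fit)) {
    abort("EM failed to fit a 2-component mixture",
          class = "nbd_numerical_error")
  }
  means <- as.numeric(fit$parameters$mean)
  sds <- sqrt(rep_len(as.numeric(fit$parameters$variance$sigmasq), 2))
  weights <- as.numeric(fit$parameters$pro)
  o <- order(means)
  means <- means[o]; sds <- sds[o]; weights <- weights[o]
  thr <- mixture_posterior_threshold(means, sds, weights, posterior_cut)
  structure(list(means = means, sds = sds, weights = weights,
                 threshold = thr, posterior_cut = posterior_cut,
                 loglik = fit$loglik, n = length(z)),
            class = "nbd_mixture_fit")
}

#' @export
print.nbd_mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("<nbd_mixture_fit> n = %d; components N(%.3f, %.3f) ",
                     "w = %.2f | N(%.3f, %.3f) w = %.2f\n",
                     "  TERT-high threshold (posterior >= %.2f): Z > %.4f\n"),
              x$n, x$means[1], x$sds[1], x$weights[1],
              x$means[2], x$sds[2], x$weights[2],
              x$posterior_cut, x$threshold))
  invisible(x)
}

#' Assign telomere maintenance mechanism labels
#'
#' A sample is *TERT-high* when its TERT expression Z-score exceeds the
#' mixture threshold and it carries neither a MYCN amplification nor a TERT
#' rearrangement. Canonical telomere maintenance (CTM) criteria are MYCN
#' amplification, TERT rearrangement, or TERT-high status; the ALT criterion
#' is a log telomere-length ratio above `tlr_cut`. The label is `Mix` when
#' both criteria hold, `CTM` or `ALT` when exactly one does, `None`
#' otherwise.
#'
#' @param features Data frame with logical columns `mycn_amp`, `tert_re` and
#'   numeric `tert_z`, `tlr`; a `sample` column, if present, is carried
#'   through.
#' @param threshold TERT-high Z threshold (scalar or [fit_tert_threshold()]
#'   fit).
#' @param tlr_cut ALT cutoff on the natural-log telomere-length ratio.
#' @return Input tibble with logical `tert_high` and character `tmm_label`
#'   appended.
#' @examples
#' classify_tmm(tibble::tibble(mycn_amp = TRUE, tert_re = FALSE,
#'                             tert_z = 0, tlr = 0.1), threshold = 1)
#' @export
classify_tmm <- function(features, threshold, tlr_cut = 0.5) {
  if (inherits(threshold, "nbd_mixture_fit")) threshold <- threshold$threshold
  f <- as_tibble(features)
  need <- c("mycn_amp", "tert_re", "tert_z", "tlr")
  miss <- setdiff(need, names(f))
  if (length(miss)) {
    input_error(paste("`features` is missing column(s):",
                      paste(miss, collapse = ", ")))
  }
  for (v in need) {
    if (anyNA(f[[v]])) {
      i <- which(is.na(f[[v]]))[1]
      id <- if ("sample" %in% names(f)) f$sample[i] else paste("row", i)
      input_error(sprintf("missing feature `%s` for sample %s", v, id))
    }
  }
  tert_high <- f$tert_z > threshold & !f$mycn_amp & !f$tert_re
  ctm <- f$mycn_amp | f$tert_re | tert_high
  alt <- f$tlr > tlr_cut
  mutate(f, tert_high = tert_high,
         tmm_label = dplyr::case_when(ctm & alt ~ "Mix",
                                      ctm ~ "CTM",
                                      alt ~ "ALT",
                                      TRUE ~ "None"))
}

#' Quantify telomeric repeat-containing RNA (TERRA)
#'
#' A paired-end fragment is TERRA-positive when either of its reads contains
#' at least `min_repeats` exact consecutive copies of TTAGGG (or its reverse
#' complement); the result is reported as fragments per million (FPM).
#' Fragments with a missing mate are counted on the remaining read, with a
#' warning.
#'
#' @param fragments Data frame with character columns `read1` and `read2`
#'   (NA allowed for a missing mate).
#' @param min_repeats Required consecutive repeat copies.
#' @param total_fragments Library size used for the per-million scaling;
#'   defaults to `nrow(fragments)`.
#' @return One-row tibble: `n_fragments`, `n_terra`, `fpm`.
#' @examples
#' fr <- tibble::tibble(read1 = strrep("TTAGGG", 5), read2 = "ACGT")
#' count_terra_fragments(fr, total_fragments = 1e6)
#' @export
count_terra_fragments <- function(fragments, min_repeats = 5,
                                  total_fragments = nrow(fragments)) {
  if (total_fragments < 1) input_error("`total_fragments` must be >= 1")
  r1 <- fragments$read1
  r2 <- fragments$read2
  if (anyNA(r1) || anyNA(r2)) {
    warn(sprintf("%d fragments with a missing mate treated as single-read",
                 sum(is.na(r1) | is.na(r2))))
  }
  hit1 <- !is.na(r1) & (has_repeats(r1, TEL_MOTIF, min_repeats) |
                          has_repeats(r1, TEL_MOTIF_RC, min_repeats))
  hit2 <- !is.na(r2) & (has_repeats(r2, TEL_MOTIF, min_repeats) |
                          has_repeats(r2, TEL_MOTIF_RC, min_repeats))
  n <- sum(hit1 | hit2)
  tibble(n_fragments = nrow(fragments), n_terra = n,
         fpm = n / total_fragments * 1e6)
}

#' Validate binary calls against experimental labels
#'
#' Sensitivity and specificity of predicted versus experimentally determined
#' status, with a one-sided (enrichment) Fisher's exact test on the 2x2
#' table.
#'
#' @param predicted,experimental Logical vectors of equal length.
#' @return One-row tibble: `tp`, `fn`, `fp`, `tn`, `sensitivity`,
#'   `specificity`, `p_fisher`. An empty truth class yields `NA` for the
#'   affected metric.
#' @examples
#' validate_calls(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
validate_calls <- function(predicted, experimental) {
  stopifnot(length(predicted) == length(experimental))
  keep <- !is.na(predicted) & !is.na(experimental)
  p <- predicted[keep]; e <- experimental[keep]
  if (!any(e) || all(e)) {
    warn("experimental labels contain a single class; metrics undefined")
  }
  tp <- sum(p & e); fn <- sum(!p & e)
  fp <- sum(p & !e); tn <- sum(!p & !e)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  pv <- if (tp + fn > 0 && tn + fp > 0) {
    fisher.test(matrix(c(tp, fn, fp, tn), 2), alternative = "greater")$p.value
  } else NA_real_
  tibble(tp = tp, fn = fn, fp = fp, tn = tn,
         sensitivity = sens, specificity = spec, p_fisher = pv)
}
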