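# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @describeIn fit_tert_threshold Tidy the mixture components (one row per
#'   component: `component`, `mean`, `sd`, `weight`).
#' @param x An `nbd_mixture_fit`.
#' @param ... Unused.
#' @export
tidy.nbd_mixture_fit <- function(x, ...) {
  tibble(component = c("low", "high"), mean = x$means, sd = x$sds,
         weight = x$weights)
}

#' @describeIn fit_tert_threshold One-row model summary (`threshold`,
#'   `posterior_cut`, `loglik`, `n`).
#' @export
glance.nbd_mixture_fit <- function(x, ...) {
  tibble(threshold = x$threshold, posterior_cut = x$posterior_cut,
         loglik = x$loglik, n = x$n)
}

#' @describeIn fit_tert_threshold Density plot of the fitted mixture with
#'   the TERT-high threshold.
#' @param object An `nbd_mixture_fit`.
#' @export
autoplot.nbd_mixture_fit <- function(object, ...) {
  z <- seq(object$means[1] - 4 * object$sds[1],
           object$means[2] + 4 * object$sds[2], length.out = 400)
  dens <- tibble(
    z = rep(z, 2),
    component = rep(c("low", "high"), each = length(z)),
    density = c(object$weights[1] * dnorm(z, object$means[1], object$sds[1]),
                object$weights[2] * dnorm(z, object$means[2], object$sds[2])))
  ggplot(dens, aes(x = .data$z, y = .data$density,
                   colour = .data$component)) +
    geom_line() +
    geom_vline(xintercept = object$threshold, linetype = "dashed") +
    labs(x = "TERT expression Z score", y = "mixture density",
         title = sprintf("TERT-high threshold: Z > %.3f", object$threshold)) +
    theme_minimal()
}

#' @describeIn decompose_expression Tidy per gene x effect table.
#' @param x An `nbd_decomposition`.
#' @param ... Unused.
#' @export
tidy.nbd_decomposition <- function(x, ...) {
  x$table
}

#' @describeIn decompose_expression One row per effect with the mean
#'   variance fraction across genes and the number of significant genes.
#' @export
glance.nbd_decomposition <- function(x, ...) {
  x$table |>
    group_by(.data$effect) |>
    summarise(mean_fraction = mean(.data$ss_fraction, na.rm = TRUE),
              n_genes = sum(!is.na(.data$ss_fraction)),
              n_significant = sum(.data$significant, na.rm = TRUE),
              .groups = "drop")
}

#' @describeIn decompose_expression Boxplots of per-gene variance fractions
#'   by effect.
#' @param object An `nbd_decomposition`.
#' @export
autoplot.nbd_decomposition <- function(object, ...) {
  tab <- filter(object$table, !is.na(.data$ss_fraction))
  ggplot(tab, aes(x = .data$effect, y = .data$ss_fraction)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    labs(x = NULL, y = "fraction of total sum of squares",
         title = sprintf("Variance decomposition of %s", object$response)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Manhattan-style plot of a region association scan
#'
#' @param scan Tibble from [arm_alt_association()] or the `bins` element of
#'   [bin_survival_association()], with columns `region`, `p`, `p_adj`,
#'   `significant`.
#' @param alpha FWER level drawn as the significance line.
#' @return A ggplot object.
#' @export
plot_association_scan <- function(scan, alpha = 0.05) {
  d <- filter(as_tibble(scan), !is.na(.data$p))
  d$idx <- seq_len(nrow(d))
  n_tests <- nrow(d)
  ggplot(d, aes(x = .data$idx, y = -log10(.data$p),
                colour = .data$significant)) +
    geom_point(size = 1) +
    geom_hline(yintercept = -log10(alpha / n_tests), linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = d$idx[d$significant],
                                labels = d$region[d$significant]) +
    labs(x = "region", y = "-log10 p") +
    theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Copy-number state profile plot for one sample
#'
#' @param segments Classified segments of one sample
#'   ([classify_cn_state()] output).
#' @return A ggplot object showing per-segment total copy number coloured by
#'   state along the genome.
#' @export
plot_cn_profile <- function(segments) {
  s <- as_tibble(segments)
  ggplot(s) +
    ggplot2::geom_segment(aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                              y = .data$cn_total, yend = .data$cn_total,
                              colour = .data$state), linewidth = 1.5) +
    facet_wrap(~chrom, scales = "free_x", nrow = 2) +
    labs(x = "position (Mb)", y = "total copy number", colour = "state") +
    theme_minimal()
}
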