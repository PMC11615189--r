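# Genetic effects on expression and allele-specific expression: cohort
# residualization, per-gene sequential-ANOVA variance decomposition, the
# allelic-dosage (ASE~expression) association, and the ALT differential
# expression scan.

#' Normalize and cohort-residualize an expression matrix
#'
#' Library-size scaling (counts per million) followed by a `log1p`
#' variance-stabilizing transform, then per-gene regression on the cohort
#' (batch) indicator, returning residuals. Residuals have mean 0
#' within each cohort for every gene; doubling all library sizes leaves the
#' result unchanged. Genes with zero counts in every sample are dropped with
#' a message.
#'
#' @param counts Long data frame with columns `sample`, `gene`, `count`.
#' @param cohorts Data frame with columns `sample`, `cohort`.
#' @return Long tibble `sample`, `gene`, `expr` (residualized expression).
#' @examples
#' counts <- tidyr::expand_grid(sample = c("s1", "s2"), gene = "g1")
#' counts$count <- c(5, 7)
#' normalize_expression(counts, tibble::tibble(sample = c("s1", "s2"),
#'                                             cohort = "A"))
#' @export
normalize_expression <- function(counts, cohorts) {
  x <- as_tibble(counts)
  if (!all(c("sample", "gene", "count") %in% names(x))) {
    input_error("`counts` must have columns sample, gene, count")
  }
  zero <- x |> group_by(.data$gene) |>
    summarise(all0 = all(.data$count == 0), .groups = "drop") |>
    filter(.data$all0)
  if (nrow(zero)) {
    rlang::inform(sprintf("dropping %d genes with zero counts everywhere",
                          nrow(zero)))
    x <- filter(x, !.data$gene %in% zero$gene)
  }
  x <- x |>
    group_by(.data$sample) |>
    mutate(libsize = sum(.data$count)) |>
    ungroup()
  x$scaled <- x$count / x$libsize * 1e6   # fixed CPM reference
  x$logv <- log1p(x$scaled)
  x <- left_join(x, as_tibble(cohorts)[, c("sample", "cohort")], by = "sample")
  x |>
    group_by(.data$gene, .data$cohort) |>
    mutate(expr = .data$logv - mean(.data$logv)) |>
    ungroup() |>
    select("sample", "gene", "expr")
}

# Per-gene sequential (Type I) ANOVA decomposition engine. `terms` is the
# fixed predictor order; the order is part of the contract since sequential
# sums of squares depend on it.
decompose_engine <- function(data, response, terms, min_obs, adjust, alpha) {
  d <- as_tibble(data)
  need <- c("gene", response, terms)
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    input_error(paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  skipped <- character(0)
  rows <- purrr::map(split(d, d$gene), function(g) {
    cc <- complete.cases(g[, c(response, terms)])
    g <- g[cc, , drop = FALSE]
    if (nrow(g) < min_obs) {
      skipped <<- c(skipped, g$gene[1] %||% NA_character_)
      return(NULL)
    }
    use <- terms[purrr::map_lgl(terms, function(t) {
      v <- g[[t]]
      length(unique(v[!is.na(v)])) > 1
    })]
    dropped <- setdiff(terms, use)
    if (length(use) == 0L) return(NULL)
    fml <- as.formula(paste(response, "~",
                            paste(sprintf("`%s`", use), collapse = " + ")))
    fit <- lm(fml, data = g)
    an <- anova(fit)
    ss <- an$`Sum Sq`
    total <- sum(ss)
    eff <- rownames(an)
    eff <- gsub("`", "", eff)
    out <- tibble(gene = g$gene[1], effect = eff,
                  df = an$Df, ss = ss,
                  ss_fraction = if (total > 0) ss / total else NA_real_,
                  p = an$`Pr(>F)`,
                  n_obs = nrow(g))
    if (length(dropped)) {
      out <- dplyr::bind_rows(out,
                              tibble(gene = g$gene[1], effect = dropped,
                                     df = NA_integer_, ss = NA_real_,
                                     ss_fraction = NA_real_, p = NA_real_,
                                     n_obs = nrow(g)))
    }
    out
  })
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0L) {
    input_error(sprintf("no gene has %d or more complete observations",
                        min_obs))
  }
  tab <- tab |>
    group_by(.data$effect) |>
    mutate(p_adj = p.adjust(.data$p, method = adjust)) |>
    ungroup() |>
    mutate(significant = !is.na(.data$p_adj) & .data$p_adj < alpha &
             .data$effect != "Residuals")
  structure(list(table = tab, response = response, terms = terms,
                 adjust = adjust, alpha = alpha, skipped = unique(skipped)),
            class = "nbd_decomposition")
}

#' Decompose per-gene expression variance into genetic effects
#'
#' Ordinary least squares of (residualized) expression on the lead eQTL
#' genotype, copy-number LogR, structural-variant breakpoint flag, promoter
#' and gene-body somatic SNV flags, with tumor purity and MYCN amplification
#' as covariates, in that fixed order. Sequential (Type I) ANOVA sums of
#' squares give each effect's share of the total sum of squares; fractions
#' over all terms plus the residual sum to 1. Per-effect p-values come from
#' the ANOVA F statistics and are Bonferroni-adjusted across genes within
#' each effect (an FDR switch is provided); effects are significant at
#' adjusted p < `alpha`. Genes with fewer than `min_obs` complete
#' observations are skipped and listed in the result. Constant predictors
#' within a gene are dropped from that gene's model and reported with
#' missing statistics.
#'
#' @param data Long data frame with columns `gene`, `expr`, `eqtl_gt`,
#'   `logr_gene`, `sv`, `prom_snv`, `gene_snv`, `purity`, `mycn_amp`.
#' @param min_obs Minimum complete observations per gene.
#' @param adjust Multiple-testing method across genes per effect.
#' @param alpha Significance level on the adjusted p.
#' @param extra_covariates Optional further covariate column names appended
#'   after the listed terms.
#' @return An `nbd_decomposition` object; `tidy()` returns the per
#'   gene x effect table (`ss_fraction`, `p`, `p_adj`, `significant`),
#'   `glance()` cohort-level means.
#' @examples
#' d <- tibble::tibble(gene = "g1", expr = rnorm(30), eqtl_gt = 1,
#'                     logr_gene = rnorm(30), sv = FALSE, prom_snv = FALSE,
#'                     gene_snv = FALSE, purity = 0.8, mycn_amp = FALSE)
#' tidy(decompose_expression(d))
#' @export
decompose_expression <- function(data, min_obs = 20,
                                 adjust = c("bonferroni", "BH"),
                                 alpha = 0.05, extra_covariates = NULL) {
  adjust <- match.arg(adjust)
  terms <- c("eqtl_gt", "logr_gene", "sv", "prom_snv", "gene_snv",
             "purity", "mycn_amp", extra_covariates)
  decompose_engine(data, "expr", terms, min_obs, adjust, alpha)
}

#' Decompose per-gene ASE-ratio variance into genetic effects
#'
#' Same contract as [decompose_expression()] with the ASE ratio as the
#' response and the predictor set lead-eQTL heterozygosity, copy-number
#' ratio, SV flag, promoter SNV, gene SNV, purity, MYCN amplification and
#' log total allelic coverage, in that fixed order.
#'
#' @param data Long data frame with columns `gene`, `ase_ratio`, `eqtl_het`,
#'   `cn_ratio`, `sv`, `prom_snv`, `gene_snv`, `purity`, `mycn_amp`,
#'   `log_cov`.
#' @inheritParams decompose_expression
#' @return An `nbd_decomposition` object.
#' @export
decompose_ase <- function(data, min_obs = 20, adjust = c("bonferroni", "BH"),
                          alpha = 0.05, extra_covariates = NULL) {
  adjust <- match.arg(adjust)
  terms <- c("eqtl_het", "cn_ratio", "sv", "prom_snv", "gene_snv",
             "purity", "mycn_amp", "log_cov", extra_covariates)
  decompose_engine(data, "ase_ratio", terms, min_obs, adjust, alpha)
}

#' @export
print.nbd_decomposition <- function(x, ...) {
  ng <- length(unique(x$table$gene))
  cat(sprintf("<nbd_decomposition> response `%s`, %d genes, %d skipped\n",
              x$response, ng, length(x$skipped)))
  invisible(x)
}

#' Allelic-dosage association of ASE ratio with expression
#'
#' Per gene, regresses the ASE ratio on expression plus the available
#' covariates (cohort, purity, log allelic coverage, normal DNA ratio); the
#' p-value for the expression term is the sequential-ANOVA F test with
#' expression entered first, adjusted across genes by Benjamini-Hochberg.
#' The sign of the expression coefficient is reported: a negative
#' coefficient means bi-allelic activation raises expression (the
#' loss-of-imprinting pattern), a positive one mono-allelic amplification.
#' Genes need `min_obs` informative samples; genes with constant expression
#' are skipped.
#'
#' @param data Long data frame with columns `gene`, `ase_ratio`, `expr` and
#'   optionally `cohort`, `purity`, `log_cov`, `normal_ratio`.
#' @param alpha_fdr FDR level for the allelic-dosage (AD) flag.
#' @param min_obs Minimum informative samples per gene.
#' @return Tibble per gene: `gene`, `n_obs`, `estimate`, `p`, `q`, `ad`.
#' @export
ad_gene_test <- function(data, alpha_fdr = 0.05, min_obs = 10) {
  d <- as_tibble(data)
  if (!all(c("gene", "ase_ratio", "expr") %in% names(d))) {
    input_error("`data` must have columns gene, ase_ratio, expr")
  }
  covars <- intersect(c("cohort", "purity", "log_cov", "normal_ratio"),
                      names(d))
  rows <- purrr::map(split(d, d$gene), function(g) {
    vars <- c("ase_ratio", "expr", covars)
    g <- g[complete.cases(g[, vars]), , drop = FALSE]
    if (nrow(g) < min_obs) return(NULL)
    if (sd(g$expr) < 1e-12) return(NULL)
    use <- covars[purrr::map_lgl(covars,
                                 ~ length(unique(g[[.x]])) > 1)]
    fml <- as.formula(paste("ase_ratio ~ expr",
                            if (length(use))
                              paste("+", paste(use, collapse = " + "))
                            else ""))
    fit <- lm(fml, data = g)
    an <- anova(fit)
    tibble(gene = g$gene[1], n_obs = nrow(g),
           estimate = coef(fit)[["expr"]],
           p = an["expr", "Pr(>F)"])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) input_error("no gene has enough informative samples")
  mutate(out, q = p.adjust(.data$p, method = "BH"),
         ad = .data$q < alpha_fdr)
}

#' Differential expression between ALT and non-ALT tumors
#'
#' Per gene, a linear model of expression on ALT status plus covariates
#' (MYCN amplification, ATRX alteration, age, sex, cohort, purity, ploidy —
#' whichever columns are present); the ALT p-value is the chi-squared ANOVA
#' between the nested models with and without the ALT term, adjusted across
#' genes by Benjamini-Hochberg. Constant covariates are dropped with a
#' warning.
#'
#' @param data Long data frame with columns `gene`, `expr`, `alt` (logical)
#'   and optional covariate columns `mycn_amp`, `atrx`, `age`, `sex`,
#'   `cohort`, `purity`, `ploidy`.
#' @param alpha_fdr FDR level.
#' @return Tibble per gene: `gene`, `estimate` (ALT coefficient), `p`, `q`,
#'   `significant`.
#' @export
alt_de_scan <- function(data, alpha_fdr = 0.05) {
  d <- as_tibble(data)
  if (!all(c("gene", "expr", "alt") %in% names(d))) {
    input_error("`data` must have columns gene, expr, alt")
  }
  if (length(unique(d$alt)) < 2) {
    input_error("both ALT and non-ALT samples are required")
  }
  covars <- intersect(c("mycn_amp", "atrx", "age", "sex", "cohort",
                        "purity", "ploidy"), names(d))
  const <- covars[purrr::map_lgl(covars, ~ length(unique(d[[.x]])) < 2)]
  if (length(const)) {
    warn(paste("dropping constant covariate(s):",
               paste(const, collapse = ", ")))
    covars <- setdiff(covars, const)
  }
  rhs0 <- if (length(covars)) paste(covars, collapse = " + ") else "1"
  rows <- purrr::map(split(d, d$gene), function(g) {
    g <- g[complete.cases(g[, c("expr", "alt", covars)]), , drop = FALSE]
    if (length(unique(g$alt)) < 2 || sd(g$expr) < 1e-12) return(NULL)
    m0 <- lm(as.formula(paste("expr ~", rhs0)), data = g)
    m1 <- lm(as.formula(paste("expr ~", rhs0, "+ alt")), data = g)
    p <- anova(m0, m1, test = "Chisq")$`Pr(>Chi)`[2]
    tibble(gene = g$gene[1], estimate = coef(m1)[["altTRUE"]], p = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) input_error("no testable genes")
  mutate(out, q = p.adjust(.data$p, method = "BH"),
         significant = .data$q < alpha_fdr)
}
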