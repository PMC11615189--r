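# Expression normalization and per-gene genetic-effect models.

make_gene_inputs <- function(n, gene = "g1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(gene = gene,
                 eqtl_gt = rbinom(n, 2, 0.3),
                 eqtl_het = rbinom(n, 1, 0.5) == 1,
                 logr_gene = rnorm(n, 0, 0.5),
                 cn_ratio = runif(n, 0.5, 1),
                 sv = runif(n) < 0.05,
                 prom_snv = runif(n) < 0.05,
                 gene_snv = runif(n) < 0.05,
                 purity = runif(n, 0.3, 1),
                 mycn_amp = runif(n) < 0.2,
                 log_cov = log(rpois(n, 60) + 1))
}

test_that("normalization centers every cohort and ignores library scale", {
  counts <- tidyr::expand_grid(sample = sprintf("s%02d", 1:8),
                               gene = c("g1", "g2"))
  set.seed(41)
  counts$count <- rpois(nrow(counts), 100)
  cohorts <- tibble::tibble(sample = sprintf("s%02d", 1:8),
                            cohort = rep(c("A", "B"), each = 4))
  res <- normalize_expression(counts, cohorts)
  means <- dplyr::left_join(res, cohorts, by = "sample") |>
    dplyr::group_by(gene, cohort) |>
    dplyr::summarise(m = mean(expr), .groups = "drop")
  expect_true(all(abs(means$m) < 1e-12))
  doubled <- dplyr::mutate(counts, count = count * 2)
  expect_equal(normalize_expression(doubled, cohorts)$expr, res$expr,
               tolerance = 1e-12)
  zero <- dplyr::mutate(counts, count = ifelse(gene == "g2", 0, count))
  expect_message(z <- normalize_expression(zero, cohorts), "zero counts")
  expect_false("g2" %in% z$gene)
})

test_that("a planted batch shift is fully removed on null genes", {
  set.seed(42)
  counts <- tidyr::expand_grid(sample = sprintf("s%02d", 1:40),
                               gene = sprintf("g%02d", 1:20))
  batch <- rep(c("A", "B"), each = 20)[match(counts$sample,
                                             sprintf("s%02d", 1:40))]
  counts$count <- rpois(nrow(counts),
                        exp(5 + 0.5 * (batch == "B") +
                              rnorm(nrow(counts), 0, 0.3)))
  cohorts <- tibble::tibble(sample = sprintf("s%02d", 1:40),
                            cohort = rep(c("A", "B"), each = 20))
  res <- normalize_expression(counts, cohorts)
  res <- dplyr::left_join(res, cohorts, by = "sample")
  expect_gt(sd(res$expr), 0)
  for (g in unique(res$gene)) {
    p <- anova(lm(expr ~ cohort, data = res[res$gene == g, ]))$`Pr(>F)`[1]
    expect_gt(p, 0.99)   # residualization removes the factor exactly
  }
})

test_that("a noise-free dosage gene puts all variance on the CN term", {
  d <- make_gene_inputs(40, seed = 43)
  d$expr <- 2 * d$logr_gene
  dec <- suppressWarnings(decompose_expression(d))  # perfect fit
  tab <- tidy(dec)
  cn <- tab[tab$effect == "logr_gene", ]
  expect_gt(cn$ss_fraction, 0.95)
  others <- tab[!tab$effect %in% c("logr_gene", "Residuals"), ]
  expect_true(all(others$ss_fraction < 0.05))
})

test_that("sequential fractions sum to one and survive affine rescaling", {
  set.seed(44)
  d <- purrr::map_dfr(1:10, function(g) {
    x <- make_gene_inputs(50, gene = sprintf("g%02d", g))
    x$expr <- 0.4 * x$logr_gene + 0.2 * x$eqtl_gt + rnorm(50, 0, 0.7)
    x
  })
  dec <- decompose_expression(d)
  sums <- tidy(dec) |>
    dplyr::filter(!is.na(ss_fraction)) |>
    dplyr::group_by(gene) |>
    dplyr::summarise(s = sum(ss_fraction))
  expect_true(all(abs(sums$s - 1) < 1e-8))
  d2 <- dplyr::mutate(d, expr = 3 * expr - 7)
  expect_equal(tidy(decompose_expression(d2))$ss_fraction,
               tidy(dec)$ss_fraction, tolerance = 1e-10)
})

test_that("genes below the completeness rule are skipped and logged", {
  d <- make_gene_inputs(30, seed = 45)
  d$expr <- rnorm(30)
  d$gene <- rep(c("big", "small"), c(25, 5))
  dec <- decompose_expression(d)
  expect_identical(dec$skipped, "small")
  expect_false("small" %in% tidy(dec)$gene)
  expect_error(decompose_expression(dplyr::mutate(d[1:5, ], gene = "x")),
               class = "nbd_input_error")
})

test_that("constant predictors are dropped per gene, not fatal", {
  d <- make_gene_inputs(30, seed = 46)
  d$sv <- FALSE
  d$expr <- rnorm(30)
  tab <- tidy(decompose_expression(d))
  expect_true(is.na(tab$ss_fraction[tab$effect == "sv"]))
  expect_false(anyNA(tab$ss_fraction[tab$effect == "logr_gene"]))
})

test_that("pure-noise genes show no significant effects", {
  set.seed(47)
  d <- purrr::map_dfr(1:40, function(g) {
    x <- make_gene_inputs(60, gene = sprintf("g%02d", g))
    x$expr <- rnorm(60)
    x
  })
  dec <- decompose_expression(d)
  tab <- tidy(dec)
  expect_lte(sum(tab$significant), 1)
  # null fractions have expectation ~ df / (n - 1)
  cn <- tab[tab$effect == "logr_gene", ]
  expect_lt(abs(mean(cn$ss_fraction) - 1 / 59), 3 * sd(cn$ss_fraction) /
              sqrt(nrow(cn)) + 0.005)
})

test_that("ASE decomposition recovers a pure copy-ratio response", {
  d <- make_gene_inputs(40, seed = 48)
  d$ase_ratio <- d$cn_ratio
  tab <- tidy(suppressWarnings(decompose_ase(d)))   # perfect fit
  expect_gt(tab$ss_fraction[tab$effect == "cn_ratio"], 0.95)
})

test_that("allelic-dosage test signs match the planted regulation", {
  set.seed(49)
  n <- 60
  # loss-of-imprinting: lower ratio, higher expression -> negative slope
  loi <- purrr::map_dfr(1:3, function(g) {
    u <- runif(n)
    tibble::tibble(gene = paste0("loi", g),
                   ase_ratio = 0.95 - 0.4 * u + rnorm(n, 0, 0.02),
                   expr = u + rnorm(n, 0, 0.1),
                   cohort = sample(c("A", "B"), n, TRUE),
                   purity = runif(n, 0.3, 1), log_cov = log(60))
  })
  # mono-allelic amplification: ratio and expression rise together
  amp <- purrr::map_dfr(1:3, function(g) {
    u <- runif(n)
    tibble::tibble(gene = paste0("amp", g),
                   ase_ratio = 0.5 + 0.45 * u + rnorm(n, 0, 0.02),
                   expr = u + rnorm(n, 0, 0.1),
                   cohort = sample(c("A", "B"), n, TRUE),
                   purity = runif(n, 0.3, 1), log_cov = log(60))
  })
  nulls <- purrr::map_dfr(1:3, function(g) {
    tibble::tibble(gene = paste0("null", g),
                   ase_ratio = 0.5 + abs(rnorm(n, 0, 0.03)),
                   expr = rnorm(n),
                   cohort = sample(c("A", "B"), n, TRUE),
                   purity = runif(n, 0.3, 1), log_cov = log(60))
  })
  got <- ad_gene_test(dplyr::bind_rows(loi, amp, nulls))
  expect_true(all(got$ad[startsWith(got$gene, "loi")]))
  expect_true(all(got$estimate[startsWith(got$gene, "loi")] < 0))
  expect_true(all(got$ad[startsWith(got$gene, "amp")]))
  expect_true(all(got$estimate[startsWith(got$gene, "amp")] > 0))
  expect_false(any(got$ad[startsWith(got$gene, "null")]))
})

test_that("ALT expression scan finds planted effects, not confounded ones", {
  set.seed(50)
  n <- 80
  alt <- rbinom(n, 1, 0.25) == 1
  mycn <- rbinom(n, 1, 0.2) == 1
  covs <- tibble::tibble(sample = seq_len(n), alt = alt, mycn_amp = mycn,
                         age = runif(n, 0, 10),
                         sex = sample(c("F", "M"), n, TRUE),
                         cohort = sample(c("A", "B"), n, TRUE),
                         purity = runif(n, 0.3, 1))
  d <- purrr::map_dfr(1:12, function(g) {
    eff <- if (g <= 4) 1.5 * alt else if (g <= 8) 1.5 * mycn else 0
    dplyr::mutate(covs, gene = sprintf("g%02d", g),
                  expr = eff + rnorm(n, 0, 0.5))
  })
  got <- alt_de_scan(d)
  planted <- got[got$gene %in% sprintf("g%02d", 1:4), ]
  expect_true(all(planted$significant))
  expect_true(all(planted$estimate > 0))
  confounded <- got[got$gene %in% sprintf("g%02d", 5:8), ]
  expect_false(any(confounded$significant))
  expect_error(alt_de_scan(dplyr::mutate(d, alt = TRUE)),
               class = "nbd_input_error")
})
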