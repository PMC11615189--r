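# ASE: site filters, bi-allelic noise test, reference bias, haplotype
# aggregation, AEI testing and per-gene summaries.

test_that("site filter implements the 8-total / 2-allelic rule", {
  s <- tibble::tibble(refCount = c(6, 7, 4), altCount = c(2, 1, 3))
  kept <- filter_sites(s)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$refCount, 6)
  expect_equal(attr(kept, "dropped"), 2)
  # "either" reading keeps sites where one allele alone reaches the cutoff
  expect_equal(nrow(filter_sites(s, rule = "either")), 2)
})

test_that("bi-allelic test uses the pooled noise rate, upper tail", {
  s <- tibble::tibble(refCount = c(20, 30), altCount = c(10, 0),
                      otherBases = c(2, 1), rawDepth = c(32, 31))
  got <- biallelic_test(s)
  p0 <- 3 / 63
  expect_equal(attr(got, "p0"), p0)
  expect_equal(got$p_biallelic[1], oracle_binom_upper(10, 30, p0),
               tolerance = 1e-12)
  expect_equal(got$p_biallelic[2], 1)           # min count 0 -> p = 1
  expect_false(got$biallelic[2])
  # p0 = 0.01, min 10 of 30: essentially 0, flagged bi-allelic
  s2 <- tibble::tibble(refCount = c(rep(300, 9), 20),
                       altCount = c(rep(0, 9), 10),
                       otherBases = rep(3, 10), rawDepth = rep(303, 10))
  got2 <- biallelic_test(s2)
  expect_lt(got2$p_biallelic[10], 1e-8)
  expect_true(got2$biallelic[10])
  expect_warning(
    biallelic_test(tibble::tibble(refCount = 10, altCount = 10,
                                  otherBases = 0, rawDepth = 20)),
    "floor")
})

test_that("mono-allelic noise sites are rejected at the FDR rate or below", {
  set.seed(12)
  n <- 5000
  depth <- rpois(n, 40) + 5
  noise <- rbinom(n, depth, 0.01)
  s <- tibble::tibble(refCount = depth - noise, altCount = noise,
                      otherBases = rbinom(n, depth, 0.005)) |>
    dplyr::mutate(rawDepth = refCount + altCount + otherBases)
  got <- biallelic_test(s)
  expect_lte(mean(got$biallelic), 0.05 * 1.1)
})

test_that("reference bias is the mean reference fraction", {
  s <- tibble::tibble(refCount = c(50, 54), altCount = c(50, 46))
  expect_equal(estimate_ref_bias(s), 0.52)
  set.seed(13)
  d <- rpois(10000, 60)
  sym <- tibble::tibble(refCount = rbinom(10000, d, 0.5))
  sym$altCount <- d - sym$refCount
  expect_lt(abs(estimate_ref_bias(sym) - 0.5), 0.005)
  bias <- tibble::tibble(refCount = rbinom(10000, d, 0.55))
  bias$altCount <- d - bias$refCount
  expect_lt(abs(estimate_ref_bias(bias) - 0.55), 0.01)
  expect_warning(out <- estimate_ref_bias(sym[0, ]), "no qualifying")
  expect_true(is.na(out))
})

test_that("haplotype aggregation is exact bookkeeping", {
  s <- tibble::tibble(gene = "g1",
                      refCount = c(10, 3), altCount = c(5, 12),
                      haplotype = c("0|1", "1|0"))
  got <- aggregate_haplotypes(s, min_counts = 10)
  expect_equal(got$a, 22)                      # 10 (ref on A) + 12 (alt on A)
  expect_equal(got$b, 8)
  expect_equal(got$ase_ratio, 22 / 30)
  # conservation: a + b equals total retained allelic counts
  expect_equal(got$a + got$b, sum(s$refCount + s$altCount))
  # gene below 10 counts is dropped
  small <- tibble::tibble(gene = "g2", refCount = 4, altCount = 5,
                          haplotype = "0|1")
  expect_equal(nrow(aggregate_haplotypes(small)), 0)
  # phase flip swaps (a, b), leaves the ratio unchanged
  flipped <- dplyr::mutate(s, haplotype = ifelse(haplotype == "0|1",
                                                 "1|0", "0|1"))
  got_f <- aggregate_haplotypes(flipped, min_counts = 10)
  expect_equal(got_f$a, got$b)
  expect_equal(got_f$ase_ratio, got$ase_ratio)
  expect_warning(
    aggregate_haplotypes(dplyr::mutate(s, haplotype = c("0/1", "1|0"))),
    "unphased")
})

test_that("ase_ratio stays in [0.5, 1] under haplotype relabeling", {
  set.seed(14)
  for (i in 1:20) {
    n_sites <- sample(1:4, 1)
    s <- tibble::tibble(gene = "g",
                        refCount = rpois(n_sites, 30),
                        altCount = rpois(n_sites, 30),
                        haplotype = sample(c("0|1", "1|0"), n_sites, TRUE))
    g <- aggregate_haplotypes(s, min_counts = 1)
    expect_gte(g$ase_ratio, 0.5)
    expect_lte(g$ase_ratio, 1)
  }
})

test_that("AEI p-values equal exact minlike enumeration", {
  g <- tibble::tibble(a = c(25, 22), b = c(25, 8))
  got <- aei_test(g)
  expect_equal(got$p_aei[1], 1)
  expect_false(got$aei[1])
  expect_equal(got$p_aei[2], oracle_binom_two_sided(22, 30),
               tolerance = 1e-12)
})

test_that("BH adjustment agrees with an independent step-up reference", {
  set.seed(15)
  for (i in 1:5) {
    p <- runif(200)^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # and the aei q-values are BH of the raw p
  a <- rbinom(100, 60, 0.6)
  got <- aei_test(tibble::tibble(a = a, b = 60 - a))
  expect_equal(got$q_aei, oracle_bh(got$p_aei), tolerance = 1e-12)
})

test_that("AEI power at ratio 0.8, depth 60 beats 0.8 and the oracle agrees", {
  set.seed(16)
  n_genes <- 2000
  is_eff <- rep(c(TRUE, FALSE), c(1000, 1000))
  a <- rbinom(n_genes, 60, ifelse(is_eff, 0.8, 0.5))
  got <- aei_test(tibble::tibble(a = a, b = 60 - a))
  power <- mean(got$aei[is_eff])
  expect_gte(power, 0.8)
  # BH with ~half the genes affected rejects near raw alpha 0.025; the
  # exact-power oracle there agrees within Monte Carlo error
  expect_lt(abs(power - oracle_binom_power(60, 0.8, alpha = 0.05 / 2)),
            0.01)
})

test_that("per-gene summaries count AEI frequency and rank imprinted genes", {
  ga <- tibble::tibble(gene = rep(c("g1", "g2"), c(3, 2)),
                       ase_ratio = c(0.9, 0.8, 0.95, 0.55, 0.5),
                       aei = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  got <- gene_ase_summary(ga)
  expect_equal(got$aei_freq[got$gene == "g1"], 2 / 3)
  # a constitutively imprinted simulated gene tops the mean-ratio ranking
  set.seed(17)
  genes <- purrr::map_dfr(1:100, function(g) {
    p <- if (g == 1) 0.96 else 0.5
    a <- rbinom(30, 80, p)
    tibble::tibble(gene = sprintf("g%03d", g), a = a, b = 80 - a)
  })
  res <- aei_test(dplyr::mutate(genes,
                                ase_ratio = pmax(a, b) / (a + b)))
  summ <- gene_ase_summary(res, imprinted = "g001")
  expect_equal(summ$gene[which.max(summ$mean_ratio)], "g001")
  enr <- attr(summ, "enrichment")
  expect_lt(enr$p_enrichment[enr$statistic == "mean_ratio"], 0.05)
})

test_that("imprinting enrichment p is calibrated under label permutation", {
  set.seed(18)
  genes <- purrr::map_dfr(1:60, function(g) {
    a <- rbinom(20, 60, 0.5)
    tibble::tibble(gene = sprintf("g%02d", g),
                   ase_ratio = pmax(a, 60 - a) / 60,
                   aei = FALSE)
  })
  ps <- replicate(200, {
    lab <- sample(unique(genes$gene), 8)
    attr(gene_ase_summary(genes, imprinted = lab),
         "enrichment")$p_enrichment[2]
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps < 0.05), 0.1)
})
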