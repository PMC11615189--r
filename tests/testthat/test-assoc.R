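# ATRX deletion detection, WGD bootstrap, Fisher enrichment and the
# arm/bin association scans.

test_that("ATRX detector applies the gap and proportion rules", {
  set.seed(61)
  del <- tibble::tibble(signal = c(rnorm(60, 0, 0.2), rnorm(40, -2, 0.2)))
  expect_true(detect_atrx_deletion(del)$deleted)
  flat <- tibble::tibble(signal = rnorm(100, 0, 0.2))
  expect_false(detect_atrx_deletion(flat)$deleted)
  # 5% of bins deleted: below the 10% weight-ratio rule
  tiny <- tibble::tibble(signal = c(rnorm(190, 0, 0.2), rnorm(10, -2, 0.2)))
  got <- detect_atrx_deletion(tiny)
  expect_false(got$deleted)
  const <- tibble::tibble(signal = rep(0.3, 100))
  res <- detect_atrx_deletion(const)
  expect_false(res$deleted)
  expect_match(res$note, "degenerate")
  expect_error(detect_atrx_deletion(tibble::tibble(signal = rnorm(10))),
               class = "nbd_input_error")
})

test_that("WGD bootstrap is exact for deterministic callers", {
  seg <- tibble::tibble(chrom = 1:22, start = 1, end = 1e6,
                        cn_major = 1, cn_minor = 1)
  always <- wgd_bootstrap(seg, caller = function(x) TRUE, seed = 1)
  expect_true(always$wgd)
  expect_equal(always$frac_positive, 1)
  never <- wgd_bootstrap(seg, caller = function(x) FALSE, seed = 1)
  expect_false(never$wgd)
  expect_equal(never$frac_positive, 0)
  # resample-independent callers give identical fractions across seeds
  expect_equal(wgd_bootstrap(seg, caller = function(x) TRUE, seed = 99),
               always)
  err <- function(x) stop("boom")
  expect_error(wgd_bootstrap(seg, caller = err),
               class = "nbd_numerical_error")
})

test_that("bootstrap positivity matches a direct resampling oracle", {
  # caller positive when >= 12 of the drawn chromosomes are tetraploid;
  # 11 of 22 source chromosomes are tetraploid, so each draw hits with
  # probability 1/2 and P(positive draw) = P(Binom(22, 0.5) >= 12)
  seg <- tibble::tibble(chrom = 1:22, start = 1, end = 1e6,
                        cn_major = rep(c(2, 1), each = 11),
                        cn_minor = rep(c(2, 1), each = 11))
  caller <- function(prof) sum(prof$cn_major == 2) >= 12
  fr <- purrr::map_dbl(1:30, function(s) {
    wgd_bootstrap(seg, caller = caller, n_boot = 100,
                  seed = s)$frac_positive
  })
  p_draw <- pbinom(11, 22, 0.5, lower.tail = FALSE)
  se <- sqrt(p_draw * (1 - p_draw) / 100) / sqrt(30)
  expect_lt(abs(mean(fr) - p_draw), 4 * se)
})

test_that("default WGD caller keys on genome length at high copy number", {
  tetra <- tibble::tibble(chrom = 1:4, start = 1, end = 1e7,
                          cn_major = 2, cn_minor = 2)
  expect_true(default_wgd_caller(tetra))
  dipl <- dplyr::mutate(tetra, cn_major = 1, cn_minor = 1)
  expect_false(default_wgd_caller(dipl))
})

test_that("WGD enrichment expectations and p-values behave", {
  d <- tibble::tibble(
    tmm_label = rep(c("None", "ALT", "CTM", "Mix"), c(51, 20, 43, 1)),
    wgd = c(rep(c(TRUE, FALSE), c(26, 25)), rep(c(TRUE, FALSE), c(2, 18)),
            rep(c(TRUE, FALSE), c(16, 27)), FALSE))
  got <- fisher_wgd_enrichment(d)
  expect_equal(got$expected[got$group == "None"], 20)
  expect_equal(got$expected[got$group == "ALT"], 8)
  expect_equal(got$expected[got$group == "CTM"], 16)
  # expected counts re-add to the WGD total within rounding
  expect_lte(abs(sum(got$expected) - sum(d$wgd)), nrow(got) * 0.5)
  # identical prevalence in every group: no enrichment anywhere
  flat <- tibble::tibble(tmm_label = rep(c("A", "B"), each = 40),
                         wgd = rep(rep(c(TRUE, FALSE), c(10, 30)), 2))
  expect_true(all(fisher_wgd_enrichment(flat)$p > 0.99))
})

test_that("arm scan flags a planted 11q loss with the right direction", {
  set.seed(62)
  n <- 100
  alt <- rbinom(n, 1, 0.25) == 1
  arms <- as.data.frame(matrix(rnorm(n * 10, 0, 0.3), n))
  names(arms) <- paste0(rep(1:5, each = 2), c("p", "q"))
  arms[["4q"]] <- ifelse(alt, rnorm(n, -0.8, 0.2), rnorm(n, 0, 0.2))
  arms$alt <- alt
  cov <- tibble::tibble(mycn_amp = rbinom(n, 1, 0.2) == 1,
                        atrx = rbinom(n, 1, 0.1) == 1,
                        age = runif(n, 0, 10),
                        sex = sample(c("F", "M"), n, TRUE),
                        cohort = sample(c("A", "B"), n, TRUE),
                        purity = runif(n, 0.3, 1),
                        ploidy = sample(c(2, 3.6), n, TRUE))
  got <- arm_alt_association(arms, cov)
  hit <- got[got$region == "4q", ]
  expect_true(hit$significant)
  expect_equal(hit$direction, "loss")
  expect_false(any(got$significant[got$region != "4q"]))
})

test_that("an ALT signal carried entirely by a covariate is not flagged", {
  set.seed(63)
  n <- 100
  atrx <- rbinom(n, 1, 0.3) == 1
  alt <- runif(n) < ifelse(atrx, 0.7, 0.1)
  arms <- tibble::tibble(`1p` = ifelse(atrx, -0.5, 0) + rnorm(n, 0, 0.3),
                         `1q` = rnorm(n, 0, 0.3), alt = alt)
  cov <- tibble::tibble(atrx = atrx, purity = runif(n, 0.3, 1))
  got <- arm_alt_association(arms, cov)
  expect_false(any(got$significant))
})

test_that("bin survival scan merges adjacent significant bins", {
  set.seed(64)
  n <- 120
  imb <- rbinom(n, 1, 0.3)
  dec <- runif(n) < plogis(-2 + 2.5 * imb)
  bins <- tibble::tibble(deceased = dec)
  for (b in 0:5) {
    bins[[sprintf("chr1:%d", b * 5e6 + 1)]] <- rnorm(n, 0, 0.05) + 0.5
  }
  # two adjacent informative bins on chr2
  bins[["chr2:1"]] <- 0.5 + 0.45 * imb + rnorm(n, 0, 0.03)
  bins[["chr2:5000001"]] <- 0.5 + 0.45 * imb + rnorm(n, 0, 0.03)
  cov <- tibble::tibble(mycn_amp = rbinom(n, 1, 0.2) == 1,
                        age = runif(n, 0, 10),
                        stage4 = rbinom(n, 1, 0.4) == 1,
                        sex = sample(c("F", "M"), n, TRUE),
                        purity = runif(n, 0.3, 1),
                        ploidy = sample(c(2, 3.6), n, TRUE))
  got <- bin_survival_association(bins, cov)
  sig <- got$bins[got$bins$significant, ]
  expect_setequal(sig$region, c("chr2:1", "chr2:5000001"))
  expect_equal(nrow(got$merged_regions), 1)
  expect_equal(got$merged_regions$n_bins, 2)
})
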