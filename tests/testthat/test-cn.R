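# BAF/LogR computation, mirrored-BAF segmentation, allele-specific
# copy-number inversion, state classification and region summaries.

test_that("compute_baf_logr applies the printed definitions and filter", {
  sites <- tibble::tibble(refT = c(15, 30, 21, 3), altT = c(15, 30, 9, 2),
                          refN = c(15, 15, 15, 20), altN = c(15, 15, 15, 10))
  out <- compute_baf_logr(sites, min_depth = 10)
  expect_equal(attr(out, "dropped"), 1)            # the depth-5 tumor site
  expect_equal(out$baf, c(0.5, 0.5, 0.3))
  # mean depths: tumor (30+60+30)/3 = 40, normal 30
  expect_equal(out$logr, log2(c(30 / 30, 60 / 30, 30 / 30) / (40 / 30)))
  d2 <- tibble::tibble(refT = c(15, 30), altT = c(15, 30),
                       refN = c(15, 15), altN = c(15, 15))
  out2 <- compute_baf_logr(d2)
  expect_equal(out2$logr[2] - out2$logr[1], 1)     # doubled depth: +1 LogR
})

test_that("segmentation finds planted breakpoints and nothing else", {
  set.seed(11)
  flat <- tibble::tibble(chrom = 1, pos = seq_len(1000) * 1e4,
                         baf = 0.5 + rnorm(1000, 0, 0.02), logr = 0)
  expect_equal(nrow(segment_baf(flat)), 1)
  step <- tibble::tibble(chrom = 1, pos = seq_len(1000) * 1e4,
                         baf = 0.5 - c(rep(0, 500), rep(0.25, 500)) +
                           rnorm(1000, 0, 0.02),
                         logr = 0)
  seg <- segment_baf(step)
  expect_equal(nrow(seg), 2)
  expect_lte(abs(seg$end_idx[1] - 500), 2)
  two <- tibble::tibble(chrom = 1, pos = seq_len(900) * 1e4,
                        baf = 0.5 - rep(c(0, 0.2, 0.05), each = 300) +
                          rnorm(900, 0, 0.02),
                        logr = 0)
  seg2 <- segment_baf(two)
  expect_equal(nrow(seg2), 3)
  expect_lte(abs(seg2$end_idx[1] - 300), 2)
  expect_lte(abs(seg2$end_idx[2] - 600), 2)
  expect_warning(segment_baf(flat[0, ]), "empty")
})

test_that("segment LogR is the mean LogR of the segment's sites", {
  x <- tibble::tibble(chrom = 1, pos = seq_len(200) * 1e3,
                      baf = rep(c(0.5, 0.25), each = 100),
                      logr = rep(c(0, 0.585), each = 100))
  seg <- segment_baf(x)
  expect_equal(seg$logr, c(0, 0.585))
})

test_that("allele-CN inversion reproduces the worked round trips", {
  expect_equal(
    estimate_allele_cn(tibble::tibble(baf = 0.5, logr = 0), 1, 2)[
      , c("cn_major", "cn_minor")],
    tibble::tibble(cn_major = 1L, cn_minor = 1L))
  expect_equal(
    estimate_allele_cn(tibble::tibble(baf = 1 / 3, logr = log2(1.5)), 1, 2)[
      , c("cn_major", "cn_minor")],
    tibble::tibble(cn_major = 2L, cn_minor = 1L))
  expect_equal(
    estimate_allele_cn(tibble::tibble(baf = 0.25, logr = 0), 0.5, 2)[
      , c("cn_major", "cn_minor")],
    tibble::tibble(cn_major = 2L, cn_minor = 0L))
  expect_error(estimate_allele_cn(tibble::tibble(baf = 0.5, logr = 0), 0, 2),
               class = "nbd_domain_error")
})

test_that("tie-breaking prefers smaller totals then larger minor counts", {
  # (0.25, -0.5) at purity 1, ploidy 2 is equidistant from (1,0), (1,1) and
  # (2,0): the smaller total wins
  t1 <- estimate_allele_cn(tibble::tibble(baf = 0.25, logr = -0.5), 1, 2)
  expect_equal(c(t1$cn_major, t1$cn_minor), c(1L, 0L))
  # (0.25, 0) is equidistant from (2,0) and (1,1): equal totals, larger
  # minor wins
  t2 <- estimate_allele_cn(tibble::tibble(baf = 0.25, logr = 0), 1, 2)
  expect_equal(c(t2$cn_major, t2$cn_minor), c(1L, 1L))
})

test_that("state classifier matches the printed worked examples", {
  got <- classify_cn_state(tibble::tibble(cn_major = c(3, 1, 2),
                                          cn_minor = c(2, 1, 0)), ploidy = 2)
  expect_equal(as.character(got$state),
               c("medium gain", "neutral", "neutral"))
  expect_equal(as.character(got$balance),
               c("weak imbalance", "balance", "strong imbalance"))
  expect_equal(got$loh, c(FALSE, FALSE, TRUE))
  amp <- classify_cn_state(
    tibble::tibble(cn_major = 6, cn_minor = 1, chrom = 1,
                   start = 1, end = 5e6, logr_seg = 1.0),
    ploidy = 2, logr_contig = 0)
  expect_equal(as.character(amp$state), "amplification")
  expect_equal(as.character(amp$balance), "amplification")
})

test_that("gene amplification combines state and gene LogR", {
  g <- tibble::tibble(state = c("amplification", "neutral", "weak gain"),
                      logr_gene = c(1.0, 2.6, 0.4))
  expect_equal(gene_amplification(g)$amplified, c(TRUE, TRUE, FALSE))
  expect_warning(gene_amplification(tibble::tibble(state = "neutral",
                                                   logr_gene = NA)),
                 "skipped")
})

test_that("region summaries follow overlap weights and the override", {
  seg <- tibble::tibble(chrom = 1, start = c(1, 3e6 + 1),
                        end = c(3e6, 5e6),
                        cn_ratio = c(1, 0.5), logr_seg = c(0, 0),
                        state = "neutral")
  bin <- tibble::tibble(region = "b", chrom = 1, start = 1, end = 5e6)
  expect_equal(summarize_region(seg, bin, values = "cn_ratio")$cn_ratio, 0.8)
  segA <- tibble::tibble(chrom = 1, start = c(1, 1e6 + 1),
                         end = c(1e6, 5e6),
                         cn_ratio = c(0.9, 0.5), logr_seg = c(3, 0),
                         state = c("amplification", "neutral"))
  got <- summarize_region(segA, bin, values = c("logr_seg", "cn_ratio"),
                          amp_override = TRUE)
  expect_equal(got$logr_seg, 3)
  expect_equal(got$cn_ratio, 0.9)
  # single segment covering an arm: summary equals the segment value
  one <- tibble::tibble(chrom = 1, start = 1, end = 1e7, cn_ratio = 0.7,
                        logr_seg = 0.2, state = "neutral")
  arm <- tibble::tibble(region = "1p", chrom = 1, start = 1, end = 1e7)
  expect_equal(summarize_region(one, arm, values = "cn_ratio")$cn_ratio, 0.7)
  # dominant state by largest overlap
  expect_equal(summarize_region(segA, bin, mode = "dominant_state")$state,
               "neutral")
  # no overlap: missing value
  far <- tibble::tibble(region = "x", chrom = 2, start = 1, end = 1e6)
  expect_true(is.na(summarize_region(seg, far,
                                     values = "cn_ratio")$cn_ratio))
})

test_that("weighted summaries are invariant to segment splitting", {
  set.seed(5)
  seg <- tibble::tibble(chrom = 1, start = c(1, 4e6 + 1), end = c(4e6, 9e6),
                        cn_ratio = c(0.8, 0.55), logr_seg = c(0.3, -0.2),
                        state = "neutral")
  split_seg <- tibble::tibble(
    chrom = 1, start = c(1, 2e6 + 1, 4e6 + 1, 7e6 + 1),
    end = c(2e6, 4e6, 7e6, 9e6),
    cn_ratio = c(0.8, 0.8, 0.55, 0.55),
    logr_seg = c(0.3, 0.3, -0.2, -0.2), state = "neutral")
  reg <- tibble::tibble(region = c("r1", "r2"), chrom = 1,
                        start = c(1, 3e6), end = c(6e6, 9e6))
  expect_equal(summarize_region(seg, reg, values = c("cn_ratio", "logr_seg")),
               summarize_region(split_seg, reg,
                                values = c("cn_ratio", "logr_seg")))
})

test_that("breakpoint recovery on planted profiles is accurate", {
  # random multi-segment mirrored-BAF profiles at the default BAF noise
  # (sd 0.02), the regime the changepoint engine is designed for; segments
  # hold >= 30 sites and steps are >= 0.08 mirrored units
  set.seed(21)
  levels_pool <- c(0, 1 / 12, 1 / 6, 0.25, 1 / 3, 0.5)
  hits <- 0; truth_n <- 0; called_n <- 0; matched_calls <- 0
  for (rep in 1:30) {
    k <- sample(1:4, 1)
    lens <- sample(30:200, k + 1, replace = TRUE)
    lv <- numeric(k + 1)
    lv[1] <- sample(levels_pool, 1)
    for (j in seq_len(k) + 1) {
      lv[j] <- sample(levels_pool[abs(levels_pool - lv[j - 1]) > 0.08], 1)
    }
    truth_bp <- cumsum(lens)[seq_len(k)]
    x <- 0.5 - rep(lv, lens) + rnorm(sum(lens), 0, 0.02)
    seg <- segment_baf(tibble::tibble(chrom = 1, pos = seq_along(x) * 1e4,
                                      baf = x, logr = 0))
    called <- seg$end_idx[-nrow(seg)]
    truth_n <- truth_n + k
    called_n <- called_n + length(called)
    for (b in truth_bp) {
      if (any(abs(called - b) <= 5)) hits <- hits + 1
    }
    for (b in called) {
      if (any(abs(truth_bp - b) <= 5)) matched_calls <- matched_calls + 1
    }
  }
  expect_gte(hits / truth_n, 0.95)             # recall
  expect_gte(matched_calls / called_n, 0.90)   # precision
})
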