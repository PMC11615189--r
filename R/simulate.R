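# Synthetic cohort generator: every input table the analysis consumes, with
# planted ground truth. The genome is abstract (integer-indexed chromosomes,
# no reference sequence); coordinates are 1-based inclusive; centromeres sit
# at 40% of each chromosome length.

TEL_MOTIF <- "TTAGGG"
TEL_MOTIF_RC <- "CCCTAA"

random_seqs <- function(n, len = 150L) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = len)
  apply(m, 2, paste0, collapse = "")
}

# Distinct sorted positions in [1, chrom_len].
random_positions <- function(n, chrom_len) {
  pos <- sort(round(runif(n, 1, chrom_len)))
  while (anyDuplicated(pos)) {
    d <- duplicated(pos)
    pos[d] <- pos[d] + 1L
    pos <- sort(pos)
  }
  pos
}

rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  rbinom(n, size, stats::rbeta(n, a, b))
}

#' Simulate per-gene haplotype RNA counts
#'
#' Draws allelic (haplotype A / haplotype B) RNA read counts for genes whose
#' expected haplotype-A fraction is given, using a binomial model (or
#' beta-binomial when `overdispersion > 0`). The expected fraction is the
#' allelic copy ratio of the gene modulated by any planted eQTL or imprinting
#' effect, which is how the cohort generator produces its allele-specific
#' expression inputs.
#'
#' @param genes Data frame with one row per gene x sample observation and a
#'   numeric column `p_a`, the expected fraction of reads from haplotype A.
#' @param depth Mean total allelic depth per observation (Poisson).
#' @param overdispersion Beta-binomial rho; 0 keeps counts binomial.
#' @param seed Integer seed.
#' @return The input tibble with integer columns `a`, `b` appended.
#' @examples
#' simulate_gene_ase(tibble::tibble(p_a = c(0.5, 0.75)), depth = 100, seed = 1)
#' @export
simulate_gene_ase <- function(genes, depth, overdispersion = 0, seed = 1L) {
  stopifnot(is.data.frame(genes), "p_a" %in% names(genes), depth >= 1)
  with_seed(seed, {
    n <- nrow(genes)
    d <- pmax(1L, rpois(n, depth))
    a <- rbetabinom(n, d, clamp01(genes$p_a), overdispersion)
    dplyr::mutate(as_tibble(genes), a = as.integer(a),
                  b = as.integer(d - a))
  })
}

# ---- sample-level truth -----------------------------------------------------

sim_sample_truth <- function(cfg) {
  n <- cfg$n_samples
  mix <- cfg$tmm_mixture
  purity <- runif(n, cfg$purity_range[1], cfg$purity_range[2])
  if (cfg$noise_sd_baf == 0 && cfg$noise_sd_logr == 0) {
    # noise-free limit: hold purity at the upper bound so expected values are
    # exactly reproducible from emitted integer counts
    purity <- rep(cfg$purity_range[2], n)
  }
  wgd <- runif(n) < cfg$wgd_fraction
  mycn_amp <- runif(n) < cfg$mycn_fraction
  tert_re <- runif(n) < cfg$tert_re_fraction
  alt_mode <- runif(n) < cfg$alt_fraction
  comp_hi <- runif(n) < mix$weights[2]
  tert_z <- rnorm(n, mix$means[comp_hi + 1L], mix$sds[comp_hi + 1L])
  tlr_true <- ifelse(alt_mode, rnorm(n, 1.2, 0.25), rnorm(n, 0, 0.15))
  l_normal <- rep(5, n)                      # arbitrary length unit; TLR
  l_tumor <- l_normal * exp(tlr_true)        # cancels the scale constant
  thr_true <- mixture_posterior_threshold(mix$means, mix$sds, mix$weights)
  tert_high <- tert_z > thr_true & !mycn_amp & !tert_re
  ctm_crit <- mycn_amp | tert_re | tert_high
  alt_crit <- tlr_true > 0.5
  tmm_label <- dplyr::case_when(ctm_crit & alt_crit ~ "Mix",
                                ctm_crit ~ "CTM",
                                alt_crit ~ "ALT",
                                TRUE ~ "None")
  atrx_del <- ifelse(alt_crit,
                     runif(n) < cfg$atrx_del_fraction_alt,
                     runif(n) < 0.02)
  tibble(sample = sprintf("S%03d", seq_len(n)),
         purity = purity, wgd = wgd,
         mycn_amp = mycn_amp, tert_re = tert_re,
         tert_z = tert_z, tert_high = tert_high,
         tlr_true = tlr_true, l_tumor = l_tumor, l_normal = l_normal,
         tmm_label = tmm_label, atrx_del = atrx_del,
         plant_11q = ifelse(alt_crit, runif(n) < 0.9, runif(n) < 0.25),
         plant_17p = runif(n) < 0.2,
         age = runif(n, 0, 10),
         sex = sample(c("F", "M"), n, replace = TRUE),
         cohort = sample(c("A", "B"), n, replace = TRUE),
         stage4 = runif(n) < 0.45,
         tert_threshold_true = thr_true)
}

# ---- genome layout ----------------------------------------------------------

sim_genome <- function(cfg) {
  n_chr <- cfg$n_chromosomes
  snps <- purrr::map_dfr(seq_len(n_chr), function(ch) {
    pos <- random_positions(cfg$snps_per_chrom, cfg$chrom_lengths[ch])
    ba <- matrix(sample(c("A", "C", "G", "T"), 2 * length(pos), replace = TRUE),
                 ncol = 2)
    ba[ba[, 1] == ba[, 2], 2] <- "T"
    ba[ba[, 1] == ba[, 2], 1] <- "A"
    tibble(chrom = ch, pos = pos, ref = ba[, 1], alt = ba[, 2],
           maf = runif(length(pos), 0.1, 0.5))
  })
  mycn_chr <- min(2L, n_chr)
  tert_chr <- min(5L, n_chr)
  genes <- purrr::map_dfr(seq_len(n_chr), function(ch) {
    L <- cfg$chrom_lengths[ch]
    start <- round(seq(0.05 * L, 0.9 * L, length.out = cfg$genes_per_chrom))
    tibble(gene = sprintf("g%02d_%03d", ch, seq_along(start)),
           chrom = ch, start = start, end = start + 5e4)
  })
  # pin the two marker genes to fixed loci on their (p-arm) chromosomes
  pin <- function(genes, ch, frac, id) {
    L <- cfg$chrom_lengths[ch]
    i <- which(genes$chrom == ch)
    j <- i[which.min(abs(genes$start[i] - frac * L))]
    genes$gene[j] <- id
    genes$start[j] <- round(frac * L)
    genes$end[j] <- genes$start[j] + 5e4
    genes
  }
  genes <- pin(genes, mycn_chr, 0.13, "MYCN")
  genes <- pin(genes, tert_chr, 0.05, "TERT")
  ng <- nrow(genes)
  genes$imprinted <- runif(ng) < cfg$imprinted_fraction
  genes$has_eqtl <- runif(ng) < cfg$eqtl_fraction
  genes$eqtl_maf <- runif(ng, 0.1, 0.5)
  genes$eqtl_beta <- ifelse(genes$has_eqtl, rnorm(ng, 0, 0.4), 0)
  genes$eqtl_ase_shift <- ifelse(genes$has_eqtl, abs(rnorm(ng, 0, 0.5)), 0)
  genes$dosage_coef <- rnorm(ng, 1, 0.15)
  genes$base_expr <- runif(ng, log(50), log(500))
  special <- genes$gene %in% c("MYCN", "TERT")
  genes$imprinted[special] <- FALSE
  genes$has_eqtl[special] <- FALSE
  genes$eqtl_beta[special] <- 0
  genes$eqtl_ase_shift[special] <- 0
  genes$base_expr[genes$gene == "TERT"] <- log(400)
  genes$dosage_coef[genes$gene == "TERT"] <- 0
  list(snps = snps, genes = genes,
       mycn_chr = mycn_chr, mycn_pos = round(0.13 * cfg$chrom_lengths[mycn_chr]))
}

# ---- copy-number segments ---------------------------------------------------

# Breakpoint positions (sorted, interior) for one chromosome.
draw_breaks <- function(rate, chrom_len) {
  k <- min(rpois(1, rate), 8L)
  if (k == 0L) return(numeric(0))
  sort(round(runif(k, 2, chrom_len - 1)))
}

alter_cn <- function(mj, mn) {
  u <- runif(1)
  if (u < 0.35) mj <- mj + 1L
  else if (u < 0.50) { mj <- mj + 1L; mn <- mn + 1L }
  else if (u < 0.75) mn <- max(0L, mn - 1L)
  else if (u < 0.95) mn <- 0L
  else mj <- mj + 2L
  c(min(mj, 12L), min(mn, 12L))
}

sim_segments_one <- function(cfg, smp, genome) {
  n_chr <- cfg$n_chromosomes
  p22 <- min(1, max(0, cfg$ploidy_options[2] - 3))   # P(tetrasomic | WGD)
  out <- vector("list", n_chr)
  for (ch in seq_len(n_chr)) {
    L <- cfg$chrom_lengths[ch]
    cen <- round(0.4 * L)
    base <- if (smp$wgd) {
      if (runif(1) < p22) c(2L, 2L) else c(2L, 1L)
    } else c(1L, 1L)
    br <- draw_breaks(cfg$segment_rate, L)
    # focal amplification: dedicated short segment
    amp_here <- runif(1) < 0.02
    amp_seg <- NULL
    if (amp_here) {
      a0 <- round(runif(1, 1, L - 9e6))
      amp_seg <- c(a0, a0 + round(runif(1, 1e6, 8e6)))
      br <- sort(unique(c(br, amp_seg[1] - 1, amp_seg[2])))
    }
    if (smp$mycn_amp && ch == genome$mycn_chr) {
      m0 <- genome$mycn_pos - 5e5
      mycn_seg <- c(m0, m0 + round(runif(1, 1e6, 4e6)))
      br <- sort(unique(c(br, mycn_seg[1] - 1, mycn_seg[2])))
    } else mycn_seg <- NULL
    starts <- c(1, br + 1)
    ends <- c(br, L)
    k <- length(starts)
    mj <- integer(k); mn <- integer(k)
    for (i in seq_len(k)) {
      cn <- base
      if (runif(1) < 0.35) cn <- alter_cn(base[1], base[2])
      mj[i] <- cn[1]; mn[i] <- cn[2]
    }
    mid <- (starts + ends) / 2
    if (!is.null(amp_seg)) {
      i <- which(starts == amp_seg[1] + ifelse(amp_seg[1] == 1, 0, 0) |
                   (starts == amp_seg[1] & ends == amp_seg[2]))
      i <- which(starts >= amp_seg[1] & ends <= amp_seg[2])
      mj[i] <- sample(8:12, length(i), replace = TRUE); mn[i] <- 1L
    }
    if (!is.null(mycn_seg)) {
      i <- which(starts >= mycn_seg[1] & ends <= mycn_seg[2])
      mj[i] <- 10L; mn[i] <- 1L
    }
    if (smp$plant_11q && ch == 11 && n_chr >= 11) {
      i <- which(mid > cen)
      mn[i] <- 0L
      mj[i] <- pmin(mj[i], base[1])
    }
    if (smp$plant_17p && ch == 17 && n_chr >= 17) {
      i <- which(mid <= cen)
      mn[i] <- 0L
      mj[i] <- base[1] + base[2]
    }
    out[[ch]] <- tibble(chrom = ch, start = starts, end = ends,
                        n_major = pmax(mj, 1L), n_minor = pmin(mn, mj),
                        major_is_hap_a = runif(k) < 0.5)
  }
  dplyr::bind_rows(out)
}

sim_segments <- function(cfg, samples, genome) {
  segs <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    dplyr::mutate(sim_segments_one(cfg, samples[i, ], genome),
                  sample = samples$sample[i], .before = 1)
  })
  segs
}

weighted_ploidy <- function(segs) {
  segs |>
    group_by(.data$sample) |>
    summarise(ploidy = sum((.data$n_major + .data$n_minor) *
                             (.data$end - .data$start + 1)) /
                sum(.data$end - .data$start + 1), .groups = "drop")
}

# ---- per-SNP allelic depths -------------------------------------------------

sim_snp_counts_one <- function(cfg, smp, segs, snps) {
  rho <- smp$purity
  psi <- smp$ploidy
  noise_free <- cfg$noise_sd_baf == 0 && cfg$noise_sd_logr == 0
  res <- vector("list", cfg$n_chromosomes)
  for (ch in seq_len(cfg$n_chromosomes)) {
    sn <- snps[snps$chrom == ch, ]
    sg <- segs[segs$chrom == ch, ]
    idx <- findInterval(sn$pos, sg$start)
    mj <- sg$n_major[idx]; mn <- sg$n_minor[idx]
    maj_a <- sg$major_is_hap_a[idx]
    tot <- mj + mn
    n <- nrow(sn)
    a1 <- as.integer(runif(n) < sn$maf)      # allele on haplotype A
    a2 <- as.integer(runif(n) < sn$maf)
    het <- a1 != a2
    cn_a <- ifelse(maj_a, mj, mn)
    cn_b <- tot - cn_a
    alt_copies <- ifelse(het, ifelse(a1 == 1L, cn_a, cn_b), (a1 + a2) / 2 * tot)
    norm_alt <- a1 + a2                       # alt copies in diploid normal
    exp_baf <- ((1 - rho) * norm_alt / 2 * 2 + rho * alt_copies) /
      ((1 - rho) * 2 + rho * tot)
    exp_logr <- log2(((1 - rho) * 2 + rho * tot) /
                       ((1 - rho) * 2 + rho * psi))
    if (noise_free) {
      d_n <- rep(as.integer(cfg$depth_mean_normal), n)
      target <- cfg$depth_mean_tumor * 2^exp_logr
      if (rho == 1) {
        d_t <- pmax(1L, as.integer(round(target / tot))) * tot
      } else {
        d_t <- pmax(1L, as.integer(round(target)))
      }
      alt_t <- as.integer(round(d_t * exp_baf))
      alt_n <- as.integer(round(d_n * norm_alt / 2))
    } else {
      d_n <- rpois(n, cfg$depth_mean_normal)
      d_t <- rpois(n, cfg$depth_mean_tumor *
                     2^(exp_logr + rnorm(n, 0, cfg$noise_sd_logr)))
      alt_t <- rbinom(n, d_t, clamp01(exp_baf + rnorm(n, 0, cfg$noise_sd_baf)))
      alt_n <- rbinom(n, d_n,
                      clamp01(norm_alt / 2 + rnorm(n, 0, cfg$noise_sd_baf)))
    }
    res[[ch]] <- tibble(chrom = ch, pos = sn$pos, ref = sn$ref, alt = sn$alt,
                        refN = as.integer(d_n - alt_n),
                        altN = as.integer(alt_n),
                        refT = as.integer(d_t - alt_t),
                        altT = as.integer(alt_t),
                        gt = ifelse(het, ifelse(a1 == 1L, "1|0", "0|1"),
                                    ifelse(a1 == 1L, "1|1", "0|0")))
  }
  dplyr::bind_rows(res)
}

# ---- gene-level tables ------------------------------------------------------

gene_segment_lookup <- function(genes, segs) {
  # segment overlapping each gene midpoint, per sample
  purrr::map_dfr(split(segs, segs$sample), function(sg) {
    purrr::map_dfr(split(sg, sg$chrom), function(sc) {
      g <- genes[genes$chrom == sc$chrom[1], ]
      if (nrow(g) == 0) return(NULL)
      idx <- findInterval((g$start + g$end) / 2, sc$start)
      tibble(sample = sc$sample[1], gene = g$gene,
             n_major = sc$n_major[idx], n_minor = sc$n_minor[idx],
             major_is_hap_a = sc$major_is_hap_a[idx])
    })
  })
}

sim_gene_sample <- function(cfg, samples, genes, segs) {
  gs <- gene_segment_lookup(genes, segs) |>
    left_join(select(samples, "sample", "purity", "ploidy", "mycn_amp",
                     "cohort", "tert_z"), by = "sample") |>
    left_join(genes, by = "gene")
  n <- nrow(gs)
  tot <- gs$n_major + gs$n_minor
  rho <- gs$purity
  gs$cn_ratio <- gs$n_major / tot
  gs$logr_gene <- log2(((1 - rho) * 2 + rho * tot) /
                         ((1 - rho) * 2 + rho * gs$ploidy))
  # lead eQTL genotype under HWE
  b1 <- as.integer(runif(n) < gs$eqtl_maf)
  b2 <- as.integer(runif(n) < gs$eqtl_maf)
  gs$eqtl_gt <- b1 + b2
  gs$eqtl_het <- b1 != b2
  gs$sv <- runif(n) < 0.02
  gs$prom_snv <- runif(n) < 0.01
  gs$gene_snv <- runif(n) < 0.03
  # haplotype-A allelic copy ratio in the RNA (normal cells express 1:1)
  cn_a <- ifelse(gs$major_is_hap_a, gs$n_major, gs$n_minor)
  p_a <- (rho * cn_a + (1 - rho)) / (rho * tot + 2 * (1 - rho))
  shift <- ifelse(gs$eqtl_het,
                  gs$eqtl_ase_shift * ifelse(runif(n) < 0.5, 1, -1), 0)
  p_a <- stats::plogis(stats::qlogis(clamp01(p_a)) + shift)
  imprint_to_a <- runif(n) < 0.5
  p_a <- ifelse(gs$imprinted, ifelse(imprint_to_a, 0.95, 0.05), p_a)
  gs$p_a <- p_a
  # expression mean model (log scale); the TERT mixture draw is the gene's
  # expression signal itself, so it carries no extra per-gene noise term
  gene_noise <- rnorm(n, 0, 0.3)
  gene_noise[gs$gene == "TERT"] <- 0
  logmu <- gs$base_expr + gs$eqtl_beta * gs$eqtl_gt +
    gs$dosage_coef * gs$logr_gene -
    0.4 * gs$sv - 0.3 * gs$prom_snv - 0.2 * gs$gene_snv +
    0.3 * gs$purity + ifelse(gs$cohort == "B", 0.3, 0) +
    ifelse(gs$gene == "TERT", 0.6 * gs$tert_z, 0) +
    gene_noise
  gs$expr_count <- rpois(n, exp(pmin(logmu, 12)))
  gs$informative <- runif(n) < 0.8
  select(gs, "sample", "gene", "n_major", "n_minor", "cn_ratio", "logr_gene",
         "eqtl_gt", "eqtl_het", "sv", "prom_snv", "gene_snv", "p_a",
         "expr_count", "informative")
}

sim_ase_sites <- function(cfg, gene_sample, genes) {
  gs <- gene_sample |>
    filter(.data$informative) |>
    left_join(select(genes, "gene", "chrom", "start", "end"), by = "gene")
  n <- nrow(gs)
  n_sites <- sample(1:3, n, replace = TRUE)
  rows <- gs[rep(seq_len(n), n_sites), ]
  rows$site_i <- sequence(n_sites)
  m <- nrow(rows)
  rows$pos <- rows$start + round(runif(m) * (rows$end - rows$start))
  depth <- pmax(1L, rpois(m, cfg$rna_depth_mean /
                            rep(n_sites, n_sites)))
  hap_a <- rbetabinom(m, depth, clamp01(rows$p_a), cfg$overdispersion)
  ref_is_a <- runif(m) < 0.5
  refc <- ifelse(ref_is_a, hap_a, depth - hap_a)
  other <- rpois(m, 0.005 * depth)
  tibble(sample = rows$sample, gene = rows$gene, chrom = rows$chrom,
         pos = as.integer(rows$pos),
         ref = "A", alt = "G",
         refCount = as.integer(refc),
         altCount = as.integer(depth - refc),
         otherBases = as.integer(other),
         rawDepth = as.integer(depth + other),
         haplotype = ifelse(ref_is_a, "0|1", "1|0"))
}

# ---- ATRX coverage bins, telomere and TERRA reads ---------------------------

sim_atrx_bins <- function(cfg, samples) {
  nb <- cfg$atrx_bins
  purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    s <- rnorm(nb, 0, 0.25)
    if (samples$atrx_del[i]) {
      prop <- runif(1, 0.3, 0.55)
      len <- round(prop * nb)
      at <- sample.int(nb - len, 1)
      s[at:(at + len - 1)] <- rnorm(len, -2, 0.25)
    }
    tibble(sample = samples$sample[i], bin = seq_len(nb),
           start = (seq_len(nb) - 1L) * 50L + 1L,
           norm_tumor = 2^s, norm_normal = 1)
  })
}

make_tel_read <- function(n, rc = FALSE) {
  if (n == 0L) return(character(0))
  motif <- if (rc) TEL_MOTIF_RC else TEL_MOTIF
  paste0(strrep(motif, 20), random_seqs(n, 30L), recycle0 = TRUE)
}

sim_tel_reads <- function(cfg, samples) {
  pool <- random_seqs(256L)
  nr <- cfg$reads_per_sample
  purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    purrr::map_dfr(c("T", "N"), function(tissue) {
      frac <- cfg$tel_read_fraction *
        if (tissue == "T") exp(samples$tlr_true[i]) else 1
      k <- rbinom(1, nr, min(frac, 0.9))
      k_rc <- rbinom(1, k, 0.5)
      seqs <- c(make_tel_read(k - k_rc), make_tel_read(k_rc, rc = TRUE),
                sample(pool, nr - k, replace = TRUE))
      tibble(sample = samples$sample[i], tissue = tissue,
             id = sprintf("%s_%s_r%05d", samples$sample[i], tissue,
                          seq_len(nr)),
             seq = sample(seqs))
    })
  })
}

sim_terra_reads <- function(cfg, samples) {
  pool <- random_seqs(256L)
  nf <- cfg$terra_fragments
  purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    frac <- 0.002 * exp(0.8 * samples$tlr_true[i])
    k <- rbinom(1, nf, min(frac, 0.5))
    r1 <- c(paste0(strrep(TEL_MOTIF, 5), random_seqs(k, 120L),
                   recycle0 = TRUE),
            sample(pool, nf - k, replace = TRUE))
    tibble(sample = samples$sample[i],
           id = sprintf("%s_f%05d", samples$sample[i], seq_len(nf)),
           read1 = r1, read2 = sample(pool, nf, replace = TRUE))
  })
}

# ---- clinical / survival ----------------------------------------------------

sim_clinical <- function(samples, segs, cfg) {
  ratio17 <- if (cfg$n_chromosomes >= 17) {
    L <- cfg$chrom_lengths[17]
    segs |>
      filter(.data$chrom == 17, (.data$start + .data$end) / 2 <= 0.4 * L) |>
      group_by(.data$sample) |>
      summarise(ratio_17p = sum(.data$n_major / (.data$n_major + .data$n_minor) *
                                  (.data$end - .data$start + 1)) /
                  sum(.data$end - .data$start + 1), .groups = "drop")
  } else {
    tibble(sample = samples$sample, ratio_17p = 0.5)
  }
  cl <- samples |>
    left_join(ratio17, by = "sample") |>
    mutate(ratio_17p = dplyr::coalesce(.data$ratio_17p, 0.5))
  lp <- -2 + 1.2 * cl$mycn_amp + 4 * (cl$ratio_17p - 0.5) + 0.6 * cl$stage4
  cl$deceased <- runif(nrow(cl)) < stats::plogis(lp)
  cl$os_years <- round(runif(nrow(cl), 0.2, 12), 2)
  cl$high_risk <- cl$mycn_amp | cl$stage4 | runif(nrow(cl)) < 0.15
  select(cl, "sample", "purity", "ploidy", "mycn_amp", "tert_re",
         "high_risk", "stage4", "age", "sex", "cohort", "deceased",
         "os_years")
}

# ---- top level --------------------------------------------------------------

#' Simulate a tumor cohort with planted ground truth
#'
#' Generates every input table of the analysis pipeline for a synthetic
#' cohort: per-SNP tumor/normal allelic depths, phased genotypes,
#' allele-specific copy-number segments, allelic RNA site counts, a raw
#' expression count matrix, clinical covariates with survival labels,
#' binned ATRX coverage, and telomere/TERRA sequencing reads. All planted
#' truth (purity, ploidy, per-segment allele copy numbers, TMM labels,
#' telomere-length ratios, per-gene regulatory effects) is returned
#' alongside, so every downstream caller can be validated against known
#' answers. Output is fully determined by `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `nbd_cohort`: a list with elements `truth`
#'   (tibbles `samples`, `segments`, `genes`, `gene_sample`) and `tables`
#'   (tibbles `snp_counts`, `genotypes`, `segments`, `ase_sites`,
#'   `expression`, `clinical`, `effects_inputs`, `atrx_bins`, `tel_reads`,
#'   `terra_reads`), plus the `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 4, n_chromosomes = 4,
#'                                      snps_per_chrom = 50,
#'                                      genes_per_chrom = 5,
#'                                      reads_per_sample = 100,
#'                                      terra_fragments = 100, seed = 7))
#' names(cohort$tables)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "nbd_sim_config")) {
    config_error("`config` must be built by sim_config()", field = "config")
  }
  with_seed(config$seed, {
    samples <- sim_sample_truth(config)
    genome <- sim_genome(config)
    segs <- sim_segments(config, samples, genome)
    samples <- left_join(samples, weighted_ploidy(segs), by = "sample")
    snp_counts <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
      dplyr::mutate(
        sim_snp_counts_one(config, samples[i, ],
                           segs[segs$sample == samples$sample[i], ],
                           genome$snps),
        sample = samples$sample[i], .before = 1)
    })
    gene_sample <- sim_gene_sample(config, samples, genome$genes, segs)
    ase_sites <- sim_ase_sites(config, gene_sample, genome$genes)
    atrx_bins <- sim_atrx_bins(config, samples)
    tel_reads <- sim_tel_reads(config, samples)
    terra_reads <- sim_terra_reads(config, samples)
    clinical <- sim_clinical(samples, segs, config)

    genotypes <- select(snp_counts, "sample", "chrom", "pos", "ref", "alt",
                        "gt")
    structure(list(
      truth = list(samples = samples,
                   segments = segs,
                   genes = genome$genes,
                   gene_sample = gene_sample),
      tables = list(
        snp_counts = select(snp_counts, -"gt"),
        genotypes = genotypes,
        segments = segs |>
          mutate(logr_seg = log2(((1 - samples$purity[match(.data$sample, samples$sample)]) * 2 +
                                    samples$purity[match(.data$sample, samples$sample)] *
                                    (.data$n_major + .data$n_minor)) /
                                   ((1 - samples$purity[match(.data$sample, samples$sample)]) * 2 +
                                      samples$purity[match(.data$sample, samples$sample)] *
                                      samples$ploidy[match(.data$sample, samples$sample)]))) |>
          select("sample", "chrom", "start", "end",
                 nMajor = "n_major", nMinor = "n_minor", "logr_seg"),
        ase_sites = ase_sites,
        genes = select(genome$genes, "gene", "chrom", "start", "end"),
        expression = select(gene_sample, "sample", "gene",
                            count = "expr_count"),
        clinical = clinical,
        effects_inputs = select(gene_sample, "sample", "gene", "eqtl_gt",
                                "eqtl_het", "cn_ratio", "logr_gene", "sv",
                                "prom_snv", "gene_snv"),
        atrx_bins = atrx_bins,
        tel_reads = tel_reads,
        terra_reads = terra_reads),
      config = config), class = "nbd_cohort")
  })
}

#' @export
print.nbd_cohort <- function(x, ...) {
  cat("<nbd_cohort> ", nrow(x$truth$samples), " samples, ",
      x$config$n_chromosomes, " chromosomes, ",
      nrow(x$truth$genes), " genes, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}
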