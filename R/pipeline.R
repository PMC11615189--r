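# Pipeline orchestration: stage functions over an in-memory cohort and the
# run_pipeline() driver that wires them in dependency order, writes TSV
# outputs and a JSON summary, and keeps all randomness derived from the one
# configuration seed via named substreams.

PIPELINE_STAGES <- c("cn", "tmm", "ase", "effects", "assoc")

stage_log <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# Extend called segments to cover whole chromosomes: first/last segments are
# stretched to the chromosome ends, interior boundaries to the midpoint
# between flanking het sites.
cover_chromosome <- function(seg, chrom_len) {
  if (nrow(seg) == 0) return(seg)
  seg <- arrange(seg, .data$start)
  if (nrow(seg) > 1) {
    mids <- floor((seg$end[-nrow(seg)] + seg$start[-1]) / 2)
    seg$end[-nrow(seg)] <- mids
    seg$start[-1] <- mids + 1
  }
  seg$start[1] <- 1
  seg$end[nrow(seg)] <- chrom_len
  seg
}

stage_cn <- function(cohort, penalty = 8, min_depth = 10, quiet = TRUE) {
  tb <- cohort$tables
  clin <- tb$clinical
  arms <- genome_arms(cohort$config$chrom_lengths)
  bins <- genome_bins(cohort$config$chrom_lengths)
  gene_regions <- dplyr::rename(tb$genes, region = "gene")
  snp <- left_join(tb$snp_counts, tb$genotypes[, c("sample", "chrom", "pos",
                                                   "gt")],
                   by = c("sample", "chrom", "pos"))
  per_sample <- purrr::map(seq_len(nrow(clin)), function(i) {
    s <- clin$sample[i]
    bl <- compute_baf_logr(snp[snp$sample == s, ], min_depth = min_depth)
    het <- bl[bl$gt %in% c("0|1", "1|0"), ]
    segs <- segment_baf(het, penalty = penalty)
    segs <- purrr::map_dfr(split(segs, segs$chrom), function(sc) {
      cover_chromosome(sc, cohort$config$chrom_lengths[sc$chrom[1]])
    })
    inv <- estimate_allele_cn(segs, purity = clin$purity[i],
                              ploidy = clin$ploidy[i])
    inv$logr_seg <- inv$logr
    cls <- classify_cn_state(inv, ploidy = clin$ploidy[i])
    cls$sample <- s
    gene_cn <- summarize_region(cls, gene_regions,
                                values = c("logr_seg", "cn_ratio")) |>
      dplyr::rename(gene = "region", logr_gene = "logr_seg",
                    cn_ratio_gene = "cn_ratio")
    gene_state <- summarize_region(cls, gene_regions,
                                   mode = "dominant_state")
    gene_cn$state <- gene_state$state
    gene_cn$sample <- s
    arm <- summarize_region(cls, arms, values = c("logr_seg", "cn_ratio"))
    arm$sample <- s
    bin <- summarize_region(cls, bins, values = c("logr_seg", "cn_ratio"),
                            amp_override = TRUE)
    bin$sample <- s
    list(segments = cls, gene_cn = gene_cn, arm = arm, bin = bin)
  })
  segments <- purrr::map_dfr(per_sample, "segments")
  gene_cn <- purrr::map_dfr(per_sample, "gene_cn") |>
    gene_amplification() |>
    suppressWarnings()
  arm_long <- purrr::map_dfr(per_sample, "arm")
  bin_long <- purrr::map_dfr(per_sample, "bin")
  arm_logr <- tidyr::pivot_wider(arm_long[, c("sample", "region",
                                              "logr_seg")],
                                 names_from = "region",
                                 values_from = "logr_seg")
  bin_ratio <- tidyr::pivot_wider(bin_long[, c("sample", "region",
                                               "cn_ratio")],
                                  names_from = "region",
                                  values_from = "cn_ratio")
  stage_log(quiet, "cn", "%d segments called across %d samples",
            nrow(segments), nrow(clin))
  list(segments = segments, gene_cn = gene_cn,
       arm_logr = arm_logr, bin_ratio = bin_ratio)
}

stage_tmm <- function(cohort, seed = 1L, quiet = TRUE, tel_k = 7,
                      posterior_cut = 0.95, tlr_cut = 0.5) {
  tb <- cohort$tables
  clin <- tb$clinical
  tel <- tb$tel_reads |>
    group_by(.data$sample, .data$tissue) |>
    summarise(n_tel = count_telomeric_reads(.data$seq, k = tel_k)$n_telomeric,
              n_reads = dplyr::n(), .groups = "drop") |>
    # 0.5 pseudocount keeps the ratio finite at zero telomeric reads
    mutate(proxy = (.data$n_tel + 0.5) / .data$n_reads) |>
    select("sample", "tissue", "proxy") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "proxy")
  tel$tlr <- telomere_length_ratio(tel$T, tel$N)
  expr <- normalize_expression(tb$expression, clin)
  tert <- expr[expr$gene == "TERT", ]
  if (nrow(tert) == 0) input_error("no TERT row in the expression matrix")
  tert$tert_z <- as.numeric(scale(tert$expr))
  features <- clin[, c("sample", "mycn_amp", "tert_re")] |>
    left_join(tert[, c("sample", "tert_z")], by = "sample") |>
    left_join(tel[, c("sample", "tlr")], by = "sample")
  fit <- fit_tert_threshold(features$tert_z, posterior_cut = posterior_cut,
                            seed = seed)
  calls <- classify_tmm(features, fit, tlr_cut = tlr_cut)
  terra <- tb$terra_reads |>
    group_by(.data$sample) |>
    summarise(fpm = count_terra_fragments(
      dplyr::pick("read1", "read2"))$fpm,
      .groups = "drop")
  stage_log(quiet, "tmm", "labels: %s",
            paste(names(table(calls$tmm_label)), table(calls$tmm_label),
                  sep = "=", collapse = " "))
  list(calls = calls, mixture_fit = fit, terra = terra)
}

stage_ase <- function(cohort, cn = NULL, quiet = TRUE, alpha_fdr = 0.05) {
  tb <- cohort$tables
  kept <- filter_sites(tb$ase_sites)
  n_dropped <- attr(kept, "dropped")
  flagged <- purrr::map_dfr(split(kept, kept$sample), biallelic_test)
  biallelic <- flagged[flagged$biallelic, ]
  ref_bias <- if (!is.null(cn)) {
    balanced <- cn$segments |>
      filter(as.character(.data$balance) == "balance") |>
      select("sample", "chrom", "start", "end")
    purrr::map_dfr(split(biallelic, biallelic$sample), function(ss) {
      b <- balanced[balanced$sample == ss$sample[1], ]
      if (nrow(b) == 0) return(tibble(sample = ss$sample[1],
                                      ref_bias = NA_real_))
      in_bal <- purrr::map_lgl(seq_len(nrow(ss)), function(j) {
        any(b$chrom == ss$chrom[j] & b$start <= ss$pos[j] &
              b$end >= ss$pos[j])
      })
      tibble(sample = ss$sample[1],
             ref_bias = suppressWarnings(estimate_ref_bias(ss[in_bal, ])))
    })
  } else NULL
  gene_ase <- aggregate_haplotypes(biallelic)
  gene_ase <- aei_test(gene_ase, alpha_fdr = alpha_fdr)
  summary <- gene_ase_summary(gene_ase)
  stage_log(quiet, "ase",
            "%d sites dropped by filters; %d gene x sample AEI tests, %d AEI",
            n_dropped, nrow(gene_ase), sum(gene_ase$aei))
  list(gene_ase = gene_ase, gene_summary = summary, ref_bias = ref_bias,
       n_sites_dropped = n_dropped)
}

stage_effects <- function(cohort, ase, tmm, quiet = TRUE,
                          min_obs = 20) {
  tb <- cohort$tables
  clin <- tb$clinical
  expr <- normalize_expression(tb$expression, clin)
  inputs <- tb$effects_inputs |>
    left_join(clin[, c("sample", "purity", "mycn_amp", "cohort", "age",
                       "sex", "ploidy")], by = "sample")
  dx <- decompose_expression(left_join(expr, inputs,
                                       by = c("sample", "gene")),
                             min_obs = min_obs)
  ase_data <- ase$gene_ase |>
    mutate(log_cov = log(.data$a + .data$b)) |>
    left_join(inputs, by = c("sample", "gene"))
  da <- decompose_ase(ase_data, min_obs = min_obs)
  ad_data <- ase$gene_ase |>
    mutate(log_cov = log(.data$a + .data$b)) |>
    left_join(expr, by = c("sample", "gene")) |>
    left_join(clin[, c("sample", "cohort", "purity")], by = "sample")
  ad <- ad_gene_test(ad_data, min_obs = min(10, min_obs))
  de_data <- expr |>
    left_join(tmm$calls[, c("sample", "tmm_label")], by = "sample") |>
    filter(.data$tmm_label != "Mix") |>
    mutate(alt = .data$tmm_label == "ALT") |>
    left_join(clin[, c("sample", "mycn_amp", "age", "sex", "cohort",
                       "purity", "ploidy")], by = "sample")
  de <- if (length(unique(de_data$alt)) > 1) alt_de_scan(de_data) else NULL
  stage_log(quiet, "effects", "%d genes decomposed (expression), %d (ASE)",
            length(unique(dx$table$gene)), length(unique(da$table$gene)))
  list(decomp_expr = dx, decomp_ase = da, ad_genes = ad, alt_de = de)
}

stage_assoc <- function(cohort, cn, tmm, seed = 1L, quiet = TRUE,
                        n_boot = 100) {
  tb <- cohort$tables
  clin <- tb$clinical
  atrx <- purrr::map_dfr(split(tb$atrx_bins, tb$atrx_bins$sample),
                         function(b) {
    mutate(detect_atrx_deletion(b, seed = sub_seed(seed, b$sample[1])),
           sample = b$sample[1], .before = 1)
  })
  wgd <- purrr::map_dfr(split(cn$segments, cn$segments$sample),
                        function(sg) {
    mutate(wgd_bootstrap(sg, n_boot = n_boot,
                         seed = sub_seed(seed, sg$sample[1])),
           sample = sg$sample[1], .before = 1)
  })
  labels <- tmm$calls[, c("sample", "tmm_label")]
  enrich <- fisher_wgd_enrichment(left_join(wgd, labels, by = "sample"))
  covar <- clin |>
    left_join(atrx[, c("sample", "deleted")], by = "sample") |>
    dplyr::rename(atrx = "deleted")
  arm_data <- cn$arm_logr |>
    left_join(labels, by = "sample") |>
    filter(.data$tmm_label != "Mix") |>
    mutate(alt = .data$tmm_label == "ALT")
  arm_cov <- covar[match(arm_data$sample, covar$sample),
                   c("mycn_amp", "atrx", "age", "sex", "cohort", "purity",
                     "ploidy")]
  arm_assoc <- arm_alt_association(select(arm_data, -"tmm_label"), arm_cov)
  bin_data <- cn$bin_ratio |>
    left_join(clin[, c("sample", "deceased")], by = "sample")
  bin_cov <- covar[match(bin_data$sample, covar$sample),
                   c("mycn_amp", "age", "stage4", "sex", "purity", "ploidy")]
  bin_assoc <- bin_survival_association(bin_data, bin_cov)
  stage_log(quiet, "assoc",
            "%d ATRX deletions, %d WGD-positive, %d significant arms",
            sum(atrx$deleted), sum(wgd$wgd), sum(arm_assoc$significant))
  list(atrx = atrx, wgd = wgd, wgd_enrichment = enrich,
       arm_assoc = arm_assoc, bin_assoc = bin_assoc)
}

resolve_stages <- function(stages) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  deps <- list(cn = character(0), tmm = character(0), ase = "cn",
               effects = c("ase", "tmm"), assoc = c("cn", "tmm"))
  needed <- stages
  repeat {
    more <- unique(unlist(deps[needed]))
    if (all(more %in% needed)) break
    needed <- union(needed, more)
  }
  list(run = PIPELINE_STAGES[PIPELINE_STAGES %in% needed],
       write = stages)
}

#' Run the full analysis pipeline on a synthetic or on-disk cohort
#'
#' Executes the analysis stages in dependency order: `cn` (BAF/LogR,
#' segmentation, allele-specific copy number, states, region summaries),
#' `tmm` (telomere counting, TERT threshold, TMM labels, TERRA), `ase`
#' (site filtering, bi-allelic test, haplotype aggregation, AEI), `effects`
#' (variance decomposition, allelic-dosage and ALT differential-expression
#' scans) and `assoc` (ATRX detection, WGD bootstrap and enrichment,
#' arm-level ALT and binned survival scans). Requesting a subset of stages
#' computes unrequested prerequisites in memory but only writes outputs for
#' the requested stages. All randomness derives from `config$seed` (or the
#' seed stored with an on-disk cohort) through named substreams, so
#' identical configuration yields byte-identical outputs.
#'
#' @param config A [sim_config()]; ignored when `input_dir` is given.
#' @param input_dir Optional directory of a cohort written by
#'   [write_cohort()].
#' @param out_dir Optional output directory for stage TSVs and
#'   `summary.json`.
#' @param stages Character vector of stages to run (default all).
#' @param write_inputs Also materialize the simulated input files under
#'   `out_dir/input`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, an `nbd_pipeline` list with one element per executed
#'   stage plus `summary`.
#' @export
run_pipeline <- function(config = sim_config(), input_dir = NULL,
                         out_dir = NULL,
                         stages = PIPELINE_STAGES,
                         effects_min_obs = 20,
                         write_inputs = FALSE, quiet = FALSE) {
  plan <- resolve_stages(stages)
  cohort <- if (is.null(input_dir)) {
    stage_log(quiet, "simulate", "seed %d, %d samples", config$seed,
              config$n_samples)
    simulate_cohort(config)
  } else {
    read_cohort(input_dir)
  }
  seed <- cohort$config$seed
  res <- list()
  if ("cn" %in% plan$run) res$cn <- stage_cn(cohort, quiet = quiet)
  if ("tmm" %in% plan$run) {
    res$tmm <- stage_tmm(cohort, seed = sub_seed(seed, "tmm"), quiet = quiet)
  }
  if ("ase" %in% plan$run) {
    res$ase <- stage_ase(cohort, cn = res$cn, quiet = quiet)
  }
  if ("effects" %in% plan$run) {
    res$effects <- stage_effects(cohort, res$ase, res$tmm, quiet = quiet,
                                 min_obs = effects_min_obs)
  }
  if ("assoc" %in% plan$run) {
    res$assoc <- stage_assoc(cohort, res$cn, res$tmm,
                             seed = sub_seed(seed, "assoc"), quiet = quiet)
  }
  summary <- pipeline_summary(cohort, res)
  if (!is.null(out_dir)) {
    write_pipeline_outputs(cohort, res, summary, out_dir, plan$write,
                           write_inputs)
  }
  invisible(structure(c(res, list(summary = summary, cohort = cohort)),
                      class = "nbd_pipeline"))
}

pipeline_summary <- function(cohort, res) {
  s <- list(n_samples = nrow(cohort$tables$clinical),
            seed = cohort$config$seed)
  if (!is.null(res$tmm)) {
    s$tmm_labels <- as.list(table(res$tmm$calls$tmm_label))
    s$tert_threshold <- res$tmm$mixture_fit$threshold
  }
  if (!is.null(res$cn)) s$n_segments <- nrow(res$cn$segments)
  if (!is.null(res$ase)) {
    s$n_aei <- sum(res$ase$gene_ase$aei)
    s$n_ase_tests <- nrow(res$ase$gene_ase)
  }
  if (!is.null(res$assoc)) {
    s$n_wgd <- sum(res$assoc$wgd$wgd)
    s$n_atrx_deleted <- sum(res$assoc$atrx$deleted)
    s$significant_arms <-
      res$assoc$arm_assoc$region[res$assoc$arm_assoc$significant]
    s$n_significant_bins <- sum(res$assoc$bin_assoc$bins$significant)
  }
  s
}

write_pipeline_outputs <- function(cohort, res, summary, out_dir, write,
                                   write_inputs) {
  # stage results into a temporary sibling, then move: a failed run leaves no
  # partial outputs in the final directory
  staging <- paste0(out_dir, ".staging")
  unlink(staging, recursive = TRUE)
  dir.create(staging, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_tsv(x, file.path(staging, name),
                                          progress = FALSE)
  if (write_inputs) write_cohort(cohort, file.path(staging, "input"))
  if ("cn" %in% write && !is.null(res$cn)) {
    w(dplyr::rename(res$cn$segments[, c("sample", "chrom", "start", "end",
                                        "cn_major", "cn_minor", "logr_seg",
                                        "state", "balance", "loh")],
                    nMajor = "cn_major", nMinor = "cn_minor"),
      "segments_called.tsv")
    w(res$cn$gene_cn, "gene_cn.tsv")
    w(res$cn$arm_logr, "arm_logr.tsv")
    w(res$cn$bin_ratio, "bin_ratio.tsv")
  }
  if ("tmm" %in% write && !is.null(res$tmm)) {
    w(res$tmm$calls, "tmm_calls.tsv")
    w(res$tmm$terra, "terra_fpm.tsv")
  }
  if ("ase" %in% write && !is.null(res$ase)) {
    w(res$ase$gene_ase, "gene_ase.tsv")
    w(res$ase$gene_summary, "ase_gene_summary.tsv")
    if (!is.null(res$ase$ref_bias)) w(res$ase$ref_bias, "ref_bias.tsv")
  }
  if ("effects" %in% write && !is.null(res$effects)) {
    w(res$effects$decomp_expr$table, "effects_expression.tsv")
    w(res$effects$decomp_ase$table, "effects_ase.tsv")
    w(res$effects$ad_genes, "ad_genes.tsv")
    if (!is.null(res$effects$alt_de)) w(res$effects$alt_de, "alt_de.tsv")
  }
  if ("assoc" %in% write && !is.null(res$assoc)) {
    w(res$assoc$atrx, "atrx_calls.tsv")
    w(res$assoc$wgd, "wgd_calls.tsv")
    w(res$assoc$wgd_enrichment, "wgd_enrichment.tsv")
    w(res$assoc$arm_assoc, "arm_assoc.tsv")
    w(res$assoc$bin_assoc$bins, "bin_assoc.tsv")
    w(res$assoc$bin_assoc$merged_regions, "bin_assoc_merged.tsv")
  }
  jsonlite::write_json(summary, file.path(staging, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(out_dir, recursive = TRUE)
  file.rename(staging, out_dir)
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return An `nbd_cohort` (without the in-memory truth tables).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) input_error(sprintf("cohort directory not found: %s",
                                            dir))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cfg$chrom_lengths <- as.numeric(cfg$chrom_lengths)
  config <- do.call(sim_config, cfg[setdiff(names(cfg), character(0))])
  snp_files <- list.files(file.path(dir, "snp_counts"), full.names = TRUE)
  snp_counts <- purrr::map_dfr(snp_files, function(f) {
    mutate(read_snp_table(f),
           sample = sub("\\.tsv$", "", basename(f)), .before = 1)
  })
  expr_wide <- readr::read_tsv(file.path(dir, "expression.tsv"),
                               show_col_types = FALSE, progress = FALSE)
  expression <- tidyr::pivot_longer(expr_wide, -"gene",
                                    names_to = "sample",
                                    values_to = "count")
  read_dir <- file.path(dir, "reads")
  tel_files <- list.files(read_dir, pattern = "_[TN]\\.fastq$",
                          full.names = TRUE)
  tel_reads <- purrr::map_dfr(tel_files, function(f) {
    parts <- stringr::str_match(basename(f), "^(.*)_([TN])\\.fastq$")
    mutate(read_fastq(f)[, c("id", "seq")],
           sample = parts[, 2], tissue = parts[, 3], .before = 1)
  })
  terra1 <- list.files(read_dir, pattern = "_terra_1\\.fastq$",
                       full.names = TRUE)
  terra_reads <- purrr::map_dfr(terra1, function(f) {
    s <- sub("_terra_1\\.fastq$", "", basename(f))
    r1 <- read_fastq(f)
    r2 <- read_fastq(sub("_terra_1\\.fastq$", "_terra_2.fastq", f))
    tibble(sample = s, id = sub("/1$", "", r1$id),
           read1 = r1$seq, read2 = r2$seq)
  })
  structure(list(
    truth = NULL,
    tables = list(
      snp_counts = snp_counts,
      genotypes = read_vcf_min(file.path(dir, "genotypes.vcf")),
      segments = read_segments(file.path(dir, "segments.tsv")),
      ase_sites = read_gene_counts(file.path(dir, "ase_sites.tsv")),
      genes = read_tsv_checked(file.path(dir, "genes.tsv"),
                               c("gene", "chrom", "start", "end"),
                               "gene table"),
      expression = expression,
      clinical = read_tsv_checked(file.path(dir, "clinical.tsv"),
                                  c("sample", "purity", "ploidy",
                                    "mycn_amp", "tert_re"),
                                  "clinical table"),
      effects_inputs = read_tsv_checked(file.path(dir, "effects_inputs.tsv"),
                                        c("sample", "gene", "eqtl_gt",
                                          "eqtl_het", "cn_ratio",
                                          "logr_gene", "sv", "prom_snv",
                                          "gene_snv"),
                                        "effects input table"),
      atrx_bins = read_tsv_checked(file.path(dir, "atrx_bins.tsv"),
                                   c("sample", "bin", "norm_tumor",
                                     "norm_normal"),
                                   "ATRX coverage table"),
      tel_reads = tel_reads,
      terra_reads = terra_reads),
    config = config), class = "nbd_cohort")
}

#' @export
print.nbd_pipeline <- function(x, ...) {
  cat("<nbd_pipeline> stages:",
      paste(setdiff(names(x), c("summary", "cohort")), collapse = ", "),
      "\n")
  utils::str(x$summary, max.level = 1, give.attr = FALSE)
  invisible(x)
}
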