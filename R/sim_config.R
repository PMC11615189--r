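#' Configuration for the synthetic tumor-cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults emulate
#' a pediatric neuroblastoma WGS/RNA-seq cohort of 115 tumors: purity between
#' 0.3 and 1, a near-diploid or near-triploid baseline karyotype, 38% of
#' samples whole-genome doubled, telomere maintenance mechanism (TMM) driven
#' by MYCN amplification, TERT rearrangement, high TERT expression or
#' alternative lengthening of telomeres (ALT), and copy-number hotspots
#' planted on 2p (MYCN amplicon), 11q (ALT-associated loss) and 17p
#' (survival-associated imbalance).
#'
#' @param n_samples Number of tumors in the cohort.
#' @param n_chromosomes Number of autosomes simulated (integer-indexed).
#' @param chrom_lengths Chromosome lengths in bp; recycled to
#'   `n_chromosomes`. Centromeres sit at 40% of each length.
#' @param snps_per_chrom Germline SNP panel size per chromosome.
#' @param genes_per_chrom Genes per chromosome, uniformly spaced.
#' @param purity_range Uniform sampling interval for tumor purity, within
#'   \[0.3, 1\].
#' @param ploidy_options Baseline average copy numbers for the non-doubled
#'   and doubled karyotypes.
#' @param wgd_fraction Fraction of samples with a whole-genome doubling.
#' @param segment_rate Expected copy-number breakpoints per chromosome
#'   (Poisson).
#' @param noise_sd_baf,noise_sd_logr Gaussian noise SDs added to the expected
#'   allele fraction and to log2 coverage before count sampling. Setting both
#'   to 0 (with `purity_range = c(1, 1)`) yields the exact noise-free limit.
#' @param depth_mean_tumor,depth_mean_normal Mean WGS depth at SNPs.
#' @param rna_depth_mean Mean allelic RNA depth per gene and sample.
#' @param tmm_mixture List with `means`, `sds`, `weights` of the
#'   two-component TERT expression mixture (cohort Z-score scale); the second
#'   component is the TERT-high mode.
#' @param mycn_fraction,tert_re_fraction,alt_fraction Prevalences of MYCN
#'   amplification, TERT rearrangement and ALT (elevated telomere-length
#'   ratio).
#' @param imprinted_fraction Fraction of genes with constitutive mono-allelic
#'   (imprinted) expression.
#' @param eqtl_fraction Fraction of genes with a planted cis-eQTL.
#' @param overdispersion Beta-binomial overdispersion `rho` for allelic RNA
#'   counts; 0 (default) keeps counts binomial so test calibration is exact.
#' @param reads_per_sample Telomere-counting reads per FASTQ (tumor and
#'   normal each); reads are 150 bp.
#' @param tel_read_fraction Telomeric read fraction in the normal sample; the
#'   tumor fraction is scaled by the true tumor/normal telomere-length ratio.
#' @param terra_fragments RNA fragments per sample for TERRA counting.
#' @param atrx_bins Number of 50 bp coverage bins over the ATRX locus.
#' @param atrx_del_fraction_alt Probability that an ALT sample carries an
#'   ATRX exon deletion.
#' @param seed Integer seed; fully determines all generator output.
#'
#' @return A validated list of class `nbd_sim_config`.
#' @examples
#' cfg <- sim_config(n_samples = 8, snps_per_chrom = 40, seed = 1)
#' @export
sim_config <- function(n_samples = 115,
                       n_chromosomes = 22,
                       chrom_lengths = round(seq(230e6, 50e6,
                                                 length.out = n_chromosomes)),
                       snps_per_chrom = 300,
                       genes_per_chrom = 25,
                       purity_range = c(0.3, 1.0),
                       ploidy_options = c(2.0, 3.6),
                       wgd_fraction = 44 / 115,
                       segment_rate = 1.5,
                       noise_sd_baf = 0.02,
                       noise_sd_logr = 0.1,
                       depth_mean_tumor = 40,
                       depth_mean_normal = 40,
                       rna_depth_mean = 60,
                       tmm_mixture = list(means = c(-0.5, 1.5),
                                          sds = c(0.3, 0.3),
                                          weights = c(0.7, 0.3)),
                       mycn_fraction = 23 / 115,
                       tert_re_fraction = 16 / 115,
                       alt_fraction = 21 / 115,
                       imprinted_fraction = 0.03,
                       eqtl_fraction = 0.3,
                       overdispersion = 0,
                       reads_per_sample = 2000,
                       tel_read_fraction = 0.05,
                       terra_fragments = 1000,
                       atrx_bins = 400,
                       atrx_del_fraction_alt = 0.45,
                       seed = 1L) {
  check_count <- function(x, name, min = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != round(x)) {
      config_error(sprintf("`%s` must be an integer >= %d", name, min),
                   field = name)
    }
  }
  check_prop <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      config_error(sprintf("`%s` must be a proportion in [0, 1]", name),
                   field = name)
    }
  }
  check_count(n_samples, "n_samples")
  check_count(n_chromosomes, "n_chromosomes")
  check_count(snps_per_chrom, "snps_per_chrom", min = 2)
  check_count(genes_per_chrom, "genes_per_chrom")
  check_count(reads_per_sample, "reads_per_sample")
  check_count(terra_fragments, "terra_fragments")
  check_count(atrx_bins, "atrx_bins", min = 50)
  check_count(seed, "seed", min = 0)
  for (p in c("wgd_fraction", "mycn_fraction", "tert_re_fraction",
              "alt_fraction", "imprinted_fraction", "eqtl_fraction",
              "tel_read_fraction", "atrx_del_fraction_alt")) {
    check_prop(get(p), p)
  }
  if (length(purity_range) != 2L || purity_range[1] > purity_range[2] ||
      purity_range[1] < 0.3 - 1e-9 || purity_range[2] > 1) {
    config_error("`purity_range` must be an interval within [0.3, 1]",
                 field = "purity_range")
  }
  if (any(ploidy_options <= 0)) {
    config_error("`ploidy_options` must be positive", field = "ploidy_options")
  }
  if (!is.list(tmm_mixture) ||
      !all(c("means", "sds", "weights") %in% names(tmm_mixture)) ||
      length(tmm_mixture$means) != 2L || length(tmm_mixture$sds) != 2L ||
      length(tmm_mixture$weights) != 2L ||
      abs(sum(tmm_mixture$weights) - 1) > 1e-8 ||
      any(tmm_mixture$sds <= 0)) {
    config_error(paste0("`tmm_mixture` must list 2 means, 2 positive sds and ",
                        "2 weights summing to 1"), field = "tmm_mixture")
  }
  if (tmm_mixture$means[2] <= tmm_mixture$means[1]) {
    config_error("`tmm_mixture` means must be increasing (high mode second)",
                 field = "tmm_mixture")
  }
  if (overdispersion < 0 || overdispersion >= 1) {
    config_error("`overdispersion` must be in [0, 1)", field = "overdispersion")
  }
  if (noise_sd_baf < 0 || noise_sd_logr < 0) {
    config_error("noise SDs must be non-negative", field = "noise_sd_baf")
  }
  cfg <- list(n_samples = as.integer(n_samples),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_lengths = rep_len(chrom_lengths, n_chromosomes),
              snps_per_chrom = as.integer(snps_per_chrom),
              genes_per_chrom = as.integer(genes_per_chrom),
              purity_range = purity_range,
              ploidy_options = ploidy_options,
              wgd_fraction = wgd_fraction,
              segment_rate = segment_rate,
              noise_sd_baf = noise_sd_baf,
              noise_sd_logr = noise_sd_logr,
              depth_mean_tumor = depth_mean_tumor,
              depth_mean_normal = depth_mean_normal,
              rna_depth_mean = rna_depth_mean,
              tmm_mixture = tmm_mixture,
              mycn_fraction = mycn_fraction,
              tert_re_fraction = tert_re_fraction,
              alt_fraction = alt_fraction,
              imprinted_fraction = imprinted_fraction,
              eqtl_fraction = eqtl_fraction,
              overdispersion = overdispersion,
              reads_per_sample = as.integer(reads_per_sample),
              tel_read_fraction = tel_read_fraction,
              terra_fragments = as.integer(terra_fragments),
              atrx_bins = as.integer(atrx_bins),
              atrx_del_fraction_alt = atrx_del_fraction_alt,
              seed = as.integer(seed))
  structure(cfg, class = "nbd_sim_config")
}
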