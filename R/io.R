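# Typed readers and writers for the pipeline's external formats: TSV tables
# (1-based inclusive coordinates), minimal VCF 4.2 with phased genotypes,
# and 4-line FASTQ. Readers validate invariants and fail with the offending
# file/record named.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    input_error(sprintf("%s file not found: %s", what, path))
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    input_error(sprintf("%s (%s) is missing column(s): %s", what, path,
                        paste(miss, collapse = ", ")))
  }
  x
}

#' Read a per-SNP allelic depth table
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `refN`, `altN`, `refT`,
#' `altT` (1-based positions, tumor/normal allelic depths). Negative depths,
#' positions below 1 and duplicate (chrom, pos) keys are rejected.
#'
#' @param path TSV file path.
#' @return Validated tibble.
#' @export
read_snp_table <- function(path) {
  x <- read_tsv_checked(path, c("chrom", "pos", "ref", "alt",
                                "refN", "altN", "refT", "altT"),
                        "SNP table")
  if (any(x$pos < 1)) input_error(sprintf("%s: positions must be >= 1", path))
  depth_cols <- c("refN", "altN", "refT", "altT")
  for (v in depth_cols) {
    if (any(x[[v]] < 0)) {
      input_error(sprintf("%s: negative depth in column %s", path, v))
    }
  }
  if (anyDuplicated(x[, c("chrom", "pos")])) {
    input_error(sprintf("%s: duplicate (chrom, pos) keys", path))
  }
  x
}

#' Read an allele-specific copy-number segment table
#'
#' TSV with columns `sample`, `chrom`, `start`, `end`, `nMajor`, `nMinor`,
#' `logr_seg`; coordinates 1-based inclusive, `start <= end`,
#' `nMajor >= nMinor >= 0`.
#'
#' @param path TSV file path.
#' @return Validated tibble.
#' @export
read_segments <- function(path) {
  x <- read_tsv_checked(path, c("sample", "chrom", "start", "end",
                                "nMajor", "nMinor", "logr_seg"),
                        "segment table")
  if (any(x$start > x$end)) input_error(sprintf("%s: start > end", path))
  if (any(x$nMinor > x$nMajor) || any(x$nMinor < 0)) {
    input_error(sprintf("%s: require nMajor >= nMinor >= 0", path))
  }
  x
}

#' Read a per-site allelic RNA count table
#'
#' TSV in allele-counter dialect: `sample`, `gene`, `chrom`, `pos`, `ref`,
#' `alt`, `refCount`, `altCount`, `otherBases`, `rawDepth`, `haplotype`
#' (phased `"0|1"`/`"1|0"`: which allele lies on haplotype A). Enforces
#' `refCount + altCount <= rawDepth`.
#'
#' @param path TSV file path.
#' @return Validated tibble.
#' @export
read_gene_counts <- function(path) {
  x <- read_tsv_checked(path, c("sample", "gene", "chrom", "pos",
                                "refCount", "altCount", "otherBases",
                                "rawDepth", "haplotype"),
                        "allelic count table")
  if (any(x$refCount + x$altCount > x$rawDepth)) {
    input_error(sprintf("%s: refCount + altCount exceeds rawDepth", path))
  }
  x
}

#' Read a minimal VCF with phased genotypes
#'
#' Supports the minimal VCF 4.2 subset the generator emits: `##` headers, a
#' `#CHROM` column line, FORMAT `GT`, one column per sample. With
#' `require_phased = TRUE` (default) any unphased genotype separator (`/`)
#' is an error naming the record.
#'
#' @param path VCF file path.
#' @param require_phased Reject unphased GT values.
#' @return Long tibble `sample`, `chrom`, `pos`, `ref`, `alt`, `gt`.
#' @export
read_vcf_min <- function(path, require_phased = TRUE) {
  if (!file.exists(path)) input_error(sprintf("VCF not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("\r$", "", lines)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1) {
    input_error(sprintf("%s: expected exactly one #CHROM header line", path))
  }
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  samples <- cols[-(1:9)]
  if (length(samples) == 0) input_error(sprintf("%s: no sample columns", path))
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (length(body) == 0) input_error(sprintf("%s: no records", path))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(cols))
  if (length(bad)) {
    input_error(sprintf("%s: record %d has %d fields, expected %d",
                        path, bad[1], lengths(parts)[bad[1]], length(cols)))
  }
  m <- do.call(rbind, parts)
  gt <- m[, -(1:9), drop = FALSE]
  gt <- sub(":.*$", "", gt)
  if (require_phased && any(grepl("/", gt, fixed = TRUE))) {
    i <- which(apply(gt, 1, function(r) any(grepl("/", r, fixed = TRUE))))[1]
    input_error(sprintf("%s: unphased genotype at record %d (%s:%s)",
                        path, i, m[i, 1], m[i, 2]))
  }
  out <- tidyr::expand_grid(record = seq_len(nrow(m)),
                            sample_i = seq_along(samples))
  tibble(sample = samples[out$sample_i],
         chrom = utils::type.convert(m[out$record, 1], as.is = TRUE),
         pos = as.integer(m[out$record, 2]),
         ref = m[out$record, 4],
         alt = m[out$record, 5],
         gt = gt[cbind(out$record, out$sample_i)])
}

#' Read a FASTQ file
#'
#' Plain 4-line-record FASTQ; CRLF line endings are accepted. Malformed
#' records (missing `@`/`+` markers, sequence/quality length mismatch,
#' truncated final record) raise an error with the record index.
#'
#' @param path FASTQ file path.
#' @return Tibble `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) input_error(sprintf("FASTQ not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) == 0) input_error(sprintf("%s: empty FASTQ", path))
  if (length(lines) %% 4 != 0) {
    input_error(sprintf("%s: truncated record %d (line count %d not a
multiple of 4)", path, length(lines) %/% 4 + 1, length(lines)))
  }
  n <- length(lines) / 4
  id <- lines[seq(1, by = 4, length.out = n)]
  seqs <- lines[seq(2, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(id, "@"))
  if (length(bad)) {
    input_error(sprintf("%s: record %d does not start with '@'", path, bad[1]))
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    input_error(sprintf("%s: record %d is missing the '+' line", path, bad[1]))
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    input_error(sprintf("%s: record %d sequence/quality length mismatch",
                        path, bad[1]))
  }
  tibble(id = sub("^@", "", id), seq = seqs, qual = qual)
}

#' Write a FASTQ file
#'
#' @param reads Data frame with columns `id`, `seq` (and optionally `qual`;
#'   constant `"I"` quality is written otherwise).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual
          else strrep("I", nchar(reads$seq))
  out <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  readr::write_lines(out, path)
  invisible(path)
}

#' Write phased genotypes as a minimal VCF 4.2
#'
#' @param genotypes Long data frame `sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `gt` (phased `a|b` strings); all samples must share the site panel.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_min <- function(genotypes, path) {
  g <- arrange(as_tibble(genotypes), .data$chrom, .data$pos, .data$sample)
  wide <- tidyr::pivot_wider(g, names_from = "sample", values_from = "gt")
  samples <- setdiff(names(wide), c("chrom", "pos", "ref", "alt"))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- do.call(paste, c(list(wide$chrom, wide$pos, ".", wide$ref,
                                wide$alt, ".", "PASS", ".", "GT"),
                           lapply(samples, function(s) wide[[s]]),
                           sep = "\t"))
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Materializes every input table of a [simulate_cohort()] object in its
#' external format: per-sample SNP depth TSVs, a multi-sample phased VCF,
#' segment/ASE/expression/clinical/coverage TSVs, telomere FASTQs (tumor
#' and normal per sample) and TERRA read-pair FASTQs, plus the generator
#' configuration as JSON. Writing is deterministic given the cohort.
#'
#' @param cohort An `nbd_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nbd_cohort"))
  tb <- cohort$tables
  dir.create(file.path(dir, "snp_counts"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  for (s in split(tb$snp_counts, tb$snp_counts$sample)) {
    readr::write_tsv(select(s, -"sample"),
                     file.path(dir, "snp_counts",
                               paste0(s$sample[1], ".tsv")), progress = FALSE)
  }
  write_vcf_min(tb$genotypes, file.path(dir, "genotypes.vcf"))
  readr::write_tsv(tb$segments, file.path(dir, "segments.tsv"),
                   progress = FALSE)
  readr::write_tsv(tb$ase_sites, file.path(dir, "ase_sites.tsv"),
                   progress = FALSE)
  readr::write_tsv(tb$genes, file.path(dir, "genes.tsv"), progress = FALSE)
  expr_wide <- tidyr::pivot_wider(tb$expression, names_from = "sample",
                                  values_from = "count")
  readr::write_tsv(expr_wide, file.path(dir, "expression.tsv"),
                   progress = FALSE)
  readr::write_tsv(tb$clinical, file.path(dir, "clinical.tsv"),
                   progress = FALSE)
  readr::write_tsv(tb$effects_inputs, file.path(dir, "effects_inputs.tsv"),
                   progress = FALSE)
  readr::write_tsv(tb$atrx_bins, file.path(dir, "atrx_bins.tsv"),
                   progress = FALSE)
  for (s in split(tb$tel_reads, paste(tb$tel_reads$sample,
                                      tb$tel_reads$tissue))) {
    write_fastq(s, file.path(dir, "reads",
                             sprintf("%s_%s.fastq", s$sample[1],
                                     s$tissue[1])))
  }
  for (s in split(tb$terra_reads, tb$terra_reads$sample)) {
    write_fastq(tibble(id = paste0(s$id, "/1"), seq = s$read1),
                file.path(dir, "reads", paste0(s$sample[1], "_terra_1.fastq")))
    write_fastq(tibble(id = paste0(s$id, "/2"), seq = s$read2),
                file.path(dir, "reads", paste0(s$sample[1], "_terra_2.fastq")))
  }
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
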