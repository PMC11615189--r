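Package: nbdosage
Title: Copy-Number Dosage, Allele-Specific Expression and Telomere
    Maintenance Analysis for Neuroblastoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrated analysis of allele-specific somatic
    copy-number alteration and allele-specific expression in tumor cohorts.
    Computes B-allele frequency and coverage log-ratio tracks from allelic
    depths, segments the genome on mirrored BAF, inverts segment summaries
    to integer major/minor allele copy numbers under a purity/ploidy mixture
    model, and classifies copy-number and allelic-balance states. Calls the
    telomere maintenance mechanism (canonical TERT-driven vs. alternative
    lengthening of telomeres) from telomeric-repeat read counting, a
    Gaussian-mixture TERT expression threshold and MYCN/TERT alteration
    flags. Tests allelic expression imbalance with exact binomial tests on
    phased haplotype counts, decomposes per-gene expression and ASE variance
    into genetic effects by sequential ANOVA, detects ATRX exon deletions
    from binned coverage, bootstraps whole-genome-doubling calls and runs
    arm-level and binned-genome association scans. Includes a synthetic
    cohort generator with planted ground truth for every input the analysis
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
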