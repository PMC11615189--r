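---
title: "Copy-number dosage, allele-specific expression and telomere maintenance: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number dosage, allele-specific expression and telomere maintenance: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbdosage)
library(dplyr)
```

nbdosage implements an integrated tumor-cohort analysis built around
*gene dosage*: how somatic copy-number alterations, germline regulatory
variants and telomere maintenance mechanisms shape total and allele-specific
gene expression in neuroblastoma. This vignette explains the models, the
tunable parameters, what the synthetic cohort generator does and does not
emulate, and the numerical choices a maintainer should know about.

## The allele-specific copy-number model

A bulk tumor sample is a mixture of tumor cells (fraction $\rho$, the
purity) and diploid normal cells. A genomic segment carrying $n_A \ge n_B$
copies of its two parental haplotypes produces, at a heterozygous SNP, an
expected minor-allele B-allele frequency (BAF) and a coverage log-ratio
(LogR) of

$$\mathrm{BAF} = \frac{(1-\rho) + \rho\, n_B}{2(1-\rho) + \rho (n_A+n_B)},
\qquad
\mathrm{LogR} = \gamma \log_2
  \frac{2(1-\rho) + \rho (n_A+n_B)}{2(1-\rho) + \rho \psi},$$

where $\psi$ is the average tumor ploidy and $\gamma$ the platform response
(1 for WGS). `forward_baf_logr()` is this generative model;
`estimate_allele_cn()` inverts it by exhaustive search over integer pairs
$(n_A, n_B)$ up to `max_cn = 12`, minimizing the squared distance in the
(BAF, LogR) plane. At zero noise the inversion is an exact inverse (this is
a tested invariant). Ties — which arise only for observations equidistant
from several lattice points — are broken toward the smaller total copy
number, then the larger minor count, so results are deterministic.

Per-SNP tracks come from `compute_baf_logr()`: sites need total depth
$\ge 10$ in both tumor and normal; $\mathrm{BAF}_i = a_i/(r_i + a_i)$ and
$\mathrm{LogR}_i = \log_2((d_{ti}/d_{ni})/(\partial_t/\partial_n))$ with
cohort mean depths $\partial$ taken over retained SNPs.

### Segmentation

Noisy coverage can oversegment; breakpoints are therefore determined from
the *mirrored* heterozygous-SNP BAF, $|\mathrm{BAF}-0.5|$, only, while each
segment's coverage is still summarized as the mean LogR of its sites.
The changepoint engine is recursive binary segmentation on the
per-chromosome sum of squares. A split is accepted when it reduces the cost
by more than $\lambda\,\hat\sigma^2 \log n$, with $\hat\sigma^2$ estimated
robustly from first differences (MAD) so level shifts do not inflate it.
The default $\lambda = 4$ is close to a BIC penalty and was chosen for its
operating point on planted profiles: near-perfect localization (within
±2 sites for a 0.25 mirrored step at noise SD 0.02) and precision above 0.9
under binomial count noise at 40×. Segments need at least `min_sites = 5`
SNPs.

A limitation worth stating plainly: the simulated panel carries ~300 SNPs
per chromosome (real phased panels carry $10^4$–$10^5$), so at 40× depth a
mirrored-BAF step below ≈0.12 carries too little information for *any*
changepoint method at this density. The breakpoint-recovery tests therefore
plant steps of ≥0.08 mirrored units at the additive noise default
(SD 0.02), which is the regime the algorithm is designed for; changes that
are balanced in BAF (e.g. $2{+}2$ from $1{+}1$ at low purity) are invisible
to a BAF-only segmentation *by design* and are recovered through the LogR
term of the inversion instead.

### Copy-number states

`classify_cn_state()` applies the rule list in order, later conditions
winning: *weak gain* if $CN_{total} > \mathrm{round}(\psi)$, *medium gain*
if $> 1.5\,\mathrm{round}(\psi)$, *strong gain* if
$> 2.5\,\mathrm{round}(\psi)$, *shallow loss* if $< \mathrm{round}(\psi)$,
*loss* if $< 0.5\,\mathrm{round}(\psi)$, else *neutral*; *amplification*
overrides everything for focal segments (<10 Mb) with $CN_{major} \ge 5$
and $\mathrm{LogR}_{seg} - \mathrm{LogR}_{contig} > 0.7$. Balance states
use $CN_{ratio} = CN_{major}/CN_{total}$ with the 2/3 threshold separating
weak from strong imbalance; $CN_{minor} = 0$ marks LOH. Note that
`round()` here is R's round-half-to-even: a ploidy estimate of exactly 2.5
rounds to 2, and 3.5 to 4. Ploidy estimates near x.5 therefore deserve
inspection, since the rounded baseline changes every state call on the
sample.

Region summaries (`summarize_region()`) are overlap-length-weighted means
(for LogR and $CN_{ratio}$) or largest-overlap dominant states. 5 Mb bins
that overlap an *amplification* segment take that segment's values
directly, discarding co-occupants — otherwise a 1 Mb amplicon would be
averaged away in a 5 Mb bin; with several amplified segments the largest
overlap wins.

## Telomere maintenance calling

Telomere length is proxied by counting reads containing at least $k = 7$
exact consecutive copies of TTAGGG (or CCCTAA; counting both strands is the
package default and switchable, G-strand-only being the convention of some
counters). GC and genome-size normalization of dedicated tools is replaced
by a single scale constant because only the tumor/normal *ratio*
$\log(L_T/L_N)$ (natural log) enters downstream, and the constant cancels.
The ALT criterion is $\log(L_T/L_N) > 0.5$, about a 1.65-fold elongation.

TERT activation is detected on the cohort's TERT expression Z-scores by a
two-component Gaussian mixture (mclust, BIC choosing equal or unequal
variances). The TERT-high threshold is the smallest Z at which the
posterior of the stronger-expression component reaches 95%, located by a
grid and refined by bisection; the posterior need not be monotone when
variances differ, so the *smallest* crossing is taken deliberately.
A sample is TERT-high only if it carries neither MYCN amplification nor a
TERT rearrangement — those flags are inputs, not inferred from reads.
Labels follow the rule table: CTM (MYCN amp, TERT rearrangement, or
TERT-high), ALT (length ratio above cutoff), Mix (both), None (neither);
the 16-case truth table is tested exhaustively.

TERRA expression counts RNA fragments where either mate carries ≥5
consecutive TTAGGG copies, reported as fragments per million. Validation
against experimental labels (APBs, C-circles) reports sensitivity,
specificity and a one-sided Fisher exact p.

## Allele-specific expression

Sites with fewer than 8 total or fewer than 2 allelic reads are removed;
"2 allelic reads" is read strictly (each allele), with an `"either"` switch.
Sites must then pass a bi-allelic test: the sample's sequencing noise rate
$p_0 = \sum \mathrm{other}/\sum \mathrm{depth}$ defines an upper-tail
binomial null for the minimum allele count; rejection at FDR 0.05 (BH)
marks genuine heterozygous signal. The upper tail is the only direction
that distinguishes true bi-allelic signal from noise, which is why it is
fixed despite the source rule naming only "a binomial test".

Phased site counts are summed per haplotype and gene
(`aggregate_haplotypes()`); genes need ≥10 haplotype counts. The ASE ratio
is $\max(A,B)/(A+B) \in [0.5, 1]$ — invariant under haplotype relabeling.
Allelic expression imbalance is the exact two-sided binomial test of $A$
against 0.5, minimum-likelihood convention (the sum of probabilities of all
outcomes no more likely than observed — conventions differ between
implementations, so this one is stated), BH-adjusted across all gene ×
sample observations jointly (the pooling scope is a package decision; the
source text leaves it open). Reference mapping bias is estimated as the
mean reference fraction over sites in copy-balanced segments and is
reported for diagnostics only; the AEI null stays at 0.5 unless
`null_prob` is set, because nothing in the source procedure re-centers it.

A calibration fact users should know: at $A+B = 50$ reads the exact test's
true type-I rate at $\alpha = 0.05$ is 0.0328, not 0.05 — discreteness
makes exact binomial tests conservative, and the next-larger rejection
region would have level 0.065. Power at depth 60 for a true ratio of 0.8
still exceeds 0.95.

## Genetic effects on expression and ASE

Expression is library-size scaled (CPM), `log1p`-transformed and
residualized per gene on the cohort indicator. This transform is a
deliberate, stated stand-in for a full variance-stabilizing transformation;
all effect estimates are validated by parameter-recovery properties, not by
matching any specific normalization's output.

Per gene, ordinary least squares decomposes the response into genetic
effects by sequential (Type I) ANOVA in a *fixed* order — lead eQTL
genotype, copy-number LogR, SV breakpoint, promoter SNV, gene-body SNV,
then purity and MYCN amplification (for the ASE model: eQTL
heterozygosity, copy-number ratio, …, plus log allelic coverage). With
sequential sums of squares the order is part of the contract: fractions
$SS_{effect}/SS_{total}$ plus the residual sum to exactly 1 (tested at
1e-8), and reordering predictors redistributes shared variance. Genes
need ≥20 complete observations. Per-effect p-values (ANOVA F) are
Bonferroni-adjusted across genes within each effect — the stricter of the
two corrections the source text mentions — with a BH switch. Planted
variance fractions between 0 and 0.7 are recovered with slope 1 ± 0.05
across 500 simulated genes at $n = 115$.

The allelic-dosage (AD) test regresses the ASE ratio on expression plus
covariates per gene; the expression term enters the sequential ANOVA first.
A negative coefficient is the loss-of-imprinting pattern (bi-allelic
activation raises expression while the ratio falls), a positive one the
mono-allelic amplification pattern. The ALT differential-expression scan
compares nested linear models with and without the ALT term, BH across
genes, Mix samples excluded.

## Structural events and association scans

The ATRX exon-deletion detector fits a two-component Gaussian mixture to
50 bp-binned $\log_2$ tumor/normal coverage over the gene and calls a
deletion when the cluster means differ by ≥1.5 units and the smaller
cluster's weight is ≥10% of the larger's — "proportion of 10% or more" is
read as a weight *ratio*; at planted deletions covering ≥30% of bins the
detector's sensitivity and specificity both exceed 0.95.

Whole-genome doubling wraps any single-profile caller in a bootstrap:
100 profiles of 22 chromosomes drawn with replacement, WGD-positive when
≥5% of runs call a doubling. The default caller — ≥50% of resampled genome
length at $CN_{total} \ge 4$ with $CN_{major} \ge 2$ — is an explicitly
replaceable stand-in for evolutionary-distance callers; the bootstrap
wrapper, not the caller, is the contribution here, and a caller that
ignores the resample yields a degenerate bootstrap fraction of exactly 0
or 1 (tested). Fisher enrichment of WGD across TMM groups reports
`round(n_g × total/N)` expected counts (the worked cohort example:
20 / 8 / 16 expected for groups of 51 / 20 / 43 with 44 WGD among 115) and
a two-sided Fisher p by default, with a sidedness flag.

The arm-level ALT scan and the binned survival scan are nested-GLM
chi-squared tests per region, Bonferroni-corrected, significant below 0.05
FWER; adjacent significant survival bins are merged. Two numerical choices
matter. First, the chi-squared statistic is the Rao score test: at this
cohort's event count (~34 deaths among 115) the deviance LRT's extreme tail
is ~1.15× anti-conservative, while the score test is nearly exact; both
are "a chi-squared test between two GLMs". Second, even so, asymptotic
tests at a few dozen events retain a measured family-wise error near 0.06
rather than 0.05 — users comparing scan output to a hard 5% FWER bound
should know the residual inflation is a property of asymptotic chi-squared
p-values at this sample size, not of the correction. Complete separation
in the logistic fits is flagged per arm in a `separated` column rather
than silently "fixed"; no penalized-likelihood fallback is shipped.

## The synthetic cohort generator

`simulate_cohort()` emulates every input the analysis consumes, with
planted truth returned alongside: per-SNP tumor/normal allelic depths over
a shared phased panel, a minimal phased VCF, allele-specific segments under
purity/ploidy mixing, allelic RNA site counts (binomial by default —
beta-binomial overdispersion is available but off, so binomial test
calibration stays checkable), a raw expression count matrix with cohort
batch effects and planted eQTL/dosage/SV/SNV effects, bimodal TERT
expression, clinical covariates with survival labels, binned ATRX coverage
and telomere/TERRA FASTQ reads (150 bp, exact repeat concatenations plus
random flanks; background reads drawn from a fixed random pool).

Defaults are the study conditions: 115 samples, 22 integer-indexed
chromosomes with lengths declining 230–50 Mb and centromeres at 40%,
purity uniform on [0.3, 1], near-diploid or near-triploid baselines
(`ploidy_options` 2.0 / 3.6), 38% WGD, MYCN amplification in 20%, TERT
rearrangement in 14%, elevated telomere ratio in 18%, and the TERT mixture
N(−0.5, 0.3) / N(1.5, 0.3) with weights 0.7 / 0.3 — a well-separated
mixture under which the threshold recovery properties are meaningful.
Copy-number hotspots are planted where the disease has them: a focal MYCN
amplicon on 2p, 11q loss in 90% of ALT samples, 17p LOH driving the
survival association. Noise magnitudes for BAF/LogR have no published
values and are free parameters (`noise_sd_baf = 0.02`,
`noise_sd_logr = 0.1`) on top of Poisson/binomial count noise at 40×.

In the exact noise-free limit (`noise_sd_baf = 0`, `noise_sd_logr = 0`,
purity pinned at its upper bound) tumor depths are rounded to multiples of
each segment's total copy number so that integer counts reproduce allelic
ratios exactly; this supports the zero-noise round-trip tests.

What the generator does *not* emulate — and hence what green tests do not
show about real data: reference-genome sequence context and mappability
(the genome is abstract), read-level error models, statistical-phasing
switch errors (phase is emitted correct), germline CNVs, subclonal
heterogeneity (one clone per sample), GC-dependent coverage waves, and
realistic telomeric read fractions (the simulated 5% is orders of
magnitude above WGS reality so that small per-sample FASTQs still carry
length signal; scaled problem sizes throughout are a deliberate choice to
keep the full suite re-runnable in minutes).

## Problem sizes used by the shipped checks

The test-suite and acceptance-script simulations use: 10,000 null genes at
$n = 50$ for AEI calibration; 200 null cohorts of $n = 115$ for the scan
FWER; 500 genes at $n = 115$ for variance-fraction recovery; 200 cohorts
of $n = 115$ for threshold recovery; 200 replicates of 400 coverage bins
for the ATRX operating point; and one full default cohort (115 samples,
22 chromosomes, 300 SNPs and 25 genes per chromosome) for the end-to-end
TMM label accuracy. These sizes are the package's chosen balance between
statistical resolution and a suite that runs in minutes on one core.

## A small worked run

```{r example, eval = FALSE}
cfg <- sim_config(n_samples = 12, n_chromosomes = 8, snps_per_chrom = 150,
                  genes_per_chrom = 10, reads_per_sample = 500,
                  terra_fragments = 300, atrx_bins = 120, seed = 1)
res <- run_pipeline(cfg, out_dir = "nbdosage_run", effects_min_obs = 10)
res$summary
autoplot(res$tmm$mixture_fit)
plot_cn_profile(dplyr::filter(res$cn$segments, sample == "S001"))
```

## Known limitations

Purity and ploidy are inputs (as in the source pipeline, which takes them
from an allele-specific caller's grid fit); no goodness-of-fit search is
performed. Sex chromosomes are out of scope. The segmentation penalty is a
free parameter; extremely short true segments (<5 SNPs in the simulated
panel) are not recoverable. Survival modeling beyond the binary
deceased-vs-other GLM (Kaplan–Meier, Cox) is delegated to the survival
package and not part of the tested surface.
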