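# asecn

Allele-specific copy number and allele-specific expression calling from
paired tumor WGS and RNA-seq.

## What it is for

In aneuploid tumors, the two alleles of a gene frequently differ in copy
number, so skewed allelic read counts in RNA-seq can reflect nothing more
than gene dosage. `asecn` is for researchers with paired tumor genome and
transcriptome data who want to tell those cases apart. It works without a
matched normal sample: the copy-number baseline comes from a reference
panel of normal genomes.

The pipeline has two halves:

**Allele-specific copy number (asCN).** Per-SNV depths are normalized to
the sample mean and compared with the panel median as a log R ratio,
`LRR = log2(d_tumor / d_panel)`. The LRR series is segmented per chromosome
by circular binary segmentation (max-t statistic, permutation p-values),
segments are classified into copy-number classes {1, 2, 3, 4, AMP(≥5)} by
nearest expected LRR `log2(c / ploidy)`, and per-segment allelic imbalance
is summarised from heterozygous sites: `AI_snp = |RAF − 0.5|`, k-means
split into high/low clusters with means `AF_h`, `AF_L`, and
`AI_seg = AF_h / AF_L`. Class and imbalance together give an integer
`(major, minor)` state per segment — e.g. (2,1) trisomy, (2,0) copy-neutral
LOH.

**Allele-specific expression (ASE).** RNA allele counts over quality-
filtered exonic heterozygous SNVs are aggregated per gene into
major/minor-haplotype totals (WGS-frequency-guided phasing on unbalanced
segments, pseudo-phasing on balanced ones) and tested with an exact
binomial test against two nulls: model 1, `p0 = 0.5` (equal expression),
and model 2, `p0 = major / (major + minor)` (expression follows dosage).
After Benjamini–Hochberg adjustment and a WGS/RNA odds-ratio gate, each
gene is classified `BALANCED`, `CNV_DRIVEN_ASE` (model 1 rejected, model 2
retained), `CNV_INDEPENDENT_ASE`, or `NOT_TESTABLE`.

A synthetic-data module generates complete studies — panel cohort,
aneuploid tumor with known karyotype and purity, RNA counts with known
allelic effects — so every stage is testable without external data.

## Worked example

Simulate a study (18 × 10 Mb chromosomes: mostly disomic, one focal
trisomic segment, one whole trisomy, one CN-LOH chromosome, one 3:1
tetrasomy; purity 1.0, 40×), call asCN, then call ASE:

```r
library(asecn)

spec  <- karyotype_spec(seed = 42)
study <- simulate_study(spec)

ascn <- call_ascn(study$tumor$snvs, study$panel, ascn_config(seed = 42))
ascn
#> Allele-specific copy-number call
#>   markers: 9000 (0 below depth filter, 0 without panel baseline)
#>   segments: 20
#>   states:   (1,1)x16 (2,0)x1 (2,1)x2 (3,1)x1

dplyr::filter(tidy(ascn), chrom >= "chr16") |>
  dplyr::select(chrom, n_markers, mean_lrr, cn_class, af_h, ai_seg, major, minor)
#> # A tibble: 3 × 8
#>   chrom n_markers mean_lrr cn_class  af_h ai_seg major minor
#>   <chr>     <int>    <dbl> <chr>    <dbl>  <dbl> <int> <int>
#> 1 chr16       500    0.455 3        0.211   2.01     2     1
#> 2 chr17       500   -0.152 2        0.5     1        2     0
#> 3 chr18       500    0.860 4        0.288   1.41     3     1
```

The trisomy sits near its expected LRR of `log2(3/2) ≈ 0.58` (lower here
because the tumor is normalized to its own slightly-aneuploid mean), the
CN-LOH chromosome has every heterozygous site fixed (`AF_h = 0.5`) at
neutral depth, and the tetrasomy combines a high LRR with the ~0.25 AI of
a 3:1 split.

```r
hets <- filter_het_snvs(study$tumor$snvs, study$rna$exons)
inp  <- prepare_ase_input(study$rna$counts, hets, tidy(ascn),
                          cpm = study$rna$cpm)
ase  <- call_ase(inp)
ase
#> Allele-specific expression call
#>   BALANCED             150
#>   CNV_DRIVEN_ASE       19
#>   CNV_INDEPENDENT_ASE  18
#>   NOT_TESTABLE         13
glance(ase)
#> # A tibble: 1 × 7
#>   n_genes n_testable n_cnv_driven n_cnv_independent n_balanced frac_ase ...
#> 1     200        187           19                18        150    0.198
```

Genes on the trisomy expressed at their 2:1 dosage come out `CNV_DRIVEN_ASE`;
disomic genes with an injected 90:10 allelic effect come out
`CNV_INDEPENDENT_ASE`; LOH genes are `NOT_TESTABLE` (no heterozygous
expression is expected there). `autoplot(ascn)` draws the segmented LRR
profile, `plot_allelic_imbalance(ascn)` the AI clusters, and
`autoplot(ase)` a volcano-style gene plot.

A command-line front end wrapping the same functions is installed at
`system.file("cli/asecn", package = "asecn")` with verbs `build-panel`,
`call-ascn`, `call-ase`, `simulate` and `run-all`.

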