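---
title: "Methods: allele-specific copy number and expression calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific copy number and expression calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asecn)
```

## The problem

In an aneuploid tumor, the two alleles of a gene are often present in
unequal copy numbers, so unequal allelic expression measured from RNA-seq
cannot by itself distinguish transcriptional regulation from simple gene
dosage. `asecn` separates the two by first estimating allele-specific copy
number (asCN) from tumor WGS against a reference panel of normal samples —
no matched normal is needed — and then testing gene-level RNA allele counts
against both an equal-expression null and the null implied by the asCN
state.

## Copy-number model

**Panel.** Each normal sample's per-SNV-site depth is divided by its mean
depth over retained sites (sites with raw depth $\le 10$ are dropped first;
the threshold is strict). Normalized X and Y values of male samples are
doubled so one sex-chromosome copy reads as the diploid baseline;
Y-chromosome sites of female samples are dropped rather than recorded as
zero, which would corrupt the baseline median. The panel value at a site is
the median of the normalized depths across samples. Two choices here are
deliberately simple because the construction is silent about them: the
per-sample mean is computed over retained sites only (a mean over all sites
would be deflated by uncovered loci), and it is computed *before* the male
×2 adjustment (the adjustment is a reporting convention for the sex
chromosomes, not a property of the library size).

**LRR.** At every tumor site present in the panel (tumor depth strictly
over 10), the log R ratio is

$$\mathrm{LRR} = \log_2 \frac{d_\text{tumor}}{d_\text{panel}}$$

with both depths in normalized units. Base 2 is the standard LRR
convention; a copy gained or lost then moves the expected LRR by the log of
a simple copy ratio.

**Segmentation.** LRR series are segmented per chromosome by circular
binary segmentation: the split statistic is the largest absolute t
statistic comparing any arc's mean against its complement, referred to a
permutation distribution of the same statistic (default 1,000 permutations,
split accepted at $\alpha = 0.01$, minimum 10 markers per segment; all
three are exposed in `ascn_config()`). The scan is implemented in C++;
permutations stop early as soon as the exceedance count makes significance
impossible, which cannot change any accept/reject decision. The common
variance factor is omitted from the statistic because it is invariant under
permutation, leaving both the argmax and the p-value unchanged.

**Copy-number classes.** A segment with mean LRR $\bar\ell$ is assigned the
class $c \in \{1, 2, 3, 4, \mathrm{AMP}(\ge 5)\}$ whose expected LRR
$\log_2(c/\pi)$ is nearest, with boundaries at midpoints of adjacent
expected values; $\pi$ is the `ploidy` parameter (default 2). Near-triploid
genomes are handled by raising `ploidy`, which recentres every class
boundary at once. Note that because the tumor is normalized to its own mean
depth, a genome that is mostly aberrant shifts its diploid baseline away
from LRR 0; `ploidy` is the intended correction for that regime as well.

**Allelic imbalance.** For each heterozygous SNV, $AI = |RAF - 0.5|$ where
RAF is the reference-allele read fraction. For segments longer than 100 kb
with at least 20 heterozygous SNVs, the AI values are split into two groups
by 1-D k-means (squared Euclidean distance, $k = 2$, ten seeded random
restarts plus deterministic starts at the data range and quartiles, best
inertia kept); $AF_h$ and $AF_L$ are the higher and lower group means and
$AI_{seg} = AF_h / AF_L$ (with $AF_L$ floored at $10^{-3}$). If all values
are identical the clusters degenerate and $AI_{seg} = 1$ by convention.

**State assignment.** The `(major, minor)` state combines the class with
the AI statistics. The candidate states per class are: class 1 — (1,0);
class 2 — (1,1), (2,0); class 3 — (2,1) (a trisomy has no balanced split);
class 4 — (2,2), (3,1), (4,0); AMP — every split of the total implied by
the mean LRR. A segment is *eligible* for an imbalanced state only when
$AF_h \ge 0.1$ and either $AI_{seg} \ge 1.4$ or the lower cluster mean is
itself $\ge 0.1$; among the candidates the state whose expected AI,
$M/(M+m) - 0.5$, is nearest to $AF_h$ is chosen (ties toward balance).
Segments failing the AI preconditions take the balanced default of their
class so that the genome stays fully covered.

Two parts of this rule are this package's own design and deserve
justification. First, the ratio $AI_{seg}$ alone cannot decide imbalance:
under binomial read noise at 40× the folded AI values of a perfectly
*balanced* segment split into a near-zero and a noise cluster with
$AI_{seg} \approx 3.5$, while a strongly imbalanced 3:1 tetrasomy — whose
het AI values all sit near 0.25 — yields $AI_{seg} \approx 1.4$. The ratio
flags *spread*, not *level*. The nearest-expected-AI comparison on $AF_h$
supplies the level information and is the same rule used to size
amplification states. Second, the "either/or" gate admits uniformly skewed
segments whose two cluster means are both high — the signature of
copy-neutral LOH, where at high purity every het site is fixed at
$AI = 0.5$ and the clusters degenerate to a tie. Without this route, pure
LOH would be unreachable by construction.

## ASE model

Heterozygous SNVs from the tumor WGS are kept when all quality annotations
pass strict thresholds (DP > 15, QD > 2, MQ > 35, MQRankSum > −12.5,
ReadPosRankSum > −8, FS < 60) and the site falls in a supplied exon. RNA
allele counts over those sites are kept when the site has at least 10
reads; genes are testable when expressed at CPM ≥ 1 and holding at least
one kept SNV. A gene spanning two segments is assigned to the segment
containing the majority of its tested SNVs (ties make it untestable).

Counts are aggregated per gene into major/minor haplotype totals. On
unbalanced segments the WGS allele frequency carries phase: the allele with
WGS RAF > 0.5 lies on the amplified haplotype (sites at exactly 0.5 are
uninformative there and are excluded). On balanced segments no copy-number
phase exists, so pseudo-phasing assigns each SNV's larger RNA count to the
major haplotype, ties to the reference allele. Pseudo-phasing biases the
aggregate toward imbalance under the null; the binomial test absorbs most
of this for the gene sizes involved, and the residual inflation is measured
directly by the type-I simulation below rather than assumed away.

Each testable gene is tested twice with an exact two-sided binomial test
(minimum-likelihood construction with a $1+10^{-7}$ tie guard): model 1
with $p_0 = 0.5$ (equal expression) and model 2 with
$p_0 = M/(M+m)$ (expression follows dosage). Genes on $(N, 0)$ LOH
segments are not testable — no heterozygous expression is expected there.
p-values are adjusted per model across all tested genes by
Benjamini–Hochberg. The WGS/RNA odds ratio

$$\mathrm{OR} = \frac{(r_\text{maj}+\tfrac12)/(r_\text{min}+\tfrac12)}
                     {(w_\text{maj}+\tfrac12)/(w_\text{min}+\tfrac12)}$$

uses Haldane–Anscombe pseudocounts so zero counts stay defined.
Classification at FDR level $\alpha = 0.05$: genes with $q_1 > \alpha$ are
`BALANCED`; on unbalanced segments, $q_1 \le \alpha$ with $q_2 > \alpha$ is
`CNV_DRIVEN_ASE` (the imbalance is explained by dosage) and with
$q_2 \le \alpha$ is `CNV_INDEPENDENT_ASE`; on balanced segments the two
nulls coincide, so $q_1 \le \alpha$ is called `CNV_INDEPENDENT_ASE` only
when the odds ratio clears the > 2 / < 0.5 gate. Restricting the OR gate to
balanced segments is a deliberate resolution of an ambiguity: on unbalanced
segments the WGS odds already differ from 1 and the OR no longer measures
expression-level imbalance alone. Model 2 uses the raw integer asCN ratio,
not a purity-adjusted expectation; in impure samples this makes the
CNV-driven call conservative.

## The synthetic-data generator

The generator emulates the three inputs at desk scale: a diploid normal
cohort for the panel (per-site depths Poisson), an aneuploid tumor with a
known segment karyotype mixed with diploid normal cells at a given purity
(site depth Poisson with mean proportional to the mixed copy number;
reference reads Binomial with the mixed allele fraction; per-site phase
random), and RNA allele counts over the tumor's het sites (genes of
1 + Poisson(1.2) consecutive het SNVs, per-SNV totals Poisson, major-
haplotype reads Binomial at the gene's true expression fraction, phased
consistently with the WGS truth).

Defaults are fixed once as the study conditions: 18 chromosomes of 10 Mb
(fourteen disomic, one focal trisomic segment, one whole-chromosome
trisomy, one copy-neutral LOH, one 3:1 tetrasomy — a mostly diploid genome,
as the mean-depth normalization presumes), 50 SNVs/Mb, 40× tumor depth,
a 20-sample panel at 30×, 35% het / 30% hom-alt site mix, RNA depth
Poisson(80) per SNV, and purities {1.0, 0.75, 0.5, 0.25} for the
contamination ladder. These sizes keep a full study at ~9,000 markers and a
complete pipeline run within seconds while leaving each segment hundreds of
markers and each gene tens of reads.

Two idealisations matter when reading test results. The generator carries
the *germline* heterozygosity flag through to the tumor table, emulating
genotypes known from panel-informed or joint genotyping; a caller genotyping
a pure-LOH region from tumor reads alone would see no heterozygous sites
there, which is precisely why LOH calling degrades in real noisy samples.
And there is no read-level simulation: no sequencing error, no mapping
bias, no overdispersion beyond Poisson/Binomial. Passing tests therefore
demonstrate correctness of the statistical machinery under its stated
model, not robustness to artefacts that upstream tools (duplicate marking,
WASP filtering) are assumed to have handled.

## Numerical choices

* Strict inequalities everywhere a threshold is stated ("over 10" keeps 11,
  drops 10; DP > 15 drops 15).
* Even-count medians are the mean of the two central values.
* k-means ties between equal cluster means are broken by declaring balance
  ($AI_{seg} = 1$).
* Class boundaries at LRR midpoints; values exactly on a boundary take the
  higher class.
* The binomial tie guard ($1+10^{-7}$) matches the convention of standard
  exact tests, so point probabilities equal to the observed one (up to
  float error) are included in the p-value.
* Segmentation, k-means restarts and all simulations run under explicit
  seeds; a fixed seed reproduces every table byte for byte.
* Chromosomes with fewer markers than `cbs_min_markers` yield one trivial
  segment with a warning rather than an error.

## Known limitations

Integer states only — no subclonal fractions; no automatic purity or
ploidy estimation (ploidy is a user parameter); no matched-normal paired
calling; no structural-variant breakpoints; trisomy is always modelled as
(2,1), so a (3,0) state is folded into its nearest modelled neighbour;
CN-LOH detection collapses below ~50% purity as the residual heterozygosity
signal falls under the imbalance gate — the same regime in which
depth-based CNV callers generally fail.
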