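#' Filter WGS variants to high-confidence exonic heterozygous SNVs
#'
#' Applies the variant-quality filters (all strict inequalities) to
#' GATK-style annotations and keeps only heterozygous SNVs overlapping a
#' supplied exon interval: `DP > 15`, `QD > 2`, `MQ > 35`,
#' `MQRankSum > -12.5`, `ReadPosRankSum > -8`, `FS < 60` (defaults from
#' [ase_thresholds()]). Records missing any annotation are dropped and
#' counted.
#'
#' @param variants A data frame with columns `chrom`, `pos`, `is_het`,
#'   `ref_depth`, `alt_depth` and annotation columns `DP`, `QD`, `MQ`,
#'   `MQRankSum`, `ReadPosRankSum`, `FS`.
#' @param exons A data frame of exon intervals: `chrom`, `start`, `end`
#'   (1-based inclusive) and `gene_id`.
#' @param thresholds An [ase_thresholds()].
#' @return A tibble of retained records with `gene_id` attached and
#'   `wgs_raf = ref_depth / (ref_depth + alt_depth)`; the number of records
#'   dropped for missing annotations is in attribute `n_missing_annotation`.
#' @export
filter_het_snvs <- function(variants, exons, thresholds = ase_thresholds()) {
  ann <- c("DP", "QD", "MQ", "MQRankSum", "ReadPosRankSum", "FS")
  stopifnot(all(c("chrom", "pos", "is_het", "ref_depth", "alt_depth", ann)
                %in% names(variants)),
            all(c("chrom", "start", "end", "gene_id") %in% names(exons)))
  v <- as_tibble(variants)
  missing_ann <- !stats::complete.cases(v[ann])
  n_missing <- sum(missing_ann)
  if (n_missing > 0) {
    inform(paste0(n_missing, " record(s) dropped for missing annotations."))
  }
  v <- v[!missing_ann, , drop = FALSE]
  v <- filter(v,
              .data$is_het,
              .data$DP > thresholds$min_dp,
              .data$QD > thresholds$min_qd,
              .data$MQ > thresholds$min_mq,
              .data$MQRankSum > thresholds$min_mqranksum,
              .data$ReadPosRankSum > thresholds$min_readposranksum,
              .data$FS < thresholds$max_fs)
  hits <- overlap_join(v, exons)
  out <- mutate(hits,
                wgs_raf = .data$ref_depth / (.data$ref_depth + .data$alt_depth))
  attr(out, "n_missing_annotation") <- n_missing
  out
}

# annotate rows of `x` (chrom, pos) with gene_id from overlapping exon rows
overlap_join <- function(x, exons) {
  if (nrow(x) == 0) return(mutate(x, gene_id = character(0)))
  q <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
  s <- GenomicRanges::GRanges(exons$chrom,
                              IRanges::IRanges(exons$start, exons$end))
  ov <- GenomicRanges::findOverlaps(q, s)
  out <- x[S4Vectors::queryHits(ov), , drop = FALSE]
  out$gene_id <- exons$gene_id[S4Vectors::subjectHits(ov)]
  distinct(out, .data$chrom, .data$pos, .data$gene_id, .keep_all = TRUE)
}

#' Filter RNA allele counts and mark testable genes
#'
#' An SNV is kept when its RNA coverage `ref_count + alt_count` is at least
#' `min_rna_total` (default 10; strictly, sites with fewer than 10 reads are
#' excluded). A gene is testable when its expression is at least `min_cpm`
#' (default CPM >= 1) and it retains at least one SNV.
#'
#' @param snvs A data frame with columns `gene_id`, `ref_count`, `alt_count`
#'   (one row per SNV).
#' @param cpm Optional data frame `gene_id`, `cpm`; genes absent from it are
#'   treated as unexpressed. `NULL` skips the expression filter.
#' @param thresholds An [ase_thresholds()].
#' @return A list with `snvs` (kept SNV rows) and `genes` (tibble `gene_id`,
#'   `n_snvs`, `cpm`, `testable`).
#' @export
filter_rna_counts <- function(snvs, cpm = NULL,
                              thresholds = ase_thresholds()) {
  stopifnot(all(c("gene_id", "ref_count", "alt_count") %in% names(snvs)))
  all_genes <- unique(snvs$gene_id)
  kept <- filter(as_tibble(snvs),
                 .data$ref_count + .data$alt_count >= thresholds$min_rna_total)
  genes <- tibble(gene_id = all_genes) |>
    left_join(count(kept, .data$gene_id, name = "n_snvs"), by = "gene_id") |>
    mutate(n_snvs = coalesce(.data$n_snvs, 0L))
  if (is.null(cpm)) {
    genes$cpm <- NA_real_
    genes$testable <- genes$n_snvs >= 1L
  } else {
    stopifnot(all(c("gene_id", "cpm") %in% names(cpm)))
    genes <- left_join(genes, cpm[c("gene_id", "cpm")], by = "gene_id")
    genes$testable <- genes$n_snvs >= 1L &
      !is.na(genes$cpm) & genes$cpm >= thresholds$min_cpm
  }
  list(snvs = kept, genes = genes)
}

#' Aggregate a gene's RNA allele counts into major/minor haplotype counts
#'
#' On an unbalanced segment (`major != minor`) the WGS reference-allele
#' frequency identifies which allele of each SNV lies on the amplified
#' haplotype: the allele with `wgs_raf > 0.5` contributes to the major
#' count. SNVs with `wgs_raf` exactly 0.5 carry no phase information there
#' and are excluded (counted in `n_excluded`). On a balanced segment the
#' phase is unknowable from copy number, so pseudo-phasing is used: each
#' SNV's larger RNA count goes to the major haplotype (ties: reference
#' allele to major).
#'
#' @param snvs A data frame (one gene) with columns `ref_count`, `alt_count`,
#'   `wgs_raf`.
#' @param major,minor The gene's segment asCN state.
#' @return A one-row tibble: `major_count`, `minor_count`, `n_used`,
#'   `n_excluded`.
#' @export
#' @examples
#' g <- tibble::tibble(ref_count = c(30, 10), alt_count = c(15, 20),
#'                     wgs_raf = c(0.67, 0.33))
#' aggregate_gene_counts(g, major = 2, minor = 1)
aggregate_gene_counts <- function(snvs, major, minor) {
  stopifnot(all(c("ref_count", "alt_count", "wgs_raf") %in% names(snvs)))
  s <- as_tibble(snvs)
  if (major != minor) {
    drop <- s$wgs_raf == 0.5
    s <- s[!drop, , drop = FALSE]
    ref_is_major <- s$wgs_raf > 0.5
    n_excluded <- sum(drop)
  } else {
    ref_is_major <- s$ref_count >= s$alt_count
    n_excluded <- 0L
  }
  tibble(
    major_count = sum(ifelse(ref_is_major, s$ref_count, s$alt_count)),
    minor_count = sum(ifelse(ref_is_major, s$alt_count, s$ref_count)),
    n_used = nrow(s),
    n_excluded = as.integer(n_excluded)
  )
}

#' Expected major-haplotype expression fraction under the asCN null
#'
#' Model 2 posits that expression follows gene dosage: a gene on a
#' `(major, minor)` segment is expected to transcribe the major haplotype at
#' `major / (major + minor)`. A segment with `minor = 0` carries no expected
#' heterozygosity, so the fraction degenerates to 1 and the gene is not
#' testable under model 2.
#'
#' @param major,minor Integer allele copy numbers, `major >= minor >= 0`,
#'   `major + minor >= 1`.
#' @return The expected major fraction (vectorized).
#' @export
#' @examples
#' expected_major_fraction(2, 1)
expected_major_fraction <- function(major, minor) {
  if (any(major + minor == 0)) abort("major + minor must be >= 1.")
  if (any(minor > major) || any(minor < 0)) {
    abort("major >= minor >= 0 is required.")
  }
  major / (major + minor)
}

#' Exact two-sided binomial test (minimum-likelihood method)
#'
#' The p-value is the total probability, under `Binomial(n, p0)`, of all
#' outcomes whose point probability does not exceed that of the observed
#' count (with a `1 + 1e-7` relative guard against floating-point ties) --
#' the construction used by standard exact tests.
#'
#' @param k_major Observed major-haplotype reads, `0 <= k_major <= n`
#'   (vectorized).
#' @param n Total reads (> 0).
#' @param p0 Null major fraction in (0, 1).
#' @return p-values in `(0, 1]`.
#' @export
#' @examples
#' binomial_ase_test(10, 10, 0.5)  # 2 * 0.5^10
binomial_ase_test <- function(k_major, n, p0) {
  if (any(n == 0)) abort("n must be positive.")
  if (any(p0 <= 0 | p0 >= 1)) abort("p0 must lie strictly in (0, 1).")
  if (any(k_major < 0 | k_major > n)) abort("k_major must lie in [0, n].")
  res <- mapply(function(k, nn, p) {
    d <- dbinom(0:nn, nn, p)
    min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
  }, k_major, n, if (length(p0) == 1) rep(p0, length(k_major)) else p0)
  as.numeric(res)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_i = min over j >= rank(i) of m * p_(j) / j`, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' WGS/RNA allelic odds ratio
#'
#' The ratio of the RNA major/minor odds to the WGS major/minor odds, with
#' Haldane-Anscombe 0.5 pseudocounts so the statistic is defined for zero
#' counts. On a balanced segment the WGS odds are ~1 and the statistic
#' reduces to the RNA expression imbalance.
#'
#' @param rna_major,rna_minor Aggregated RNA reads per haplotype.
#' @param wgs_major_depth,wgs_minor_depth Aggregated WGS reads per haplotype.
#' @return Positive odds ratios (vectorized).
#' @export
#' @examples
#' wgs_rna_odds_ratio(40, 10, 20, 10)
wgs_rna_odds_ratio <- function(rna_major, rna_minor,
                               wgs_major_depth, wgs_minor_depth) {
  if (any(c(rna_major, rna_minor, wgs_major_depth, wgs_minor_depth) < 0)) {
    abort("counts must be non-negative.")
  }
  ((rna_major + 0.5) / (rna_minor + 0.5)) /
    ((wgs_major_depth + 0.5) / (wgs_minor_depth + 0.5))
}

#' Assemble per-gene ASE inputs from RNA counts, het SNVs and segments
#'
#' Joins the RNA allele counts onto the filtered heterozygous WGS SNVs,
#' places each SNV in its copy-number segment, and assigns every gene to the
#' segment holding the majority of its testable SNVs (ties: the gene is not
#' testable).
#'
#' @param rna_counts A data frame `chrom`, `pos`, `ref_count`, `alt_count`
#'   (from [read_ase_counts()]).
#' @param het_snvs Output of [filter_het_snvs()] (columns `chrom`, `pos`,
#'   `gene_id`, `wgs_raf`, `ref_depth`, `alt_depth`).
#' @param segments A segment table with `chrom`, `start`, `end`, `major`,
#'   `minor` (e.g. `tidy()` of an `ascn_call`).
#' @param cpm Optional `gene_id`/`cpm` table.
#' @param thresholds An [ase_thresholds()].
#' @return A tibble, one row per testable SNV, with gene, counts, WGS depths,
#'   segment state and gene-level `cpm`/`testable` columns; genes dropped at
#'   this stage are recorded in attribute `untestable` with a reason.
#' @export
prepare_ase_input <- function(rna_counts, het_snvs, segments, cpm = NULL,
                              thresholds = ase_thresholds()) {
  stopifnot(all(c("chrom", "pos", "ref_count", "alt_count") %in%
                  names(rna_counts)))
  snv <- inner_join(
    as_tibble(het_snvs),
    as_tibble(rna_counts)[c("chrom", "pos", "ref_count", "alt_count")],
    by = c("chrom", "pos")
  )
  flt <- filter_rna_counts(snv, cpm = cpm, thresholds = thresholds)
  kept <- flt$snvs

  seg <- as_tibble(segments) |>
    mutate(segment_id = paste0(.data$chrom, ":", .data$start, "-", .data$end))
  if (nrow(kept) > 0) {
    q <- GenomicRanges::GRanges(kept$chrom, IRanges::IRanges(kept$pos, kept$pos))
    s <- GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(seg$start, seg$end))
    ov <- GenomicRanges::findOverlaps(q, s, select = "first")
    kept$segment_id <- seg$segment_id[ov]
    kept$seg_major <- seg$major[ov]
    kept$seg_minor <- seg$minor[ov]
  } else {
    kept$segment_id <- character(0)
    kept$seg_major <- integer(0)
    kept$seg_minor <- integer(0)
  }

  # gene -> segment by majority of its testable SNVs; ties -> untestable
  assign <- kept |>
    filter(!is.na(.data$segment_id)) |>
    count(.data$gene_id, .data$segment_id) |>
    group_by(.data$gene_id) |>
    filter(.data$n == max(.data$n)) |>
    summarise(segment_id = if (n() == 1) .data$segment_id else NA_character_)

  untestable <- bind_rows(
    filter(flt$genes, !.data$testable) |>
      transmute(.data$gene_id,
                reason = if_else(.data$n_snvs == 0, "no covered SNV",
                                 "below CPM threshold")),
    filter(assign, is.na(.data$segment_id)) |>
      transmute(.data$gene_id, reason = "segment tie"),
    anti_join(distinct(kept, .data$gene_id), assign, by = "gene_id") |>
      transmute(.data$gene_id, reason = "no overlapping segment")
  )

  out <- kept |>
    inner_join(filter(assign, !is.na(.data$segment_id)),
               by = c("gene_id", "segment_id")) |>
    semi_join(filter(flt$genes, .data$testable), by = "gene_id") |>
    left_join(select(flt$genes, "gene_id", "cpm"), by = "gene_id") |>
    select("gene_id", "chrom", "pos", "ref_count", "alt_count", "wgs_raf",
           wgs_ref_depth = "ref_depth", wgs_alt_depth = "alt_depth",
           "segment_id", major = "seg_major", minor = "seg_minor", "cpm")
  attr(out, "untestable") <- untestable
  out
}

#' Call allele-specific expression per gene
#'
#' For every testable gene: aggregate the RNA allele counts into major/minor
#' haplotype counts ([aggregate_gene_counts()]), test them against the
#' equal-expression null (model 1, `p0 = 0.5`) and against the asCN-derived
#' null (model 2, `p0 = major / (major + minor)`), adjust each model's
#' p-values across all tested genes by Benjamini-Hochberg, compute the
#' WGS/RNA odds ratio, and classify:
#'
#' * `q1 > alpha` -> `BALANCED`;
#' * `q1 <= alpha` on an unbalanced segment: `q2 > alpha` ->
#'   `CNV_DRIVEN_ASE` (expression follows the copy-number ratio), otherwise
#'   `CNV_INDEPENDENT_ASE`;
#' * `q1 <= alpha` on a balanced segment (where both nulls coincide):
#'   `CNV_INDEPENDENT_ASE` when the odds ratio clears the `> 2` / `< 0.5`
#'   gate, otherwise `BALANCED`;
#' * genes on `(N, 0)` LOH segments, on no segment, or failing the
#'   count/expression filters -> `NOT_TESTABLE`.
#'
#' @param gene_inputs Per-SNV input tibble from [prepare_ase_input()] (or of
#'   the same shape).
#' @param thresholds An [ase_thresholds()].
#' @return An object of class `ase_call` wrapping the per-gene result tibble
#'   (`gene_id`, `n_snvs`, `major_count`, `minor_count`, `expected_major`,
#'   `p_model1`, `q_model1`, `p_model2`, `q_model2`, `odds_ratio`, `major`,
#'   `minor`, `ase_class`), sorted by `gene_id`.
#' @export
call_ase <- function(gene_inputs, thresholds = ase_thresholds()) {
  need <- c("gene_id", "ref_count", "alt_count", "wgs_raf",
            "wgs_ref_depth", "wgs_alt_depth", "major", "minor")
  stopifnot(all(need %in% names(gene_inputs)))
  gi <- as_tibble(gene_inputs)
  untestable <- attr(gene_inputs, "untestable") %||%
    tibble(gene_id = character(0), reason = character(0))

  loh <- gi |>
    distinct(.data$gene_id, .data$minor) |>
    filter(.data$minor == 0)
  untestable <- bind_rows(untestable,
                          transmute(loh, .data$gene_id,
                                    reason = "LOH segment (minor = 0)"))
  gi <- anti_join(gi, loh, by = "gene_id")

  per_gene <- gi |>
    group_by(.data$gene_id, .data$major, .data$minor) |>
    group_modify(function(d, key) {
      agg <- aggregate_gene_counts(d, key$major, key$minor)
      ref_is_major <- if (key$major != key$minor) {
        d$wgs_raf > 0.5
      } else {
        d$ref_count >= d$alt_count
      }
      usable <- if (key$major != key$minor) d$wgs_raf != 0.5 else rep(TRUE, nrow(d))
      mutate(agg,
             wgs_major_depth = sum(ifelse(ref_is_major, d$wgs_ref_depth,
                                          d$wgs_alt_depth)[usable]),
             wgs_minor_depth = sum(ifelse(ref_is_major, d$wgs_alt_depth,
                                          d$wgs_ref_depth)[usable]))
    }) |>
    ungroup() |>
    filter(.data$n_used > 0, .data$major_count + .data$minor_count > 0)

  alpha <- thresholds$fdr_alpha
  res <- per_gene |>
    mutate(
      expected_major = expected_major_fraction(.data$major, .data$minor),
      n_total = .data$major_count + .data$minor_count,
      p_model1 = binomial_ase_test(.data$major_count, .data$n_total, 0.5),
      p_model2 = binomial_ase_test(.data$major_count, .data$n_total,
                                   .data$expected_major),
      q_model1 = bh_fdr(.data$p_model1),
      q_model2 = bh_fdr(.data$p_model2),
      odds_ratio = wgs_rna_odds_ratio(.data$major_count, .data$minor_count,
                                      .data$wgs_major_depth,
                                      .data$wgs_minor_depth),
      balanced_seg = .data$major == .data$minor,
      or_pass = .data$odds_ratio > thresholds$or_high |
        .data$odds_ratio < thresholds$or_low,
      ase_class = case_when(
        .data$q_model1 > alpha ~ "BALANCED",
        .data$balanced_seg & .data$or_pass ~ "CNV_INDEPENDENT_ASE",
        .data$balanced_seg ~ "BALANCED",
        .data$q_model2 > alpha ~ "CNV_DRIVEN_ASE",
        TRUE ~ "CNV_INDEPENDENT_ASE"
      )
    ) |>
    transmute(.data$gene_id, n_snvs = .data$n_used,
              .data$major_count, .data$minor_count, .data$expected_major,
              .data$p_model1, .data$q_model1, .data$p_model2, .data$q_model2,
              .data$odds_ratio, .data$major, .data$minor, .data$ase_class)

  nt <- untestable |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    anti_join(res, by = "gene_id") |>
    transmute(.data$gene_id, n_snvs = NA_integer_,
              major_count = NA_real_, minor_count = NA_real_,
              expected_major = NA_real_, p_model1 = NA_real_,
              q_model1 = NA_real_, p_model2 = NA_real_, q_model2 = NA_real_,
              odds_ratio = NA_real_, major = NA_integer_, minor = NA_integer_,
              ase_class = "NOT_TESTABLE")

  out <- bind_rows(res, nt) |> arrange(.data$gene_id)
  structure(list(genes = out, thresholds = thresholds,
                 untestable = untestable),
            class = "ase_call")
}

#' @exportS3Method base::print
print.ase_call <- function(x, ...) {
  cat("Allele-specific expression call\n")
  tab <- table(x$genes$ase_class)
  for (cl in names(tab)) cat(sprintf("  %-20s %d\n", cl, tab[[cl]]))
  invisible(x)
}
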