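exon_for <- function(chrom = "chr1", pos = 100L, gene = "G1") {
  tibble::tibble(chrom = chrom, start = pos - 10, end = pos + 10,
                 gene_id = gene)
}

variant_row <- function(pos = 100L, is_het = TRUE, DP = 30L, QD = 10,
                        MQ = 60, MQRankSum = 0, ReadPosRankSum = 0, FS = 5) {
  tibble::tibble(chrom = "chr1", pos = pos, is_het = is_het,
                 ref_depth = 15L, alt_depth = 15L, DP = DP, QD = QD, MQ = MQ,
                 MQRankSum = MQRankSum, ReadPosRankSum = ReadPosRankSum,
                 FS = FS)
}

test_that("het-SNV quality filters are strict on both sides of every
           boundary", {
  ex <- exon_for()
  keep1 <- variant_row(DP = 16L, QD = 3, MQ = 40)
  expect_equal(nrow(filter_het_snvs(keep1, ex)), 1L)

  cases <- list(
    list(DP = 15L, keep = FALSE), list(DP = 16L, keep = TRUE),
    list(QD = 2, keep = FALSE), list(QD = 2.01, keep = TRUE),
    list(MQ = 35, keep = FALSE), list(MQ = 35.5, keep = TRUE),
    list(MQRankSum = -12.5, keep = FALSE), list(MQRankSum = -12.4, keep = TRUE),
    list(ReadPosRankSum = -8, keep = FALSE), list(ReadPosRankSum = -7.9, keep = TRUE),
    list(FS = 60, keep = FALSE), list(FS = 59.9, keep = TRUE)
  )
  for (cs in cases) {
    keep <- cs$keep
    cs$keep <- NULL
    v <- do.call(variant_row, cs)
    expect_equal(nrow(filter_het_snvs(v, ex)), as.integer(keep),
                 info = paste(names(cs), cs, collapse = "="))
  }
  # homozygous or non-exonic records drop regardless of quality
  expect_equal(nrow(filter_het_snvs(variant_row(is_het = FALSE), ex)), 0L)
  expect_equal(nrow(filter_het_snvs(variant_row(pos = 500L), ex)), 0L)
  # missing annotation drops with a message
  v_na <- variant_row()
  v_na$QD <- NA_real_
  expect_message(out <- filter_het_snvs(v_na, ex), "missing annotations")
  expect_equal(nrow(out), 0L)
})

test_that("RNA count and CPM filters use inclusive >= 10 and >= 1 bounds", {
  snvs <- tibble::tibble(gene_id = c("A", "A", "B", "C"),
                         ref_count = c(6L, 5L, 5L, 100L),
                         alt_count = c(4L, 4L, 4L, 100L))
  cpm <- tibble::tibble(gene_id = c("A", "B", "C"), cpm = c(2, 2, 0.5))
  out <- filter_rna_counts(snvs, cpm)
  expect_equal(nrow(out$snvs), 2L)           # 6+4 = 10 kept, 5+4 = 9 dropped
  g <- out$genes
  expect_true(g$testable[g$gene_id == "A"])
  expect_false(g$testable[g$gene_id == "B"])  # no SNV survives
  expect_false(g$testable[g$gene_id == "C"])  # CPM 0.5 < 1
})

test_that("gene aggregation phases by WGS frequency on unbalanced segments
           and by RNA counts on balanced ones", {
  tri <- tibble::tibble(ref_count = c(30L, 10L), alt_count = c(15L, 20L),
                        wgs_raf = c(0.67, 0.33))
  agg <- aggregate_gene_counts(tri, major = 2, minor = 1)
  expect_equal(agg$major_count, 50)
  expect_equal(agg$minor_count, 25)

  dis <- tibble::tibble(ref_count = 12L, alt_count = 8L, wgs_raf = 0.5)
  agg2 <- aggregate_gene_counts(dis, major = 1, minor = 1)
  expect_equal(c(agg2$major_count, agg2$minor_count), c(12, 8))

  tie <- tibble::tibble(ref_count = 10L, alt_count = 10L, wgs_raf = 0.5)
  agg3 <- aggregate_gene_counts(tie, major = 1, minor = 1)
  expect_equal(c(agg3$major_count, agg3$minor_count), c(10, 10))

  # uninformative WGS frequency on an unbalanced segment is excluded
  mix <- tibble::tibble(ref_count = c(30L, 9L), alt_count = c(15L, 9L),
                        wgs_raf = c(0.67, 0.5))
  agg4 <- aggregate_gene_counts(mix, major = 2, minor = 1)
  expect_equal(agg4$n_excluded, 1L)
  expect_equal(agg4$major_count, 30)

  # invariant to SNV input order
  set.seed(41)
  g <- tibble::tibble(ref_count = rpois(6, 40), alt_count = rpois(6, 20),
                      wgs_raf = rep(c(0.7, 0.3), 3))
  a <- aggregate_gene_counts(g, 2, 1)
  b <- aggregate_gene_counts(g[sample(6), ], 2, 1)
  expect_equal(a, b)
})

test_that("expected major fraction reflects gene dosage", {
  expect_equal(expected_major_fraction(1, 1), 0.5)
  expect_equal(expected_major_fraction(2, 1), 2 / 3)
  expect_equal(expected_major_fraction(3, 1), 0.75)
  expect_error(expected_major_fraction(0, 0), ">= 1")
})

test_that("exact binomial p-values match enumeration and are symmetric at
           p0 = 0.5", {
  expect_equal(binomial_ase_test(5, 10, 0.5), 1.0)
  expect_equal(binomial_ase_test(10, 10, 0.5), 2 * 0.5^10)
  expect_equal(binomial_ase_test(12, 12, 2 / 3),
               binom_enum_oracle(12, 12, 2 / 3), tolerance = 1e-12)
  for (n in c(7, 20, 33)) {
    for (k in 0:n) {
      expect_equal(binomial_ase_test(k, n, 0.5),
                   binomial_ase_test(n - k, n, 0.5))
    }
  }
  # cross-check against the stats package on a scattered grid
  set.seed(42)
  for (r in 1:50) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    p0 <- sample(c(0.5, 2 / 3, 0.75, 0.9), 1)
    expect_equal(binomial_ase_test(k, n, p0),
                 stats::binom.test(k, n, p0)$p.value, tolerance = 1e-9)
  }
  expect_error(binomial_ase_test(1, 0, 0.5), "positive")
  expect_error(binomial_ase_test(1, 2, 1), "strictly")
})

test_that("BH q-values equal the step-up definition and are permutation
           stable", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  set.seed(43)
  for (r in 1:25) {
    p <- runif(sample(5:80, 1))
    expect_equal(bh_fdr(p), bh_stepup_oracle(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
    # monotone in p after sorting
    q <- bh_fdr(p)[order(p)]
    expect_true(all(diff(q) >= -1e-12))
    expect_true(all(q >= 0 & q <= 1))
  }
})

test_that("the WGS/RNA odds ratio uses Haldane-Anscombe pseudocounts", {
  expect_equal(wgs_rna_odds_ratio(20, 10, 20, 10), 1.0)
  expect_equal(wgs_rna_odds_ratio(40, 10, 20, 10), 40.5 / 20.5)
  or0 <- wgs_rna_odds_ratio(10, 0, 10, 10)
  expect_true(is.finite(or0) && or0 > 1)
  expect_error(wgs_rna_odds_ratio(-1, 1, 1, 1), "non-negative")
})

test_that("gene classification separates CNV-driven from CNV-independent
           ASE", {
  gi <- dplyr::bind_rows(
    # trisomic gene expressed at its dosage ratio
    tibble::tibble(gene_id = "tri", chrom = "chr1", pos = 1L,
                   ref_count = 66L, alt_count = 34L, wgs_raf = 2 / 3,
                   wgs_ref_depth = 40L, wgs_alt_depth = 20L,
                   major = 2L, minor = 1L),
    # balanced gene, balanced expression
    tibble::tibble(gene_id = "bal", chrom = "chr2", pos = 1L,
                   ref_count = 50L, alt_count = 50L, wgs_raf = 0.5,
                   wgs_ref_depth = 20L, wgs_alt_depth = 20L,
                   major = 1L, minor = 1L),
    # balanced gene, strong mono-allelic expression
    tibble::tibble(gene_id = "ind", chrom = "chr3", pos = 1L,
                   ref_count = 95L, alt_count = 5L, wgs_raf = 0.5,
                   wgs_ref_depth = 20L, wgs_alt_depth = 20L,
                   major = 1L, minor = 1L),
    # LOH gene: no expected heterozygosity
    tibble::tibble(gene_id = "loh", chrom = "chr4", pos = 1L,
                   ref_count = 80L, alt_count = 0L, wgs_raf = 1,
                   wgs_ref_depth = 40L, wgs_alt_depth = 0L,
                   major = 2L, minor = 0L)
  )
  res <- tidy(call_ase(gi))
  expect_equal(res$ase_class[res$gene_id == "tri"], "CNV_DRIVEN_ASE")
  expect_equal(res$ase_class[res$gene_id == "bal"], "BALANCED")
  expect_equal(res$ase_class[res$gene_id == "ind"], "CNV_INDEPENDENT_ASE")
  expect_equal(res$ase_class[res$gene_id == "loh"], "NOT_TESTABLE")
  expect_equal(res$gene_id, sort(res$gene_id))
  # p-values and q-values in range; q monotone in p within each model
  ok <- !is.na(res$p_model1)
  expect_true(all(res$p_model1[ok] >= 0 & res$p_model1[ok] <= 1))
  expect_true(all(res$q_model1[ok] >= 0 & res$q_model1[ok] <= 1))
})

test_that("prepare_ase_input joins counts, segments and genes and flags
           untestable genes", {
  het <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L, 300L),
                        gene_id = c("A", "A", "B"),
                        wgs_raf = c(0.66, 0.34, 0.5),
                        ref_depth = c(26L, 14L, 20L),
                        alt_depth = c(14L, 26L, 20L))
  rna <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L, 300L),
                        ref_count = c(40L, 20L, 4L),
                        alt_count = c(20L, 40L, 3L))
  segs <- tibble::tibble(chrom = "chr1", start = 1, end = 1000,
                         major = 2L, minor = 1L)
  cpm <- tibble::tibble(gene_id = c("A", "B"), cpm = c(10, 10))
  inp <- prepare_ase_input(rna, het, segs, cpm)
  expect_equal(sort(unique(inp$gene_id)), "A")   # B has < 10 RNA reads
  expect_equal(nrow(inp), 2L)
  expect_equal(attr(inp, "untestable")$gene_id, "B")
  res <- tidy(call_ase(inp))
  expect_equal(res$major_count[res$gene_id == "A"], 80)
  expect_equal(res$minor_count[res$gene_id == "A"], 40)
})
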