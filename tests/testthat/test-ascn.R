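test_that("LRR is the base-2 log of the depth ratio", {
  expect_equal(compute_lrr(1, 1), 0)
  expect_equal(compute_lrr(2, 1), 1)
  expect_equal(compute_lrr(0.75, 1.5), -1)
  expect_error(compute_lrr(0, 1), "positive")
})

test_that("copy-number classes sit at midpoint boundaries and recentre with
           ploidy", {
  expect_equal(classify_cn(0, ploidy = 2), "2")
  expect_equal(classify_cn(log2(3 / 2), ploidy = 2), "3")
  expect_equal(classify_cn(-1, ploidy = 2), "1")
  expect_equal(classify_cn(1, ploidy = 2), "4")
  expect_equal(classify_cn(1.5, ploidy = 2), "AMP")
  # triploid baseline: LRR 0 means three copies
  expect_equal(classify_cn(0, ploidy = 3), "3")
  # monotone non-decreasing in mean_lrr for fixed ploidy
  grid <- seq(-2, 2, by = 0.01)
  cls <- match(classify_cn(grid, 2), c("1", "2", "3", "4", "AMP"))
  expect_true(all(diff(cls) >= 0))
})

test_that("per-SNV allelic imbalance is |RAF - 0.5|", {
  expect_equal(compute_ai_snp(0.5), 0)
  expect_equal(compute_ai_snp(1), 0.5)
  expect_equal(compute_ai_snp(2 / 3), 1 / 6)
  expect_error(compute_ai_snp(1.2), "0, 1")
})

test_that("segment AI statistics: two-point split is exact, degenerate and
           under-powered segments are handled", {
  cfg <- ascn_config()
  res <- compute_ai_seg(c(rep(0.05, 10), rep(0.20, 10)), cfg)
  expect_equal(res$af_h, 0.20)
  expect_equal(res$af_l, 0.05)
  expect_equal(res$ai_seg, 4.0)

  degen <- compute_ai_seg(rep(0.10, 20), cfg)
  expect_equal(degen$ai_seg, 1.0)
  expect_equal(degen$af_h, 0.10)

  expect_true(is.na(compute_ai_seg(rep(0.2, 19), cfg)$ai_seg))
})

test_that("k-means split equals the best contiguous 2-partition of sorted
           AI values for small segments", {
  set.seed(31)
  for (r in 1:40) {
    n <- sample(20:25, 1)
    x <- round(runif(n, 0, 0.5), 3)
    if (length(unique(x)) < 2) next
    got <- compute_ai_seg(x, ascn_config(seed = r))
    want <- contiguous_split_oracle(x)
    expect_equal(got$af_l, want$af_l, tolerance = 1e-12)
    expect_equal(got$af_h, want$af_h, tolerance = 1e-12)
    expect_gte(got$ai_seg, 1)
  }
})

test_that("asCN states follow the class mapping and the imbalance gate", {
  cfg <- ascn_config()
  expect_equal(unlist(estimate_ascn("3", 0.25, 2.5, cfg)), c(major = 2, minor = 1))
  expect_equal(unlist(estimate_ascn("3", NA, NA, cfg)), c(major = 2, minor = 1))
  # below the imbalance gate -> balanced disomy
  expect_equal(unlist(estimate_ascn("2", 0.05, 1.05, cfg)), c(major = 1, minor = 1))
  # strong uniform imbalance -> copy-neutral LOH
  expect_equal(unlist(estimate_ascn("2", 0.45, 8, cfg)), c(major = 2, minor = 0))
  # pure LOH: degenerate clusters at AI 0.5
  expect_equal(unlist(estimate_ascn("2", 0.5, 1.0, cfg)), c(major = 2, minor = 0))
  # noise-split disomy: gate passes but the nearest expected AI is 0
  expect_equal(unlist(estimate_ascn("2", 0.12, 3.5, cfg)), c(major = 1, minor = 1))
  expect_equal(unlist(estimate_ascn("1", 0.5, 1.0, cfg)), c(major = 1, minor = 0))
  expect_equal(unlist(estimate_ascn("4", 0.27, 1.4, cfg)), c(major = 3, minor = 1))
  expect_equal(unlist(estimate_ascn("4", 0.08, 3, cfg)), c(major = 2, minor = 2))
  # AMP: total sized from the LRR, minor by nearest expected AI
  amp <- estimate_ascn("AMP", 0.3, 2, cfg, mean_lrr = log2(6 / 2))
  expect_equal(amp$major + amp$minor, 6L)
  expect_equal(unlist(amp), c(major = 5, minor = 1))
})

test_that("call_ascn recovers a simple aneuploid genome and its invariants
           hold", {
  spec <- karyotype_spec(
    segments = tibble::tibble(
      chrom = sprintf("chr%02d", 1:6),
      start = 1, end = 5e6,
      major = c(1L, 1L, 1L, 1L, 2L, 2L),
      minor = c(1L, 1L, 1L, 1L, 1L, 0L)
    ),
    seed = 5
  )
  st <- simulate_study(spec, n_genes = 0)
  asc <- call_ascn(st$tumor$snvs, st$panel, ascn_config(seed = 5))
  segs <- tidy(asc)
  # every marker covered, invariants hold
  expect_equal(sum(segs$n_markers), nrow(asc$snvs))
  expect_true(all(segs$major >= segs$minor))
  expect_true(all(segs$minor >= 0))
  expect_true(all(segs$ai_seg >= 1, na.rm = TRUE))
  expect_true(all(segs$af_h >= segs$af_l, na.rm = TRUE))
  agree <- marker_state_agreement(asc, st$tumor$truth$phase)
  expect_gte(mean(agree$ok), 0.99)
  # trisomic chromosome called (2,1), CN-LOH called (2,0)
  expect_true(all(segs$major[segs$chrom == "chr05"] == 2 &
                    segs$minor[segs$chrom == "chr05"] == 1))
  expect_true(all(segs$major[segs$chrom == "chr06"] == 2 &
                    segs$minor[segs$chrom == "chr06"] == 0))
  # determinism
  asc2 <- call_ascn(st$tumor$snvs, st$panel, ascn_config(seed = 5))
  expect_identical(tidy(asc2), segs)
})

test_that("a 50/50 mix of a trisomic segment reads between the class-2 and
           class-3 centres", {
  spec <- karyotype_spec(
    segments = tibble::tibble(chrom = c("chr01", "chr02"), start = 1,
                              end = c(20e6, 5e6),
                              major = c(1L, 2L), minor = c(1L, 1L)),
    purity = 0.5, seed = 6
  )
  st <- simulate_study(spec, n_genes = 0)
  asc <- call_ascn(st$tumor$snvs, st$panel, ascn_config(seed = 6))
  segs <- tidy(asc)
  tri <- segs[segs$chrom == "chr02", ]
  lrr <- sum(tri$mean_lrr * tri$n_markers) / sum(tri$n_markers)
  expect_lt(abs(lrr - log2(2.5 / 2)), 0.1)
  expect_gt(lrr, 0)
  expect_lt(lrr, log2(3 / 2))
})

test_that("disjoint tumor/panel loci raise an error", {
  tum <- tibble::tibble(chrom = "chr1", pos = 1:20, ref_depth = 20L,
                        alt_depth = 20L, is_het = TRUE)
  pan <- tibble::tibble(chrom = "chr2", pos = 1:20, median_norm_depth = 1,
                        n_samples = 5L)
  expect_error(call_ascn(tum, pan), "no usable loci")
})

test_that("glance summarises marker-weighted genome fractions", {
  spec <- karyotype_spec(
    segments = tibble::tibble(chrom = c("chr01", "chr02"), start = 1, end = 5e6,
                              major = c(1L, 2L), minor = c(1L, 0L)),
    seed = 8
  )
  st <- simulate_study(spec, n_genes = 0)
  asc <- call_ascn(st$tumor$snvs, st$panel, ascn_config(seed = 8))
  g <- glance(asc)
  expect_equal(g$frac_diploid + g$frac_loh, 1, tolerance = 0.02)
  expect_equal(g$frac_loh, 0.5, tolerance = 0.05)
})
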