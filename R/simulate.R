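# Synthetic study generator: a diploid normal cohort for the reference
# panel, an aneuploid tumor with known segment karyotype and purity, and
# RNA-seq allele counts with known per-gene allelic effects. Depth noise is
# Poisson and allele splits are Binomial; read-level artefacts (sequencing
# error, mapping bias) are not modelled.

#' Describe a simulated tumor genome
#'
#' @param segments A data frame `chrom`, `start`, `end`, `major`, `minor`
#'   tiling each chromosome with non-overlapping segments
#'   (default [default_karyotype()]).
#' @param purity Tumor cell fraction in (0, 1]; the remaining cells are
#'   diploid `(1,1)` normal.
#' @param mean_depth Mean WGS depth of a diploid site, default 40.
#' @param n_snvs_per_mb SNV marker density, default 50.
#' @param het_fraction,hom_alt_fraction Germline genotype mix at marker
#'   sites (the remainder is homozygous reference), defaults 0.35 / 0.30.
#' @param seed Integer seed; child stages derive their own streams from it.
#' @return A list of class `karyotype_spec`.
#' @export
karyotype_spec <- function(segments = default_karyotype(), purity = 1,
                           mean_depth = 40, n_snvs_per_mb = 50,
                           het_fraction = 0.35, hom_alt_fraction = 0.30,
                           seed = 1L) {
  stopifnot(all(c("chrom", "start", "end", "major", "minor") %in%
                  names(segments)),
            purity > 0, purity <= 1, mean_depth > 0, n_snvs_per_mb > 0,
            het_fraction >= 0, hom_alt_fraction >= 0,
            het_fraction + hom_alt_fraction <= 1)
  segments <- arrange(as_tibble(segments), .data$chrom, .data$start)
  bad <- segments |>
    group_by(.data$chrom) |>
    summarise(ov = any(head(.data$end, -1) >= tail(.data$start, -1)))
  if (any(bad$ov)) abort("karyotype segments overlap within a chromosome.")
  if (any(segments$minor > segments$major) || any(segments$minor < 0) ||
      any(segments$major < 1)) {
    abort("each segment needs major >= max(minor, 1) and minor >= 0.")
  }
  structure(list(segments = segments, purity = purity,
                 mean_depth = mean_depth, n_snvs_per_mb = n_snvs_per_mb,
                 het_fraction = het_fraction,
                 hom_alt_fraction = hom_alt_fraction,
                 seed = as.integer(seed)),
            class = "karyotype_spec")
}

#' Default simulated karyotype
#'
#' Eighteen 10-Mb chromosomes: fourteen disomic, one with a focal trisomic
#' segment, one whole-chromosome trisomy `(2,1)`, one copy-neutral LOH
#' chromosome `(2,0)` and one 3:1 tetrasomy `(3,1)` -- a mostly diploid
#' genome (marker-weighted mean copy number ~2.2) so that the sample-mean
#' depth normalisation leaves the diploid baseline near LRR 0.
#'
#' @return A segment tibble suitable for [karyotype_spec()].
#' @export
default_karyotype <- function() {
  len <- 10e6
  disomic <- map(1:14, function(i) {
    tibble(chrom = sprintf("chr%02d", i), start = 1, end = len,
           major = 1L, minor = 1L)
  }) |> list_rbind()
  focal <- tibble(chrom = "chr15",
                  start = c(1, 4e6 + 1, 7e6 + 1),
                  end = c(4e6, 7e6, len),
                  major = c(1L, 2L, 1L), minor = c(1L, 1L, 1L))
  whole <- tibble(chrom = c("chr16", "chr17", "chr18"),
                  start = 1, end = len,
                  major = c(2L, 2L, 3L), minor = c(1L, 0L, 1L))
  bind_rows(disomic, focal, whole)
}

# marker sites for a karyotype: uniform positions at the requested density
sim_sites <- function(spec) {
  local_seed(spec$seed + 101L, {
    spec$segments |>
      summarise(len = max(.data$end), .by = "chrom") |>
      pmap(function(chrom, len) {
        n <- max(2L, round(len / 1e6 * spec$n_snvs_per_mb))
        tibble(chrom = chrom, pos = sort(sample.int(len, n)))
      }) |>
      list_rbind()
  })
}

#' Simulate a diploid normal cohort for the reference panel
#'
#' Every sample is diploid at every site; per-site depths are
#' `Poisson(mean_depth)`. At high depth the resulting panel medians
#' concentrate at 1.0.
#'
#' @param sites A data frame `chrom`, `pos` of marker sites (e.g. from a
#'   [karyotype_spec()] via [simulate_study()]); or `NULL` to generate
#'   `n_sites` sites on one synthetic chromosome.
#' @param n_samples Cohort size, default 20.
#' @param mean_depth Mean depth, default 30.
#' @param n_sites Used only when `sites` is `NULL`, default 1000.
#' @param seed Integer seed.
#' @return A named list of per-sample depth tibbles (`chrom`, `pos`,
#'   `depth`).
#' @export
simulate_panel <- function(sites = NULL, n_samples = 20, mean_depth = 30,
                           n_sites = 1000, seed = 1L) {
  stopifnot(n_samples >= 1, mean_depth >= 1)
  if (is.null(sites)) {
    sites <- local_seed(seed + 7L,
                        tibble(chrom = "chr01",
                               pos = sort(sample.int(100e6, n_sites))))
  }
  local_seed(seed + 211L, {
    out <- map(seq_len(n_samples), function(i) {
      tibble(chrom = sites$chrom, pos = sites$pos,
             depth = rpois(nrow(sites), mean_depth))
    })
  })
  setNames(out, sprintf("N%03d", seq_len(n_samples)))
}

#' Simulate tumor WGS allele depths under a karyotype
#'
#' Each marker site receives a germline genotype (het / hom-alt / hom-ref at
#' the spec's mix), a total depth
#' `Poisson(mean_depth * (purity * (M + m) + (1 - purity) * 2) / 2)`, and --
#' for heterozygous sites -- a reference-allele count
#' `Binomial(depth, f)` with
#' `f = (purity * c_ref + (1 - purity)) / (purity * (M + m) + (1 - purity) * 2)`,
#' where `c_ref` is `M` or `m` according to a random per-site phase. The
#' emitted `is_het` flag is the germline truth (heterozygosity assumed known
#' to the caller even where the tumor has lost one allele). GATK-style
#' quality annotations consistent with clean calls are attached so the
#' records pass the het-SNV filters.
#'
#' @param spec A [karyotype_spec()].
#' @param sites Optional marker sites (`chrom`, `pos`); generated from the
#'   spec by default.
#' @return A list with `snvs` (tumor SNV tibble: `chrom`, `pos`,
#'   `ref_depth`, `alt_depth`, `is_het`, annotations) and `truth` (`segments`
#'   plus the per-site tibble `phase` with the germline genotype, the
#'   `(major, minor)` state and `ref_is_major`).
#' @export
simulate_tumor_wgs <- function(spec, sites = NULL) {
  stopifnot(inherits(spec, "karyotype_spec"))
  if (is.null(sites)) sites <- sim_sites(spec)
  seg <- spec$segments
  q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  s <- GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(seg$start, seg$end))
  hit <- GenomicRanges::findOverlaps(q, s, select = "first")
  if (anyNA(hit)) abort("karyotype segments do not cover all marker sites.")
  M <- seg$major[hit]
  m <- seg$minor[hit]
  p <- spec$purity

  local_seed(spec$seed + 307L, {
    n <- nrow(sites)
    u <- runif(n)
    geno <- ifelse(u < spec$het_fraction, "het",
                   ifelse(u < spec$het_fraction + spec$hom_alt_fraction,
                          "hom_alt", "hom_ref"))
    tumor_total <- p * (M + m) + (1 - p) * 2
    depth <- rpois(n, spec$mean_depth * tumor_total / 2)
    ref_is_major <- runif(n) < 0.5
    c_ref <- ifelse(ref_is_major, M, m)
    f_het <- (p * c_ref + (1 - p)) / tumor_total
    ref_depth <- integer(n)
    ref_depth[geno == "het"] <- rbinom(sum(geno == "het"),
                                       depth[geno == "het"],
                                       f_het[geno == "het"])
    ref_depth[geno == "hom_ref"] <- depth[geno == "hom_ref"]
    # hom_alt stays 0
    fs <- runif(n, 0, 5)
    qd <- runif(n, 15, 30)
  })

  snvs <- tibble(
    chrom = sites$chrom, pos = sites$pos,
    ref_depth = as.integer(ref_depth),
    alt_depth = as.integer(depth - ref_depth),
    is_het = geno == "het",
    DP = as.integer(depth), QD = qd, MQ = 60, MQRankSum = 0,
    ReadPosRankSum = 0, FS = fs
  )
  phase <- tibble(chrom = sites$chrom, pos = sites$pos, genotype = geno,
                  major = M, minor = m, ref_is_major = ref_is_major)
  list(snvs = snvs, truth = list(segments = seg, phase = phase))
}

#' Simulate gene models and RNA-seq allele counts with known ASE truth
#'
#' Genes are laid over the tumor's heterozygous marker sites (one to a few
#' consecutive het SNVs per gene, each wrapped in a small exon). By default
#' every gene expresses its haplotypes at the segment's dosage ratio
#' (`major / (major + minor)`), so genes on unbalanced segments are truly
#' CNV-driven ASE and disomic genes are balanced; a fraction of disomic
#' genes can be given an injected, CNV-independent allelic effect. Per-SNV
#' totals are `Poisson(rna_depth)` and major-haplotype reads are
#' `Binomial(total, f_true)`, phased consistently with the WGS truth.
#'
#' @param tumor Output of [simulate_tumor_wgs()].
#' @param n_genes Number of genes, default 200.
#' @param rna_depth Mean RNA reads per SNV, default 80.
#' @param prop_independent Fraction of balanced-segment genes given an
#'   injected allelic effect, default 0.1.
#' @param f_independent The injected major-haplotype fraction, default 0.9.
#' @param mean_snvs_per_gene Mean number of het SNVs beyond the first,
#'   default 1.2 (gene SNV counts are `1 + Poisson(mean_snvs_per_gene)`).
#' @param seed Integer seed; defaults to the tumor spec's stream.
#' @return A list with `counts` (RNA allele counts: `chrom`, `pos`,
#'   `ref_count`, `alt_count`), `exons` (gene exon intervals), `cpm`
#'   (gene expression), and `truth` (per gene: segment state, `f_true`,
#'   `ase_label`).
#' @export
simulate_rna_counts <- function(tumor, n_genes = 200, rna_depth = 80,
                                prop_independent = 0.1, f_independent = 0.9,
                                mean_snvs_per_gene = 1.2, seed = 1L) {
  phase <- tumor$truth$phase
  hets <- filter(phase, .data$genotype == "het") |>
    arrange(.data$chrom, .data$pos)
  if (n_genes == 0) {
    empty_truth <- tibble(gene_id = character(0), chrom = character(0),
                          major = integer(0), minor = integer(0),
                          n_snvs = integer(0), f_true = double(0),
                          cpm = double(0), ase_label = character(0))
    return(list(counts = tibble(chrom = character(0), pos = integer(0),
                                ref_count = integer(0), alt_count = integer(0)),
                exons = tibble(chrom = character(0), start = double(0),
                               end = double(0), gene_id = character(0)),
                cpm = empty_truth[c("gene_id", "cpm")], truth = empty_truth))
  }

  local_seed(seed + 401L, {
    sizes <- 1L + rpois(n_genes, mean_snvs_per_gene)
    # walk consecutive het sites chromosome by chromosome
    hets <- mutate(hets, used = FALSE)
    idx_by_chrom <- split(seq_len(nrow(hets)), hets$chrom)
    cursors <- lapply(idx_by_chrom, function(ix) ix)
    chroms <- rep(names(idx_by_chrom), length.out = n_genes)
    genes <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      ch <- chroms[[g]]
      avail <- cursors[[ch]]
      if (length(avail) < sizes[g]) next
      take <- avail[seq_len(sizes[g])]
      # skip genes whose SNVs straddle two different states
      if (length(unique(hets$major[take])) > 1 ||
          length(unique(hets$minor[take])) > 1) {
        cursors[[ch]] <- avail[-seq_len(sizes[g])]
        next
      }
      cursors[[ch]] <- avail[-seq_len(sizes[g])]
      genes[[g]] <- tibble(gene_id = sprintf("G%04d", g),
                           row = take)
    }
    genes <- list_rbind(genes[!vapply(genes, is.null, logical(1))])
    gene_snvs <- bind_cols(genes["gene_id"], hets[genes$row, ])

    truth <- gene_snvs |>
      summarise(chrom = first(.data$chrom), major = first(.data$major),
                minor = first(.data$minor), n_snvs = n(),
                .by = "gene_id")
    balanced <- truth$major == truth$minor
    inject <- balanced & runif(nrow(truth)) < prop_independent
    truth$f_true <- ifelse(inject, f_independent,
                           truth$major / (truth$major + truth$minor))
    truth$cpm <- 2^rnorm(nrow(truth), mean = 4, sd = 2)
    truth$ase_label <- case_when(
      truth$cpm < 1 ~ "NOT_TESTABLE",
      truth$minor == 0 ~ "NOT_TESTABLE",
      inject ~ "CNV_INDEPENDENT_ASE",
      truth$major != truth$minor ~ "CNV_DRIVEN_ASE",
      TRUE ~ "BALANCED"
    )

    gene_snvs <- left_join(gene_snvs,
                           truth[c("gene_id", "f_true")], by = "gene_id")
    # hap A is the overexpressed haplotype; on unbalanced segments it is the
    # major haplotype, so the WGS phase dictates which allele it carries
    ref_on_hapA <- ifelse(gene_snvs$major != gene_snvs$minor,
                          gene_snvs$ref_is_major,
                          runif(nrow(gene_snvs)) < 0.5)
    total <- rpois(nrow(gene_snvs), rna_depth)
    hapA <- rbinom(nrow(gene_snvs), total, gene_snvs$f_true)
    ref_count <- ifelse(ref_on_hapA, hapA, total - hapA)
  })

  counts <- tibble(chrom = gene_snvs$chrom, pos = gene_snvs$pos,
                   ref_count = as.integer(ref_count),
                   alt_count = as.integer(total - ref_count))
  exons <- gene_snvs |>
    transmute(chrom = .data$chrom, start = pmax(1, .data$pos - 50),
              end = .data$pos + 50, gene_id = .data$gene_id)
  list(counts = counts, exons = exons,
       cpm = truth[c("gene_id", "cpm")], truth = truth)
}

#' Simulate a complete study: panel cohort, tumor WGS and RNA counts
#'
#' Convenience wrapper wiring [simulate_panel()], [simulate_tumor_wgs()] and
#' [simulate_rna_counts()] to shared marker sites, plus the built panel.
#'
#' @param spec A [karyotype_spec()].
#' @param n_panel Panel cohort size, default 20.
#' @param panel_depth Panel mean depth, default 30.
#' @param n_genes,rna_depth,prop_independent,f_independent Passed to
#'   [simulate_rna_counts()].
#' @return A list: `sites`, `panel_samples`, `panel`, `tumor`, `rna`.
#' @export
simulate_study <- function(spec = karyotype_spec(), n_panel = 20,
                           panel_depth = 30, n_genes = 200, rna_depth = 80,
                           prop_independent = 0.1, f_independent = 0.9) {
  sites <- sim_sites(spec)
  panel_samples <- simulate_panel(sites, n_samples = n_panel,
                                  mean_depth = panel_depth,
                                  seed = spec$seed)
  panel <- build_panel(imap(panel_samples, function(d, id) {
    normalize_depths(d, sex = "female", sample_id = id)
  }))
  tumor <- simulate_tumor_wgs(spec, sites)
  rna <- simulate_rna_counts(tumor, n_genes = n_genes, rna_depth = rna_depth,
                             prop_independent = prop_independent,
                             f_independent = f_independent,
                             seed = spec$seed)
  list(sites = sites, panel_samples = panel_samples, panel = panel,
       tumor = tumor, rna = rna)
}
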