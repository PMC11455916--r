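# Readers and writers for the formats the pipeline touches. All writers are
# deterministic: fixed column order, tabs, "." for missing, %.6g floats.

fmt_cell <- function(x) {
  if (is.double(x)) {
    out <- ifelse(is.na(x), ".", sprintf("%.6g", x))
  } else {
    out <- ifelse(is.na(x), ".", as.character(x))
  }
  out
}

write_tsv_dot <- function(df, path) {
  cols <- map(df, fmt_cell)
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read tumor SNV observations from a VCF
#'
#' Parses a VCF 4.x file (first sample column), keeping biallelic SNVs only;
#' multiallelic and indel records are skipped and counted. Depths come from
#' the `AD` field (falling back to `DP` split by genotype is not attempted:
#' `AD` is required), heterozygosity from `GT`, and the quality annotations
#' `QD`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `FS` from `INFO` when present.
#' Positions stay 1-based.
#'
#' @param path Path to a VCF (optionally bgzip/gzip compressed).
#' @return A tibble `chrom`, `pos`, `ref_depth`, `alt_depth`, `is_het`,
#'   `DP`, `QD`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `FS`; the numbers of
#'   skipped multiallelic/indel records are in attributes
#'   `n_multiallelic` and `n_indel`.
#' @export
read_vcf_sites <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(0), pos = integer(0),
                  ref_depth = integer(0), alt_depth = integer(0),
                  is_het = logical(0), DP = integer(0), QD = double(0),
                  MQ = double(0), MQRankSum = double(0),
                  ReadPosRankSum = double(0), FS = double(0)))
  }
  multi <- grepl(",", fix$ALT %||% "")
  snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  keep <- !multi & snv
  n_multiallelic <- sum(multi)
  n_indel <- sum(!snv & !multi)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, 1]
  ad <- vcfR::extract.gt(v, element = "AD")[keep, 1]
  if (all(is.na(ad))) abort("VCF lacks per-sample AD depths.")
  ad_split <- stringr::str_split_fixed(ad, ",", 2)
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key)[keep]
    suppressWarnings(as.numeric(x))
  }
  out <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref_depth = suppressWarnings(as.integer(ad_split[, 1])),
    alt_depth = suppressWarnings(as.integer(ad_split[, 2])),
    is_het = gt %in% c("0/1", "1/0", "0|1", "1|0"),
    QD = info_num("QD"), MQ = info_num("MQ"),
    MQRankSum = info_num("MQRankSum"),
    ReadPosRankSum = info_num("ReadPosRankSum"), FS = info_num("FS")
  )
  dp <- info_num("DP")
  out$DP <- ifelse(is.na(dp), out$ref_depth + out$alt_depth, as.integer(dp))
  out <- relocate(out, "DP", .after = "is_het")
  attr(out, "n_multiallelic") <- n_multiallelic
  attr(out, "n_indel") <- n_indel
  out
}

#' Read an ASEReadCounter-style RNA allele-count table
#'
#' Requires the columns `contig`, `position`, `refAllele`, `altAllele`,
#' `refCount`, `altCount`, `totalCount`. Rows whose `totalCount` differs
#' from `refCount + altCount` by more than the `otherBases` column (when
#' present) draw a warning and are kept using `refCount + altCount`.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble `chrom`, `pos`, `ref_allele`, `alt_allele`,
#'   `ref_count`, `alt_count`.
#' @export
read_ase_counts <- function(path) {
  if (!file.exists(path)) abort(paste0("counts file not found: ", path))
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mandatory <- c("contig", "position", "refAllele", "altAllele",
                 "refCount", "altCount", "totalCount")
  miss <- setdiff(mandatory, names(d))
  if (length(miss)) {
    abort(paste0("missing mandatory column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(d) == 0) {
    return(tibble(chrom = character(0), pos = integer(0),
                  ref_allele = character(0), alt_allele = character(0),
                  ref_count = integer(0), alt_count = integer(0)))
  }
  other <- if ("otherBases" %in% names(d)) d$otherBases else 0
  slack <- abs(d$totalCount - d$refCount - d$altCount) > other
  if (any(slack)) {
    warn(paste0(sum(slack), " row(s) with totalCount != refCount + altCount",
                " beyond otherBases; using refCount + altCount."))
  }
  tibble(chrom = as.character(d$contig), pos = as.integer(d$position),
         ref_allele = d$refAllele, alt_allele = d$altAllele,
         ref_count = as.integer(d$refCount),
         alt_count = as.integer(d$altCount))
}

#' Write / read a segment table
#'
#' Tab-separated with columns `chrom`, `start`, `end`, `n_markers`,
#' `mean_lrr`, `cn_class`, `af_h`, `af_l`, `ai_seg`, `n_het`, `major`,
#' `minor`; coordinates 1-based inclusive, missing values written as `.`.
#'
#' @param segments A segment tibble (e.g. `tidy()` of an `ascn_call`).
#' @param path File path (`.gz` for gzip).
#' @return `write_segments()` returns `path` invisibly; `read_segments()`
#'   the segment tibble.
#' @export
write_segments <- function(segments, path) {
  cols <- c("chrom", "start", "end", "n_markers", "mean_lrr", "cn_class",
            "af_h", "af_l", "ai_seg", "n_het", "major", "minor")
  stopifnot(all(cols %in% names(segments)))
  if (any(segments$start > segments$end) || any(segments$start < 1)) {
    abort("segment coordinates must satisfy 1 <= start <= end.")
  }
  write_tsv_dot(as_tibble(segments)[cols], path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  d <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         start = readr::col_double(),
                         end = readr::col_double(),
                         n_markers = readr::col_integer(),
                         mean_lrr = readr::col_double(),
                         cn_class = readr::col_character(),
                         af_h = readr::col_double(),
                         af_l = readr::col_double(),
                         ai_seg = readr::col_double(),
                         n_het = readr::col_integer(),
                         major = readr::col_integer(),
                         minor = readr::col_integer()))
  if (any(d$start > d$end) || any(d$start < 1)) {
    abort("segment coordinates must satisfy 1 <= start <= end.")
  }
  d
}

#' Export segments as BED
#'
#' BED uses 0-based half-open coordinates; the internal 1-based inclusive
#' `start` is shifted down by one. The name field carries the asCN state.
#'
#' @param segments A segment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  lines <- sprintf("%s\t%d\t%d\t%d,%d\t%s\t.",
                   segments$chrom, as.integer(segments$start) - 1L,
                   as.integer(segments$end), segments$major, segments$minor,
                   fmt_cell(segments$mean_lrr))
  writeLines(lines, path)
  invisible(path)
}

#' Write per-gene ASE results
#'
#' @param ase An `ase_call` object or its `tidy()` tibble.
#' @param path Output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_gene_results <- function(ase, path) {
  d <- if (inherits(ase, "ase_call")) ase$genes else as_tibble(ase)
  write_tsv_dot(d, path)
}

#' Read gene models from a BED file
#'
#' BED12 records yield one exon interval per block; BED6 (or narrower)
#' records yield a single interval covering the record. Coordinates are
#' converted to 1-based inclusive. Overlapping blocks within one record are
#' rejected.
#'
#' @param path Path to a BED file.
#' @return An exon tibble `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED not found: ", path))
  g <- rtracklayer::import(path, format = "BED")
  ids <- if (!is.null(g$name)) g$name else sprintf("gene%05d", seq_along(g))
  if (!is.null(g$blocks)) {
    per_rec <- map(seq_along(g), function(i) {
      bl <- IRanges::shift(g$blocks[[i]], GenomicRanges::start(g)[i] - 1L)
      red <- IRanges::reduce(bl)
      if (length(red) != length(bl)) {
        abort(paste0("overlapping BED blocks in record ", ids[i]))
      }
      tibble(chrom = as.character(GenomicRanges::seqnames(g))[i],
             start = IRanges::start(bl), end = IRanges::end(bl),
             gene_id = ids[i])
    })
    list_rbind(per_rec)
  } else {
    tibble(chrom = as.character(GenomicRanges::seqnames(g)),
           start = GenomicRanges::start(g), end = GenomicRanges::end(g),
           gene_id = ids)
  }
}

#' Write exon intervals as BED6
#'
#' @param exons An exon tibble `chrom`, `start`, `end`, `gene_id`
#'   (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(exons, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t+", exons$chrom,
                   as.integer(exons$start) - 1L, as.integer(exons$end),
                   exons$gene_id)
  writeLines(lines, path)
  invisible(path)
}
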