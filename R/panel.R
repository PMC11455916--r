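#' Normalize a sample's per-site sequencing depths
#'
#' Converts raw per-SNV-site read depths into depths relative to the sample
#' mean, the unit in which the copy-number reference panel and the tumor log R
#' ratios are expressed. Sites with raw depth at or below `min_depth` are
#' dropped first (strictly "over" the threshold is required), the mean is
#' taken over the retained sites, and for male samples the normalized X and Y
#' values are doubled so that one X/Y copy reads as the diploid baseline.
#' Y-chromosome sites of female samples are dropped.
#'
#' @param depths A data frame with columns `chrom`, `pos` (1-based) and
#'   `depth` (raw reads). `(chrom, pos)` must be unique.
#' @param sex `"female"`, `"male"` or `"unknown"`. Required (i.e. must not be
#'   `"unknown"`) when X or Y sites are present.
#' @param min_depth Strict lower depth bound; default 10.
#' @param sample_id Optional label used in error messages and carried in the
#'   output.
#'
#' @return A tibble with columns `chrom`, `pos`, `norm_depth` (and
#'   `sample_id` if given), sorted by chromosome then position.
#' @export
#' @examples
#' d <- tibble::tibble(chrom = "chr1", pos = 1:3, depth = c(20, 40, 60))
#' normalize_depths(d, sex = "female")
normalize_depths <- function(depths, sex = c("unknown", "female", "male"),
                             min_depth = 10, sample_id = NULL) {
  sex <- match.arg(sex)
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depths)))
  if (nrow(depths) == 0) abort("empty depth table.")
  if (anyDuplicated(depths[c("chrom", "pos")])) {
    abort("duplicated (chrom, pos) in depth table.")
  }
  if (any(depths$pos < 1) || any(depths$depth < 0)) {
    abort("pos must be >= 1 and depth >= 0.")
  }
  d <- as_tibble(depths)
  is_x <- chrom_is(d$chrom, "X")
  is_y <- chrom_is(d$chrom, "Y")
  if (any(is_x | is_y) && sex == "unknown") {
    abort(paste0("sex is required for X/Y sites",
                 if (!is.null(sample_id)) paste0(" (sample ", sample_id, ")")))
  }
  if (sex == "female") {
    d <- d[!is_y, , drop = FALSE]
    is_x <- chrom_is(d$chrom, "X")
    is_y <- rep(FALSE, nrow(d))
  }
  d <- filter(d, .data$depth > min_depth)
  if (nrow(d) == 0) abort("no sites retained after depth filtering.")
  mean_depth <- mean(d$depth)
  d$norm_depth <- d$depth / mean_depth
  if (sex == "male") {
    sexchrom <- chrom_is(d$chrom, "X") | chrom_is(d$chrom, "Y")
    d$norm_depth[sexchrom] <- 2 * d$norm_depth[sexchrom]
  }
  out <- select(d, "chrom", "pos", "norm_depth")
  if (!is.null(sample_id)) out <- mutate(out, sample_id = sample_id, .before = 1)
  arrange(out, .data$chrom, .data$pos)
}

chrom_is <- function(chrom, which) {
  sub("^chr", "", chrom) == which
}

#' Build the copy-number reference panel
#'
#' Collapses normalized depth tables from a cohort of normal samples into one
#' baseline value per SNV site: the median of the normalized depths across the
#' samples covering that site. An even number of contributing samples yields
#' the mean of the two central values (the usual sample median).
#'
#' @param samples A list of tibbles as returned by [normalize_depths()], or a
#'   single long tibble with columns `sample_id`, `chrom`, `pos`,
#'   `norm_depth`.
#' @param min_samples Minimum number of samples that must cover a site for it
#'   to enter the panel; default 1.
#'
#' @return A tibble with columns `chrom`, `pos`, `median_norm_depth`,
#'   `n_samples`, sorted by chromosome then position.
#' @export
#' @examples
#' s1 <- tibble::tibble(chrom = "chr1", pos = 1:2, norm_depth = c(0.8, 1.0))
#' s2 <- tibble::tibble(chrom = "chr1", pos = 1:2, norm_depth = c(1.2, 1.0))
#' build_panel(list(s1, s2))
build_panel <- function(samples, min_samples = 1) {
  if (is.data.frame(samples)) {
    long <- as_tibble(samples)
    stopifnot(all(c("chrom", "pos", "norm_depth") %in% names(long)))
  } else {
    if (length(samples) == 0) abort("panel requires at least one sample.")
    long <- list_rbind(map(samples, function(s) {
      stopifnot(all(c("chrom", "pos", "norm_depth") %in% names(s)))
      as_tibble(s)[c("chrom", "pos", "norm_depth")]
    }))
  }
  if (nrow(long) == 0) abort("panel requires at least one sample.")
  long |>
    summarise(median_norm_depth = median(.data$norm_depth),
              n_samples = n(),
              .by = c("chrom", "pos")) |>
    filter(.data$n_samples >= min_samples) |>
    arrange(.data$chrom, .data$pos)
}

#' Write / read a reference panel
#'
#' The panel is persisted as a tab-separated table (`chrom`, `pos`,
#' `median_norm_depth`, `n_samples`) with a single `#` header line carrying
#' the genome-build label. A `.gz` extension triggers gzip compression.
#'
#' @param panel A panel tibble from [build_panel()].
#' @param path Output (or input) file path; gzip is autodetected from a
#'   `.gz` suffix.
#' @param genome_build Label recorded in the header line.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` returns
#'   the panel tibble with the genome build in attribute `genome_build`.
#' @export
write_panel <- function(panel, path, genome_build = "unspecified") {
  stopifnot(all(c("chrom", "pos", "median_norm_depth", "n_samples") %in%
                  names(panel)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# genome_build=", genome_build), con)
  writeLines(paste(c("chrom", "pos", "median_norm_depth", "n_samples"),
                   collapse = "\t"), con)
  body <- sprintf("%s\t%d\t%.6g\t%d", panel$chrom, as.integer(panel$pos),
                  panel$median_norm_depth, as.integer(panel$n_samples))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("panel file not found: ", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  first <- readLines(con, n = 1)
  close(con)
  build <- if (startsWith(first, "# genome_build=")) {
    sub("^# genome_build=", "", first)
  } else {
    "unspecified"
  }
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           pos = readr::col_integer(),
                           median_norm_depth = readr::col_double(),
                           n_samples = readr::col_integer()))
  attr(out, "genome_build") <- build
  out
}
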