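#' Log R ratio of tumor over panel depth
#'
#' The per-locus copy-number signal: the base-2 log ratio of the tumor's
#' normalized depth to the reference-panel median normalized depth at the
#' same site.
#'
#' @param tumor_norm_depth Tumor normalized depth(s) (> 0).
#' @param panel_norm_depth Panel median normalized depth(s) (> 0).
#' @return Numeric vector of LRR values.
#' @export
#' @examples
#' compute_lrr(2, 1)    # one extra copy's worth of depth -> 1
#' compute_lrr(0.75, 1.5)
compute_lrr <- function(tumor_norm_depth, panel_norm_depth) {
  if (any(tumor_norm_depth <= 0) || any(panel_norm_depth <= 0)) {
    abort("normalized depths must be positive.")
  }
  log2(tumor_norm_depth / panel_norm_depth)
}

#' Copy-number class of a segment mean LRR
#'
#' Assigns one of five classes -- 1 copy (hemizygous deletion), 2 (wild
#' type), 3, 4, or `AMP` (>= 5 copies, high amplification). The expected LRR
#' of `c` total copies is `log2(c / ploidy)`; a segment takes the class whose
#' expected LRR is nearest, with boundaries at the midpoints between adjacent
#' class centres. Everything at or beyond the 4/5 midpoint is `AMP`.
#'
#' @param mean_lrr Segment mean LRR (finite; vectorized).
#' @param ploidy Baseline total copy number (default 2).
#' @return Character vector over `"1"`, `"2"`, `"3"`, `"4"`, `"AMP"`.
#' @export
#' @examples
#' classify_cn(c(0, 0.585, -1), ploidy = 2)
classify_cn <- function(mean_lrr, ploidy = 2) {
  if (!all(is.finite(mean_lrr))) abort("mean_lrr must be finite.")
  stopifnot(ploidy >= 1)
  centers <- log2((1:5) / ploidy)
  mids <- (head(centers, -1) + tail(centers, -1)) / 2
  cls <- 1L + findInterval(mean_lrr, mids)
  c("1", "2", "3", "4", "AMP")[cls]
}

#' Per-SNV allelic imbalance
#'
#' `AI_snp = |RAF - 0.5|`, where RAF is the reference-allele read fraction.
#'
#' @param raf Reference allele frequency in `[0, 1]` (vectorized).
#' @return Values in `[0, 0.5]`.
#' @export
compute_ai_snp <- function(raf) {
  if (any(raf < 0 | raf > 1, na.rm = TRUE)) abort("raf must lie in [0, 1].")
  abs(raf - 0.5)
}

#' Segment allelic-imbalance statistics
#'
#' Splits the heterozygous-SNV AI values of a segment into two groups by
#' 1-D k-means (squared Euclidean distance, `k = 2`; ten seeded random
#' restarts plus deterministic starts at the data range and quartiles, best
#' inertia kept) and
#' reports the higher and lower cluster means (`AF_h`, `AF_L`) and their
#' ratio `AI_seg = AF_h / AF_L`. With fewer than `config$ai_min_het` values
#' all three are `NA` (the segment falls back to its balanced state). If all
#' values are identical the clusters degenerate: `AF_h = AF_L` and
#' `AI_seg = 1`. `AF_L` is floored at `config$ai_epsilon` before division.
#'
#' @param het_ais Numeric vector of AI values (from [compute_ai_snp()]) of
#'   the segment's heterozygous SNVs.
#' @param config An [ascn_config()].
#' @return A one-row tibble with columns `af_h`, `af_l`, `ai_seg`.
#' @export
#' @examples
#' compute_ai_seg(c(rep(0.05, 10), rep(0.20, 10)), ascn_config())
compute_ai_seg <- function(het_ais, config = ascn_config()) {
  if (length(het_ais) < config$ai_min_het) {
    return(tibble(af_h = NA_real_, af_l = NA_real_, ai_seg = NA_real_))
  }
  if (length(unique(het_ais)) < 2) {
    v <- het_ais[1]
    return(tibble(af_h = v, af_l = v, ai_seg = 1.0))
  }
  km <- local_seed(config$seed, {
    fits <- list(kmeans(het_ais, centers = 2, nstart = 10))
    # deterministic starts guard against unlucky random initialisations
    for (cen in list(range(het_ais),
                     stats::quantile(het_ais, c(0.25, 0.75), names = FALSE))) {
      if (cen[1] < cen[2]) {
        fits <- c(fits, list(kmeans(het_ais, centers = matrix(cen))))
      }
    }
    fits[[which.min(vapply(fits, function(f) f$tot.withinss, 0))]]
  })
  m <- sort(as.numeric(km$centers))
  af_l <- m[1]
  af_h <- m[2]
  ai_seg <- if (af_h == af_l) 1.0 else af_h / max(af_l, config$ai_epsilon)
  tibble(af_h = af_h, af_l = af_l, ai_seg = ai_seg)
}

#' Integer allele-specific copy-number state of a segment
#'
#' Combines the copy-number class with the segment allelic-imbalance
#' statistics into an integer `(major, minor)` state. A segment is eligible
#' for an imbalanced state only if `AF_h >= ai_min_af_h` and either
#' `AI_seg >= ai_imbalance_threshold` or the implied lower cluster mean
#' (`AF_h / AI_seg`) is itself `>= ai_min_af_h` (a uniformly skewed segment,
#' the signature of LOH at high purity). Among the class's candidate states
#' the one whose expected AI -- `M / (M + m) - 0.5` -- is nearest to `AF_h`
#' is chosen; ties go to the more balanced state. When `AI_seg` is undefined
#' the balanced default of the class is returned.
#'
#' Candidate states: class 1 `(1,0)`; class 2 `(1,1)`/`(2,0)`; class 3
#' `(2,1)` (a trisomy has no balanced split); class 4 `(2,2)`/`(3,1)`/`(4,0)`;
#' `AMP` all splits of the total copy number implied by `mean_lrr`
#' (at least 5).
#'
#' @param cn_class `"1"`, `"2"`, `"3"`, `"4"` or `"AMP"`.
#' @param af_h,ai_seg Segment AI statistics from [compute_ai_seg()] (may be
#'   `NA`).
#' @param config An [ascn_config()].
#' @param mean_lrr Segment mean LRR; used only to size the total copy number
#'   of `AMP` segments.
#' @return A one-row tibble with integer columns `major`, `minor`.
#' @export
#' @examples
#' estimate_ascn("2", af_h = 0.45, ai_seg = 8, config = ascn_config())
estimate_ascn <- function(cn_class, af_h, ai_seg, config = ascn_config(),
                          mean_lrr = NA_real_) {
  states <- ascn_candidates(cn_class, config$ploidy, mean_lrr)
  balanced <- states[nrow(states), , drop = FALSE]  # most balanced split last
  if (is.na(ai_seg) || is.na(af_h)) {
    return(as_tibble(balanced))
  }
  af_l_implied <- af_h / ai_seg
  imbalance_ok <- af_h >= config$ai_min_af_h &&
    (ai_seg >= config$ai_imbalance_threshold ||
       af_l_implied >= config$ai_min_af_h)
  if (!imbalance_ok) {
    return(as_tibble(balanced))
  }
  expected_ai <- states$major / (states$major + states$minor) - 0.5
  # ties resolved toward balance: states are ordered imbalanced -> balanced
  pick <- which.min(rev(abs(expected_ai - af_h)))
  as_tibble(states[nrow(states) + 1 - pick, , drop = FALSE])
}

ascn_candidates <- function(cn_class, ploidy, mean_lrr) {
  total <- switch(cn_class,
    "1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L,
    "AMP" = max(5L, as.integer(round(ploidy * 2^mean_lrr)))
  )
  if (is.null(total)) abort(paste0("unknown cn_class: ", cn_class))
  if (cn_class == "3") {
    minors <- 1L  # (3,0) is not modelled; a trisomy is always (2,1)
  } else {
    minors <- 0:(total %/% 2L)
  }
  tibble(major = as.integer(total - minors), minor = as.integer(minors))
}

#' Call allele-specific copy number genome-wide
#'
#' The full asCN pipeline: depth-filter the tumor SNV table, normalize to the
#' sample mean depth, intersect with the reference panel, compute per-site
#' log R ratios, segment them per chromosome by circular binary segmentation,
#' classify each segment's copy number, compute the segment allelic-imbalance
#' statistics over its heterozygous SNVs (segments longer than
#' `ai_min_length` with at least `ai_min_het` het SNVs), and assign integer
#' `(major, minor)` states.
#'
#' @param tumor A data frame of tumor SNV observations with columns `chrom`,
#'   `pos`, `ref_depth`, `alt_depth` and logical `is_het`.
#' @param panel A panel tibble from [build_panel()] / [read_panel()].
#' @param config An [ascn_config()].
#'
#' @return An object of class `ascn_call`: a list with `segments` (the
#'   per-segment tibble: `chrom`, `start`, `end`, `n_markers`, `mean_lrr`,
#'   `cn_class`, `af_h`, `af_l`, `ai_seg`, `major`, `minor`), `snvs` (the
#'   retained per-site table with `lrr`, `raf`, `ai`), `config`, and `log`
#'   (site counts read / depth-filtered / missing from the panel).
#' @export
call_ascn <- function(tumor, panel, config = ascn_config()) {
  stopifnot(all(c("chrom", "pos", "ref_depth", "alt_depth", "is_het") %in%
                  names(tumor)))
  tum <- as_tibble(tumor) |>
    mutate(depth = .data$ref_depth + .data$alt_depth)
  n_input <- nrow(tum)
  tum <- filter(tum, .data$depth > config$min_depth)
  n_depth_filtered <- n_input - nrow(tum)
  if (nrow(tum) == 0) abort("no tumor sites pass the depth filter.")
  tum$norm_depth <- tum$depth / mean(tum$depth)

  pan <- select(panel, "chrom", "pos", "median_norm_depth")
  merged <- inner_join(tum, pan, by = c("chrom", "pos"))
  n_no_panel <- nrow(tum) - nrow(merged)
  bad_panel <- merged$median_norm_depth <= 0
  n_zero_panel <- sum(bad_panel)
  merged <- merged[!bad_panel, , drop = FALSE]
  if (nrow(merged) == 0) abort("tumor and panel share no usable loci.")

  snvs <- merged |>
    mutate(raf = .data$ref_depth / .data$depth,
           lrr = compute_lrr(.data$norm_depth, .data$median_norm_depth),
           ai = compute_ai_snp(.data$raf)) |>
    arrange(.data$chrom, .data$pos)

  segs <- segment_lrr(select(snvs, "chrom", "pos", "lrr"), config)
  segs$cn_class <- classify_cn(segs$mean_lrr, config$ploidy)

  ai_stats <- pmap(list(segs$chrom, segs$start, segs$end), function(ch, s, e) {
    long_enough <- (e - s + 1) > config$ai_min_length
    hets <- snvs$ai[snvs$chrom == ch & snvs$pos >= s & snvs$pos <= e &
                      snvs$is_het]
    if (!long_enough) {
      tibble(af_h = NA_real_, af_l = NA_real_, ai_seg = NA_real_,
             n_het = length(hets))
    } else {
      mutate(compute_ai_seg(hets, config), n_het = length(hets))
    }
  }) |> list_rbind()
  segs <- bind_cols(segs, ai_stats)

  states <- pmap(list(segs$cn_class, segs$af_h, segs$ai_seg, segs$mean_lrr),
                 function(cls, afh, ais, ml) {
                   estimate_ascn(cls, afh, ais, config, mean_lrr = ml)
                 }) |> list_rbind()
  segs <- bind_cols(segs, states)

  structure(
    list(segments = segs, snvs = snvs, config = config,
         log = list(n_input = n_input, n_depth_filtered = n_depth_filtered,
                    n_no_panel = n_no_panel, n_zero_panel = n_zero_panel)),
    class = "ascn_call"
  )
}

#' @exportS3Method base::print
print.ascn_call <- function(x, ...) {
  cat("Allele-specific copy-number call\n")
  cat("  markers: ", nrow(x$snvs), " (", x$log$n_depth_filtered,
      " below depth filter, ", x$log$n_no_panel + x$log$n_zero_panel,
      " without panel baseline)\n", sep = "")
  cat("  segments:", nrow(x$segments), "\n")
  st <- count(x$segments, .data$major, .data$minor)
  cat("  states:  ",
      paste0("(", st$major, ",", st$minor, ")x", st$n, collapse = " "), "\n")
  invisible(x)
}
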