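# Circular binary segmentation of log R ratio series.
#
# The split statistic is the circular max-t: for every arc of the marker
# series the arc mean is compared with the mean of the complement, and the
# largest absolute t statistic is referred to a permutation distribution.
# A split is accepted when the permutation p-value is at or below
# `cbs_alpha`; the series is then cut at the arc boundaries and each piece
# is scanned recursively.

#' Segment a log R ratio series by circular binary segmentation
#'
#' @param points A data frame with columns `chrom`, `pos` and `lrr`, sorted
#'   by position within chromosome. All LRR values must be finite.
#' @param config An [ascn_config()]; `cbs_alpha`, `cbs_min_markers`,
#'   `cbs_n_perm` and `seed` are used.
#'
#' @return A tibble with one row per segment: `chrom`, `start`, `end`
#'   (positions of the first and last member marker, 1-based inclusive),
#'   `n_markers`, `mean_lrr`.
#' @export
#' @examples
#' pts <- tibble::tibble(chrom = "chr1", pos = 1:50 * 1000,
#'                       lrr = rep(c(0, 1), each = 25))
#' segment_lrr(pts, ascn_config(cbs_n_perm = 100))
segment_lrr <- function(points, config = ascn_config()) {
  stopifnot(all(c("chrom", "pos", "lrr") %in% names(points)))
  if (!all(is.finite(points$lrr))) abort("non-finite LRR values.")
  pts <- as_tibble(points)
  local_seed(config$seed, {
    out <- pts |>
      group_by(.data$chrom) |>
      group_modify(function(d, key) {
        if (is.unsorted(d$pos)) abort("positions must be sorted within chromosome.")
        segment_one_chrom(d, config)
      }) |>
      ungroup()
  })
  arrange(out, .data$chrom, .data$start)
}

segment_one_chrom <- function(d, config) {
  n <- nrow(d)
  minw <- config$cbs_min_markers
  if (n < minw) {
    warn(paste0("fewer than ", minw, " markers; emitting one trivial segment."))
    ends <- n
  } else {
    ends <- cbs_recurse(d$lrr, 1L, n, minw, config$cbs_n_perm, config$cbs_alpha)
  }
  starts <- c(1L, head(ends, -1) + 1L)
  tibble(
    start = d$pos[starts],
    end = d$pos[ends],
    n_markers = ends - starts + 1L,
    mean_lrr = map2_dbl(starts, ends, function(s, e) mean(d$lrr[s:e]))
  )
}

# returns the sorted end indices (relative to the full series) of the
# segments found in x[lo:hi]
cbs_recurse <- function(x, lo, hi, minw, n_perm, alpha) {
  n <- hi - lo + 1L
  if (n < 2L * minw) return(hi)
  scan <- cbs_scan_cpp(x[lo:hi], minw, n_perm, alpha)
  if (is.na(scan$stat) || scan$p > alpha) return(hi)
  cuts <- integer(0)
  if (scan$i > 0L) cuts <- c(cuts, lo + scan$i - 1L)
  if (scan$j < n) cuts <- c(cuts, lo + scan$j - 1L)
  if (length(cuts) == 0L) return(hi)
  bounds <- c(lo - 1L, cuts, hi)
  unlist(map2(head(bounds, -1) + 1L, tail(bounds, -1), function(s, e) {
    cbs_recurse(x, s, e, minw, n_perm, alpha)
  }))
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

map2_dbl <- function(x, y, f) purrr::map2_dbl(x, y, f)
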