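#' Tidy an asCN call into its segment table
#'
#' @param x An `ascn_call` from [call_ascn()].
#' @param ... Unused.
#' @return The per-segment tibble.
#' @export
tidy.ascn_call <- function(x, ...) {
  x$segments
}

#' One-row summary of an asCN call
#'
#' @param x An `ascn_call`.
#' @param ... Unused.
#' @return A tibble with marker/segment counts, the marker-weighted fraction
#'   of the genome in each aberration category, and the ploidy used.
#' @export
glance.ascn_call <- function(x, ...) {
  s <- x$segments
  w <- s$n_markers / sum(s$n_markers)
  tibble(
    n_markers = nrow(x$snvs),
    n_segments = nrow(s),
    frac_diploid = sum(w[s$major == 1 & s$minor == 1]),
    frac_imbalanced = sum(w[s$major != s$minor]),
    frac_loh = sum(w[s$minor == 0]),
    ploidy = x$config$ploidy
  )
}

#' Tidy an ASE call into its per-gene table
#'
#' @param x An `ase_call` from [call_ase()].
#' @param ... Unused.
#' @return The per-gene result tibble.
#' @export
tidy.ase_call <- function(x, ...) {
  x$genes
}

#' One-row summary of an ASE call
#'
#' @param x An `ase_call`.
#' @param ... Unused.
#' @return A tibble of gene counts per class and the fraction of testable
#'   genes showing ASE.
#' @export
glance.ase_call <- function(x, ...) {
  g <- x$genes
  testable <- g$ase_class != "NOT_TESTABLE"
  ase <- g$ase_class %in% c("CNV_DRIVEN_ASE", "CNV_INDEPENDENT_ASE")
  tibble(
    n_genes = nrow(g),
    n_testable = sum(testable),
    n_cnv_driven = sum(g$ase_class == "CNV_DRIVEN_ASE"),
    n_cnv_independent = sum(g$ase_class == "CNV_INDEPENDENT_ASE"),
    n_balanced = sum(g$ase_class == "BALANCED"),
    frac_ase = if (any(testable)) sum(ase) / sum(testable) else NA_real_,
    fdr_alpha = x$thresholds$fdr_alpha
  )
}
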