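#' Configuration for allele-specific copy-number calling
#'
#' Bundles the tunable parameters of the asCN caller. `ploidy` recentres the
#' copy-number baseline: the expected log R ratio of a segment with `c` total
#' copies is `log2(c / ploidy)`, so near-triploid tumors are handled by
#' raising `ploidy` rather than by rescaling the data.
#'
#' @param ploidy Expected baseline total copy number (default 2). Must be >= 1.
#' @param cbs_alpha Significance level for accepting a segmentation split
#'   (permutation p-value), default 0.01.
#' @param cbs_min_markers Minimum markers per segment, default 10.
#' @param cbs_n_perm Number of permutations for the split test, default 1000.
#' @param ai_imbalance_threshold Minimum segment allelic-imbalance ratio
#'   (`AI_seg = AF_h / AF_L`) for the imbalance gate, default 1.4.
#' @param ai_min_af_h Minimum high-cluster mean AI (`AF_h`) for a segment to be
#'   eligible for an imbalanced state, default 0.1. The same floor applied to
#'   `AF_L` opens the gate for uniformly skewed segments (e.g. pure CN-LOH,
#'   where every heterozygous site is fixed and the two cluster means tie).
#' @param ai_min_het Minimum heterozygous SNVs for `AI_seg` to be defined,
#'   default 20.
#' @param ai_min_length Minimum segment length (bp) for `AI_seg`, default 1e5.
#' @param ai_epsilon Floor applied to `AF_L` before division, default 1e-3.
#' @param min_depth Strict lower bound on raw site depth; sites with depth
#'   `<= min_depth` are dropped, default 10.
#' @param seed Integer seed controlling k-means restarts and the CBS
#'   permutation stream, default 1.
#'
#' @return A list of class `ascn_config`.
#' @export
#' @examples
#' ascn_config(ploidy = 3)
ascn_config <- function(ploidy = 2,
                        cbs_alpha = 0.01,
                        cbs_min_markers = 10,
                        cbs_n_perm = 1000,
                        ai_imbalance_threshold = 1.4,
                        ai_min_af_h = 0.1,
                        ai_min_het = 20,
                        ai_min_length = 1e5,
                        ai_epsilon = 1e-3,
                        min_depth = 10,
                        seed = 1L) {
  stopifnot(is.numeric(ploidy), length(ploidy) == 1, ploidy >= 1)
  if (!(cbs_alpha > 0 && cbs_alpha < 1)) {
    abort("`cbs_alpha` must be in (0, 1).")
  }
  stopifnot(cbs_min_markers >= 2, cbs_n_perm >= 1,
            ai_imbalance_threshold >= 1, ai_min_af_h >= 0,
            ai_min_het >= 1, ai_min_length > 0, ai_epsilon > 0,
            min_depth >= 0)
  structure(
    list(ploidy = ploidy,
         cbs_alpha = cbs_alpha,
         cbs_min_markers = as.integer(cbs_min_markers),
         cbs_n_perm = as.integer(cbs_n_perm),
         ai_imbalance_threshold = ai_imbalance_threshold,
         ai_min_af_h = ai_min_af_h,
         ai_min_het = as.integer(ai_min_het),
         ai_min_length = ai_min_length,
         ai_epsilon = ai_epsilon,
         min_depth = min_depth,
         seed = as.integer(seed)),
    class = "ascn_config"
  )
}

#' Filtering and testing thresholds for ASE calling
#'
#' Heterozygous-SNV quality filters applied to the WGS variant annotations
#' (all strict inequalities), the RNA-seq count and expression filters, and
#' the ASE decision thresholds.
#'
#' @param min_dp Strict minimum total depth (`DP > min_dp`), default 15.
#' @param min_qd Strict minimum quality-by-depth, default 2.
#' @param min_mq Strict minimum mapping quality, default 35.
#' @param min_mqranksum Strict minimum MQRankSum, default -12.5.
#' @param min_readposranksum Strict minimum ReadPosRankSum, default -8.
#' @param max_fs Strict maximum FisherStrand, default 60.
#' @param min_rna_total Minimum RNA reads over an SNV (inclusive), default 10.
#' @param min_cpm Minimum gene expression in counts per million (inclusive),
#'   default 1.
#' @param fdr_alpha Benjamini-Hochberg false-discovery-rate level, default 0.05.
#' @param or_high,or_low WGS/RNA odds-ratio gates: on balanced segments a gene
#'   must also have OR > `or_high` or OR < `or_low` to be called ASE.
#'   Defaults 2 and 0.5.
#'
#' @return A list of class `ase_thresholds`.
#' @export
#' @examples
#' ase_thresholds(fdr_alpha = 0.1)
ase_thresholds <- function(min_dp = 15,
                           min_qd = 2,
                           min_mq = 35,
                           min_mqranksum = -12.5,
                           min_readposranksum = -8,
                           max_fs = 60,
                           min_rna_total = 10,
                           min_cpm = 1,
                           fdr_alpha = 0.05,
                           or_high = 2,
                           or_low = 0.5) {
  vals <- c(min_dp, min_qd, min_mq, min_mqranksum, min_readposranksum,
            max_fs, min_rna_total, min_cpm, fdr_alpha, or_high, or_low)
  if (!all(is.finite(vals))) abort("all thresholds must be finite.")
  if (!(fdr_alpha > 0 && fdr_alpha < 1)) abort("`fdr_alpha` must be in (0, 1).")
  structure(
    list(min_dp = min_dp, min_qd = min_qd, min_mq = min_mq,
         min_mqranksum = min_mqranksum,
         min_readposranksum = min_readposranksum, max_fs = max_fs,
         min_rna_total = min_rna_total, min_cpm = min_cpm,
         fdr_alpha = fdr_alpha, or_high = or_high, or_low = or_low),
    class = "ase_thresholds"
  )
}

#' Read a run configuration from a YAML file
#'
#' The file may contain top-level keys `genome_build`, `seed`, `log_level`,
#' `ascn` (passed to [ascn_config()]) and `ase` (passed to
#' [ase_thresholds()]). Unknown keys, at either level, are rejected.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `genome_build`, `seed`, `log_level`, `ascn`
#'   (an `ascn_config`) and `ase` (an `ase_thresholds`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  allowed <- c("genome_build", "seed", "log_level", "ascn", "ase")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  check_sub <- function(x, fn, label) {
    x <- x %||% list()
    unknown <- setdiff(names(x), names(formals(fn)))
    if (length(unknown)) {
      abort(paste0("unknown ", label, " config key(s): ",
                   paste(unknown, collapse = ", ")))
    }
    do.call(fn, x)
  }
  list(
    genome_build = raw$genome_build %||% "unspecified",
    seed = as.integer(raw$seed %||% 1L),
    log_level = raw$log_level %||% "info",
    ascn = check_sub(raw$ascn, ascn_config, "ascn"),
    ase = check_sub(raw$ase, ase_thresholds, "ase")
  )
}
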