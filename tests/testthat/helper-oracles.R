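# Independent oracles used across the suite.

# Exact two-sided binomial p-value by explicit likelihood-sorted enumeration
# (independent of the package's vectorised implementation and of binom.test).
binom_enum_oracle <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  o <- order(d)
  sorted <- d[o]
  cum <- cumsum(sorted)
  # last enumeration position whose likelihood is within the tie guard of d[k+1]
  idx <- max(which(sorted <= d[k + 1] * (1 + 1e-7)))
  min(1, cum[idx])
}

# Benjamini-Hochberg step-up, written directly from the definition.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# Best contiguous 2-partition of the sorted values by total within-cluster
# sum of squares (the optimal 1-D k=2 clustering is contiguous in sorted
# order).
contiguous_split_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  best <- Inf
  bi <- 1L
  for (i in 1:(n - 1)) {
    a <- s[1:i]
    b <- s[(i + 1):n]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best) {
      best <- ss
      bi <- i
    }
  }
  list(af_l = mean(s[1:bi]), af_h = mean(s[(bi + 1):n]),
       low = s[1:bi], high = s[(bi + 1):n])
}

# Exhaustive single-change-point t-scan: the split index maximising the
# two-sample t statistic between the left and right parts.
single_changepoint_oracle <- function(x) {
  n <- length(x)
  ts <- vapply(1:(n - 1), function(i) {
    abs(mean(x[1:i]) - mean(x[(i + 1):n])) / sqrt(1 / i + 1 / (n - i))
  }, 0)
  which.max(ts)
}

# Per-marker (major, minor) truth-vs-called agreement for an ascn_call
# against the simulator's phase table.
marker_state_agreement <- function(ascn, phase) {
  segs <- tidy(ascn)
  snv <- ascn$snvs
  tm <- match(paste(snv$chrom, snv$pos), paste(phase$chrom, phase$pos))
  idx <- mapply(function(ch, p) {
    which(segs$chrom == ch & segs$start <= p & segs$end >= p)[1]
  }, snv$chrom, snv$pos)
  tibble::tibble(
    chrom = snv$chrom,
    ok = segs$major[idx] == phase$major[tm] & segs$minor[idx] == phase$minor[tm],
    true_major = phase$major[tm],
    true_minor = phase$minor[tm]
  )
}

# Build a call_ase() input tibble for synthetic genes with a common segment
# state and true major-haplotype expression fraction.
make_gene_inputs <- function(n_genes, f_true, major, minor, prefix,
                             rna_depth = 80, wgs_depth = 40,
                             snvs_lambda = 1.2, min_total = 10) {
  nsnv <- 1L + rpois(n_genes, snvs_lambda)
  wgs_f <- if (major != minor) major / (major + minor) else 0.5
  purrr::map(seq_len(n_genes), function(g) {
    tot <- rpois(nsnv[g], rna_depth)
    tot[tot < min_total] <- min_total
    hap_major <- rbinom(nsnv[g], tot, f_true)
    tibble::tibble(
      gene_id = sprintf("%s%05d", prefix, g),
      chrom = prefix, pos = g * 100L + seq_len(nsnv[g]),
      ref_count = hap_major, alt_count = tot - hap_major,
      wgs_raf = wgs_f,
      wgs_ref_depth = round(wgs_depth * wgs_f),
      wgs_alt_depth = round(wgs_depth * (1 - wgs_f)),
      major = as.integer(major), minor = as.integer(minor)
    )
  }) |> purrr::list_rbind()
}
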