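# Independent oracles and small fixture builders used across test files.

# Brute-force Benjamini-Hochberg step-up, written as the textbook double
# loop; deliberately independent of stats::p.adjust.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (k in seq_len(m)) {
    q[k] <- min(1, min(ps[k:m] * m / (k:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force G-score: explicit loops over markers and samples.
gscore_bruteforce <- function(values, theta, direction) {
  m <- nrow(values)
  g <- numeric(m)
  for (i in seq_len(m)) {
    for (j in seq_len(ncol(values))) {
      v <- values[i, j]
      if (is.na(v)) next
      if (direction == "AMP" && v >= theta) g[i] <- g[i] + v
      if (direction == "DEL" && v <= -theta) g[i] <- g[i] - v
    }
  }
  g
}

# Exact null tail by enumeration: every combination of one marker draw per
# sample (feasible only for tiny grids).
null_tail_exact <- function(contrib, g) {
  draws <- do.call(expand.grid, lapply(seq_len(ncol(contrib)),
                                       function(j) contrib[, j]))
  sums <- rowSums(as.matrix(draws))
  vapply(g, function(x) mean(sums >= x - 1e-12), numeric(1))
}

# Write a small marker-matrix file; returns its path.
write_matrix_fixture <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "matrix.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Default arm table for chromosomes with positions up to max_pos.
toy_arms <- function(chroms, max_pos = 1e7) {
  do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch, arm = c("p", "q"),
               start = c(1, max_pos / 2 + 1), end = c(max_pos / 2, max_pos))
  }))
}

# Assemble a cn_matrix directly from a value matrix on one toy chromosome.
toy_cn <- function(values, spacing = 1000L, chrom = "1") {
  m <- nrow(values)
  markers <- data.frame(marker = sprintf("m%03d", seq_len(m)), chrom = chrom,
                        pos = seq_len(m) * spacing)
  arms <- data.frame(chrom = chrom, arm = c("p", "q"),
                     start = c(1L, (m %/% 2L) * spacing + 1L),
                     end = c((m %/% 2L) * spacing, m * spacing))
  grid <- marker_grid(markers, arms = arms)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  }
  cn_matrix(values, grid)
}

# Standard small cohort spec used by the variant-comparison tests: one broad
# amplification, one focal amplification on another chromosome, one focal
# deletion inside the broad event's chromosome.
variant_cohort <- function(seed) {
  events <- data.frame(
    chrom = c(1L, 2L, 1L),
    start = c(20L, 60L, 110L),
    end = c(100L, 70L, 120L),
    amplitude = c(0.6, 1.2, 1.0),
    fraction = c(0.5, 0.4, 0.4),
    direction = c("AMP", "AMP", "DEL"),
    stringsAsFactors = FALSE
  )
  simulate_cohort(sim_spec(n_chrom = 2L, markers_per_chrom = 150L,
                           n_samples = 8L, noise_sd = 0.1, events = events,
                           seed = seed))
}

peak_key <- function(peaks) {
  peaks[order(peaks$chrom, peaks$start_idx),
        c("chrom", "start_idx", "end_idx", "peak_idx")]
}
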