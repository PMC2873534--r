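# Peak annotation, enrichment testing, and s-tuning diagnostics.

#' Genes overlapping a peak region
#'
#' A gene is reported when its \[start, end\] interval overlaps the peak's
#' genomic span by at least one base pair (1-based inclusive coordinates).
#'
#' @param peak a single peak row (with \code{chrom}, \code{start_bp},
#'   \code{end_bp}) or a list with those fields.
#' @param genes a gene table ([gene_table()]).
#' @return character vector of gene symbols.
#' @export
genes_in_peak <- function(peak, genes) {
  hit <- genes$chrom == normalize_chrom(peak$chrom) &
    genes$start <= peak$end_bp & genes$end >= peak$start_bp
  genes$symbol[hit]
}

#' Peak-shift permutation enrichment test
#'
#' Tests whether reported peaks contain likely driver genes more often than
#' random regions of the same sizes. Each iteration relocates every peak to
#' a uniformly random genome position preserving its length (a chromosome is
#' chosen with probability proportional to its number of valid start
#' positions, so placement is uniform over the genome), then counts how many
#' relocated peaks contain at least one driver gene. The p-value uses the
#' add-one estimator p = (1 + #\{permutation count >= observed\}) /
#' (1 + n_iter), so it is never exactly zero.
#'
#' @param peaks peak data.frame (columns \code{chrom}, \code{start_bp},
#'   \code{end_bp}).
#' @param drivers character vector of driver gene symbols (nonempty).
#' @param genes gene table with the locations of all genes.
#' @param grid [marker_grid()] defining chromosome extents (the maximal
#'   marker position per chromosome).
#' @param n_iter number of permutation iterations (>= 1).
#' @param seed RNG seed.
#' @return list with \code{observed} (driver-containing peak count),
#'   \code{perm_counts} (length \code{n_iter}), and \code{p_value}.
#' @export
peak_shift_test <- function(peaks, drivers, genes, grid, n_iter = 10000L,
                            seed = 1L) {
  if (length(drivers) == 0) stop("driver gene set is empty")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (nrow(peaks) == 0) stop("no peaks to test")
  dgenes <- genes[genes$symbol %in% drivers, , drop = FALSE]
  chroms <- unique(grid$chrom)
  chrom_len <- vapply(chroms, function(ch) max(grid$pos[grid$chrom == ch]),
                      numeric(1))
  lens <- peaks$end_bp - peaks$start_bp + 1L
  if (any(lens > max(chrom_len))) {
    stop("peak longer than every chromosome")
  }
  contains_driver <- function(ch, start, end) {
    any(dgenes$chrom == ch & dgenes$start <= end & dgenes$end >= start)
  }
  observed <- sum(vapply(seq_len(nrow(peaks)), function(i) {
    contains_driver(peaks$chrom[i], peaks$start_bp[i], peaks$end_bp[i])
  }, logical(1)))
  set.seed(seed)
  perm_counts <- integer(n_iter)
  for (r in seq_len(n_iter)) {
    cnt <- 0L
    for (i in seq_len(nrow(peaks))) {
      L <- lens[i]
      valid <- pmax(0, chrom_len - L + 1)
      ch <- sample(chroms, 1L, prob = valid)
      start <- sample.int(chrom_len[[ch]] - L + 1L, 1L)
      if (contains_driver(ch, start, start + L - 1L)) cnt <- cnt + 1L
    }
    perm_counts[r] <- cnt
  }
  p <- (1 + sum(perm_counts >= observed)) / (1 + n_iter)
  list(observed = observed, perm_counts = perm_counts, p_value = p)
}

#' Histogram of segment sizes in markers
#'
#' Diagnostic used to pick candidate values for the persistence parameter s:
#' segment-size counts typically decay with size, and sizes where the decay
#' steepens are natural candidates. The size of a segment is the number of
#' grid markers it covers.
#'
#' @param segs a \code{segment_set}.
#' @param grid a [marker_grid()].
#' @param path optional path; when given, the histogram is also written as a
#'   tab-delimited table (columns \code{size}, \code{count}).
#' @return data.frame with columns \code{size} (markers) and \code{count}.
#' @export
segment_size_histogram <- function(segs, grid, path = NULL) {
  if (nrow(segs) == 0) {
    out <- data.frame(size = integer(), count = integer())
  } else {
    sizes <- vapply(seq_len(nrow(segs)), function(i) {
      sum(grid$chrom == segs$chrom[i] &
            grid$pos >= segs$start[i] & grid$pos <= segs$end[i])
    }, integer(1))
    tab <- table(sizes)
    out <- data.frame(size = as.integer(names(tab)),
                      count = as.integer(tab))
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Minimum distance between peaks
#'
#' For each peak, the base-pair gap to the nearest other peak on the same
#' chromosome (the number of bases strictly between the two spans). Peaks
#' that are the only peak on their chromosome are omitted with a message.
#' The distribution of these distances is the diagnostic used to choose s:
#' an excess of near-adjacent peaks indicates spurious splitting.
#'
#' @param peaks peak data.frame.
#' @return data.frame with columns \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{min_dist_bp}; zero rows if fewer than two peaks
#'   share a chromosome.
#' @export
min_peak_distance <- function(peaks) {
  out <- data.frame(chrom = character(), start_bp = integer(),
                    end_bp = integer(), min_dist_bp = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(peaks) < 2) return(out)
  n_lonely <- 0L
  for (i in seq_len(nrow(peaks))) {
    same <- which(peaks$chrom == peaks$chrom[i])
    same <- setdiff(same, i)
    if (length(same) == 0) {
      n_lonely <- n_lonely + 1L
      next
    }
    gaps <- vapply(same, function(j) {
      if (peaks$start_bp[j] > peaks$end_bp[i]) {
        peaks$start_bp[j] - peaks$end_bp[i] - 1L
      } else if (peaks$end_bp[j] < peaks$start_bp[i]) {
        peaks$start_bp[i] - peaks$end_bp[j] - 1L
      } else {
        0L  # overlapping spans (possible across variants/runs)
      }
    }, numeric(1))
    out <- rbind(out, data.frame(chrom = peaks$chrom[i],
                                 start_bp = peaks$start_bp[i],
                                 end_bp = peaks$end_bp[i],
                                 min_dist_bp = min(gaps),
                                 stringsAsFactors = FALSE))
  }
  if (n_lonely > 0) {
    message(n_lonely, " peak(s) alone on their chromosome omitted")
  }
  out
}

#' Read a driver gene list
#'
#' One gene symbol per line; blank lines and lines starting with '#' are
#' skipped.
#'
#' @param path file path.
#' @return character vector of symbols.
#' @export
read_driver_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
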