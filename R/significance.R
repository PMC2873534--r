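#' Build the permutation null distribution of G-scores
#'
#' Models the G-score expected by chance under marker independence: each
#' sample contributes one draw from its own empirical distribution of
#' per-marker contributions, and the null score is the sum of one draw per
#' sample. Two estimators are available:
#'
#' * \code{"convolution"} (default): each sample's contributions are binned
#'   and the per-sample histograms convolved; deterministic and semi-exact
#'   (error bounded by the bin width, and conservative, because contributions
#'   are rounded up to their bin edge).
#' * \code{"montecarlo"}: \code{n_perm} genome-wide permutations, each
#'   permuting every sample's contribution vector independently and recording
#'   all permuted per-marker sums; requires a seed.
#'
#' @param contrib non-negative markers-by-samples contribution matrix (from a
#'   \code{gscore_track}).
#' @param method \code{"convolution"} or \code{"montecarlo"}.
#' @param n_bins number of bins spanning the maximal possible score
#'   (default 10000).
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed RNG seed, mandatory for the Monte-Carlo method.
#' @return a \code{null_dist}: binned tail-probability table with bin width
#'   \code{w}; \code{tail[k + 1]} approximates Pr(G >= k * w).
#' @export
build_null <- function(contrib, method = c("convolution", "montecarlo"),
                       n_bins = 10000L, n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (method == "montecarlo" && n_perm < 1) stop("n_perm must be >= 1")
  if (any(contrib < 0, na.rm = TRUE)) stop("contributions must be >= 0")
  m <- nrow(contrib)
  n <- ncol(contrib)
  total_max <- sum(apply(contrib, 2, max))
  if (total_max == 0) {
    # degenerate: no aberrant entries anywhere; any positive score is
    # off-support
    return(structure(list(w = 1, tail = 1, method = method, n_samples = n,
                          min_tail = 1 / max(1, n_perm * m)),
                     class = "null_dist"))
  }
  w <- total_max / n_bins
  bin_of <- function(g) pmax(0L, as.integer(ceiling(g / w - 1e-9)))
  if (method == "convolution") {
    dist <- 1
    for (j in seq_len(n)) {
      k <- bin_of(contrib[, j])
      probs <- tabulate(k + 1L, nbins = max(k) + 1L) / m
      dist <- stats::convolve(dist, rev(probs), type = "open")
    }
    dist <- pmax(dist, 0)
    dist <- dist / sum(dist)
    tail <- rev(cumsum(rev(dist)))
    tail <- pmin(tail, 1)
    min_tail <- min(tail[tail > 0])
  } else {
    if (is.null(seed)) stop("montecarlo null requires a seed")
    set.seed(seed)
    # max bin index: per-sample rounding can add one bin each
    counts <- numeric(n_bins + n + 1L)
    for (r in seq_len(n_perm)) {
      sc <- numeric(m)
      for (j in seq_len(n)) {
        sc <- sc + contrib[sample.int(m), j]
      }
      k <- pmin(bin_of(sc), length(counts) - 1L)
      t <- tabulate(k + 1L, nbins = length(counts))
      counts <- counts + t
    }
    total <- n_perm * m
    tail <- rev(cumsum(rev(counts))) / total
    min_tail <- 1 / total
  }
  structure(list(w = w, tail = tail, method = method, n_samples = n,
                 min_tail = min_tail),
            class = "null_dist")
}

#' @export
print.null_dist <- function(x, ...) {
  cat("null_dist (", x$method, "): ", length(x$tail), " bins, width ",
      format(x$w, digits = 4), ", ", x$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Null tail probability at given scores
#'
#' Looks up Pr(G >= g) in a [build_null()] table. Scores are mapped to bins
#' right-closed (rounded up to the next bin edge), which together with the
#' rounding-up used when building the null makes the resulting p-values
#' conservative. Scores beyond the null support are assigned the smallest
#' representable tail mass, with a message.
#'
#' @param null a \code{null_dist}.
#' @param g numeric vector of scores (>= 0).
#' @return tail probabilities in (0, 1].
#' @export
null_tail <- function(null, g) {
  k <- pmax(0L, as.integer(ceiling(g / null$w - 1e-9)))
  p <- rep(NA_real_, length(g))
  inside <- k < length(null$tail)
  p[inside] <- null$tail[k[inside] + 1L]
  n_out <- sum(!inside) + sum(p <= 0, na.rm = TRUE)
  if (n_out > 0) {
    message(n_out, " score(s) beyond null support; assigned smallest tail mass ",
            format(null$min_tail, digits = 3))
  }
  p[!inside | p <= 0] <- null$min_tail
  pmin(p, 1)
}

#' Per-marker p-values from a G-score track
#'
#' @param track a \code{gscore_track}, or a bare numeric score vector.
#' @param null a \code{null_dist} built from the matching contribution grid.
#' @return numeric vector of p-values.
#' @export
pvalues <- function(track, null) {
  g <- if (inherits(track, "gscore_track")) track$score else track
  null_tail(null, g)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment across all markers of one direction:
#' with p sorted ascending, q_(k) = min over j >= k of p_(j) * M / j,
#' capped at 1, mapped back to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as \code{p}.
#' @export
qvalues <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Invert a q-value threshold to a G-score threshold
#'
#' Returns the smallest score whose null tail probability is at most
#' \code{q_target}: a marker attaining that score has p <= q_target and hence,
#' at the most favorable Benjamini-Hochberg rank (M of M), q <= q_target.
#' This is the score-scale equivalent of the significance cutoff and is used
#' as G_thres by the limited peel-off.
#'
#' @param q_target target q-value in (0, 1).
#' @param null a \code{null_dist}.
#' @param n_markers number of markers tested (kept for the BH rationale;
#'   the bound used is rank-M, which does not depend on it numerically).
#' @return score threshold (same units as G-scores).
#' @export
gscore_for_q <- function(q_target, null, n_markers = NULL) {
  if (q_target <= 0 || q_target >= 1) stop("q_target must be in (0, 1)")
  idx <- which(null$tail <= q_target)
  if (length(idx) == 0) {
    stop("q_target ", q_target, " unreachable within null support; ",
         "increase n_bins or n_perm")
  }
  (min(idx) - 1L) * null$w
}
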