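# Iterative peak discovery and peel-off.
#
# All four variants share the loop: score the working contribution grid,
# convert to p/q against a frozen null, take the most significant marker,
# extend it to a region by leave-one-out, then remove the peak's influence
# from the working grid. They differ only in the removal step:
#   standard/focal - zero the whole contiguous aberrant run of every sample
#                    whose aberration includes the peak;
#   arm            - zero the whole chromosome arm for those samples;
#   limited        - decompose each contribution into a peak-attributable
#                    part G_r and a peak-independent part G_n and abort the
#                    peel where the summed G_n indicates an independent peak.

# Maximal contiguous run of strictly positive x containing index m, within
# [lo, hi]. NULL if x[m] <= 0.
run_bounds <- function(x, m, lo, hi) {
  if (is.na(x[m]) || x[m] <= 0) return(NULL)
  a <- m
  while (a > lo && x[a - 1L] > 0) a <- a - 1L
  b <- m
  while (b < hi && x[b + 1L] > 0) b <- b + 1L
  c(a, b)
}

#' Most significant peak marker
#'
#' Returns the marker with minimal q-value, ties broken by maximal G-score
#' then by smallest genomic coordinate; \code{NA} when no marker is below
#' the q-threshold (the discovery loop then terminates).
#'
#' @param q per-marker q-values.
#' @param g per-marker G-scores (aligned with \code{q}).
#' @param q_threshold significance cutoff (default 0.25).
#' @return integer marker index, or \code{NA_integer_}.
#' @export
find_peak <- function(q, g, q_threshold = 0.25) {
  stopifnot(length(q) == length(g))
  best <- order(q, -g)[1]  # order() is stable: leftmost wins remaining ties
  if (q[best] >= q_threshold) NA_integer_ else as.integer(best)
}

# Maximal contiguous plateau of markers around m whose q-values equal q[m]
# (within tolerance), restricted to [lo, hi].
q_plateau <- function(q, m, lo, hi, tol = 1e-9) {
  lim <- q[m] + tol * (1 + abs(q[m]))
  a <- m
  while (a > lo && q[a - 1L] <= lim) a <- a - 1L
  b <- m
  while (b < hi && q[b + 1L] <= lim) b <- b + 1L
  c(a, b)
}

#' Extend a peak to its reported region by leave-one-out
#'
#' A peak defined by few samples can have unstable boundaries. Each sample
#' is left out in turn; scores and q-values are recomputed (against the same
#' frozen null), and the q-minimum plateau around the peak is re-derived on
#' the reduced cohort. The reported region is the union of the all-samples
#' plateau and the N leave-one-out plateaus, clipped to the chromosome and
#' to previously reported regions of the same direction.
#'
#' @param contrib current working contribution grid.
#' @param null frozen \code{null_dist} for the direction.
#' @param q all-samples q-values on the current grid.
#' @param peak peak marker index (current q-minimum).
#' @param grid the [marker_grid()].
#' @param prev_spans list of previously reported c(first, last) marker spans
#'   used for clipping (may be empty).
#' @param mode \code{"union"} (default) or \code{"intersection"} of the
#'   leave-one-out plateaus.
#' @return c(first, last) marker indices of the region (contains the peak).
#' @export
extend_peak_loo <- function(contrib, null, q, peak, grid,
                            prev_spans = list(),
                            mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  ch <- chrom_bounds_of(grid, peak)
  lo <- ch[1]; hi <- ch[2]
  region <- q_plateau(q, peak, lo, hi)
  n <- ncol(contrib)
  score_all <- rowSums(contrib)
  if (n > 1) {
    for (i in seq_len(n)) {
      s_loo <- score_all - contrib[, i]
      if (s_loo[peak] <= 0) next  # peak defined solely by sample i
      q_loo <- qvalues(pvalues(s_loo, null))
      rb <- run_bounds(s_loo, peak, lo, hi)
      sub <- rb[1]:rb[2]
      best <- sub[order(q_loo[sub], -s_loo[sub])[1]]
      pl <- q_plateau(q_loo, best, rb[1], rb[2])
      # keep the original peak inside the candidate region
      pl <- c(min(pl[1], peak), max(pl[2], peak))
      region <- if (mode == "union") {
        c(min(region[1], pl[1]), max(region[2], pl[2]))
      } else {
        c(max(region[1], pl[1]), min(region[2], pl[2]))
      }
    }
  }
  region <- c(min(region[1], peak), max(region[2], peak))
  # clip against previously reported regions that do not contain the peak
  for (sp in prev_spans) {
    if (sp[2] < peak && sp[2] >= region[1]) region[1] <- sp[2] + 1L
    if (sp[1] > peak && sp[1] <= region[2]) region[2] <- sp[1] - 1L
  }
  as.integer(region)
}

#' Standard peel-off
#'
#' For every sample whose contribution at the peak marker is positive, zeroes
#' the maximal contiguous run of positive contributions containing the peak
#' (the whole aberration overlapping the peak). Other samples are untouched.
#'
#' @param contrib working contribution grid.
#' @param peak peak marker index.
#' @param grid the [marker_grid()].
#' @return the edited contribution grid.
#' @export
standard_peel <- function(contrib, peak, grid) {
  ch <- chrom_bounds_of(grid, peak)
  for (i in which(contrib[peak, ] > 0)) {
    rb <- run_bounds(contrib[, i], peak, ch[1], ch[2])
    contrib[rb[1]:rb[2], i] <- 0
  }
  contrib
}

#' Arm peel-off
#'
#' Zeroes the full chromosome arm containing the peak for every sample whose
#' aberration includes the peak; other chromosomes and the sister arm are
#' untouched.
#'
#' @inheritParams standard_peel
#' @return the edited contribution grid.
#' @export
arm_peel <- function(contrib, peak, grid) {
  if (is.null(grid$arm)) stop("arm peel-off requires arm assignments")
  idx <- which(grid$chrom == grid$chrom[peak] & grid$arm == grid$arm[peak])
  for (i in which(contrib[peak, ] > 0)) {
    contrib[idx, i] <- 0
  }
  contrib
}

#' Peak-attributable / peak-independent score decomposition
#'
#' Walking outward from a region edge within one sample's aberrant run, the
#' peak-attributable component G_r starts at the edge contribution and can
#' only decrease; a decrease is accepted only when sustained for at least
#' \code{s} consecutive markers (look-ahead window of \code{s} markers
#' including the current one), so transient dips do not release signal. The
#' peak-independent component is G_n = max(0, G - G_r).
#'
#' @param g contributions of one sample along the walk, ordered from the
#'   region edge (first element) outward to the run end.
#' @param s persistence parameter (markers, >= 0); \code{s = 0} and
#'   \code{s = 1} both accept instantaneous dips.
#' @return list with components \code{gr} and \code{gn}, aligned with
#'   \code{g}.
#' @export
limited_residual <- function(g, s) {
  if (s < 0) stop("persistence parameter s must be >= 0")
  len <- length(g)
  win <- max(as.integer(s), 1L)
  gr <- numeric(len)
  if (len == 0) return(list(gr = gr, gn = gr))
  gr[1] <- g[1]
  if (len > 1) {
    for (t in 2:len) {
      look <- g[t:min(t + win - 1L, len)]
      gr[t] <- min(gr[t - 1L], max(look))
    }
  }
  list(gr = gr, gn = pmax(0, g - gr))
}

#' Limited peel-off
#'
#' Removes only the component of each aberration attributable to the peak.
#' On each side of the region independently, per-sample decompositions
#' ([limited_residual()]) are computed walking outward to the chromosome end
#' (beyond a sample's run, or for samples whose aberration does not include
#' the peak, G_r = 0 and the whole contribution is peak-independent). The
#' summed peak-independent component sum_i G_n(m, i) is the score marker m
#' would retain after the peel; at the first marker where it reaches
#' \code{g_thres} — i.e. where the remaining signal would be significant on
#' its own — the peel is aborted on that side: markers from the abort marker
#' outward keep their current contributions, markers between the region edge
#' and the abort marker are reduced by G_r (to G_n), and the region itself is
#' zeroed. If a side's walk completes without aborting there is no evidence
#' of an independent peak on that side, and the run is zeroed as in
#' [standard_peel()]. Samples whose aberration does not include the peak are
#' never edited.
#'
#' @param contrib working contribution grid.
#' @param region c(first, last) marker indices of the reported region.
#' @param peak peak marker index within the region.
#' @param grid the [marker_grid()].
#' @param s persistence parameter (markers).
#' @param g_thres abort threshold on the G-score scale, normally obtained
#'   from [gscore_for_q()] on the focal-variant null; \code{Inf} reproduces
#'   the standard variant exactly.
#' @return the edited contribution grid.
#' @export
limited_peel <- function(contrib, region, peak, grid, s = 10, g_thres = Inf) {
  if (s < 0) stop("persistence parameter s must be >= 0")
  ch <- chrom_bounds_of(grid, peak)
  included <- which(contrib[peak, ] > 0)
  runs <- lapply(included, function(i) run_bounds(contrib[, i], peak, ch[1], ch[2]))

  peel_side <- function(contrib, edge, step, far_limit) {
    if (step * (far_limit - edge) <= 0) return(contrib)
    idx <- seq(edge, far_limit, by = step)
    len <- length(idx)
    # total score each walk marker would retain after subtracting G_r
    total_gn <- rowSums(contrib[idx, , drop = FALSE])
    run_len <- integer(length(included))  # walk markers inside each run
    gn_runs <- vector("list", length(included))
    for (k in seq_along(included)) {
      i <- included[k]
      run <- runs[[k]]
      run_end <- if (step > 0) run[2] else run[1]
      if (step * (run_end - edge) < 0) next  # run stops before this edge
      L <- abs(run_end - edge) + 1L
      dec <- limited_residual(contrib[idx[1:L], i], s)
      run_len[k] <- L
      gn_runs[[k]] <- dec$gn
      total_gn[1:L] <- total_gn[1:L] - contrib[idx[1:L], i] + dec$gn
    }
    # abort check starts one marker beyond the region edge
    hit <- if (len > 1) which(total_gn[-1] >= g_thres) else integer()
    if (length(hit) > 0) {
      t_abort <- hit[1] + 1L  # walk coordinate (edge = 1)
      for (k in seq_along(included)) {
        upto <- min(t_abort - 1L, run_len[k])
        if (upto >= 2L) {
          contrib[idx[2:upto], included[k]] <- gn_runs[[k]][2:upto]
        }
        # markers at/beyond the abort marker keep current contributions
      }
    } else {
      for (k in seq_along(included)) {
        if (run_len[k] >= 2L) {
          contrib[idx[2:run_len[k]], included[k]] <- 0
        }
      }
    }
    contrib
  }

  contrib <- peel_side(contrib, edge = region[2], step = +1L, far_limit = ch[2])
  contrib <- peel_side(contrib, edge = region[1], step = -1L, far_limit = ch[1])
  # the region itself: fully attributable to the peak, zeroed within each
  # included sample's run (leave-one-out extension may cross a zero gap of a
  # sample; markers outside its run are not part of its aberration)
  for (k in seq_along(included)) {
    i <- included[k]
    run <- runs[[k]]
    a <- max(region[1], run[1])
    b <- min(region[2], run[2])
    contrib[a:b, i] <- 0
  }
  contrib
}

#' Run one peel-off variant end to end
#'
#' The full discovery loop for one direction: compute the variant's G-score
#' track, freeze the permutation null, then iteratively (score -> p -> q ->
#' peak -> leave-one-out extension -> peel) until no marker is significant.
#' q-values are recomputed each iteration against the original null, which
#' models the chance aberration background and is not biased by the signal
#' already removed.
#'
#' For the limited variant, \code{g_thres} defaults to the score threshold
#' equivalent to \code{q_threshold} on the focal-variant null
#' ([gscore_for_q()]): the same cutoff judges a peak on baseline copy number
#' and a sub-peak within a broader region.
#'
#' @param cn a [cn_matrix()] (grid must carry arms for focal/limited/arm).
#' @param params a [score_params()].
#' @param direction \code{"AMP"} or \code{"DEL"}.
#' @param variant one of \code{"standard"}, \code{"focal"}, \code{"limited"},
#'   \code{"arm"}.
#' @param q_threshold significance cutoff on q-values (default 0.25).
#' @param s persistence parameter for the limited variant (markers).
#' @param g_thres abort threshold override for the limited variant
#'   (score units); \code{NULL} derives it from the focal null, \code{Inf}
#'   reproduces the standard variant.
#' @param null_method,n_bins,n_perm,seed passed to [build_null()].
#' @param extension \code{"union"} or \code{"intersection"} leave-one-out
#'   boundary combination.
#' @param verbose log one line per iteration.
#' @return data.frame of peak regions in discovery order with columns
#'   \code{direction}, \code{chrom}, \code{start_idx}, \code{end_idx},
#'   \code{peak_idx}, \code{start_bp}, \code{end_bp}, \code{q_peak},
#'   \code{g_peak}, \code{order}, \code{variant}.
#' @export
run_variant <- function(cn, params = score_params(),
                        direction = c("AMP", "DEL"),
                        variant = c("standard", "focal", "limited", "arm"),
                        q_threshold = 0.25, s = 10, g_thres = NULL,
                        null_method = c("convolution", "montecarlo"),
                        n_bins = 10000L, n_perm = 10000L, seed = NULL,
                        extension = c("union", "intersection"),
                        verbose = FALSE) {
  direction <- match.arg(direction)
  variant <- match.arg(variant)
  null_method <- match.arg(null_method)
  extension <- match.arg(extension)
  track <- if (variant == "focal") {
    compute_focal_gscore(cn, params, direction)
  } else {
    compute_gscore(cn, params, direction)
  }
  null <- build_null(track$contrib, method = null_method, n_bins = n_bins,
                     n_perm = n_perm, seed = seed)
  if (variant == "limited" && is.null(g_thres)) {
    ftrack <- compute_focal_gscore(cn, params, direction)
    fnull <- build_null(ftrack$contrib, method = null_method, n_bins = n_bins,
                        n_perm = n_perm, seed = seed)
    # no focal score can reach significance (e.g. no aberrations in this
    # direction, or focal signal indistinguishable from chance): the
    # equivalent score threshold is unattainable and the peel is unlimited
    g_thres <- tryCatch(gscore_for_q(q_threshold, fnull, nrow(cn$values)),
                        error = function(e) Inf)
    if (verbose) message("derived G_thres = ", format(g_thres, digits = 4))
  }
  grid <- cn$grid
  working <- track$contrib
  peaks <- list()
  spans_by_chrom <- list()
  max_iter <- nrow(working)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("internal error: peel-off loop did not terminate")
    score <- rowSums(working)
    q <- qvalues(pvalues(score, null))
    peak <- find_peak(q, score, q_threshold)
    if (is.na(peak)) break
    ckey <- grid$chrom[peak]
    prev <- spans_by_chrom[[ckey]]
    if (is.null(prev)) prev <- list()
    region <- extend_peak_loo(working, null, q, peak, grid,
                              prev_spans = prev, mode = extension)
    if (verbose) {
      message(sprintf("iter %d: %s peak at %s:%d (marker %d), q = %.3g, G = %.3g, region markers %d-%d",
                      iter, direction, ckey, grid$pos[peak], peak,
                      q[peak], score[peak], region[1], region[2]))
    }
    peaks[[iter]] <- data.frame(
      direction = direction, chrom = ckey,
      start_idx = region[1], end_idx = region[2], peak_idx = peak,
      start_bp = grid$pos[region[1]], end_bp = grid$pos[region[2]],
      q_peak = q[peak], g_peak = score[peak],
      order = iter, variant = variant, stringsAsFactors = FALSE)
    spans_by_chrom[[ckey]] <- c(prev, list(region))
    working <- switch(variant,
      standard = standard_peel(working, peak, grid),
      focal = standard_peel(working, peak, grid),
      arm = arm_peel(working, peak, grid),
      limited = limited_peel(working, region, peak, grid, s = s,
                             g_thres = g_thres))
    stopifnot(sum(working) < sum(score))  # peel must strictly reduce mass
  }
  if (length(peaks) == 0) {
    return(data.frame(direction = character(), chrom = character(),
                      start_idx = integer(), end_idx = integer(),
                      peak_idx = integer(), start_bp = integer(),
                      end_bp = integer(), q_peak = numeric(),
                      g_peak = numeric(), order = integer(),
                      variant = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, peaks)
}
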