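#' Scoring parameters
#'
#' Aberration thresholds on the log2-ratio scale. A copy-number value counts
#' toward the amplification G-score when it is at least \code{theta_amp}, and
#' toward the deletion G-score when it is at most \code{-theta_del}; the
#' boundary value itself is aberrant. Defaults of 0.1 are a conventional
#' operating point for segmented log2-ratio input.
#'
#' @param theta_amp amplification threshold (> 0), log2-ratio units.
#' @param theta_del deletion threshold (> 0), applied with the opposite sign.
#' @return a \code{score_params} list.
#' @export
score_params <- function(theta_amp = 0.1, theta_del = 0.1) {
  if (!is.numeric(theta_amp) || theta_amp <= 0 ||
      !is.numeric(theta_del) || theta_del <= 0) {
    stop("thresholds must be strictly positive")
  }
  structure(list(theta_amp = theta_amp, theta_del = theta_del),
            class = "score_params")
}

theta_for <- function(params, direction) {
  if (direction == "AMP") params$theta_amp else params$theta_del
}

#' Per-entry G-score contribution
#'
#' The G-score contribution of one (marker, sample) copy-number value under
#' an indicator-gated amplitude sum: for amplifications, \code{cn} if
#' \code{cn >= threshold} else 0; for deletions, \code{-cn} if
#' \code{cn <= -threshold} else 0. Missing values contribute 0.
#'
#' @param cn numeric vector of log2 ratios (NA allowed).
#' @param threshold positive threshold (log2 ratio); may be a scalar or one
#'   value per element of \code{cn}.
#' @param direction \code{"AMP"} or \code{"DEL"}.
#' @return non-negative numeric vector of contributions.
#' @export
cn_contrib <- function(cn, threshold, direction = c("AMP", "DEL")) {
  direction <- match.arg(direction)
  if (any(threshold <= 0)) stop("threshold must be > 0")
  out <- if (direction == "AMP") {
    ifelse(!is.na(cn) & cn >= threshold, cn, 0)
  } else {
    ifelse(!is.na(cn) & cn <= -threshold, -cn, 0)
  }
  as.numeric(out)
}

new_gscore_track <- function(contrib, direction, variant, grid, samples,
                             thresholds) {
  structure(list(direction = direction, variant = variant,
                 score = unname(rowSums(contrib)), contrib = contrib,
                 grid = grid, samples = samples, thresholds = thresholds),
            class = "gscore_track")
}

#' @export
print.gscore_track <- function(x, ...) {
  cat("gscore_track (", x$variant, ", ", x$direction, "): ",
      length(x$score), " markers, ", length(x$samples), " samples; max G = ",
      format(max(x$score), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Compute the standard G-score track
#'
#' The G-score of marker m is the sum over samples of the supra-threshold
#' copy number, G(m) = sum_i CN(m,i) I(CN(m,i) >= theta) for amplifications
#' (sign-mirrored for deletions). The per-(marker, sample) contribution grid
#' is retained because the peel-off step edits it sample-wise.
#'
#' @param cn a [cn_matrix()].
#' @param params a [score_params()].
#' @param direction \code{"AMP"} or \code{"DEL"}.
#' @return a \code{gscore_track}.
#' @export
compute_gscore <- function(cn, params = score_params(),
                           direction = c("AMP", "DEL")) {
  direction <- match.arg(direction)
  if (ncol(cn$values) == 0) stop("copy-number matrix has no samples")
  if (nrow(cn$values) == 0) stop("copy-number matrix has no markers")
  theta <- theta_for(params, direction)
  contrib <- matrix(cn_contrib(cn$values, theta, direction),
                    nrow = nrow(cn$values),
                    dimnames = dimnames(cn$values))
  new_gscore_track(contrib, direction, "standard", cn$grid, cn$samples,
                   rep(theta, length(cn$samples)))
}

#' Sample-specific focal thresholds
#'
#' Broad aberrations (at least half a chromosome arm) shift whole-arm
#' medians; the focal variant discounts them by raising each sample's
#' threshold to the standard threshold plus the largest arm median observed
#' in that sample (for deletions, minus the smallest). The focal threshold is
#' never laxer than the standard one: when all arm medians sit on the wrong
#' side of zero it is floored at the standard threshold.
#'
#' @param cn a [cn_matrix()] whose grid carries an \code{arm} column.
#' @param params a [score_params()].
#' @param direction \code{"AMP"} or \code{"DEL"}.
#' @return numeric vector, one positive threshold per sample (applied as
#'   \code{cn >= t} for AMP, \code{cn <= -t} for DEL).
#' @export
focal_thresholds <- function(cn, params = score_params(),
                             direction = c("AMP", "DEL")) {
  direction <- match.arg(direction)
  if (is.null(cn$grid$arm)) {
    stop("marker grid has no arm assignments; build it with an arm table")
  }
  theta <- theta_for(params, direction)
  armfac <- factor(paste0(cn$grid$chrom, cn$grid$arm))
  meds <- apply(cn$values, 2, function(v) {
    tapply(v, armfac, stats::median, na.rm = TRUE)
  })
  meds <- matrix(meds, ncol = ncol(cn$values))
  all_missing <- apply(is.na(meds), 2, all)
  if (any(all_missing)) {
    stop("sample has no non-missing data: ",
         cn$samples[which(all_missing)[1]])
  }
  if (direction == "AMP") {
    theta + pmax(0, apply(meds, 2, max, na.rm = TRUE))
  } else {
    theta + pmax(0, -apply(meds, 2, min, na.rm = TRUE))
  }
}

#' Compute the focal G-score track
#'
#' Same amplitude sum as [compute_gscore()] but gating each sample's values
#' with its own [focal_thresholds()], so contributions driven by broad
#' (arm-scale) events drop out and only high-level focal signal remains. The
#' focal track is marker-wise less than or equal to the standard track.
#'
#' @inheritParams compute_gscore
#' @return a \code{gscore_track} with variant \code{"focal"}.
#' @export
compute_focal_gscore <- function(cn, params = score_params(),
                                 direction = c("AMP", "DEL")) {
  direction <- match.arg(direction)
  if (ncol(cn$values) == 0) stop("copy-number matrix has no samples")
  thr <- focal_thresholds(cn, params, direction)
  contrib <- cn$values
  for (j in seq_along(thr)) {
    contrib[, j] <- cn_contrib(cn$values[, j], thr[j], direction)
  }
  new_gscore_track(contrib, direction, "focal", cn$grid, cn$samples, thr)
}
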