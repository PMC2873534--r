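# Peak discovery, leave-one-out extension and the four peel-off variants.

test_that("peak selection minimizes q with G and position tie-breaks", {
  expect_equal(find_peak(c(0.5, 0.01, 0.5), c(1, 1, 1), 0.25), 2L)
  expect_true(is.na(find_peak(c(0.3, 0.25, 0.9), c(1, 2, 1), 0.25)))
  # tie on q: larger G wins
  expect_equal(find_peak(c(0.01, 0.01), c(3, 5), 0.25), 2L)
  # tie on q and G: leftmost wins
  expect_equal(find_peak(c(0.01, 0.01), c(5, 5), 0.25), 1L)
})

test_that("residual decomposition accepts only sustained reductions", {
  # hand trace: dip accepted at s = 1
  d1 <- limited_residual(c(1.0, 0.4, 1.0, 1.0), s = 1)
  expect_equal(d1$gr, c(1.0, 0.4, 0.4, 0.4))
  expect_equal(d1$gn, c(0, 0, 0.6, 0.6))
  # the same transient dip is masked by the look-ahead window at s = 2
  d2 <- limited_residual(c(1.0, 0.4, 1.0, 1.0), s = 2)
  expect_equal(d2$gr, rep(1.0, 4))
  expect_equal(d2$gn, rep(0, 4))
  # s = 0 behaves like s = 1 (instantaneous dips accepted)
  expect_equal(limited_residual(c(1.0, 0.4, 1.0), s = 0)$gr,
               c(1.0, 0.4, 0.4))
  # flat run: nothing to release
  d3 <- limited_residual(rep(0.7, 5), s = 3)
  expect_equal(d3$gr, rep(0.7, 5))
  expect_equal(d3$gn, rep(0, 5))
  # sustained drop is accepted for any s <= its length
  d4 <- limited_residual(c(1.0, 0.3, 0.3, 0.3, 0.3), s = 4)
  expect_equal(d4$gr, c(1.0, rep(0.3, 4)))
  expect_error(limited_residual(c(1, 1), s = -1), ">= 0")
  # invariants: G_r non-increasing, G_r + G_n >= G, both non-negative
  set.seed(8)
  for (rep in 1:10) {
    g <- pmax(0, rnorm(30, mean = 0.5, sd = 0.4))
    s <- sample(0:6, 1)
    d <- limited_residual(g, s)
    expect_true(all(diff(d$gr) <= 1e-12))
    expect_true(all(d$gr >= 0) && all(d$gn >= 0))
    expect_true(all(d$gr + d$gn >= g - 1e-12))
  }
})

test_that("standard peel-off zeroes only runs containing the peak", {
  # sample 1: aberrant across the whole chromosome; sample 2: zero at the
  # peak; sample 3: two disjoint runs, peak in the first
  contrib <- cbind(rep(0.5, 10),
                   c(0, 0, 0, 0, 0, 0.5, 0.5, 0.5, 0.5, 0.5),
                   c(0.4, 0.4, 0.4, 0, 0.6, 0.6, 0, 0, 0, 0))
  cn <- toy_cn(matrix(0, 10, 3))
  peeled <- standard_peel(contrib, peak = 2L, grid = cn$grid)
  expect_true(all(peeled[, 1] == 0))                 # whole run zeroed
  expect_equal(peeled[, 2], contrib[, 2])            # untouched: 0 at peak
  expect_equal(peeled[1:3, 3], rep(0, 3))            # first run zeroed
  expect_equal(peeled[5:6, 3], c(0.6, 0.6))          # second run survives
})

test_that("arm peel-off zeroes the peak arm only, for included samples", {
  contrib <- cbind(rep(0.5, 20), c(rep(0, 10), rep(0.3, 10)))
  cn <- toy_cn(matrix(0, 20, 2))  # p arm: markers 1-10, q arm: 11-20
  peeled <- arm_peel(contrib, peak = 15L, grid = cn$grid)
  expect_equal(peeled[1:10, 1], rep(0.5, 10))  # p arm of sample 1 intact
  expect_equal(peeled[11:20, 1], rep(0, 10))
  expect_equal(peeled[11:20, 2], rep(0, 10))
  # locality: a second chromosome is never touched
  sim <- simulate_cohort(sim_spec(n_chrom = 2L, markers_per_chrom = 20L,
                                  n_samples = 3L, noise_sd = 0,
                                  events = data.frame(chrom = 1:2,
                                                      start = 1L, end = 20L,
                                                      amplitude = 0.5,
                                                      fraction = 1,
                                                      direction = "AMP"),
                                  seed = 2L))
  tr <- compute_gscore(sim$cn, score_params(), "AMP")
  peeled2 <- arm_peel(tr$contrib, peak = 5L, grid = sim$cn$grid)
  expect_equal(peeled2[21:40, ], tr$contrib[21:40, ])
})

test_that("limited peel-off degenerates to standard when no independent signal exists", {
  contrib <- cbind(c(0, 0.5, 0.5, 0.5, 0.5, 0.5, 0), rep(0, 7))
  cn <- toy_cn(matrix(0, 7, 2))
  std <- standard_peel(contrib, peak = 4L, grid = cn$grid)
  lim <- limited_peel(contrib, region = c(4L, 4L), peak = 4L, grid = cn$grid,
                      s = 2, g_thres = 0.2)
  # flat plateau: G_n == 0 everywhere, no abort regardless of threshold
  expect_equal(lim, std)
})

test_that("limited peel-off aborts at a recovered sub-peak and preserves it", {
  # plateau 0.5 with a stronger sub-region after a sustained dip
  g <- c(0, rep(0.5, 3), 1.2, 1.2, rep(0.5, 3), 1.0, 1.0, rep(0.5, 2), 0)
  contrib <- cbind(g, g)  # two identical samples
  cn <- toy_cn(matrix(0, length(g), 2))
  lim <- limited_peel(contrib, region = c(5L, 6L), peak = 5L, grid = cn$grid,
                      s = 2, g_thres = 0.9)
  # at the recovery marker (10), total G_n = 2 * (1.0 - 0.5) = 1.0 >= 0.9
  expect_equal(lim[10:14, 1], g[10:14])   # beyond abort: untouched
  expect_equal(lim[5:6, 1], c(0, 0))      # region zeroed
  expect_equal(lim[7:9, 1], rep(0, 3))    # dip reduced by G_r (0.5) to 0
  expect_equal(lim[2:4, 1], rep(0, 3))    # left side: no abort, zeroed
  # with an infinite threshold the result is exactly the standard peel
  lim_inf <- limited_peel(contrib, region = c(5L, 6L), peak = 5L,
                          grid = cn$grid, s = 2, g_thres = Inf)
  expect_equal(lim_inf, standard_peel(contrib, peak = 5L, grid = cn$grid))
})

test_that("leave-one-out extension recovers the underlying plateau", {
  # samples 1-2: broad plateau markers 5-12; sample 3: focal spike at 8
  v <- matrix(0, 24, 3)
  v[5:12, 1:2] <- 0.5
  v[8, 3] <- 1.0
  cn <- toy_cn(v)
  tr <- compute_gscore(cn, score_params(), "AMP")
  null <- build_null(tr$contrib, n_bins = 2000)
  q <- qvalues(pvalues(tr$score, null))
  peak <- find_peak(q, tr$score, 0.25)
  expect_equal(peak, 8L)
  region <- extend_peak_loo(tr$contrib, null, q, peak, cn$grid)
  # leaving sample 3 out leaves a flat plateau over 5-12
  expect_equal(region, c(5L, 12L))

  # identical samples: region equals the all-samples plateau
  v2 <- matrix(0, 16, 3)
  v2[6:9, ] <- 0.8
  cn2 <- toy_cn(v2)
  tr2 <- compute_gscore(cn2, score_params(), "AMP")
  null2 <- build_null(tr2$contrib, n_bins = 2000)
  q2 <- qvalues(pvalues(tr2$score, null2))
  p2 <- find_peak(q2, tr2$score, 0.25)
  expect_equal(extend_peak_loo(tr2$contrib, null2, q2, p2, cn2$grid),
               c(6L, 9L))

  # single-sample cohort: a permutation null built from the same profile
  # makes every q-value 1, so no peak can be declared (degenerate case)
  v3 <- matrix(0, 16, 1)
  v3[6:9, ] <- 0.8
  cn3 <- toy_cn(v3)
  peaks3 <- run_variant(cn3, variant = "standard", direction = "AMP")
  expect_equal(nrow(peaks3), 0L)
})

test_that("a planted focal event is recovered as a single peak", {
  events <- data.frame(chrom = 1L, start = 240L, end = 260L, amplitude = 1.0,
                       fraction = 0.4, direction = "AMP")
  sim <- simulate_cohort(sim_spec(n_chrom = 1L, markers_per_chrom = 500L,
                                  n_samples = 20L, noise_sd = 0.1,
                                  events = events, seed = 14L))
  peaks <- run_variant(sim$cn, variant = "standard", direction = "AMP")
  expect_equal(nrow(peaks), 1L)
  expect_true(peaks$start_idx <= 260L && peaks$end_idx >= 240L)
  # nothing on the deletion side
  del <- run_variant(sim$cn, variant = "standard", direction = "DEL")
  expect_equal(nrow(del), 0L)
})

test_that("peel steps never increase contributions and reported spans do not overlap", {
  sim <- variant_cohort(seed = 99L)
  for (variant in c("standard", "focal", "limited", "arm")) {
    peaks <- run_variant(sim$cn, variant = variant, direction = "AMP", s = 3)
    if (nrow(peaks) >= 2) {
      for (ch in unique(peaks$chrom)) {
        p <- peaks[peaks$chrom == ch, , drop = FALSE]
        p <- p[order(p$start_idx), , drop = FALSE]
        if (nrow(p) >= 2) {
          expect_true(all(p$start_idx[-1] > p$end_idx[-nrow(p)]))
        }
      }
    }
    expect_true(all(peaks$q_peak < 0.25))
    expect_true(all(peaks$end_idx >= peaks$start_idx))
  }
})
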