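# Readers, writers and the coordinate conventions they must preserve.

test_that("marker matrix reading validates, sorts and flags missing data", {
  df <- data.frame(marker = c("m1", "m2", "m3"), chrom = "1",
                   pos = c(100L, 200L, 300L),
                   A = c("0.1", "NA", "-0.3"), B = c("0.2", "0.4", "x"),
                   stringsAsFactors = FALSE)
  path <- write_matrix_fixture(df)
  cn <- read_marker_matrix(path)
  expect_identical(dim(cn), c(3L, 2L))
  expect_true(is.na(cn$values["m2", "A"]))
  expect_true(is.na(cn$values["m3", "B"]))
  expect_equal(cn$values["m1", "B"], 0.2)

  # duplicated marker id names the offender
  df_dup <- df
  df_dup$marker[2] <- "m1"
  expect_error(read_marker_matrix(write_matrix_fixture(df_dup)),
               "duplicate marker id: m1")

  # unsorted positions: error by default, sortable on request
  df_rev <- df[c(2, 1, 3), ]
  p_rev <- write_matrix_fixture(df_rev)
  expect_error(read_marker_matrix(p_rev), "not sorted")
  expect_warning(cn2 <- read_marker_matrix(p_rev, unsorted = "sort"),
                 "reordering")
  expect_identical(cn2$grid$marker, c("m1", "m2", "m3"))
  expect_equal(cn2$values["m2", "B"], 0.4)
})

test_that("segment projection follows 1-based inclusive containment", {
  grid <- marker_grid(data.frame(marker = c("a", "b"), chrom = "1",
                                 pos = c(150L, 250L)))
  segs <- segment_set(data.frame(sample = "S1", chrom = "1",
                                 start = 100L, end = 200L, value = 0.5))
  cn <- project_segments(segs, grid)
  expect_equal(cn$values["a", "S1"], 0.5)
  expect_true(is.na(cn$values["b", "S1"]))

  # abutting segments: boundary markers belong to their containing segment
  grid2 <- marker_grid(data.frame(marker = c("a", "b"), chrom = "1",
                                  pos = c(200L, 201L)))
  segs2 <- segment_set(data.frame(sample = "S1", chrom = "1",
                                  start = c(100L, 201L), end = c(200L, 300L),
                                  value = c(0.1, 0.9)))
  cn2 <- project_segments(segs2, grid2)
  expect_equal(unname(cn2$values[, "S1"]), c(0.1, 0.9))

  # overlapping segments of one sample are rejected with the conflict named
  expect_error(
    segment_set(data.frame(sample = "S1", chrom = "1",
                           start = c(100L, 150L), end = c(200L, 250L),
                           value = 0)),
    "overlapping segments.*100-200.*150-250")
})

test_that("SEG round-trip reproduces the matrix on covered markers", {
  set.seed(42)
  sim <- simulate_cohort(sim_spec(n_chrom = 2L, markers_per_chrom = 40L,
                                  n_samples = 3L, noise_sd = 0,
                                  events = data.frame(chrom = 1L, start = 5L,
                                                      end = 15L,
                                                      amplitude = 0.8,
                                                      fraction = 1,
                                                      direction = "AMP"),
                                  seed = 7L))
  dir <- withr::local_tempdir()
  seg_path <- file.path(dir, "x.seg")
  write_seg(sim$cn, seg_path)
  segs <- read_seg(seg_path)
  back <- project_segments(segs, sim$cn$grid)
  expect_equal(back$values[, sim$cn$samples], sim$cn$values,
               tolerance = 1e-12)
})

test_that("SEG reader tolerates 5-column dialect and missing header", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "nohead.seg")
  writeLines(c("S1\tchr1\t100\t200\t0.5", "S1\t1\t300\t400\t-0.25"), path)
  segs <- read_seg(path)
  expect_equal(nrow(segs), 2L)
  expect_identical(segs$chrom, c("1", "1"))  # chr prefix stripped
  expect_equal(segs$value, c(0.5, -0.25))
})

test_that("arm assignment drops centromere-gap markers and rejects unknown chromosomes", {
  markers <- data.frame(marker = c("m1", "m2", "m3"), chrom = "1",
                        pos = c(100L, 5100L, 20000L))
  arms <- data.frame(chrom = "1", arm = c("p", "q"),
                     start = c(1L, 10000L), end = c(5000L, 30000L))
  expect_message(g <- marker_grid(markers, arms = arms), "centromere")
  expect_identical(g$marker, c("m1", "m3"))
  expect_identical(g$arm, c("p", "q"))

  markers2 <- data.frame(marker = "m1", chrom = "2", pos = 100L)
  expect_error(marker_grid(markers2, arms = arms), "chromosome 2")
})

test_that("peak reports round-trip and tolerate geneless peaks", {
  peaks <- data.frame(direction = "AMP", chrom = c("1", "2"),
                      start_idx = c(5L, 9L), end_idx = c(9L, 9L),
                      peak_idx = c(6L, 9L),
                      start_bp = c(5000L, 9000L), end_bp = c(9000L, 9000L),
                      q_peak = c(0.01, 0.2), g_peak = c(3, 2),
                      order = 1:2, variant = "limited",
                      stringsAsFactors = FALSE)
  genes <- gene_table(data.frame(symbol = "GENE1", chrom = "1",
                                 start = 6000L, end = 7000L))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "peaks.tsv")
  write_peak_report(peaks, genes, path)
  back <- read_peak_report(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$genes[1], "GENE1")
  expect_true(is.na(back$genes[2]) || back$genes[2] == "")
  expect_equal(back$start[1], 5000L)
  expect_equal(back$end[2], 9000L)
})

test_that("IGV and BED tracks use the expected coordinate conventions", {
  vals <- matrix(c(0.5, 0), nrow = 2,
                 dimnames = list(NULL, "S1"))
  cn <- toy_cn(vals, spacing = 100L)
  track <- compute_gscore(cn, score_params(), "AMP")
  peaks <- data.frame(direction = "AMP", chrom = "1", start_idx = 1L,
                      end_idx = 2L, peak_idx = 1L, start_bp = 100L,
                      end_bp = 200L, q_peak = 0.1, g_peak = 0.5,
                      order = 1L, variant = "standard",
                      stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  paths <- write_igv_tracks(track, peaks, cn$grid, file.path(dir, "t"))
  igv <- read.delim(paths[["igv"]])
  expect_equal(nrow(igv), 2L)  # one row per marker
  bed <- readLines(paths[["bed"]])
  expect_match(bed[1], "^track")
  # 1-based inclusive [100, 200] -> BED 0-based half-open [99, 200)
  expect_identical(strsplit(bed[2], "\t")[[1]][2:3], c("99", "200"))

  # empty peak list still yields a valid header-only BED
  paths2 <- write_igv_tracks(track, peaks[0, ], cn$grid, file.path(dir, "e"))
  expect_identical(length(readLines(paths2[["bed"]])), 1L)
})
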