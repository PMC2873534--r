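# End-to-end pipeline: I/O -> scoring -> significance -> peel-off ->
# annotation, with deterministic seeding and a run log.

#' Pipeline configuration
#'
#' Collects every tunable of a run. Either \code{matrix_path} or both
#' \code{seg_path} and \code{markers_path} must be given.
#'
#' @param matrix_path marker-level copy-number matrix (tab-delimited).
#' @param seg_path SEG file of segmented copy number.
#' @param markers_path marker table (marker, chrom, pos) used with
#'   \code{seg_path}.
#' @param arms_path chromosome-arm table (required for focal/limited/arm).
#' @param genes_path optional gene location table for peak annotation.
#' @param variant peel-off variant.
#' @param theta_amp,theta_del aberration thresholds (log2 ratio).
#' @param q_threshold significance cutoff on q-values.
#' @param s persistence parameter for limited peel-off (markers).
#' @param null_method,n_bins,n_perm null-distribution settings.
#' @param seed RNG seed for every stochastic step.
#' @param directions analyses to run (both by default).
#' @param out_dir output directory (created if absent).
#' @return a \code{run_config} list.
#' @export
run_config <- function(matrix_path = NULL, seg_path = NULL,
                       markers_path = NULL, arms_path = NULL,
                       genes_path = NULL,
                       variant = c("standard", "focal", "limited", "arm"),
                       theta_amp = 0.1, theta_del = 0.1, q_threshold = 0.25,
                       s = 10L, null_method = c("convolution", "montecarlo"),
                       n_bins = 10000L, n_perm = 10000L, seed = 1L,
                       directions = c("AMP", "DEL"), out_dir = ".") {
  variant <- match.arg(variant)
  null_method <- match.arg(null_method)
  directions <- match.arg(directions, several.ok = TRUE)
  if (is.null(matrix_path) && (is.null(seg_path) || is.null(markers_path))) {
    stop("provide matrix_path, or seg_path together with markers_path")
  }
  structure(list(matrix_path = matrix_path, seg_path = seg_path,
                 markers_path = markers_path, arms_path = arms_path,
                 genes_path = genes_path, variant = variant,
                 theta_amp = theta_amp, theta_del = theta_del,
                 q_threshold = q_threshold, s = as.integer(s),
                 null_method = null_method, n_bins = as.integer(n_bins),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 directions = directions, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis
#'
#' Reads the inputs, runs the amplification and deletion analyses for the
#' configured variant, and writes to the output directory: a peak report per
#' direction, per-marker G/p/q track tables, IGV and BED tracks, an echo of
#' the configuration, and a log with the per-iteration discovery trace.
#'
#' @param config a [run_config()].
#' @return invisibly, a named list of peak data.frames by direction.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logf <- function(...) {
    writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...), log_con)
  }
  logf("cnapeel ", as.character(utils::packageVersion("cnapeel")),
       " | variant=", config$variant, " seed=", config$seed)

  # configuration echo
  cfg <- config
  class(cfg) <- NULL
  writeLines(paste0(names(cfg), ": ",
                    vapply(cfg, function(v) paste(format(v), collapse = ","),
                           character(1))),
             file.path(config$out_dir, "config.txt"))

  arms <- if (!is.null(config$arms_path)) read_arm_table(config$arms_path)
  stage <- "genome_io"
  result <- tryCatch({
    cn <- if (!is.null(config$matrix_path)) {
      read_marker_matrix(config$matrix_path, arms = arms)
    } else {
      markers <- utils::read.delim(config$markers_path,
                                   stringsAsFactors = FALSE)
      names(markers)[1:3] <- c("marker", "chrom", "pos")
      grid <- marker_grid(markers, arms = arms)
      project_segments(read_seg(config$seg_path), grid)
    }
    genes <- if (!is.null(config$genes_path)) read_gene_table(config$genes_path)
    params <- score_params(config$theta_amp, config$theta_del)
    logf("loaded ", nrow(cn$values), " markers x ", ncol(cn$values), " samples")

    peaks_by_dir <- list()
    for (direction in config$directions) {
      stage <- paste0("run_variant[", direction, "]")
      peaks <- withCallingHandlers(
        run_variant(cn, params, direction = direction,
                    variant = config$variant,
                    q_threshold = config$q_threshold, s = config$s,
                    null_method = config$null_method,
                    n_bins = config$n_bins, n_perm = config$n_perm,
                    seed = config$seed, verbose = TRUE),
        message = function(m) {
          logf(direction, ": ", conditionMessage(m))
          invokeRestart("muffleMessage")
        })
      peaks_by_dir[[direction]] <- peaks
      stage <- paste0("output[", direction, "]")
      track <- if (config$variant == "focal") {
        compute_focal_gscore(cn, params, direction)
      } else {
        compute_gscore(cn, params, direction)
      }
      null <- build_null(track$contrib, method = config$null_method,
                         n_bins = config$n_bins, n_perm = config$n_perm,
                         seed = config$seed)
      p <- suppressMessages(pvalues(track, null))
      marker_tab <- data.frame(marker = cn$grid$marker, chrom = cn$grid$chrom,
                               pos = cn$grid$pos, g_score = track$score,
                               p_value = p, q_value = qvalues(p))
      utils::write.table(marker_tab,
                         file.path(config$out_dir,
                                   paste0("markers_", direction, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_peak_report(peaks, genes,
                        file.path(config$out_dir,
                                  paste0("peaks_", direction, ".tsv")))
      write_igv_tracks(track, peaks, cn$grid,
                       file.path(config$out_dir, paste0("track_", direction)))
      logf(direction, ": ", nrow(peaks), " peak(s) reported")
    }
    peaks_by_dir
  }, error = function(e) {
    logf("ERROR in stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed in stage ", stage, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
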