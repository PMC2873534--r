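#' Read a marker-level copy-number matrix
#'
#' Expects a tab-delimited file with a header row: the first three columns
#' are marker id, chromosome and position, followed by one column of
#' segmented log2 ratios per sample. Non-numeric cells (e.g. \code{"NA"},
#' \code{""}) become missing entries.
#'
#' @param path file path.
#' @param arms optional arm table used to resolve marker arms at load.
#' @param unsorted passed to [marker_grid()]: \code{"error"} or \code{"sort"}.
#' @return a [cn_matrix()].
#' @export
read_marker_matrix <- function(path, arms = NULL, unsorted = c("error", "sort")) {
  unsorted <- match.arg(unsorted)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 4) {
    stop("marker matrix needs >= 4 columns (marker, chrom, pos, samples): ", path)
  }
  markers <- data.frame(marker = tab[[1]], chrom = tab[[2]],
                        pos = suppressWarnings(as.integer(tab[[3]])),
                        stringsAsFactors = FALSE)
  samples <- colnames(tab)[-(1:3)]
  vals <- suppressWarnings(
    vapply(tab[-(1:3)], function(col) as.numeric(col), numeric(nrow(tab)))
  )
  vals <- matrix(vals, nrow = nrow(tab), dimnames = list(markers$marker, samples))
  grid <- marker_grid(markers, arms = arms, unsorted = unsorted)
  # grid may have dropped or reordered markers; realign value rows by id
  vals <- vals[match(grid$marker, markers$marker), , drop = FALSE]
  cn_matrix(vals, grid, samples)
}

#' Read a SEG file of segmented copy number
#'
#' Accepts the common SEG dialect: tab-delimited columns sample, chromosome,
#' start, end, [number of markers,] segment value; a header line is detected
#' and skipped automatically. Coordinates are 1-based inclusive. Segments of
#' one sample on one chromosome must not overlap.
#'
#' @param path file path.
#' @return a \code{segment_set}: data.frame with columns \code{sample},
#'   \code{chrom}, \code{start}, \code{end}, \code{value}.
#' @export
read_seg <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 5) stop("SEG file needs >= 5 columns: ", path)
  # header detection: start column of the first row non-numeric
  first_start <- suppressWarnings(as.numeric(raw[1, 3]))
  if (is.na(first_start)) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0) stop("SEG file has no data rows: ", path)
  value_col <- if (ncol(raw) >= 6) 6L else 5L
  segs <- data.frame(
    sample = raw[[1]],
    chrom = normalize_chrom(raw[[2]]),
    start = suppressWarnings(as.integer(raw[[3]])),
    end = suppressWarnings(as.integer(raw[[4]])),
    value = suppressWarnings(as.numeric(raw[[value_col]])),
    stringsAsFactors = FALSE
  )
  segment_set(segs)
}

#' Construct a validated segment set
#'
#' @param segs data.frame with columns \code{sample}, \code{chrom},
#'   \code{start}, \code{end}, \code{value}.
#' @return a \code{segment_set}.
#' @export
segment_set <- function(segs) {
  need <- c("sample", "chrom", "start", "end", "value")
  if (!all(need %in% names(segs))) {
    stop("segment set needs columns: ", paste(need, collapse = ", "))
  }
  segs <- segs[need]
  segs$chrom <- normalize_chrom(segs$chrom)
  if (anyNA(segs$start) || anyNA(segs$end)) stop("non-numeric segment coordinates")
  if (any(segs$start > segs$end)) {
    i <- which(segs$start > segs$end)[1]
    stop("segment start > end for sample ", segs$sample[i],
         " at ", segs$chrom[i], ":", segs$start[i], "-", segs$end[i])
  }
  key <- interaction(segs$sample, segs$chrom, drop = TRUE)
  for (k in levels(key)) {
    s <- segs[key == k, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1) {
      bad <- which(s$end[-nrow(s)] >= s$start[-1])
      if (length(bad) > 0) {
        i <- bad[1]
        stop("overlapping segments for sample ", s$sample[i], " on chromosome ",
             s$chrom[i], ": ", s$start[i], "-", s$end[i], " and ",
             s$start[i + 1], "-", s$end[i + 1])
      }
    }
  }
  rownames(segs) <- NULL
  class(segs) <- c("segment_set", "data.frame")
  segs
}

#' Project segments onto a marker grid
#'
#' Each marker takes the value of the segment containing its position
#' (1-based inclusive containment). Markers covered by no segment of a sample
#' are missing for that sample.
#'
#' @param segs a \code{segment_set}.
#' @param grid a [marker_grid()].
#' @return a [cn_matrix()].
#' @export
project_segments <- function(segs, grid) {
  if (!inherits(grid, "marker_grid")) stop("grid must be a marker_grid")
  samples <- unique(segs$sample)
  vals <- matrix(NA_real_, nrow = nrow(grid), ncol = length(samples),
                 dimnames = list(grid$marker, samples))
  for (si in seq_along(samples)) {
    s_all <- segs[segs$sample == samples[si], , drop = FALSE]
    for (ch in unique(s_all$chrom)) {
      s <- s_all[s_all$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      midx <- which(grid$chrom == ch)
      if (length(midx) == 0) next
      pos <- grid$pos[midx]
      j <- findInterval(pos, s$start)
      hit <- j >= 1 & pos <= s$end[pmax(j, 1L)]
      vals[midx[hit], si] <- s$value[j[hit]]
    }
  }
  cn_matrix(vals, grid, samples)
}

#' Read a gene location table
#'
#' Tab-delimited with header: symbol, chromosome, start, end (1-based
#' inclusive).
#'
#' @param path file path.
#' @return data.frame with columns \code{symbol}, \code{chrom}, \code{start},
#'   \code{end}.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(tab)[1:4] <- c("symbol", "chrom", "start", "end")
  gene_table(tab)
}

#' Construct a validated gene table
#' @param genes data.frame with columns symbol, chrom, start, end.
#' @return validated data.frame.
#' @export
gene_table <- function(genes) {
  need <- c("symbol", "chrom", "start", "end")
  if (!all(need %in% names(genes))) {
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  }
  genes <- genes[need]
  genes$chrom <- normalize_chrom(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start > genes$end)) stop("gene start > end")
  genes
}

#' Read a chromosome-arm table
#'
#' Tab-delimited with header: chromosome, arm ("p"/"q"), start, end.
#'
#' @param path file path.
#' @return validated arm table data.frame.
#' @export
read_arm_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(tab)[1:4] <- c("chrom", "arm", "start", "end")
  validate_arm_table(tab)
}

#' Write a peak report
#'
#' One row per reported peak region: direction, chromosome, genomic span,
#' a compact span string, q-value at the peak, discovery order, variant, and
#' the symbols of genes overlapping the span.
#'
#' @param peaks peak data.frame as returned by [run_variant()].
#' @param genes gene table (or NULL to skip gene annotation).
#' @param path output path (tab-delimited).
#' @export
write_peak_report <- function(peaks, genes, path) {
  rep_df <- data.frame(
    direction = peaks$direction,
    chrom = peaks$chrom,
    start = peaks$start_bp,
    end = peaks$end_bp,
    span = sprintf("%s:%d-%d", peaks$chrom, peaks$start_bp, peaks$end_bp),
    q_value = peaks$q_peak,
    order = peaks$order,
    variant = peaks$variant,
    genes = vapply(seq_len(nrow(peaks)), function(i) {
      if (is.null(genes)) return("")
      paste(genes_in_peak(peaks[i, , drop = FALSE], genes), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(rep_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a peak report
#' @param path path written by [write_peak_report()].
#' @return data.frame of the report rows.
#' @export
read_peak_report <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Write IGV-compatible output tracks
#'
#' Emits \code{<prefix>.gscore.igv}, a marker-value track of G-scores (one
#' row per marker: chromosome, start, end, feature, value; 0-based half-open
#' single-base intervals), and \code{<prefix>.peaks.bed}, a BED track of peak
#' regions (0-based half-open).
#'
#' @param gscore a \code{gscore_track}.
#' @param peaks peak data.frame (may have zero rows).
#' @param grid the [marker_grid()] the track lives on.
#' @param path_prefix output path prefix.
#' @return invisibly, the two paths written.
#' @export
write_igv_tracks <- function(gscore, peaks, grid, path_prefix) {
  igv_path <- paste0(path_prefix, ".gscore.igv")
  bed_path <- paste0(path_prefix, ".peaks.bed")
  track_name <- paste0("Gscore_", gscore$direction)
  igv <- data.frame(Chromosome = paste0("chr", grid$chrom),
                    Start = grid$pos - 1L, End = grid$pos,
                    Feature = grid$marker, value = gscore$score,
                    stringsAsFactors = FALSE)
  names(igv)[5] <- track_name
  utils::write.table(igv, igv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed_lines <- paste0("track name=peaks_", gscore$direction,
                      " description=\"peak regions (", gscore$direction, ")\"")
  if (!is.null(peaks) && nrow(peaks) > 0) {
    bed_lines <- c(bed_lines,
                   paste(paste0("chr", peaks$chrom),
                         peaks$start_bp - 1L, peaks$end_bp,
                         paste0("peak_", peaks$order), sep = "\t"))
  }
  writeLines(bed_lines, bed_path)
  invisible(c(igv = igv_path, bed = bed_path))
}

#' Write a cn_matrix as a tab-delimited marker matrix
#'
#' Inverse of [read_marker_matrix()]; useful for exporting simulated cohorts.
#'
#' @param cn a [cn_matrix()].
#' @param path output path.
#' @export
write_marker_matrix <- function(cn, path) {
  out <- data.frame(marker = cn$grid$marker, chrom = cn$grid$chrom,
                    pos = cn$grid$pos, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cn$values))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cn_matrix as a SEG file
#'
#' Collapses runs of identical consecutive values per sample and chromosome
#' into segments; missing stretches produce no segment.
#'
#' @param cn a [cn_matrix()].
#' @param path output path.
#' @export
write_seg <- function(cn, path) {
  rows <- list()
  bl <- chrom_blocks(cn$grid)
  for (si in seq_along(cn$samples)) {
    for (bi in seq_len(nrow(bl))) {
      idx <- bl$first[bi]:bl$last[bi]
      v <- cn$values[idx, si]
      pos <- cn$grid$pos[idx]
      r <- rle(ifelse(is.na(v), "NA", format(v, digits = 17)))
      last <- cumsum(r$lengths)
      first <- c(1L, head(last, -1L) + 1L)
      keep <- r$values != "NA"
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample = cn$samples[si], chrom = bl$chrom[bi],
        start = pos[first[keep]], end = pos[last[keep]],
        num_markers = r$lengths[keep],
        value = v[first[keep]], stringsAsFactors = FALSE)
    }
  }
  seg <- do.call(rbind, rows)
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
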