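#' @keywords internal
#' @importFrom utils head
#' @importFrom stats median
"_PACKAGE"

#' Normalize chromosome names
#'
#' Strips a leading \code{"chr"} prefix so that \code{"chr1"} and \code{"1"}
#' compare equal. X and Y are kept as-is.
#'
#' @param x character or factor vector of chromosome labels.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x))
}

# Sort key for chromosomes: numeric first in numeric order, then X, Y,
# then anything else alphabetically.
chrom_rank <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  r <- ifelse(!is.na(n), n,
              ifelse(chrom == "X", 1e6,
                     ifelse(chrom == "Y", 1e6 + 1, NA_real_)))
  other <- is.na(r)
  if (any(other)) {
    r[other] <- 2e6 + as.numeric(factor(chrom[other], levels = sort(unique(chrom[other]))))
  }
  r
}

is_mito <- function(chrom) chrom %in% c("M", "MT", "mt", "m")

#' Build a validated marker grid
#'
#' The marker grid is the coordinate system every per-marker track lives on:
#' an ordered table of genomic probe positions. Markers are sorted by
#' (chromosome, position); positions must be strictly increasing within a
#' chromosome and marker identifiers must be unique. When an arm table is
#' supplied every marker is assigned to its chromosome arm; markers falling
#' into neither arm interval (centromere gaps) are dropped with a message,
#' since arm medians must be well defined for focal scoring. Mitochondrial
#' markers are excluded by default.
#'
#' @param markers data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos} (1-based base-pair position).
#' @param arms optional arm table (see [read_arm_table()]); if supplied, an
#'   \code{arm} column ("p"/"q") is resolved for every marker.
#' @param unsorted what to do if input positions are not sorted:
#'   \code{"error"} (default) or \code{"sort"} (reorder with a warning).
#' @param drop_mito drop mitochondrial markers (default TRUE).
#' @return a \code{marker_grid}: data.frame with columns \code{marker},
#'   \code{chrom}, \code{pos} and (if arms were given) \code{arm}.
#' @export
marker_grid <- function(markers, arms = NULL, unsorted = c("error", "sort"),
                        drop_mito = TRUE) {
  unsorted <- match.arg(unsorted)
  stopifnot(is.data.frame(markers))
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(markers))) {
    stop("marker table must have columns: ", paste(need, collapse = ", "))
  }
  g <- data.frame(marker = as.character(markers$marker),
                  chrom = normalize_chrom(markers$chrom),
                  pos = as.integer(markers$pos),
                  stringsAsFactors = FALSE)
  if (anyNA(g$pos) || any(g$pos < 1)) {
    stop("marker positions must be integers >= 1")
  }
  dup <- duplicated(g$marker)
  if (any(dup)) {
    stop("duplicate marker id: ", g$marker[which(dup)[1]])
  }
  if (drop_mito && any(is_mito(g$chrom))) {
    n_mt <- sum(is_mito(g$chrom))
    message("dropping ", n_mt, " mitochondrial marker(s)")
    g <- g[!is_mito(g$chrom), , drop = FALSE]
  }
  ord <- order(chrom_rank(g$chrom), g$pos)
  if (!identical(ord, seq_len(nrow(g)))) {
    if (unsorted == "error") {
      stop("markers are not sorted by (chromosome, position); ",
           "pass unsorted = \"sort\" to reorder")
    }
    warning("markers were not sorted by (chromosome, position); reordering")
    g <- g[ord, , drop = FALSE]
  }
  # strictly increasing positions within each chromosome
  same <- g$chrom[-1] == g$chrom[-nrow(g)]
  if (nrow(g) > 1 && any(same & diff(g$pos) <= 0)) {
    i <- which(same & diff(g$pos) <= 0)[1]
    stop("positions not strictly increasing on chromosome ", g$chrom[i + 1],
         " near marker ", g$marker[i + 1])
  }
  if (!is.null(arms)) {
    g$arm <- assign_arms(g, arms)
    unmapped <- is.na(g$arm)
    if (any(unmapped)) {
      message("dropping ", sum(unmapped),
              " marker(s) in no arm interval (centromere gap)")
      g <- g[!unmapped, , drop = FALSE]
    }
  }
  rownames(g) <- NULL
  class(g) <- c("marker_grid", "data.frame")
  g
}

# Resolve the arm ("p"/"q") of each marker; NA for markers in neither
# interval. Errors if a chromosome present in the grid has no arm rows.
assign_arms <- function(grid, arms) {
  arms <- validate_arm_table(arms)
  out <- rep(NA_character_, nrow(grid))
  for (ch in unique(grid$chrom)) {
    a <- arms[arms$chrom == ch, , drop = FALSE]
    if (nrow(a) == 0) {
      stop("no arm definitions for chromosome ", ch)
    }
    idx <- which(grid$chrom == ch)
    for (j in seq_len(nrow(a))) {
      hit <- grid$pos[idx] >= a$start[j] & grid$pos[idx] <= a$end[j]
      out[idx[hit]] <- a$arm[j]
    }
  }
  out
}

validate_arm_table <- function(arms) {
  stopifnot(is.data.frame(arms))
  need <- c("chrom", "arm", "start", "end")
  if (!all(need %in% names(arms))) {
    stop("arm table must have columns: ", paste(need, collapse = ", "))
  }
  arms$chrom <- normalize_chrom(arms$chrom)
  arms$arm <- as.character(arms$arm)
  if (!all(arms$arm %in% c("p", "q"))) stop("arm labels must be 'p' or 'q'")
  if (any(arms$start > arms$end)) stop("arm start > end")
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (nrow(a) > 1 && any(a$end[-nrow(a)] >= a$start[-1])) {
      stop("overlapping arm intervals on chromosome ", ch)
    }
  }
  arms
}

# Per-chromosome first/last row index of a grid (grids are sorted, so each
# chromosome occupies one contiguous block).
chrom_blocks <- function(grid) {
  r <- rle(grid$chrom)
  last <- cumsum(r$lengths)
  data.frame(chrom = r$values,
             first = c(1L, head(last, -1L) + 1L),
             last = last,
             stringsAsFactors = FALSE)
}

chrom_bounds_of <- function(grid, idx) {
  bl <- chrom_blocks(grid)
  row <- bl[bl$first <= idx & bl$last >= idx, , drop = FALSE]
  c(row$first[1], row$last[1])
}

#' Construct a copy-number matrix
#'
#' Bundles a markers-by-samples grid of segmented log2 copy-number ratios with
#' its [marker_grid()]. Values are centered at 0 for diploid (log2 ratio
#' scale); missing entries are explicit \code{NA}, never silently zero.
#'
#' @param values numeric matrix, one row per marker (in grid order), one
#'   column per sample.
#' @param grid a \code{marker_grid}.
#' @param samples sample identifiers; defaults to \code{colnames(values)}.
#' @return a \code{cn_matrix} object.
#' @export
cn_matrix <- function(values, grid, samples = colnames(values)) {
  values <- as.matrix(values)
  if (!inherits(grid, "marker_grid")) stop("grid must be a marker_grid")
  if (nrow(values) != nrow(grid)) {
    stop("value matrix has ", nrow(values), " rows but grid has ",
         nrow(grid), " markers")
  }
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(values)))
  if (length(samples) != ncol(values)) stop("one sample id per column required")
  storage.mode(values) <- "double"
  dimnames(values) <- list(grid$marker, samples)
  structure(list(values = values, grid = grid, samples = samples),
            class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat("cn_matrix: ", nrow(x$values), " markers x ", ncol(x$values),
      " samples on ", length(unique(x$grid$chrom)), " chromosome(s)\n", sep = "")
  cat("  missing entries: ", sum(is.na(x$values)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cn_matrix <- function(x) dim(x$values)
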