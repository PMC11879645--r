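#' Binned Hi-C contact matrix for one chromosome
#'
#' Constructs the basic container used throughout the package: a symmetric,
#' non-negative, integer-valued contact matrix at a fixed bin resolution.
#' Counts are stored sparsely (whole chromosomes at 10 kb are large and mostly
#' zero); windows are densified on extraction.
#'
#' @param counts square matrix of contact counts (base matrix or any
#'   `Matrix::Matrix`); must be symmetric, non-negative and integer-valued.
#' @param chrom chromosome name.
#' @param resolution bin size in bp (default 10000).
#' @return An object of class `binned_contacts` with fields `chrom`,
#'   `resolution`, `n_bins` and `counts` (a sparse `dgCMatrix`).
#' @export
binned_contacts <- function(counts, chrom = "chr1", resolution = 10000L) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != ncol(counts)) {
    stop("contact matrix must be square")
  }
  if (!Matrix::isSymmetric(counts)) {
    stop("contact matrix must be symmetric")
  }
  v <- counts@x
  if (any(v < 0)) stop("contact counts must be non-negative")
  if (any(v != round(v))) stop("contact counts must be integer-valued")
  structure(
    list(chrom = as.character(chrom), resolution = as.integer(resolution),
         n_bins = nrow(counts), counts = counts),
    class = "binned_contacts"
  )
}

#' @export
print.binned_contacts <- function(x, ...) {
  nz <- length(x$counts@x)
  cat(sprintf("binned_contacts: %s, %d bins @ %d bp, %d stored cells, total %.0f\n",
              x$chrom, x$n_bins, x$resolution, nz, sum(x$counts@x)))
  invisible(x)
}

#' Read a contact matrix from sparse triplet text
#'
#' Reads tab-separated rows `bin_i<TAB>bin_j<TAB>count` with 0-based bin
#' indices and returns a symmetrized [binned_contacts] object: every triplet
#' populates both (i, j) and (j, i); unlisted cells are zero.
#'
#' @param path file path.
#' @param chrom chromosome name to attach.
#' @param resolution bin size in bp.
#' @param n_bins number of bins; if `NULL`, inferred as `max(bin) + 1`.
#' @param format input format; only `"triplet_text"` is supported.
#' @return A [binned_contacts] object.
#' @export
load_contacts <- function(path, chrom = "chr1", resolution = 10000L,
                          n_bins = NULL, format = "triplet_text") {
  format <- match.arg(format, "triplet_text")
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("bin_i", "bin_j", "count"),
                          colClasses = "numeric")
  bad <- which(df$count < 0)
  if (length(bad)) {
    stop(sprintf("negative count at row %d of %s", bad[1], path))
  }
  bad <- which(df$count != round(df$count))
  if (length(bad)) {
    stop(sprintf("non-integer count at row %d of %s", bad[1], path))
  }
  bad <- which(df$bin_i < 0 | df$bin_j < 0 |
                 df$bin_i != round(df$bin_i) | df$bin_j != round(df$bin_j))
  if (length(bad)) {
    stop(sprintf("invalid bin index at row %d of %s", bad[1], path))
  }
  if (is.null(n_bins)) {
    n_bins <- if (nrow(df)) max(df$bin_i, df$bin_j) + 1 else 0L
  }
  bad <- which(df$bin_i >= n_bins | df$bin_j >= n_bins)
  if (length(bad)) {
    stop(sprintf("bin index out of range at row %d of %s", bad[1], path))
  }
  # symmetrize: emit both (i,j) and (j,i), collapse duplicates on the diagonal
  off <- df$bin_i != df$bin_j
  i <- c(df$bin_i, df$bin_j[off]) + 1L
  j <- c(df$bin_j, df$bin_i[off]) + 1L
  x <- c(df$count, df$count[off])
  m <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n_bins, n_bins))
  binned_contacts(m, chrom = chrom, resolution = resolution)
}

#' Write a contact matrix as sparse triplet text
#'
#' Writes the upper triangle (including the diagonal) of the counts as
#' 0-based `bin_i<TAB>bin_j<TAB>count` rows; the round trip through
#' [load_contacts()] is lossless for integer counts.
#'
#' @param x a [binned_contacts] object.
#' @param path output file path.
#' @export
write_contacts <- function(x, path) {
  stopifnot(inherits(x, "binned_contacts"))
  tm <- methods::as(Matrix::triu(x$counts), "TsparseMatrix")
  keep <- tm@x != 0
  df <- data.frame(bin_i = tm@i[keep], bin_j = tm@j[keep],
                   count = tm@x[keep])
  df <- df[order(df$bin_i, df$bin_j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Partition a chromosome into overlapping sliding windows
#'
#' Windows of side `d` bins advance by steps of `d/2`, so consecutive windows
#' overlap in a `d/2`-wide band and every in-range bin pair is covered by at
#' least one window. Stepping stops once a window reaches the chromosome end;
#' a final partial window is truncated, never padded.
#'
#' @param n_bins number of bins on the chromosome.
#' @param d window side length in bins; must be even and >= 4.
#' @return A data.frame with one row per window: `k` (0-based ordinal),
#'   `offset` (first bin, 0-based) and `size` (actual side length; equal to
#'   `d` except for a truncated final window).
#' @export
make_windows <- function(n_bins, d = 1000L) {
  if (d %% 2 != 0) stop("window size d must be even")
  if (d < 4) stop("window size d must be >= 4")
  if (d >= n_bins) {
    return(data.frame(k = 0L, offset = 0L, size = as.integer(n_bins)))
  }
  step <- d %/% 2
  n_win <- ceiling((n_bins - d) / step) + 1L
  k <- seq_len(n_win) - 1L
  offset <- k * step
  size <- pmin(d, n_bins - offset)
  data.frame(k = as.integer(k), offset = as.integer(offset),
             size = as.integer(size))
}

#' Extract a dense count window
#'
#' @param x a [binned_contacts] object.
#' @param window one row of [make_windows()] output (or a list with `offset`
#'   and `size`).
#' @return A dense base-matrix of counts of dimension `size x size`.
#' @export
extract_window <- function(x, window) {
  stopifnot(inherits(x, "binned_contacts"))
  idx <- seq.int(window$offset + 1L, window$offset + window$size)
  as.matrix(x$counts[idx, idx, drop = FALSE])
}

#' Map sheared-window pixel coordinates back to genomic bins
#'
#' The band-removal shear (see [remove_bands()]) re-indexes the retained
#' off-diagonals of a `d x d` window into a `(d-c-1) x (d-c-1)` matrix. This
#' maps a pixel (i, j) of that sheared matrix (1-based) back to the 0-based
#' genomic bin pair it came from. Vectorized over `i`/`j`.
#'
#' @param offset window offset (first bin, 0-based).
#' @param c number of off-diagonal bands removed.
#' @param i,j 1-based pixel coordinates within the sheared window.
#' @param size actual window side length (defaults to `d`; pass the truncated
#'   size for a terminal window) used only for range checking.
#' @param d nominal window side length in bins.
#' @return A data.frame with columns `bin_a < bin_b` (0-based genomic bins).
#' @export
sheared_to_genomic <- function(offset, c, i, j, d = 1000L, size = d) {
  m <- size - c - 1L
  if (any(i < 1 | i > m | j < 1 | j > m)) {
    stop("pixel coordinates outside the sheared window")
  }
  data.frame(bin_a = offset + pmin(i, j) - 1L,
             bin_b = offset + pmax(i, j) + c)
}

#' Write loop calls as 10-column BEDPE
#'
#' Columns: chrom1 start1 end1 chrom2 start2 end2 name score strand1 strand2,
#' with `name` carrying the loop category (`A_specific`, `B_specific` or
#' `shared`) and `score` the cluster strength; strands are `"."`.
#'
#' @param loops a loop-call data.frame (see [compare_cell_types()]).
#' @param path output file path.
#' @param chrom chromosome name used for both anchors.
#' @export
write_bedpe <- function(loops, path, chrom = "chr1") {
  bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
  df <- data.frame(
    chrom1 = chrom, start1 = bp(loops$start1), end1 = bp(loops$end1),
    chrom2 = chrom, start2 = bp(loops$start2), end2 = bp(loops$end2),
    name = loops$category, score = signif(loops$strength, 6),
    strand1 = ".", strand2 = "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE loop file
#'
#' Accepts >= 6 tab-separated columns; columns 7 and 8 (name/score) are kept
#' when present. Anchor centers (bp midpoints) are added for overlap and APA
#' computations.
#'
#' @param path BEDPE file path.
#' @return A data.frame with columns `chrom1,start1,end1,chrom2,start2,end2`,
#'   optional `category`/`strength`, and derived `center1`/`center2`.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("BEDPE requires at least 6 columns: ", path)
  out <- data.frame(chrom1 = df[[1]], start1 = df[[2]], end1 = df[[3]],
                    chrom2 = df[[4]], start2 = df[[5]], end2 = df[[6]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 7) out$category <- df[[7]]
  if (ncol(df) >= 8) out$strength <- suppressWarnings(as.numeric(df[[8]]))
  out$center1 <- (out$start1 + out$end1) / 2
  out$center2 <- (out$start2 + out$end2) / 2
  out
}
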