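#' Log-transform a count window
#'
#' Elementwise natural log of (count + 1); zeros map to zeros, so sparsity is
#' preserved and the transform is monotone.
#'
#' @param X matrix of non-negative counts.
#' @return Matrix of log-counts `log(X + 1)`.
#' @export
log_transform <- function(X) {
  if (any(X < 0)) stop("counts must be non-negative")
  log(X + 1)
}

#' Match the nonzero-entry medians of two log windows
#'
#' Equalizes library depth between two conditions locally, per window: the
#' window with the larger median of its nonzero entries has the median
#' difference subtracted from every nonzero entry, and any entry driven
#' negative is clipped to zero. Zeros are untouched; the smaller-median window
#' is returned unchanged. Clipping can break exact post-shift median equality;
#' the report records how many entries were clipped rather than iterating.
#'
#' @param A,B same-shape matrices of log-counts for the two conditions.
#' @return A list with `A`, `B` (adjusted matrices) and `report`, a list with
#'   `median_A`, `median_B`, `shift` (non-negative amount subtracted),
#'   `shifted_label` (`"A"`, `"B"` or `"none"`), `clipped_count` and
#'   `degenerate` (TRUE when either window had no nonzero entries).
#' @export
median_match <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  nzA <- A[A != 0]
  nzB <- B[B != 0]
  report <- list(median_A = NA_real_, median_B = NA_real_, shift = 0,
                 shifted_label = "none", clipped_count = 0L,
                 degenerate = FALSE)
  if (!length(nzA) || !length(nzB)) {
    report$degenerate <- TRUE
    warning("median_match: window with no nonzero entries; returned unchanged")
    return(list(A = A, B = B, report = report))
  }
  mA <- stats::median(nzA)
  mB <- stats::median(nzB)
  report$median_A <- mA
  report$median_B <- mB
  report$shift <- abs(mA - mB)
  if (mA == mB) {
    return(list(A = A, B = B, report = report))
  }
  if (mA > mB) {
    shifted <- A
    report$shifted_label <- "A"
  } else {
    shifted <- B
    report$shifted_label <- "B"
  }
  nz <- shifted != 0
  shifted[nz] <- shifted[nz] - report$shift
  # entries driven to zero or below lose their value; record how many
  report$clipped_count <- sum(nz & shifted <= 0)
  shifted[shifted < 0] <- 0
  if (mA > mB) A <- shifted else B <- shifted
  list(A = A, B = B, report = report)
}

#' Remove diagonal bands by shearing a symmetric window
#'
#' Deletes the main diagonal and the first `c` off-diagonals of a symmetric
#' `d x d` window and re-indexes the surviving upper triangle into a
#' `(d-c-1) x (d-c-1)` symmetric matrix: in 1-based terms,
#' `new(i, j) = old(min(i, j), max(i, j) + c + 1)`. The main diagonal of the
#' output holds the first retained off-diagonal of the input, so smoothing
#' operates on a square field with no diagonal artifact.
#'
#' @param X symmetric `d x d` matrix (log-counts).
#' @param c number of off-diagonal bands to remove (0 keeps all but the main
#'   diagonal); must satisfy `0 <= c <= d - 2`.
#' @return The `(d-c-1) x (d-c-1)` sheared matrix.
#' @export
remove_bands <- function(X, c) {
  d <- nrow(X)
  stopifnot(d == ncol(X))
  if (c < 0 || c >= d - 1) stop("band count c must satisfy 0 <= c <= d - 2")
  m <- d - c - 1L
  r <- rep(seq_len(m), times = m)
  q <- rep(seq_len(m), each = m)
  out <- X[cbind(pmin(r, q), pmax(r, q) + c + 1L)]
  dim(out) <- c(m, m)
  out
}

#' Preprocess one window pair for curvature inference
#'
#' Applies the full preprocessing chain in order: log transform, median
#' matching between the two conditions, then band removal at offset `c`.
#'
#' @param XA,XB raw count windows (same shape) for conditions A and B.
#' @param c number of diagonal bands to remove.
#' @return A list with sheared log-matrices `A`, `B` and the median-match
#'   `report`.
#' @export
preprocess_window_pair <- function(XA, XB, c) {
  mm <- median_match(log_transform(XA), log_transform(XB))
  list(A = remove_bands(mm$A, c), B = remove_bands(mm$B, c),
       report = mm$report)
}
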