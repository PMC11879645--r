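# From per-window significance masks to genome-coordinate loop calls, and
# shared / cell-type-specific labelling between two conditions.

# Encode (bin_a, bin_b) pixel pairs as a single key for set operations.
pixel_key <- function(bin_a, bin_b, base) bin_a * base + bin_b

#' Extract significant peak pixels of one window in genomic coordinates
#'
#' Takes the upper triangle (i <= j) of the window's peak mask — each such
#' pixel maps to a unique genomic bin pair — and converts sheared pixel
#' coordinates to 0-based bin pairs. Pixel strength is the standardized
#' |lambda+|.
#'
#' @param field a [curvature_field()] for the sheared window.
#' @param offset window offset (first bin, 0-based).
#' @param c number of diagonal bands removed.
#' @param size actual (possibly truncated) window side length in bins.
#' @return Data.frame with columns `bin_a`, `bin_b`, `strength`.
#' @export
window_peak_pixels <- function(field, offset, c, size) {
  mask <- significance_mask(field)
  idx <- which(mask == "peak", arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(bin_a = integer(), bin_b = integer(),
                      strength = numeric()))
  }
  keep <- idx[, 1] <= idx[, 2]
  idx <- idx[keep, , drop = FALSE]
  g <- sheared_to_genomic(offset, c, idx[, 1], idx[, 2],
                          d = size, size = size)
  g$strength <- abs(field$z_plus[idx])
  g
}

#' Merge per-window peak-pixel masks into one genome-level mask
#'
#' Windows advance by half their width, so interior pixels are covered by
#' more than one window; a pixel significant in any covering window is kept,
#' with the maximum strength over windows. All masks must come from the same
#' chromosome, condition and (h, c) parameters.
#'
#' @param masks list of per-window results, each a list with fields `pixels`
#'   (data.frame from [window_peak_pixels()]), `h`, `c` and `chrom`.
#' @return Data.frame of deduplicated pixels `bin_a`, `bin_b`, `strength`.
#' @export
merge_windows <- function(masks) {
  if (!length(masks)) {
    return(data.frame(bin_a = integer(), bin_b = integer(),
                      strength = numeric()))
  }
  par <- unique(t(vapply(masks, function(m) {
    c(as.character(m$h), as.character(m$c), as.character(m$chrom))
  }, character(3))))
  if (nrow(par) != 1) {
    stop("merge_windows: masks have inconsistent (h, c, chrom) parameters")
  }
  px <- do.call(rbind, lapply(masks, `[[`, "pixels"))
  if (!nrow(px)) return(px)
  key <- pixel_key(px$bin_a, px$bin_b, max(px$bin_b) + 1)
  agg <- tapply(px$strength, key, max)
  first <- !duplicated(key)
  out <- px[first, , drop = FALSE]
  out$strength <- as.numeric(agg[as.character(key[first])])
  rownames(out) <- NULL
  out[order(out$bin_a, out$bin_b), , drop = FALSE]
}

#' Cluster significant pixels into loops by 8-adjacency
#'
#' Connected components of the significant-pixel set under 8-adjacency
#' (vertically, horizontally or diagonally adjacent) on the (bin_a, bin_b)
#' lattice; each significant pixel belongs to exactly one cluster.
#'
#' @param pixels data.frame with columns `bin_a`, `bin_b` and optionally
#'   `strength`.
#' @return List of data.frames, one per cluster (order: by minimum pixel).
#' @export
cluster_pixels <- function(pixels) {
  n <- nrow(pixels)
  if (!n) return(list())
  if (is.null(pixels$strength)) pixels$strength <- NA_real_
  base <- max(pixels$bin_b) + 2
  key <- pixel_key(pixels$bin_a, pixels$bin_b, base)
  edges <- integer(0)
  for (shift in list(c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
    nb <- match(pixel_key(pixels$bin_a + shift[1], pixels$bin_b + shift[2],
                          base), key)
    hit <- which(!is.na(nb))
    if (length(hit)) edges <- c(edges, rbind(hit, nb[hit]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  out <- split(pixels, comp)
  names(out) <- NULL
  ord <- order(vapply(out, function(cl) min(pixel_key(cl$bin_a, cl$bin_b,
                                                      base)), numeric(1)))
  out[ord]
}

#' Summarize a pixel cluster as a loop call
#'
#' Anchors are the bounding bin ranges of the cluster pixels, converted to bp
#' as 0-based half-open intervals; strength is the maximum standardized
#' |lambda+| over member pixels and the representative centre is the pixel
#' attaining it.
#'
#' @param cluster data.frame of pixels (`bin_a`, `bin_b`, `strength`).
#' @param resolution bin size in bp.
#' @param category loop category label to attach.
#' @return One-row data.frame with anchor intervals (`start1`, `end1`,
#'   `start2`, `end2`), `category`, `strength`, `n_pixels`, centre bins
#'   (`center_a`, `center_b`) and centre midpoints in bp (`center1`,
#'   `center2`).
#' @export
cluster_to_loopcall <- function(cluster, resolution = 10000L,
                                category = NA_character_) {
  stopifnot(nrow(cluster) >= 1)
  s <- cluster$strength
  top <- if (all(is.na(s))) 1L else which.max(s)
  data.frame(
    start1 = min(cluster$bin_a) * resolution,
    end1 = (max(cluster$bin_a) + 1) * resolution,
    start2 = min(cluster$bin_b) * resolution,
    end2 = (max(cluster$bin_b) + 1) * resolution,
    category = category,
    strength = if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE),
    n_pixels = nrow(cluster),
    center_a = cluster$bin_a[top],
    center_b = cluster$bin_b[top],
    center1 = (cluster$bin_a[top] + 0.5) * resolution,
    center2 = (cluster$bin_b[top] + 0.5) * resolution
  )
}

#' Label loops as shared or cell-type specific between two conditions
#'
#' Builds the bipartite overlap graph on clusters from conditions A and B
#' (an edge whenever two clusters share at least one pixel) and takes its
#' connected components. A component containing clusters from both
#' conditions becomes one `shared` loop whose pixel set is the union of all
#' member clusters; components with clusters from only one condition become
#' `A_specific` or `B_specific` loops. Every input cluster contributes to
#' exactly one call, and the labelling is symmetric: swapping the inputs
#' swaps the specific labels and leaves shared calls identical.
#'
#' @param clusters_A,clusters_B lists of pixel-cluster data.frames (from
#'   [cluster_pixels()]) in genomic bin-pair coordinates, called with
#'   identical parameters.
#' @param resolution bin size in bp.
#' @return Data.frame of loop calls (see [cluster_to_loopcall()]) with
#'   additional columns `n_clusters_A`, `n_clusters_B`.
#' @export
compare_cell_types <- function(clusters_A, clusters_B, resolution = 10000L) {
  nA <- length(clusters_A); nB <- length(clusters_B)
  empty <- cbind(
    cluster_to_loopcall(data.frame(bin_a = 0L, bin_b = 1L, strength = 1),
                        resolution)[0, ],
    data.frame(n_clusters_A = integer(), n_clusters_B = integer())
  )
  if (nA + nB == 0) return(empty)
  all_cl <- c(clusters_A, clusters_B)
  side <- rep(c("A", "B"), c(nA, nB))
  base <- max(vapply(all_cl, function(cl) max(cl$bin_b), numeric(1))) + 2
  keys <- lapply(all_cl, function(cl) pixel_key(cl$bin_a, cl$bin_b, base))
  # cluster-cluster edges through shared pixels
  pix <- data.frame(key = unlist(keys),
                    cl = rep(seq_along(all_cl), lengths(keys)))
  edges <- integer(0)
  if (nA && nB) {
    by_pix <- split(pix$cl, pix$key)
    multi <- by_pix[lengths(by_pix) > 1]
    if (length(multi)) {
      edges <- unlist(lapply(multi, function(cls) {
        cls <- sort(unique(cls))
        rbind(cls[1], cls[-1])
      }))
    }
  }
  g <- igraph::make_empty_graph(length(all_cl), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  calls <- lapply(split(seq_along(all_cl), comp), function(members) {
    has_A <- any(side[members] == "A")
    has_B <- any(side[members] == "B")
    category <- if (has_A && has_B) "shared"
                else if (has_A) "A_specific" else "B_specific"
    px <- do.call(rbind, all_cl[members])
    key <- pixel_key(px$bin_a, px$bin_b, base)
    agg <- tapply(px$strength, key, function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
    first <- !duplicated(key)
    px <- px[first, , drop = FALSE]
    px$strength <- as.numeric(agg[as.character(key[first])])
    cbind(cluster_to_loopcall(px, resolution, category),
          data.frame(n_clusters_A = sum(side[members] == "A"),
                     n_clusters_B = sum(side[members] == "B")))
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out[order(out$start1, out$start2), , drop = FALSE]
}

#' Call loops on a pair of contact matrices
#'
#' The full two-condition pipeline: sliding windows, log transform, median
#' matching, band removal, scale-space curvature inference per window and
#' condition, window merging, pixel clustering, and shared/specific
#' labelling. Both conditions are analysed with identical `(h, c, alpha)` so
#' the comparison is meaningful.
#'
#' @param contacts_A,contacts_B [binned_contacts()] for the two conditions,
#'   same chromosome and bin count.
#' @param c number of diagonal bands removed (default 6).
#' @param h smoothing bandwidth in pixels (default `2^1.75`).
#' @param alpha family-wise significance level per window (default 0.05).
#' @param d sliding-window side in bins (default 1000).
#' @param radius_factor kernel truncation radius in units of `h`.
#' @param se_constant multiplier on the propagated eigenvalue SE.
#' @return List of class `loop_calls` with elements `loops` (loop-call
#'   data.frame), `clusters_A`, `clusters_B` (pixel clusters per condition),
#'   `params`, and `window_log` (per-window median-match report, noise SD,
#'   block count and critical value for each condition).
#' @export
call_loops <- function(contacts_A, contacts_B, c = 6L, h = 2^1.75,
                       alpha = 0.05, d = 1000L, radius_factor = 4,
                       se_constant = 1) {
  stopifnot(inherits(contacts_A, "binned_contacts"),
            inherits(contacts_B, "binned_contacts"))
  if (contacts_A$n_bins != contacts_B$n_bins) {
    stop("the two conditions must have the same bin count")
  }
  if (contacts_A$resolution != contacts_B$resolution) {
    stop("the two conditions must share a resolution")
  }
  chrom <- contacts_A$chrom
  resolution <- contacts_A$resolution
  windows <- make_windows(contacts_A$n_bins, d)
  masks_A <- list(); masks_B <- list(); window_log <- list()
  for (w in seq_len(nrow(windows))) {
    win <- windows[w, ]
    if (win$size - c - 1L < 3L) next  # too small for inference after shearing
    pp <- preprocess_window_pair(extract_window(contacts_A, win),
                                 extract_window(contacts_B, win), c)
    fA <- curvature_field(pp$A, h, alpha, radius_factor, se_constant)
    fB <- curvature_field(pp$B, h, alpha, radius_factor, se_constant)
    masks_A[[length(masks_A) + 1L]] <- list(
      pixels = window_peak_pixels(fA, win$offset, c, win$size),
      h = h, c = c, chrom = chrom)
    masks_B[[length(masks_B) + 1L]] <- list(
      pixels = window_peak_pixels(fB, win$offset, c, win$size),
      h = h, c = c, chrom = chrom)
    window_log[[length(window_log) + 1L]] <- list(
      k = win$k, offset = win$offset, size = win$size,
      median_match = pp$report,
      sigma_hat_A = fA$sigma_hat, sigma_hat_B = fB$sigma_hat,
      m_blocks = fA$m_blocks, q = fA$q)
  }
  clusters_A <- cluster_pixels(merge_windows(masks_A))
  clusters_B <- cluster_pixels(merge_windows(masks_B))
  loops <- compare_cell_types(clusters_A, clusters_B, resolution)
  structure(
    list(loops = loops, clusters_A = clusters_A, clusters_B = clusters_B,
         params = list(chrom = chrom, resolution = resolution, c = c, h = h,
                       alpha = alpha, d = d, radius_factor = radius_factor,
                       se_constant = se_constant),
         window_log = window_log),
    class = "loop_calls"
  )
}

#' @export
print.loop_calls <- function(x, ...) {
  tab <- table(factor(x$loops$category,
                      levels = c("A_specific", "B_specific", "shared")))
  cat(sprintf(
    "loop_calls: %s @ %d bp, c = %d, h = %.3f | %d loops (A-specific %d, B-specific %d, shared %d)\n",
    x$params$chrom, x$params$resolution, x$params$c, x$params$h,
    nrow(x$loops), tab["A_specific"], tab["B_specific"], tab["shared"]))
  invisible(x)
}
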