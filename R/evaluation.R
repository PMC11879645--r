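# Evaluation battery: normalized aggregate peak analysis, loop-size
# statistics, loop-set overlap, promoter/marker-gene anchoring, and the
# (c, h) tuning summary.

loop_centers_bp <- function(loops) {
  c1 <- if (!is.null(loops$center1)) loops$center1
        else (loops$start1 + loops$end1) / 2
  c2 <- if (!is.null(loops$center2)) loops$center2
        else (loops$start2 + loops$end2) / 2
  cbind(c1, c2)
}

#' Normalized aggregate peak analysis
#'
#' Averages per-loop raw-count submatrices centred on each loop's
#' representative pixel, after dividing each submatrix by its own mean
#' (normalized APA). Loops whose anchors are separated by `min_separation`
#' bp or less are excluded (strictly-greater filter, default 300 kb) to
#' limit distance-decay bias, as are loops whose flank window leaves the
#' matrix. Two enrichment scores are reported: the centre value divided by
#' the mean of the lower-left flank-by-flank corner quadrant (the
#' short-distance background side), and the mean of the 3x3 block around the
#' centre.
#'
#' @param contacts a [binned_contacts()] with the raw counts being evaluated.
#' @param loops loop data.frame with centre coordinates (`center_a`/
#'   `center_b` bins from the caller, or bp centres from [read_bedpe()]).
#' @param flank pixels on each side of the centre (default 10, i.e. 21x21).
#' @param min_separation minimum anchor-centre separation in bp, strict
#'   (default 300000).
#' @return List of class `apa_result`: `aggregate` matrix,
#'   `normalized_apa_score`, `apa3x3_score`, `n_loops_used`,
#'   `n_loops_filtered` (separation or bounds), `n_loops_skipped`
#'   (zero-mean submatrices).
#' @export
apa <- function(contacts, loops, flank = 10L, min_separation = 300000) {
  stopifnot(inherits(contacts, "binned_contacts"))
  if (flank < 1) stop("flank must be >= 1")
  n <- contacts$n_bins
  res <- contacts$resolution
  if (!nrow(loops)) stop("no loops supplied")
  if (!is.null(loops$center_a)) {
    ca <- loops$center_a; cb <- loops$center_b
    sep_bp <- (cb - ca) * res
  } else {
    ctr <- loop_centers_bp(loops)
    ca <- floor(ctr[, 1] / res); cb <- floor(ctr[, 2] / res)
    sep_bp <- abs(ctr[, 2] - ctr[, 1])
  }
  in_bounds <- ca - flank >= 0 & cb + flank <= n - 1 &
    cb - flank >= 0 & ca + flank <= n - 1
  keep <- sep_bp > min_separation & in_bounds
  n_filtered <- sum(!keep)
  side <- 2L * flank + 1L
  aggregate <- matrix(0, side, side)
  n_used <- 0L; n_skipped <- 0L
  for (r in which(keep)) {
    sub <- as.matrix(contacts$counts[(ca[r] - flank):(ca[r] + flank) + 1L,
                                     (cb[r] - flank):(cb[r] + flank) + 1L])
    mu <- mean(sub)
    if (mu == 0) {
      warning(sprintf("apa: zero-mean submatrix at loop %d skipped", r))
      n_skipped <- n_skipped + 1L
      next
    }
    aggregate <- aggregate + sub / mu
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("apa: no usable loops after filtering")
  aggregate <- aggregate / n_used
  ctr_idx <- flank + 1L
  background <- mean(aggregate[(flank + 2L):side, 1:flank])
  structure(
    list(aggregate = aggregate,
         normalized_apa_score = aggregate[ctr_idx, ctr_idx] / background,
         apa3x3_score = mean(aggregate[(ctr_idx - 1L):(ctr_idx + 1L),
                                       (ctr_idx - 1L):(ctr_idx + 1L)]),
         n_loops_used = n_used, n_loops_filtered = n_filtered,
         n_loops_skipped = n_skipped),
    class = "apa_result"
  )
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf(
    "apa_result: %d loops used (%d filtered, %d skipped), normalized APA %.3f, 3x3 APA %.3f\n",
    x$n_loops_used, x$n_loops_filtered, x$n_loops_skipped,
    x$normalized_apa_score, x$apa3x3_score))
  invisible(x)
}

#' Loop-size distribution
#'
#' Loop size is the distance between anchor midpoints in bp.
#'
#' @param loops loop data.frame with anchor intervals.
#' @return List with `sizes` (bp) and `quantiles` at probabilities
#'   0, 0.25, 0.5, 0.75, 1; both empty for an empty loop list.
#' @export
loop_sizes <- function(loops) {
  if (!nrow(loops)) {
    return(list(sizes = numeric(0), quantiles = numeric(0)))
  }
  sizes <- (loops$start2 + loops$end2) / 2 - (loops$start1 + loops$end1) / 2
  list(sizes = sizes,
       quantiles = stats::quantile(sizes, probs = c(0, 0.25, 0.5, 0.75, 1)))
}

#' Overlap between two loop sets at a bin-distance threshold
#'
#' A loop in `set_B` is matched if some loop in `set_A` has both
#' anchor-centre distances within `threshold` bins (Chebyshev distance on
#' the anchor-pair plane). The matched count is monotone nondecreasing in
#' the threshold.
#'
#' @param set_A,set_B loop data.frames on the same genome and resolution.
#' @param threshold maximum centre distance in bins (units of `resolution`).
#' @param resolution bin size in bp.
#' @return List with `n_overlap` (matched loops of `set_B`) and
#'   `fraction_of_B`.
#' @export
overlap_loop_sets <- function(set_A, set_B, threshold = 1,
                              resolution = 10000L) {
  if (!nrow(set_B)) return(list(n_overlap = 0L, fraction_of_B = NA_real_))
  if (!nrow(set_A)) return(list(n_overlap = 0L, fraction_of_B = 0))
  ca <- loop_centers_bp(set_A)
  cb <- loop_centers_bp(set_B)
  tol <- threshold * resolution
  matched <- vapply(seq_len(nrow(cb)), function(i) {
    any(pmax(abs(ca[, 1] - cb[i, 1]), abs(ca[, 2] - cb[i, 2])) <= tol)
  }, logical(1))
  list(n_overlap = sum(matched), fraction_of_B = mean(matched))
}

#' Bundled neuronal and glial marker genes
#'
#' Nine neuronal and nine glial marker-gene symbols used to check that
#' cell-type-specific loops anchor the expected cell type's genes.
#'
#' @return Data.frame with columns `symbol` and `cell_class`
#'   (`"neuron"`/`"glia"`).
#' @export
marker_genes <- function() {
  path <- system.file("extdata", "marker_genes.tsv", package = "loopscape",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Derive promoter intervals from transcription start sites
#'
#' Promoters are defined as TSS +/- `flank` bp (half-open), a configurable
#' convention.
#'
#' @param tss data.frame with columns `chrom`, `tss` (bp) and `gene`.
#' @param flank bp on each side of the TSS (default 2000).
#' @return BED4-style data.frame `chrom`, `start`, `end`, `gene`.
#' @export
promoters_from_tss <- function(tss, flank = 2000L) {
  data.frame(chrom = tss$chrom, start = pmax(0, tss$tss - flank),
             end = tss$tss + flank, gene = tss$gene,
             stringsAsFactors = FALSE)
}

#' Genes whose promoters fall in loop anchors, by loop category
#'
#' A gene is counted for a loop when its promoter interval intersects either
#' anchor interval (half-open bp coordinates). Results are invariant to loop
#' and promoter order. When the loop table carries `chrom1`/`chrom2`
#' columns, chromosomes must match; otherwise a single-chromosome analysis
#' is assumed and the promoter `chrom` column is ignored.
#'
#' @param loops loop data.frame with `start1,end1,start2,end2` and
#'   `category`.
#' @param promoters BED4-style data.frame (`chrom`, `start`, `end`, `gene`).
#' @param markers optional marker table (see [marker_genes()]).
#' @return List with `genes_by_category` (character vectors of gene symbols
#'   per category), `counts` (genes per category), and, when `markers` is
#'   given, `marker_counts` (data.frame category x cell_class x n).
#' @export
annotate_promoters <- function(loops, promoters, markers = NULL) {
  cats <- c("A_specific", "B_specific", "shared")
  genes_by_category <- stats::setNames(
    rep(list(character(0)), length(cats)), cats)
  if (nrow(loops) && nrow(promoters)) {
    pr <- IRanges::IRanges(start = promoters$start + 1L,
                           end = promoters$end)
    for (anchor in 1:2) {
      s <- loops[[paste0("start", anchor)]]
      e <- loops[[paste0("end", anchor)]]
      an <- IRanges::IRanges(start = s + 1L, end = e)
      hits <- IRanges::findOverlaps(an, pr)
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      chrom_col <- paste0("chrom", anchor)
      if (!is.null(loops[[chrom_col]])) {
        ok <- loops[[chrom_col]][qh] == promoters$chrom[sh]
        qh <- qh[ok]; sh <- sh[ok]
      }
      for (cat in cats) {
        sel <- loops$category[qh] == cat
        genes_by_category[[cat]] <- union(genes_by_category[[cat]],
                                          promoters$gene[sh[sel]])
      }
    }
  }
  genes_by_category <- lapply(genes_by_category, sort)
  out <- list(genes_by_category = genes_by_category,
              counts = vapply(genes_by_category, length, integer(1)))
  if (!is.null(markers)) {
    mc <- expand.grid(category = cats,
                      cell_class = unique(markers$cell_class),
                      stringsAsFactors = FALSE)
    mc$n <- mapply(function(cat, cls) {
      length(intersect(genes_by_category[[cat]],
                       markers$symbol[markers$cell_class == cls]))
    }, mc$category, mc$cell_class)
    out$marker_counts <- mc
  }
  out
}

#' Parameter-tuning summary over a (c, h) grid
#'
#' One row per grid point with the three tuning criteria: (a) the total
#' number of genes anchored by the discovered loops, (b) marker-gene hits
#' split by loop category, and (c) overlap with a reference loop set at a
#' bin-distance threshold. Grid points whose calls are missing are flagged
#' absent (`NA` row), never fabricated.
#'
#' @param grid_results list; each element a list with `c`, `h` and `loops`
#'   (a loop-call data.frame, or `NULL` if that grid point was not run).
#' @param promoters BED4 promoter table.
#' @param markers optional marker table (see [marker_genes()]).
#' @param reference optional reference loop set (e.g. another caller's
#'   BEDPE, via [read_bedpe()]).
#' @param threshold overlap threshold in bins for criterion (c).
#' @param resolution bin size in bp.
#' @return Data.frame with one row per grid point.
#' @export
tuning_summary <- function(grid_results, promoters, markers = NULL,
                           reference = NULL, threshold = 1,
                           resolution = 10000L) {
  rows <- lapply(grid_results, function(gr) {
    row <- data.frame(c = gr$c, h = gr$h, absent = is.null(gr$loops),
                      n_loops = NA_integer_, n_specific = NA_integer_,
                      n_shared = NA_integer_, total_genes = NA_integer_,
                      genes_specific = NA_integer_,
                      genes_shared = NA_integer_,
                      markers_specific = NA_integer_,
                      markers_shared = NA_integer_,
                      ref_overlap = NA_integer_,
                      ref_fraction = NA_real_)
    if (is.null(gr$loops)) return(row)
    loops <- gr$loops
    ann <- annotate_promoters(loops, promoters, markers)
    specific <- loops$category %in% c("A_specific", "B_specific")
    row$n_loops <- nrow(loops)
    row$n_specific <- sum(specific)
    row$n_shared <- sum(loops$category == "shared")
    row$total_genes <- length(unique(unlist(ann$genes_by_category)))
    row$genes_specific <- length(unique(unlist(
      ann$genes_by_category[c("A_specific", "B_specific")])))
    row$genes_shared <- length(ann$genes_by_category$shared)
    if (!is.null(markers)) {
      mc <- ann$marker_counts
      row$markers_specific <- sum(mc$n[mc$category != "shared"])
      row$markers_shared <- sum(mc$n[mc$category == "shared"])
    }
    if (!is.null(reference) && nrow(loops)) {
      ov <- overlap_loop_sets(reference, loops, threshold, resolution)
      row$ref_overlap <- ov$n_overlap
      row$ref_fraction <- ov$fraction_of_B
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
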