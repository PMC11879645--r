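# Synthetic Hi-C generator: power-law distance decay, Poisson counts,
# zero-inflation, library-depth differences between conditions, and planted
# loop enrichments with known ground truth.

#' Specification for a synthetic Hi-C contact-matrix pair
#'
#' Expected background at bin separation `s` follows the power-law decay
#' `decay_scale * (s + 1)^(-decay_exponent)`; condition B is scaled by
#' `depth_factor_B` to emulate library-depth differences. Planted loops
#' multiply the background by `1 + amplitude * G` where `G` is an isotropic
#' Gaussian bump of SD `width` bins centred on the loop, present in condition
#' A, B or both. Counts are Poisson draws around the expected surface, then
#' zero-inflated.
#'
#' @param n_bins number of bins per condition.
#' @param resolution bin size in bp.
#' @param decay_scale expected count at separation 0 (default 100).
#' @param decay_exponent power-law exponent (default 1).
#' @param depth_factor_B multiplicative depth ratio for condition B
#'   (default 1.5).
#' @param loops data.frame with columns `bin_a`, `bin_b`, `amplitude`,
#'   `width`, `presence` (one of `"A"`, `"B"`, `"both"`); may be empty.
#' @param zero_inflation probability that a cell (symmetrically) is zeroed
#'   (default 0.05).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bins = 1000L, resolution = 10000L,
                           decay_scale = 100, decay_exponent = 1,
                           depth_factor_B = 1.5,
                           loops = empty_loop_panel(),
                           zero_inflation = 0.05) {
  if (decay_exponent <= 0) stop("decay_exponent must be positive")
  if (decay_scale <= 0) stop("decay_scale must be positive")
  if (depth_factor_B <= 0) stop("depth_factor_B must be positive")
  if (zero_inflation < 0 || zero_inflation >= 1) {
    stop("zero_inflation must lie in [0, 1)")
  }
  loops <- as.data.frame(loops)
  if (nrow(loops)) {
    stopifnot(all(c("bin_a", "bin_b", "amplitude", "width", "presence")
                  %in% names(loops)))
    if (any(loops$amplitude < 0)) stop("loop amplitudes must be >= 0")
    if (any(loops$bin_a < 0 | loops$bin_b >= n_bins |
              loops$bin_a >= loops$bin_b)) {
      stop("loop coordinates must satisfy 0 <= bin_a < bin_b < n_bins")
    }
    if (!all(loops$presence %in% c("A", "B", "both"))) {
      stop("loop presence must be one of A, B, both")
    }
  }
  structure(list(n_bins = as.integer(n_bins),
                 resolution = as.integer(resolution),
                 decay_scale = decay_scale, decay_exponent = decay_exponent,
                 depth_factor_B = depth_factor_B, loops = loops,
                 zero_inflation = zero_inflation),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
empty_loop_panel <- function() {
  data.frame(bin_a = integer(), bin_b = integer(), amplitude = numeric(),
             width = numeric(), presence = character())
}

#' Deterministic panel of planted loops
#'
#' Places `n_A + n_B + n_shared` loops on a regular layout with anchor
#' separations cycling through `separations` (bins), well apart from each
#' other and from the matrix edges, with presence flags cycling
#' A, B, both. Deterministic (no RNG), so the truth table is identical
#' across simulation seeds.
#'
#' @param n_bins number of bins.
#' @param n_A,n_B,n_shared loop counts per presence class.
#' @param amplitude fold-enrichment amplitude for every loop.
#' @param width bump SD in bins.
#' @param separations anchor separations (bins) cycled across loops; the
#'   default scales with `n_bins` (90, 140, 190, 240 bins at `n_bins` 1000).
#' @return Loop data.frame suitable for [synthetic_spec()].
#' @export
synthetic_loop_panel <- function(n_bins = 1000L, n_A = 4L, n_B = 4L,
                                 n_shared = 4L, amplitude = 10,
                                 width = 2^1.75,
                                 separations = pmax(20L, as.integer(
                                   round(n_bins * c(0.09, 0.14, 0.19, 0.24))))) {
  n <- n_A + n_B + n_shared
  margin <- max(10L, min(40L, n_bins %/% 8))
  sep <- rep_len(separations, n)
  lo <- margin
  hi <- n_bins - margin - max(sep)
  if (hi <= lo) stop("n_bins too small for the requested loop panel")
  bin_a <- as.integer(round(seq(lo, hi, length.out = n)))
  data.frame(bin_a = bin_a, bin_b = bin_a + sep,
             amplitude = amplitude, width = width,
             presence = rep_len(c("A", "B", "both"), n))
}

# Expected-count surface for one condition ("A" or "B").
expected_surface <- function(spec, condition) {
  n <- spec$n_bins
  s <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- spec$decay_scale * (s + 1)^(-spec$decay_exponent)
  enrich <- matrix(1, n, n)
  loops <- spec$loops
  if (nrow(loops)) {
    keep <- loops$presence == "both" | loops$presence == condition
    for (r in which(keep)) {
      a <- loops$bin_a[r] + 1L; b <- loops$bin_b[r] + 1L
      w <- loops$width[r]; amp <- loops$amplitude[r]
      reach <- ceiling(4 * w)
      ii <- max(1L, a - reach):min(n, a + reach)
      jj <- max(1L, b - reach):min(n, b + reach)
      bump <- amp * outer(exp(-(ii - a)^2 / (2 * w^2)),
                          exp(-(jj - b)^2 / (2 * w^2)))
      enrich[ii, jj] <- enrich[ii, jj] + bump
      enrich[jj, ii] <- enrich[jj, ii] + t(bump)  # mirror below diagonal
    }
  }
  depth <- if (condition == "B") spec$depth_factor_B else 1
  E * enrich * depth
}

# Symmetric Poisson + zero-inflation draw around an expected surface.
sample_counts <- function(E, zero_inflation) {
  n <- nrow(E)
  ut <- upper.tri(E, diag = TRUE)
  x <- stats::rpois(sum(ut), E[ut])
  if (zero_inflation > 0) {
    x[stats::runif(length(x)) < zero_inflation] <- 0L
  }
  M <- matrix(0, n, n)
  M[ut] <- x
  M + t(M) - diag(diag(M))
}

#' Generate a synthetic Hi-C contact-matrix pair with ground truth
#'
#' Draws the two conditions' count matrices around their expected surfaces
#' (see [synthetic_spec()]); symmetric, integer-valued and deterministic for
#' a given seed.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer RNG seed (deterministic output per seed).
#' @param chrom chromosome name to attach.
#' @return List with [binned_contacts()] `A` and `B` and the `truth`
#'   data.frame (the planted-loop table).
#' @export
generate_pair <- function(spec, seed = 1L, chrom = "chrS") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  A <- sample_counts(expected_surface(spec, "A"), spec$zero_inflation)
  B <- sample_counts(expected_surface(spec, "B"), spec$zero_inflation)
  list(A = binned_contacts(A, chrom = chrom, resolution = spec$resolution),
       B = binned_contacts(B, chrom = chrom, resolution = spec$resolution),
       truth = spec$loops)
}

#' Pipeline noise level on a matched null window
#'
#' Generates a loop-free pair from the same background model and returns the
#' noise SD the pipeline estimates on the preprocessed (log, median-matched,
#' band-removed) condition-A window. Used to express planted-loop amplitudes
#' in units of the log-scale noise SD where the curvature inference operates.
#'
#' @param spec a [synthetic_spec()] (its loops are ignored).
#' @param c number of diagonal bands removed.
#' @param seed RNG seed for the null draw.
#' @return Scalar noise SD estimate.
#' @export
reference_noise_sd <- function(spec, c = 6L, seed = 1L) {
  null_spec <- spec
  null_spec$loops <- empty_loop_panel()
  pair <- generate_pair(null_spec, seed = seed)
  pp <- preprocess_window_pair(as.matrix(pair$A$counts),
                               as.matrix(pair$B$counts), c)
  estimate_noise_sd(pp$A)
}
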