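# Scale-space curvature inference: Gaussian smoothing, Hessian eigenvalue
# fields, noise-level estimation, simultaneous critical value and per-pixel
# feature classification.

# Symmetric (edge-inclusive) reflection of out-of-range indices onto 1..n.
reflect_index <- function(k, n) {
  r <- (k - 1) %% (2L * n)
  ifelse(r < n, r + 1L, 2L * n - r)
}

# Correlate one axis of a matrix with a 1-D tap vector w (offsets -R..R).
# axis = 1 filters down columns (over the row index), axis = 2 across rows.
# pad = "reflect" mirrors at the edges; "zero" treats outside as 0.
filter_axis <- function(Y, w, axis = 1L, pad = "reflect") {
  R <- (length(w) - 1L) %/% 2L
  if (axis == 2L) return(t(filter_axis(t(Y), w, 1L, pad)))
  n <- nrow(Y)
  out <- matrix(0, n, ncol(Y))
  for (t in seq_along(w)) {
    u <- t - R - 1L
    idx <- seq_len(n) + u
    if (pad == "reflect") {
      out <- out + w[t] * Y[reflect_index(idx, n), , drop = FALSE]
    } else {
      ok <- idx >= 1L & idx <= n
      if (any(ok)) {
        out[ok, ] <- out[ok, ] + w[t] * Y[idx[ok], , drop = FALSE]
      }
    }
  }
  out
}

#' Discrete Gaussian derivative taps for a bandwidth
#'
#' Builds the 1-D tap vectors from which the 2-D smoothing and Hessian kernels
#' are assembled as outer products: `c0` (smoother, unit mass), `c1` (first
#' derivative, exact on linear ramps) and `c2` (second derivative, zero mass
#' and exact curvature 2 on `u^2`). Taps are samples of the Gaussian density
#' and its derivatives at integer offsets, truncated at `radius_factor * h`
#' and corrected so those discrete moment constraints hold exactly; the
#' corrections make constant fields exact fixed points (smoother) or exact
#' zeros (derivatives) and quadratic surfaces exact in the interior.
#'
#' @param h bandwidth (Gaussian SD) in pixels.
#' @param radius_factor kernel truncation radius in units of `h` (default 4).
#' @return List with tap vectors `c0`, `c1`, `c2`, the raw (unit-mass
#'   normalised) Gaussian taps `phi`, and the truncation radius `R`.
#' @export
gaussian_taps <- function(h, radius_factor = 4) {
  if (h <= 0) stop("bandwidth h must be positive")
  if (radius_factor < 3) stop("truncation radius must be >= 3 h")
  R <- as.integer(ceiling(radius_factor * h))
  u <- seq.int(-R, R)
  phi <- stats::dnorm(u, sd = h)
  c0 <- phi / sum(phi)
  c1 <- u * phi
  c1 <- c1 / sum(c1 * u)
  # c2 = a*(u^2 - h^2)*phi + b*phi with sum(c2) = 0 and sum(c2 * u^2) = 2
  k2 <- (u^2 - h^2) * phi
  s2 <- sum(k2); s0 <- sum(phi)
  s2u <- sum(k2 * u^2); s0u <- sum(phi * u^2)
  den <- s2u * s0 - s2 * s0u
  a <- 2 * s0 / den
  b <- -a * s2 / s0
  c2 <- a * k2 + b * phi
  list(c0 = c0, c1 = c1, c2 = c2, phi = phi, R = R)
}

#' Gaussian window smoother
#'
#' Smooths a 2-D field by discrete correlation with an isotropic Gaussian of
#' SD `h` pixels, truncated at `radius_factor * h` and renormalised to unit
#' mass over the in-range support, so constants are preserved everywhere
#' including edges (no padding).
#'
#' @param Y numeric matrix (finite values).
#' @param h bandwidth in pixels.
#' @param radius_factor truncation radius in units of `h`.
#' @return The smoothed matrix, same dimensions as `Y`.
#' @export
gaussian_smooth <- function(Y, h, radius_factor = 4) {
  tp <- gaussian_taps(h, radius_factor)
  num <- filter_axis(filter_axis(Y, tp$c0, 1L, pad = "zero"),
                     tp$c0, 2L, pad = "zero")
  mass <- function(n) {
    filter_axis(matrix(1, n, 1L), tp$c0, 1L, pad = "zero")[, 1L]
  }
  num / outer(mass(nrow(Y)), mass(ncol(Y)))
}

#' Smoothed second-derivative (Hessian) fields
#'
#' Computes the three Hessian component fields of the Gaussian-smoothed
#' surface by correlating `Y` with the second partial derivatives of the
#' Gaussian kernel (separable outer products of [gaussian_taps()]). Edges are
#' handled by symmetric reflection, so constant fields give exactly zero
#' curvature everywhere.
#'
#' @inheritParams gaussian_smooth
#' @return List of matrices `fxx`, `fxy`, `fyy` (`fxx` differentiates along
#'   the row index).
#' @export
hessian_fields <- function(Y, h, radius_factor = 4) {
  tp <- gaussian_taps(h, radius_factor)
  list(
    fxx = filter_axis(filter_axis(Y, tp$c2, 1L), tp$c0, 2L),
    fxy = filter_axis(filter_axis(Y, tp$c1, 1L), tp$c1, 2L),
    fyy = filter_axis(filter_axis(Y, tp$c0, 1L), tp$c2, 2L)
  )
}

#' L2 norms of the three Hessian derivative kernels
#'
#' Each derivative field is a fixed linear filter of the data, so under
#' i.i.d. noise of SD sigma its SD is `sigma * ||K||_2`. The separable
#' construction gives the norms as products of 1-D tap norms.
#'
#' @inheritParams gaussian_smooth
#' @return Named vector with elements `xx`, `xy`, `yy`.
#' @export
hessian_kernel_norms <- function(h, radius_factor = 4) {
  tp <- gaussian_taps(h, radius_factor)
  n0 <- sqrt(sum(tp$c0^2)); n1 <- sqrt(sum(tp$c1^2)); n2 <- sqrt(sum(tp$c2^2))
  c(xx = n2 * n0, xy = n1 * n1, yy = n0 * n2)
}

#' Eigenvalues of a symmetric 2x2 Hessian
#'
#' Closed-form eigenvalues, vectorized over pixel fields:
#' `lambda± = ((fxx + fyy) ± sqrt((fxx - fyy)^2 + 4 fxy^2)) / 2`, with
#' `lambda_plus >= lambda_minus` everywhere.
#'
#' @param fxx,fxy,fyy Hessian component values (scalars, vectors or matrices
#'   of equal shape).
#' @return List with `lambda_plus` and `lambda_minus`.
#' @export
eigen2x2 <- function(fxx, fxy, fyy) {
  tr <- fxx + fyy
  disc <- sqrt((fxx - fyy)^2 + 4 * fxy^2)
  list(lambda_plus = (tr + disc) / 2, lambda_minus = (tr - disc) / 2)
}

#' Robust noise-SD estimate from Laplacian pseudo-residuals
#'
#' Applies the discrete 3x3 Laplacian stencil (centre -4, cross +1), which
#' annihilates locally linear signal, and rescales the MAD of the interior
#' residuals for Gaussian consistency: for i.i.d. noise the stencil output
#' has variance `20 sigma^2`, so `sigma_hat = mad(L) / sqrt(20)` (with the
#' usual 1.4826 MAD constant). Degree-1 homogeneous: `sigma_hat(c Y) =
#' |c| sigma_hat(Y)`; exactly zero on constant fields.
#'
#' @param Y numeric matrix with at least 9 pixels.
#' @return Non-negative scalar noise SD estimate.
#' @export
estimate_noise_sd <- function(Y) {
  n <- nrow(Y); m <- ncol(Y)
  if (n * m < 9 || n < 3 || m < 3) stop("field must be at least 3 x 3")
  ci <- 2:(n - 1); cj <- 2:(m - 1)
  L <- Y[ci - 1, cj] + Y[ci + 1, cj] + Y[ci, cj - 1] + Y[ci, cj + 1] -
    4 * Y[ci, cj]
  stats::mad(L) / sqrt(20)
}

#' Simultaneous Gaussian critical value over independent blocks
#'
#' Two-sided Gaussian quantile adjusted for simultaneous inference over `m`
#' effectively independent blocks:
#' `q = qnorm((1 + (1 - alpha)^(1/m)) / 2)`. Strictly increasing in `m`,
#' decreasing in `alpha`.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m number of independent blocks (>= 1).
#' @return The critical value `q`.
#' @export
critical_value <- function(alpha, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.finite(m) || m < 1) stop("m must be >= 1")
  stats::qnorm((1 + (1 - alpha)^(1 / m)) / 2)
}

#' Number of effectively independent blocks in a smoothed window
#'
#' Counts kernel-sized tiles among the tested pixels: a Gaussian smoother of
#' bandwidth `h` has an effective reach of about `h` in each direction, so
#' tiles of side `2h` are treated as approximately independent:
#' `m = max(1, round(n_pixels / (2h)^2))`.
#'
#' @param n_pixels number of tested pixels.
#' @param h bandwidth in pixels.
#' @return Integer block count >= 1.
#' @export
independent_blocks <- function(n_pixels, h) {
  if (n_pixels < 1) stop("n_pixels must be >= 1")
  if (h <= 0) stop("bandwidth h must be positive")
  max(1L, as.integer(round(n_pixels / (2 * h)^2)))
}

#' Classify pixels into geometric features from standardized eigenvalues
#'
#' Applies the curvature feature table to standardized Hessian eigenvalues
#' `z± = lambda± / SE`: a peak requires both eigenvalues significantly
#' negative (`z+ < -q` and `z- < -q`), a hole both significantly positive;
#' valleys, ridges and saddles are mixed cases; everything else is `none`.
#'
#' @param z_plus,z_minus standardized eigenvalue fields (equal shape).
#' @param q simultaneous critical value.
#' @return Character matrix of labels in `{peak, hole, long_valley,
#'   saddle_point, long_ridge, none}`.
#' @export
classify_features <- function(z_plus, z_minus, q) {
  stopifnot(all(dim(z_plus) == dim(z_minus)))
  lab <- matrix("none", nrow(z_plus), ncol(z_plus))
  lab[z_plus > q & z_minus > q] <- "hole"
  lab[z_plus > q & abs(z_minus) < q] <- "long_valley"
  lab[z_plus > q & z_minus < -q] <- "saddle_point"
  lab[abs(z_plus) < q & z_minus < -q] <- "long_ridge"
  lab[z_plus < -q & z_minus < -q] <- "peak"
  lab
}

#' Full curvature inference on one window
#'
#' Runs the complete scale-space inference chain on a preprocessed (sheared,
#' log-scale) window: Gaussian smoothing, Hessian eigenvalue fields, robust
#' noise-SD estimation, standard-error propagation, independent-blocks
#' critical value and per-pixel feature classification.
#'
#' The standard error of both eigenvalues is propagated from the noise SD via
#' the exact L2 norms of the derivative kernels under the i.i.d.-noise model,
#' using the conservative linearization
#' `SE = sigma_hat * (max(||Kxx||, ||Kyy||) + ||Kxy||) * se_constant`.
#' A window with `sigma_hat = 0` (e.g. all-constant) yields an empty mask.
#'
#' @param Y preprocessed window matrix.
#' @param h bandwidth in pixels.
#' @param alpha family-wise significance level (default 0.05).
#' @param radius_factor kernel truncation radius in units of `h`.
#' @param se_constant multiplier on the propagated SE (default 1); exposed so
#'   alternative propagations can be swapped in.
#' @return An object of class `curvature_field`: list with the smoothed field
#'   (`smooth`), Hessian fields (`fxx`, `fxy`, `fyy`), eigenvalue fields
#'   (`lambda_plus`, `lambda_minus`), standardized fields (`z_plus`,
#'   `z_minus`), `sigma_hat`, `se`, `m_blocks`, `q`, `h`, `alpha` and the
#'   label matrix `mask`.
#' @export
curvature_field <- function(Y, h, alpha = 0.05, radius_factor = 4,
                            se_constant = 1) {
  if (!all(is.finite(Y))) stop("field must be finite")
  hess <- hessian_fields(Y, h, radius_factor)
  ev <- eigen2x2(hess$fxx, hess$fxy, hess$fyy)
  sigma_hat <- estimate_noise_sd(Y)
  norms <- hessian_kernel_norms(h, radius_factor)
  se <- sigma_hat * (max(norms["xx"], norms["yy"]) + norms["xy"]) * se_constant
  m_blocks <- independent_blocks(length(Y), h)
  q <- critical_value(alpha, m_blocks)
  if (se > 0) {
    z_plus <- ev$lambda_plus / se
    z_minus <- ev$lambda_minus / se
    mask <- classify_features(z_plus, z_minus, q)
  } else {
    z_plus <- z_minus <- matrix(0, nrow(Y), ncol(Y))
    mask <- matrix("none", nrow(Y), ncol(Y))
  }
  structure(
    list(smooth = gaussian_smooth(Y, h, radius_factor),
         fxx = hess$fxx, fxy = hess$fxy, fyy = hess$fyy,
         lambda_plus = ev$lambda_plus, lambda_minus = ev$lambda_minus,
         z_plus = z_plus, z_minus = z_minus,
         sigma_hat = sigma_hat, se = se, m_blocks = m_blocks, q = q,
         h = h, alpha = alpha, mask = mask),
    class = "curvature_field"
  )
}

#' Per-pixel significance mask of a curvature field
#'
#' Re-evaluates the feature classification of a [curvature_field()] at a
#' given level, recomputing the critical value from the field's block count.
#'
#' @param field a `curvature_field` object.
#' @param alpha family-wise significance level.
#' @return Character label matrix (see [classify_features()]).
#' @export
significance_mask <- function(field, alpha = field$alpha) {
  stopifnot(inherits(field, "curvature_field"))
  if (field$se <= 0) {
    return(matrix("none", nrow(field$z_plus), ncol(field$z_plus)))
  }
  q <- critical_value(alpha, field$m_blocks)
  classify_features(field$z_plus, field$z_minus, q)
}

#' @export
print.curvature_field <- function(x, ...) {
  mask <- significance_mask(x)
  cat(sprintf(
    "curvature_field: %d x %d, h = %.3f, sigma_hat = %.4g, m = %d, q = %.3f, %d peak pixels\n",
    nrow(x$z_plus), ncol(x$z_plus), x$h, x$sigma_hat, x$m_blocks, x$q,
    sum(mask == "peak")))
  invisible(x)
}
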