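---
title: "Calling chromatin loops by significance of curvature in scale space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling chromatin loops by significance of curvature in scale space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopscape)
```

## The problem and the model

A Hi-C experiment produces, per chromosome, a symmetric matrix of contact
counts between fixed-size genomic bins (10 kb by default here). Chromatin
loops — pairs of loci in contact more often than the local background —
appear as focal peaks in this matrix, buried in substantial counting noise
and sparsity. `loopscape` treats loop detection as a statistical inference
problem on a noisy surface:

$$Y_{i,j} = s(i,j) + \varepsilon_{i,j},$$

where $s$ is a smooth underlying contact intensity and $\varepsilon$ is
independent noise. The signal is estimated by a Gaussian window smoother
with bandwidth $h$ (pixels),

$$\hat s_h(i,j) = \sum_{k,l} Y_{k,l}\, K_h(i-k,\, j-l),$$

and peaks are characterised by curvature: at a peak both eigenvalues
$\lambda_+ \ge \lambda_-$ of the Hessian of $\hat s_h$ are strongly
negative. The test statistic at each pixel is the larger standardized
eigenvalue; a pixel is a significant peak when **both** standardized
eigenvalues fall below $-\hat q$, where $\hat q$ is a simultaneous Gaussian
critical value (below). Other sign patterns of the two eigenvalues are
reported as holes, valleys, ridges and saddles for diagnostics only; only
peaks feed the loop caller. Because features live at different scales,
$h$ is a first-class tuning parameter with the grid
$\{2^1, 2^{1.25}, \dots, 2^{2.5}\}$; the default $h = 2^{1.75} \approx 3.36$
pixels and band removal $c = 6$ are the recommended operating point of the
tuning procedure sketched at the end.

## Preprocessing

Whole-chromosome matrices are analysed in sliding windows of $d = 1000$
bins advancing by $d/2$, so every locus is interior to at least one window.
Stepping stops once a window reaches the chromosome end; a final partial
window is truncated rather than zero-padded, because padding would create
artificial flat regions that bias the noise-SD estimate downwards. Within
each window, in order:

1. **Log transform.** $x = \log(\tilde x + 1)$, which compresses the count
   scale towards the roughly additive-noise regime the model assumes.
2. **Median matching.** To adjust for library depth and quality differences
   between the two conditions, the medians of the *nonzero* log-counts are
   compared per window; the larger-median window has the difference
   subtracted from every nonzero entry, negatives are clipped to zero, and
   zeros are untouched. Clipping can break exact post-shift median
   equality; we apply the rule verbatim and record the number of clipped
   entries in the run log rather than iterating, since iteration would not
   converge to anything better-defined. All-zero (degenerate) windows are
   passed through with a warning flag so window indexing stays aligned
   between conditions; they later produce no significant pixels because
   their noise SD is zero.
3. **Band removal.** The main diagonal and the first $c$ off-diagonals
   dominate the intensity range and carry no loop information, so they are
   removed by a shear: the surviving upper triangle is re-indexed into a
   $(d-c-1)\times(d-c-1)$ symmetric matrix via
   $\text{new}(i,j) = \text{old}(\min(i,j),\, \max(i,j)+c+1)$. Smoothing
   and inference operate on this square sheared field, and significant
   pixels are mapped back to genomic bin pairs afterwards.

## Numerical choices in the inference chain

**Kernels.** The 2-D smoothing and derivative kernels are separable outer
products of 1-D taps sampled from the Gaussian density and its
derivatives, truncated at $4h$ (configurable, at least $3h$). The taps are
corrected to satisfy the exact discrete moment conditions — unit mass for
the smoother, zero mass and curvature response exactly 2 for the
second-derivative taps — so constants are exact fixed points (or exact
zeros) and quadratic surfaces have exact interior curvature.

**Boundaries.** The smoother renormalises the truncated kernel to unit
mass over the in-range support (no padding), so constants are preserved at
edges. For the derivative fields, renormalising a zero-sum kernel has no
unique analogue; they use symmetric reflection at the edges instead, which
preserves the required invariant (zero curvature on constants everywhere,
including edges). Edge pixels consequently have slightly understated
standard errors; the strongly conservative SE propagation below absorbs
this, as the type-I-error simulations confirm.

**Noise level.** The noise SD is estimated robustly from the discrete
3×3 Laplacian (centre −4, cross +1) of the window, which annihilates
locally linear signal: for i.i.d. noise its output has variance
$20\sigma^2$, so $\hat\sigma = \mathrm{MAD}(L)/\sqrt{20}$ with the usual
1.4826 Gaussian-consistency constant. The estimator is exactly
scale-equivariant and zero on constants; on i.i.d. standard Gaussian
fields it lands in $[0.95, 1.05]$ (property-tested). A single
$\hat\sigma$ per window deliberately averages over the mild
heteroscedasticity of log-transformed counts along the distance-decay
gradient.

**Standard errors.** Each derivative field is a fixed linear filter of the
data, so under i.i.d. noise $\mathrm{SD}(f_{ab}) = \hat\sigma\,\|K_{ab}\|_2$
exactly. The eigenvalues are nonlinear in the three fields; we use the
conservative linearization
$\mathrm{SE}(\hat\lambda_\pm) = \hat\sigma\,(\max(\|K_{xx}\|_2,
\|K_{yy}\|_2) + \|K_{xy}\|_2)$. Any propagation used here must scale
exactly in $\hat\sigma$ and err on the conservative side; both properties
are what the type-I-error simulation checks, and the multiplier is exposed
(`se_constant`) so alternative propagations can be swapped in.

**Multiplicity.** Simultaneous inference across the window uses the
independent-blocks device: a smoother of bandwidth $h$ has reach about
$h$, so tiles of side $2h$ are treated as effectively independent, giving
$m = \max(1, \mathrm{round}(n_{\text{pixels}}/(2h)^2))$ blocks and the
critical value

$$\hat q = \Phi^{-1}\!\left(\tfrac{1}{2}\left(1 + (1-\alpha)^{1/m}\right)\right),$$

the two-sided Gaussian quantile whose family-wise error over $m$
independent tests is $\alpha$ (default 0.05). The literature on
scale-space inference offers more refined extreme-value constructions;
this package uses the block-quantile form above and validates it
empirically: on pure-noise fields the observed family-wise rate of
flagging any peak is far below the nominal level (the procedure is
designed conservative).

## From pixels to loops

Significant peak pixels from all windows are mapped to genomic bin pairs
and unioned (a pixel significant in any covering window is significant;
duplicates keep their maximum strength), then clustered by 8-adjacency on
the (bin\_a, bin\_b) lattice — vertically, horizontally or diagonally
adjacent pixels form one loop. Clustering happens after window merging so
window seams cannot split a cluster. A loop call's anchors are the
bounding bin ranges of its pixels; its strength is the maximum
standardized $|\lambda_+|$ and its representative centre the pixel
attaining it.

To compare two conditions called with identical $(h, c, \alpha)$, clusters
from both sides are joined whenever they share a pixel; connected
components of this overlap graph containing both sides become single
`shared` calls whose pixel set is the union, while one-sided components
become `A_specific` or `B_specific`. Overlap is closed transitively (if
A1 touches B1 and B1 touches A2, all three merge) — the only associative
extension of pairwise merging. Representing loops as pixel clusters rather
than single pixels is what makes this comparison robust to small
positional shifts between conditions.

## Evaluation tools

- **Normalized APA.** Each called loop contributes its raw-count
  submatrix (21×21 by default) centred on the representative pixel,
  divided by its own mean; the aggregate is the mean of these. Loops with
  anchor separation of 300 kb or less are excluded (strictly greater
  than `min_separation` survives) to limit distance-decay bias. The
  normalized APA score divides the centre by the mean of the lower-left
  flank×flank corner quadrant — the short-separation side, i.e. the
  conservative background convention; the 3×3 score is the mean of the
  3×3 centre block. APA uses raw counts of the condition being evaluated:
  log or median-matched values would distort enrichment ratios.
- **Loop-set overlap.** A loop matches a reference set when some
  reference loop has both anchor centres within a threshold number of
  bins (Chebyshev distance on the anchor-pair plane — anchor centres
  rather than any-pixel overlap, a documented choice).
- **Promoter anchoring.** A gene counts for a loop when its promoter
  interval (TSS ± 2 kb when derived from an annotation; configurable)
  intersects either anchor. A bundled panel of nine neuronal and nine
  glial marker genes supports checking that condition-specific loops
  anchor the expected cell type's genes.
- **Tuning.** `tuning_summary()` tabulates, per $(c, h)$: total anchored
  genes, marker hits split by category, and overlap with a reference loop
  set — the three criteria used to pick the recommended $c = 6$,
  $h = 2^{1.75}$.

## The synthetic generator

Real neuron/glia Hi-C data is access-restricted, so the package ships a
generator that emulates the features the method must cope with: power-law
distance decay $A(s+1)^{-\gamma}$ (defaults $A = 100$, $\gamma = 1$),
Poisson counting noise (deliberately not Gaussian — the inference then
faces realistic misspecification, as with real Hi-C), zero-inflation
(default 0.05), a library-depth ratio between conditions (default 1.5,
exercising median matching), and planted loops as multiplicative
fold-enrichment bumps — isotropic Gaussians in the matrix plane — present
in A, B or both, mirroring how real loops sit on the expected-count
surface. Ground truth is returned alongside the matrices, and generation
is deterministic per seed.

For recovery experiments, planted amplitudes are expressed in units of
the noise the pipeline actually faces: the fold-change is set to
$e^{8\hat\sigma_{\mathrm{ref}}} - 1$, where
$\hat\sigma_{\mathrm{ref}}$ is the pipeline's own noise-SD estimate on a
matched loop-free window — an ~8-SD bump on the log scale where the
curvature test operates. Saturation of $\log(x+1)$ at low background
counts makes the realised log-scale bump somewhat smaller than nominal;
the detection margin absorbs this.

The generator does **not** emulate TADs and compartments (block and
checkerboard structure), stripe features, restriction-fragment or
mappability biases, or between-replicate variation. Passing the recovery
tests therefore demonstrates correctness of the inference machinery under
the stated noise model, not performance on real tissue Hi-C; the tuning
and APA machinery exist precisely to validate calls against real data.

## Problem sizes and test design

The validation suite runs entirely on synthetic data at sizes chosen to
exercise every code path while staying comfortably interactive: type-I
error on 200 pure-noise fields of 200×200; planted-loop recovery on
1000-bin chromosomes (one full-size window after shearing) with 12 loops
(4 A-only, 4 B-only, 4 shared) across 20 seeds, requiring ≥ 90 % correct
category recovery and under one false loop per 500×500 null region; exact
brute-force oracles for smoothing, eigenvalues, shearing and clustering.
Deeper nulls or longer chromosomes change none of the logic, only the
constants' precision.

## Known limitations

- Two conditions only; no multi-way comparison or differential strength
  test beyond the shared/specific labels.
- Raw counts plus per-window median matching stand in for matrix
  balancing (no ICE/KR); this is intrinsic to the method's design.
- The single per-window noise SD underestimates noise near the diagonal
  and overestimates it far out; the conservative SE propagation
  compensates globally, not locally.
- Sparse input is supported via triplet text; binary cooler/.hic readers
  are out of scope for this package.
- Ridge labels are emitted by the feature classifier, but no stripe
  calling pipeline is built on them.

## A minimal session

```{r example, eval = FALSE}
spec <- synthetic_spec(n_bins = 1000,
                       loops = synthetic_loop_panel(1000, amplitude = 10))
pair <- generate_pair(spec, seed = 1)
res <- call_loops(pair$A, pair$B, c = 6, h = 2^1.75)
res$loops[, c("start1", "start2", "category", "strength", "n_pixels")]
apa(pair$A, res$loops[res$loops$category != "B_specific", ])
```
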