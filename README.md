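# loopscape

Chromatin loop calling from Hi-C contact maps by statistical significance
of curvature in scale space, with shared vs. cell-type-specific labelling
between two conditions.

## What it does, and for whom

Hi-C profiles genome-wide chromosome conformation as a symmetric matrix of
contact counts between genomic bins (10 kb by default). Chromatin loops —
locus pairs in contact more often than the local background — show up as
focal peaks in that matrix, and the loops that differ between cell types
are the ones most informative about cell-type-specific gene regulation.
`loopscape` is for analysts who have binned contact matrices from two cell
types or conditions and want statistically controlled loop calls, each
labelled *A-specific*, *B-specific* or *shared*.

The core model treats a preprocessed contact window as a noisy surface

    Y(i,j) = s(i,j) + eps(i,j),

estimates `s` with a Gaussian window smoother at bandwidth *h* (scale
space), and tests each pixel's curvature: with `lambda+ >= lambda-` the
eigenvalues of the Hessian of the smoothed surface, a pixel is a
significant peak when both standardized eigenvalues fall below `-q`, where

    q = qnorm((1 + (1 - alpha)^(1/m)) / 2)

is a simultaneous Gaussian critical value over `m` effectively independent
kernel-sized blocks (family-wise level `alpha = 0.05`). Preprocessing is
`log(x+1)`, per-window median matching of the two conditions' nonzero
entries (library-depth adjustment), and removal of the diagonal and first
`c` off-diagonal bands via a shear. Significant pixels are clustered by
8-adjacency into loops; clusters from the two conditions that share pixels
merge into `shared` calls. Defaults `c = 6`, `h = 2^1.75` are the
recommended operating point of the included tuning machinery. An
evaluation battery (normalized aggregate peak analysis, loop-size
distributions, loop-set overlap, promoter/marker-gene anchoring) and a
synthetic Hi-C generator with planted ground-truth loops round the package
out; see the vignette in `vignettes/` for the method details.

## Worked example

Simulate a 1000-bin chromosome pair (10-kb bins) with power-law distance
decay, Poisson noise, a 1.5× depth difference and twelve planted loops —
four per presence class — then call loops:

```r
library(loopscape)

spec <- synthetic_spec(n_bins = 1000,
                       loops = synthetic_loop_panel(1000, amplitude = 10))
pair <- generate_pair(spec, seed = 1)
res  <- call_loops(pair$A, pair$B, c = 6, h = 2^1.75)
res
#> loop_calls: chrS @ 10000 bp, c = 6, h = 3.364 | 13 loops (A-specific 4, B-specific 5, shared 4)

head(res$loops[, c("start1", "start2", "category", "strength", "n_pixels")])
#>     start1  start2   category  strength n_pixels
#> 1   370000 1270000 A_specific 11.650689       43
#> 9   990000 2390000 B_specific  7.186569       36
#> 2  1610000 3510000     shared  8.302021       40
#> 3  2230000 4630000 A_specific  9.013384       31
#> 10 2840000 3730000 B_specific  8.847471       40
#> 4  3460000 4860000     shared 11.405386       48
```

All twelve planted loops are recovered with the correct category (the
thirteenth call is a single-pixel false positive; at the default settings
false calls run well under one per 500×500 null region). `strength` is the
maximum standardized |lambda+| over the cluster's pixels — how many
standard errors the peak curvature sits below zero; `start1`/`start2` are
the 0-based bp starts of the two anchors. Aggregate peak analysis over the
loops present in condition A confirms the calls are backed by raw-count
enrichment:

```r
apa(pair$A, res$loops[res$loops$category != "B_specific", ])
#> apa_result: 8 loops used (0 filtered, 0 skipped), normalized APA 2.785, 3x3 APA 4.071
```

A value of 1 would mean no enrichment over the surrounding background;
2.8-fold central enrichment is strong loop signal. Loops with anchors
closer than 300 kb are excluded from APA by default (here none were).

A thin command-line front end wrapping these functions (subcommands
`simulate`, `call`, `apa`, `overlap`, `annotate`, `tune`) is installed at
`system.file("cli", "loopscape", package = "loopscape")`.

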