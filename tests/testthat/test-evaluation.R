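make_loops <- function(center_a, center_b, resolution = 10000) {
  data.frame(
    start1 = (center_a - 1) * resolution, end1 = (center_a + 2) * resolution,
    start2 = (center_b - 1) * resolution, end2 = (center_b + 2) * resolution,
    category = "shared", strength = 1, n_pixels = 3L,
    center_a = center_a, center_b = center_b,
    center1 = (center_a + 0.5) * resolution,
    center2 = (center_b + 0.5) * resolution
  )
}

test_that("APA on a constant matrix is exactly 1 everywhere", {
  n <- 200
  x <- binned_contacts(matrix(5L, n, n), resolution = 10000)
  loops <- make_loops(c(30, 60, 90), c(80, 140, 170))
  res <- apa(x, loops, flank = 10)
  expect_equal(res$aggregate, matrix(1, 21, 21))
  expect_equal(res$normalized_apa_score, 1)
  expect_equal(res$apa3x3_score, 1)
  expect_equal(res$n_loops_used, 3L)
})

test_that("the separation filter is strictly greater than t", {
  n <- 300
  x <- binned_contacts(matrix(2L, n, n), resolution = 10000)
  # separations 100, 250, 299, 301, 500 kb at 10-kb bins via bp centres
  sep_kb <- c(100, 250, 299, 301, 500)
  loops <- data.frame(
    start1 = 1e6, end1 = 1e6 + 1e4,
    start2 = 1e6 + sep_kb * 1000, end2 = 1e6 + sep_kb * 1000 + 1e4
  )
  loops$category <- "shared"
  res <- apa(x, loops, flank = 5, min_separation = 300000)
  expect_equal(res$n_loops_used, 2L)
  expect_equal(res$n_loops_filtered, 3L)
})

test_that("planted loops enrich the APA centre above a shifted control", {
  panel <- synthetic_loop_panel(600, n_A = 0, n_B = 0, n_shared = 5,
                                amplitude = 25, width = 2.5,
                                separations = c(60L, 80L, 100L))
  spec <- synthetic_spec(n_bins = 600, loops = panel, depth_factor_B = 1,
                         zero_inflation = 0)
  pair <- generate_pair(spec, seed = 9)
  loops <- make_loops(panel$bin_a, panel$bin_b)
  res <- apa(pair$A, loops, flank = 10, min_separation = 300000)
  shifted <- make_loops(panel$bin_a + 15, panel$bin_b + 15)
  ctrl <- apa(pair$A, shifted, flank = 10, min_separation = 300000)
  expect_gt(res$apa3x3_score, 1)
  expect_gt(res$apa3x3_score, ctrl$apa3x3_score)
  expect_gt(res$normalized_apa_score, ctrl$normalized_apa_score)
})

test_that("APA errors without usable loops and skips zero-mean submatrices", {
  n <- 100
  x <- binned_contacts(matrix(1L, n, n))
  near <- make_loops(40, 45)  # 50 kb apart: filtered out
  expect_error(apa(x, near), "no usable loops")
  z <- binned_contacts(matrix(0L, n, n))
  far <- make_loops(30, 70)
  expect_error(expect_warning(apa(z, far), "zero-mean"), "no usable")
})

test_that("loop sizes are anchor-midpoint distances with sort-based quantiles", {
  l <- data.frame(start1 = 0, end1 = 10000, start2 = 500000, end2 = 510000)
  res <- loop_sizes(l)
  expect_equal(res$sizes, 500000)

  expect_length(loop_sizes(l[0, ])$sizes, 0)

  set.seed(31)
  l <- make_loops(sample(20:50, 10), sample(100:200, 10))
  res <- loop_sizes(l)
  sizes <- (l$start2 + l$end2) / 2 - (l$start1 + l$end1) / 2
  s <- sort(sizes)
  expect_equal(unname(res$quantiles[c(1, 5)]), c(s[1], s[10]))
  expect_equal(unname(res$quantiles[3]), median(sizes))
})

test_that("loop-set overlap matches brute force and is monotone in threshold", {
  A <- make_loops(c(10, 40, 80), c(60, 90, 140))
  expect_equal(overlap_loop_sets(A, A, threshold = 0)$fraction_of_B, 1)

  B <- make_loops(c(10, 40) + 12, c(60, 90) + 12)
  expect_equal(overlap_loop_sets(A, B, threshold = 1)$n_overlap, 0L)

  set.seed(71)
  A <- make_loops(sample(10:80, 8), sample(100:200, 8))
  B <- make_loops(sample(10:80, 6), sample(100:200, 6))
  prev <- -1
  for (thr in 0:10) {
    got <- overlap_loop_sets(A, B, threshold = thr)
    brute <- sum(vapply(seq_len(nrow(B)), function(i) {
      any(vapply(seq_len(nrow(A)), function(j) {
        max(abs(A$center1[j] - B$center1[i]),
            abs(A$center2[j] - B$center2[i])) <= thr * 10000
      }, logical(1)))
    }, logical(1)))
    expect_equal(got$n_overlap, brute)
    expect_gte(got$n_overlap, prev)
    prev <- got$n_overlap
  }
})

test_that("the bundled marker table has 9 + 9 disjoint symbols", {
  mk <- marker_genes()
  expect_equal(sum(mk$cell_class == "neuron"), 9)
  expect_equal(sum(mk$cell_class == "glia"), 9)
  expect_length(intersect(mk$symbol[mk$cell_class == "neuron"],
                          mk$symbol[mk$cell_class == "glia"]), 0)
  expect_false(any(duplicated(mk$symbol)))
})

test_that("promoters intersecting either anchor are counted per category", {
  loops <- data.frame(start1 = c(100000, 300000), end1 = c(110000, 320000),
                      start2 = c(500000, 700000), end2 = c(510000, 710000),
                      category = c("A_specific", "shared"))
  promoters <- data.frame(chrom = "chr1",
                          start = c(105000, 505000, 305000, 900000),
                          end = c(106000, 506000, 306000, 901000),
                          gene = c("P1", "P2", "P3", "P4"))
  ann <- annotate_promoters(loops, promoters)
  expect_setequal(ann$genes_by_category$A_specific, c("P1", "P2"))
  expect_setequal(ann$genes_by_category$shared, "P3")
  expect_equal(unname(ann$counts["B_specific"]), 0L)

  # invariance to loop and promoter order
  ann2 <- annotate_promoters(loops[2:1, ], promoters[sample(4), ])
  expect_equal(ann2$genes_by_category, ann$genes_by_category)

  none <- annotate_promoters(loops[0, ], promoters)
  expect_true(all(none$counts == 0))
})

test_that("marker hits are tallied by category and cell class", {
  loops <- data.frame(start1 = 100000, end1 = 120000,
                      start2 = 800000, end2 = 820000,
                      category = "A_specific")
  promoters <- data.frame(chrom = "chr1", start = c(105000, 805000),
                          end = c(107000, 807000),
                          gene = c("GRIN1", "AQP4"))
  ann <- annotate_promoters(loops, promoters, markers = marker_genes())
  mc <- ann$marker_counts
  expect_equal(mc$n[mc$category == "A_specific" & mc$cell_class == "neuron"],
               1L)
  expect_equal(mc$n[mc$category == "A_specific" & mc$cell_class == "glia"],
               1L)
  expect_true(all(mc$n[mc$category != "A_specific"] == 0))
})

test_that("tuning summary reports the three criteria per grid point", {
  loops <- data.frame(start1 = c(100000, 300000), end1 = c(110000, 320000),
                      start2 = c(500000, 700000), end2 = c(510000, 710000),
                      category = c("A_specific", "shared"),
                      strength = c(3, 4), n_pixels = c(2L, 3L),
                      center_a = c(10, 30), center_b = c(50, 70),
                      center1 = c(105000, 305000),
                      center2 = c(505000, 705000))
  promoters <- data.frame(chrom = "chr1",
                          start = c(105000, 305000), end = c(106000, 306000),
                          gene = c("GRIN1", "GFAP"))
  grid <- list(list(c = 6, h = 2^1.75, loops = loops),
               list(c = 5, h = 2^1.75, loops = NULL))
  tab <- tuning_summary(grid, promoters, markers = marker_genes())
  expect_equal(nrow(tab), 2)
  expect_false(tab$absent[1])
  expect_true(tab$absent[2])
  expect_equal(tab$total_genes[1], 2L)
  expect_equal(tab$markers_specific[1], 1L)  # GRIN1 in the specific loop
  expect_equal(tab$markers_shared[1], 1L)    # GFAP in the shared loop
  expect_true(is.na(tab$ref_overlap[1]))
  expect_true(is.na(tab$n_loops[2]))

  # criterion (c) against a reference set, and recount through BEDPE output
  path <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(loops, path)
  reread <- read_bedpe(path)
  tab2 <- tuning_summary(list(list(c = 6, h = 2^1.75, loops = loops)),
                         promoters, reference = reread, threshold = 1)
  expect_equal(tab2$ref_overlap[1], 2L)
  expect_equal(tab2$ref_fraction[1], 1)
  expect_equal(tab2$n_loops[1], nrow(reread))
})
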