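test_that("hormone classifier applies the printed criteria exactly", {
  cc <- classify_config()
  lab <- function(...) classify_hormone_enhancer(...)$label
  ## all four criteria met: fc = 13/6 with pseudocount 1
  expect_equal(lab(20, 12, 5, 5750, TRUE, cc), "megatrans")
  ## fold change in the open band, nascent floor met in both conditions
  expect_equal(lab(20, 12, 10, 5750, TRUE, cc), "eralpha_other_active")
  expect_equal(lab(20, 12, 10, 5750, FALSE, cc), "other_active")
  ## the floor applies to both conditions: one condition at 9 fails
  expect_equal(lab(20, 10, 9, 5750, TRUE, cc), "unclassified")
  ## gate violations
  expect_equal(lab(20, 12, 5, 2000, TRUE, cc), "unclassified")
  expect_equal(lab(15.99, 12, 5, 5750, TRUE, cc), "unclassified")
  expect_error(classify_hormone_enhancer(-1, 12, 5, 5750, TRUE, cc),
               "negative")
  ## metrics are recorded alongside the label
  r <- classify_hormone_enhancer(20, 12, 5, 5750, TRUE, cc)
  expect_equal(r$fc, 13 / 6)
  expect_equal(r$k27ac, 20)
})

test_that("threshold boundaries behave per inclusive/exclusive rules", {
  cc <- classify_config()
  lab <- function(...) classify_hormone_enhancer(...)$label
  ## >= 16 H3K27Ac, >= 10 nascent, >= 3000 bp, fc >= 1.5 all inclusive
  expect_equal(lab(16, 14, 9, 3000, TRUE, cc), "megatrans")  # fc == 1.5
  expect_equal(lab(16, 10, 10, 3000, TRUE, cc), "eralpha_other_active")
  ## band (0.67, 1.5) is open: fc exactly 0.67 or 1.5 is outside
  expect_equal(lab(16, 66, 99, 3000, TRUE, cc), "unclassified")  # fc=0.67
  expect_equal(lab(16, 66, 99, 3000, FALSE, cc), "unclassified")
  ## fc == 1.5 without the era mark: not band, not megatrans
  expect_equal(lab(16, 14, 9, 3000, FALSE, cc), "unclassified")
  ## floors are sharp
  expect_equal(lab(16, 9.99, 9.99, 3000, TRUE, cc), "unclassified")
  expect_equal(lab(16, 14, 9, 2999, TRUE, cc), "unclassified")
})

test_that("induced-scheme classifiers follow their per-scheme criteria", {
  cc <- classify_config()
  lab <- function(...) classify_induced_enhancer(...)$label
  ## proinflammatory: both floors at 16, no fold-change criterion
  expect_equal(lab(18, 17, NA, 20, 4000, "proinflammatory", cc),
               "proinflammatory")
  expect_equal(lab(18, 15.9, NA, 20, 4000, "proinflammatory", cc),
               "unclassified")
  ## androgen: floors at 10 plus Pol II fc >= 1.5
  expect_equal(lab(18, 12, 12, 15, 4000, "androgen", cc), "unclassified")
  expect_equal(lab(18, 30, 10, 15, 4000, "androgen", cc),
               "androgen_induced")
  ## neuronal: TF ignored
  expect_equal(lab(18, 15, 4, NA, 4000, "neuronal", cc),
               "neuronal_induced")
  expect_equal(classify_induced_enhancer(18, 15, 4, NA, 4000, "neuronal",
                                         cc)$fc, 16 / 5)
  expect_error(lab(18, 15, 4, NA, 4000, "volcanic", cc))
})

test_that("monotonicity: raising treated nascent never unclassifies", {
  cc <- classify_config()
  withr::local_seed(41)
  for (i in 1:50) {
    k27 <- runif(1, 0, 40); nc <- runif(1, 0, 30); d <- runif(1, 0, 8000)
    nt <- sort(runif(6, 0, 60))
    labs <- classify_hormone_enhancer(k27, nt, nc, d, TRUE, cc)$label
    mega_idx <- which(labs == "megatrans")
    if (length(mega_idx))
      expect_true(all(labs[seq(min(mega_idx), 6)] == "megatrans"))
  }
})

test_that("feature-enrichment flag matches the pairwise oracle", {
  regions <- genomic_intervals("chr1", c(1000, 5000, 9000),
                               c(3000, 7000, 11000))
  peaks <- data.table::data.table(chrom = "chr1", start = 1900, end = 2100,
                                  summit = 2000L)
  got <- annotate_feature_enrichment(regions, peaks)
  expect_equal(got$top1cc_enriched, c(TRUE, FALSE, FALSE))
  ## exact boundary: center + 1000 flags, center + 1001 does not
  p2 <- data.table::data.table(chrom = "chr1", start = 0, end = 10,
                               summit = c(3000L, 7001L))
  got2 <- annotate_feature_enrichment(regions, p2)
  expect_equal(got2$top1cc_enriched, c(TRUE, FALSE, FALSE))

  withr::local_seed(42)
  for (i in 1:20) {
    r <- rand_intervals(15)
    pk <- rand_intervals(10)
    pk$summit <- region_centers(pk)
    got <- annotate_feature_enrichment(r, pk)$top1cc_enriched
    expect_equal(got, oracle_feature_flag(r, pk))
  }
})

test_that("classify_all recovers planted labels on the small world", {
  w <- small_world()
  regions <- truth_regions(w$truth)
  calls <- classify_all(regions, w$bundle, w$ann$tss, scheme = "hormone",
                        marked_peaks = truth_marked_peaks(w$truth))
  truthmap <- setNames(w$truth$loci$class, w$truth$loci$locus)
  hormone <- truthmap[calls$name] %in%
    c("megatrans", "eralpha_other_active", "other_active")
  acc <- mean(calls$label[hormone] == truthmap[calls$name][hormone])
  expect_gte(acc, 0.9)
  ## decoys and induced loci are unclassified under the hormone scheme
  expect_true(all(calls$label[!hormone] == "unclassified"))

  ## empty input and permutation determinism
  expect_equal(nrow(classify_all(regions[0], w$bundle, w$ann$tss,
                                 scheme = "hormone")), 0L)
  withr::local_seed(43)
  perm <- sample(nrow(regions))
  calls2 <- classify_all(regions[perm], w$bundle, w$ann$tss,
                         scheme = "hormone",
                         marked_peaks = truth_marked_peaks(w$truth))
  expect_equal(calls2$label, calls$label[perm])
})

test_that("classify_all names missing bundle keys", {
  w <- small_world()
  partial <- assay_bundle(w$bundle[c("k27ac/treated", "nascent/treated")])
  expect_error(classify_all(truth_regions(w$truth), partial, w$ann$tss,
                            scheme = "hormone"),
               "nascent/control")
})
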