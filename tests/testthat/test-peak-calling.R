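test_that("Poisson tail used by the caller matches direct summation", {
  ## the caller's significance rule is P(X >= k | lambda) via ppois;
  ## check the tail itself against brute-force summation
  for (k in c(1, 5, 10, 50)) {
    for (lambda in c(0.2, 1, 4)) {
      expect_equal(ppois(k - 1, lambda, lower.tail = FALSE),
                   oracle_poisson_tail(k, lambda), tolerance = 1e-12)
    }
  }
})

test_that("a planted spike yields one merged peak at the right summit", {
  withr::local_seed(31)
  cs <- c(chr1 = 200000)
  bg <- data.frame(chrom = "chr1",
                   pos = sample(0:199999, 400, replace = TRUE),
                   strand = "+")
  spike <- data.frame(chrom = "chr1",
                      pos = as.integer(round(rnorm(50, 100000, 20))),
                      strand = "+")
  d <- build_tag_directory(rbind(bg, spike), chrom_sizes = cs)
  cfg <- peak_call_config()
  pk <- call_peaks(d, cfg, cs)
  expect_equal(nrow(pk), 1L)
  expect_lte(abs(pk$summit - 100000), cfg$step + 60)
  expect_true(pk$start <= pk$summit && pk$summit < pk$end)
  expect_equal(pk$score, normalized_count(d, sum(
    d$tags[chrom == "chr1" & pos >= pk$start & pos < pk$end, n])))
})

test_that("merged peaks are sorted, disjoint, and monotone in pvalue_max", {
  withr::local_seed(32)
  cs <- c(chr1 = 300000)
  spikes <- do.call(rbind, lapply(c(50000, 51000, 150000, 250000),
    function(c0) data.frame(chrom = "chr1",
                            pos = as.integer(round(rnorm(40, c0, 100))),
                            strand = "+")))
  bg <- data.frame(chrom = "chr1",
                   pos = sample(0:299999, 500, replace = TRUE),
                   strand = "+")
  d <- build_tag_directory(rbind(bg, spikes), chrom_sizes = cs)
  pk <- call_peaks(d, peak_call_config(), cs)
  expect_gte(nrow(pk), 3L)
  expect_false(is.unsorted(pk$start))
  expect_true(all(pk$start[-1] >= pk$end[-nrow(pk)]))
  ## stricter threshold never adds peaks
  pk_strict <- call_peaks(d, peak_call_config(pvalue_max = 1e-9), cs)
  expect_lte(nrow(pk_strict), nrow(pk))
  expect_error(call_peaks(d, peak_call_config(window = 500),
                          c(chr1 = 300000, tiny = 400)),
               "smallest chromosome")
})

test_that("null calibration: discovery rate bounded by pvalue_max", {
  ## light version of the acceptance sweep: 20 null genomes of 0.5 Mb
  cfg <- peak_call_config()
  rates <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      L <- 5e5
      n <- rpois(1, 0.01 * L)
      d <- build_tag_directory(
        data.frame(chrom = "chr1",
                   pos = sample(0:(L - 1), n, replace = TRUE),
                   strand = "+"),
        chrom_sizes = c(chr1 = L))
      pk <- call_peaks(d, cfg, c(chr1 = L))
      nw <- length(seq(0, L - cfg$window, by = cfg$step))
      ## each merged peak corresponds to >= 1 significant window
      nrow(pk) / nw
    })
  }, numeric(1))
  expect_lte(mean(rates), cfg$pvalue_max * 1.2)
})

test_that("concordance filter keeps jittered and drops disjoint summits", {
  withr::local_seed(33)
  base <- data.table::data.table(
    chrom = "chr1", start = seq(1000, 50000, by = 1000),
    end = seq(1400, 50400, by = 1000), name = paste0("p", 1:50), score = 1,
    strand = ".", summit = seq(1200, 50200, by = 1000))
  jitter <- data.table::copy(base)
  jitter$summit <- jitter$summit + sample(-80:80, 50, replace = TRUE)
  far <- data.table::copy(base)
  far$summit <- far$summit + 500000L
  far$chrom <- "chr2"

  expect_equal(concordant_peaks(list(base, base)), base)
  expect_equal(nrow(concordant_peaks(list(base, jitter),
                                     max_center_dist = 100)), 50L)
  expect_equal(nrow(concordant_peaks(list(base, far))), 0L)
  ## 2-of-3 support
  expect_equal(nrow(concordant_peaks(list(base, jitter, far),
                                     min_replicates = 2)), 50L)
  expect_equal(nrow(concordant_peaks(list(base, jitter, far),
                                     min_replicates = 3)), 0L)
  expect_error(concordant_peaks(list(base)), ">= 2")
  expect_error(concordant_peaks(list(base, base), min_replicates = 5),
               "exceeds")
})

test_that("putative enhancers are flanked anchors with K27Ac scores", {
  withr::local_seed(34)
  cs <- c(chr1 = 100000)
  k27 <- build_tag_directory(
    data.frame(chrom = "chr1",
               pos = sample(0:99999, 3000, replace = TRUE),
               strand = sample(c("+", "-"), 3000, replace = TRUE)),
    chrom_sizes = cs)
  anchors <- data.table::data.table(chrom = "chr1",
                                    start = c(4000, 30000, 70000),
                                    end = c(6000, 32000, 72000),
                                    summit = c(5000L, 31000L, 71000L))
  enh <- define_putative_enhancers(anchors, k27, flank = 1000)
  expect_equal(enh$start, c(4000L, 30000L, 70000L))
  expect_equal(enh$end, c(6000L, 32000L, 72000L))
  tags <- expand_tags(k27)
  expect_equal(enh$k27ac, normalized_count(k27, vapply(
    enh$center, function(c0) oracle_count_window(tags, "chr1", c0, 1000),
    numeric(1))))
  ## TSS-proximal anchors are dropped ("at least 3 kb away")
  tsx <- tss_records("g1", "chr1", 32000L, "+", 60000L)
  enh2 <- define_putative_enhancers(anchors, k27, flank = 1000,
                                    tss_set = tsx, tss_min_dist = 3000)
  expect_equal(enh2$center, c(5000L, 71000L))
  ## edge anchors are dropped with a warning
  a2 <- data.table::data.table(chrom = "chr1", start = 0, end = 800,
                               summit = 400L)
  expect_warning(e3 <- define_putative_enhancers(a2, k27, flank = 1000),
                 "edge")
  expect_equal(nrow(e3), 0L)
})
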