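test_that("overlap_count uses half-open semantics and matches the oracle", {
  a <- genomic_intervals("chr1", 0, 100)
  expect_equal(overlap_count(a, genomic_intervals("chr1", 50, 150)), 1L)
  ## abutting intervals do not overlap
  expect_equal(overlap_count(a, genomic_intervals("chr1", 100, 200)), 0L)
  expect_equal(overlap_count(a, genomic_intervals("chr2", 0, 100)), 0L)
  ## min_bp applies to a single subject interval
  b <- genomic_intervals("chr1", c(90, 95), c(110, 180))
  expect_equal(overlap_count(a, b, min_bp = 10), 1L)
  expect_equal(overlap_count(a, b, min_bp = 11), 0L)

  withr::local_seed(61)
  for (i in 1:10) {
    q <- rand_intervals(200)
    s <- rand_intervals(200)
    expect_equal(overlap_count(q, s), oracle_overlap_count(q, s))
    expect_equal(overlap_count(q, s, min_bp = 100),
                 oracle_overlap_count(q, s, 100))
    expect_lte(overlap_count(q, s), nrow(q))
  }
  ## saturation: subject covering the genome counts every query
  q <- rand_intervals(50)
  genome <- genomic_intervals(c("chrA", "chrB"), 0, c(50000, 30000))
  expect_equal(overlap_count(q, genome), 50L)
})

test_that("venn_partition matches hand enumeration and sums to set sizes", {
  A <- genomic_intervals("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350))
  dup <- data.table::copy(A)
  v <- venn_partition(list(x = A, y = dup))
  expect_equal(v[v$set == "x" & v$pattern == "x&y", ]$count, 4L)

  disj <- genomic_intervals("chr1", c(1000, 2000), c(1500, 2500))
  v <- venn_partition(list(x = A, y = disj))
  expect_equal(v[v$set == "x", ]$pattern, "x")
  expect_equal(v[v$set == "y", ]$pattern, "y")

  ## constructed 3-set fixture, enumerated by hand:
  ## a1 overlaps b1 and c1; a2 overlaps b2 only; a3 alone
  A3 <- genomic_intervals("chr1", c(0, 500, 900), c(100, 600, 950))
  B3 <- genomic_intervals("chr1", c(50, 550), c(120, 620))
  C3 <- genomic_intervals("chr1", c(80, 2000), c(130, 2100))
  v <- venn_partition(list(a = A3, b = B3, c = C3))
  va <- v[v$set == "a", ]
  expect_equal(va$count[match(c("a&b&c", "a&b", "a"), va$pattern)],
               c(1L, 1L, 1L))
  vc <- v[v$set == "c", ]
  expect_equal(vc$count[match(c("a&b&c", "c"), vc$pattern)], c(1L, 1L))
  ## per-set pattern counts sum to set sizes
  sums <- tapply(v$count, v$set, sum)
  expect_equal(as.integer(sums[c("a", "b", "c")]), c(3L, 2L, 2L))
  expect_error(venn_partition(list(A, B3)), "named")
  expect_error(venn_partition(list(a = A, b = B3, c = C3, d = A3)),
               "2 or 3")
})

test_that("random_regions is seeded, length-matched and proportional", {
  cs <- c(c1 = 100000, c2 = 200000)
  r1 <- random_regions(cs, 500, length = 1000, seed = 99)
  r2 <- random_regions(cs, 500, length = 1000, seed = 99)
  expect_identical(r1, r2)
  expect_false(identical(r1, random_regions(cs, 500, length = 1000,
                                            seed = 100)))
  validate_intervals(r1, cs)
  expect_true(all(r1$end - r1$start == 1000))
  ## chromosome share proportional to length (within binomial error)
  r <- random_regions(cs, 10000, length = 100, seed = 7)
  share <- mean(r$chrom == "c2")
  expect_lt(abs(share - 2 / 3), 4 * sqrt(2 / 9 / 10000) + 0.01)
  ## matched-to mode resamples the input length multiset
  proto <- genomic_intervals("c1", c(0, 10, 20), c(5, 40, 220))
  rm <- random_regions(cs, 300, match_to = proto, seed = 1)
  expect_true(all((rm$end - rm$start) %in% c(5, 30, 200)))
  expect_error(random_regions(cs, 5, length = 5e5), "longest chromosome")
  ## exclusion set is honored
  excl <- genomic_intervals("c1", 0, 100000)
  re <- random_regions(cs, 200, length = 100, seed = 3, exclude = excl)
  expect_true(all(re$chrom == "c2"))
})

test_that("enrichment_profile reports observed vs random overlap", {
  withr::local_seed(62)
  cs <- c(chrA = 50000, chrB = 30000)
  ## disjoint query intervals so "first half" covers exactly 50 of them
  q <- genomic_intervals("chrA", seq(0, 49500, by = 500),
                         seq(100, 49600, by = 500))
  half <- q[1:50]
  tab <- enrichment_profile(q, list(half = half, none = q[0]), cs,
                            n_random = 500, seed = 5)
  expect_equal(tab$observed, c(50L, 0L))
  expect_equal(tab$n_query, c(100L, 100L))
  expect_gte(tab$enrichment[1], 1)
  ## whole-genome feature saturates
  genome <- genomic_intervals(names(cs), 0, unname(cs))
  tab2 <- enrichment_profile(q, list(all = genome), cs, n_random = 200,
                             seed = 5)
  expect_equal(tab2$observed, 100L)
  expect_equal(tab2$random, 200L)
})

test_that("region_tag_correlation matches the closed-form Pearson", {
  withr::local_seed(63)
  d <- rand_directory(500)
  regions <- rand_intervals(20, max_len = 1500)
  expect_equal(region_tag_correlation(d, d, regions)$r, 1)

  d2 <- rand_directory(500)
  got <- region_tag_correlation(d, d2, regions, log2 = TRUE)
  a <- log2(count_window(d, regions$chrom, region_centers(regions),
                         1000) + 1)
  b <- log2(count_window(d2, regions$chrom, region_centers(regions),
                         1000) + 1)
  n <- 20
  r_direct <- (n * sum(a * b) - sum(a) * sum(b)) /
    sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  expect_equal(got$r, r_direct, tolerance = 1e-12)
  tstat <- r_direct * sqrt((n - 2) / (1 - r_direct^2))
  expect_equal(got$pvalue, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-9)
  ## one-tailed option
  g1 <- region_tag_correlation(d, d2, regions, alternative = "greater")
  expect_equal(g1$pvalue, pt(tstat, n - 2, lower.tail = FALSE),
               tolerance = 1e-9)
  ## degenerate input
  empty <- rand_directory(5, chroms = c(chrA = 50000))
  expect_error(region_tag_correlation(
    empty, d, genomic_intervals("chrB", c(0, 100, 200),
                                c(50, 150, 250))),
    "zero variance|unknown")
})
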