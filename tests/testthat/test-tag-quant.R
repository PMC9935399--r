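test_that("clonal cap retains at most cap tags per position", {
  rec <- data.frame(chrom = "chr1", pos = rep(100L, 5), strand = "+")
  expect_equal(build_tag_directory(rec, per_position_cap = 2)$capped_total,
               2L)
  ## nascent-transcription mode keeps up to three per unique position
  expect_equal(build_tag_directory(rec, per_position_cap = 3)$capped_total,
               3L)
  expect_error(build_tag_directory(rec[0, ], per_position_cap = 2),
               "no tags")

  ## hash-count oracle on a random tag set
  withr::local_seed(3)
  n <- 500
  rec <- data.frame(chrom = "chr1",
                    pos = sample(1:80, n, replace = TRUE),
                    strand = sample(c("+", "-"), n, replace = TRUE))
  d <- build_tag_directory(rec, per_position_cap = 2)
  key <- paste(rec$chrom, rec$pos, rec$strand)
  expect_equal(d$capped_total, sum(pmin(table(key), 2)))
  expect_equal(d$raw_total, n)
  ## strand-blind cap pools both strands per base pair
  d2 <- build_tag_directory(rec, per_position_cap = 2,
                            strand_aware_cap = FALSE)
  expect_equal(d2$capped_total,
               sum(pmin(table(paste(rec$chrom, rec$pos)), 2)))
})

test_that("normalized_count rescales to tags-per-10M", {
  d <- list(norm_target = 1e7, capped_total = 5e6)
  expect_equal(normalized_count(d, 8), 16)
  expect_equal(normalized_count(d, 0), 0)
  d$capped_total <- 1e7
  expect_equal(normalized_count(d, 10), 10)
})

test_that("count_window matches examples and the linear-scan oracle", {
  d <- rand_directory(10)
  expect_equal(count_window(d, "chrA", 100, 50), 0)
  expect_error(count_window(d, "chrZ", 100, 50), "unknown chromosome")
  expect_error(count_window(d, "chrA", 100, 50, strand_mode = "sense"),
               "ref_strand")

  withr::local_seed(21)
  d <- rand_directory(400)
  tags <- expand_tags(d)
  for (mode in c("both", "sense", "antisense")) {
    ch <- sample(c("chrA", "chrB"), 100, replace = TRUE)
    ctr <- sample(0:49999, 100)
    ref <- sample(c("+", "-"), 100, replace = TRUE)
    got <- count_window(d, ch, ctr, halfwidth = 700, strand_mode = mode,
                        ref_strand = ref, normalize = FALSE)
    want <- vapply(1:100, function(i)
      oracle_count_window(tags, ch[i], ctr[i], 700, mode, ref[i]),
      numeric(1))
    expect_equal(got, want)
  }
})

test_that("normalized counts are depth-invariant and linear", {
  withr::local_seed(8)
  rec <- data.frame(chrom = "chrA", pos = sample(1:40000, 300),
                    strand = "+")  # unique positions, below cap
  d1 <- build_tag_directory(rec, per_position_cap = 2,
                            chrom_sizes = c(chrA = 50000))
  d2 <- build_tag_directory(rbind(rec, rec), per_position_cap = 2,
                            chrom_sizes = c(chrA = 50000))
  ctr <- sample(500:39500, 30)
  expect_equal(count_window(d1, "chrA", ctr, 400),
               count_window(d2, "chrA", ctr, 400))
})

test_that("genome tiling of normalized counts sums to the target", {
  withr::local_seed(9)
  L <- 1001L * 40L
  rec <- data.frame(chrom = "chrA",
                    pos = sample(0:(L - 1), 2000, replace = TRUE),
                    strand = sample(c("+", "-"), 2000, replace = TRUE))
  d <- build_tag_directory(rec, chrom_sizes = c(chrA = L))
  centers <- seq(500, L - 1, by = 1001)  # windows [c-500, c+500] tile L
  expect_equal(sum(count_window(d, "chrA", centers, 500)), 1e7)
})

test_that("profile_matrix agrees with per-bin window oracle and flags edges", {
  withr::local_seed(13)
  d <- rand_directory(600)
  tags <- expand_tags(d)
  centers <- data.frame(chrom = sample(c("chrA", "chrB"), 20,
                                       replace = TRUE),
                        pos = sample(4000:25000, 20),
                        strand = sample(c("+", "-"), 20, replace = TRUE))
  m <- profile_matrix(d, centers, flank = 3000, binsize = 100)
  expect_equal(dim(m), c(20L, 60L))
  for (i in c(1, 7, 20)) {
    want <- vapply(seq(-3000, 2900, 100), function(off)
      oracle_count_window(tags, centers$chrom[i],
                          centers$pos[i] + off + 49.5, 49.5),
      numeric(1))
    want <- normalized_count(d, want)
    if (centers$strand[i] == "-") want <- rev(want)
    expect_equal(unname(m[i, ]), want)
  }
  ## row sums equal the full-window count (half-open [c-flank, c+flank))
  rs <- count_window(d, centers$chrom, centers$pos, 3000,
                     normalize = FALSE) -
    count_window(d, centers$chrom, centers$pos + 3000, 0.5,
                 normalize = FALSE)
  expect_equal(unname(rowSums(m)), normalized_count(d, rs))

  ## edge centers are excluded from the histogram
  ce <- data.frame(chrom = "chrA", pos = c(100L, 10000L))
  me <- profile_matrix(d, ce, flank = 3000, binsize = 100)
  expect_equal(attr(me, "excluded"), c(TRUE, FALSE))
  expect_equal(profile_histogram(me), me[2, ])

  ## single tag at a center occupies only the central bin
  d1 <- build_tag_directory(data.frame(chrom = "chrA", pos = 5000L,
                                       strand = "+"),
                            chrom_sizes = c(chrA = 20000))
  m1 <- profile_matrix(d1, data.frame(chrom = "chrA", pos = 5000L),
                       flank = 500, binsize = 100)
  expect_equal(which(m1[1, ] != 0), setNames(6L, "0"))
})

test_that("gene-body quantification follows the 13 kb / 500 bp rule", {
  cs <- c(chr1 = 100000)
  ## + strand gene, tags only in the promoter-proximal exclusion zone
  g <- tss_records("g1", "chr1", 20000L, "+", 40000L)
  rec <- data.frame(chrom = "chr1", pos = 20000:20499, strand = "+")
  d <- build_tag_directory(rec, per_position_cap = 3, chrom_sizes = cs)
  expect_equal(quantify_gene_body(d, g), 0)

  ## uniform sense tags against the analytic window, both strands
  withr::local_seed(17)
  rec <- data.frame(chrom = "chr1",
                    pos = sample(0:99999, 5000, replace = TRUE),
                    strand = sample(c("+", "-"), 5000, replace = TRUE))
  d <- build_tag_directory(rec, per_position_cap = 3, chrom_sizes = cs)
  tags <- expand_tags(d)
  genes <- tss_records(c("gp", "gm", "gshort"), "chr1",
                       c(20000L, 80000L, 50000L), c("+", "-", "+"),
                       c(40000L, 60000L, 58000L))
  got <- quantify_gene_body(d, genes, normalize = FALSE)
  want <- c(
    sum(tags$pos >= 20500 & tags$pos < 33000 & tags$strand == "+"),
    sum(tags$pos > 67000 & tags$pos <= 79500 & tags$strand == "-"),
    sum(tags$pos >= 50500 & tags$pos < 58000 & tags$strand == "+"))
  expect_equal(got, want)
  expect_error(quantify_gene_body(
    d, tss_records("tiny", "chr1", 100L, "+", 500L)), "shorter")
})

test_that("tag directories serialize and reload losslessly", {
  withr::local_seed(19)
  d <- rand_directory(150)
  p <- withr::local_tempdir()
  write_tag_directory(d, p)
  d2 <- read_tag_directory(p)
  expect_equal(d2$tags, d$tags)
  expect_equal(d2$capped_total, d$capped_total)
  expect_equal(d2$chrom_sizes, d$chrom_sizes)

  ## tagAlign round trip preserves the tag multiset
  f <- withr::local_tempfile()
  write_tags(d, f)
  d3 <- build_tag_directory(read_tags(f), per_position_cap = 2,
                            chrom_sizes = d$chrom_sizes)
  expect_equal(d3$tags, d$tags)
})
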