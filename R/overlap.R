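## Interval overlap counting, Venn partitions, random-background enrichment
## and per-region tag correlations.
##
## Overlap semantics are half-open (BED/BEDTools): abutting intervals do not
## overlap; each query interval counts at most once however many subjects it
## touches.

#' Count query intervals overlapping a subject set
#'
#' A query interval is counted iff it shares at least `min_bp` base pairs
#' with some single subject interval (half-open coordinates; an abutment is
#' 0 bp of overlap).
#'
#' @param query,subject interval tables.
#' @param min_bp minimum single-subject overlap, bp.
#' @return integer count of overlapping query intervals.
#' @examples
#' a <- genomic_intervals("chr1", 0, 100)
#' b <- genomic_intervals("chr1", 50, 150)
#' overlap_count(a, b)  # 1
#' @export
overlap_count <- function(query, subject, min_bp = 1) {
  length(overlap_hits(query, subject, min_bp))
}

## indices of query intervals with >= min_bp overlap with some subject
overlap_hits <- function(query, subject, min_bp = 1) {
  validate_intervals(query)
  validate_intervals(subject)
  if (nrow(query) == 0 || nrow(subject) == 0) return(integer(0))
  q <- data.table(chrom = query$chrom, qs = query$start, qe = query$end,
                  qid = seq_len(nrow(query)))
  s <- data.table(chrom = subject$chrom, ss = subject$start,
                  se = subject$end)
  ## closed-interval join on [start, end - 1]
  q[, `:=`(lo = qs, hi = qe - 1L)]
  s[, `:=`(lo = ss, hi = se - 1L)]
  hits <- s[q, .(qid = i.qid, ov = pmin(x.hi + 1L, i.hi + 1L) -
                   pmax(x.lo, i.lo)),
            on = .(chrom, lo <= hi, hi >= lo), nomatch = 0L,
            allow.cartesian = TRUE]
  sort(unique(hits[ov >= min_bp, qid]))
}

#' Fraction of query intervals overlapping a subject set
#' @inheritParams overlap_count
#' @return `overlap_count / nrow(query)` (NaN for an empty query).
#' @export
overlap_fraction <- function(query, subject, min_bp = 1) {
  overlap_count(query, subject, min_bp) / nrow(query)
}

#' Venn partition of 2-3 named interval sets
#'
#' Each interval of each set gets a membership pattern from any-overlap
#' against the other sets; counting is per-set (an interval overlapping
#' several intervals of another set still counts once), so pattern counts
#' from different sets need not agree — both are reported.
#'
#' @param sets named list of 2 or 3 interval tables.
#' @param min_bp minimum overlap, bp.
#' @return `data.table`: set, pattern (member set names joined by "&"),
#'   count. Pattern counts within a set sum to that set's size.
#' @export
venn_partition <- function(sets, min_bp = 1) {
  if (length(sets) < 2 || length(sets) > 3)
    stop("venn_partition takes 2 or 3 sets", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named", call. = FALSE)
  nms <- names(sets)
  out <- list()
  for (i in seq_along(sets)) {
    x <- sets[[i]]
    member <- matrix(FALSE, nrow(x), length(sets),
                     dimnames = list(NULL, nms))
    member[, i] <- TRUE
    for (j in setdiff(seq_along(sets), i))
      member[overlap_hits(x, sets[[j]], min_bp), j] <- TRUE
    pattern <- apply(member, 1, function(m) paste(nms[m], collapse = "&"))
    tab <- table(pattern)
    out[[i]] <- data.table(set = nms[i], pattern = names(tab),
                           count = as.integer(tab))
  }
  rbindlist(out)
}

#' Seeded uniform random genomic regions
#'
#' Chromosomes are drawn with probability proportional to their length and
#' starts uniformly so the region fits; lengths are fixed (`length`) or
#' resampled with replacement from a matched interval set (`match_to`).
#' Bit-reproducible under `seed`; the caller's RNG stream is untouched.
#'
#' @param chrom_sizes named chromosome lengths.
#' @param n number of regions.
#' @param length fixed region length, bp (ignored when `match_to` given).
#' @param match_to optional interval table whose length distribution is
#'   resampled.
#' @param seed integer seed (`NULL` = use current RNG stream).
#' @param exclude optional interval table (e.g. assembly gaps); sampled
#'   regions overlapping it are redrawn (up to 100 rounds).
#' @return interval table of `n` regions.
#' @export
random_regions <- function(chrom_sizes, n, length = 1000, match_to = NULL,
                           seed = NULL, exclude = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  lens <- if (!is.null(match_to)) {
    if (nrow(match_to) == 0) stop("match_to is empty", call. = FALSE)
    widths <- match_to$end - match_to$start
    NULL  # sampled inside the seed scope below
  } else rep(as.integer(length), n)
  if (max(if (is.null(lens)) match_to$end - match_to$start else lens) >
      max(chrom_sizes))
    stop("region length exceeds the longest chromosome", call. = FALSE)
  with_seed(seed, {
    if (is.null(lens)) lens <- sample(widths, n, replace = TRUE)
    draw <- function(m, lenv) {
      ch <- sample(names(chrom_sizes), m, replace = TRUE,
                   prob = as.numeric(chrom_sizes))
      maxs <- unname(chrom_sizes[ch]) - lenv
      ok <- maxs >= 0
      st <- integer(m)
      st[ok] <- as.integer(floor(runif(sum(ok)) * (maxs[ok] + 1)))
      list(chrom = ch, start = st, ok = ok)
    }
    res <- data.table(chrom = NA_character_, start = NA_integer_,
                      len = lens)
    todo <- seq_len(n)
    for (round in 1:100) {
      if (!length(todo)) break
      d <- draw(length(todo), res$len[todo])
      good <- d$ok
      if (!is.null(exclude) && nrow(exclude) && any(good)) {
        cand <- data.table(chrom = d$chrom, start = d$start,
                           end = d$start + res$len[todo])[good]
        bad_idx <- overlap_hits(cand, exclude)
        good[which(good)[bad_idx]] <- FALSE
      }
      res$chrom[todo[good]] <- d$chrom[good]
      res$start[todo[good]] <- d$start[good]
      todo <- todo[!good]
    }
    if (length(todo))
      stop("could not place ", length(todo), " random region(s); ",
           "exclusion set too dense or regions too long", call. = FALSE)
    genomic_intervals(res$chrom, res$start, res$start + res$len,
                      name = paste0("rand_", seq_len(n)))
  })
}

#' Observed-vs-random overlap enrichment table
#'
#' For each named feature set, reports how many query intervals overlap it
#' and how many overlap a size-matched random background (regions resampled
#' from the query length distribution), plus the empirical enrichment ratio.
#'
#' @param query_peaks interval table (e.g. TOP1cc-enriched regions).
#' @param feature_sets named list of interval tables (e.g. ATAC, H3K27Ac,
#'   chromatin-mark peak sets).
#' @param chrom_sizes named chromosome lengths.
#' @param n_random number of random background regions.
#' @param seed seed for the background draw.
#' @param min_bp minimum overlap, bp.
#' @return `data.table`: feature, observed, random, n_query, n_random,
#'   enrichment (observed/n_query over random/n_random).
#' @export
enrichment_profile <- function(query_peaks, feature_sets, chrom_sizes,
                               n_random = 10000, seed = 1, min_bp = 1) {
  if (!length(feature_sets) || is.null(names(feature_sets)))
    stop("feature_sets must be a named, non-empty list", call. = FALSE)
  bg <- random_regions(chrom_sizes, n_random, match_to = query_peaks,
                       seed = seed)
  rbindlist(lapply(names(feature_sets), function(nm) {
    f <- feature_sets[[nm]]
    obs <- overlap_count(query_peaks, f, min_bp)
    rnd <- overlap_count(bg, f, min_bp)
    data.table(feature = nm, observed = obs, random = rnd,
               n_query = nrow(query_peaks), n_random = n_random,
               enrichment = (obs / nrow(query_peaks)) /
                 max(rnd / n_random, .Machine$double.eps))
  }))
}

#' Pearson correlation of per-region tag counts between two directories
#'
#' Counts normalized tags in `+/- halfwidth` windows of each region center in
#' both directories, optionally log2(x + pc) transforms, and returns the
#' Pearson r with its t-distributed p-value (two-sided by default; one-sided
#' "greater" available, matching one-tailed correlation testing).
#'
#' @param dir_a,dir_b `tag_directory` objects.
#' @param regions interval table (>= 3 regions).
#' @param halfwidth window half-width, bp.
#' @param log2 apply `log2(x + pc)` before correlating.
#' @param pc pseudocount for the log transform.
#' @param alternative "two.sided" (default) or "greater".
#' @return list: `r`, `pvalue`, `n`, plus the two count vectors (`a`, `b`).
#' @export
region_tag_correlation <- function(dir_a, dir_b, regions, halfwidth = 1000,
                                   log2 = TRUE, pc = 1,
                                   alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  validate_intervals(regions)
  if (nrow(regions) < 3) stop(">= 3 regions required", call. = FALSE)
  centers <- region_centers(regions)
  a <- count_window(dir_a, regions$chrom, centers, halfwidth)
  b <- count_window(dir_b, regions$chrom, centers, halfwidth)
  if (log2) {
    a <- base::log2(a + pc)
    b <- base::log2(b + pc)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in a count vector; correlation undefined",
         call. = FALSE)
  ct <- cor.test(a, b, method = "pearson", alternative = alternative)
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = nrow(regions),
       a = a, b = b)
}
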