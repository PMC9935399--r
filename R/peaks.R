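## Poisson-background peak calling and replicate concordance.
##
## The caller slides fixed windows, tests each against the larger of the
## genome-wide and local Poisson rates, and merges significant windows. It is
## deliberately pluggable: every consumer of peaks also accepts an external
## BED, because peak location (not the caller) is what the downstream
## enhancer definitions depend on.

#' Peak-caller configuration
#'
#' @param window sliding window width, bp.
#' @param step window step, bp (`window >= step > 0`).
#' @param pvalue_max Poisson upper-tail significance threshold.
#' @param fold_over_local_min minimum fold of the observed window count over
#'   the genome-wide expectation.
#' @param local_bg_span span (bp) of the local background window centered on
#'   each sliding window.
#' @param merge_gap significant windows closer than this are merged
#'   (default: `window`).
#' @return list of class `peak_call_config`.
#' @export
peak_call_config <- function(window = 200, step = 50, pvalue_max = 1e-5,
                             fold_over_local_min = 4, local_bg_span = 10000,
                             merge_gap = window) {
  if (!(window >= step && step > 0))
    stop("need window >= step > 0", call. = FALSE)
  if (!(pvalue_max > 0 && pvalue_max < 1))
    stop("pvalue_max must be in (0, 1)", call. = FALSE)
  structure(list(window = window, step = step, pvalue_max = pvalue_max,
                 fold_over_local_min = fold_over_local_min,
                 local_bg_span = local_bg_span, merge_gap = merge_gap),
            class = "peak_call_config")
}

## cumulative count of tags at positions <= x, given sorted pos / cumsum w
cnt_le <- function(posv, cw, x) {
  i <- findInterval(x, posv)
  ifelse(i == 0, 0, cw[pmax(i, 1)])
}

#' Call tag-enriched regions with a Poisson background model
#'
#' A window with `k` tags is significant iff the Poisson upper tail
#' `P(X >= k | lambda) <= pvalue_max`, with
#' `lambda = max(genome rate, local rate over local_bg_span) * window`, and
#' the fold over the genome-wide expectation `k / lambda_genome` is at least
#' `fold_over_local_min`. Overlapping or near-adjacent (<= `merge_gap`)
#' significant windows are merged; the summit is the (leftmost) position of
#' maximum tag count in the merged region and the score is its normalized
#' tag count.
#'
#' @param dir a `tag_directory`.
#' @param config a [peak_call_config()].
#' @param chrom_sizes named chromosome lengths (defines the search space).
#' @return peak table: chrom, start, end, name, score (tags-per-10M),
#'   strand ".", summit.
#' @export
call_peaks <- function(dir, config = peak_call_config(), chrom_sizes) {
  if (is.null(chrom_sizes)) stop("chrom_sizes required", call. = FALSE)
  if (config$window > min(chrom_sizes))
    stop("window larger than the smallest chromosome", call. = FALSE)
  genome_rate <- dir$capped_total / sum(chrom_sizes)
  span <- config$local_bg_span
  out <- list()
  for (ch in names(chrom_sizes)) {
    len <- chrom_sizes[[ch]]
    pc <- dir$tags[chrom == ch, .(w = sum(n)), by = pos]
    setorder(pc, pos)
    if (nrow(pc) == 0) next
    posv <- pc$pos
    cw <- cumsum(pc$w)
    starts <- seq(0, len - config$window, by = config$step)
    k <- cnt_le(posv, cw, starts + config$window - 1) -
      cnt_le(posv, cw, starts - 1)
    centers <- starts + config$window / 2
    llo <- pmax(0, centers - span / 2)
    lhi <- pmin(len, centers + span / 2)
    lk <- cnt_le(posv, cw, lhi - 1) - cnt_le(posv, cw, llo - 1)
    local_rate <- lk / (lhi - llo)
    lambda <- pmax(genome_rate, local_rate) * config$window
    pv <- ppois(k - 1, lambda, lower.tail = FALSE)
    sig <- k > 0 & pv <= config$pvalue_max &
      k >= config$fold_over_local_min * genome_rate * config$window
    if (!any(sig)) next
    s <- starts[sig]
    cl <- cumsum(c(TRUE, s[-1] - (s[-length(s)] + config$window) >
                     config$merge_gap))
    for (ci in unique(cl)) {
      cs <- s[cl == ci]
      rs <- min(cs)
      re <- max(cs) + config$window
      sub <- pc[pos >= rs & pos < re]
      summit <- sub$pos[which.max(sub$w)]
      raw <- sum(sub$w)
      out[[length(out) + 1L]] <- data.table(
        chrom = ch, start = as.integer(rs), end = as.integer(re),
        score = normalized_count(dir, raw), strand = ".",
        summit = as.integer(summit))
    }
  }
  if (!length(out))
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), summit = integer()))
  peaks <- rbindlist(out)
  setorder(peaks, chrom, start)
  peaks[, name := paste0("peak_", .I)]
  setcolorder(peaks, c("chrom", "start", "end", "name", "score", "strand",
                       "summit"))
  peaks[]
}

#' Read / write peaks as BED6+1 (summit offset in column 7)
#'
#' @param peaks peak table from [call_peaks()].
#' @param path file path.
#' @return the peak table / the path, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  lines <- paste(peaks$chrom, fmt_num(peaks$start), fmt_num(peaks$end),
                 peaks$name, fmt_num(peaks$score), peaks$strand,
                 fmt_num(peaks$summit - peaks$start), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  x <- read_intervals(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  off <- vapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) >= 7) suppressWarnings(as.integer(f[7])) else NA_integer_
  }, integer(1))
  x[, summit := ifelse(is.na(off), region_centers(x), start + off)]
  x[]
}

#' Peak summits (falling back to region centers)
#' @param peaks peak/interval table.
#' @return integer positions.
#' @export
peak_summits <- function(peaks) {
  if (!is.null(peaks$summit)) as.integer(peaks$summit)
  else region_centers(peaks)
}

#' Replicate-concordant peaks (summit-distance filter)
#'
#' Retains peaks from the first set whose summit lies within
#' `max_center_dist` of a summit in at least `min_replicates - 1` of the
#' other sets. This is a documented, deterministic substitute for the IDR
#' reproducibility framework (the copula-mixture IDR model is out of scope).
#'
#' @param peak_sets list (length >= 2) of peak tables.
#' @param min_replicates number of sets (including the first) a peak must be
#'   supported by.
#' @param max_center_dist summit distance tolerance, bp.
#' @return the concordant subset of `peak_sets[[1]]`.
#' @export
concordant_peaks <- function(peak_sets, min_replicates = 2,
                             max_center_dist = 100) {
  if (length(peak_sets) < 2) stop(">= 2 peak sets required", call. = FALSE)
  if (min_replicates > length(peak_sets))
    stop("min_replicates exceeds the number of peak sets", call. = FALSE)
  p1 <- peak_sets[[1]]
  if (nrow(p1) == 0) return(p1)
  s1 <- peak_summits(p1)
  support <- rep(0L, nrow(p1))
  for (other in peak_sets[-1]) {
    if (nrow(other) == 0) next
    so <- peak_summits(other)
    hit <- vapply(seq_len(nrow(p1)), function(i) {
      j <- other$chrom == p1$chrom[i]
      any(j) && min(abs(so[j] - s1[i])) <= max_center_dist
    }, logical(1))
    support <- support + hit
  }
  p1[support >= min_replicates - 1L]
}

#' Putative enhancers: fixed flanks around anchor peak centers
#'
#' Emits `[center - flank, center + flank)` around each anchor (TF or
#' accessibility) peak center, annotated with the normalized H3K27Ac tag
#' count of the window, and drops regions whose center lies within
#' `tss_min_dist` of an annotated TSS when a TSS set is supplied. Anchors
#' whose window would extend past a chromosome edge are dropped (with a
#' warning) when `chrom_sizes` is available.
#'
#' @param anchor_peaks peak table (summits used as centers when present).
#' @param k27ac_dir H3K27Ac `tag_directory` used for window scores.
#' @param flank half-width, bp (default 1000).
#' @param tss_set optional TSS table for the distal filter.
#' @param tss_min_dist minimum center-to-TSS distance, bp (default 3000).
#' @param chrom_sizes optional chromosome lengths (edge handling).
#' @return interval table with columns chrom, start, end, name, score,
#'   strand, center, k27ac, tss_dist.
#' @export
define_putative_enhancers <- function(anchor_peaks, k27ac_dir, flank = 1000,
                                      tss_set = NULL, tss_min_dist = 3000,
                                      chrom_sizes = NULL) {
  centers <- peak_summits(anchor_peaks)
  x <- data.table(chrom = anchor_peaks$chrom,
                  start = as.integer(centers - flank),
                  end = as.integer(centers + flank),
                  name = paste0("enh_", seq_along(centers)),
                  score = 0, strand = ".", center = as.integer(centers))
  chrom_sizes <- chrom_sizes %||% k27ac_dir$chrom_sizes
  if (!is.null(chrom_sizes)) {
    ok <- x$start >= 0 & x$end <= unname(chrom_sizes[x$chrom])
    if (!all(ok)) {
      warning(sum(!ok), " anchor(s) within one flank of a chromosome edge ",
              "dropped")
      x <- x[ok]
    }
  } else if (any(x$start < 0)) {
    warning(sum(x$start < 0), " anchor(s) too close to position 0 dropped")
    x <- x[start >= 0]
  }
  if (nrow(x) == 0) {
    x[, `:=`(k27ac = numeric(0), tss_dist = numeric(0))]
    return(x[])
  }
  x[, k27ac := count_window(k27ac_dir, chrom, center, halfwidth = flank)]
  x[, score := k27ac]
  if (!is.null(tss_set) && nrow(tss_set)) {
    x[, tss_dist := distance_to_nearest_tss(x, tss_set)]
    x <- x[tss_dist >= tss_min_dist]
  } else x[, tss_dist := Inf]
  x[]
}
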