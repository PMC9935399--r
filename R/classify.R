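## Enhancer-group classification.
##
## All six signal-dependent enhancer groups share a common distal/active gate
## (center >= 3 kb from any TSS, >= 16 normalized H3K27Ac tags in the
## +/- 1 kb window) and then differ in which nascent-transcription or Pol II
## criteria they apply. Thresholds are inclusive (>= 16, >= 10, FC >= 1.5)
## except the "unchanged" fold-change band, which is the open interval
## (0.67, 1.5).

#' Classification thresholds
#'
#' Defaults are the published tag-count criteria: distal gate 3 kb from TSSs,
#' H3K27Ac floor 16 tags-per-10M, nascent (PRO-seq) floor 10, Pol II floor
#' 10 (16 together with the TF floor in the proinflammatory scheme),
#' induction fold-change 1.5 with the unchanged band (0.67, 1.5) exclusive.
#' The fold-change pseudocount (1 normalized tag) is this package's choice
#' and is configurable.
#'
#' @param tss_min_dist bp, minimum center-to-TSS distance.
#' @param k27ac_min tags-per-10M H3K27Ac floor.
#' @param nascent_min tags-per-10M PRO-seq floor.
#' @param fc_up induced fold-change threshold (inclusive).
#' @param fc_band_lo lower edge of the unchanged band (exclusive); upper edge
#'   is `fc_up` (exclusive).
#' @param polii_min tags-per-10M Pol II floor (androgen/neuronal schemes).
#' @param polii_tf_min tags-per-10M Pol II and TF floor (proinflammatory).
#' @param fc_pseudocount pseudocount added to both sides of fold changes.
#' @return list of class `classify_config`.
#' @export
classify_config <- function(tss_min_dist = 3000, k27ac_min = 16,
                            nascent_min = 10, fc_up = 1.5, fc_band_lo = 0.67,
                            polii_min = 10, polii_tf_min = 16,
                            fc_pseudocount = 1) {
  stopifnot(tss_min_dist > 0, k27ac_min > 0, nascent_min > 0, fc_up > 0,
            fc_band_lo > 0, fc_band_lo < fc_up, polii_min > 0,
            polii_tf_min > 0, fc_pseudocount >= 0)
  structure(list(tss_min_dist = tss_min_dist, k27ac_min = k27ac_min,
                 nascent_min = nascent_min, fc_up = fc_up,
                 fc_band_lo = fc_band_lo, polii_min = polii_min,
                 polii_tf_min = polii_tf_min,
                 fc_pseudocount = fc_pseudocount),
            class = "classify_config")
}

#' Enhancer class labels
#' @return character vector of every label the classifiers can emit.
#' @export
enhancer_labels <- function() {
  c("megatrans", "eralpha_other_active", "other_active", "proinflammatory",
    "androgen_induced", "neuronal_induced", "unclassified")
}

#' Classify hormone-responsive enhancers (MegaTrans / other-active groups)
#'
#' Vectorized over regions. Gate: `tss_dist >= tss_min_dist` and
#' `k27ac >= k27ac_min`, else unclassified. With
#' `fc = (nascent_treated + pc) / (nascent_control + pc)`:
#' * ER-marked, `nascent_treated >= nascent_min`, `fc >= fc_up` -> megatrans
#'   (robustly hormone-induced eRNA transcription);
#' * ER-marked, both conditions `>= nascent_min`, fc in the open band ->
#'   eralpha_other_active (constitutively transcribed, receptor-bound);
#' * not ER-marked, both conditions `>= nascent_min`, fc in the band ->
#'   other_active;
#' * anything else -> unclassified.
#'
#' @param k27ac normalized H3K27Ac tags in the region window.
#' @param nascent_treated,nascent_control normalized PRO-seq tags in the
#'   +/- 1 kb window under treated / vehicle conditions.
#' @param tss_dist center-to-TSS distance, bp.
#' @param era_marked logical: region anchored by an ER-alpha peak.
#' @param config a [classify_config()].
#' @return `data.table` with `label` plus every compared metric
#'   (tss_dist, k27ac, nascent_treated, nascent_control, fc, era_marked).
#' @export
classify_hormone_enhancer <- function(k27ac, nascent_treated,
                                      nascent_control, tss_dist, era_marked,
                                      config = classify_config()) {
  nq <- max(length(k27ac), length(nascent_treated), length(nascent_control),
            length(tss_dist), length(era_marked))
  k27ac <- rep_len(k27ac, nq); nascent_treated <- rep_len(nascent_treated, nq)
  nascent_control <- rep_len(nascent_control, nq)
  tss_dist <- rep_len(tss_dist, nq); era_marked <- rep_len(era_marked, nq)
  if (any(c(k27ac, nascent_treated, nascent_control) < 0))
    stop("negative tag counts", call. = FALSE)
  pc <- config$fc_pseudocount
  fc <- (nascent_treated + pc) / (nascent_control + pc)
  gate <- tss_dist >= config$tss_min_dist & k27ac >= config$k27ac_min
  in_band <- fc > config$fc_band_lo & fc < config$fc_up
  mega <- gate & era_marked & nascent_treated >= config$nascent_min &
    fc >= config$fc_up
  band_ok <- gate & pmin(nascent_treated, nascent_control) >=
    config$nascent_min & in_band
  label <- rep("unclassified", nq)
  label[band_ok & !era_marked] <- "other_active"
  label[band_ok & era_marked] <- "eralpha_other_active"
  label[mega] <- "megatrans"
  data.table(label = label, tss_dist = tss_dist, k27ac = k27ac,
             nascent_treated = nascent_treated,
             nascent_control = nascent_control, fc = fc,
             era_marked = era_marked)
}

#' Classify acutely induced enhancers (TNF-alpha / DHT / KCl schemes)
#'
#' Common gate as in [classify_hormone_enhancer()]. Then:
#' * `proinflammatory`: Pol II and TF (p65) treated counts both
#'   `>= polii_tf_min` — no fold-change criterion;
#' * `androgen`: Pol II and TF (AR) treated counts `>= polii_min` and Pol II
#'   fold change (treated over vehicle, pseudocounted) `>= fc_up` ->
#'   androgen_induced;
#' * `neuronal`: Pol II treated `>= polii_min` and Pol II fold change
#'   (KCl 30 min over 0 min) `>= fc_up` -> neuronal_induced (TF ignored).
#'
#' @param k27ac normalized H3K27Ac tags.
#' @param polii_treated,polii_control normalized Pol II tags per condition
#'   (`polii_control` ignored by the proinflammatory scheme).
#' @param tf_treated normalized signal-dependent TF tags (ignored by the
#'   neuronal scheme).
#' @param tss_dist center-to-TSS distance, bp.
#' @param scheme "proinflammatory", "androgen" or "neuronal".
#' @param config a [classify_config()].
#' @return `data.table` with `label` and the compared metrics.
#' @export
classify_induced_enhancer <- function(k27ac, polii_treated,
                                      polii_control = NA_real_,
                                      tf_treated = NA_real_, tss_dist,
                                      scheme = c("proinflammatory",
                                                 "androgen", "neuronal"),
                                      config = classify_config()) {
  scheme <- match.arg(scheme)
  nq <- max(length(k27ac), length(polii_treated), length(polii_control),
            length(tf_treated), length(tss_dist))
  k27ac <- rep_len(k27ac, nq); polii_treated <- rep_len(polii_treated, nq)
  polii_control <- rep_len(polii_control, nq)
  tf_treated <- rep_len(tf_treated, nq); tss_dist <- rep_len(tss_dist, nq)
  if (any(stats::na.omit(c(k27ac, polii_treated, polii_control,
                           tf_treated)) < 0))
    stop("negative tag counts", call. = FALSE)
  pc <- config$fc_pseudocount
  gate <- tss_dist >= config$tss_min_dist & k27ac >= config$k27ac_min
  fc <- (polii_treated + pc) / (polii_control + pc)
  hit <- switch(scheme,
    proinflammatory = polii_treated >= config$polii_tf_min &
      tf_treated >= config$polii_tf_min,
    androgen = polii_treated >= config$polii_min &
      tf_treated >= config$polii_min & fc >= config$fc_up,
    neuronal = polii_treated >= config$polii_min & fc >= config$fc_up)
  target <- switch(scheme, proinflammatory = "proinflammatory",
                   androgen = "androgen_induced",
                   neuronal = "neuronal_induced")
  label <- ifelse(gate & !is.na(hit) & hit, target, "unclassified")
  out <- data.table(label = label, tss_dist = tss_dist, k27ac = k27ac,
                    polii_treated = polii_treated)
  if (scheme != "proinflammatory") out[, `:=`(polii_control = polii_control,
                                              fc = fc)]
  if (scheme != "neuronal") out[, tf_treated := tf_treated]
  out[]
}

#' Flag regions enriched for a feature (e.g. TOP1cc) by summit proximity
#'
#' A region is flagged iff some feature-peak summit lies within
#' `max_center_dist` of the region center. The +/- 1,000 bp default matches
#' the putative-enhancer flank. Partitions any class into enriched /
#' non-enriched subsets.
#'
#' @param calls table with chrom/start/end columns (e.g. [classify_all()]
#'   output).
#' @param feature_peaks peak table (summits used when present).
#' @param max_center_dist bp tolerance.
#' @param flag_name name of the added logical column.
#' @return `calls` with the flag column added.
#' @export
annotate_feature_enrichment <- function(calls, feature_peaks,
                                        max_center_dist = 1000,
                                        flag_name = "top1cc_enriched") {
  calls <- as.data.table(calls)
  centers <- region_centers(calls)
  flag <- rep(FALSE, nrow(calls))
  if (nrow(feature_peaks)) {
    su <- peak_summits(feature_peaks)
    by_chrom <- split(su, feature_peaks$chrom)
    flag <- vapply(seq_len(nrow(calls)), function(i) {
      s <- by_chrom[[calls$chrom[i]]]
      !is.null(s) && min(abs(s - centers[i])) <= max_center_dist
    }, logical(1))
  }
  calls[, (flag_name) := flag]
  calls[]
}

#' Bundle tag directories by (assay, condition)
#'
#' The unit the vectorized classifier consumes: a keyed map
#' `"assay/condition" -> tag_directory`.
#'
#' @param ... `tag_directory` objects (keys derived from their labels), or a
#'   single named list of directories.
#' @return list of class `assay_bundle`.
#' @export
assay_bundle <- function(...) {
  dirs <- list(...)
  if (length(dirs) == 1 && is.list(dirs[[1]]) &&
      !inherits(dirs[[1]], "tag_directory"))
    dirs <- dirs[[1]]
  if (is.null(names(dirs)) || any(!nzchar(names(dirs))))
    names(dirs) <- vapply(dirs, function(d)
      paste(d$assay, d$condition, sep = "/"), "")
  if (anyDuplicated(names(dirs)))
    stop("duplicate (assay, condition) keys in bundle", call. = FALSE)
  structure(dirs, class = "assay_bundle")
}

scheme_keys <- function(scheme) {
  switch(scheme,
         hormone = c("k27ac/treated", "nascent/treated", "nascent/control"),
         proinflammatory = c("k27ac/treated", "polii/treated", "tf/treated"),
         androgen = c("k27ac/treated", "polii/treated", "polii/control",
                      "tf/treated"),
         neuronal = c("k27ac/treated", "polii/treated", "polii/control"),
         stop("unknown scheme: ", scheme, call. = FALSE))
}

bundle_get <- function(bundle, keys) {
  miss <- setdiff(keys, names(bundle))
  if (length(miss))
    stop("bundle is missing required (assay, condition) key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bundle[keys]
}

#' Classify a set of candidate regions from tag data
#'
#' Vectorized driver: computes every metric with [count_window()]
#' (H3K27Ac over the region window; nascent/Pol II over +/- `halfwidth` of
#' the region center, both strands pooled), derives TSS distances and
#' optional receptor marking from anchor peaks, then applies the per-region
#' classifier for the requested scheme. Deterministic given inputs.
#'
#' @param regions interval table of candidate enhancers (typically from
#'   [define_putative_enhancers()]).
#' @param bundle an [assay_bundle()]; required keys per scheme:
#'   hormone -> k27ac/treated, nascent/treated, nascent/control;
#'   proinflammatory -> k27ac/treated, polii/treated, tf/treated;
#'   androgen -> those plus polii/control; neuronal -> k27ac/treated,
#'   polii/treated, polii/control.
#' @param tss_set TSS table for the distal gate.
#' @param scheme "hormone", "proinflammatory", "androgen" or "neuronal".
#' @param config a [classify_config()].
#' @param marked_peaks optional receptor (ER-alpha) anchor peaks; a region is
#'   marked iff a summit lies within `halfwidth` of its center. For the
#'   hormone scheme, omitting it marks every region.
#' @param halfwidth quantification half-width, bp (default 1000).
#' @return `data.table`: chrom, start, end, name, label, metrics.
#' @export
classify_all <- function(regions, bundle, tss_set,
                         scheme = c("hormone", "proinflammatory", "androgen",
                                    "neuronal"),
                         config = classify_config(), marked_peaks = NULL,
                         halfwidth = 1000) {
  scheme <- match.arg(scheme)
  regions <- as.data.table(regions)
  validate_intervals(regions)
  if (nrow(regions) == 0)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      label = character()))
  dirs <- bundle_get(bundle, scheme_keys(scheme))
  centers <- region_centers(regions)
  tss_dist <- distance_to_nearest_tss(regions, tss_set)
  k27 <- count_window(dirs[["k27ac/treated"]], regions$chrom, centers,
                      halfwidth = halfwidth)
  marked <- if (is.null(marked_peaks)) rep(TRUE, nrow(regions)) else {
    flagged <- annotate_feature_enrichment(
      regions[, .(chrom, start, end)], marked_peaks,
      max_center_dist = halfwidth, flag_name = "marked")
    flagged$marked
  }
  res <- if (scheme == "hormone") {
    nt <- count_window(dirs[["nascent/treated"]], regions$chrom, centers,
                       halfwidth = halfwidth)
    nc <- count_window(dirs[["nascent/control"]], regions$chrom, centers,
                       halfwidth = halfwidth)
    classify_hormone_enhancer(k27, nt, nc, tss_dist, marked, config)
  } else {
    pt <- count_window(dirs[["polii/treated"]], regions$chrom, centers,
                       halfwidth = halfwidth)
    pc0 <- if ("polii/control" %in% names(dirs))
      count_window(dirs[["polii/control"]], regions$chrom, centers,
                   halfwidth = halfwidth) else NA_real_
    tf <- if ("tf/treated" %in% names(dirs))
      count_window(dirs[["tf/treated"]], regions$chrom, centers,
                   halfwidth = halfwidth) else NA_real_
    classify_induced_enhancer(k27, pt, pc0, tf, tss_dist, scheme, config)
  }
  nm <- if (is.null(regions$name)) paste0("region_", seq_len(nrow(regions)))
        else regions$name
  cbind(data.table(chrom = regions$chrom, start = regions$start,
                   end = regions$end, name = nm), res)
}

#' Write classification calls as TSV
#'
#' chrom, start, end, label, flags, then one column per metric.
#'
#' @param calls [classify_all()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  fwrite(calls, path, sep = "\t")
  invisible(path)
}
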