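## End-to-end orchestration: simulate (optional) -> tag directories ->
## peaks -> putative enhancers -> classification -> TOP1cc annotation ->
## differential -> overlap enrichment -> profile matrices, with a
## machine-readable run log. All stage outputs are plain TSV/JSON and
## byte-reproducible under a fixed manifest + seed.

read_manifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1) {
    if (!file.exists(manifest))
      stop("manifest not found: ", manifest, call. = FALSE)
    if (grepl("\\.json$", manifest))
      jsonlite::read_json(manifest, simplifyVector = TRUE)
    else yaml::read_yaml(manifest)
  } else if (is.list(manifest)) manifest
  else stop("manifest must be a path or a list", call. = FALSE)
}

log_line <- function(con, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

#' Run the full analysis pipeline from a manifest
#'
#' In synthetic mode (`manifest$synthetic`, a list of [synthetic_config()]
#' overrides — possibly empty) the world is generated and every stage runs
#' against it, ending with a label-recovery report against the planted
#' truth. In fixture mode (`manifest$fixture`, a directory written by
#' [write_fixture_bundle()], or explicit `manifest$tags` +
#' `manifest$chrom_sizes` + `manifest$tss` paths) tags are read from disk.
#' A missing (assay, condition) key required by the requested scheme(s)
#' aborts with an error naming the key. Outputs: stage TSVs, a JSON
#' recovery report (synthetic mode) and a JSON-lines run log echoing every
#' parameter; reruns with the same manifest are byte-identical.
#'
#' @param manifest list, or path to a YAML/JSON manifest.
#' @param outdir output directory (created; reused if existing).
#' @return invisibly, a list with the main in-memory results (truth, calls,
#'   peaks, differential tables, enrichment, recovery).
#' @export
run_pipeline <- function(manifest = list(synthetic = list()),
                         outdir = tempfile("enhancerkit_run_")) {
  m <- read_manifest(manifest)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(outdir, "run_log.jsonl"), "w")
  on.exit(close(logf))
  schemes <- m$schemes %||% NULL

  if (!is.null(m$synthetic) || (is.null(m$fixture) && is.null(m$tags))) {
    cfg <- do.call(synthetic_config, m$synthetic %||% list())
    log_line(logf, "config", package = "enhancerkit",
             version = as.character(utils::packageVersion("enhancerkit")),
             mode = "synthetic", parameters = unclass(cfg))
    annotation <- generate_annotation(cfg)
    truth <- plant_enhancers(cfg, annotation)
    bundle <- simulate_bundle(truth)
    write_chrom_sizes(annotation$chrom_sizes,
                      file.path(outdir, "chrom.sizes"))
    write_tss(annotation$tss, file.path(outdir, "tss.tsv"))
    fwrite(truth$loci, file.path(outdir, "truth_loci.tsv"), sep = "\t")
    fwrite(truth$genes, file.path(outdir, "truth_genes.tsv"), sep = "\t")
    chrom_sizes <- annotation$chrom_sizes
    tss <- annotation$tss
    if (is.null(schemes))
      schemes <- c("hormone",
                   if (cfg$n_induced > 0) cfg$induced_scheme)
    seed <- cfg$seed
  } else {
    truth <- NULL
    if (!is.null(m$fixture)) {
      fx <- read_manifest(file.path(m$fixture, "manifest.yaml"))
      base <- m$fixture
      chrom_sizes <- read_chrom_sizes(file.path(base, fx$chrom_sizes))
      tss <- read_tss(file.path(base, fx$tss))
      tag_paths <- lapply(fx$tags, function(f) file.path(base, f))
      seed <- fx$seed %||% 1
      if (!is.null(fx$truth_loci) &&
          file.exists(file.path(base, fx$truth_loci))) {
        loci <- fread(file.path(base, fx$truth_loci), sep = "\t")
        genes <- fread(file.path(base, fx$truth_genes), sep = "\t")
        truth <- structure(list(loci = loci, genes = genes,
                                config = synthetic_config(
                                  genome = chrom_sizes, seed = seed,
                                  induced_scheme = fx$induced_scheme %||%
                                    "androgen"),
                                annotation = list(chrom_sizes = chrom_sizes,
                                                  tss = tss)),
                           class = "truth_table")
        if (is.null(schemes))
          schemes <- c("hormone", fx$induced_scheme %||% "androgen")
      }
    } else {
      chrom_sizes <- read_chrom_sizes(m$chrom_sizes)
      tss <- read_tss(m$tss)
      tag_paths <- m$tags
      seed <- m$seed %||% 1
    }
    schemes <- schemes %||% "hormone"
    needed <- unique(c(unlist(lapply(schemes, scheme_keys)),
                       "top1cc/treated", "era/treated"))
    miss <- setdiff(intersect(needed, unlist(lapply(schemes, scheme_keys))),
                    names(tag_paths))
    if (length(miss))
      stop("manifest is missing tag file(s) for key(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    bundle <- assay_bundle(lapply(
      setNames(names(tag_paths), names(tag_paths)), function(k) {
        parts <- strsplit(k, "/", fixed = TRUE)[[1]]
        build_tag_directory(
          read_tags(tag_paths[[k]]), assay = parts[1],
          condition = parts[2] %||% "treated",
          per_position_cap = if (parts[1] == "nascent") 3L else 2L,
          chrom_sizes = chrom_sizes)
      }))
    log_line(logf, "config", package = "enhancerkit",
             version = as.character(utils::packageVersion("enhancerkit")),
             mode = "fixture", schemes = schemes, seed = seed)
  }
  ccfg <- do.call(classify_config, m$classify %||% list())
  pcfg <- do.call(peak_call_config, m$peaks %||% list())
  log_line(logf, "thresholds", classify = unclass(ccfg),
           peak_calling = unclass(pcfg))

  ## peak calling on TOP1cc and the receptor anchor assay
  top1cc_peaks <- era_peaks <- NULL
  if ("top1cc/treated" %in% names(bundle)) {
    top1cc_peaks <- call_peaks(bundle[["top1cc/treated"]], pcfg,
                               chrom_sizes)
    write_peaks(top1cc_peaks, file.path(outdir, "top1cc_peaks.bed"))
    log_line(logf, "callpeaks", assay = "top1cc", n = nrow(top1cc_peaks))
  }
  if ("era/treated" %in% names(bundle)) {
    era_peaks <- call_peaks(bundle[["era/treated"]], pcfg, chrom_sizes)
    write_peaks(era_peaks, file.path(outdir, "era_peaks.bed"))
    log_line(logf, "callpeaks", assay = "era", n = nrow(era_peaks))
  }

  ## putative enhancers anchored on receptor peaks
  enhancers <- NULL
  if (!is.null(era_peaks) && "k27ac/treated" %in% names(bundle)) {
    enhancers <- define_putative_enhancers(
      era_peaks, bundle[["k27ac/treated"]], flank = 1000, tss_set = tss,
      tss_min_dist = ccfg$tss_min_dist, chrom_sizes = chrom_sizes)
    write_intervals(enhancers[, .(chrom, start, end, name, score,
                                  strand)],
                    file.path(outdir, "putative_enhancers.bed"))
    log_line(logf, "enhancers", n = nrow(enhancers))
  }

  ## classification: planted regions when truth is available, otherwise the
  ## putative-enhancer set
  calls <- list()
  recovery <- NULL
  region_src <- if (!is.null(truth)) truth_regions(truth)
                else enhancers
  for (scheme in schemes) {
    regions <- region_src
    res <- classify_all(regions, bundle, tss, scheme = scheme,
                        config = ccfg, marked_peaks = era_peaks)
    if (!is.null(top1cc_peaks))
      res <- annotate_feature_enrichment(res, top1cc_peaks)
    calls[[scheme]] <- res
    write_calls(res, file.path(outdir, paste0("calls_", scheme, ".tsv")))
    log_line(logf, "classify", scheme = scheme,
             labels = as.list(table(res$label)))
  }
  if (!is.null(truth)) {
    recovery <- recovery_report(truth, calls,
                                top1cc_peaks = top1cc_peaks)
    jsonlite::write_json(recovery, file.path(outdir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line(logf, "recovery", label_recovery = recovery$label_recovery,
             decoy_rejection = recovery$decoy_rejection,
             top1cc_recall = recovery$top1cc_recall)
  }

  ## differential eRNAs / genes between nascent conditions
  diff_ernas <- diff_genes <- NULL
  if (all(c("nascent/treated", "nascent/control") %in% names(bundle))) {
    centers <- if (!is.null(truth))
      data.table(chrom = truth$loci$chrom, pos = truth$loci$center,
                 name = truth$loci$locus)
    else if (!is.null(enhancers))
      data.table(chrom = enhancers$chrom, pos = region_centers(enhancers),
                 name = enhancers$name)
    if (!is.null(centers)) {
      diff_ernas <- differential_ernas(bundle[["nascent/control"]],
                                       bundle[["nascent/treated"]],
                                       centers)
      fwrite(diff_ernas, file.path(outdir, "differential_ernas.tsv"),
             sep = "\t")
      log_line(logf, "diff_ernas", calls = as.list(table(diff_ernas$call)))
    }
    if (nrow(tss)) {
      diff_genes <- differential_genes(bundle[["nascent/control"]],
                                       bundle[["nascent/treated"]], tss,
                                       test = "poisson_exact")
      fwrite(diff_genes, file.path(outdir, "differential_genes.tsv"),
             sep = "\t")
      log_line(logf, "diff_genes", calls = as.list(table(diff_genes$call)))
    }
  }

  ## overlap enrichment of TOP1cc regions vs features and random background
  enrichment <- NULL
  if (!is.null(top1cc_peaks) && nrow(top1cc_peaks) &&
      !is.null(era_peaks)) {
    feats <- list(era = era_peaks)
    if (!is.null(enhancers) && nrow(enhancers))
      feats$putative_enhancers <- enhancers
    enrichment <- enrichment_profile(top1cc_peaks, feats, chrom_sizes,
                                     n_random = m$n_random %||% 2000,
                                     seed = child_seed(seed, "enrichment"))
    fwrite(enrichment, file.path(outdir, "enrichment.tsv"), sep = "\t")
    log_line(logf, "enrichment", n_features = nrow(enrichment))
  }

  ## average profile of TOP1cc signal around classified enhancer centers
  if (!is.null(top1cc_peaks) && length(calls)) {
    first <- calls[[1]]
    hit <- first[label != "unclassified"]
    if (nrow(hit) >= 2) {
      pm <- profile_matrix(bundle[["top1cc/treated"]],
                           data.table(chrom = hit$chrom,
                                      pos = region_centers(hit)),
                           flank = 3000, binsize = 100,
                           chrom_sizes = chrom_sizes)
      hist <- profile_histogram(pm)
      fwrite(data.table(offset = as.integer(names(hist)),
                        mean_tags = hist),
             file.path(outdir, "top1cc_profile.tsv"), sep = "\t")
      log_line(logf, "profile", n_regions = nrow(hit))
    }
  }
  log_line(logf, "done", outdir = outdir)
  invisible(list(truth = truth, bundle = bundle, calls = calls,
                 top1cc_peaks = top1cc_peaks, era_peaks = era_peaks,
                 enhancers = enhancers, diff_ernas = diff_ernas,
                 diff_genes = diff_genes, enrichment = enrichment,
                 recovery = recovery, outdir = outdir))
}

#' Label-recovery report against planted truth
#'
#' Compares classifier output to the planted classes: fraction of planted
#' (non-decoy) labels recovered by the matching scheme, fraction of decoys
#' rejected (labelled unclassified), and TOP1cc flag recall at planted
#' TOP1cc loci.
#'
#' @param truth a `truth_table`.
#' @param calls named list of [classify_all()] outputs (one per scheme),
#'   with regions named by truth locus ids.
#' @param top1cc_peaks optional peak table used for flag recall.
#' @return list with per-class tallies and the three headline rates.
#' @export
recovery_report <- function(truth, calls, top1cc_peaks = NULL) {
  li <- truth$loci
  hormone_classes <- c("megatrans", "eralpha_other_active", "other_active")
  induced_classes <- c("proinflammatory", "androgen_induced",
                       "neuronal_induced")
  got <- rbindlist(lapply(names(calls), function(s)
    data.table(scheme = s, name = calls[[s]]$name,
               label = calls[[s]]$label)), fill = TRUE)
  per_class <- list()
  n_ok <- n_tot <- 0
  for (cl in intersect(unique(li$class),
                       c(hormone_classes, induced_classes))) {
    scheme_wanted <- if (cl %in% hormone_classes) "hormone"
      else switch(cl, proinflammatory = "proinflammatory",
                  androgen_induced = "androgen",
                  neuronal_induced = "neuronal")
    ids <- li[class == cl, locus]
    sub <- got[scheme == scheme_wanted & name %in% ids]
    ok <- sum(sub$label == cl)
    per_class[[cl]] <- list(planted = length(ids), recovered = ok)
    n_ok <- n_ok + ok
    n_tot <- n_tot + length(ids)
  }
  decoy_ids <- li[grepl("^decoy", class), locus]
  decoy_rej <- NA_real_
  if (length(decoy_ids)) {
    sub <- got[name %in% decoy_ids]
    by_id <- sub[, .(rejected = all(label == "unclassified")), by = name]
    decoy_rej <- mean(by_id$rejected)
  }
  top1cc_recall <- NA_real_
  if (!is.null(top1cc_peaks)) {
    flagged <- li[top1cc == TRUE]
    if (nrow(flagged)) {
      ann <- annotate_feature_enrichment(
        data.table(chrom = flagged$chrom, start = flagged$center - 1000L,
                   end = flagged$center + 1000L),
        top1cc_peaks)
      top1cc_recall <- mean(ann$top1cc_enriched)
    }
  }
  list(label_recovery = if (n_tot) n_ok / n_tot else NA_real_,
       decoy_rejection = decoy_rej, top1cc_recall = top1cc_recall,
       per_class = per_class, n_planted = n_tot)
}
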