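## Synthetic genome, annotation and tag data with planted ground truth.
##
## The generator states a desk-scale world: a 10-Mb chromosome whose
## libraries are dominated by planted signal (Poisson tag masses with
## Gaussian positional spread) over a very sparse uniform background, with
## per-condition expected library sizes balanced by uniform filler tags so
## that per-directory normalization does not distort planted fold changes
## (emulating depth-matched sequencing). Ground truth (locus classes,
## masses, flags) is carried in a truth table for recovery testing.

#' Synthetic-world configuration
#'
#' Defaults plant 200 enhancers across classes (50 hormone-induced
#' "megatrans", 50 receptor-bound band, 50 unbound band, 50 acutely induced
#' under the chosen scheme) plus 30 decoys that each violate exactly one
#' classification gate (TSS distance, H3K27Ac floor, nascent floor).
#'
#' @param genome named chromosome lengths (default one 10-Mb chromosome).
#' @param n_genes number of genes; bodies are placed without overlap, gene
#'   lengths log-uniform in `gene_length_range`.
#' @param gene_length_range bp range for gene lengths.
#' @param n_megatrans,n_eralpha_other,n_other_active,n_induced per-class
#'   enhancer counts.
#' @param induced_scheme which acute scheme the induced loci emulate.
#' @param n_decoy_tss,n_decoy_k27ac,n_decoy_nascent decoy counts violating,
#'   respectively, the TSS-distance gate, the H3K27Ac floor and the nascent
#'   floor.
#' @param background_rate uniform background tags per bp per directory.
#' @param spread_sd Gaussian positional spread of planted tags, bp.
#' @param k27ac_mass,nascent_mass,band_mass,polii_mass,tf_mass,era_mass,top1cc_mass
#'   expected planted tag counts per locus per directory (nascent_mass is
#'   the treated mass at hormone-induced loci; band_mass the vehicle mass at
#'   band loci).
#' @param erna_fc planted eRNA fold change at hormone-induced loci.
#' @param band_fc_range planted fold-change range (uniform) at band loci.
#' @param polii_fc planted Pol II fold change at induced loci.
#' @param top1cc_coupling probability a TOP1cc mass is planted at acutely
#'   induced loci (hormone-induced + induced scheme).
#' @param top1cc_coupling_other same for all other loci.
#' @param gene_body_mass expected nascent tags per gene body per condition.
#' @param n_genes_up,n_genes_down genes planted differentially transcribed.
#' @param gene_fc planted gene fold change (up: `gene_fc`, down:
#'   `1/gene_fc`).
#' @param promoter_polii_mass expected Pol II tags at each promoter (both
#'   conditions).
#' @param depth_balance add uniform filler tags to the lighter condition of
#'   two-condition assays so expected library sizes match.
#' @param seed master seed; every stream derives from it via [child_seed()].
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(genome = c(chr1 = 1e7), n_genes = 40,
                             gene_length_range = c(5e3, 5e4),
                             n_megatrans = 50, n_eralpha_other = 50,
                             n_other_active = 50, n_induced = 50,
                             induced_scheme = c("androgen",
                                                "proinflammatory",
                                                "neuronal"),
                             n_decoy_tss = 10, n_decoy_k27ac = 10,
                             n_decoy_nascent = 10,
                             background_rate = 1e-7, spread_sd = 150,
                             k27ac_mass = 200, nascent_mass = 600,
                             erna_fc = 3.0, band_fc_range = c(0.75, 1.33),
                             band_mass = 400, polii_mass = 150,
                             polii_fc = 3.0, tf_mass = 100, era_mass = 150,
                             top1cc_mass = 100, top1cc_coupling = 1.0,
                             top1cc_coupling_other = 0.05,
                             gene_body_mass = 2000, n_genes_up = 5,
                             n_genes_down = 5, gene_fc = 2.0,
                             promoter_polii_mass = 500,
                             depth_balance = TRUE, seed = 1) {
  induced_scheme <- match.arg(induced_scheme)
  genome <- unlist(genome)  # tolerate manifests parsed as named lists
  band_fc_range <- unlist(band_fc_range)
  gene_length_range <- unlist(gene_length_range)
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[grep("^n_", names(cfg))]) >= 0),
            background_rate >= 0, spread_sd > 0, erna_fc > 0, polii_fc > 0,
            all(genome > 0))
  structure(cfg, class = "synthetic_config")
}

synth_classes <- function(config) {
  induced_label <- switch(config$induced_scheme,
                          androgen = "androgen_induced",
                          proinflammatory = "proinflammatory",
                          neuronal = "neuronal_induced")
  list(induced_label = induced_label)
}

#' Generate a toy genome annotation
#'
#' Places `n_genes` non-overlapping gene bodies with at least `min_gap` bp
#' between them (random gaps otherwise), strands random, lengths log-uniform
#' in `gene_length_range`. Deterministic under the config seed.
#'
#' @param config a [synthetic_config()].
#' @param min_gap minimum intergenic gap, bp.
#' @return list: `chrom_sizes` (named lengths), `tss` (TSS table).
#' @export
generate_annotation <- function(config, min_gap = 5000) {
  sizes <- config$genome
  n <- config$n_genes
  if (n == 0)
    return(list(chrom_sizes = sizes,
                tss = tss_records(character(), character(), integer(),
                                  character(), integer())))
  with_seed(child_seed(config$seed, "annotation"), {
    ## genes to chromosomes, proportional to length
    chrs <- sort(sample(names(sizes), n, replace = TRUE,
                        prob = as.numeric(sizes)))
    lr <- log(config$gene_length_range)
    rows <- list()
    gid <- 0L
    for (ch in unique(chrs)) {
      m <- sum(chrs == ch)
      lens <- round(exp(runif(m, lr[1], lr[2])))
      free <- sizes[[ch]] - sum(lens) - (m + 1) * min_gap
      if (free < 0)
        stop("genome too small for ", n, " genes", call. = FALSE)
      cuts <- sort(runif(m))
      gaps <- diff(c(0, cuts, 1)) * free + min_gap
      starts <- round(cumsum(gaps[seq_len(m)]) + cumsum(c(0, lens[-m])))
      strands <- sample(c("+", "-"), m, replace = TRUE)
      rows[[ch]] <- data.table(
        gene = paste0("gene_", gid + seq_len(m)), chrom = ch,
        tss = as.integer(ifelse(strands == "+", starts, starts + lens)),
        strand = strands,
        gene_end = as.integer(ifelse(strands == "+", starts + lens,
                                     starts)))
      gid <- gid + m
    }
    list(chrom_sizes = sizes, tss = validate_tss(rbindlist(rows)))
  })
}

## candidate enhancer centers: intergenic, clear of gene bodies +- margin,
## clear of chromosome edges, spaced on a fixed grid
enhancer_grid <- function(annotation, margin = 2500, edge = 1200,
                          step = 4000) {
  sizes <- annotation$chrom_sizes
  tssx <- annotation$tss
  out <- list()
  for (ch in names(sizes)) {
    len <- sizes[[ch]]
    cand <- seq(edge, len - edge, by = step)
    g <- tssx[chrom == ch]
    if (nrow(g)) {
      lo <- pmin(g$tss, g$gene_end) - margin
      hi <- pmax(g$tss, g$gene_end) + margin
      bad <- rep(FALSE, length(cand))
      for (i in seq_along(lo)) bad <- bad | (cand >= lo[i] & cand <= hi[i])
      cand <- cand[!bad]
    }
    out[[ch]] <- data.table(chrom = ch, center = as.integer(cand))
  }
  rbindlist(out)
}

#' Plant enhancer loci and their ground-truth parameters
#'
#' Assigns intergenic centers to classes and sets class-conditional planted
#' masses: hormone-induced loci get treated nascent mass `nascent_mass` with
#' fold change `erna_fc`; band loci get vehicle mass `band_mass` with fold
#' changes uniform in `band_fc_range`; induced loci get Pol II/TF masses;
#' each decoy class zeroes or violates exactly one gate (TSS-proximal
#' placement, zero H3K27Ac mass, zero treated nascent mass). TOP1cc mass is
#' planted with probability `top1cc_coupling` at acutely induced loci and
#' `top1cc_coupling_other` elsewhere, so planted TOP1cc mass and eRNA
#' induction are positively coupled across loci.
#'
#' @param config a [synthetic_config()].
#' @param annotation from [generate_annotation()].
#' @return list of class `truth_table`: `loci` (one row per planted locus:
#'   center, class, flags, per-assay masses per condition), `genes` (gene
#'   table with planted nascent masses and differential status), `config`,
#'   `annotation`.
#' @export
plant_enhancers <- function(config, annotation) {
  cls <- synth_classes(config)
  n_dist <- config$n_megatrans + config$n_eralpha_other +
    config$n_other_active + config$n_induced + config$n_decoy_k27ac +
    config$n_decoy_nascent
  with_seed(child_seed(config$seed, "plant"), {
    grid <- enhancer_grid(annotation)
    if (nrow(grid) < n_dist)
      stop("insufficient intergenic space: need ", n_dist,
           " enhancer slots, have ", nrow(grid), call. = FALSE)
    pick <- grid[sample(.N, n_dist)]
    classes <- rep(c("megatrans", "eralpha_other_active", "other_active",
                     cls$induced_label, "decoy_k27ac", "decoy_nascent"),
                   c(config$n_megatrans, config$n_eralpha_other,
                     config$n_other_active, config$n_induced,
                     config$n_decoy_k27ac, config$n_decoy_nascent))
    loci <- data.table(chrom = pick$chrom, center = pick$center,
                       class = classes)
    ## TSS-proximal decoys sit 1.5 kb downstream of a gene's TSS
    if (config$n_decoy_tss > 0) {
      if (nrow(annotation$tss) < config$n_decoy_tss)
        stop("not enough genes for TSS-proximal decoys", call. = FALSE)
      gi <- sample(nrow(annotation$tss), config$n_decoy_tss)
      g <- annotation$tss[gi]
      loci <- rbind(loci, data.table(
        chrom = g$chrom,
        center = as.integer(ifelse(g$strand == "+", g$tss + 1500,
                                   g$tss - 1500)),
        class = "decoy_tss"))
    }
    n <- nrow(loci)
    loci[, locus := paste0("locus_", seq_len(n))]
    hormone_like <- loci$class %in% c("megatrans", "decoy_tss",
                                      "decoy_k27ac")
    band <- loci$class %in% c("eralpha_other_active", "other_active")
    induced <- loci$class == cls$induced_label
    decoy_nas <- loci$class == "decoy_nascent"

    loci[, era_marked := class %in% c("megatrans", "eralpha_other_active",
                                      "decoy_tss", "decoy_k27ac",
                                      "decoy_nascent")]
    loci[, erna_fc := 1.0]
    loci[hormone_like, erna_fc := config$erna_fc]
    loci[band, erna_fc := runif(sum(band), config$band_fc_range[1],
                                config$band_fc_range[2])]
    loci[, mass_k27ac_treated := ifelse(class == "decoy_k27ac", 0,
                                        config$k27ac_mass)]
    loci[, mass_nascent_treated := 0]
    loci[, mass_nascent_control := 0]
    loci[hormone_like, `:=`(mass_nascent_treated = config$nascent_mass,
                            mass_nascent_control =
                              config$nascent_mass / config$erna_fc)]
    loci[band, `:=`(mass_nascent_control = config$band_mass,
                    mass_nascent_treated = config$band_mass * erna_fc)]
    loci[decoy_nas, `:=`(mass_nascent_treated = 0,
                         mass_nascent_control = config$band_mass)]
    loci[, mass_polii_treated := ifelse(induced, config$polii_mass, 0)]
    loci[, mass_polii_control := ifelse(induced,
                                        config$polii_mass / config$polii_fc,
                                        0)]
    loci[, mass_tf_treated := ifelse(induced, config$tf_mass, 0)]
    loci[, mass_era_treated := ifelse(era_marked, config$era_mass, 0)]
    acute <- loci$class %in% c("megatrans", cls$induced_label)
    p_flag <- ifelse(acute, config$top1cc_coupling,
                     config$top1cc_coupling_other)
    loci[, top1cc := runif(n) < p_flag]
    loci[, mass_top1cc_treated := ifelse(top1cc, config$top1cc_mass, 0)]

    genes <- copy(annotation$tss)
    status <- rep("flat", nrow(genes))
    if (nrow(genes)) {
      ud <- sample(nrow(genes), min(nrow(genes),
                                    config$n_genes_up + config$n_genes_down))
      status[ud[seq_len(min(config$n_genes_up, length(ud)))]] <- "up"
      if (length(ud) > config$n_genes_up)
        status[ud[(config$n_genes_up + 1):length(ud)]] <- "down"
    }
    genes[, status := status]
    genes[, mass_nascent_control := config$gene_body_mass]
    genes[, mass_nascent_treated := config$gene_body_mass *
            ifelse(status == "up", config$gene_fc,
                   ifelse(status == "down", 1 / config$gene_fc, 1))]
    genes[, mass_polii_treated := config$promoter_polii_mass]
    genes[, mass_polii_control := config$promoter_polii_mass]
    structure(list(loci = loci[], genes = genes[], config = config,
                   annotation = annotation),
              class = "truth_table")
  })
}

## expected library size (sum of planted masses + background) for one
## directory; used for the depth-balancing filler
expected_library <- function(truth, assay, condition) {
  cfg <- truth$config
  col <- paste0("mass_", assay, "_", condition)
  total <- if (col %in% names(truth$loci)) sum(truth$loci[[col]]) else 0
  if (assay == "nascent" && col %in% names(truth$genes))
    total <- total + sum(truth$genes[[col]])
  if (assay == "polii" && col %in% names(truth$genes))
    total <- total + sum(truth$genes[[col]])
  total + cfg$background_rate * sum(cfg$genome)
}

#' Simulate tag records for one (assay, condition, replicate) directory
#'
#' Background tags are uniform Poisson; each planted locus contributes
#' `Poisson(mass)` tags at `Normal(center, spread_sd)` positions (clipped to
#' the chromosome). Nascent tags are strand-split by the sign of the offset
#' (divergent eRNA geometry: "+" downstream, "-" upstream of the center);
#' gene-body nascent tags are uniform over the body on the sense strand and
#' promoter Pol II tags are planted at TSSs. When `depth_balance` is on,
#' uniform filler tags are added to the lighter condition of two-condition
#' assays so expected library sizes match. Reproducible under
#' `(seed, assay, condition, replicate)`.
#'
#' @param truth a `truth_table` from [plant_enhancers()].
#' @param assay one of "k27ac", "nascent", "polii", "tf", "top1cc", "era".
#' @param condition "treated" or "control".
#' @param replicate replicate label (part of the seed stream).
#' @return `data.table` of tag records (chrom, pos, strand) for
#'   [build_tag_directory()].
#' @export
simulate_tags <- function(truth, assay, condition = "treated",
                          replicate = "r1") {
  if (!assay %in% c("k27ac", "nascent", "polii", "tf", "top1cc", "era"))
    stop("unknown assay: ", assay, call. = FALSE)
  cfg <- truth$config
  sizes <- cfg$genome
  col <- paste0("mass_", assay, "_", condition)
  with_seed(child_seed(cfg$seed, "tags", assay, condition, replicate), {
    parts <- list()
    ## uniform background
    bg_mass <- cfg$background_rate * sum(sizes)
    if (cfg$depth_balance && assay %in% c("nascent", "polii")) {
      here <- expected_library(truth, assay, condition)
      other <- expected_library(truth, assay,
                                setdiff(c("treated", "control"), condition))
      bg_mass <- bg_mass + max(0, other - here)
    }
    nb <- rpois(1, bg_mass)
    if (nb > 0) {
      ch <- sample(names(sizes), nb, replace = TRUE,
                   prob = as.numeric(sizes))
      parts$bg <- data.table(
        chrom = ch, pos = as.integer(floor(runif(nb) * sizes[ch])),
        strand = sample(c("+", "-"), nb, replace = TRUE))
    }
    ## planted loci
    if (col %in% names(truth$loci)) {
      li <- truth$loci[get(col) > 0]
      if (nrow(li)) {
        counts <- rpois(nrow(li), li[[col]])
        idx <- rep(seq_len(nrow(li)), counts)
        if (length(idx)) {
          off <- rnorm(length(idx), 0, cfg$spread_sd)
          pos <- round(li$center[idx] + off)
          pos <- pmax(0, pmin(pos, unname(sizes[li$chrom[idx]]) - 1))
          strand <- if (assay == "nascent")
            ifelse(off >= 0, "+", "-")
          else sample(c("+", "-"), length(idx), replace = TRUE)
          parts$loci <- data.table(chrom = li$chrom[idx],
                                   pos = as.integer(pos), strand = strand)
        }
      }
    }
    ## gene-body transcription (nascent) / promoter Pol II
    if (assay == "nascent" && col %in% names(truth$genes) &&
        nrow(truth$genes)) {
      g <- truth$genes
      counts <- rpois(nrow(g), g[[col]])
      idx <- rep(seq_len(nrow(g)), counts)
      if (length(idx)) {
        len <- abs(g$gene_end - g$tss)[idx]
        d <- floor(runif(length(idx)) * len)
        pos <- ifelse(g$strand[idx] == "+", g$tss[idx] + d, g$tss[idx] - d)
        parts$genes <- data.table(chrom = g$chrom[idx],
                                  pos = as.integer(pos),
                                  strand = g$strand[idx])
      }
    }
    if (assay == "polii" && col %in% names(truth$genes) &&
        nrow(truth$genes)) {
      g <- truth$genes
      counts <- rpois(nrow(g), g[[col]])
      idx <- rep(seq_len(nrow(g)), counts)
      if (length(idx)) {
        pos <- round(rnorm(length(idx), g$tss[idx], cfg$spread_sd))
        pos <- pmax(0, pmin(pos, unname(sizes[g$chrom[idx]]) - 1))
        parts$prom <- data.table(chrom = g$chrom[idx],
                                 pos = as.integer(pos),
                                 strand = sample(c("+", "-"), length(idx),
                                                 replace = TRUE))
      }
    }
    if (!length(parts))
      return(data.table(chrom = character(), pos = integer(),
                        strand = character()))
    rbindlist(parts)
  })
}

#' Simulate the full directory bundle the classifiers consume
#'
#' Builds tag directories for every assay/condition the synthetic world
#' defines (clonal cap 3 for nascent, 2 elsewhere).
#'
#' @param truth a `truth_table`.
#' @param replicate replicate label.
#' @return an [assay_bundle()] keyed "assay/condition"; includes
#'   "top1cc/treated" and "era/treated".
#' @export
simulate_bundle <- function(truth, replicate = "r1") {
  cfg <- truth$config
  keys <- list(c("k27ac", "treated"), c("nascent", "treated"),
               c("nascent", "control"), c("polii", "treated"),
               c("polii", "control"), c("tf", "treated"),
               c("top1cc", "treated"), c("era", "treated"))
  dirs <- lapply(keys, function(k) {
    rec <- simulate_tags(truth, k[1], k[2], replicate)
    if (nrow(rec) == 0) return(NULL)  # assay absent from this world
    build_tag_directory(rec, assay = k[1], condition = k[2],
                        replicate = replicate,
                        per_position_cap = if (k[1] == "nascent") 3L else 2L,
                        chrom_sizes = cfg$genome)
  })
  names(dirs) <- vapply(keys, paste, "", collapse = "/")
  assay_bundle(Filter(Negate(is.null), dirs))
}

#' Candidate regions / marked anchor peaks from a truth table
#'
#' `truth_regions()` returns the +/- `flank` windows around planted centers
#' (optionally restricted by class); `truth_marked_peaks()` returns
#' receptor anchor peaks (summit = center) for the receptor-marked loci.
#'
#' @param truth a `truth_table`.
#' @param classes optional class filter.
#' @param flank half-width, bp.
#' @return interval / peak table.
#' @export
truth_regions <- function(truth, classes = NULL, flank = 1000) {
  li <- truth$loci
  if (!is.null(classes)) li <- li[class %in% classes]
  data.table(chrom = li$chrom, start = as.integer(li$center - flank),
             end = as.integer(li$center + flank), name = li$locus,
             score = 0, strand = ".", center = li$center,
             class = li$class)
}

#' @rdname truth_regions
#' @export
truth_marked_peaks <- function(truth) {
  li <- truth$loci[era_marked == TRUE]
  data.table(chrom = li$chrom, start = as.integer(li$center - 100),
             end = as.integer(li$center + 100), name = li$locus, score = 0,
             strand = ".", summit = li$center)
}

#' Write a self-contained fixture bundle to disk
#'
#' Emits chrom.sizes, the TSS TSV, one tagAlign BED per directory, the truth
#' tables and a YAML manifest (file list with md5 checksums plus the
#' parameters needed to rerun the pipeline).
#'
#' @param truth a `truth_table`.
#' @param directories named list/bundle of `tag_directory` objects.
#' @param outdir output directory.
#' @param force overwrite a non-empty `outdir`.
#' @return path to the manifest, invisibly.
#' @export
write_fixture_bundle <- function(truth, directories, outdir,
                                 force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("output directory not empty (use force = TRUE): ", outdir,
         call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  p <- file.path(outdir, "chrom.sizes")
  write_chrom_sizes(truth$annotation$chrom_sizes, p)
  files["chrom_sizes"] <- p
  p <- file.path(outdir, "tss.tsv")
  write_tss(truth$annotation$tss, p)
  files["tss"] <- p
  p <- file.path(outdir, "truth_loci.tsv")
  fwrite(truth$loci, p, sep = "\t")
  files["truth_loci"] <- p
  p <- file.path(outdir, "truth_genes.tsv")
  fwrite(truth$genes, p, sep = "\t")
  files["truth_genes"] <- p
  tag_files <- list()
  for (key in names(directories)) {
    fn <- file.path(outdir, paste0(gsub("/", "_", key), ".tagAlign"))
    write_tags(directories[[key]], fn)
    tag_files[[key]] <- basename(fn)
    files[paste0("tags:", key)] <- fn
  }
  manifest <- list(
    format = "enhancerkit-fixture",
    seed = truth$config$seed,
    induced_scheme = truth$config$induced_scheme,
    chrom_sizes = basename(files[["chrom_sizes"]]),
    tss = basename(files[["tss"]]),
    truth_loci = basename(files[["truth_loci"]]),
    truth_genes = basename(files[["truth_genes"]]),
    tags = tag_files,
    checksums = as.list(setNames(unname(tools::md5sum(files)),
                                 basename(files))))
  mp <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  invisible(mp)
}
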