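## Tag directories: per-position clonal cap + normalization to a fixed total.
##
## A tag is the 5' end of an aligned read: (chrom, pos, strand). Directories
## store the capped multiset as per-position counts and quantify everything in
## tags-per-10-million so samples of different depth are comparable.

#' Read aligned tags from a tagAlign / BED6 file
#'
#' The 5' end is taken as `start` for "+" (and unstranded) tags and `end - 1`
#' for "-" tags.
#'
#' @param path tagAlign/BED6 path (tab-separated, no header).
#' @return `data.table` with columns chrom, pos, strand — the record format
#'   consumed by [build_tag_directory()].
#' @export
read_tags <- function(path) {
  x <- fread(path, header = FALSE, sep = "\t",
             colClasses = list(character = 1))
  if (ncol(x) < 3) stop("tag file needs >= 3 columns: ", path, call. = FALSE)
  strand <- if (ncol(x) >= 6) as.character(x[[6]]) else rep(".", nrow(x))
  data.table(chrom = x[[1]],
             pos = as.integer(ifelse(strand == "-", x[[3]] - 1L, x[[2]])),
             strand = strand)
}

#' Build a tag directory (clonal cap + normalization factor)
#'
#' Duplicate tags beyond `per_position_cap` at one genomic position are
#' discarded (clonal-amplification control). ChIP-seq/CUT&RUN conventionally
#' uses a cap of 2; nascent-transcription (PRO-seq) mode uses 3. The
#' normalization factor rescales the post-cap total to `norm_target`
#' (10 million) tags.
#'
#' @param records data.frame/data.table with columns chrom, pos, strand and
#'   optionally n (pre-aggregated counts; default 1 per row).
#' @param assay,condition,replicate labels carried on the directory.
#' @param per_position_cap max tags kept per position (>= 1).
#' @param norm_target normalization target, default 1e7.
#' @param chrom_sizes optional named lengths; when given, tag positions are
#'   bounds-checked and the directory remembers its chromosome universe.
#' @param strand_aware_cap cap per (chrom, pos, strand) triple (default, the
#'   right choice for strand-specific assays) or per (chrom, pos) when FALSE.
#' @return object of class `tag_directory`: list with `tags` (data.table
#'   chrom/pos/strand/n, keyed), `raw_total`, `capped_total`,
#'   `per_position_cap`, `norm_target`, labels and optional `chrom_sizes`.
#' @examples
#' d <- build_tag_directory(
#'   data.frame(chrom = "chr1", pos = rep(100L, 5), strand = "+"),
#'   per_position_cap = 2)
#' d$capped_total  # 2
#' @export
build_tag_directory <- function(records, assay = "", condition = "",
                                replicate = "", per_position_cap = 2L,
                                norm_target = 1e7, chrom_sizes = NULL,
                                strand_aware_cap = TRUE) {
  if (per_position_cap < 1) stop("per_position_cap must be >= 1",
                                 call. = FALSE)
  stop_if_not_cols(records, c("chrom", "pos", "strand"), "tag records")
  dt <- as.data.table(records)
  if (!"n" %in% names(dt)) dt[, n := 1L]
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(dt$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("tag chromosome(s) absent from chrom sizes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (nrow(dt) && any(dt$pos < 0 | dt$pos >= unname(chrom_sizes[dt$chrom])))
      stop("tag position outside chromosome bounds", call. = FALSE)
  }
  raw_total <- sum(dt$n)
  agg <- dt[, .(n = sum(n)), by = .(chrom, pos, strand)]
  if (strand_aware_cap) {
    agg[, n := pmin(n, as.integer(per_position_cap))]
  } else {
    ## cap the per-(chrom,pos) total; trim deterministically, "+" kept first
    setorder(agg, chrom, pos, strand)
    agg[, cum := cumsum(n), by = .(chrom, pos)]
    agg[, n := pmin(n, pmax(0L, as.integer(per_position_cap) - (cum - n)))]
    agg[, cum := NULL]
    agg <- agg[n > 0L]
  }
  capped_total <- sum(agg$n)
  if (capped_total == 0)
    stop("no tags remain after capping; normalization undefined",
         call. = FALSE)
  setkey(agg, chrom, pos)
  structure(list(tags = agg, assay = assay, condition = condition,
                 replicate = replicate,
                 per_position_cap = as.integer(per_position_cap),
                 raw_total = raw_total, capped_total = capped_total,
                 norm_target = norm_target, chrom_sizes = chrom_sizes),
            class = "tag_directory")
}

#' @export
print.tag_directory <- function(x, ...) {
  cat("<tag_directory>", x$assay, x$condition, x$replicate, "\n",
      " tags:", x$capped_total, "capped /", x$raw_total, "raw; cap =",
      x$per_position_cap, "\n",
      " norm factor:", format(norm_factor(x), digits = 6),
      "(target", format(x$norm_target, scientific = FALSE), "tags)\n")
  invisible(x)
}

#' Normalization factor of a directory
#' @param dir a `tag_directory`.
#' @return `norm_target / capped_total`.
#' @export
norm_factor <- function(dir) dir$norm_target / dir$capped_total

#' Rescale a raw tag count to tags-per-10-million
#'
#' @param dir a `tag_directory`.
#' @param raw raw (post-cap) tag count(s).
#' @return `raw * norm_target / capped_total`.
#' @export
normalized_count <- function(dir, raw) raw * dir$norm_target / dir$capped_total

known_chroms <- function(dir) {
  if (!is.null(dir$chrom_sizes)) names(dir$chrom_sizes)
  else unique(dir$tags$chrom)
}

## strand filter helper: which tag strands count under a mode + ref strand
strand_keep <- function(tag_strand, mode, ref) {
  switch(mode,
         both = rep(TRUE, length(tag_strand)),
         sense = tag_strand == ref,
         antisense = tag_strand == flip_strand(ref),
         stop("unknown strand_mode: ", mode, call. = FALSE))
}

flip_strand <- function(s) chartr("+-", "-+", s)

#' Count tags in windows around centers
#'
#' Counts tags with position in `[center - halfwidth, center + halfwidth]`
#' (inclusive on both ends — the symmetric reading of a "+/- 1,000 bp"
#' window). Vectorized over `chrom`/`center`.
#'
#' @param dir a `tag_directory`.
#' @param chrom chromosome name(s).
#' @param center window center position(s), bp.
#' @param halfwidth window half-width, bp (> 0); default 1000 (the eRNA
#'   quantification window).
#' @param strand_mode "both", "sense" or "antisense" relative to `ref_strand`.
#' @param ref_strand reference strand(s), required unless mode is "both".
#' @param normalize return tags-per-10M (default) or raw capped counts.
#' @return numeric vector of counts, one per window.
#' @export
count_window <- function(dir, chrom, center, halfwidth = 1000,
                         strand_mode = c("both", "sense", "antisense"),
                         ref_strand = NULL, normalize = TRUE) {
  strand_mode <- match.arg(strand_mode)
  if (halfwidth <= 0) stop("halfwidth must be > 0", call. = FALSE)
  nq <- max(length(chrom), length(center))
  chrom <- rep_len(as.character(chrom), nq)
  center <- rep_len(as.numeric(center), nq)
  unknown <- setdiff(unique(chrom), known_chroms(dir))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (strand_mode != "both") {
    if (is.null(ref_strand))
      stop("ref_strand required for strand_mode = ", strand_mode,
           call. = FALSE)
    ref_strand <- rep_len(as.character(ref_strand), nq)
  } else ref_strand <- rep_len(".", nq)
  q <- data.table(chrom = chrom, lo = center - halfwidth,
                  hi = center + halfwidth, ref = ref_strand,
                  qid = seq_len(nq))
  hits <- dir$tags[q, .(qid = i.qid, n = x.n, strand = x.strand, ref = i.ref),
                   on = .(chrom, pos >= lo, pos <= hi), nomatch = 0L,
                   allow.cartesian = TRUE]
  if (nrow(hits)) hits <- hits[strand_keep(strand, strand_mode, ref)]
  out <- numeric(nq)
  if (nrow(hits)) {
    agg <- hits[, .(n = sum(n)), by = qid]
    out[agg$qid] <- agg$n
  }
  if (normalize) normalized_count(dir, out) else out
}

#' Profile matrix of normalized tag counts around centers
#'
#' Tabulates normalized tags in fixed-size bins within `+/- flank` of each
#' center — the input for average-density histograms and heatmaps. Bins are
#' half-open `[lo, lo + binsize)` so they tile without double counting; rows
#' for "-" strand centers are reversed so columns always read 5' to 3'.
#' Centers closer than `flank` to a chromosome edge are flagged in the
#' `"excluded"` attribute and dropped from [profile_histogram()] column means.
#'
#' @param dir a `tag_directory`.
#' @param centers data.frame with columns chrom, pos and optionally strand.
#' @param flank distance covered on each side, bp; must be a multiple of
#'   `binsize`. Typical figure contexts use 3000 or 5000.
#' @param binsize bin width, bp (default 100).
#' @param strand_mode "both" (default), "sense" or "antisense" relative to
#'   each center's strand.
#' @param chrom_sizes chromosome lengths for edge flagging; defaults to the
#'   directory's own table and is required from one of the two sources.
#' @return numeric matrix, rows = centers, columns = bins (named by the bp
#'   offset of the bin start relative to the center), with attribute
#'   `"excluded"` (logical per row).
#' @export
profile_matrix <- function(dir, centers, flank = 3000, binsize = 100,
                           strand_mode = c("both", "sense", "antisense"),
                           chrom_sizes = NULL) {
  strand_mode <- match.arg(strand_mode)
  stop_if_not_cols(centers, c("chrom", "pos"), "centers")
  if (flank %% binsize != 0 || flank <= 0 || binsize <= 0)
    stop("flank must be a positive multiple of binsize", call. = FALSE)
  chrom_sizes <- chrom_sizes %||% dir$chrom_sizes
  if (is.null(chrom_sizes))
    stop("chrom_sizes needed (argument or directory) for edge handling",
         call. = FALSE)
  centers <- as.data.table(centers)
  if (!"strand" %in% names(centers)) centers[, strand := "+"]
  nb <- as.integer(2 * flank / binsize)
  nr <- nrow(centers)
  offs <- seq(-flank, flank - binsize, by = binsize)
  mat <- matrix(0, nrow = nr, ncol = nb,
                dimnames = list(NULL, as.character(offs)))
  excluded <- centers$pos - flank < 0 |
    centers$pos + flank > unname(chrom_sizes[centers$chrom])
  if (anyNA(excluded))
    stop("centers on chromosome(s) absent from chrom sizes", call. = FALSE)
  if (nr) {
    q <- data.table(qid = rep(seq_len(nr), each = nb),
                    bin = rep(seq_len(nb), nr),
                    chrom = rep(centers$chrom, each = nb),
                    ref = rep(centers$strand, each = nb))
    q[, lo := rep(centers$pos, each = nb) + rep(offs, nr)]
    q[, hi := lo + binsize - 1]
    hits <- dir$tags[q,
                     .(qid = i.qid, bin, n = x.n, strand = x.strand,
                       ref = i.ref),
                     on = .(chrom, pos >= lo, pos <= hi), nomatch = 0L,
                     allow.cartesian = TRUE]
    if (nrow(hits) && strand_mode != "both")
      hits <- hits[strand_keep(strand, strand_mode, ref)]
    if (nrow(hits)) {
      agg <- hits[, .(n = sum(n)), by = .(qid, bin)]
      mat[cbind(agg$qid, agg$bin)] <- normalized_count(dir, agg$n)
    }
    rev_rows <- which(centers$strand == "-")
    if (length(rev_rows)) mat[rev_rows, ] <- mat[rev_rows, nb:1, drop = FALSE]
  }
  attr(mat, "excluded") <- excluded
  mat
}

#' Average tag-density histogram from a profile matrix
#'
#' Column means over rows not flagged as edge-excluded.
#'
#' @param mat a matrix from [profile_matrix()].
#' @return numeric vector, one mean normalized count per bin.
#' @export
profile_histogram <- function(mat) {
  excl <- attr(mat, "excluded") %||% rep(FALSE, nrow(mat))
  colMeans(mat[!excl, , drop = FALSE])
}

#' Gene-body nascent-transcription quantification
#'
#' Counts sense-strand tags over the first `body_cap` (13 kb) of the gene
#' body, excluding the `promoter_exclusion` (500 bp) promoter-proximal
#' region, oriented 5' to 3' by gene strand: oriented offsets `d` from the
#' TSS with `promoter_exclusion <= d < min(body_cap, gene length)`.
#'
#' @param dir a `tag_directory` (PRO-seq mode: cap 3).
#' @param genes TSS table (see [tss_records()]); vectorized over rows.
#' @param body_cap maximum body length counted, bp.
#' @param promoter_exclusion promoter-proximal bp excluded at the 5' end.
#' @param strand_mode "sense" (default), "antisense" or "both" relative to
#'   the gene strand.
#' @param normalize return tags-per-10M (default) or raw capped counts.
#' @return numeric vector of counts, one per gene.
#' @export
quantify_gene_body <- function(dir, genes, body_cap = 13000,
                               promoter_exclusion = 500,
                               strand_mode = c("sense", "antisense", "both"),
                               normalize = TRUE) {
  strand_mode <- match.arg(strand_mode)
  validate_tss(genes)
  len <- abs(genes$gene_end - genes$tss)
  if (any(len <= promoter_exclusion))
    stop("gene(s) shorter than the promoter exclusion zone: ",
         paste(genes$gene[len <= promoter_exclusion], collapse = ", "),
         call. = FALSE)
  L <- pmin(body_cap, len)
  plus <- genes$strand == "+"
  lo <- ifelse(plus, genes$tss + promoter_exclusion, genes$tss - L + 1)
  hi <- ifelse(plus, genes$tss + L - 1, genes$tss - promoter_exclusion)
  nq <- nrow(genes)
  q <- data.table(chrom = genes$chrom, lo = as.numeric(lo),
                  hi = as.numeric(hi), ref = genes$strand, qid = seq_len(nq))
  hits <- dir$tags[q, .(qid = i.qid, n = x.n, strand = x.strand, ref = i.ref),
                   on = .(chrom, pos >= lo, pos <= hi), nomatch = 0L,
                   allow.cartesian = TRUE]
  if (nrow(hits)) hits <- hits[strand_keep(strand, strand_mode, ref)]
  out <- numeric(nq)
  if (nrow(hits)) {
    agg <- hits[, .(n = sum(n)), by = qid]
    out[agg$qid] <- agg$n
  }
  if (normalize) normalized_count(dir, out) else out
}

#' Serialize / load a tag directory
#'
#' Writes `tags.tsv` (chrom, pos, strand, n) plus a `meta.json` sidecar with
#' totals, cap and labels into `path` (a directory).
#'
#' @param dir a `tag_directory`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_tag_directory <- function(dir, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fwrite(dir$tags, file.path(path, "tags.tsv"), sep = "\t")
  meta <- list(assay = dir$assay, condition = dir$condition,
               replicate = dir$replicate,
               per_position_cap = dir$per_position_cap,
               raw_total = dir$raw_total, capped_total = dir$capped_total,
               norm_target = dir$norm_target,
               chrom_sizes = as.list(dir$chrom_sizes))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tag_directory
#' @export
read_tag_directory <- function(path) {
  tags <- fread(file.path(path, "tags.tsv"), sep = "\t",
                colClasses = list(character = c("chrom", "strand")))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  cs <- if (length(meta$chrom_sizes)) unlist(meta$chrom_sizes) else NULL
  tags[, pos := as.integer(pos)]
  tags[, n := as.integer(n)]
  setkey(tags, chrom, pos)
  structure(list(tags = tags, assay = meta$assay, condition = meta$condition,
                 replicate = meta$replicate,
                 per_position_cap = as.integer(meta$per_position_cap),
                 raw_total = meta$raw_total,
                 capped_total = meta$capped_total,
                 norm_target = meta$norm_target, chrom_sizes = cs),
            class = "tag_directory")
}

#' Write a directory's tags as tagAlign BED6
#'
#' One line per retained tag (positions with count n emit n lines), 5' end
#' conventions mirrored by [read_tags()].
#'
#' @param dir a `tag_directory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tags <- function(dir, path) {
  t <- dir$tags[rep(seq_len(.N), n)]
  setorder(t, chrom, pos, strand)
  lines <- paste(t$chrom, fmt_num(t$pos), fmt_num(t$pos + 1L), ".", 0,
                 ifelse(t$strand %in% c("+", "-"), t$strand, "."),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
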