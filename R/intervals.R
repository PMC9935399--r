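## Domain types and BED/TSV readers-writers.
##
## All coordinates are 0-based half-open ([start, end)), the BED convention,
## everywhere inside the package. Any 1-based dialect must be converted at the
## reader boundary. Strand is "+", "-" or "." (unstranded).

#' Construct a table of genomic intervals
#'
#' The package's interval container is a plain `data.table` with columns
#' `chrom`, `start`, `end`, `name`, `score`, `strand` in BED column order.
#' Coordinates are 0-based half-open.
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open coordinates, `0 <= start < end`.
#' @param strand "+", "-" or "." (recycled).
#' @param name optional labels (recycled; `NA` means unnamed).
#' @param score optional numeric scores (recycled).
#' @param chrom_sizes optional named vector of chromosome lengths; when given,
#'   every interval is validated against it.
#' @return a `data.table` with columns chrom, start, end, name, score, strand.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".",
                              name = NA_character_, score = 0,
                              chrom_sizes = NULL) {
  x <- data.table(chrom = as.character(chrom),
                  start = as.integer(start), end = as.integer(end),
                  name = as.character(name), score = as.numeric(score),
                  strand = as.character(strand))
  validate_intervals(x, chrom_sizes)
  x
}

#' Validate interval invariants
#'
#' Checks `0 <= start < end`, legal strand codes and, when `chrom_sizes` is
#' supplied, that every chromosome is present in the governing sizes table and
#' `end <=` chromosome length. Chromosomes absent from `chrom_sizes` are an
#' error, never silently dropped.
#'
#' @param x interval table (see [genomic_intervals()]).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL) {
  stop_if_not_cols(x, c("chrom", "start", "end"), "interval table")
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at row ", bad[1], ": ",
         x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]],
         call. = FALSE)
  if (!is.null(x$strand)) {
    bads <- which(!x$strand %in% c("+", "-", "."))
    if (length(bads))
      stop("invalid strand at row ", bads[1], ": '", x$strand[bads[1]], "'",
           call. = FALSE)
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("chromosome(s) absent from chrom sizes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    over <- which(x$end > unname(chrom_sizes[x$chrom]))
    if (length(over))
      stop("interval exceeds chromosome length at row ", over[1], ": ",
           x$chrom[over[1]], ":", x$start[over[1]], "-", x$end[over[1]],
           call. = FALSE)
  }
  invisible(x)
}

#' Read intervals from a BED3/BED6 file
#'
#' Tab-separated, headerless. Columns beyond the first three are optional:
#' col 4 name ("." means unnamed), col 5 score, col 6 strand. Input order is
#' preserved. Malformed lines raise an error naming the line number.
#'
#' @param path BED file path.
#' @param chrom_sizes optional named vector; intervals are validated against
#'   it when given.
#' @return interval `data.table` (see [genomic_intervals()]).
#' @export
read_intervals <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(lines)
  if (!any(keep))
    return(genomic_intervals(character(), integer(), integer()))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 tab-separated columns", call. = FALSE)
  get_col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  start <- suppressWarnings(as.integer(get_col(2, NA)))
  end <- suppressWarnings(as.integer(get_col(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], ": non-integer coordinates",
         call. = FALSE)
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop("invalid interval at line ", lineno[bad[1]],
         ": need 0 <= start < end", call. = FALSE)
  nm <- get_col(4, ".")
  nm[nm == "."] <- NA_character_
  score <- suppressWarnings(as.numeric(get_col(5, "0")))
  score[is.na(score)] <- 0
  x <- genomic_intervals(get_col(1, NA), start, end,
                         strand = get_col(6, "."), name = nm, score = score,
                         chrom_sizes = chrom_sizes)
  x
}

#' Write intervals as BED
#'
#' Emits BED6 when any interval carries a name or a strand, BED3 otherwise;
#' deterministic column order, no header. `read_intervals()` followed by
#' `write_intervals()` is byte-identical on files this function produced.
#'
#' @param x interval table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  validate_intervals(x)
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  nm <- if (is.null(x$name)) rep(NA_character_, nrow(x)) else x$name
  strand <- if (is.null(x$strand)) rep(".", nrow(x)) else x$strand
  score <- if (is.null(x$score)) rep(0, nrow(x)) else x$score
  bed6 <- any(!is.na(nm)) || any(strand != ".")
  lines <- if (bed6) {
    nm[is.na(nm)] <- "."
    paste(x$chrom, fmt_num(x$start), fmt_num(x$end), nm, fmt_num(score),
          strand, sep = "\t")
  } else {
    paste(x$chrom, fmt_num(x$start), fmt_num(x$end), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a chrom.sizes table
#'
#' Two tab-separated columns (chromosome name, length), no header.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- fread(path, header = FALSE, sep = "\t",
             colClasses = list(character = 1))
  if (ncol(x) < 2) stop("chrom.sizes needs two columns", call. = FALSE)
  sizes <- as.integer(x[[2]])
  names(sizes) <- x[[1]]
  if (anyDuplicated(names(sizes))) stop("duplicated chromosome names",
                                        call. = FALSE)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  sizes
}

#' @rdname read_chrom_sizes
#' @param sizes named vector of positive lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), fmt_num(unname(sizes)), sep = "\t"), path)
  invisible(path)
}

#' Construct / validate TSS records
#'
#' One row per gene: identifier, chromosome, TSS position, strand and gene
#' end. For "+" genes `tss < gene_end`; for "-" genes `tss > gene_end` (the
#' TSS is the 5' end of the transcription unit in genomic coordinates).
#'
#' @param gene character ids.
#' @param chrom chromosome names.
#' @param tss,gene_end integer positions.
#' @param strand "+" or "-".
#' @return a `data.table` with columns gene, chrom, tss, strand, gene_end.
#' @export
tss_records <- function(gene, chrom, tss, strand, gene_end) {
  x <- data.table(gene = as.character(gene), chrom = as.character(chrom),
                  tss = as.integer(tss), strand = as.character(strand),
                  gene_end = as.integer(gene_end))
  validate_tss(x)
  x
}

validate_tss <- function(x) {
  stop_if_not_cols(x, c("gene", "chrom", "tss", "strand", "gene_end"),
                   "TSS table")
  if (nrow(x) == 0) return(invisible(x))
  if (any(!x$strand %in% c("+", "-")))
    stop("TSS strand must be '+' or '-'", call. = FALSE)
  bad <- which((x$strand == "+" & x$tss >= x$gene_end) |
               (x$strand == "-" & x$tss <= x$gene_end))
  if (length(bad))
    stop("TSS/gene_end inconsistent with strand at row ", bad[1],
         " (gene ", x$gene[bad[1]], ")", call. = FALSE)
  invisible(x)
}

#' Read / write TSS annotation as a 5-column TSV
#'
#' Columns (with header): gene, chrom, tss, strand, gene_end.
#'
#' @param path file path.
#' @return TSS `data.table` (see [tss_records()]).
#' @export
read_tss <- function(path) {
  x <- fread(path, sep = "\t", header = TRUE,
             colClasses = list(character = c("gene", "chrom", "strand")))
  tss_records(x$gene, x$chrom, x$tss, x$strand, x$gene_end)
}

#' @rdname read_tss
#' @param x TSS table.
#' @export
write_tss <- function(x, path) {
  validate_tss(x)
  fwrite(x[, .(gene, chrom, tss, strand, gene_end)], path, sep = "\t")
  invisible(path)
}

#' Distance from region centers to the nearest annotated TSS
#'
#' Strand-agnostic distance from the region center,
#' `floor((start + end) / 2)`, to the nearest TSS on the same chromosome.
#' Regions on chromosomes with no annotated TSS get `Inf`. Used to impose
#' the "at least 3 kb away from annotated TSSs" gate on distal enhancers.
#'
#' @param regions interval table.
#' @param tss_set TSS table; must be non-empty.
#' @return numeric vector of non-negative distances (bp), one per region.
#' @examples
#' r <- genomic_intervals("chr1", 4000, 4500)
#' t <- tss_records("g1", "chr1", 10000, "+", 20000)
#' distance_to_nearest_tss(r, t)  # |4250 - 10000| = 5750
#' @export
distance_to_nearest_tss <- function(regions, tss_set) {
  validate_intervals(regions)
  validate_tss(tss_set)
  if (nrow(tss_set) == 0) stop("tss_set is empty", call. = FALSE)
  centers <- floor((regions$start + regions$end) / 2)
  by_chrom <- split(tss_set$tss, tss_set$chrom)
  vapply(seq_len(nrow(regions)), function(i) {
    tt <- by_chrom[[regions$chrom[i]]]
    if (is.null(tt)) return(Inf)
    min(abs(centers[i] - tt))
  }, numeric(1))
}

#' Region centers
#'
#' `floor((start + end) / 2)`, the convention used for TSS distances, window
#' anchoring and feature-enrichment flags throughout the package.
#'
#' @param x interval table.
#' @return integer vector of center positions.
#' @export
region_centers <- function(x) {
  as.integer(floor((x$start + x$end) / 2))
}
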