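## Fold-change differential layer for eRNAs and gene bodies.
##
## The enhancer definitions consume fold changes and tag floors, not a
## dispersion model, so the differential layer is FC + floor with an optional
## exact test (two-sided binomial, i.e. the Poisson test conditioned on the
## two library totals) and Benjamini-Hochberg adjustment.

diff_calls_factor <- c("up", "down", "unchanged", "low_expressed")

#' Differential eRNA calls in windows around enhancer centers
#'
#' Counts normalized tags (both strands pooled — bidirectional eRNA) in
#' `+/- halfwidth` windows per condition and calls, with
#' `fc = (count_b + pc) / (count_a + pc)`:
#' up iff `fc > fc_cut` and `count_b >= floor` (strict inequality — the
#' published eRNA rule is "FC > 1.5"); down iff `fc < 1/fc_cut` and
#' `count_a >= floor`; low_expressed iff both counts are below `floor`;
#' unchanged otherwise.
#'
#' @param dir_a,dir_b `tag_directory` objects for the two conditions
#'   (a = control, b = treated).
#' @param centers data.frame with columns chrom, pos (and optional name).
#' @param halfwidth window half-width, bp.
#' @param fc_cut fold-change threshold (strict).
#' @param floor tags-per-10M expression floor.
#' @param pc pseudocount (normalized tags).
#' @param strand_mode passed to [count_window()]; default both strands.
#' @return `data.table`: chrom, pos, name, count_a, count_b, fc, call.
#' @export
differential_ernas <- function(dir_a, dir_b, centers, halfwidth = 1000,
                               fc_cut = 1.5, floor = 10, pc = 1,
                               strand_mode = "both") {
  stop_if_not_cols(centers, c("chrom", "pos"), "centers")
  shared <- intersect(known_chroms(dir_a), known_chroms(dir_b))
  if (!length(shared))
    stop("directories share no chromosomes: mismatched genomes?",
         call. = FALSE)
  centers <- as.data.table(centers)
  a <- count_window(dir_a, centers$chrom, centers$pos, halfwidth,
                    strand_mode = strand_mode)
  b <- count_window(dir_b, centers$chrom, centers$pos, halfwidth,
                    strand_mode = strand_mode)
  fc <- (b + pc) / (a + pc)
  call <- rep("unchanged", nrow(centers))
  call[fc > fc_cut & b >= floor] <- "up"
  call[fc < 1 / fc_cut & a >= floor] <- "down"
  call[pmax(a, b) < floor] <- "low_expressed"
  nm <- centers$name %||% paste0("erna_", seq_len(nrow(centers)))
  data.table(chrom = centers$chrom, pos = centers$pos, name = nm,
             count_a = a, count_b = b, fc = fc, call = call)
}

## two-sided exact binomial p for x successes of n at rate p0
## (doubled smaller tail, capped at 1)
binom_two_sided <- function(x, n, p0) {
  lowr <- pbinom(x, n, p0)
  uppr <- pbinom(x - 1, n, p0, lower.tail = FALSE)
  pmin(1, 2 * pmin(lowr, uppr))
}

#' Differential gene-body transcription calls
#'
#' Quantifies each gene with [quantify_gene_body()] per condition. With
#' `fc = (count_b + pc) / (count_a + pc)`: up iff `fc >= fc_cut` (inclusive
#' — the published gene rule is "FC >= 1.5"); down iff `fc <= 1/fc_cut`;
#' low_expressed iff both read densities (normalized counts per kb of
#' quantified body) are below `density_floor`. The optional exact test is a
#' two-sided binomial on raw capped counts conditioned on the two library
#' totals, Benjamini-Hochberg adjusted across the result set.
#'
#' @param dir_a,dir_b `tag_directory` objects (a = control, b = treated).
#' @param genes TSS table.
#' @param fc_cut fold-change threshold (inclusive).
#' @param density_floor tags-per-10M per kb floor below which a gene is
#'   low_expressed.
#' @param test "none" or "poisson_exact".
#' @param pc pseudocount.
#' @param body_cap,promoter_exclusion passed to [quantify_gene_body()].
#' @return `data.table`: gene, count_a, count_b, density_a, density_b, fc,
#'   call, and pvalue/padj when a test is requested.
#' @export
differential_genes <- function(dir_a, dir_b, genes, fc_cut = 1.5,
                               density_floor = 10,
                               test = c("none", "poisson_exact"), pc = 1,
                               body_cap = 13000, promoter_exclusion = 500) {
  test <- match.arg(test)
  if (nrow(genes) == 0)
    return(data.table(gene = character(), count_a = numeric(),
                      count_b = numeric(), fc = numeric(),
                      call = character()))
  a <- quantify_gene_body(dir_a, genes, body_cap, promoter_exclusion)
  b <- quantify_gene_body(dir_b, genes, body_cap, promoter_exclusion)
  kb <- (pmin(body_cap, abs(genes$gene_end - genes$tss)) -
           promoter_exclusion) / 1000
  da <- a / kb
  db <- b / kb
  fc <- (b + pc) / (a + pc)
  call <- rep("unchanged", nrow(genes))
  call[fc >= fc_cut] <- "up"
  call[fc <= 1 / fc_cut] <- "down"
  call[pmax(da, db) < density_floor] <- "low_expressed"
  out <- data.table(gene = genes$gene, count_a = a, count_b = b,
                    density_a = da, density_b = db, fc = fc, call = call)
  if (test == "poisson_exact") {
    ra <- round(quantify_gene_body(dir_a, genes, body_cap,
                                   promoter_exclusion, normalize = FALSE))
    rb <- round(quantify_gene_body(dir_b, genes, body_cap,
                                   promoter_exclusion, normalize = FALSE))
    p0 <- dir_a$capped_total / (dir_a$capped_total + dir_b$capped_total)
    out[, pvalue := binom_two_sided(ra, ra + rb, p0)]
    out[, padj := p.adjust(pvalue, method = "BH")]
  }
  out[]
}
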