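# Independent brute-force oracles (plain loops, no package internals).

## expand a directory's capped tags to one row per tag
expand_tags <- function(dir) {
  t <- as.data.frame(dir$tags)
  t[rep(seq_len(nrow(t)), t$n), c("chrom", "pos", "strand")]
}

oracle_count_window <- function(tags, chrom, center, hw, mode = "both",
                                ref = NULL) {
  hit <- tags$chrom == chrom & tags$pos >= center - hw &
    tags$pos <= center + hw
  if (mode == "sense") hit <- hit & tags$strand == ref
  if (mode == "antisense")
    hit <- hit & tags$strand == c("+" = "-", "-" = "+")[ref]
  sum(hit)
}

oracle_overlap_count <- function(q, s, min_bp = 1) {
  cnt <- 0L
  for (i in seq_len(nrow(q))) {
    found <- FALSE
    for (j in seq_len(nrow(s))) {
      if (q$chrom[i] != s$chrom[j]) next
      ov <- min(q$end[i], s$end[j]) - max(q$start[i], s$start[j])
      if (ov >= min_bp) { found <- TRUE; break }
    }
    cnt <- cnt + found
  }
  cnt
}

oracle_nearest_tss <- function(regions, tss) {
  out <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ctr <- floor((regions$start[i] + regions$end[i]) / 2)
    best <- Inf
    for (j in seq_len(nrow(tss))) {
      if (tss$chrom[j] != regions$chrom[i]) next
      best <- min(best, abs(ctr - tss$tss[j]))
    }
    out[i] <- best
  }
  out
}

oracle_feature_flag <- function(regions, peaks, max_dist = 1000) {
  out <- logical(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ctr <- floor((regions$start[i] + regions$end[i]) / 2)
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != regions$chrom[i]) next
      if (abs(peaks$summit[j] - ctr) <= max_dist) { out[i] <- TRUE; break }
    }
  }
  out
}

## direct-summation Poisson upper tail P(X >= k)
oracle_poisson_tail <- function(k, lambda, terms = 2000) {
  if (k <= 0) return(1)
  j <- k:(k + terms)
  sum(exp(-lambda + j * log(lambda) - lgamma(j + 1)))
}

## two-sided exact binomial by direct tail summation (doubled smaller tail)
oracle_binom_two_sided <- function(x, n, p) {
  low <- sum(dbinom(0:x, n, p))
  upp <- sum(dbinom(x:n, n, p))
  min(1, 2 * min(low, upp))
}

## random small tag set + directory for oracle comparisons
rand_directory <- function(n_tags = 200, chroms = c(chrA = 50000,
                                                    chrB = 30000),
                           cap = 2) {
  ch <- sample(names(chroms), n_tags, replace = TRUE)
  rec <- data.frame(chrom = ch,
                    pos = as.integer(floor(runif(n_tags) * chroms[ch])),
                    strand = sample(c("+", "-"), n_tags, replace = TRUE))
  build_tag_directory(rec, per_position_cap = cap, chrom_sizes = chroms)
}

rand_intervals <- function(n, chroms = c(chrA = 50000, chrB = 30000),
                           max_len = 2000) {
  ch <- sample(names(chroms), n, replace = TRUE)
  len <- sample(50:max_len, n, replace = TRUE)
  st <- as.integer(floor(runif(n) * (chroms[ch] - len)))
  genomic_intervals(ch, st, st + len)
}

## shared small synthetic world (built once per test run)
small_config <- function(seed = 7) {
  synthetic_config(genome = c(chr1 = 2e6), n_genes = 10, n_megatrans = 10,
                   n_eralpha_other = 10, n_other_active = 10,
                   n_induced = 10, n_decoy_tss = 3, n_decoy_k27ac = 3,
                   n_decoy_nascent = 3, n_genes_up = 2, n_genes_down = 2,
                   seed = seed)
}

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config()
      ann <- generate_annotation(cfg)
      truth <- plant_enhancers(cfg, ann)
      cache <<- list(cfg = cfg, ann = ann, truth = truth,
                     bundle = simulate_bundle(truth))
    }
    cache
  }
})
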