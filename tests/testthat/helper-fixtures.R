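# Shared fixtures and independent brute-force oracles, all built in code.

feat <- function(starts, ends) tibble::tibble(start = starts, end = ends)

# Two hand-built genes on a 10 kb contig: one coding (+), one non-coding (-),
# with intergenic space around them.
toy_genes <- function() {
  emptyf <- feat(numeric(), numeric())
  tibble::tibble(
    gene_id = c("gA", "gB"),
    biotype = c("coding", "noncoding"),
    chrom = "chrT",
    start = c(1000, 5000), end = c(4000, 7000),
    strand = c("+", "-"),
    exons = list(feat(c(1000, 2000, 3500), c(1400, 2300, 4000)),
                 feat(c(5000, 6800), c(5200, 7000))),
    cds = list(feat(c(1200, 2000, 3500), c(1400, 2300, 3700)), emptyf),
    utr5 = list(feat(1000, 1200), emptyf),
    utr3 = list(feat(3700, 4000), emptyf)
  )
}

random_reads <- function(n, contig_len, seed, chrom = "chrT", read_len = 50) {
  withr::with_seed(seed, {
    starts <- sample.int(contig_len - read_len, n, replace = TRUE) - 1
    tibble::tibble(
      chrom = chrom, start = starts, end = starts + read_len,
      name = sprintf("r%04d", seq_len(n)), score = 0,
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
  })
}

# Brute-force per-position coverage: loop over positions, count reads.
bf_coverage <- function(reads, contig, strand, len) {
  vapply(seq_len(len) - 1, function(pos) {
    sel <- reads$chrom == contig & reads$start <= pos & reads$end > pos
    if (strand != "*") sel <- sel & reads$strand == strand
    sum(sel)
  }, numeric(1))
}

# Brute-force transcriptome count: per-read scan over every exon interval.
bf_tx_count <- function(reads, genes, stranded = TRUE) {
  hits <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] != r$chrom) next
      if (stranded && genes$strand[g] != r$strand) next
      ex <- genes$exons[[g]]
      if (any(ex$start < r$end & ex$end > r$start)) return(TRUE)
    }
    FALSE
  }, logical(1))
  sum(hits)
}

# Brute-force peak annotation by per-base membership scan.
bf_classify <- function(peak, genes) {
  positions <- seq(peak$start, peak$end - 1)
  in_gene <- function(g, pos) genes$start[g] <= pos & pos < genes$end[g]
  on_chrom <- which(genes$chrom == peak$chrom)
  cover_coding <- on_chrom[genes$biotype[on_chrom] == "coding"]
  cover_nc <- on_chrom[genes$biotype[on_chrom] == "noncoding"]
  ov_bases <- function(gs) {
    vapply(gs, function(g) sum(in_gene(g, positions)), numeric(1))
  }
  cod_ov <- ov_bases(cover_coding)
  nc_ov <- ov_bases(cover_nc)
  if (!any(cod_ov > 0) && !any(nc_ov > 0)) {
    return(list(category = "intergenic", feature = "none"))
  }
  if (any(cod_ov > 0)) {
    g <- cover_coding[which.max(cod_ov)]
    category <- "coding_gene"
  } else {
    g <- cover_nc[which.max(nc_ov)]
    category <- "noncoding_gene"
  }
  in_feat <- function(tbl, pos) {
    any(tbl$start <= pos & pos < tbl$end)
  }
  gene_pos <- positions[in_gene(g, positions)]
  if (category == "coding_gene") {
    counts <- c(
      cds = sum(vapply(gene_pos, function(p) in_feat(genes$cds[[g]], p), logical(1))),
      utr5 = sum(vapply(gene_pos, function(p) in_feat(genes$utr5[[g]], p), logical(1))),
      utr3 = sum(vapply(gene_pos, function(p) in_feat(genes$utr3[[g]], p), logical(1)))
    )
    counts <- c(counts, intron = length(gene_pos) - sum(vapply(
      gene_pos, function(p) in_feat(genes$exons[[g]], p), logical(1))))
  } else {
    exon_b <- sum(vapply(gene_pos, function(p) in_feat(genes$exons[[g]], p), logical(1)))
    counts <- c(exon_nc = exon_b, intron = length(gene_pos) - exon_b)
  }
  list(category = category, feature = names(counts)[which.max(counts)])
}

# Independent log-space term-by-term Poisson upper-tail summation.
bf_poisson_sf <- function(k, lam, terms = 2000) {
  if (k == 0) return(1)
  kk <- k:(k + terms)
  sum(exp(-lam + kk * log(lam) - lgamma(kk + 1)))
}

# Small simulation used by several peak-calling tests.
small_sim <- function(seed = 11, enrichment_fold = 5) {
  cfg <- sim_config(seed = seed, enrichment_fold = enrichment_fold)
  genes <- simulate_annotation(cfg)
  regions <- simulate_regions(cfg, genes)
  reads <- simulate_reads(cfg, regions)
  list(cfg = cfg, genes = genes, regions = regions, reads = reads)
}
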