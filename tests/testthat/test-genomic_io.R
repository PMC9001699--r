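test_that("read_bed maps fields verbatim and defaults missing columns", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t60\tr1\t0\t+", "chr1\t5\t20\tr2\t3\t-"), f)
  x <- read_bed(f, sample = "EZH2_rep1")
  expect_equal(x$start, c(10, 5))
  expect_equal(x$end, c(60, 20))
  expect_equal(x$strand, c("+", "-"))
  expect_equal(unique(x$sample), "EZH2_rep1")

  writeLines("chr1\t10\t60", f)
  x3 <- read_bed(f)
  expect_equal(x3$strand, "*")
  expect_equal(x3$name, ".")

  writeLines("", f)
  expect_equal(nrow(read_bed(f)), 0)
})

test_that("read_bed reports malformed lines by number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t60\tr\t0\t+", "chr1\t5\t5\tr\t0\t+"), f)
  expect_error(read_bed(f), "line 2.*empty interval")
  writeLines("chr1\tten\t60", f)
  expect_error(read_bed(f), "line 1.*non-integer")
  expect_error(read_bed(file.path(tempdir(), "nope.bed")), "no such file")
})

test_that("BED round-trip is byte-identical for canonical sorted input", {
  reads <- random_reads(50, 5000, seed = 4)
  reads <- dplyr::arrange(reads, chrom, start, end)
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(reads, f1)
  write_bed(read_bed(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("write_bed sorts records and encodes peak scores from max_fold", {
  f <- withr::local_tempfile(fileext = ".bed")
  peaks <- tibble::tibble(
    chrom = "chr1", start = c(500, 100), end = c(700, 300),
    name = c("p2", "p1"), strand = "+", max_fold = c(2.0, 15)
  )
  write_bed(peaks, f)
  lines <- readLines(f)
  expect_equal(length(lines), 2)
  expect_match(lines[1], "^chr1\t100\t300\tp1\t1000\t\\+$") # fold capped at 10
  expect_match(lines[2], "^chr1\t500\t700\tp2\t200\t\\+$")
  write_bed(peaks[0, ], f)
  expect_equal(length(readLines(f)), 0)
})

make_gtf <- function(path, lines) writeLines(lines, path)

test_that("read_gtf converts coordinates, unions exons, maps biotypes", {
  f <- withr::local_tempfile(fileext = ".gtf")
  at <- function(id, bt) sprintf('gene_id "%s"; gene_biotype "%s";', id, bt)
  make_gtf(f, c(
    paste0("chr1\tx\tgene\t101\t200\t.\t+\t.\t", at("g1", "protein_coding")),
    paste0("chr1\tx\texon\t101\t150\t.\t+\t.\t", at("g1", "protein_coding")),
    paste0("chr1\tx\texon\t141\t180\t.\t+\t.\t", at("g1", "protein_coding")),
    paste0("chr1\tx\tgene\t301\t400\t.\t-\t.\t", at("g2", "lincRNA")),
    paste0("chr1\tx\texon\t301\t350\t.\t-\t.\t", at("g2", "lincRNA"))
  ))
  g <- read_gtf(f)
  expect_equal(g$start[g$gene_id == "g1"], 100) # 1-based 101 -> 0-based 100
  expect_equal(g$end[g$gene_id == "g1"], 200)
  # overlapping transcript exons (100,150) + (140,180) union to (100,180)
  expect_equal(g$exons[[which(g$gene_id == "g1")]],
               tibble::tibble(start = 100, end = 180))
  expect_equal(g$biotype, c("coding", "noncoding"))
})

test_that("read_gtf rejects exons outside the gene span", {
  f <- withr::local_tempfile(fileext = ".gtf")
  at <- 'gene_id "g1"; gene_biotype "protein_coding";'
  make_gtf(f, c(
    paste0("chr1\tx\tgene\t101\t200\t.\t+\t.\t", at),
    paste0("chr1\tx\texon\t101\t300\t.\t+\t.\t", at)
  ))
  expect_error(read_gtf(f), "outside gene span")
})

test_that("gene models survive a GTF write/read round trip with exonic bases preserved", {
  genes <- toy_genes()
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(genes, f)
  back <- read_gtf(f)
  back <- back[match(genes$gene_id, back$gene_id), ]
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$biotype, genes$biotype)
  # total exonic base count per gene vs brute-force per-base membership scan
  for (i in seq_len(nrow(genes))) {
    scan <- sum(vapply(seq(genes$start[i], genes$end[i] - 1), function(p) {
      ex <- genes$exons[[i]]
      any(ex$start <= p & p < ex$end)
    }, logical(1)))
    expect_equal(sum(back$exons[[i]]$end - back$exons[[i]]$start), scan)
  }
})

test_that("read_fasta uppercases, trims names, rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgt", "ACGT", ">chr2", "ttt"), f)
  s <- read_fasta(f)
  expect_equal(names(s), c("chr1", "chr2"))
  # multi-line records concatenate without separators (vs single-pass oracle)
  expect_equal(as.character(s[["chr1"]]), "ACGTACGT")
  writeLines(c(">chr1", "aa", ">chr1", "cc"), f)
  expect_error(read_fasta(f), "duplicate contig")
})

test_that("bedGraph writer run-length encodes and omits zero runs", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  tr <- coverage_track("chr1", "+", c(0, 0, 2, 2, 1))
  write_bedgraph(tr, f)
  expect_equal(readLines(f), c("chr1\t2\t4\t2", "chr1\t4\t5\t1"))
  write_bedgraph(coverage_track("chr1", "+", rep(0, 10)), f)
  expect_equal(length(readLines(f)), 0)
})

test_that("bedGraph round-trip reproduces per-base values", {
  withr::with_seed(9, {
    vals <- sample(0:3, 200, replace = TRUE)
  })
  tr <- coverage_track("chr1", "+", vals)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, "chr1", 200, "+")
  expect_equal(back$values, as.numeric(vals))
})

test_that("fraction count tables round-trip through the readers", {
  counts <- tibble::tibble(
    fragment_id = c("f1", "f2"), nuclear = c(10, 0), cytoplasmic = c(2, 5),
    nuc_polya_plus = c(1, 1), nuc_polya_minus = c(8, 0)
  )
  totals <- tibble::tibble(
    fraction = c("nuclear", "cytoplasmic", "nuc_polya_plus", "nuc_polya_minus"),
    total = 1e6
  )
  fc <- withr::local_tempfile(fileext = ".tsv")
  ft <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(counts, fc)
  readr::write_tsv(totals, ft)
  got <- read_fraction_counts(fc, ft)
  expect_equal(as.data.frame(got$counts), as.data.frame(counts))
  expect_equal(got$totals$total, rep(1e6, 4))
})
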