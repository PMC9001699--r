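#' Read aligned-read intervals from a BED file
#'
#' Reads a BED3+ file into a tibble of 0-based half-open stranded intervals.
#' BED coordinates are already 0-based half-open and are taken verbatim.
#' Records without a strand column are marked `"*"` (unstranded); such records
#' can only be used by the peak caller with `strand_mode = "ignore"`.
#'
#' @param path Path to a tab-separated BED file (>= 3 columns, no header).
#' @param sample Optional sample label attached as a `sample` column
#'   (e.g. `"EZH2_rep1"`).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (and `sample` when given), one row per record, in file order.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t60\tr1\t0\t+", f)
#' read_bed(f)
#' @export
read_bed <- function(path, sample = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  empty <- tibble(
    chrom = character(), start = numeric(), end = numeric(),
    name = character(), score = numeric(), strand = character()
  )
  if (nrow(raw) == 0) {
    if (!is.null(sample)) empty$sample <- character()
    return(empty)
  }
  if (ncol(raw) < 3) {
    abort(paste0("BED parse error in ", path, ": fewer than 3 columns"))
  }
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad) > 0) {
    abort(paste0("BED parse error at line ", bad[1], " of ", path,
                 ": non-integer coordinates"))
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(paste0("BED parse error at line ", bad[1], " of ", path,
                 ": empty interval (start >= end)"))
  }
  if (any(start < 0)) {
    abort(paste0("BED parse error at line ", which(start < 0)[1], " of ", path,
                 ": negative coordinate"))
  }
  strand <- if (ncol(raw) >= 6) raw[[6]] else rep("*", nrow(raw))
  strand[is.na(strand) | strand == "."] <- "*"
  bad <- which(!strand %in% VALID_STRANDS)
  if (length(bad) > 0) {
    abort(paste0("BED parse error at line ", bad[1], " of ", path,
                 ": invalid strand '", strand[bad[1]], "'"))
  }
  score <- if (ncol(raw) >= 5) suppressWarnings(as.numeric(raw[[5]])) else rep(0, nrow(raw))
  score[is.na(score)] <- 0
  out <- tibble(
    chrom = raw[[1]],
    start = start,
    end = end,
    name = if (ncol(raw) >= 4) raw[[4]] else rep(".", nrow(raw)),
    score = score,
    strand = strand
  )
  if (!is.null(sample)) out$sample <- sample
  out
}

#' Write intervals to a 6-column BED file
#'
#' Records are sorted by (chrom, start, end). When a `max_fold` column is
#' present (called peaks), the BED score is `round(1000 * min(max_fold, 10) /
#' 10)`; otherwise an existing `score` column is used, defaulting to 0.
#'
#' @param x Interval tibble with at least `chrom`, `start`, `end`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "BED records")
  name <- if ("name" %in% names(x)) x$name else rep(".", nrow(x))
  strand <- if ("strand" %in% names(x)) x$strand else rep("*", nrow(x))
  score <- if ("max_fold" %in% names(x)) {
    round_half_up(1000 * pmin(x$max_fold, 10) / 10)
  } else if ("score" %in% names(x)) {
    x$score
  } else {
    rep(0, nrow(x))
  }
  strand_out <- if_else(strand == "*", ".", strand)
  out <- tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = name, score = score, strand = strand_out
  )
  out <- arrange(out, .data$chrom, .data$start, .data$end)
  lines <- sprintf(
    "%s\t%s\t%s\t%s\t%s\t%s",
    out$chrom, format_coord(out$start), format_coord(out$end),
    out$name, format_num(out$score), out$strand
  )
  readr::write_lines(lines, path)
  invisible(path)
}

format_coord <- function(x) sprintf("%.0f", x)

format_num <- function(x) {
  if_else(x == floor(x), sprintf("%.0f", x), vapply(x, function(v) format(v, digits = 15, scientific = FALSE), ""))
}

#' Read gene models from a GTF file
#'
#' Parses GENCODE-dialect GTF (1-based inclusive coordinates, `gene_id` and
#' `gene_biotype`/`gene_type` attributes) into one row per gene with nested
#' feature intervals, all converted to 0-based half-open coordinates. Exons
#' from multiple transcripts of a gene are unioned; `protein_coding` maps to
#' biotype `"coding"`, everything else to `"noncoding"`.
#'
#' @param path Path to a GTF file containing `gene`, `exon`, `CDS`,
#'   `five_prime_utr` and `three_prime_utr` features.
#' @return A tibble with columns `gene_id`, `biotype`, `chrom`, `start`,
#'   `end`, `strand` and list-columns `exons`, `cds`, `utr5`, `utr3`, each a
#'   tibble of `start`/`end` (0-based half-open, sorted, non-overlapping).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  if (!"gene_id" %in% names(df)) abort("GTF lacks gene_id attribute")
  if (!"gene_biotype" %in% names(df)) {
    if ("gene_type" %in% names(df)) {
      df$gene_biotype <- df$gene_type
    } else {
      abort("GTF lacks gene_biotype/gene_type attribute")
    }
  }
  df <- mutate(df,
    chrom = as.character(.data$seqnames),
    start0 = .data$start - 1, end0 = as.numeric(.data$end),
    strand = as.character(.data$strand),
    type = as.character(.data$type)
  )
  genes <- filter(df, .data$type == "gene")
  if (nrow(genes) == 0) abort("GTF contains no gene features")
  feature_tbl <- function(sub) {
    if (nrow(sub) == 0) return(tibble(start = numeric(), end = numeric()))
    red <- IRanges::reduce(IRanges::IRanges(sub$start0 + 1, sub$end0))
    tibble(start = IRanges::start(red) - 1, end = as.numeric(IRanges::end(red)))
  }
  out <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    sub <- filter(df, .data$gene_id == g$gene_id, .data$type != "gene")
    exons <- feature_tbl(filter(sub, .data$type == "exon"))
    if (nrow(exons) > 0 &&
        (min(exons$start) < g$start0 || max(exons$end) > g$end0)) {
      abort(paste0("gene ", g$gene_id, ": exon outside gene span"))
    }
    cds <- feature_tbl(filter(sub, .data$type == "CDS"))
    utr5 <- feature_tbl(filter(sub, .data$type == "five_prime_utr"))
    utr3 <- feature_tbl(filter(sub, .data$type == "three_prime_utr"))
    tibble(
      gene_id = g$gene_id,
      biotype = if (g$gene_biotype == "protein_coding") "coding" else "noncoding",
      chrom = g$chrom, start = g$start0, end = g$end0, strand = g$strand,
      exons = list(exons), cds = list(cds), utr5 = list(utr5), utr3 = list(utr3)
    )
  })
  out
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_gtf()]: emits `gene`, `exon`, `CDS`, `five_prime_utr` and
#' `three_prime_utr` lines with 1-based inclusive coordinates and `gene_id` /
#' `gene_biotype` attributes.
#'
#' @param genes Gene tibble as returned by [read_gtf()] or
#'   [simulate_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  biotype_out <- if_else(genes$biotype == "coding", "protein_coding", "lncRNA")
  lines <- character()
  gtf_line <- function(chrom, src, type, start0, end0, strand, gid, bt) {
    sprintf("%s\t%s\t%s\t%.0f\t%.0f\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
            chrom, src, type, start0 + 1, end0, strand, gid, bt)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    bt <- biotype_out[i]
    lines <- c(lines, gtf_line(g$chrom, "nascentrip", "gene", g$start, g$end, g$strand, g$gene_id, bt))
    feat <- function(tbl, type) {
      if (nrow(tbl) == 0) return(character())
      sprintf("%s\t%s\t%s\t%.0f\t%.0f\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
              g$chrom, "nascentrip", type, tbl$start + 1, tbl$end, g$strand, g$gene_id, bt)
    }
    lines <- c(lines,
               feat(g$exons[[1]], "exon"),
               feat(g$cds[[1]], "CDS"),
               feat(g$utr5[[1]], "five_prime_utr"),
               feat(g$utr3[[1]], "three_prime_utr"))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a reference FASTA into a sequence store
#'
#' @param path Path to a FASTA file.
#' @return An uppercased [Biostrings::DNAStringSet]; names are the header
#'   token before the first whitespace. Duplicate contig names are an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    abort(paste0("duplicate contig name in ", path, ": ",
                 names(seqs)[duplicated(names(seqs))][1]))
  }
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write a FASTA file
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal values are collapsed into one interval (run-length
#' encoding); zero-valued runs are omitted, so an all-zero track produces an
#' empty file.
#'
#' @param track A [coverage_track()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  lines <- sprintf("%s\t%.0f\t%.0f\t%s",
                   track$contig, starts[keep], ends[keep],
                   format_num(r$values[keep]))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a bedGraph file back into per-base values
#'
#' @param path Path to a bedGraph file.
#' @param contig Contig to extract.
#' @param length Contig length in bases.
#' @param strand Strand label to attach to the returned track.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, contig, length, strand = "*") {
  raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         col_types = "cddd", progress = FALSE)
  values <- numeric(length)
  raw <- filter(raw, .data$chrom == contig)
  for (i in seq_len(nrow(raw))) {
    values[(raw$start[i] + 1):raw$end[i]] <- raw$value[i]
  }
  coverage_track(contig, strand, values)
}

#' Read a fragment count table with per-fraction totals
#'
#' The count table is a TSV with header `fragment_id`, `nuclear`,
#' `cytoplasmic`, `nuc_polya_plus`, `nuc_polya_minus` (integer counts). The
#' totals sidecar is a TSV with header `fraction`, `total` giving total mapped
#' reads per fraction, used for RPM normalization.
#'
#' @param counts_path Path to the count table.
#' @param totals_path Path to the totals sidecar.
#' @return A list with tibbles `counts` and `totals`.
#' @export
read_fraction_counts <- function(counts_path, totals_path) {
  counts <- readr::read_tsv(counts_path, col_types = "cdddd", progress = FALSE)
  needed <- c("fragment_id", "nuclear", "cytoplasmic", "nuc_polya_plus", "nuc_polya_minus")
  if (!all(needed %in% names(counts))) {
    abort(paste0("fraction count table must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  totals <- readr::read_tsv(totals_path, col_types = "cd", progress = FALSE)
  if (!all(c("fraction", "total") %in% names(totals))) {
    abort("totals sidecar must have columns fraction, total")
  }
  list(counts = counts, totals = totals)
}
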