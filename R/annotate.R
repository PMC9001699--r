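#' Assign a peak to a gene category and feature
#'
#' Category follows overlap with gene spans, with precedence coding gene >
#' non-coding gene > intergenic; among genes of the winning category the one
#' with most overlapping bases is used (leftmost on ties). The feature is
#' decided by overlap-base majority within the assigned gene: for coding
#' genes CDS > 5'UTR > 3'UTR > intron on tie, for non-coding genes exon vs
#' intron. A peak overlapping no gene span is intergenic with feature
#' `"none"`.
#'
#' @param peak One-row interval tibble (or list with `chrom`, `start`,
#'   `end`, optionally `strand`).
#' @param genes Gene tibble (see [read_gtf()]).
#' @param strand_aware If `TRUE`, only genes on the peak's strand are
#'   considered. Default `FALSE`: RIP fragments are assigned to genes on
#'   either strand.
#' @param method `"base_majority"` (default) scores feature overlap over the
#'   whole peak; `"summit"` uses only the summit position (requires a
#'   `summit` field).
#' @return A list with `category`, `feature`, `gene_id`.
#' @export
classify_peak <- function(peak, genes, strand_aware = FALSE,
                          method = c("base_majority", "summit")) {
  method <- match.arg(method)
  qs <- peak$start
  qe <- peak$end
  if (method == "summit") {
    if (is.null(peak$summit)) abort("summit method requires a summit field")
    qs <- peak$summit
    qe <- peak$summit + 1
  }
  cand <- genes[genes$chrom == peak$chrom &
                  genes$start < qe & genes$end > qs, , drop = FALSE]
  if (strand_aware && !is.null(peak$strand) && peak$strand != "*") {
    cand <- cand[cand$strand == peak$strand, , drop = FALSE]
  }
  if (nrow(cand) == 0) {
    return(list(category = "intergenic", feature = "none", gene_id = NA_character_))
  }
  has_coding <- any(cand$biotype == "coding")
  cand <- cand[cand$biotype == (if (has_coding) "coding" else "noncoding"), ,
               drop = FALSE]
  ov <- pmin(cand$end, qe) - pmax(cand$start, qs)
  g <- cand[which.max(ov), ]
  overlap_bases <- function(tbl) {
    if (nrow(tbl) == 0) return(0)
    sum(pmax(0, pmin(tbl$end, qe) - pmax(tbl$start, qs)))
  }
  exonic <- overlap_bases(g$exons[[1]])
  gene_ov <- pmin(g$end, qe) - pmax(g$start, qs)
  intron_b <- gene_ov - exonic
  if (g$biotype == "coding") {
    scores <- c(
      cds = overlap_bases(g$cds[[1]]),
      utr5 = overlap_bases(g$utr5[[1]]),
      utr3 = overlap_bases(g$utr3[[1]]),
      intron = intron_b
    )
  } else {
    scores <- c(exon_nc = exonic, intron = intron_b)
  }
  feature <- names(scores)[which.max(scores)] # which.max: first on ties,
  # and scores are ordered by the documented precedence
  list(
    category = if (g$biotype == "coding") "coding_gene" else "noncoding_gene",
    feature = feature,
    gene_id = g$gene_id
  )
}

#' Annotate a peak table against gene models
#'
#' Vectorised [classify_peak()] over a tibble of peaks.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, ...).
#' @param genes Gene tibble.
#' @inheritParams classify_peak
#' @return `peaks` with `category`, `feature` and `gene_id` columns added.
#' @export
annotate_peaks <- function(peaks, genes, strand_aware = FALSE,
                           method = c("base_majority", "summit")) {
  method <- match.arg(method)
  validate_intervals(peaks, "peaks")
  calls <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    as_tibble(classify_peak(peaks[i, ], genes, strand_aware, method))
  })
  bind_rows(bind_cols(peaks, calls))
}

#' Summarise annotation calls into proportion tables
#'
#' @param calls Tibble with `category` and `feature` columns, as produced by
#'   [annotate_peaks()].
#' @return A list of two tibbles: `category` (proportions of coding /
#'   non-coding / intergenic over all calls) and `feature` (feature
#'   proportions within the coding and non-coding categories). Each
#'   proportion set sums to 1.
#' @export
annotation_summary <- function(calls) {
  if (nrow(calls) == 0) abort("annotation_summary: no calls")
  cat_tbl <- count(calls, .data$category, name = "n")
  cat_tbl <- mutate(cat_tbl, proportion = n / sum(n))
  feat_tbl <- filter(calls, .data$category != "intergenic")
  feat_tbl <- count(feat_tbl, .data$category, .data$feature, name = "n")
  feat_tbl <- mutate(group_by(feat_tbl, .data$category),
                     proportion = n / sum(n))
  list(category = cat_tbl, feature = ungroup(feat_tbl))
}

#' Bar-chart of peak annotation proportions
#'
#' @param summary Output of [annotation_summary()].
#' @return A ggplot object with one panel for gene categories and one for
#'   gene features.
#' @export
plot_annotation <- function(summary) {
  cat_df <- mutate(summary$category, panel = "category",
                   label = .data$category)
  feat_df <- mutate(summary$feature, panel = paste0(.data$category, " features"),
                    label = .data$feature)
  df <- bind_rows(select(cat_df, "panel", "label", "proportion"),
                  select(feat_df, "panel", "label", "proportion"))
  ggplot(df, aes(x = .data$label, y = .data$proportion)) +
    geom_col() +
    facet_wrap(~panel, scales = "free_x") +
    labs(x = NULL, y = "proportion of peaks",
         title = "Peak annotation by gene category and feature") +
    theme_bw()
}
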