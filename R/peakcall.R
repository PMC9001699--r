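#' Upper-tail Poisson probability P(X >= k)
#'
#' The per-site enrichment p-value of the peak caller: the probability that a
#' Poisson variable with mean `lam` (derived from the IgG control) reaches at
#' least the observed RIP window count `k`. Wraps the numerically stable
#' upper-tail of [stats::ppois()]; `k = 0` returns exactly 1.
#'
#' @param k Non-negative integer count(s).
#' @param lam Positive Poisson mean(s); recycled against `k`.
#' @return Probabilities in `[0, 1]`.
#' @examples
#' poisson_sf(1, 1) # 1 - exp(-1)
#' @export
poisson_sf <- function(k, lam) {
  if (any(lam <= 0)) abort("poisson_sf: lam must be > 0")
  if (any(k < 0) || any(k != floor(k))) {
    abort("poisson_sf: k must be a non-negative integer")
  }
  p <- ppois(k - 1, lam, lower.tail = FALSE)
  p[k == 0] <- 1
  p
}

#' Count reads overlapping the annotated transcriptome
#'
#' The number of reads whose interval overlaps at least 1 bp of any annotated
#' exon. This is the library "size" used for matching the RIP and IgG
#' libraries before peak calling.
#'
#' @param reads Read tibble.
#' @param genes Gene tibble (see [read_gtf()]).
#' @param strand_mode `"stranded"`: a read counts only against exons of genes
#'   on its own strand; `"ignore"`: either strand.
#' @return Integer count.
#' @export
count_transcriptome_reads <- function(reads, genes,
                                      strand_mode = c("stranded", "ignore")) {
  strand_mode <- match.arg(strand_mode)
  validate_intervals(reads, "reads")
  if (nrow(reads) == 0) return(0L)
  sum(transcriptome_overlap(reads, genes, strand_mode))
}

# Logical vector: does each read overlap >= 1 bp of any exon?
transcriptome_overlap <- function(reads, genes, strand_mode) {
  exons <- flatten_exons(genes)
  if (nrow(exons) == 0) return(rep(FALSE, nrow(reads)))
  if (strand_mode == "stranded" && any(reads$strand == "*")) {
    abort("unstranded reads present; use strand_mode = \"ignore\"")
  }
  reads_gr <- as_granges0(reads)
  exons_gr <- as_granges0(exons)
  GenomicRanges::countOverlaps(
    reads_gr, exons_gr, minoverlap = 1L,
    ignore.strand = (strand_mode == "ignore")
  ) > 0
}

flatten_exons <- function(genes) {
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    if (nrow(ex) == 0) return(NULL)
    tibble(chrom = genes$chrom[i], start = ex$start, end = ex$end,
           strand = genes$strand[i])
  })
}

#' Match two libraries by downsampling the larger one
#'
#' The library with the larger transcriptome read count (see
#' [count_transcriptome_reads()]) is subsampled uniformly at random, without
#' replacement, until its transcriptome count exactly equals the smaller
#' library's; non-transcriptome reads are thinned at the same rate. Two
#' phases make the match exact and deterministic: (1) sample all reads at
#' rate `target/current`, (2) repair by randomly adding back or removing
#' transcriptome-overlapping reads until the counts agree.
#'
#' @param reads_a,reads_b Read tibbles for the two libraries.
#' @param genes Gene tibble used to define the transcriptome.
#' @param seed RNG seed; a fixed seed gives a bit-identical subsample.
#' @param strand_mode Passed to [count_transcriptome_reads()].
#' @return A list with `a` and `b` (the matched read tibbles, in argument
#'   order) and `sizes`, a tibble of transcriptome counts before and after.
#' @export
downsample_to_match <- function(reads_a, reads_b, genes, seed = 17,
                                strand_mode = c("stranded", "ignore")) {
  strand_mode <- match.arg(strand_mode)
  tx_a <- transcriptome_overlap(reads_a, genes, strand_mode)
  tx_b <- transcriptome_overlap(reads_b, genes, strand_mode)
  n_a <- sum(tx_a); n_b <- sum(tx_b)
  if (n_a == 0 || n_b == 0) abort("cannot match empty library")
  sizes <- tibble(library = c("a", "b"), transcriptome_before = c(n_a, n_b))
  if (n_a == n_b) {
    sizes$transcriptome_after <- c(n_a, n_b)
    return(list(a = reads_a, b = reads_b, sizes = sizes))
  }
  if (n_a > n_b) {
    big <- reads_a; tx <- tx_a; target <- n_b
  } else {
    big <- reads_b; tx <- tx_b; target <- n_a
  }
  rate <- target / sum(tx)
  down <- withr::with_seed(seed, {
    keep <- sort(sample.int(nrow(big), size = round(nrow(big) * rate)))
    kept_tx <- intersect(keep, which(tx))
    excess <- length(kept_tx) - target
    if (excess > 0) {
      drop <- sample(kept_tx, excess)
      keep <- setdiff(keep, drop)
    } else if (excess < 0) {
      pool <- setdiff(which(tx), keep)
      keep <- c(keep, sample(pool, -excess))
    }
    big[sort(keep), ]
  })
  if (n_a > n_b) {
    out <- list(a = down, b = reads_b)
  } else {
    out <- list(a = reads_a, b = down)
  }
  sizes$transcriptome_after <- c(
    sum(transcriptome_overlap(out$a, genes, strand_mode)),
    sum(transcriptome_overlap(out$b, genes, strand_mode))
  )
  out$sizes <- sizes
  out
}

# All per-position tracks needed for seeding/extension on one contig/strand.
peakcall_tracks <- function(rip_counts, ctrl_counts, config) {
  w <- config$w_half
  rip_s <- smooth_coverage(rip_counts, w)
  ctrl_s <- smooth_coverage(ctrl_counts, w)
  fold <- fold_track(rip_s, ctrl_s, config$lambda_min / (2 * w + 1))
  rip_ws <- window_sum(rip_counts, w)
  ctrl_ws <- window_sum(ctrl_counts, w)
  list(
    fold = fold,
    k = round_half_up(rip_ws$values),
    lam = pmax(ctrl_ws$values, config$lambda_min)
  )
}

#' Seed positions of the comparative Poisson test
#'
#' Position `i` (0-based) is a seed iff the smoothed RIP/control fold there
#' is at least `f_seed` and the Poisson upper-tail probability of the RIP
#' window sum `k_i` under the control-derived mean `lambda_i =
#' max(window_sum(ctrl)[i], lambda_min)` is at most `p_max`.
#'
#' @param rip_counts,ctrl_counts Raw per-base count [coverage_track()]s of a
#'   matched library pair (same contig/strand).
#' @param config A [peakcall_config()].
#' @return Sorted integer vector of 0-based seed positions.
#' @export
call_seed_sites <- function(rip_counts, ctrl_counts, config = peakcall_config()) {
  tr <- peakcall_tracks(rip_counts, ctrl_counts, config)
  cand <- which(tr$fold$values >= config$f_seed)
  if (length(cand) == 0) return(integer())
  p <- poisson_sf(tr$k[cand], tr$lam[cand])
  sort(cand[p <= config$p_max]) - 1L
}

#' Build peaks from seed sites by fold-bounded extension
#'
#' Maximal runs of consecutive seed positions form proto-peaks; each is
#' extended base-by-base in both directions while the fold stays at or above
#' `f_ext`; overlapping or adjacent extended intervals are unioned. The
#' summit is the leftmost position of maximal fold within the peak; the peak
#' also records its maximum fold and minimum Poisson p-value.
#'
#' @inheritParams call_seed_sites
#' @param replicate Replicate label recorded on each peak.
#' @return Peak tibble: `chrom`, `start`, `end`, `strand`, `summit`,
#'   `max_fold`, `min_p`, `replicate`.
#' @export
build_peaks <- function(rip_counts, ctrl_counts, config = peakcall_config(),
                        replicate = "rep1") {
  tr <- peakcall_tracks(rip_counts, ctrl_counts, config)
  cand <- which(tr$fold$values >= config$f_seed)
  seed_idx <- integer()
  if (length(cand) > 0) {
    p <- poisson_sf(tr$k[cand], tr$lam[cand])
    seed_idx <- cand[p <= config$p_max]
  }
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character(), summit = numeric(),
                  max_fold = numeric(), min_p = numeric(),
                  replicate = character())
  if (length(seed_idx) == 0) return(empty)
  # Since f_seed >= f_ext, extending a seed run while fold >= f_ext yields
  # exactly the maximal fold >= f_ext run containing it, and runs from
  # different seeds within one such run coincide; maximal runs are never
  # adjacent, so the union step is implicit.
  above <- tr$fold$values >= config$f_ext
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  is_seed <- logical(length(above))
  is_seed[seed_idx] <- TRUE
  seed_cum <- c(0, cumsum(is_seed))
  keep <- which(r$values & (seed_cum[run_end + 1] - seed_cum[run_start]) > 0)
  purrr::map_dfr(keep, function(j) {
    s <- run_start[j]; e <- run_end[j]
    span_fold <- tr$fold$values[s:e]
    summit <- s + which.max(span_fold) - 1
    p_span <- poisson_sf(tr$k[s:e], tr$lam[s:e])
    tibble(
      chrom = tr$fold$contig, start = s - 1, end = e,
      strand = tr$fold$strand, summit = summit - 1,
      max_fold = max(span_fold), min_p = min(p_span),
      replicate = replicate
    )
  })
}

#' Merge per-replicate peaks into reproducible peaks
#'
#' Two peaks from different replicates are linked when the gap between their
#' intervals is at most `d_merge` (overlapping intervals have gap 0).
#' Connected components of this cross-replicate link graph that contain at
#' least one peak from each replicate become reproducible peaks spanning the
#' union of their members; peaks supported by a single replicate are
#' discarded. The operation is symmetric in the replicate arguments.
#'
#' @param peaks_rep1,peaks_rep2 Peak tibbles from [build_peaks()] for the two
#'   replicates.
#' @param d_merge Maximum inter-interval gap in bases.
#' @return Tibble of reproducible peaks: `chrom`, `start`, `end`, `strand`,
#'   `name`, `n_members`, `max_fold`, `min_p`, and a `members` list-column
#'   holding the contributing per-replicate peaks.
#' @export
merge_reproducible <- function(peaks_rep1, peaks_rep2, d_merge = 1000) {
  all <- bind_rows(
    mutate(peaks_rep1, .rep = "r1"),
    mutate(peaks_rep2, .rep = "r2")
  )
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character(), name = character(),
                  n_members = integer(), max_fold = numeric(),
                  min_p = numeric(), members = list())
  if (nrow(all) == 0) return(empty)
  out <- list()
  for (key in unique(paste(all$chrom, all$strand))) {
    grp <- all[paste(all$chrom, all$strand) == key, ]
    grp <- arrange(grp, .data$start, .data$end)
    n <- nrow(grp)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        gap <- max(grp$start[j] - grp$end[i], grp$start[i] - grp$end[j], 0)
        if (gap <= d_merge && grp$.rep[i] != grp$.rep[j]) {
          parent[find(j)] <- find(i)
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (c_id in unique(comp)) {
      members <- grp[comp == c_id, ]
      if (length(unique(members$.rep)) < 2) next
      out[[length(out) + 1]] <- tibble(
        chrom = members$chrom[1],
        start = min(members$start), end = max(members$end),
        strand = members$strand[1],
        n_members = nrow(members),
        max_fold = max(members$max_fold),
        min_p = min(members$min_p),
        members = list(select(members, -".rep"))
      )
    }
  }
  if (length(out) == 0) return(empty)
  res <- arrange(bind_rows(out), .data$chrom, .data$start, .data$end)
  res$name <- sprintf("RP%04d", seq_len(nrow(res)))
  select(res, "chrom", "start", "end", "strand", "name", "n_members",
         "max_fold", "min_p", "members")
}

#' Call reproducible RIP-seq peaks against an IgG control
#'
#' Full comparative peak-calling workflow for two RIP / IgG replicate pairs:
#' per pair, the libraries are matched by transcriptome read count
#' ([downsample_to_match()]), per-base count tracks are built for every
#' contig (and strand, in stranded mode), seeds are called with the fold +
#' Poisson test and extended into peaks ([build_peaks()]); per-replicate
#' peaks are then merged across replicates ([merge_reproducible()]).
#'
#' @param rip List of 2 read tibbles (or BED file paths) for the RIP
#'   replicates.
#' @param igg List of 2 read tibbles (or BED file paths) for the matched IgG
#'   controls.
#' @param genes Gene tibble (or GTF file path) defining the transcriptome
#'   used for library matching.
#' @param config A [peakcall_config()].
#' @param contig_lengths Optional named vector of contig lengths; inferred
#'   from the inputs when omitted.
#' @param keep_tracks If `TRUE`, retain the smoothed coverage and fold
#'   tracks (element `tracks`, one entry per replicate/contig/strand) for
#'   bedGraph export.
#' @return An object of class `rip_peakcall` with elements `peaks`
#'   (per-replicate peak tibble), `reproducible` (merged peak tibble),
#'   `library_sizes`, `config`, and `contig_lengths`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
call_peaks <- function(rip, igg, genes, config = peakcall_config(),
                       contig_lengths = NULL, keep_tracks = FALSE) {
  load_reads <- function(x, label) {
    if (is.character(x)) read_bed(x, sample = label) else x
  }
  if (length(rip) != 2 || length(igg) != 2) {
    abort("call_peaks expects exactly 2 RIP and 2 IgG read sets")
  }
  rip <- purrr::imap(rip, ~ load_reads(.x, paste0("rip", .y)))
  igg <- purrr::imap(igg, ~ load_reads(.x, paste0("igg", .y)))
  if (is.character(genes)) genes <- read_gtf(genes)
  gene_spans <- genes[, c("chrom", "start", "end")]
  contig_lengths <- infer_contig_lengths(c(rip, igg, list(gene_spans)),
                                         contig_lengths)
  strands <- if (config$strand_mode == "stranded") c("+", "-") else "*"
  peaks <- list()
  sizes <- list()
  tracks <- list()
  for (rep_i in 1:2) {
    matched <- downsample_to_match(
      rip[[rep_i]], igg[[rep_i]], genes,
      seed = config$seed + rep_i, strand_mode = config$strand_mode
    )
    sz <- matched$sizes
    sz$library <- c(paste0("rip", rep_i), paste0("igg", rep_i))
    sz$reads_after <- c(nrow(matched$a), nrow(matched$b))
    sizes[[rep_i]] <- sz
    for (contig in names(contig_lengths)) {
      L <- contig_lengths[[contig]]
      for (strand in strands) {
        rip_tr <- per_base_counts(matched$a, contig, strand, L)
        ctrl_tr <- per_base_counts(matched$b, contig, strand, L)
        peaks[[length(peaks) + 1]] <- build_peaks(
          rip_tr, ctrl_tr, config, replicate = paste0("rep", rep_i)
        )
        if (keep_tracks) {
          rip_s <- smooth_coverage(rip_tr, config$w_half)
          ctrl_s <- smooth_coverage(ctrl_tr, config$w_half)
          fold <- fold_track(rip_s, ctrl_s,
                             config$lambda_min / (2 * config$w_half + 1))
          key <- paste0("rep", rep_i, "_", contig, "_", strand)
          tracks[[key]] <- list(rip = rip_s, ctrl = ctrl_s, fold = fold)
        }
      }
    }
  }
  peaks <- bind_rows(peaks)
  reproducible <- merge_reproducible(
    filter(peaks, .data$replicate == "rep1"),
    filter(peaks, .data$replicate == "rep2"),
    d_merge = config$d_merge
  )
  structure(list(
    peaks = peaks,
    reproducible = reproducible,
    library_sizes = bind_rows(sizes),
    config = config,
    contig_lengths = contig_lengths,
    tracks = if (keep_tracks) tracks else NULL
  ), class = "rip_peakcall")
}

#' @export
print.rip_peakcall <- function(x, ...) {
  cat("<rip_peakcall>\n")
  cat("  per-replicate peaks:",
      sum(x$peaks$replicate == "rep1"), "(rep1) /",
      sum(x$peaks$replicate == "rep2"), "(rep2)\n")
  cat("  reproducible peaks:", nrow(x$reproducible), "\n")
  cat("  preset:", x$config$preset, "\n")
  invisible(x)
}

#' @rdname call_peaks
#' @param x An `rip_peakcall` object.
#' @param ... Unused.
#' @method tidy rip_peakcall
#' @export
tidy.rip_peakcall <- function(x, ...) {
  select(x$reproducible, -"members")
}

#' @rdname call_peaks
#' @method glance rip_peakcall
#' @export
glance.rip_peakcall <- function(x, ...) {
  tibble(
    n_peaks_rep1 = sum(x$peaks$replicate == "rep1"),
    n_peaks_rep2 = sum(x$peaks$replicate == "rep2"),
    n_reproducible = nrow(x$reproducible),
    preset = x$config$preset,
    f_seed = x$config$f_seed,
    p_max = x$config$p_max
  )
}

#' @rdname call_peaks
#' @param object An `rip_peakcall` object.
#' @method autoplot rip_peakcall
#' @export
autoplot.rip_peakcall <- function(object, ...) {
  spans <- bind_rows(
    mutate(object$peaks, track = .data$replicate),
    mutate(select(object$reproducible, -"members"), track = "reproducible",
           replicate = "reproducible")
  )
  ggplot(spans, aes(x = .data$start, xend = .data$end,
                    y = .data$track, yend = .data$track)) +
    geom_segment(linewidth = 3) +
    facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    labs(x = "position (bp)", y = NULL,
         title = "Called peaks per replicate and after merging") +
    theme_bw()
}
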