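#' Extract peak sequences for motif discovery (foreground)
#'
#' One FASTA record per peak, named `"peakID|chrom:start-end(strand)"`;
#' minus-strand peaks are reverse-complemented so records read in the sense
#' of the bound RNA. Peaks shorter than `min_peak_len` are skipped with a
#' message.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `strand`, optional
#'   `name`).
#' @param sequences A named [Biostrings::DNAStringSet] (see [read_fasta()]).
#' @param min_peak_len Minimum peak length in bases.
#' @return A [Biostrings::DNAStringSet] of foreground sequences.
#' @export
extract_foreground <- function(peaks, sequences, min_peak_len = 50) {
  validate_intervals(peaks, "peaks")
  if (min_peak_len <= 0) abort("min_peak_len must be > 0")
  nm <- peaks[["name"]] %||% sprintf("peak%04d", seq_len(nrow(peaks)))
  strand <- if ("strand" %in% names(peaks)) peaks$strand else rep("*", nrow(peaks))
  keep <- (peaks$end - peaks$start) >= min_peak_len
  if (any(!keep)) {
    inform(paste0(sum(!keep), " peak(s) shorter than ", min_peak_len,
                  " bp skipped"))
  }
  peaks <- peaks[keep, ]; nm <- nm[keep]; strand <- strand[keep]
  out <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ctg <- peaks$chrom[i]
    if (!ctg %in% names(sequences)) {
      abort(paste0("peak ", nm[i], ": contig ", ctg, " not in reference"))
    }
    if (peaks$end[i] > Biostrings::width(sequences[ctg])) {
      abort(paste0("peak ", nm[i], " extends beyond contig ", ctg))
    }
    s <- Biostrings::subseq(sequences[[ctg]], peaks$start[i] + 1, peaks$end[i])
    if (strand[i] == "-") s <- Biostrings::reverseComplement(s)
    out[i] <- as.character(s)
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- sprintf("%s|%s:%.0f-%.0f(%s)", nm, peaks$chrom,
                        peaks$start, peaks$end, strand)
  res
}

#' Extract flanking sequences as motif-discovery background
#'
#' For each peak, one upstream and one downstream flank. In
#' `"equal_length"` mode each flank has the peak's own length; in
#' `"fixed_length"` mode each has `fixed_flank` bases. Flanks are clipped at
#' contig ends and against every peak interval, so background never overlaps
#' foreground; a flank fully consumed by clipping is omitted with a message.
#' Minus-strand peaks have their flanks reverse-complemented.
#'
#' @inheritParams extract_foreground
#' @param flank_mode `"equal_length"` or `"fixed_length"`.
#' @param fixed_flank Flank size in bases for `"fixed_length"` mode.
#' @return A [Biostrings::DNAStringSet] of background sequences, records
#'   named `"peakID|chrom:start-end(strand)|up"` / `"...|down"`.
#' @export
extract_background <- function(peaks, sequences,
                               flank_mode = c("equal_length", "fixed_length"),
                               fixed_flank = 500, min_peak_len = 50) {
  flank_mode <- match.arg(flank_mode)
  if (fixed_flank <= 0) abort("fixed_flank must be > 0")
  validate_intervals(peaks, "peaks")
  nm <- peaks[["name"]] %||% sprintf("peak%04d", seq_len(nrow(peaks)))
  strand <- if ("strand" %in% names(peaks)) peaks$strand else rep("*", nrow(peaks))
  keep <- (peaks$end - peaks$start) >= min_peak_len
  peaks <- peaks[keep, ]; nm <- nm[keep]; strand <- strand[keep]
  seqs <- character(); ids <- character()
  for (i in seq_len(nrow(peaks))) {
    ctg <- peaks$chrom[i]
    L <- Biostrings::width(sequences[ctg])
    fl <- if (flank_mode == "equal_length") peaks$end[i] - peaks$start[i] else fixed_flank
    others <- peaks[peaks$chrom == ctg, ]
    for (side in c("up", "down")) {
      if (side == "up") {
        fs <- max(0, peaks$start[i] - fl); fe <- peaks$start[i]
        # clip against any peak intruding from the left
        intr <- others$end[others$end <= fe & others$end > fs]
        if (length(intr) > 0) fs <- max(fs, max(intr))
        anchor <- fe - 1
      } else {
        fs <- peaks$end[i]; fe <- min(L, peaks$end[i] + fl)
        intr <- others$start[others$start >= fs & others$start < fe]
        if (length(intr) > 0) fe <- min(fe, min(intr))
        anchor <- fs
      }
      # keep only the piece adjacent to the source peak that avoids all peaks
      if (fe <= fs || anchor < fs || anchor >= fe) {
        inform(paste0("flank ", side, " of ", nm[i],
                      " fully consumed by clipping; omitted"))
        next
      }
      ov <- others[others$start < fe & others$end > fs, ]
      if (nrow(ov) > 0 && !(nrow(ov) == 1 && ov$start[1] == peaks$start[i] &&
                              ov$end[1] == peaks$end[i])) {
        # residual overlap with a peak other than pure adjacency: shrink
        for (j in seq_len(nrow(ov))) {
          if (ov$start[j] == peaks$start[i] && ov$end[j] == peaks$end[i]) next
          if (side == "up" && ov$end[j] <= fe) fs <- max(fs, ov$end[j])
          if (side == "down" && ov$start[j] >= fs) fe <- min(fe, ov$start[j])
        }
      }
      if (fe <= fs) {
        inform(paste0("flank ", side, " of ", nm[i],
                      " fully consumed by clipping; omitted"))
        next
      }
      s <- Biostrings::subseq(sequences[[ctg]], fs + 1, fe)
      if (strand[i] == "-") s <- Biostrings::reverseComplement(s)
      seqs <- c(seqs, as.character(s))
      ids <- c(ids, sprintf("%s|%s:%.0f-%.0f(%s)|%s", nm[i], ctg, fs, fe,
                            strand[i], side))
    }
  }
  res <- Biostrings::DNAStringSet(seqs)
  names(res) <- ids
  res
}

#' G+A fraction of a sequence
#'
#' `(G + A) / (length - N)`; `N` bases are excluded from the denominator.
#' An all-N sequence returns 0 with a warning. The complementary strand
#' satisfies `ga_fraction(revcomp(s)) = 1 - ga_fraction(s)` for N-free `s`.
#'
#' @param x A character vector, [Biostrings::DNAString] or
#'   [Biostrings::DNAStringSet] over the alphabet `{A, C, G, T, N}`.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' ga_fraction("GAGA") # 1
#' ga_fraction("GACN") # 2/3
#' @export
ga_fraction <- function(x) {
  if (is.character(x)) {
    if (any(grepl("[^ACGTN]", x))) {
      abort("ga_fraction: sequence contains characters outside {A, C, G, T, N}")
    }
    x <- Biostrings::DNAStringSet(x)
  }
  if (inherits(x, "DNAString")) x <- Biostrings::DNAStringSet(list(x))
  freq <- Biostrings::letterFrequency(x, c("A", "C", "G", "T", "N"))
  if (any(rowSums(freq) != Biostrings::width(x))) {
    abort("ga_fraction: sequence contains characters outside {A, C, G, T, N}")
  }
  denom <- Biostrings::width(x) - freq[, "N"]
  if (any(denom == 0)) {
    warn("all-N sequence(s); ga_fraction set to 0")
  }
  out <- ifelse(denom == 0, 0, (freq[, "G"] + freq[, "A"]) / denom)
  unname(out)
}

#' Compare G+A composition of foreground vs background sequences
#'
#' A quantitative companion to differential motif discovery: reports the
#' mean per-sequence G+A fraction of each set, their difference, and a
#' two-sided label-shuffling permutation p-value.
#'
#' @param foreground,background Non-empty [Biostrings::DNAStringSet]s (or
#'   character vectors).
#' @param n_perm Number of label permutations.
#' @param seed RNG seed for the permutation.
#' @return A one-row tibble with `mean_ga_foreground`, `mean_ga_background`,
#'   `difference`, `p_value`, `n_foreground`, `n_background`, `n_perm`.
#' @export
ga_enrichment_report <- function(foreground, background, n_perm = 10000,
                                 seed = 1) {
  ga_fg <- ga_fraction(foreground)
  ga_bg <- ga_fraction(background)
  if (length(ga_fg) == 0 || length(ga_bg) == 0) {
    abort("ga_enrichment_report: empty sequence set")
  }
  obs <- mean(ga_fg) - mean(ga_bg)
  pooled <- c(ga_fg, ga_bg)
  n_fg <- length(ga_fg)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), n_fg)
      mean(pooled[idx]) - mean(pooled[-idx])
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  tibble(
    mean_ga_foreground = mean(ga_fg),
    mean_ga_background = mean(ga_bg),
    difference = obs,
    p_value = p,
    n_foreground = n_fg,
    n_background = length(ga_bg),
    n_perm = n_perm
  )
}
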