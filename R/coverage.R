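#' Dense per-base coverage track
#'
#' A lightweight container for one contig/strand worth of per-base values:
#' raw read counts, smoothed coverage, or fold enrichment.
#'
#' @param contig Contig name.
#' @param strand Strand (`"+"`, `"-"` or `"*"`).
#' @param values Numeric vector, one entry per base, all finite and >= 0.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(contig, strand, values) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("coverage track values must be finite and >= 0")
  }
  if (!strand %in% VALID_STRANDS) abort("strand must be one of +, -, *")
  structure(
    list(contig = contig, strand = strand, values = values),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", x$contig, " (", x$strand, "), ",
      length(x$values), " bp, total ", sum(x$values), "\n", sep = "")
  invisible(x)
}

#' @export
length.coverage_track <- function(x) length(x$values)

#' @rdname coverage_track
#' @param x A `coverage_track`.
#' @param ... Unused.
#' @method as_tibble coverage_track
#' @export
as_tibble.coverage_track <- function(x, ...) {
  tibble(contig = x$contig, strand = x$strand,
         pos = seq_along(x$values) - 1, value = x$values)
}

#' Per-base read counts for one contig and strand
#'
#' `values[i]` is the number of reads whose interval covers position `i`
#' (0-based). In stranded mode only reads on the matching strand count.
#' Reads extending past the contig end are clipped with a warning.
#'
#' @param reads Read tibble (`chrom`, `start`, `end`, `strand`).
#' @param contig Contig name.
#' @param strand `"+"`, `"-"`, or `"*"` to pool both strands.
#' @param length Contig length in bases.
#' @return A [coverage_track()] of raw counts.
#' @export
per_base_counts <- function(reads, contig, strand, length) {
  validate_intervals(reads, "reads")
  sel <- reads$chrom == contig
  if (strand != "*") sel <- sel & reads$strand == strand
  r <- reads[sel, ]
  if (nrow(r) > 0 && any(r$end > length)) {
    warn(paste0(sum(r$end > length), " read(s) extend past the end of ",
                contig, "; clipped"))
    r$end <- pmin(r$end, length)
    r <- r[r$start < r$end, ]
  }
  if (nrow(r) == 0) return(coverage_track(contig, strand, numeric(length)))
  cov <- IRanges::coverage(as_iranges0(r), width = length)
  coverage_track(contig, strand, as.numeric(cov))
}

# Truncated-window running sums via cumulative sums: sum of values over
# [i - w, i + w] clipped to the track. Returns list(sum, width).
window_stats <- function(values, w_half) {
  L <- length(values)
  idx <- seq_len(L)
  lo <- pmax(idx - w_half, 1L)
  hi <- pmin(idx + w_half, L)
  cs <- c(0, cumsum(values))
  list(sum = cs[hi + 1] - cs[lo], width = hi - lo + 1)
}

#' Smooth a coverage track with a centered window mean
#'
#' `out[i]` is the mean of the raw values over positions `i - w_half` to
#' `i + w_half`, truncated at contig edges (the divisor is the actual window
#' size). `w_half = 0` is the identity. The default half-window of 150 bases
#' gives the +/-150 bp averaged read coverage the peak caller tests.
#'
#' @param track A [coverage_track()] of raw counts.
#' @param w_half Half-window in bases (>= 0).
#' @return A [coverage_track()] of smoothed coverage.
#' @export
smooth_coverage <- function(track, w_half = 150) {
  stopifnot(inherits(track, "coverage_track"), w_half >= 0)
  ws <- window_stats(track$values, as.integer(w_half))
  coverage_track(track$contig, track$strand, ws$sum / ws$width)
}

#' Windowed sums of a raw count track
#'
#' Same truncated window as [smooth_coverage()] but summed, not averaged:
#' the integer-scale event counts fed to the Poisson enrichment test.
#'
#' @inheritParams smooth_coverage
#' @return A [coverage_track()] of window sums.
#' @export
window_sum <- function(track, w_half = 150) {
  stopifnot(inherits(track, "coverage_track"), w_half >= 0)
  ws <- window_stats(track$values, as.integer(w_half))
  coverage_track(track$contig, track$strand, ws$sum)
}

#' Fold-enrichment track of RIP over control
#'
#' `fold[i] = rip[i] / max(ctrl[i], lambda_min_per_base)`. The per-base floor
#' (default `lambda_min / (2 * w_half + 1)`) prevents division by an empty
#' control while keeping the fold of truly empty RIP regions at 0.
#'
#' @param rip_smoothed,ctrl_smoothed Smoothed [coverage_track()]s for the same
#'   contig/strand/length.
#' @param lambda_min_per_base Floor applied to the smoothed control.
#' @return A [coverage_track()] of fold enrichment.
#' @export
fold_track <- function(rip_smoothed, ctrl_smoothed, lambda_min_per_base) {
  stopifnot(inherits(rip_smoothed, "coverage_track"),
            inherits(ctrl_smoothed, "coverage_track"))
  if (length(rip_smoothed$values) != length(ctrl_smoothed$values)) {
    abort("fold_track: track length mismatch")
  }
  if (rip_smoothed$contig != ctrl_smoothed$contig ||
      rip_smoothed$strand != ctrl_smoothed$strand) {
    abort("fold_track: contig/strand mismatch")
  }
  if (lambda_min_per_base <= 0) abort("lambda_min_per_base must be > 0")
  fold <- rip_smoothed$values / pmax(ctrl_smoothed$values, lambda_min_per_base)
  coverage_track(rip_smoothed$contig, rip_smoothed$strand, fold)
}
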