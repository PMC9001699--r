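# Internal helpers shared across modules.

# Round half away from zero (half-up for the non-negative values used here).
# round() rounds half to even, which is not reproducible across a change of
# convention; peak calling needs a fixed deterministic rule for integerising
# window sums.
round_half_up <- function(x) floor(x + 0.5)

# Derive a stage-specific RNG seed from one top-level seed so that stages can
# be re-run in isolation yet the whole pipeline flows from a single integer.
derive_seed <- function(seed, stage) {
  offsets <- c(
    reference = 101L, annotation = 211L, regions = 223L, reads = 307L,
    fractions = 401L, downsample = 503L, permutation = 601L
  )
  if (!stage %in% names(offsets)) {
    abort(paste0("unknown stage '", stage, "'"))
  }
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

VALID_STRANDS <- c("+", "-", "*")

# Validate a reads/intervals tibble: chrom/start/end (+ optional strand).
validate_intervals <- function(x, what = "interval table") {
  if (!is.data.frame(x)) abort(paste0(what, " must be a data frame"))
  needed <- c("chrom", "start", "end")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(what, " lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
    abort(paste0(what, ": non-finite coordinates"))
  }
  if (any(x$start < 0)) abort(paste0(what, ": negative start coordinate"))
  if (any(x$start >= x$end)) {
    bad <- which(x$start >= x$end)[1]
    abort(paste0(what, ": empty or inverted interval at row ", bad,
                 " (start >= end); coordinates are 0-based half-open"))
  }
  if ("strand" %in% names(x) && !all(x$strand %in% VALID_STRANDS)) {
    abort(paste0(what, ": strand must be one of +, -, *"))
  }
  invisible(x)
}

# IRanges view of a 0-based half-open interval tibble (1-based closed inside
# IRanges).
as_iranges0 <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

# GRanges view; strand "*" kept as-is.
as_granges0 <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# Infer contig lengths (named vector) as the max end seen per contig across
# a list of interval tibbles, unless explicit lengths are supplied.
infer_contig_lengths <- function(tbls, contig_lengths = NULL) {
  if (!is.null(contig_lengths)) {
    if (is.null(names(contig_lengths))) abort("contig_lengths must be named")
    return(contig_lengths)
  }
  all <- bind_rows(lapply(tbls, function(t) t[, c("chrom", "end")]))
  if (nrow(all) == 0) abort("cannot infer contig lengths from empty inputs")
  out <- tapply(all$end, all$chrom, max)
  setNames(as.numeric(out), names(out))
}
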