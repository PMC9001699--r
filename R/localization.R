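#' Reads-per-million normalization
#'
#' @param count Read count(s).
#' @param total_mapped Total mapped reads of the library (> 0).
#' @return `count * 1e6 / total_mapped`.
#' @examples
#' rpm(50, 1e6) # 50
#' @export
rpm <- function(count, total_mapped) {
  if (any(total_mapped <= 0)) abort("rpm: total_mapped must be > 0")
  count * 1e6 / total_mapped
}

#' RPM-quantify fragments across the four RNA fractions
#'
#' Counts reads overlapping each fragment by at least 1 bp in each fraction
#' and converts the counts to RPM with each fraction's total mapped reads.
#'
#' @param fragments Interval tibble with a `fragment_id` column (peak names
#'   are used when `fragment_id` is absent but `name` is present).
#' @param fraction_reads Named list of read tibbles for fractions `nuclear`,
#'   `cytoplasmic`, `nuc_polya_plus`, `nuc_polya_minus`.
#' @param totals Named numeric vector of total mapped reads per fraction.
#' @param strand_aware If `TRUE`, count only reads on the fragment's strand.
#' @return A tibble with `fragment_id` and columns `rpm_nuclear`,
#'   `rpm_cytoplasmic`, `rpm_nuc_polya_plus`, `rpm_nuc_polya_minus`.
#' @export
quantify_fragments <- function(fragments, fraction_reads, totals,
                               strand_aware = TRUE) {
  validate_intervals(fragments, "fragments")
  fractions <- c("nuclear", "cytoplasmic", "nuc_polya_plus", "nuc_polya_minus")
  if (!all(fractions %in% names(fraction_reads))) {
    abort(paste0("fraction_reads must name: ", paste(fractions, collapse = ", ")))
  }
  if (!all(fractions %in% names(totals))) {
    abort(paste0("totals must name: ", paste(fractions, collapse = ", ")))
  }
  id <- fragments[["fragment_id"]] %||% fragments[["name"]] %||%
    sprintf("frag%04d", seq_len(nrow(fragments)))
  frag_gr <- as_granges0(fragments)
  out <- tibble(fragment_id = id)
  for (f in fractions) {
    reads <- fraction_reads[[f]]
    validate_intervals(reads, paste0(f, " reads"))
    cnt <- if (nrow(reads) == 0) {
      rep(0, nrow(fragments))
    } else {
      GenomicRanges::countOverlaps(
        frag_gr, as_granges0(reads), minoverlap = 1L,
        ignore.strand = !strand_aware
      )
    }
    out[[paste0("rpm_", f)]] <- rpm(cnt, totals[[f]])
  }
  out
}

#' Convert a fraction count table to RPM values
#'
#' @param counts Count tibble (`fragment_id` plus the four fraction columns),
#'   e.g. from [read_fraction_counts()].
#' @param totals Tibble with `fraction`, `total`, or a named numeric vector.
#' @return RPM tibble as from [quantify_fragments()].
#' @export
fraction_rpm <- function(counts, totals) {
  if (is.data.frame(totals)) totals <- setNames(totals$total, totals$fraction)
  out <- tibble(fragment_id = counts$fragment_id)
  for (f in c("nuclear", "cytoplasmic", "nuc_polya_plus", "nuc_polya_minus")) {
    out[[paste0("rpm_", f)]] <- rpm(counts[[f]], totals[[f]])
  }
  out
}

#' Classify fragment localization from fractionated RPM values
#'
#' A fragment is called `nuclear` iff its nuclear RPM strictly exceeds its
#' cytoplasmic RPM (ties go to `cytoplasmic`). Nuclear fragments are further
#' called `minus` (non-polyadenylated) iff nuclear polyA- RPM strictly
#' exceeds nuclear polyA+ RPM (ties go to `plus`); cytoplasmic fragments get
#' polyA `"not_assessed"`. Because RPM cancels sequencing depth, the calls
#' are invariant to each fraction's depth.
#'
#' @param quant RPM tibble (see [quantify_fragments()] / [fraction_rpm()]).
#' @return Tibble with `fragment_id`, `compartment`, `polya`.
#' @export
classify_localization <- function(quant) {
  needed <- c("rpm_nuclear", "rpm_cytoplasmic", "rpm_nuc_polya_plus",
              "rpm_nuc_polya_minus")
  if (!all(needed %in% names(quant))) {
    abort(paste0("quant must have columns: ", paste(needed, collapse = ", ")))
  }
  if (any(unlist(quant[needed]) < 0) || any(!is.finite(unlist(quant[needed])))) {
    abort("RPM values must be finite and >= 0")
  }
  mutate(
    tibble(fragment_id = quant$fragment_id),
    compartment = if_else(quant$rpm_nuclear > quant$rpm_cytoplasmic,
                          "nuclear", "cytoplasmic"),
    polya = case_when(
      .data$compartment == "cytoplasmic" ~ "not_assessed",
      quant$rpm_nuc_polya_minus > quant$rpm_nuc_polya_plus ~ "minus",
      TRUE ~ "plus"
    )
  )
}

#' Summarise localization calls
#'
#' @param calls Tibble from [classify_localization()].
#' @return One-row tibble with `fraction_nuclear` (proportion of fragments
#'   called nuclear), `fraction_polya_minus_among_nuclear`, and `n`.
#' @export
localization_summary <- function(calls) {
  if (nrow(calls) == 0) abort("localization_summary: no calls")
  n_nuc <- sum(calls$compartment == "nuclear")
  tibble(
    fraction_nuclear = n_nuc / nrow(calls),
    fraction_polya_minus_among_nuclear =
      if (n_nuc > 0) sum(calls$polya == "minus") / n_nuc else NA_real_,
    n = nrow(calls)
  )
}

#' Nuclear-vs-cytoplasmic RPM scatter
#'
#' The classic fractionation diagnostic: each fragment's nuclear RPM against
#' its cytoplasmic RPM with the identity diagonal; points below the diagonal
#' (nuclear > cytoplasmic) indicate nuclear retention.
#'
#' @param quant RPM tibble.
#' @param log If `TRUE` (default) use log10 axes (zeros offset by the
#'   smallest positive value).
#' @return A ggplot object.
#' @export
plot_localization <- function(quant, log = TRUE) {
  calls <- classify_localization(quant)
  df <- left_join(quant, calls, by = "fragment_id")
  p <- ggplot(df, aes(x = .data$rpm_nuclear, y = .data$rpm_cytoplasmic,
                      colour = .data$compartment)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "nuclear RPM", y = "cytoplasmic RPM",
         title = "Fragment localization by fractionated RNA-seq") +
    theme_bw()
  if (log) {
    eps <- min(c(df$rpm_nuclear[df$rpm_nuclear > 0],
                 df$rpm_cytoplasmic[df$rpm_cytoplasmic > 0], 1))
    p <- ggplot(df, aes(x = .data$rpm_nuclear + eps,
                        y = .data$rpm_cytoplasmic + eps,
                        colour = .data$compartment)) +
      geom_point(alpha = 0.5, size = 0.8) +
      geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      scale_x_log10() + scale_y_log10() +
      labs(x = "nuclear RPM", y = "cytoplasmic RPM",
           title = "Fragment localization by fractionated RNA-seq") +
      theme_bw()
  }
  p
}
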