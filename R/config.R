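#' Peak-calling configuration
#'
#' Collects every tunable parameter of the comparative RIP-vs-IgG peak
#' caller. Two presets mirror the two published threshold sets: the
#' `"stringent"` preset used for the reproducible-peak catalogue (fold >= 2,
#' Poisson p <= 1e-5) and the `"replicate_track"` preset used for
#' per-replicate browser tracks (fold >= 1.7, p <= 1e-3; extension threshold
#' follows the seed fold).
#'
#' @param preset `"stringent"` (default) or `"replicate_track"`. Explicit
#'   arguments override preset values.
#' @param w_half Smoothing half-window in bases (coverage is averaged over
#'   +/- `w_half`).
#' @param f_seed Minimum fold enrichment at seed sites.
#' @param p_max Maximum Poisson p-value at seed sites.
#' @param f_ext Fold threshold during peak extension.
#' @param d_merge Maximum gap in bases for cross-replicate merging.
#' @param lambda_min Floor on the Poisson mean (window-sum scale).
#' @param strand_mode `"stranded"` (process + and - independently) or
#'   `"ignore"` (pool strands).
#' @param seed RNG seed for library downsampling.
#' @return A list of class `peakcall_config`.
#' @export
peakcall_config <- function(preset = c("stringent", "replicate_track"),
                            w_half = 150, f_seed = NULL, p_max = NULL,
                            f_ext = NULL, d_merge = 1000, lambda_min = 1,
                            strand_mode = c("stranded", "ignore"), seed = 17) {
  preset <- match.arg(preset)
  strand_mode <- match.arg(strand_mode)
  defaults <- switch(preset,
    stringent = list(f_seed = 2.0, p_max = 1e-5, f_ext = 2.0),
    replicate_track = list(f_seed = 1.7, p_max = 1e-3, f_ext = 1.7)
  )
  cfg <- list(
    preset = preset,
    w_half = as.integer(w_half),
    f_seed = f_seed %||% defaults$f_seed,
    p_max = p_max %||% defaults$p_max,
    f_ext = f_ext %||% defaults$f_ext,
    d_merge = d_merge,
    lambda_min = lambda_min,
    strand_mode = strand_mode,
    seed = as.integer(seed)
  )
  if (cfg$w_half < 0) abort("w_half must be >= 0")
  if (!(cfg$f_seed >= cfg$f_ext && cfg$f_ext >= 1)) {
    abort("need f_seed >= f_ext >= 1")
  }
  if (!(cfg$p_max > 0 && cfg$p_max < 1)) abort("p_max must be in (0, 1)")
  if (cfg$d_merge < 0) abort("d_merge must be >= 0")
  if (cfg$lambda_min <= 0) abort("lambda_min must be > 0")
  structure(cfg, class = "peakcall_config")
}

#' @export
print.peakcall_config <- function(x, ...) {
  cat("<peakcall_config> preset:", x$preset,
      "| w_half:", x$w_half,
      "| f_seed:", x$f_seed,
      "| p_max:", format(x$p_max),
      "| f_ext:", x$f_ext,
      "| d_merge:", x$d_merge,
      "| lambda_min:", x$lambda_min,
      "| strand_mode:", x$strand_mode,
      "| seed:", x$seed, "\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults describe the study
#' conditions the pipeline is validated under: a 100 kb contig, 10 planted
#' enriched regions at 5-fold RIP enrichment over a homogeneous Poisson
#' background, two RIP replicates with unequal library sizes (forcing
#' library matching), a toy annotation with coding (UTR/CDS/intron) and
#' non-coding genes plus intergenic space, and a fragment fractionation table
#' with 89% truly nuclear fragments of which 75% are polyA-.
#'
#' @param contig Contig name.
#' @param contig_length Contig length in bases.
#' @param n_regions Number of planted enriched regions.
#' @param region_length_range Planted-region length range in bases (uniform;
#'   clipped to the hosting intron/intergenic slot).
#' @param enrichment_fold Multiplicative RIP read-start rate increase inside
#'   planted regions (phi).
#' @param background_rate Baseline read-start intensity per base; the shape
#'   of the intensity only, since per-sample totals are rescaled to
#'   `library_sizes`.
#' @param read_length Read length in bases.
#' @param library_sizes Named read counts for samples `rip1`, `rip2`, `igg1`,
#'   `igg2`.
#' @param n_genes Number of toy genes (half coding, half non-coding).
#' @param frac_table List with `n_fragments`, `true_nuclear_fraction`,
#'   `true_polya_minus_fraction`, `noise_sigma` (log-normal sigma) and
#'   `fraction_totals` (total mapped reads per fraction, for RPM).
#' @param ga_bias If `TRUE`, raise the G+A frequency to 0.7 inside planted
#'   regions of the simulated reference (for motif-prep tests).
#' @param seed Top-level RNG seed; per-stage seeds are derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(contig = "chrS",
                       contig_length = 100000,
                       n_regions = 10,
                       region_length_range = c(300, 2000),
                       enrichment_fold = 5,
                       background_rate = 0.005,
                       read_length = 75,
                       library_sizes = c(rip1 = 40000, rip2 = 32000,
                                         igg1 = 35000, igg2 = 35000),
                       n_genes = 12,
                       frac_table = list(n_fragments = 1000,
                                         true_nuclear_fraction = 0.89,
                                         true_polya_minus_fraction = 0.75,
                                         noise_sigma = 0.5,
                                         fraction_totals = 1e6),
                       ga_bias = FALSE,
                       seed = 7) {
  if (enrichment_fold < 1) abort("enrichment_fold must be >= 1")
  if (background_rate <= 0) abort("background_rate must be > 0")
  if (!all(c("rip1", "rip2", "igg1", "igg2") %in% names(library_sizes))) {
    abort("library_sizes must name rip1, rip2, igg1, igg2")
  }
  ft_defaults <- list(n_fragments = 1000, true_nuclear_fraction = 0.89,
                      true_polya_minus_fraction = 0.75, noise_sigma = 0.5,
                      fraction_totals = 1e6)
  frac_table <- utils::modifyList(ft_defaults, frac_table)
  if (frac_table$true_nuclear_fraction < 0 || frac_table$true_nuclear_fraction > 1 ||
      frac_table$true_polya_minus_fraction < 0 || frac_table$true_polya_minus_fraction > 1) {
    abort("fractions must be in [0, 1]")
  }
  structure(list(
    contig = contig, contig_length = contig_length, n_regions = n_regions,
    region_length_range = region_length_range,
    enrichment_fold = enrichment_fold, background_rate = background_rate,
    read_length = read_length, library_sizes = library_sizes,
    n_genes = n_genes, frac_table = frac_table, ga_bias = ga_bias,
    seed = as.integer(seed)
  ), class = "sim_config")
}
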