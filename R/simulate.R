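# Synthetic-data generator: fully seeded inputs with the statistical
# structure the peak caller assumes (homogeneous Poisson background with
# multiplicative enrichment in planted regions), plus ground truth.

#' Simulate a toy gene annotation
#'
#' Lays out `n_genes` genes (alternating coding/non-coding, alternating
#' strand) evenly along the contig with intergenic gaps between and around
#' them (>= 20% of the contig stays intergenic). Coding genes have a
#' 3-exon structure with 5'UTR/CDS/3'UTR and two long introns; non-coding
#' genes have two exons around one long intron. The layout is deterministic
#' given the configuration.
#'
#' @param config A [sim_config()].
#' @return Gene tibble in the [read_gtf()] format.
#' @export
simulate_annotation <- function(config) {
  n <- config$n_genes
  L <- config$contig_length
  gene_len <- floor(L * 0.66 / n)
  gap <- floor((L - n * gene_len) / (n + 1))
  if (gene_len < 1000 || gap < 300) {
    abort("annotation packing infeasible; reduce n_genes or enlarge the contig")
  }
  r <- function(f) round(gene_len * f)
  # relative sub-feature layout on the + strand
  exons_rel <- tibble(start = c(0, r(0.44), r(0.85)),
                      end = c(r(0.08), r(0.49), gene_len))
  utr5_rel <- tibble(start = 0, end = r(0.05))
  cds_rel <- tibble(start = c(r(0.05), r(0.44), r(0.85)),
                    end = c(r(0.08), r(0.49), r(0.90)))
  utr3_rel <- tibble(start = r(0.90), end = gene_len)
  exons_nc_rel <- tibble(start = c(0, r(0.85)), end = c(r(0.08), gene_len))
  reflect <- function(tbl) {
    out <- tibble(start = gene_len - tbl$end, end = gene_len - tbl$start)
    arrange(out, .data$start)
  }
  purrr::map_dfr(seq_len(n), function(i) {
    g_start <- gap * i + gene_len * (i - 1)
    strand <- if (i %% 2 == 1) "+" else "-"
    coding <- i <= ceiling(n / 2)
    shift <- function(tbl) {
      if (strand == "-") tbl <- reflect(tbl)
      tibble(start = tbl$start + g_start, end = tbl$end + g_start)
    }
    if (coding) {
      tibble(
        gene_id = sprintf("gene%02d", i), biotype = "coding",
        chrom = config$contig, start = g_start, end = g_start + gene_len,
        strand = strand,
        exons = list(shift(exons_rel)), cds = list(shift(cds_rel)),
        utr5 = list(shift(utr5_rel)), utr3 = list(shift(utr3_rel))
      )
    } else {
      emptyf <- tibble(start = numeric(), end = numeric())
      tibble(
        gene_id = sprintf("gene%02d", i), biotype = "noncoding",
        chrom = config$contig, start = g_start, end = g_start + gene_len,
        strand = strand,
        exons = list(shift(exons_nc_rel)), cds = list(emptyf),
        utr5 = list(emptyf), utr3 = list(emptyf)
      )
    }
  })
}

# Candidate slots for planted regions: introns and intergenic gaps.
region_slots <- function(config, genes) {
  L <- config$contig_length
  slots <- list()
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    gaps_ir <- IRanges::setdiff(
      IRanges::IRanges(genes$start[i] + 1, genes$end[i]),
      IRanges::IRanges(ex$start + 1, ex$end)
    )
    if (length(gaps_ir) > 0) {
      slots[[length(slots) + 1]] <- tibble(
        start = IRanges::start(gaps_ir) - 1, end = as.numeric(IRanges::end(gaps_ir)),
        type = "intron", strand = genes$strand[i]
      )
    }
  }
  inter_ir <- IRanges::setdiff(
    IRanges::IRanges(1, L),
    IRanges::IRanges(genes$start + 1, genes$end)
  )
  slots[[length(slots) + 1]] <- tibble(
    start = IRanges::start(inter_ir) - 1, end = as.numeric(IRanges::end(inter_ir)),
    type = "intergenic", strand = "*"
  )
  out <- bind_rows(slots)
  # leave a margin inside each slot so regions stay clear of slot edges
  out <- mutate(out, start = .data$start + 100, end = .data$end - 100)
  filter(out, .data$end - .data$start >= config$region_length_range[1])
}

#' Place planted enriched regions
#'
#' Draws `n_regions` non-overlapping regions, alternating between intronic
#' and intergenic slots so both placements occur (mirroring preferential
#' intronic binding), with lengths uniform in `region_length_range` (clipped
#' to the hosting slot) and pairwise spacing of at least 2500 bp so that
#' distinct regions are never bridged by the 1000 bp reproducible-peak merge.
#' Each region is transcribed from a defined strand: the host gene's strand
#' for intronic regions (nascent intronic RNA), a random strand for
#' intergenic ones.
#'
#' @param config A [sim_config()].
#' @param genes Gene tibble from [simulate_annotation()].
#' @return Region tibble: `chrom`, `start`, `end`, `strand`, `slot_type`.
#' @export
simulate_regions <- function(config, genes) {
  slots <- region_slots(config, genes)
  min_spacing <- 2500
  withr::with_seed(derive_seed(config$seed, "regions"), {
    placed <- tibble(chrom = character(), start = numeric(), end = numeric(),
                     strand = character(), slot_type = character())
    used <- rep(FALSE, nrow(slots))
    for (j in seq_len(config$n_regions)) {
      want <- if (j %% 2 == 1) "intron" else "intergenic"
      order_try <- sample(nrow(slots))
      order_try <- order_try[order(slots$type[order_try] != want)]
      ok <- FALSE
      for (s in order_try) {
        if (used[s]) next
        cap <- slots$end[s] - slots$start[s]
        if (cap < config$region_length_range[1]) next
        len <- round(stats::runif(
          1, config$region_length_range[1],
          min(config$region_length_range[2], cap)
        ))
        rs <- round(stats::runif(1, slots$start[s], slots$end[s] - len))
        re <- rs + len
        if (nrow(placed) > 0 &&
            any(pmax(placed$start - re, rs - placed$end) < min_spacing)) next
        strand <- slots$strand[s]
        if (strand == "*") strand <- sample(c("+", "-"), 1)
        placed <- bind_rows(placed, tibble(
          chrom = config$contig, start = rs, end = re, strand = strand,
          slot_type = slots$type[s]
        ))
        used[s] <- TRUE
        ok <- TRUE
        break
      }
      if (!ok) {
        abort("could not place all planted regions; reduce n_regions or spacing")
      }
    }
    arrange(placed, .data$start)
  })
}

#' Simulate a reference sequence
#'
#' I.i.d. uniform A/C/G/T of the configured contig length. With
#' `ga_bias = TRUE` in the configuration, positions inside planted regions
#' are drawn with G+A frequency 0.7 on the region's transcribed strand
#' instead, so motif-prep foreground sequences (extracted in RNA sense) are
#' compositionally distinct from their flanks.
#'
#' @param config A [sim_config()].
#' @param regions Planted-region tibble (required when `ga_bias` is set).
#' @return A named [Biostrings::DNAStringSet] of length 1.
#' @export
simulate_reference <- function(config, regions = NULL) {
  withr::with_seed(derive_seed(config$seed, "reference"), {
    bases <- sample(c("A", "C", "G", "T"), config$contig_length, replace = TRUE)
    if (config$ga_bias) {
      if (is.null(regions)) abort("ga_bias needs the planted regions")
      for (i in seq_len(nrow(regions))) {
        idx <- (regions$start[i] + 1):regions$end[i]
        # G/A-rich in the sense of the transcribed strand: on the genomic +
        # strand that is G/A for +-strand regions and C/T for --strand ones
        prob <- if (regions$strand[i] == "-") {
          c(0.15, 0.35, 0.15, 0.35)
        } else {
          c(0.35, 0.15, 0.35, 0.15)
        }
        bases[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE,
                             prob = prob)
      }
    }
    seqs <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(seqs) <- config$contig
    seqs
  })
}

#' Simulate RIP and IgG read sets
#'
#' Read starts follow an inhomogeneous Poisson process: a flat background
#' intensity scaled so the expected background total equals the sample's
#' configured library size (`background_rate` sets only the relative shape;
#' the realised per-base background start rate is `library_size /
#' contig_length`), plus, for the two RIP samples only, extra region-derived
#' starts at `enrichment_fold - 1` times the background rate inside each
#' planted region. Totals are Poisson. Background reads get uniform random
#' strands; region-derived reads carry the region's transcribed strand, as a
#' stranded RIP library of nascent RNA would.
#'
#' @param config A [sim_config()].
#' @param regions Planted-region tibble from [simulate_regions()].
#' @return Named list of read tibbles (`rip1`, `rip2`, `igg1`, `igg2`).
#' @export
simulate_reads <- function(config, regions) {
  L <- config$contig_length
  rl <- config$read_length
  n_start <- L - rl + 1
  region_len <- pmin(regions$end, n_start) - regions$start
  samples <- c("rip1", "rip2", "igg1", "igg2")
  out <- list()
  for (s_i in seq_along(samples)) {
    s <- samples[s_i]
    lib <- config$library_sizes[[s]]
    is_rip <- startsWith(s, "rip")
    out[[s]] <- withr::with_seed(derive_seed(config$seed, "reads") + s_i, {
      n_bg <- rpois(1, lib)
      starts0 <- sample.int(n_start, n_bg, replace = TRUE) - 1
      strand <- sample(c("+", "-"), n_bg, replace = TRUE)
      if (is_rip && nrow(regions) > 0) {
        rate_ex <- lib / n_start * (config$enrichment_fold - 1)
        for (i in seq_len(nrow(regions))) {
          n_ex <- rpois(1, rate_ex * region_len[i])
          # region-derived fragments are contained in the region (the bound
          # RNA is the region's transcript), so starts stop rl short of it
          n_pos <- max(region_len[i] - rl + 1, 1)
          ex0 <- regions$start[i] + sample.int(n_pos, n_ex, replace = TRUE) - 1
          starts0 <- c(starts0, ex0)
          strand <- c(strand, rep(regions$strand[i], n_ex))
        }
      }
      ord <- order(starts0)
      starts0 <- starts0[ord]
      strand <- strand[ord]
      n <- length(starts0)
      tibble(
        chrom = config$contig, start = starts0, end = starts0 + rl,
        name = sprintf("%s_%06d", s, seq_len(n)), score = 0,
        strand = strand, sample = s
      )
    })
  }
  out
}

#' Simulate a fragment fractionation count table
#'
#' Each fragment gets a true compartment label (Bernoulli with the
#' configured nuclear fraction) and, if nuclear, a polyA- label. Expected
#' counts follow a 4:1 RPM ratio in favour of the true compartment (and the
#' true polyA state within nuclear fragments), on a log-normal per-fragment
#' abundance, with multiplicative log-normal noise of the configured sigma
#' per fraction; observed counts are Poisson around those expectations.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (integer count tibble), `totals` (per-fraction
#'   total mapped reads), and `truth` (true labels per fragment).
#' @export
simulate_fraction_table <- function(config) {
  ft <- config$frac_table
  n <- ft$n_fragments
  withr::with_seed(derive_seed(config$seed, "fractions"), {
    is_nuc <- stats::rbinom(n, 1, ft$true_nuclear_fraction) == 1
    is_minus <- is_nuc & (stats::rbinom(n, 1, ft$true_polya_minus_fraction) == 1)
    base <- rlnorm(n, log(100), 0.5)
    noisy <- function(mult) {
      rpois(n, base * mult * exp(rnorm(n, 0, ft$noise_sigma)))
    }
    counts <- tibble(
      fragment_id = sprintf("frag%04d", seq_len(n)),
      nuclear = noisy(if_else(is_nuc, 4, 1)),
      cytoplasmic = noisy(if_else(is_nuc, 1, 4)),
      nuc_polya_plus = noisy(case_when(!is_nuc ~ 1, is_minus ~ 1, TRUE ~ 4)),
      nuc_polya_minus = noisy(case_when(!is_nuc ~ 1, is_minus ~ 4, TRUE ~ 1))
    )
    truth <- tibble(
      fragment_id = counts$fragment_id,
      compartment = if_else(is_nuc, "nuclear", "cytoplasmic"),
      polya = case_when(!is_nuc ~ "not_assessed", is_minus ~ "minus",
                        TRUE ~ "plus")
    )
    totals <- tibble(
      fraction = c("nuclear", "cytoplasmic", "nuc_polya_plus", "nuc_polya_minus"),
      total = ft$fraction_totals
    )
    list(counts = counts, totals = totals, truth = truth)
  })
}

#' Generate a complete synthetic data set
#'
#' Runs every generator stage from one seeded configuration: annotation,
#' planted regions, reference sequence, the four read sets, and the
#' fractionation table with its ground truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `rip_simulation` with elements `config`, `genes`,
#'   `regions`, `reference`, `reads`, `fractions`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genes <- simulate_annotation(config)
  regions <- simulate_regions(config, genes)
  reference <- simulate_reference(config, regions)
  reads <- simulate_reads(config, regions)
  fractions <- simulate_fraction_table(config)
  structure(list(
    config = config, genes = genes, regions = regions,
    reference = reference, reads = reads, fractions = fractions
  ), class = "rip_simulation")
}

#' @export
print.rip_simulation <- function(x, ...) {
  cat("<rip_simulation> contig", x$config$contig,
      paste0("(", x$config$contig_length, " bp);"),
      nrow(x$genes), "genes;", nrow(x$regions), "planted regions;",
      "reads:", paste(vapply(x$reads, nrow, 1L), collapse = "/"), "\n")
  invisible(x)
}

#' Write a simulated data set to disk
#'
#' Writes `ref.fa`, `ann.gtf`, one BED per sample, `fractions.tsv`,
#' `fraction_totals.tsv` and `truth.json` into a directory.
#'
#' @param sim An `rip_simulation` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    ref = file.path(dir, "ref.fa"),
    gtf = file.path(dir, "ann.gtf"),
    fractions = file.path(dir, "fractions.tsv"),
    fraction_totals = file.path(dir, "fraction_totals.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_fasta(sim$reference, paths$ref)
  write_gtf(sim$genes, paths$gtf)
  for (s in names(sim$reads)) {
    paths[[s]] <- file.path(dir, paste0(s, ".bed"))
    write_bed(sim$reads[[s]], paths[[s]])
  }
  readr::write_tsv(sim$fractions$counts, paths$fractions)
  readr::write_tsv(sim$fractions$totals, paths$fraction_totals)
  jsonlite::write_json(
    list(regions = sim$regions, fraction_truth = sim$fractions$truth),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' Score recovery of planted regions by reproducible peaks
#'
#' A planted region counts as recovered when some reproducible peak (on any
#' strand) matches it with boundary error at most `tol` bases on each side.
#'
#' @param reproducible Reproducible-peak tibble (see [merge_reproducible()]).
#' @param regions Planted-region tibble.
#' @param tol Boundary tolerance in bases per side.
#' @return `regions` with a logical `recovered` column.
#' @export
assess_recovery <- function(reproducible, regions, tol = 150) {
  recovered <- vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    hit <- reproducible$chrom == r$chrom &
      abs(reproducible$start - r$start) <= tol &
      abs(reproducible$end - r$end) <= tol
    any(hit)
  }, logical(1))
  mutate(regions, recovered = recovered)
}
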