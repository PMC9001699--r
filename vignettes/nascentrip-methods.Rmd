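---
title: "Methods: comparative Poisson peak calling for RIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative Poisson peak calling for RIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

RNA immunoprecipitation sequencing (RIP-seq) asks which RNAs a protein binds
in vivo. For a promiscuous RNA-binding complex such as PRC2/EZH2 the
informative contrast is not "coverage vs nothing" but "RIP coverage vs a
mock (IgG) immunoprecipitation sequenced the same way": genuine binding
shows up as localized read-coverage enrichment of the RIP library over the
IgG control. `nascentrip` implements that comparative analysis as a tested,
reusable pipeline: a Poisson-based peak caller with cross-replicate
reconciliation, a gene-feature annotator for the called fragments, a
nuclear/cytoplasmic localization classifier for fractionated RNA-seq
quantifications, and preparation of foreground/background sequence sets for
external differential motif discovery.

# The peak-calling model

All coordinates are 0-based half-open throughout the package; GTF input is
converted once at the boundary (`read_gtf()`), and no other function
performs coordinate conversion.

**Library matching.** RIP and IgG libraries differ in depth, and a per-base
coverage comparison is only meaningful at matched depth. The "size" of a
library is its transcriptome read count — the number of reads overlapping
at least one annotated exon by ≥ 1 bp — and the larger library of each
RIP/IgG pair is downsampled until the two transcriptome counts are exactly
equal (`downsample_to_match()`). The transcriptome count, rather than total
reads, is used because total counts are inflated by library-specific
amounts of intergenic background. Downsampling is two-phase: an initial
uniform thinning at the target/current ratio, then a random add/remove
repair restricted to transcriptome-overlapping reads so the match is exact
and, under a fixed seed, bit-reproducible. Peak calling itself runs on all
matched reads genome-wide (not only the exonic subset), because the
fragments of interest are predominantly intronic; a user who wants
exon-restricted calling can pre-filter the BED inputs.

**Smoothed coverage and fold enrichment.** Per-base raw counts (reads
covering each position, strand-resolved by default) are smoothed with a
centered ±150 bp mean, truncated at contig edges with the divisor equal to
the actual window size. The fold track is

  fold[i] = rip_smooth[i] / max(ctrl_smooth[i], λ_min / (2·w + 1)),

with w = 150 and λ_min = 1 by default. Flooring the control (rather than
adding a pseudocount to both tracks) keeps the fold of truly empty RIP
regions at zero and mirrors the floor used in the Poisson test.

**Seeding.** Position i is a *seed* when two conditions hold jointly:
fold[i] ≥ f_seed, and P(X ≥ k_i) ≤ p_max for X ~ Poisson(λ_i), where
k_i is the RIP window sum over ±150 bp rounded half-up to an integer and
λ_i = max(ctrl window sum, λ_min). The window sums are the natural
integer-scale event counts consistent with the ±150 bp coverage
definition; the λ floor prevents degenerate tests over empty control
regions. The upper tail is computed by `stats::ppois(k − 1, λ, lower.tail
= FALSE)`; the test suite verifies it against an independent log-space
term-by-term pmf summation to 1e-12 relative error.

**Extension and peaks.** Maximal runs of seeds are extended base-by-base in
both directions while fold ≥ f_ext, with no gap tolerance — a single
sub-threshold base stops extension, which is the literal reading of
"extend until the fold drops below the threshold"; the ±150 bp smoothing
already bridges short dips. Because f_seed ≥ f_ext, the extended interval
is exactly the maximal fold ≥ f_ext run containing the seed run, so
overlapping extensions union automatically. Each peak records its summit
(leftmost argmax of fold — leftmost for determinism), maximum fold and
minimum per-position Poisson p.

**Two presets.** `peakcall_config("stringent")` (f_seed = 2, p ≤ 1e-5)
defines the reproducible-peak catalogue; `peakcall_config("replicate_track")`
(f_seed = 1.7, p ≤ 1e-3) reproduces the more permissive per-replicate
browser-track setting. The replicate-track preset also extends at 1.7: a
config with f_ext above f_seed would let the extension threshold exceed the
seed threshold, which the config class rejects as incoherent, and the
published per-replicate track gives no indication of a second fold cutoff.
Tightening any of f_seed, p_max, f_ext can only shrink the peak set
(set-containment), which the tests check.

**Reproducible peaks.** Peaks from the two replicates are linked when their
interval gap is ≤ 1000 bp (overlap counts as gap 0); gap semantics — rather
than summit distance or required overlap — is the most direct reading of
peaks lying "within 1000 bp" of one another, and the distance is
configurable (`d_merge`). Links are only cross-replicate; connected
components containing at least one peak from each replicate become
reproducible peaks spanning the union of their members, and everything else
is discarded. The operation is symmetric in its arguments and idempotent on
its own output.

# Annotation and localization

`annotate_peaks()` assigns each peak one gene category with precedence
coding gene > non-coding gene > intergenic (a deterministic single label
per peak, matching a pie-chart partition), then one feature by
overlap-base majority within the assigned gene — CDS > 5'UTR > 3'UTR >
intron on ties for coding genes, exon vs intron for non-coding ones.
Majority over the whole peak is the default because RIP fragments are long
and a single-position assignment is brittle; a summit-only mode exists.
Annotation ignores strand by default — the direction of the precipitated
fragment relative to annotation is not always trustworthy — with a
`strand_aware` switch.

`classify_localization()` implements the fractionation readout: a fragment
is *nuclear* iff its nuclear RPM strictly exceeds its cytoplasmic RPM (ties
fall to cytoplasmic — "higher in nuclear" read strictly), and nuclear
fragments are *polyA−* iff nuclear polyA− RPM strictly exceeds nuclear
polyA+ RPM. RPM (count × 10⁶ / total mapped reads) cancels sequencing
depth, so calls are invariant to per-fraction depth; no pseudocounts are
added, and 0/0 comparisons fall to the tie rules. The polyA call is made
only for nuclear fragments, mirroring the nuclear polyA−/polyA+ contrast.
When fragments are quantified from per-fraction read sets
(`quantify_fragments()`), overlap counting is ≥ 1 bp and strand-aware by
default; both are documented choices the data do not pin down.

# Motif preparation

`extract_foreground()` emits one record per reproducible peak,
reverse-complemented for minus-strand peaks so sequences read in RNA sense;
`extract_background()` emits an upstream and a downstream flank per peak —
by default of the peak's own length, the common differential-motif-input
convention; a fixed-length mode exists. Flanks are clipped at contig ends
and against *every* peak interval so the background never overlaps any
foreground sequence; without that clipping a flank could contain a
neighbouring peak and contaminate the background model. `ga_fraction()` and
`ga_enrichment_report()` quantify the G+A composition contrast between the
two sets with a seeded two-sided label-permutation test (10,000 shuffles,
add-one p-value), a quantitative companion to running MEME-style
differential discovery externally (the discovery step itself is out of
scope: the outputs are MEME-ready FASTA pairs).

# What the synthetic data emulate

`simulate_dataset()` generates every input the pipeline consumes, fully
determined by one seed (per-stage seeds are derived from it so stages can
be re-run in isolation):

* **Annotation** — 12 genes (half coding with 5'UTR/CDS/3'UTR and two long
  introns, half non-coding), alternating strands, with ≥ 20% of the 100 kb
  contig intergenic.
* **Planted regions** — 10 non-overlapping enriched regions, 300–2000 bp
  (clipped to the hosting slot), alternating between intronic and
  intergenic placements. Regions are spaced ≥ 2500 bp apart so two distinct
  planted signals can never be bridged into one reproducible peak by the
  1000 bp merge; without that floor a recovery test would conflate merge
  behaviour with detection. Each region has a transcribed strand (the host
  gene's for intronic regions), as nascent RNA does.
* **Reads** — background read starts are a homogeneous Poisson process at
  rate library_size / contig_length per base with uniform random strands;
  RIP samples additionally receive region-derived fragments at
  (φ − 1) × background rate inside each region (φ = 5 by default), carrying
  the region's strand and contained within the region, as size-selected
  fragments of the bound RNA would be. Library sizes (40k/32k/35k/35k)
  are deliberately unequal to force library matching. The homogeneous
  background matches the peak caller's test statistic — an intentionally
  favourable regime; real libraries have overdispersed, transcript-shaped
  backgrounds.
* **Fractionation table** — 1000 fragments with true nuclear fraction 0.89
  and true polyA− fraction 0.75 among nuclear; expected counts follow a
  4:1 ratio in favour of the true compartment on a log-normal abundance
  (median 100 counts), with multiplicative log-normal noise (σ = 0.5) and
  Poisson count noise, at 10⁶ mapped reads per fraction. The 4:1 ratio
  makes the diagonal classification nearly — not perfectly — separable at
  this σ, so recovered proportions land close to, and usually slightly
  below, the planted ones (misclassification is biased toward the majority
  class boundary).
* **Reference** — i.i.d. uniform A/C/G/T; with `ga_bias = TRUE` the G+A
  frequency inside planted regions rises to 0.7 *in the sense of the
  region's strand*, so foreground sequences are compositionally distinct
  from flanks the way a strand-specific binding motif would be.

What passing tests on these data do **not** show: robustness to
overdispersed backgrounds, splice-aware read placement, mappability
artefacts, transcript-level (rather than flattened gene-level) structure,
or PCR duplication — real-data behaviour on those axes is untested by
construction.

# Numerical and validation choices

* Window sums are integerised by round-half-up (`floor(x + 0.5)`), a fixed
  deterministic rule across platforms.
* All randomness flows through `withr::with_seed()`; generator, matching,
  and permutation results are bit-reproducible, and a full `run_all()` is
  byte-identical when repeated with one seed (the JSON manifest carries no
  timestamps).
* Validation problem sizes: one 100 kb contig; recovery is measured over
  20 generator seeds, the null control (φ = 1, expecting zero reproducible
  peaks) over 100 seeds, and a planted region counts as recovered when a
  reproducible peak matches it within 150 bp (= the smoothing half-window)
  per side. These sizes keep the whole suite fast while leaving the
  binomial/Poisson concentration arguments behind each threshold valid.
* Degenerate inputs: empty read sets produce zero tracks; an empty
  transcriptome makes library matching fail loudly ("cannot match empty
  library"); all-N sequences get G+A fraction 0 with a warning; reads past
  a contig end are clipped with a warning.

# Known limitations

The per-site Poisson p-value is used with a fixed cutoff, with no
multiple-testing correction across positions — deliberately replicating the
published procedure rather than improving on it. The Poisson test treats
the ±150 bp window sum as independent events although per-base coverage is
autocorrelated over a read length, so the stated p-values are
anticonservative in absolute terms; the paired fold threshold is what
controls false positives in practice (the null-simulation test quantifies
the joint behaviour). The merge step assumes exactly two replicates.
BAM/CRAM input, bigWig output, and input-free (no-IgG) background
estimation are out of scope.
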