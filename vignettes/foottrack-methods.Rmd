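---
title: "Models and methods behind foottrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind foottrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foottrack)
```

## The measurement

A double-stranded-DNA cytosine deaminase applied to permeabilized cells
converts accessible cytosines to uracil; PCR then reads these events out as
C-to-T changes on the deaminated strand (and G-to-A when the sequenced read
follows the opposite strand). DNA wrapped in nucleosomes or covered by a
bound transcription factor is shielded from the enzyme, so protein occupancy
appears as a local depletion of the conversion rate. `foottrack` turns
coordinate-sorted alignments of such reads plus the reference genome into
per-cytosine *conversion tracks* and derives occupancy statistics from them.

Every record of a track is one cytosine on one strand: its 0-based position,
the number of reads with a determinate base there (`n_total`), the number
reporting the converted base (`n_conv`), and its sequence context. Three
rules matter for counting:

* a read contributes only on its own conversion strand, taken from an
  aligner tag when present and otherwise inferred from the read's mismatch
  majority (C-to-T vs G-to-A), with ties discarded;
* bases inconsistent with the conversion chemistry (e.g. C read as A) are
  treated as sequencing error and excluded from `n_total` rather than
  counted as protected;
* observations sharing a read name at one cytosine (overlapping mates) are
  counted once, keeping the higher base quality.

The sample-level conversion rate — the pooled `n_conv / n_total` over
cytosines with coverage of at least 3 (configurable) — labels the sample and
feeds QC: rates between 25% and 40% give good footprint contrast, while
harder deamination starts to erode footprints, so `qc_conversion_rate()`
flags samples outside that operating range.

## Sequence-context bias correction

Deaminases prefer some sequence contexts (the TC-over-GC preference of some
family members is the best-known case). Uncorrected, this imprints motif
sequence composition onto occupancy scores. `fit_bias_model()` estimates,
from a naked (protein-free) DNA control, the expected conversion rate of
every k-mer context with a central C (k = 3 by default — the 5' neighbour
dominates the preference; k = 5 is available). `correct_track()` then
rescales each cytosine's rate by `genome_rate / expected_rate(context)`,
clipped to [0, 1].

The correction is multiplicative rather than subtractive because rates are
probabilities: a ratio preserves the unit interval after clipping, keeps
rank order within a context, and reduces the naked-DNA per-context mean to
the genome rate by construction. Contexts backed by fewer than 200
observations, or absent from the control, fall back to the genome rate (a
no-op correction) instead of injecting noise; a context observed at exactly
zero cannot be rescaled and its cytosines are dropped with a warning. Bias
is fitted per strand and pooled unless the strand rates differ by more than
10%. Deep-learning bias models are out of scope.

## Occupancy at known sites: FOS and TFOS

The footprint occupancy score of one binding site is

```
FOS = mean rate over the two 50 bp flanks - mean rate over the motif
```

with both strands pooled and the full motif interval (not a fixed centre
window) as the protected region. A site is valid only when both motif and
flank contain at least two informative cytosines — AT-rich motifs can fail
this, and such sites are excluded with an explicit reason rather than
scored as zero. The TF occupancy score (TFOS) is the arithmetic mean FOS
over a factor's valid sites, optionally within one region class (open vs
closed chromatin, histone-state strata via `stratify_sites()`); a
positive-only aggregation variant is exposed and labelled because
comparisons against binding-signal assays sometimes restrict to sites with
positive FOS. Flanking accessibility — the flank side of the FOS on its own
— serves as a local chromatin-openness readout, and `change_ratio()`
compares any of these scores between conditions as
`(treated - control) / control`, excluding factors whose control score is
unstable (below 0.02 or fewer than 200 sites by default; both are explicit
stand-ins for an unpublished robustness filter and are configurable).

Under the simulator's generative model (below), a site with occupancy
`theta`, open-state conversion probability `p_open` and protected-state
probability `p_protected` has

```
E[FOS] = theta * (p_open - p_protected)
```

which the test suite verifies across the occupancy grid.

## De novo footprint detection

Both strategies operate inside user-supplied open chromatin regions to
avoid conflating nucleosome and TF protection, and both offer a local or a
global background. The local background of an interval is the mean rate in
a ±200 bp ring around it (excluding the interval); the global background is
the search-region-wide mean. On simulations with heterogeneous per-region
accessibility the local mode separates bound from unbound motifs better —
a global rate misreads everything inside a less-accessible region as
depleted — and the test suite asserts exactly that ordering.

**Motif-score strategy.** `scan_motifs()` finds motif occurrences with a
log2-odds scanner whose score threshold is calibrated to a p-value by exact
dynamic programming over the discretised null score distribution (scores
are quantized to the same 0.01-log2-unit grid the DP uses, so the
calibration is exact for the scanner; the unit tests compare it against
exhaustive enumeration). `footprint_scan_scores()` then scores every
occurrence as background ring minus motif rate and calibrates significance
against a positional null: random same-length positions drawn within the
same search regions, preserving their rate composition. p-values are
rank-based tail probabilities, BH-corrected per motif; a motif with fewer
than 100 valid null draws is aborted with a reason.

**Binomial-region strategy.** `detect_footprint_regions()` slides a 15 bp
window (step 1) across the track; each window's summed counts are tested
one-sided against Binomial(n, p0) with p0 from the chosen background, and
BH correction runs across all windows. Significant windows merge across
gaps of up to 5 bp, and the merged interval is trimmed to the span of its
individually depleted cytosines (per-cytosine binomial p < 0.01 — strict
enough that chance dips in open flanking cytosines do not stretch the call,
while true footprint cytosines at realistic coverage sit far below it).
Calls narrower than 6 bp are dropped. The window width resolves the 6-30 bp
footprints typical of TFs and all constants are arguments. Treating reads
over cytosines as independent trials ignores molecule-level correlation
within a window; the per-window minimum of 3 informative cytosines and the
null-calibration test (empirical window-level false-call rate at the
nominal level over 50 protein-free replicates) bound the practical effect.
Motif annotation labels a footprint matched when a motif overlaps at least
half its length; footprint density is reported per 200 bp of searched
region, with both the full-length and covered-bp denominators because the
choice is not standardised.

**Differential binding.** Site scores from two conditions over one
candidate universe are quantile-normalized across conditions
(`limma::normalizeQuantiles`); each motif cluster's differential score is
its mean per-site difference. Significance comes from size-matched random
site subsets drawn from all clusters (10,000 by default), giving a z-score
and a two-sided normal p, BH-corrected. The z is centred on the median
cluster shift rather than the pooled mean: quantile normalization
redistributes a strong change in one cluster across all others, and the
median keeps genuinely unchanged clusters at z ≈ 0. The exact statistic
behind published volcano analyses of this kind is not standardised; this
permutation z is the package's explicit choice. Motif clusters are
user-supplied, with `cluster_motifs()` (best ungapped-alignment Pearson
correlation of PFMs ≥ 0.8, forward or reverse complement, single linkage)
as a default.

## Single molecules and single cells

Each read spanning a motif is classified from its own conversion fraction
over the site window. Two rules are available:

* **threshold** (default): bound when at most 1/3 of informative window
  cytosines are converted, unbound at 2/3 or more, ambiguous between —
  simple, transparent, and with the 2-cytosine minimum a tiny window yields
  a determinate call only when unanimous. Its weakness is structural: when
  one population's true conversion rate falls inside the ambiguous band the
  resulting bound fraction is biased, and no threshold pair works for every
  enzyme operating point.
* **likelihood**: each molecule is classified at the binomial
  likelihood-ratio boundary between the bound and unbound conversion rates;
  those two rates (and the mixture weight) are fitted per site by a
  two-component binomial-mixture EM when not supplied. `site_bound_fraction()`
  then reports the mean posterior bound probability, which corrects the
  residual hard-assignment bias at small informative-cytosine counts. This
  is the rule the occupancy-recovery validation uses.

Classification uses raw per-read base calls: context bias is a rate-level
property and cannot be applied to a single binary observation; requiring
several informative cytosines dilutes it instead. Only reads spanning the
full motif enter (a read grazing the window edge sees mostly flank
cytosines and carries no occupancy information). Co-occupancy joins
determinate calls at two sites on the read name and reports the four joint
states, their fractions, a Haldane-corrected odds ratio and Fisher's exact
p; pairs are only meaningful within one fragment span. Per-cell analysis
splits reads by barcode tag, extracts one track per cell plus a merged
track whose counts equal the per-cell sum exactly, and `smooth_track()`
applies the 5 bp centred moving average used for sparse single-cell
display, leaving positions without data absent rather than zero.

## The simulator

`simulate_molecules()` generates the data every guarantee is tested
against. Per molecule it samples a fragment and a conversion strand, draws
per-site occupancy from Bernoulli(theta), decides per open-chromatin region
whether this molecule's copy is accessible (probability `openness`;
molecules carrying a bound TF in the region are always accessible), builds
the protection mask (bound-TF footprints, closed-region spans, and phased
nucleosome arrays with per-molecule Gaussian jitter outside open regions),
converts cytosines on the molecule's strand with probability
`p_open * context_multiplier` (capped at 1) when accessible and
`p_protected` when masked, and applies uniform sequencing error. Reads are
emitted as perfectly aligned SAM (decoupling pipeline tests from an
external aligner) with the conversion strand in tag `XG` and cell barcodes
in `CB`; ground truth (per-molecule occupancy, masks, expected per-cytosine
probabilities) is retained on request and is byte-reproducible under a
seed.

Defaults and the reasoning behind them:

* `p_open = 0.6`, `p_protected = 0.05`: a protected rate of exactly zero is
  unrealistic — real footprints retain residual conversion — and 0.05
  keeps the closed-form FOS expectation non-degenerate.
* nucleosome width 147 bp, repeat 190 bp, jitter SD 10 bp: canonical
  nucleosomal DNA length and a typical repeat; the jitter reproduces
  phasing decay with distance. These are field-standard magnitudes, not
  measured constants.
* fragment length 200 ± 20 bp, error rate 0 by default (error is switched
  on where a test exercises the filtering rules).
* condition series vary per-TF `theta` and per-region `openness`.

The `openness` parameter deserves a note. Chromatin closing is modelled as
a reduction in the fraction of molecules whose region is accessible, not as
a smaller per-cytosine enzyme rate. The two are not interchangeable: the
FOS expectation `theta * (p_open - p_protected)` is linear in `p_open`, so
scaling the enzyme rate scales occupancy scores and flanking accessibility
by the same factor, whereas reducing `openness` with occupancy constant
lowers flanking accessibility while leaving the FOS expectation unchanged
(bound molecules keep their locus open and contribute the same contrast).
Only the second regime reproduces the pioneer-factor phenotype — flanking
accessibility collapsing under a chromatin-remodeler inhibitor while the
occupancy score barely moves — and the dynamics validation uses it.

What the simulator does not emulate: PCR duplication structure, indels,
insertion-site bias of tagmentation, methylation-dependent deamination
efficiency, mappability artefacts, and aligner errors (reads are emitted
pre-aligned). Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not robustness to
every artefact of real libraries.

## Problem sizes and numerical choices

The validation suite runs, by choice, at desk scale: 100 kb contigs and
20,000 molecules for bias-model recovery; 10 sites × 2,000 molecules per
occupancy level for the FOS/bound-fraction sweep; 50 protein-free
replicates for the null calibration of the region caller; 40 regions × 10
motifs × 1,200 molecules per condition for the differential spike-in.
Published applications of this assay type operate at hundreds of millions
of reads; none of those full-scale results are restated here — every number
in the tests and the acceptance script is computed by the package at run
time.

Numerical conventions worth knowing: coordinates are 0-based half-open
everywhere internally (stated in the TSV header); minus-strand cytosines
are reported at the reference G with a reverse-complemented context;
profile matrices orient minus-strand sites so motif 5' is left; empty
inputs yield empty, flagged results (an empty track has an *undefined*
global rate, never 0); BH q-values come from `stats::p.adjust`; Wilson
intervals are used for bound fractions; the motif DP uses a 0.01 log2-unit
score grid; and ties in strand inference are discarded rather than guessed.

## Known limitations

AT-rich motifs with too few cytosines cannot be scored and are reported as
invalid rather than imputed. Footprint assignment inherits motif redundancy
within TF families; clusters mitigate but do not resolve it. The
single-molecule thresholds are operating-point dependent (see above).
Cross-fragment phasing, barcode error correction, de novo motif discovery
from unmatched footprints, and peak calling are out of scope — regions and
peaks are inputs.
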