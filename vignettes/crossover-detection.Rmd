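---
title: "Detecting meiotic crossovers in gamete pools from long reads"
author: "gametecross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting meiotic crossovers in gamete pools from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gametecross)
```

## The problem

Sequencing a pool of sperm from one individual samples thousands of
independent meioses at once: every read comes from a single haploid gamete,
and a read whose alleles switch from one parental haplotype to the other is
direct physical evidence of a crossover.  Long nanopore-style reads span
enough heterozygous sites to make this classification per molecule, but
their dominant error mode — miscalled homopolymer lengths — would swamp a
naive allele-by-allele comparison.  `gametecross` therefore works entirely
in *homopolymer-compressed* space: every maximal run of identical bases in
the reads and in the reference is collapsed to a single base
(`AGTTTCG` becomes `AGTCG`), which removes most indel errors while leaving
the heterozygous substitution signal intact.  An exact run-length position
map restores all reported intervals to original coordinates.

## The detection model

For a read with observed base $G_n$ at heterozygous site $n$, with phased
alleles $H^{ref}_n$ (haplotype A) and $H^{alt}_n$ (haplotype B), the
haplotype score is

$$H_k = \begin{cases} +1 & G_n = H^{ref}_n \\ -1 & G_n = H^{alt}_n \\ 0 &
\text{otherwise (error, deletion, unknown)} \end{cases}$$

A window of seven sites (the centre and three on each side) slides along
the score vector with step one, from the fourth site to the fourth-from-last.
With $L_n$ the number of non-zero scores in window $n$, the centre site's
phase is

$$\text{call}(n) = \begin{cases} \text{HapA} & \sum H_k / L_n \ge 4/6 \\
\text{HapB} & \sum H_k / L_n \le -4/6 \\ \text{NA} & \text{otherwise, or
too few informative sites} \end{cases}$$

with both inequalities inclusive.  After dropping NA calls, a read whose
phase vector contains both HapA and HapB is a candidate recombinant
molecule; the switch interval runs from the last call of the outgoing phase
to the first call of the incoming phase and is reported half-open so that
the true exchange point is contained in it.  With error-free data this
containment is exact: a window can only vote $\ge 4/6$ for a phase when its
centre site truly carries that phase, so the transition is bracketed by
correctly phased calls.

**The minimum-representation rule.**  The window rule requires "enough"
informative variants, which we operationalise as $L_n \ge$
`min_represented` (default 5): a seven-site window cannot hold five
informative sites *per haplotype*, and a read never shows both haplotypes
simultaneously at one site, so the only internally consistent reading is a
floor on informative sites per window.  The parameter is exposed
(`min_represented`) for users who prefer a stricter or looser floor.

**Phase sets.**  Real phasing tools emit phase blocks; phase is meaningless
across a block boundary.  Scoring and window traversal therefore never mix
sites from different phase sets — each (chromosome, phase set) produces its
own score vector, and switches are only called within one set.  A
chromosome phased as a single block behaves exactly as the single-pair
model above.

**Label symmetry.**  "Haplotype A" is the allele left of the phase
separator in the VCF — an arbitrary convention.  Negating every score swaps
HapA and HapB calls and leaves the set of recombinant reads unchanged; this
symmetry is enforced by tests end to end.

## Quality control ahead of detection

Detection assumes a clean site list and clean alignments:

* **Alignments**: secondary and supplementary records are removed, as are
  records with mapping quality below 60 (`min_mapq`); at 60, minimap2-class
  aligners assert unique placement.
* **Variant quality threshold**: long-read variant callers produce a
  bimodal quality distribution (error mode low, true-variant mode high).
  `find_quality_cutoff()` smooths the distribution with a kernel density,
  takes the two highest modes, and returns the quality at the valley
  between them plus 50 — a deliberate shift into the clean flank of the
  upper mode.  If the distribution has fewer than two detectable modes the
  function falls back to the 5th percentile with a warning; the bimodal
  assumption simply does not hold and a conservative low cutoff is the
  safest default.
* **Clustered variants**: any window of 10 bases containing more than 3
  variants is discarded *entirely* (all members, not just the excess);
  such clusters are overwhelmingly alignment artifacts.  Both window ends
  are inclusive: positions $p$ and $p+9$ are "within 10 bases".
* **Site list**: only phased, heterozygous, biallelic SNVs enter the
  haplotype table; indels and structural alleles are disregarded because
  they are exactly the variant classes homopolymer compression and
  long-read alignment handle worst.

After detection, candidate recombinants in regions of anomalous depth are
removed: the mean depth over the supporting read's aligned span must lie
within [0.25x, 2x] of the genome median (`low_mult`, `high_mult`).  The
bounds are symmetric on a log scale — guarding equally against dropouts
and collapsed-repeat pileups — and configurable; `c(0, Inf)` disables the
filter.  Whether a fixed or distribution-based rule is preferable is an
open modelling question; a fixed multiple of the median is transparent and
monotone in its parameters (widening the bounds never removes a kept
call).

## The landscape

Events are binned into fixed windows (1 Mb default) on *original*
coordinates after liftover.  Each event counts once, in the window
containing its switch-interval midpoint; midpoint assignment avoids
double-counting wide intervals that straddle a window edge
(`method = "overlap"` distributes fractional weight instead, for users who
prefer it).  The final partial window is retained with its true length.
Sex chromosomes recombine only in the pseudoautosomal region and are
excluded by default.

## The simulator

`simulate_genome()` / `simulate_reads()` generate a synthetic gamete pool
at desk scale.  Design choices, and what they do and do not emulate:

* **Compressed-space construction.**  The compressed reference is drawn
  directly (no adjacent duplicate bases); each compressed position carries
  a geometric original run length with mean 1.4, matching the ~0.7
  compression ratio of mammalian genomes.  The original reference, the
  position map and original chromosome sizes are thereby exact by
  construction.
* **Structure-preserving SNVs.**  Heterozygous sites are placed only at
  run-length-1 positions, at least two compressed bases apart, with the
  alternate allele differing from both neighbours, so that both haplotypes
  share a single compressed coordinate system.  Real SNVs inside
  homopolymer runs shift compressed coordinates between haplotypes; the
  pipeline consumes an externally aligned BAM in real use, so this
  simplification affects only the simulator.  Site spacing is
  near-exponential with mean `snv_spacing` original bases (100/200/300 in
  the validation grid).
* **Reads.**  Read lengths are normal with mean 15,000 and sd 3,000
  compressed bases (roughly a 20 +/- 4 kb size-selected nanopore library
  before compression).  A fraction `recomb_fraction` (default 0.1) of
  reads switches haplotype at a uniform internal breakpoint.  Reads are
  emitted pre-aligned with truthful CIGARs: the external aligner is out of
  scope, and bypassing it keeps the truth set exact.
* **Errors.**  A parametric model replaces trained ONT profiles: 2%
  substitution, 2% insertion, 3% deletion per compressed base, with indel
  probabilities multiplied by 3 at positions whose original run length is
  at least 2 — the residual homopolymer error mode that compression does
  not fully remove.  The detector's thresholds, not the error model's fine
  structure, are what the validation exercises; the model is deliberately
  simple, seed-reproducible and download-free.
* **QC decoys.**  The simulated VCF also carries low-quality decoy
  variants (10% of true sites), clustered high-quality decoys (groups of
  four within ten bases), unphased heterozygotes and indels, so a full run
  exercises every QC rule, not just the caller.
* **Depth** is the mean alignment coverage of the *compressed* genome —
  the quantity the depth filter and the detector actually see.

What passing simulated tests does **not** show: robustness to reference
bias, chimeric reads, segmental duplications, phasing switch errors in the
input VCF, or basecaller-specific error correlations.  Those require real
data; the simulator validates the decision rule, not the upstream stack.

## Validation harness and problem sizes

`run_grid()` runs genome simulation, variant QC, detection, coverage
filtering and evaluation per cell of (SNV spacing) x (depth) x
(replicate), and reports per-read sensitivity (fraction of truly
recombinant molecules detected) and error rate (fraction of non-recombinant
molecules miscalled), with normal-approximation Monte-Carlo confidence
intervals across replicates.  The package's standard validation uses a
5 Mb genome, spacings {100, 200, 300} bp per SNV, depths 20-70x and three
replicates per cell — several hundred to a few thousand recombinant
molecules per cell, enough to resolve the qualitative trends (sensitivity
rising with depth and variant density, errors concentrated at low depth
and sparse variants) while a full grid completes in minutes on one CPU.
In this simulator, per-read sensitivity is nearly depth-independent —
depth changes how many molecules are sampled, not how well one molecule is
classified — because haplotype construction is taken as given; on real
data, depth additionally degrades phasing itself, which is the stronger
depth effect the full pipeline inherits from its inputs.

Expected sensitivity is dominated by breakpoint placement: a switch is
only callable when both flanks carry at least seven sites, so a uniform
breakpoint in a read of $m$ sites is detectable with probability roughly
$(m - 13)/m$ — about 93% at 100 bp spacing and 15 kb compressed reads,
degrading with sparser variants.  False calls require about six of seven
window sites to flip sign simultaneously, which is vanishingly rare under
percent-level substitution rates; observed error rates in the grid are
accordingly near zero.

## Numerical and degenerate-input choices

* Threshold comparisons use the inclusive inequalities exactly as the
  window rule states them; scores and window sums are integers, so the
  floating-point comparison against `threshold * Ln` is exact for all
  practically reachable values.
* Score vectors shorter than `2*window_flank + 1` sites yield no phase
  calls and can never produce a crossover.
* Reads whose CIGAR-implied length disagrees with their sequence are
  skipped with a warning, not a pipeline failure.
* Reads with two or more switches are emitted but flagged `multi_switch`;
  short double-switch tracts are more often artifacts (or gene
  conversions, which this package deliberately does not classify).
* FASTQ qualities are compressed by keeping the maximum quality within
  each collapsed run — the strongest evidence for the retained base; the
  alternatives (first, mean) discard information without being more
  principled.
* N runs compress like any other base run.
* Empty inputs return empty, typed results with warnings; genuinely
  malformed inputs (truncated FASTQ records, unsorted variant tables,
  out-of-range liftover intervals) are errors that name the offending
  record.
* All randomness flows through a single integer seed; grid cells derive
  their seeds deterministically from it, so every result table is
  bit-reproducible.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(genome_length = 1e6, snv_spacing = 100, depth = 20,
                  seed = 7)
sim <- simulate_genome(cfg)
haps <- sim_qc_haplotypes(sim)         # QC: quality valley, clusters, phasing
cell <- run_sim_cell(sim, haps = haps, seed = 8)
cell$eval
# crossover_eval: sensitivity 0.9184 (90/98), error rate 0.00000 (0/854),
#                 mean breakpoint error 0
```

## Limitations

* Gene conversion (double switches within short tracts) is reported only
  as `multi_switch`, never classified.
* The coverage filter uses raw depth; no mappability or GC correction.
* The landscape is a raw event count per window, not a cM/Mb genetic map,
  and carries no hotspot statistics.
* Alignment, variant calling and phasing are consumed as inputs; their
  errors propagate.  In particular the phasing tool's own switch errors
  masquerade as recombination at the affected sites.
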