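---
title: "Karyotype analysis from Hi-C contact maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype analysis from Hi-C contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyohic)
library(data.table)
```

## The problem

Continuous cell lines accumulate chromosomal rearrangements, and in birds
classical karyotyping is nearly blind to them: a chicken-like karyotype has
dozens of microchromosomes that are indistinguishable by banding and easily
lost from metaphase spreads.  Hi-C offers a way around the microscope.  A
genome-wide contact map read against the reference assembly shows every
large structural variant as a characteristic anomaly: a translocation
produces an interchromosomal block of enriched contacts with a gradient
that decays away from the fusion junction, a deletion removes coverage and
pulls its flanks together, an inversion reflects contacts into "butterfly"
corners, and a duplication raises both coverage and, proportionally, trans
contacts.

`karyohic` implements this reading as a tested pipeline: a generative
simulator of contact maps under an edited (derivative) karyotype, the
map-level QC statistics, A/B-compartment and domain callers used to
characterize 3D-genome organization, detectors for inter- and
intrachromosomal rearrangements, and a breakpoint-graph assembler that
turns calls into candidate derivative chromosomes.

## The generative model

The simulator works in *derivative coordinates*.  A karyotype is a set of
haplotypes, each an ordered list of oriented reference segments
(`apply_edits()` builds them from edit lists expressed in reference
coordinates).  Two loci that are co-resident on one derivative chromosome
at separation $s$ contact with density

$$ B\,(s + s_0)^{-\alpha}\,\bigl(1 + \delta\, e_i e_j\bigr)\,(1+\tau)^{k}, $$

per bp$^2$, where $\alpha$ is the distance-decay exponent (default 1, the
fractal-globule regime), $s_0$ a 10 kb offset that regularizes the decay at
sub-fragment scale, $e$ a $\pm 1$ compartment track (alternating 500 kb
blocks by default, i.e. ten 50 kb bins per block), and $k$ the number of
planted nested domains containing both loci, each multiplying contacts by
$1 + \tau$.  Copy pairs never co-resident contact at a flat background
$B_t$.  Expected bin counts are densities times bin areas, evaluated at bin
midpoints, scaled so the genome-wide total matches `total_contacts`
(default 3e8, a combined-replicate avian library), and sampled as
independent Poisson draws.  Overdispersion is deliberately not modeled:
Poisson noise is sufficient for pattern-level detection, which is what the
package tests.

Two calibrations are part of the stated world rather than free dials.
First, `trans_background = "auto"` solves for the $B_t$ that gives the
*unedited* genome an expected cis/trans ratio of 1.9, the center of the
1.6–2.3 band reported for low-noise chicken Hi-C libraries; rearranged
karyotypes then show elevated trans fractions exactly as real rearranged
lines do, because fusions convert cis contacts into reference-trans ones.
For degenerate genomes (a single chromosome, or two chromosomes so unequal
that the band is unattainable) the background falls back to the cis density
at half-genome separation.  Second, heterozygosity is a two-population cell
mixture: a fraction $w$ of cells carries the edited diploid karyotype and
$1-w$ the unedited one, so every rearrangement retains residual wild-type
signal — the feature that lets a real map reveal an intact homologue behind
a derivative.  An edit placed on one haplotype is heterozygous even at
$w = 1$; a deletion carried on one haplotype by all cells halves normalized
coverage, which is the arithmetic the coverage-CNV thresholds assume.

Because per-pixel enumeration at 5 kb genome-wide is infeasible, the
simulator is multi-resolution: genome-wide maps are drawn at the scan
resolution (250 kb), and `hic_fetcher()` lazily simulates fine windows (5
kb) around candidate junctions from the same calibrated model with
region-derived seeds.  Coarse map and fine windows are therefore
independent Poisson draws of one expectation — statistically equivalent to
re-sequencing, not a resampling of the same reads.

What a green test on this generator does *not* establish: robustness to
restriction-fragment structure, mapping artifacts, ICE-scale biases,
overdispersed counts, or assembly errors (which real comparative analyses
must separate from true rearrangements using a second cell type).

## Detection

`detect_translocations()` formalizes the visual procedure used on real
maps:

1. **Scan.** Each chromosome pair is tested at 250 kb against a null of
   flat background scaled by the product of the two bins' *trans-only*
   coverages.  The coverage product absorbs copy-number-driven enrichment —
   a duplicated or amplified region contacts everything more, in real maps
   and in the model alike, and must not be called a translocation.  Using
   trans-only marginals (corrected for the size of the bin's own
   chromosome) avoids leaking compartment-driven cis variation into the
   null.  The background rate is estimated robustly as the median over
   chromosome pairs of the pair-median normalized intensity, because for a
   pair joined into one derivative chain the signal covers the whole
   rectangle and any within-pair estimate would mask itself.  Box-smoothed
   counts get Poisson tail tests, Benjamini–Hochberg-adjusted per pair;
   significant pixels are joined 8-connectedly, and a block must contain at
   least two significant *unsmoothed* pixels so a single Poisson spike
   cannot seed a call.  Components whose pixels fall into complementary
   quadrants touching at a corner — the signature of a reciprocal
   (balanced) exchange — are split back into their two blocks.
2. **Localize.** The junction is where the enrichment gradient peaks.  A
   2D argmax picks one junction corner (an interior insertion has two
   equivalent corners), each axis marginal is conditioned on the other axis
   near that corner, and the junction boundary is refined at 5 kb by a
   two-segment Poisson change-point on a strip marginal — the step from
   background to signal is sharp there even when the gradient itself decays
   smoothly.  Refinement is constrained to one scan bin around the coarse
   estimate.  Segment edges away from the junction are refined the same
   way; orientation follows from which segment end carries the junction
   and which side of the acceptor it joins.
3. **Classify.** Reciprocal complementary blocks are balanced; a donor
   segment with ~1.5x coverage is a translocated duplication (three copies
   against a diploid baseline); blocks spanning ≥ 90 % of a chromosome are
   terminal fusions with a `ter` insertion, the geometry typical of
   acrocentric microchromosomes whose true breakpoints sit in unassembled
   terminal repeats.

A deliberate deviation from a plain change-point reading: the marginal
profile of a translocation is a decaying gradient, not a step, so a single
two-segment fit on the full marginal lands mid-gradient.  The
argmax-plus-conditioned-strip construction recovers planted junctions to
one 5 kb bin at realistic depth.

Intrachromosomal events combine two channels.  `cnv_segments()` segments
the log2 coverage ratio by recursive binary splitting under a BIC-style
penalty (deterministic, and checkable against an exhaustive change-point
oracle for segments spanning at least a few bins — greedy splitting is not
guaranteed to isolate single-bin spikes whose one-split projection falls
below the penalty); the thresholds −0.5/−3/+0.4/+1 separate the 1-, 0-, 3- and ≥4-copy
states of a diploid mixture.  `detect_inversion()` scores butterfly corner
boxes of the observed/reference log-ratio (a reference map is required —
the pattern is defined comparatively), and `detect_cis_deletion()` couples
coverage loss with gap-bridging contact enrichment.

## Compartments and domains

`compartment_eigenvector()` is the classical pipeline — coarsen to 50 kb,
mask zero and bottom-2 % coverage bins, observed/expected by per-diagonal
means (no smoothing; adequate at this resolution), Pearson correlation
matrix, leading eigenvector by deterministic power iteration.  The sign is
arbitrary, so `orient_sign()` requires an explicit activity proxy (the
planted track for synthetic data; coverage or gene density for real maps)
and flags orientations with $|r| < 0.05$ as ambiguous.  The leading
eigenvalue over the trace is reported as variance explained; below 0.1 the
track is marked unreliable — a compartment-free map should not be assigned
A/B labels.

`armatus_segment()` maximizes the sum of positive window qualities
$q_\gamma(i,j) = s_\gamma(i,j) - \mu_\gamma(\ell)$ by dynamic programming,
with $s_\gamma$ the scaled triangle sum and $\mu_\gamma$ the per-length
mean over the same chromosome's windows.  Domains are capped at 6 Mb
(visible vertebrate domains are at most a few Mb, and the cap bounds the
DP), the minimum domain is 2 bins, and ties break toward the longer
terminal domain, then leftmost, so output is deterministic.  The DP is
property-tested against exhaustive enumeration of all $2^{n-1}$ boundary
placements for $n \le 12$.  `consensus_domains()` unions the γ grid
(0.2–0.3 by default; larger γ = finer), keeping overlapping domains from
different γ as hierarchy levels.  Segmentations are compared by boundary
coincidence at a 1-bin tolerance and by variation of information over the
bin partition (gap bins as singletons, log base 2).

## Assembly

`build_breakpoint_graph()` cuts chromosomes at all reported breakpoints
and wires calls as adjacency edges between *segment extremities* — the end
awareness is what lets conflicting evidence (two calls claiming the same
donor end) produce branching.  `reconstruct_derivatives()` walks maximal
alternating paths from free extremities, emitting ranked, oriented segment
lists; pure cycles are reported as unresolvable rather than forced into
linear chromosomes.  Reconstructions are labeled candidates, never truths
— on real data the same evidence often admits several arrangements.
`estimate_chromosome_count()` does the fusion arithmetic: per-chromosome
copies (ploidy, or rounded coverage) minus $k-1$ for every derivative
joining $k$ near-whole chromosomes.

## The planted example karyotype

`hd3_like_edits()` encodes, as derivative chains, the 26 large
interchromosomal rearrangements reported for the HD3 chicken erythroblast
line (e.g. der(5) = 5 + 7p + 4p, der(6) = 6 + 19 + 4q.1,
der(23) = 23 + 21 + 28ter + 12, the many microchromosomal terminal
fusions, and the translocated duplication of GGA1qter into GGA2).  Chains
are this package's design choice: the published table lists pairwise
interactions, and a chain of $k$ guests realizes all $\binom{k}{2}$ listed
pairs at once, exactly as multiway FISH evidence suggests.  Donors that
recur across rows are planted as duplications or on the second haplotype
(total copy number capped at 3, mirroring subclonal heterogeneity), and
guest order keeps every pairwise separation within ~8 Mb so each pair stays
detectable at the default depth.  Scanning a map simulated from this
karyotype returns exactly the 26 planted pairs:

```{r, eval = FALSE}
g <- galgal_like_genome()
kar <- apply_edits(g, hd3_like_edits(include_intra = FALSE))
p <- simulation_params(seed = 1)
m <- simulate_map(kar, p, 250e3)
calls <- detect_translocations(m, detection_params(),
                               refine = hic_fetcher(kar, p, 5e3), genome = g)
nrow(calls)   # 26
```

## Numerical choices and limitations

* Coordinates are 0-based half-open internally; report text is 1-based.
* Edit coordinates are resolved through the *current* haplotype mapping,
  in list order; an insertion at an already-used boundary stacks after
  previously inserted material; `ter` insertions join before the first /
  after the last reference bp of the arm.
* Bins are assigned to segments by midpoint, so edits should be aligned to
  the finest simulation bin (5 kb here; the tabulated coordinates all
  are).
* The refinement change-point is accepted only with ≥ 2-fold contrast and
  within one scan bin of the coarse estimate; otherwise the coarse value
  stands, with the uncertainty reported accordingly.
* Donor/acceptor labeling is heuristic when both junctions are near
  chromosome ends (terminal fusions): either reading is consistent with
  the map, as on real heatmaps.
* Armatus window means are always per-chromosome; very short chromosomes
  (fewer than ~3 windows of the longest length) would need pooled means
  and are outside the tested envelope.
* The chromosome-number estimator reproduces fusion arithmetic on
  simulated karyotypes; its mapping to a cytogenetic count on real data is
  untested by design.
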