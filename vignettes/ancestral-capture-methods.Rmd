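---
title: "Ancestral-capture enrichment analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral-capture enrichment analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anccap)
```

# The problem

Hybridisation capture with baits designed from a *reconstructed ancestral*
mitogenome lets one enrich mitochondrial DNA from species that have no
close extant relative with a published reference — typically degraded
historical museum specimens. The approach has a characteristic failure
mode: enrichment efficiency falls steeply with local bait-to-target
sequence divergence, so divergent regions of the target mitogenome drop
out of the capture data even though an untargeted shotgun library covers
them evenly.

`anccap` implements the full analysis around this phenomenon as a tested
pipeline: bait tiling, mapping-quality filtering, PCR-duplicate removal
keyed on joint fragment-end coordinates, depth/majority consensus calling
with screening against nuclear-mitochondrial insertions (numts),
sliding-window divergence-versus-depth analysis, recovery of the logistic
retention curve, pre-capture pooling plans, and a minimum spanning
haplotype network. A synthetic-data generator produces every input with
ground truth, so each claim the pipeline makes is testable end to end.

# The synthetic-data generator

The generator emulates a degraded-specimen capture experiment on a
circular ~16.5 kb mitogenome, linearized at position 0 (fragments never
span the origin; wrap-around coordinates buy nothing at this scale and
complicate every downstream interval operation).

**Ancestor and descendant.** The ancestral (bait-source) genome is drawn
i.i.d. with a configurable GC content (default 0.40, a typical vertebrate
mitochondrial value). The descendant target evolves from it under a
*divergence track*: an ordered segmentation of the genome, each segment
with a target per-site substitution probability. The default track places
20 graded segments across the central 2–15 kb analysis region with
divergence targets following a power-law grid from 0 to 27% whose discrete
mean is exactly 12%, interleaved low/high so every sub-region sees the
full range; the flanks (the rRNA/control-region analog, excluded from the
window analysis) sit at the 12% mean, making the genome-wide expected
divergence 12% as well. These three numbers — span 0–27%, mean 12% — are
the descendant-to-bait divergence profile the pipeline is designed to
operate over. Substitutions are uniform over the three alternative bases;
an optional deletion mode exists solely to exercise window gap-flagging.

**Fragments and damage.** Fragment lengths are lognormal with mean 70 bp
and SD 25 bp, truncated below at 30 bp — typical historical-specimen
sizes, with the floor matching the usual post-trimming read-length cutoff.
The spec of record for the emulated experiment gives no fragment-length or
damage statistics, so these are stated assumptions, not measured values.
Postmortem deamination is modelled as C→T conversion at read position *k*
(0-based from the 5' end) with probability `rate_5prime * decay^k`
(defaults 0.3 and 0.5). Damage is applied in read orientation;
minus-strand reads are then stored reference-oriented, so their damage
surfaces as G→A at the reference-3' end, as in real libraries. Sequencing
error beyond deamination, quality scores and paired-end structure are
deliberately out of scope: none of them interact with the divergence
mechanism under study.

**Capture retention.** Each fragment's affinity for the bait set is its
*best bait identity*: the maximum over all baits, both orientations and
all ungapped offsets of matches over `min(fragment length, bait length)`
compared positions (N always mismatches). A capture library retains each
fragment independently with probability

$$p(\mathrm{id}) = \frac{p_{\max}}{1 + e^{-s\,(\mathrm{id} - \mathrm{id}_{50})}}$$

with defaults $p_{\max} = 0.95$, $\mathrm{id}_{50} = 0.80$, $s = 40$:
retention is near-maximal below ~10% divergence and near zero above ~20%,
the qualitative enrichment cliff reported for ancestral capture. A shotgun
library retains every fragment. Retained fragments receive
`1 + Geometric(dup_rate)` PCR copies (so `dup_rate = 0` means no
duplicates), and every read carries its truth placement.

All randomness flows from a single per-call seed; identical inputs give
byte-identical libraries, and the pipeline derives stage seeds
deterministically from one master seed.

# Bait design

Baits of fixed length (default 60 nt) are anchored every `step` bp
(default 2 bp — dense array-style tiling). The probe length of the
emulated assay is not on record; 60 nt was chosen to match the 60 bp
analysis window used to relate divergence to capture efficiency, and is
configurable. If the last regular anchor misses the 3' end, one extra bait
is anchored at `L - bait_length`, so the tiling always reconstructs the
full source interval.

One sharp corner is worth knowing: with 2 bp tiling, a source fragment of
*exactly* bait length anchored at an off-grid (odd) coordinate matches no
bait perfectly, so its best identity is below 1. Any source fragment at
least one base longer always spans an on-grid bait start and scores
exactly 1. The identity scan itself is a 2-bit-packed XOR/popcount
comparison in C++ against every bait, orientation and offset — brute
force, exact, and fast enough (~1 ms per fragment against ~8,200 baits)
that no heuristic prefilter is needed at mitogenome scale.

# Read processing

Internal coordinates are 0-based half-open everywhere; conversion to
1-based happens only at the SAM boundary, and BED output is 0-based. A
single convention prevents off-by-one drift.

The SAM dialect written by the simulator is the standard 11 mandatory
columns with full-length-match CIGARs; the reader additionally accepts
soft-clips (trimmed on read) and rejects indel CIGARs with a clear error,
because the pileup assumes column-aligned reads. Reads below MAPQ 30 are
removed (strict `<` threshold: a MAPQ-30 read passes).

Duplicates are identified by the joint key (reference, 5' start, 3' end,
strand) — both fragment ends, not just the start, which matters for
variably-sized degraded fragments. Strand is part of the key: reads on
opposite strands derive from different template strands and are never
duplicates here (the emulated study's tool does not document its choice;
this is the conservative reading). The retained representative is the read
with the fewest N bases, ties broken by input order.

# Consensus calling and the numt safeguard

A position is called when depth (N bases never count) reaches
`min_depth = 3` and one state — a base or a deletion — reaches
`majority = 0.90` of that depth; otherwise it is N. The majority is
applied as ≥ (a 9-of-10 column is called), with a 1e-9 epsilon so the
boundary is not lost to floating point. The stringency is the point: a
co-enriched numt present above 10% of reads leaves its discordant sites
uncallable rather than contaminating the consensus. Deletions compete in
the vote and are excised from the reported sequence but kept in the depth
vector. Raising `min_depth` can only turn calls into N, never the
reverse.

Two further screens mirror standard practice: translated CDS are checked
for internal stop codons under the vertebrate mitochondrial code (where
AGA/AGG are stops — a numt's hallmark), and multi-sample alignments drop
every column containing missing data before any distance computation.

# The window analysis

Windows of 60 bp at 30 bp step tile the 2–15 kb region (windows are
clipped to lie entirely inside the region; the flanking rRNA/control
regions are excluded as indel-rich). Window identity counts only columns
with unambiguous bases in both rows; any gap or N flags the window, and
flagged windows are excluded from the response table. Per-window depth is
the mean per-position read depth.

The *divergence response* bins gap-free windows by divergence (bin width
0.02, a design choice — the emulated analysis does not state its binning)
and reports per bin the proportion of windows and the proportion of
capture and shotgun depth, plus their ratio. Trendlines use degree-1
loess (tricube-weighted local linear regression, direct surface) — exact
on collinear input; equivalence with any particular loess implementation
is explicitly not a contract. Bins with fewer than 5 windows trigger a
warning.

The banded global aligner (Gotoh, affine gaps costing
`gap_open + L * gap_extend`, default band half-width 200) exists for
real-data mode, where the bait source and the target are distinct
molecules that must be aligned before windowing; it widens the band with
a warning whenever the optimal path touches the boundary, and its
identity excludes terminal gap runs.

# Recovering the capture model

Two estimators are provided, and the difference between them is a methods
point in its own right.

`fit_capture_model()` fits the logistic curve to per-window
capture/shotgun *depth ratios* by least squares — the direct windowed
readout. Its identity axis, however, is a noisy and downward-offset proxy
for what retention actually responded to: fragments (~70 bp) take the
best identity over ~11 ungapped offsets, carry damage, and straddle
window boundaries. The result is classical errors-in-variables behaviour:
the fitted slope is attenuated (roughly 18 when the truth is 40) and the
midpoint shifts by a few percent identity, while the window-resampling
bootstrap — which sees only variance, not bias — produces tight intervals
around the biased value. The estimator is still useful descriptively, is
exact on noiseless logistic input, and rejects degenerate (flat or
single-bin) data, but its intervals should not be read as covering the
generative midpoint.

`fit_capture_model_reads()` removes the scale mismatch instead of
modelling it: every unique read of both libraries is scored with the same
best-bait-identity statistic that capture acts on, reads are binned by
identity, and the logistic is fitted to per-bin capture/shotgun *count*
ratios. The shotgun library supplies the pre-capture identity
distribution, so the ratio estimates retention point-wise on the correct
axis; damage and the offset-max effect appear identically in numerator
and denominator. Under the default study conditions this recovers
id~50~ to within ±0.005 and the slope to within ~10%, with equal
sequencing effort the amplitude estimates $p_{\max}$ directly, and the
read-resampling bootstrap intervals cover the truth. The pipeline reports
this fit as its headline recovery and keeps the window fit alongside for
the descriptive plot.

# Pooling

When libraries of unequal quality share one capture reaction, volume
fractions proportional to `1 / (target_content x molarity)` equalize the
expected on-target molecules per library — the simplest rule consistent
with aiming for equal post-capture representation (the emulated study
states the inputs of its pooling but not its formula; this rule is
declared, not inferred). An optional per-library cap (default 0.5)
prevents a very poor library from dominating; capped libraries are
warned about, since exact equalization no longer holds for them.

# Haplotype network

Consensus sequences are collapsed to haplotypes, pairwise differences are
counted over complete columns only, and a minimum spanning tree is built
with Kruskal's algorithm under deterministic tie-breaking (ascending
weight, then lexicographic node pair). The deepest split — the matriline
partition — is the removal of the largest tree edge; by the MST cut
property this is exactly the maximal-separation bipartition, which is the
biological readout of interest. Median vectors and reticulations of full
median-joining networks are intentionally out of scope: the deepest split
does not depend on them.

# Problem sizes and numerical choices

The default configuration — 16.5 kb genome, 8,221 baits, 20,000 capture
plus 20,000 shotgun fragments, 15% duplication, 8 matriline samples of
4,000 fragments, 100 bootstrap replicates — runs in a few minutes on one
CPU and was chosen as the smallest scale at which every statistical claim
(segment-level divergence recovery, monotone retention, shotgun
neutrality at α = 0.01, capture-model recovery) is comfortably inside its
sampling tolerances. The test suite uses further-reduced sizes for
orchestration checks and keeps full scale only where a claim is about the
study conditions themselves.

Numerical corner cases handled explicitly: the majority boundary epsilon
(above); tie-breaking in consensus votes is moot because only one state
can reach a >0.5 majority; windows at the region edge are clipped inward;
the response-table ratio is reported missing where a bin has no shotgun
depth; the aligner refuses no input but widens its band, and the fit
functions reject degenerate spreads rather than returning arbitrary
estimates.

# What passing tests do and do not show

The generator draws sites i.i.d. within segments, so window-level
divergence scatters binomially around segment targets — the maximum
*window* divergence under a 27% segment is ~40%, whereas real mitogenomes
have smoother local divergence. Fragment placement is uniform, so there
is no GC or secondary-structure coverage bias; the only enrichment force
is the logistic identity response. Damage is pure C→T with geometric
decay; there is no sequencing error elsewhere. Consequently, passing
tests validate the *operations* (tiling, filtering, dedup, calling,
windowing, fitting, network) and the *statistical machinery* under a
controlled generative model; they do not certify retention-curve
parameters of any real capture chemistry, and real data will add coverage
biases this generator deliberately omits.

# Session

```{r}
sessionInfo()
```
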