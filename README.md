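# anccap — ancestral mitogenome capture simulation and enrichment analysis

Hybridisation capture with baits designed from a **reconstructed
ancestral mitogenome** makes it possible to enrich mitochondrial DNA from
species with no close sequenced relative — typically degraded historical
museum specimens. Its characteristic behaviour is a steep loss of
enrichment efficiency with local bait-to-target sequence divergence:
conserved regions come back at high depth, divergent regions drop out,
while an untargeted shotgun library covers everything evenly.

`anccap` is an R package for scientists designing or analysing such
experiments. It implements the full analysis as a tested pipeline:

- **bait design**: fixed-length probes tiled at a dense step (default
  60 nt every 2 bp) across an ancestral reference;
- **read processing**: mapping-quality filtering (MAPQ < 30 removed) and
  PCR-duplicate removal keyed on the joint (5' start, 3' end, strand)
  fragment coordinates;
- **consensus calling**: per-position pileups called under a minimum
  depth of 3x and a 90% majority rule, so positions carrying a
  co-enriched nuclear copy (numt) above 10% of reads stay uncalled;
  internal-stop-codon screening under the vertebrate mitochondrial code;
- **window analysis**: 60 bp / 30 bp-step sliding-window bait-to-target
  identity and per-window capture and shotgun depth over the 2–15 kb
  region, binned into a divergence-response table with loess trendlines;
- **capture-model recovery**: the retention probability is modelled as a
  logistic in best-bait identity,
  `p(id) = p_max / (1 + exp(-slope * (id - id_50)))`, and recovered from
  the data two ways (a descriptive per-window depth-ratio fit, and a
  consistent read-level count-ratio fit — see the methods vignette);
- **pooling**: pre-capture volume fractions proportional to
  `1 / (target_content × molarity)`, equalizing expected on-target
  molecules across libraries of unequal quality;
- **haplotype network**: pairwise differences over complete alignment
  columns and a minimum spanning network whose largest edge defines the
  deepest (matriline) split;
- **synthetic data**: a generator that emulates the whole experiment —
  ancestor, descendant with a controlled 0–27% (mean 12%) divergence
  track, lognormal 70 ± 25 bp fragments (≥ 30 bp), 5' C→T deamination,
  logistic capture retention, PCR duplicates — with full ground truth.

## Worked example

The whole study analog runs from one configuration object:

```r
library(anccap)
report <- run_capture_study(default_config(seed = 42))
print(report)
```

```
<run_report>
Per-library recovery:
 sample_id    mode n_reads n_unique n_duplicates fraction_at_min_depth
   capture capture   17947    15256         2691             0.9989091
   shotgun shotgun   23566    19914         3652             0.9996970
 mean_depth
   65.85018
   84.74158

Windows: 432 (0 gap-flagged); divergence mean 0.123, max 0.367
<capture_fit> id_50 = 0.801, slope = 37.2, amplitude = 0.95 (23 support points)
  id_50 CI [0.797, 0.805], slope CI [33.1, 43.2]
Matriline split (104 differences): {PL01,PL02,PL03,PL04} | {PL05,PL06,PL07,PL08}
```

Reading this: 20,000 simulated capture fragments yielded 17,947 reads
(15% PCR duplication), of which 15,256 were unique after
joint-fragment-end deduplication; 99.9% of the 16.5 kb genome was
recovered at ≥ 3x with mean depth 66x. The 432 gap-free 60 bp windows of
the 2–15 kb region average 12.3% divergence from the bait source. The
read-level fit recovers the simulated retention curve — truth
`id_50 = 0.80`, `slope = 40`, `p_max = 0.95` — as 0.801 / 37.2 / 0.95,
with the bootstrap interval covering the truth. The eight simulated
samples split into their two matrilines at a 104-difference edge.

Individual steps are plain functions on plain data: `design_baits()`,
`read_sam()` / `write_sam()`, `filter_mapq()`,
`mark_duplicates_start_end()`, `pileup()`, `call_consensus()`,
`completeness()`, `screen_stop_codons()`, `window_identity()`,
`window_depth()`, `divergence_response()`, `fit_capture_model_reads()`,
`plan_pool()`, `haplotype_network()`. A thin command-line interface
(`inst/exec/anccap`) wraps the file-to-file steps:

```sh
anccap run --config inst/extdata/example_config.yaml --out runs/demo
anccap pool-plan --table inst/extdata/example_pool.tsv --out plan.tsv
```

## Documentation

The methods vignette
(`vignettes/ancestral-capture-methods.Rmd`) describes the generative
model and its assumptions, every tunable parameter with its default and
rationale, the two capture-model estimators and why the window-ratio one
is attenuated, numerical corner cases, and what the synthetic tests do
and do not establish about real capture data.
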