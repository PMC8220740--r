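---
title: "Models and methods behind srnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srnakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnakit)
```

`srnakit` packages three connected analyses: calibration of short-RNA
quantification against an equimolar reference pool, discovery and
classification of bacterial small non-coding RNAs (sRNAs) from
strand-specific coverage, and a logistic model of structure-dependent
capture bias. This vignette explains each model, the parameters that
matter, and the design choices that were genuinely open.

## Coordinate and sequence conventions

All internal coordinates are 0-based half-open; GFF3 on disk is 1-based
inclusive and BED 0-based half-open, with conversion confined to the
readers/writers. A single convention applied everywhere is the cheapest
insurance against silent off-by-one errors in boundary statistics that are
sensitive at the 2-nt scale. Genomic sequences are DNA (`U` normalized to
`T` at parse time; `N` allowed but excluded from GC statistics); reads and
reference species tolerate RNA alphabet on input. Circular contigs wrap:
intervals crossing the origin are stored with `end > length` and all
overlap and coverage arithmetic is performed modulo the genome length.

## Equimolar pool quantification

The reference pool emulates a commercial equimolar calibration standard:
1005 species of 16–28 nt. Quantification is deliberately exact-match only:

1. **Read filtering** (`preprocess_reads`): drop reads < 10 nt, reads with
   `N`, and reads without a 3' adapter; collapse to one record per
   distinct sequence (dedup); keep lengths 15–34 nt. Raw multiplicities
   are retained in a `raw_count` side channel. Collapsed counts equal
   molecule counts only when reads carry unique molecular identifiers; the
   synthetic reads here do not, so the calibration statistics below use
   the raw-multiplicity channel.
2. **Cropped references** (`build_cropped_reference`): at crop level
   *x* ∈ 0..5 each species is truncated by *x* 3'-terminal nt; cropped
   sequences colliding between species are excluded at that level, so
   surviving entries map one-to-one to species.
3. **Counting** (`count_exact`): each read is assigned at the *smallest*
   level at which it exactly equals a library entry. Smallest-level
   assignment makes the levels nested and each read count unambiguous;
   no mismatches are tolerated anywhere.
4. **Detection and deviation**: the detected fraction at level *x* uses
   counts cumulated over levels ≤ *x* against a CPM threshold (default
   1 CPM; CPM is count / total assigned × 10⁶ — a single-sample pipeline,
   so no between-sample normalization applies). Fold deviation compares
   each species' share with 1/1005; |log2| ≤ 1 (two-fold) counts as
   unbiased, among species meeting the ≥ 1 CPM inclusion rule in every
   library supplied.

`positional_deviation` contrasts base frequencies over the 16 3'-terminal
positions of a (count-weighted) read subset against the unweighted pool
background; the four per-position deviations sum to zero by construction.
`demux_adapter_variants` ranks 3-base adapter variant tags by read count
(ties lexicographic, for determinism) and reports an unweighted position
frequency matrix over the top k (default 30), as for a sequence logo.

## sRNA discovery from coverage

The discovery pipeline assumes strand-specific per-base coverage from ≥ 1
replicates per library on one (usually circular) genome.

* **Segmentation** (`segment_coverage`) is plumbing, not a contribution: a
  maximal-run detector on the replicate-**mean** depth with threshold
  `min_cov` (default 5), allowing internal sub-threshold gaps ≤ `max_gap`
  nt (default 5), trimmed to threshold-meeting boundary positions and
  filtered to 50–500 nt (the size selection of bacterial sRNA libraries).
  The mean (rather than the sum) across replicates is the package's
  definition of "pooled" depth: with background coverage ~1 per replicate,
  a summed threshold of 5 would qualify ~18% of pure-background positions
  and erode candidate boundaries, while the replicate-mean keeps the
  background qualification probability below 10⁻⁶ and boundary detection
  exact.
* **Boundary crosscheck** (`boundary_ratios`, `refine_candidates`) is the
  scientific filter: a genuine transcript edge shows a coverage step, so
  we require `r = (mean depth over w positions inside + 0.5) /
  (mean depth over w positions outside + 0.5) ≥ t` at **both** ends, with
  w = 2 nt and t = 3, in at least one replicate. The symmetric 0.5
  pseudocount keeps the ratio defined over zero background (anything with
  inside depth ≥ 2 passes over empty background) and monotone in the
  inside depth. Two readings of the replicate rule exist; the default
  demands both ends pass *within the same replicate*, the per-end
  independent alternative is available via `same_replicate = FALSE`. The
  threshold is ≥ 3 ("less than three-fold" being the filter-out rule);
  both t and w are configurable.
* **Merging** (`merge_across_libraries`): same-strand candidates whose 5'
  ends and 3' ends each differ by ≤ δ nt (default 5) are grouped
  transitively and replaced by their widest extent; contributing libraries
  are recorded, which yields the shared/unique (Venn) tallies. δ = 5 was
  chosen to cover the 1–2 nt end heterogeneity typical between library
  chemistries with margin.
* **Counting and retention** (`count_features`, `tmm_factors`,
  `cpm_filter`): a fragment counts toward every same-strand candidate it
  overlaps by ≥ 1 nt (configurable to unique-only). TMM normalization is
  computed from the published definition — upper-quartile-based reference
  selection, pairwise zero removal, 30%/5% two-sided trims on M/A values,
  inverse-asymptotic-variance weights, geometric-mean rescaling — and is
  verified in the tests against an independent implementation to 1e-10.
  Because the weights depend on absolute counts, scaling one sample
  changes its factor slightly (far less than the scale itself, which the
  library size absorbs); this matches the canonical implementation's
  behaviour. Candidates need mean CPM ≥ 15 (inclusive) in at least one
  library to survive.

## Genomic-context classification

Bacterial annotations rarely include UTRs, so UTR-derived context is
approximated by windows: `u5` nt upstream of each CDS start and `u3` nt
downstream of each CDS end on the CDS strand (defaults 150 nt each),
truncated at the first base of any annotated CDS and wrapping across the
origin. A label fires when ≥ `min_frac` (default 0.5) of the sRNA's length
overlaps the corresponding region set — same-strand 5'/3' UTR windows
(utr5/utr3), same-strand CDS (intragenic), opposite-strand CDS including
its UTR windows (antisense). Zero labels give intergenic, one gives that
class, two or more give mixed with the constituents recorded. The window
lengths and the half-length threshold are declared package defaults, not
reproductions of any published rule; both are prominent arguments.
Counting opposite-strand UTR windows toward antisense mirrors how mixed
classes such as "3'UTR-derived/antisense" arise in practice and can be
switched off.

GC skew `(G − C)/(G + C)` is computed over 10,000-nt windows every 200 nt
(both configurable), with `N` positions excluded and windows without G/C
yielding `NA`. Replication origin and terminus are located at the global
minimum and maximum of the per-base cumulative skew — the standard
replichore construction — unless explicit hints are stored on the genome
record, which take precedence. A forward-strand feature is *leading* when
its midpoint lies on the origin→terminus arc; a reverse-strand feature on
the complementary arc.

## Structure features and the capture-bias model

The default folding engine maximizes base pairs (Watson–Crick + G·U,
nested structures, minimum hairpin loop 3 nt) by dynamic programming in
C++, with a deterministic traceback (a position is left unpaired whenever
optimal, else paired with its leftmost admissible partner) so pairing
strings are reproducible across platforms. The score is
`mfe_score = −pair_count`, a stability *proxy* on an arbitrary scale; a
thermodynamic folder returning dot-bracket + energy can be plugged in via
the `engine` argument and its energy is then used directly. The second
feature, `tail3_len`, is the run of unpaired positions at the 3' end — the
stretch accessible to 3'-acting enzymes.

The capture model is logistic in these two features and acts on *species*,
not individual reads: ligation bias depletes whole species from a library.
`logistic_compare` inverts the model: it fits group membership (A vs B) on
`mfe_score` and `tail3_len` by glm/IRLS (tolerance 1e-8, ≤ 100
iterations), reports Wald tests (a likelihood-ratio test would also be
defensible; Wald matches common logistic output and is deterministic), and
refuses to report p-values under complete or quasi-complete separation
(fitted probabilities pinned at 0/1 or runaway slopes) rather than
returning inflated estimates. Constant features are refused by name.

In the recovery simulations, capture probabilities under the reference
coefficients (0, −0.8, +0.5) sit close to 1 for most random species
(−0.8 × score is non-negative), so dropped species are rare; the simulator
therefore folds species in batches and takes the first *n* captured and
*n* dropped — case-control sampling, which leaves the slope estimates
consistent and shifts only the intercept.

## The synthetic-data generators

The generators define the package's reference study conditions and are
deterministic under a master seed, split into independent substreams per
entity (genome, truth set, each library × replicate) so adding a replicate
never perturbs earlier draws.

* `make_genome`: circular chromosome with origin at 0 and terminus at
  L/2; G-vs-C composition skewed by `skew_strength` on the leading strand
  and 72% of CDSs placed leading — the co-orientation bias typical of
  bacterial chromosomes. CDSs are non-overlapping; packing failure raises
  an error rather than silently overlapping.
* `plant_srnas`: sRNAs of the six context classes, each verified against
  the package's own classifier under the same settings (generator and
  classifier are contractually consistent); planted intergenic sRNAs carry
  strictly zero annotation overlap. Same-strand clearance of 30 nt keeps
  segmentation from fusing neighbours. Abundances are log-normal
  (meanlog 0, sdlog 0.25 — mild, realistic spread that keeps every planted
  sRNA comfortably above the CPM filter at the default depth).
* `simulate_coverage`: each sRNA emits Poisson(depth × abundance)
  fragments per replicate. *Sharp* sRNAs produce fragments spanning
  exactly their interval, so coverage steps at the boundaries; *ramped*
  decoys displace both fragment ends symmetrically by signed geometric
  amounts (scale 15 nt), producing a gradual rise with no step anywhere —
  the negative control the ≥ 3× filter must reject. Background is modeled
  as random fragments (geometric lengths, mean 75 nt) at a rate giving
  mean per-base coverage `background_rate`; modeling background as
  fragments (rather than independent per-position noise) is what mapped
  libraries actually look like and supplies the fragment table that
  overlap counting consumes.
* `simulate_mirna_pool` / `simulate_mirna_reads`: unique species,
  multinomial reads over (species × crop) cells. Default 3'-truncation
  probabilities (0.90, 0.06, 0.02, 0.01, 0.005, 0.005) keep > 90% of
  reads full length — a qualitatively realistic regime, not a claim about
  any particular chemistry. Capture bias, when enabled, reweights species
  by their capture probability.

The reference study (`simulate_srna_study`) uses an 80 kb genome with 60
CDSs, 30 sharp + 10 ramped sRNAs, fragment depth 50, background 1,
3 replicates × 2 libraries — sizes chosen so the full pipeline runs in
about a second while every stage still has realistic structure. What the
generator does **not** emulate: sequencing errors and quality scores, PCR
duplicate families, transcription start/stop heterogeneity beyond the
ramp model, overlapping genes, multi-contig genomes, and RNA
modifications. Passing the end-to-end tests therefore demonstrates the
pipeline's correctness on data satisfying its assumptions, not robustness
to every artefact of real libraries.

## Numerical and degenerate-input choices

* Boundary ratios use a symmetric 0.5 pseudocount; candidates shorter than
  the window raise an error.
* Ties in adapter-variant ranking are lexicographic; ties in folding
  traceback are fixed (leftmost partner); both for byte-reproducibility.
* Windows with no G/C give `NA` skew; flat cumulative skew raises an error
  advising explicit origin/terminus hints.
* Zero-count species are excluded from fold deviation and reported;
  an empty read set after filtering is a warning, not an error.
* All-zero samples are refused by TMM with the sample named.

## Limitations

Exact matching cannot credit reads with internal errors to their species;
the folding proxy scores pairs, not free energy, so its absolute scale is
not comparable to thermodynamic predictions (use the `engine` hook for
that); the segmentation detector is intentionally simple and is not a
reimplementation of any published sRNA caller; and the UTR windows are
fixed-length approximations, so UTR-derived/antisense proportions depend
on `u5`/`u3`/`min_frac` and should be read comparatively, not absolutely.
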