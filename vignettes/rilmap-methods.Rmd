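---
title: "Methods: RAD-seq linkage mapping of recombinant inbred lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RAD-seq linkage mapping of recombinant inbred lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilmap)
```

`rilmap` reconstructs, as one tested toolchain, the computational path from
raw reduced-representation sequencing reads of a biparental F8 recombinant
inbred line (RIL) population to a sequence-defined genetic linkage map, with
genome-survey statistics from k-mer histograms, anchoring of assembly
scaffolds onto the map, and co-segregation scanning for markers tied to
binary monogenic traits. The motivating setting is a legume crop cross
(two homozygous domesticated cultivars, 94 F8 RILs genotyped by EcoRI
RAD-seq), but every stage is generic. Because no raw read set of that kind
is publicly available at desk scale, the package carries a meiosis-level
simulator whose outputs have known ground truth; all recovery claims below
are made against that truth.

## The population and sequencing model

**Founders and cross design.** Two fully homozygous founders, A and B,
differ by SNPs and short (1–10 bp) indels. An F1 is selfed and advanced by
single seed descent; generation g has undergone g − 1 meioses from the F1,
so expected residual heterozygosity at F8 is (1/2)^7 ≈ 0.78%. The simulator
does not force heterozygosity to zero: the genotype caller's heterozygous
path is exercised by design.

**Meiosis.** Crossovers per chromosome are Poisson with mean L/100 for a
chromosome of genetic length L cM, with breakpoints uniform in genetic
coordinates and no interference — the Haldane model. This matches the
mapping theory used downstream and keeps closed-form oracles available: the
single-meiosis recombinant fraction over d cM is r = (1 − e^(−2d/100))/2,
and the asymptotic selfing-RIL recombinant fraction is R = 2r/(1 + 2r)
(Haldane–Waddington). Physical position maps linearly to genetic position
within a chromosome.

**RAD libraries.** For every occurrence of the recognition site
(EcoRI, `G/AATTC`), 100-bp reads are emitted from both flanks starting at
the cut site: an 8-nt inline barcode followed by the 92-bp tag. Both-flank
emission is the standard RAD geometry and is assumed here. Depth is drawn
per (site, flank) — Poisson by default, fixed for exact tests — and reads
are split evenly between haplotypes, so a heterozygous site yields both
parental tags at roughly half depth each. Substitution errors are applied
per tag base at a configurable rate (≤ 5%); barcodes are error-free by
default, since demultiplexing is exact-match, and a barcode-error option
exists solely to exercise the unassigned-read sink.

What the generator does *not* emulate: paired-end libraries, fragment-size
selection, PCR duplicates, quality-score structure (a fixed Q35 placeholder
is written), or sequence-composition biases. Tests that pass on this
simulator therefore validate the algorithmic path, not robustness to every
artefact of real libraries.

## Genome survey from k-mer histograms

`count_kmers()` builds a canonical k-mer depth histogram (k = 17 by
default; 2-bit rolling encoding, lexicographic minimum of the two strands,
windows with non-ACGT skipped). The survey statistics follow the standard
model: the histogram volume (total k-mer instances, the "K-number") divided
by the modal depth of the single-copy peak estimates genome size; total
sequenced bases over genome size gives coverage. The error bump at low
depth is excluded by a `min_peak_depth` of 4; ties between adjacent depths
resolve to the smaller depth, documented behaviour rather than an accident
of `which.max`. The share of k-mer volume at or above twice the peak depth
is reported as a repeat-volume statistic. We deliberately do not convert it
into a repeat *genome fraction*: no formula in the source material connects
the two, so the package exposes the raw volume shares only.

## Marker discovery and genotyping

Reads demultiplex by exact barcode prefix; one mismatch routes a read to
the unassigned sink (counted, never silently dropped). Within each sample,
identical 92-bp tags cluster by identity — sequencing errors stay in
separate, typically singleton, tags rather than being corrected. Tags with
more than 100 reads are removed as collapsed repeats; the boundary is
deliberately "more than" (100 kept, 101 removed).

Marker calling compares the two parents' tag sets. Monomorphic tags
(identical across parents) are discarded outright. A SNP marker requires a
cross-parent tag pair at Hamming distance exactly 1 that is unique in both
directions; an indel marker requires a unique pair aligning with a single
1–10 bp gap and zero mismatches. Any tag with two or more candidate
partners is discarded — the conservative choice that avoids collapsing
paralogues into false markers. Each parental tag must reach a minimum
depth (default 3). RIL genotypes then follow a depth rule per marker:
only tag A at depth ≥ 3 codes `A`; only tag B codes `B`; both code `H`;
anything else is missing. The defaults are declared choices for
low-coverage RAD practice; the source protocol states no thresholds.

One detectability limit is built into the simulator on purpose: an indel
whose anchor sits within ~11 bp of the end of a tag window leaves no
aligned suffix inside the 92-bp tag, so no single-gap aligner can
distinguish it from a terminal substitution. When variants are placed into
tag windows explicitly, indels are kept at least 12 bp inside their window
(gap ≤ 10 plus an anchor base); a variant drawn closer to the edge becomes
a SNP instead.

## Linkage map construction

`ril_map()` is the package's central estimator and returns a classed object
with `print`, `summary` and `plot` methods.

**Two-point estimates.** For each marker pair, over RILs with both calls in
{A, B}: k discordant calls out of n informative gives R̂ = k/n. Residual
heterozygotes are treated as missing — the F8 analysis is two-class, and
the recombinant status of an `H` call is ambiguous. The meiotic fraction is
recovered by inverting the Haldane–Waddington relation, r = R̂/(2(1 − R̂)),
clamped to [0, 0.5]. This uses the RIL-∞ limit; the exact F8 correction is
slightly smaller, a documented approximation gap whose practical effect at
94 RILs is within the noise of R̂ itself (the simulator tests allow for
it explicitly). The LOD score is k·log10(R̂/0.5) + (n − k)·log10((1 − R̂)/0.5),
with the k = 0 limit n·log10 2. Pairs with fewer than 10 informative RILs
are marked uninformative and excluded from grouping.

**Grouping.** Single-linkage components at LOD > 6 form the initial
stringent partition. While the component count exceeds the target (20, the
haploid chromosome number in the motivating species), the threshold drops
in 0.5 steps to a floor of 3, and at each step only merges that attach a
*small* group (< 5% of markers) to another are allowed. Two established
large groups never fuse during relaxation — that mirrors the published
protocol of distributing small groups into large ones, and the 0.5 step and
5% bound are implementation choices where the protocol says only
"gradually reducing". Failure to reach the target count is reported, not
fatal.

**Ordering.** Within each group the order minimises COUNT — the sum of
observed recombination events between adjacent markers, with uninformative
cells imputed as zero. The search is randomised greedy insertion, a window
ripple of sizes 2 and 3, then a 2-opt/relocation polish and a final ripple,
over 10 seeded restarts (25 for groups of ≤ 10 markers, where restarts are
cheap and the space is small); every third restart starts from a pure
random order to diversify the basins reached. The polish step goes beyond
plain insertion-plus-ripple because random small instances occasionally
have local optima that windows of size ≤ 3 cannot escape; with it, the
search attains the exhaustive-permutation minimum on all random instances
of ≤ 7 markers we test (1,000 trials). An order and its reversal have equal
COUNT; the orientation with the lexicographically smaller terminal marker
id is returned, and two-marker ties resolve the same way.

**Loci and positions.** Consecutive markers with zero observed recombinants
collapse into one locus named for its first member. Positions are
cumulative mapping-function distances between the first members of adjacent
loci. Kosambi is the default — the de facto standard for legume RIL maps of
this era — with Haldane selectable; the source never names its function.
Adjacent loci at r = 0.5 would be infinitely distant; such intervals are
capped at 50 cM and flagged. Intervals longer than 20 cM are reported as
map gaps by `find_gaps()`. Groups are named `SLG-1`, `SLG-2`, … by
decreasing genetic length, and `summary()` produces the per-group table
(markers, loci, length, anchored scaffolds and span) with exact column
totals, marker density per cM, and markers per locus.

## Scaffold anchoring and trait scans

A marker anchors to a scaffold only when its reference (parent A) tag has
exactly one full-length, exact match site across all scaffolds, on either
strand. "100% match" is interpreted strictly — full tag length, no gaps or
mismatches — which is more conservative than a local aligner's 100%
identity and fully deterministic. Multiple hits on one scaffold are
rejected just like hits on two scaffolds (the source does not say how such
markers were treated; we reject them). SNP anchors record the 1-based
forward-strand coordinate of the SNP site itself; indel anchors record the
tag start. Scaffolds whose markers land in two or more linkage groups are
reported as conflicts and excluded from per-group counts and spans.

A binary trait is treated as one extra two-class marker: the donor parent's
phenotype class maps to its allele (F8 phenotypes are taken as homozygous
classes; dominance is out of scope and documented as such). The trait is
placed on the group of its highest-LOD marker at the locus of its nearest
marker, markers within 5 cM (configurable) form the linked set, markers
with zero recombinants form the co-segregating set, and distinct anchored
scaffolds carrying co-segregating markers are the candidates. An external
genotype–phenotype panel can be cross-tabulated with
`validate_panel()`, excluding and counting missing genotypes.

## Numerical and design choices, in brief

- Variant placement keeps ≥ 92 bp between variants by default (one variant
  per tag window); a flag permits multi-variant tags to exercise the
  caller's ambiguity rejection.
- The spaced-position sampler accumulates uniform draws and keeps an
  earliest-first maximal spaced subset, so placements are unbiased along
  the chromosome.
- All randomness flows from user-supplied seeds; identical configuration
  and seed reproduce byte-identical FASTQ, tables and maps.
- Depth distributions: Poisson for realism, `"fixed"` for exact
  construction tests.
- k-mer counting is in-memory with a 2-bit encoding; the scale target is
  desk-size simulation studies, not full crop-genome read sets.
- CSV with headers for every table; FASTA/FASTQ through Biostrings.

## Problem sizes used in the shipped checks

The package's own verification uses: a 5-chromosome, 500-marker, 94-RIL
simulation for map recovery (grouping purity, per-group Kendall tau against
the true physical order, total length against simulated truth); 1,000
random ≤ 7-marker instances against an exhaustive-permutation COUNT oracle;
analytic round trips of the Haldane–Waddington correction and the mapping
functions; ~40 unlinked-site chromosomes × 150–200 RILs for the F8
heterozygosity check; and an error-free two-chromosome RAD run (26
variants, 94 RILs) for end-to-end truth recovery including the causal-
scaffold trait scan. These sizes were chosen as the smallest at which the
statistical checks have useful power.

## Known limitations

- The RIL-∞ Haldane–Waddington correction slightly overstates map length
  at F8 relative to the exact finite-generation correction.
- Kosambi positioning of data simulated without interference compresses
  long intervals relative to Haldane; recovered total lengths sit a few
  percent below simulated truth, well inside the tolerances tested.
- Identity clustering never merges error reads into their source tag, so
  per-tag depth is split at high error rates; the default error rate
  (0.1%) makes this negligible.
- The grouping relaxation can leave more groups than chromosomes when
  marker density is low relative to chromosome length (adjacent-marker LOD
  below the floor); this is reported rather than hidden.
- Candidate-scaffold annotation is a slot for external tools; gene
  prediction is not reimplemented.
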