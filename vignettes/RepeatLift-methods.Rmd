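---
title: "RepeatLift: methods and design notes"
author: "RepeatLift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RepeatLift: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what RepeatLift computes, the assumptions behind it,
and the design decisions that were genuinely open — the things a maintainer
or a careful user would want written down.

## The problem

KRAB zinc finger proteins (ZNFs) silence transposable elements, and young
repeat families (the LINE-1 member L1HS is the canonical case) are so
recently expanded that their genomic copies are nearly identical. ChIP-seq
or ChIP-exo reads from inside such repeats align to many loci at once;
per-locus signal is undefined, and pipelines that drop or randomly place
multi-mappers produce coverage holes exactly over the binding sites.

The resolution is to change coordinate systems. Every genomic copy of a
repeat carries a pairwise alignment to the family's *consensus* sequence
(RepeatMasker emits these in its `.align` output). Composing a read's
genomic position with that alignment sends the read to a position on the
consensus — the same position for every copy the read could have come from.
On consensus coordinates, multi-mapping is not a bug but the point: the
signal is interpreted as the *average* occupancy over all instances of the
family.

## Coordinate machinery

### Chains from RepeatMasker alignments

Each `.align` record is converted to a UCSC-format chain whose target is
the genome (forward strand) and whose query is the consensus. The
conversion scans aligned columns: columns with a base on both sides extend
the current block — substitutions deliberately stay *inside* blocks, as in
liftOver — while a gap in the consensus contributes target-only bases
(`dt`) and a gap in the genome contributes query-only bases (`dq`).
Adjacent blocks are merged canonically, so a given alignment has exactly
one serialization and chain files are byte-reproducible. For instances on
the minus strand the aligned columns are walked in reverse so that blocks
advance along the forward genomic strand, and query coordinates are
expressed in the reversed-strand frame as the UCSC chain spec requires.
The test suite verifies that files written this way are consumed
identically by `rtracklayer::liftOver`, an independent implementation of
chain lifting.

Building chains *directly* from the `.align` file (rather than re-aligning
instances with some other aligner) is what keeps consensus coordinates
consistent with the consensus sequences the annotation was made against.

One chain is emitted per `.align` record. Fragmented elements (one
instance split across several records) are not stitched: no stitching rule
is defined by the annotation itself, and the record id preserves the
correspondence for users who need it.

### Coordinate conventions

All in-memory coordinates are 1-based inclusive, the IRanges/GRanges
convention — one convention everywhere eliminates the classic
off-by-one errors of mixing genomic and consensus frames. The three file
conventions involved (RepeatMasker: 1-based inclusive; UCSC chain: 0-based
half-open; BED/bedGraph: 0-based half-open) are converted exactly once, at
their I/O boundary.

### liftIn

`liftIntervals()` maps a genomic interval piecewise through every
overlapping chain: each intersection with a block maps linearly; pieces of
one chain that abut on the consensus (i.e. are separated only by a
genomic insertion) are merged; bases inside `dt` gaps map nowhere. Reads
are lifted as full intervals — not 5′ ends or midpoints — and coverage is
computed from the mapped pieces, so no minimum-match threshold is needed
and the accounting is exact: the mapped length of a read never exceeds the
read length, with equality exactly when the read crosses no gap.

**Deduplication.** A multi-mapping read appears as several BED records
sharing a name. After lifting, all segments sharing (read id, consensus
name) are reduced to the segments of a single chain, so each read counts
at most once per consensus regardless of copy number. The winning chain is
the one whose lifted segment starts at the smallest forward consensus
position, with ties broken by genomic chromosome, genomic start, and chain
id — deterministic and independent of input order. When the copies are
exact, every candidate gives the same consensus interval and the rule is
invisible; it only matters for diverged copies, where the choice shifts a
segment by at most the local indel offsets. Note one nuance: a read whose
interval crosses a genomic-insertion gap legitimately lifts to more than
one piece *through the same chain*; those pieces are all kept, because
discarding them would silently delete mapped bases. A read overlapping two
different consensus names contributes once to each; this is a deliberate
sensitivity choice and is visible in the output via the `qName` of each
segment.

### liftOut

For a locus (repeat, start, end) on the consensus, `liftOut()` inverts the
per-record alignment map. Instances whose alignment only partially covers
the locus are skipped and counted. By default instances with an indel
inside the locus are also skipped (and counted), because downstream
PFM/PEM arithmetic assumes a fixed site length; with `allowIndel = TRUE`
they are emitted at the locus length with deleted positions as `-` and
genomic insertions dropped. Indel-free sites are fetched from the genome
sequence itself (not reconstructed from the alignment strings), so the
returned sequence is guaranteed to equal the genome, reverse-complemented
for minus-strand instances so all sites read in consensus orientation.

## Signal: Fold Change over Control

Coverage is aggregated in non-overlapping windows anchored at consensus
position 1 (window size `w`, default 10 nt — fine enough to resolve a
zinc-finger footprint, coarse enough to pool reads; the trailing partial
window is kept). For window $k$:

$$\mathrm{fcc}_k=\frac{(\mathrm{chip}_k+\alpha)/N_\mathrm{chip}}{(\mathrm{input}_k+\alpha)/N_\mathrm{input}}$$

* $N$ are **total library sizes before lifting**. Normalizing by lifted
  read counts instead would erase exactly the family-level enrichment the
  method is meant to compare across families. The trade-off is a mild
  compression of the ratio when the enriched loci hold a non-negligible
  share of the ChIP library; on toy genomes that are mostly repeat this is
  visible (see the README example), at realistic proportions it is a
  few-percent effect.
* $\alpha$ (default 1) guards small windows against zero-input artifacts;
  $\alpha = 0$ is supported and used by the identity tests (identical
  libraries then give fcc exactly 1 wherever input is covered). With
  $\alpha = 0$ a zero-input window gets `NA` and a flag — never a silent
  infinity.
* Windows with input coverage below `minInput` (default 5) are flagged
  low-confidence and listed in the bedGraph's companion mask file.

Under this definition fcc is exactly invariant to duplicating both
libraries, monotone in chip counts, antitone in input counts, and — the
property that makes cross-family comparison meaningful — invariant to the
repeat's copy number at a fixed per-instance ChIP:input ratio.

Per-strand tracks can be formed by partitioning lifted segments on the
`readStrand` column before `consensusCoverage()`; the default track pools
both strands.

## Binding models

A **PFM** is built from a lifted-out site set as
$f(b,i) = (\mathrm{count}(b,i)+\beta)/(n_i+4\beta)$, where $n_i$ counts
non-N observations at position $i$: N bases are excluded from both
numerator and denominator rather than imputed, so they cannot bias the
frequency estimates that get compared across subfamilies. $\beta$ defaults
to 0 (the matrices describe the sites, not a smoothed model); any
$\beta > 0$ moves frequencies strictly toward 0.25 without reordering
bases.

A **PEM** stores additive energy contributions $\epsilon(b,i)$ in kT,
lower = stronger. Site energy is the exact positional sum; sequences must
match the matrix length and contain no N (no implicit trimming or
imputation — a site that cannot be scored is reported as excluded).
Matrices are stored as given: thresholds such as −4.5 kT are meaningful on
the matrix's own scale, so no re-anchoring is ever applied implicitly
(`reanchorPEM()` exists for users who want per-position minima at zero).
`scanConsensus()` is the only double-stranded operation — lifted-out sites
are already in consensus orientation — and breaks exact ties by smallest
forward offset, then plus strand.

## The simulator: what it emulates, what it does not

`simulateRepeatGenome()` plants independently mutated copies of a
consensus on one synthetic chromosome: per-base substitutions at
`subRate`, indel events at `indelRate` with geometric lengths (mean 2 nt,
never touching instance ends so the alignment bookkeeping stays exact), a
fraction of instances reverse-complemented, and a fraction 5′-truncated
(as real LINE-1 copies overwhelmingly are). The emitted `.align`/`.out`
files agree with the in-memory truth by construction — that is the
property every round-trip test leans on.

`simulateReads()` draws input reads uniformly at a chosen per-base depth
and ChIP reads as the same background plus extra reads, at
`enrichment − 1` times the local background rate, over each genomic
projection of the planted locus, so the expected ChIP:input coverage ratio
at the locus is the planted `r` and 1 elsewhere. Read names are unique and
library totals are returned.

Defaults reflect the biology the package targets: substitution rates of
5–10% and indel rates of 1–2% bracket the divergence of mid-age LINE-1
subfamilies from their consensus; 36-nt single-end reads match
ChIP-exo-era read lengths; 20-nt loci match a long-ZNF footprint; planted
enrichments of 6–8 match the strongest fold changes such experiments
report.

Deliberately **not** modeled: a realistic LINE-1 phylogeny (instances
mutate independently, real copies share derivation history), sequencing
errors, fragment-length/paired-end structure, mappability bias, and
chromatin-driven nonuniform input. Consequently, passing tests demonstrate
the *coordinate algebra, normalization and scoring* are exact and the
statistical recovery works under clean assumptions — they do not
demonstrate robustness to correlated divergence or experimental artifacts
in real libraries.

## Numerical and degenerate-input choices

* PFM column sums are validated to 1 ± 1e-9; energies must be finite.
* Alignments must begin and end on aligned columns (RepeatMasker's do);
  both-gap columns are structural errors, as is any mismatch between
  aligned base counts and header spans — parsing fails loudly with the
  record id rather than propagating shifted coordinates.
* Chain parsing re-verifies the span equations
  ($\sum \mathrm{size} + \sum dt = t$-span, $\sum\mathrm{size} + \sum dq =
  q$-span) for every chain and names the offending chain id.
* Empty results are valid where the science says so (a read overlapping no
  chain, a peak near no repeat); errors are reserved for contract
  violations (unknown repeat name, zero scoreable sites, a lifted segment
  outside the consensus — which can only mean a corrupt chain).
* Peak annotation assigns the instance with maximal overlap, ties broken
  by distance, repeat name, then position, making the result invariant to
  instance order; `within`/`near`/`none` partition the peaks with `near`
  bounded by an explicit, user-visible `maxDist` (default 500 bp —
  ChIP-exo footprints are narrow, but summit-to-boundary offsets of a few
  hundred bp are routine).

## Problem sizes

The test suite and `scripts/acceptance.R` run entirely on simulated data
sized for a single CPU: oracle comparisons on 100 alignments of a 300-nt
consensus at substitution rate up to 0.3 and indel rate 0.05 on both
strands; enrichment recovery on a 2-kb consensus with 20 and 40 instances
at 50× depth (roughly 0.9 M reads across the four libraries); and an
end-to-end run on a ~2 Mb genome with 200 instances of a 6-kb consensus at
2× depth, which also exercises the shell interface. These sizes were
chosen to make the stochastic checks statistically comfortable (window
counts in the thousands, so Poisson noise is ≪ the tolerance bands) while
keeping the whole suite in minutes.

## Known limitations

* One chain per `.align` record; no stitching of fragmented instances.
* `.align` naming (grouped ORF-region consensus names) and `.out` naming
  (per-subfamily) differ in real RepeatMasker output; the package keeps
  both verbatim and does not attempt to reconcile them — a mapping between
  the two schemes is user-supplied knowledge.
* Ambiguity codes other than N are rejected rather than translated.
* BAM input is out of scope; reads enter as BED intervals (convert
  upstream with, e.g., `bedtools bamtobed`).
* No peak calling or significance testing on consensus tracks: F.C.C. is
  a ratio estimate, and its interpretation is the mean occupancy over
  instances, not a per-locus claim.
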