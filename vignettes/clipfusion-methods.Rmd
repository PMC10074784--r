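---
title: "ClipFusion: soft-clip evidence for EML4-ALK detection in liquid biopsies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ClipFusion: soft-clip evidence for EML4-ALK detection in liquid biopsies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClipFusion)
```

## The problem

EML4-ALK gene fusions drive a subset of non-small cell lung cancers and are
targetable with ALK tyrosine-kinase inhibitors. In plasma, circulating
tumor DNA (ctDNA) carrying the fusion is present as short cell-free DNA
(cfDNA) fragments of roughly 165 bp. Hybridization-capture panels that bait
*ALK* also pull down hybrid EML4-ALK fragments, so after 100 bp paired-end
sequencing the fusion leaves two characteristic footprints in the BAM:

1. **Discordant mates** — a read aligned inside the *EML4* gene body whose
   mate aligns inside *ALK* (the two genes are ~13 Mb apart on chr2, in
   opposite orientation, so a wild-type fragment essentially never does
   this).
2. **Soft-clipped junction reads** — a read crossing the genomic
   breakpoint aligns up to the *EML4* breakpoint, and the aligner stores
   the *ALK*-derived remainder as a terminal `S` (soft clip) operation in
   the CIGAR.

Commercial variant callers frequently miss low-burden fusion samples;
re-mining the aligned BAM for exactly these two footprints recovers them.
ClipFusion implements that procedure as a small, auditable library with a
command-line surface, plus a ground-truthed cfDNA read simulator so every
stage can be verified without access to patient data.

## The detection model

`detectFusion(bam, target)` composes four steps over a `FusionTarget`
(gene windows plus thresholds; `builtinTarget("EML4-ALK", "hg38")` uses
EML4 chr2:42,169,353-42,332,548 and ALK chr2:29,192,774-29,921,586):

1. **Region scan.** All records whose aligned span (CIGAR `M/D/N/=/X`)
   overlaps the 5' (EML4) window are streamed from the indexed BAM.
   The default record filter drops unmapped, mate-unmapped, secondary,
   supplementary, QC-fail and duplicate-flagged records: inputs are
   expected to be position-deduplicated, and duplicates or split-alignment
   artifacts must not inflate evidence counts. No mapping-quality cut is
   applied by default (`minMapq` exposes one). `chr2` / `2` header
   dialects are reconciled automatically.
2. **Mate filter.** Reads whose mate chromosome is the 3' (ALK) window
   chromosome and whose mate position lies inside the window (1-based,
   both bounds inclusive) are kept. `nPairs` counts *distinct read
   identifiers* among them, not records, so overlapping mates are never
   double-counted — the threshold is a per-fragment quantity.
3. **Soft-clip evidence.** Among the kept reads, every CIGAR containing
   `S` contributes one `ClipEvidence`. When both read ends are clipped the
   longer clip is used (junction clips dominate adapter/quality clips in
   length); equal lengths go to the right end, where junction clips sit in
   the canonical EML4(+)/ALK(-) geometry. The putative breakpoint is the
   reference coordinate of the aligned base adjacent to the used clip:
   `pos + reference_width - 1` for a right clip, `pos` for a left clip.
   Evidence whose breakpoint falls outside the 5' window is discarded.
4. **Verdict.** The sample is *positive* iff `nPairs >= minPairs` (default
   2) **and** `nClipReads >= minClipReads` (default 2). A negative call
   carries an empty evidence set and absent characterization fields, and
   is never an error.

Only 5'-window reads are scanned; the reciprocal scan (ALK-anchored reads
clipped into EML4) is deliberately out of scope to match the published
procedure this reimplements. Strand annotation on the windows is never
used by the detection logic.

### Breakpoint consensus and flanks

The breakpoint table tallies evidence breakpoints; the consensus is the
modal position with ties broken toward the smallest coordinate — a
documented, deterministic rule chosen because genuine junctions produce a
sharp mode while clip-length jitter is rare and symmetric.

The **5' flank** is a per-column majority consensus of the aligned bases
of consensus-supporting reads over reference positions
`[consensus - flankLen + 1, consensus]`. Insertions are skipped and
deletion gaps cast no vote; a column with no coverage or a tied vote
emits `N` rather than an IUPAC code, keeping the output directly usable
for (digital) PCR primer design.

The **3' flank** is the analogous consensus over the soft-clipped bases,
with columns walking away from the junction: right-end clips are read as
stored and left-end clips are reversed, because the junction-adjacent base
of a left clip is its *last* base — anchoring all clips at the junction is
what makes the columns comparable. The output is truncated at
`min(flankLen, longest supporting clip)`; clips shorter than a column
simply do not vote there. Bases are reported **as sequenced**: since EML4
and ALK lie on opposite genomic strands, the clipped bases are the reverse
complement of the ALK plus-strand reference. The JSON report carries an
explicit orientation note so downstream primer design is not misled.

### Breakpoint read depth

`breakpointDepth()` counts filter-passing records whose aligned span
covers the consensus position, where `M/D/=/X` count as covering (a
fragment with a small deletion still physically spans the locus) and `N`
skips do not. The depth is a surrogate for the ctDNA burden of the sample
and is the natural quantity to monitor across serial plasma draws.

### Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `minPairs` | 2 | read pairs | discordant-mate threshold for positivity |
| `minClipReads` | 2 | reads | soft-clipped junction-read threshold |
| `flankLen` | 20 | bp | reported consensus length per breakpoint side |
| `minMapq` | none | phred | optional mapping-quality cut on streamed reads |

The two thresholds of 2 are the published defaults of the procedure; a
single molecule of each evidence class is deliberately insufficient,
which is what yields the 100% specificity property below. `flankLen = 20`
is this package's choice (the published description does not state a
reported flank length); 20 bp per side is the scale primer design needs.

### hg19 coordinates

Only the hg38 windows are published. They coincide with the RefSeq
EML4/ALK gene spans on hg38, so the shipped hg19 windows are the
corresponding RefSeq gene spans on hg19 (EML4 chr2:42,396,490-42,559,688;
ALK chr2:29,415,640-30,144,432), marked as derived in
`inst/extdata/eml4_alk_hg19.json`. Any window set can be supplied through
`loadTargetConfig()`, which also enables other fusion pairs.

## The simulator

`simulateSample(SimConfig(...), prefix)` emulates the laboratory setting
end to end and writes a coordinate-sorted indexed BAM, the synthetic
window references as FASTA, and a ground-truth JSON:

* **References** are uniformly random A/C/G/T of the window widths,
  deterministic in the seed (one RNG stream per sample).
* **Fusion template**: 5' window sequence up to `breakpoint5p` joined to
  the reverse complement of the 3' window sequence up to `breakpoint3p`,
  modeling the EML4/ALK opposite-strand inversion.
* **Fragments**: lengths are normal with mean 165 bp and sd 10 bp — the
  cfDNA fragmentation peak and this package's dispersion choice —
  truncated to `[readLen/2, 2 * fragLenMean]` by clamping (one draw per
  fragment keeps the stream reproducible; at sd 10 the bounds are never
  reached in practice). Fusion fragment midpoints are uniform over a
  junction-centered span of `2 * fragLenMean`, so the expected
  junction-spanning fraction has a closed form that the tests check by
  exhaustive enumeration. Wild-type fragments are placed uniformly in
  each window at a count reaching `wildtypeDepth` sequenced-base coverage
  in expectation.
* **Oracle alignment**: the simulator is its own aligner, which removes
  nondeterministic third-party behaviour from the tests. Each fragment
  yields two 100 bp reads (the second sequenced as the reverse
  complement). Junction-spanning reads are anchored on the side with at
  least `minAnchor = 20` aligned bases (both or neither qualifying: the
  longer side, ties to the 5' side) and the remainder becomes a terminal
  soft clip placed exactly at the junction; 20 bp approximates where real
  aligners stop rescuing short anchors and is configurable. Base
  qualities are constant; substitution errors are injected per base at
  `errorRate`.
* **Truth**: besides all junction-clipped read ids, the truth JSON
  separately records `eml4_junction_read_ids` — junction reads anchored
  in the 5' window with mate in the 3' window, i.e. the evidence class
  the detector is defined over. A junction read anchored on the ALK side
  is invisible to the published procedure by design, so properties about
  detection are stated over this subset.

### What the simulator does and does not model

It reproduces the geometry the method exploits: fragment-length scale,
paired-end reads, junction soft clips adjacent to the breakpoint,
discordant mates, strand inversion, background coverage, substitution
noise. It does **not** model indels or PCR artifacts, UMI/duplicate
structure (inputs are treated as already deduplicated), capture-efficiency
bias across the windows, quality-score decay, or the empirical clip-length
distribution of any particular commercial aligner. Passing tests
therefore demonstrate correctness of the algorithmic chain under the
stated read model — not clinical sensitivity on real plasma, which
depends on input mass, capture chemistry and upstream pipeline behaviour.

## Statistics

`fisherExactTwoSided()` implements the exact conditional test by the
probability-mass rule: with margins fixed, the p-value sums the
hypergeometric probabilities of all tables no more probable than the
observed one, using a relative tolerance of 1e-7 in the comparison so
ties are not lost to floating point. This is the mainstream two-sided
definition (and what `fisher.test` uses); it is stated explicitly because
two-sided Fisher conventions vary. The tests verify it against brute-force
margin enumeration for every table with total at most 40. On the
reference comparison tables, 15/41 vs 25/41 detected gives p = 0.0461 and
7/24 vs 15/24 gives p = 0.0415.

`confusionSummary()` reports sensitivity `TP/(TP+FN)` and specificity
`TN/(TN+FP)`, with undefined ratios reported as absent (`NA`), never 0.

## Verification strategy and problem sizes

The test suite builds everything it needs at run time. Unit tests use
hand-crafted alignment records and tiny BAMs written through the same SAM
text path the simulator uses. The end-to-end properties run on synthetic
windows of 3-6 kb per gene — large enough for the 165 bp / 100 bp read
geometry with wide margins, small enough to keep the full suite around a
minute: 50+ seeded error-free positive simulations (80 fusion fragments,
20x background) must all be detected with the consensus breakpoint equal
to truth; 50 fusion-free simulations at 10-500x coverage must all be
negative; flank consensus must reproduce the truth references exactly at
error rate 0 and degrade only to `N` columns at 1% substitution noise.
Streaming, Fisher and depth are each checked against independent
brute-force oracles (an index-free whole-file rescan, margin enumeration,
and a text-level `samtools view` pileup walk).

## Known limitations

* Only the 5'-window scan of the published procedure is implemented; a
  fusion whose junction reads all anchor on the ALK side would be seen
  only through its mate pairs.
* Multi-clonal samples with several distinct breakpoints report a single
  modal consensus (the full breakpoint table is retained in the report).
* The fusion-allele fraction is not estimated; breakpoint read depth is
  reported instead.
* hg19 windows are derived, not published; override them via
  `loadTargetConfig()` when an exact match to another pipeline's windows
  is required.
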