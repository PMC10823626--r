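---
title: "Simulating and analysing concatemer long-read isoform libraries"
author: "flicsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing concatemer long-read isoform libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package models

A single PacBio HiFi read is one circular-consensus pass over one
SMRTbell template. When the template is a single cDNA molecule, read
yield per run is bounded by the number of templates loaded. Concatemer
protocols circumvent that bound: several cDNA molecules are ligated into
one array, separated by known junction barcodes, and the sequenced read
is computationally split back into its segments ("s-reads"). `flicsim`
simulates this library type end to end with hidden per-read truth, so
that every downstream analysis step — splitting, refinement, collapsing,
classification, comparison — can be validated against an oracle rather
than against another tool's output.

## The simulation model, stage by stage

**Reference.** The spike-in panel emulates the structure (not the
sequence) of a commercial isoform reference: seven genes on separate
contigs carrying 69 isoforms with spliced lengths uniform on 160–2,940
bp. Isoforms of a gene share a master exon skeleton, so splice sites
recur across isoforms; terminal exons are trimmed to hit target lengths
exactly (alternative starts/ends), one internal exon may be skipped, one
transcript is mono-exonic, one multi-exonic, and one is antisense within
a host gene's span. Splice sites are written as GT..AG on the transcript
strand so donor/acceptor logic in the classifier operates on realistic
dinucleotides. A long module emits mono-exonic transcripts at roughly
4/6/8/10/12 kb (three per size, within 1% of nominal — the sizes are
nominal in the protocol this emulates). A background module (default 50
genes / 150 isoforms, 400–4,000 bp so both size fractions are populated)
stands in for the complexity of a total-RNA sample. Two panel isoforms
are never generated within the collapse thresholds of each other
(see *Collapse*), otherwise per-isoform recall would be ill-defined by
construction.

**Expression.** Spike-ins are equimolar among themselves and receive a
configurable fraction of molecules (default 2%, the library design
point); background transcripts draw log-normal abundances (sdlog 1.5 by
default). TPM values are the design abundances and sum to exactly 1e6;
molecule counts are one multinomial draw. An optional per-gene fold
vector spikes differential expression into one condition.

**cDNA synthesis.** Each molecule is `p5 + insert + poly(A) + p3` with a
30-base tail and fixed synthetic 24-mer primers. Template-switching
(TSO) artifacts are added at a configurable rate (default 2%; the
protocol literature reports the phenomenon but not a rate): an internal
transcript fragment flanked by primers but lacking the oligo(dT)
structure. The bead-capture step removes every artifact and additionally
thins long molecules: retention is 1 up to a 2,000-bp knee, then
declines logistically in log-length (steepness 35, midpoint 8,000 bp,
floor 0). This calibration — chosen once as the package's model of
steric-hindrance capture loss — gives ~1e-6 retention at 12 kb (zero
survivors in a 10,000-molecule draw) and ~4e-4 at 10 kb (a handful of
survivors), reproducing the qualitative pattern that 10-kb spike-ins are
detected while 12-kb ones are absent.

**Size selection and concatenation.** Molecules over 2,000 bp feed dimer
arrays; 500–2,000 bp (bounds inclusive; 2,000 itself goes to the short
fraction) feed tetramers; under 500 bp is discarded. A full array is
`B1 m1 B2 m2 ... B(k+1)` over `arity` molecules drawn without
replacement; with probability `1 - full_array_rate` (defaults 0.777 and
0.727 for dimers and tetramers, the published efficiencies) an array is
truncated uniformly to 1..arity-1 segments, modelling incomplete
ligation with a single aggregate parameter since no truncation-length
distribution is published. Junction barcodes are synthetic 16-mers with
pairwise edit distance ≥ 5 — only their distinguishability matters.
Each read is emitted on a random strand.

**Errors.** Substitutions, insertions and deletions at 0.1% per base
total (the ~Q30 HiFi operating point), in a 2:1:1 ratio (configurable;
the ratio is not published). Truth segment offsets are shifted through
every indel.

## The analysis model

**Splitting.** Junction barcodes are located by a batch Hamming scan at
edit budget 3 (~19% of a 16-bp barcode) over both read orientations;
whole-read orientation is decided once per read by total hit count.
Expected barcodes the Hamming pass missed are re-sought per read with an
edit-distance search allowing indels, keeping only hits whose width is
within one base of the barcode — at HiFi error rates a barcode with two
or more indels is vanishingly rare, while permissive multi-indel windows
are the dominant source of spurious matches. Hits are accepted in order
of (edit distance, position), subject to non-overlap, uniqueness of each
barcode index, and design barcode order; this makes tie-breaking
deterministic. The s-reads are the maximal intervals between accepted
hits; a read with no interior hit yields itself; segments under 50 bp
are flagged rather than dropped. A missed junction therefore produces a
fused s-read spanning two true segments — exactly the artifact the
refinement screen and the fusion sentinel downstream are designed to
catch.

**Refinement.** Primer pairs are tested at both ends in both
orientations with a bounded-edit terminal match; the poly(A) rule
requires a trailing run holding ≥ 20 A's with ≤ 1 non-A (the upstream
tools' defaults are unpublished; these are the package's). The
residual-concatemer screen looks for internal primer/barcode remnants
with a mismatch budget that scales with pattern length (one per 12 bp,
capped at the edit budget): every real junction carries the 24-bp
primers on both sides, so the screen keeps full sensitivity there while
short barcodes no longer fire on chance matches in genuine transcript
sequence. TSO artifacts that bypass capture die at the poly(A) step.
Inserts under 80 bp after trimming are statused `short` and excluded
from clustering (no spike-in is affected; the panel minimum is 160 bp).

**Alignment stand-in.** In simulation mode each FLNC read inherits its
source transcript's exon chain (the truth join is by s-read/segment
coordinate overlap). Optional strand-aware Gaussian end jitter emulates
mapper end variability and is switched on in parameter-recovery tests;
the default is exact chains, so collapse-threshold behaviour is
exercised by dedicated tests rather than by every run. Real-data mode
consumes externally produced BED12 exon chains; spliced alignment itself
is out of scope.

**Collapse.** Two reads merge when their strand-aware 5'/3' genomic ends
differ by < 100 / < 30 bp and their internal junctions agree within a
10-bp wobble (10 passes, 11 fails — "exceeds ten" fixes the boundary).
Clusters are connected components of this relation (single linkage,
deterministic processing order); the documented consequence that distant
reads can chain through intermediates is asserted in a test.
Representative = longest genomic span, ties to the smallest id. The
support filter at 2 (default), 4 and 10 CCS reads reproduces the
threshold analysis.

**Classification.** Nine structural categories with a fixed, documented
decision order: splice-match classes first against same-contig/strand
transcripts (FSM = identical intron chain, or mono-exon containment in a
mono-exon reference ± 50 bp; ISM = contiguous intron sub-chain, or a
mono-exon inside one annotated exon), with intron retention suppressing
ISM — a retained intron with annotated boundaries is novel-in-catalog;
then fusion (≥ 2 same-strand gene loci), then splice-site membership
(NIC if every donor and acceptor is annotated, NNC otherwise); chains
without same-strand gene overlap fall through to antisense /
genic_intronic / intergenic, and mono-exon leftovers to genic_genomic.
Intergenic isoforms receive novel gene ids, one per overlap cluster, so
unique-gene counts include novel loci.

**Comparison and filters.** Cross-sample merging reuses the collapse
rule (a deliberate unification — the external merging tool's tolerance
is unpublished), sums per-sample support over merged members, and drops
intergenic rows as the "unknown"-class analog. Replicate concordance,
fold changes (half-up, pseudocount one for zero support, whole-number
folds at ≥ 1,000), mean recall, the TPM = 0.5 low-expression panel and
its detection rates follow the published arithmetic exactly; the twelve
worked examples in the test suite pin the rounding convention. The
differential filter is a deterministic conjunction (FSM, ≥ 10 tumor
reads, ≥ 10 tumor TPM, both folds ≥ 5 — inclusive, per "at least
five-fold") applied in a single pass; the novel-isoform filter requires
NIC/NNC, ≥ 10 tumor reads and zero comparator reads, ignoring TPM.
Fusion candidates must span ≥ 2 loci with ≥ 5% of the read per locus,
≥ 99% combined coverage and ≥ 5 FLNC reads; passing fusions with a
spike-in partner are flagged as concatenation-artifact sentinels.

## What the simulation does and does not establish

The generator reproduces the *structural* conditions of a spike-in
benchmark: known isoform complexity, equimolar spike-ins at 2%,
length-dependent capture loss, incomplete arrays at the published
efficiencies, and ~Q30 errors. It does not model PCR duplicates (the
protocol uses no UMIs; one molecule = one copy), polymerase kinetics,
5'-degradation beyond the TSO-artifact flag, real barcode or primer
sequences, or mapping ambiguity on a real genome. Passing tests
therefore demonstrate that the analysis logic is correct under the
stated noise model, not that any particular real library will reach the
same recall; in particular real-data end variability enters only through
the optional jitter model.

## Numerical choices and degenerate inputs

Percentages and folds round half away from zero to one decimal (the
reporting convention of the domain); filters compare unrounded values.
Coordinates are 0-based half-open internally, 1-based inclusive in
GTF/BED output; read coordinates are 1-based inclusive. Empty inputs
return empty typed outputs (`size_select`, `concatenate`,
`collapse_flnc`, `length_bins`); an empty annotation classifies
everything intergenic; a zero denominator in fold gain is an error; both
operands zero in `fold_change` give 1.0 via the pseudocount. All
randomness descends from one master seed through named substreams, so
stages can be re-run independently and byte-identical reproduction of a
whole run is a tested property.

## Problem sizes used in the shipped analyses

The test suite and `scripts/acceptance.R` run the simulations at desk
scale, chosen so each stage still operates in its intended regime: a
20,000-array mixed dimer/tetramer run (~100,000 molecules, array mix in
the proportion implied by the published per-design s-read totals) for
efficiency recovery and s-read yield; 10,000-molecule draws for the
capture curve; two 12,000-molecule conditions over 50 genes for the
differential filter (the spiked set is deliberately a < 5% share of the
transcriptome — a large spiked share would be compressed by library-size
renormalisation, as in any compositional assay); and three
5,000-molecule replicates for concordance and threshold monotonicity.
The one published comparison that needs a comparator arm — the s-read
fold gain — uses a monomer read count at the published per-cell yield
ratio of the two library types, since at *equal* read counts a
dimer/tetramer mix yields ~2.6 segments per read by arithmetic, and the
published 3.4-fold figure reflects the comparator's smaller yield.

## Known limitations

Single-linkage collapse can chain distinct isoforms whose ends drift
through intermediates; the splitter's indel fallback can, in the rare
case of a destroyed junction, place a spurious low-quality barcode hit
inside a fused segment; classification of mono-exon reads inside
opposite-strand introns follows this package's documented order
(antisense requires exon overlap) where upstream tools are silent; and
the simulation's alignment stand-in bypasses mapping error entirely.
Each of these is either asserted as documented behaviour or discussed
above.
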