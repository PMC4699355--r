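---
title: "Circularizing long-read assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circularizing long-read assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circweld)
```

## The problem

Long-read assemblers emit linear contigs even when the underlying molecule -
a bacterial chromosome, a plasmid, an organelle genome - is circular. The
linear representation is rarely clean. Three pathologies dominate:

* **duplicated ends**: the contig carries the same (often low-quality)
  sequence at both ends, because reads crossing the replication origin were
  assembled twice;
* **missing junction sequence**: the contig stops short and the bases joining
  its end to its start are absent;
* **tandem multi-copies**: a replicon shorter than the read length is
  assembled as two or more concatenated copies of itself.

A fourth situation is the dangerous impostor: a *linear* fragment whose ends
carry two copies of the same repeat, because assemblies typically break at
long repeats. Any method that circularizes purely on end-overlap evidence will
falsely circularize such contigs.

`circweld` resolves circular replicons with read evidence rather than
end-overlap evidence: corrected long reads near contig ends are reassembled
locally, and the resulting **local units** - independent, read-derived
assemblies that span putative junctions - drive all decisions.

## Pipeline

`run_pipeline()` applies four stages in fixed order.

1. **Merge** (`merge_to_fixpoint()`). Reads are mapped to the assembly and
   filtered: on *long* contigs (at least `b2r_length_cutoff` = 100,000 bases)
   only reads mapping within the first or last `b2r_end_window` = 50,000
   bases are kept, trimmed at the window boundary (at least 250 bases must
   survive trimming); reads on short contigs and unmapped reads are kept
   whole. The filtered reads are assembled by a greedy exact-overlap
   assembler, and a unit whose two end-matches (at least 4,000 bases, within
   1,000 bases of the unit ends and 15,000 bases of the contig ends - more
   slack on the contig side, whose ends are often low quality) touch two
   different contigs, with no longer match of that unit anywhere, merges
   them. Filtering, assembly and merging repeat until a round applies no
   merge.
2. **Circularize** (`circularize_contigs()`). Per contig, two paths in fixed
   order. *Replacement*: if hits to one circular unit cover at least 95% of
   the contig and one hit spans at least 95% of the unit, the contig becomes
   the unit - this collapses tandem multi-copy contigs, which always contain
   a full rotation of the unit. *End-join*: the longest hits near the contig
   start and end (second-longest substituting when they coincide) must land
   on the same unit, touch the unit's end and start respectively, and be
   strictly ordered on the unit; the contig is then closed through the unit,
   removing duplicated junction sequence or restoring missing sequence.
3. **Refine** (`refine_contigs()`). Contigs shorter than 2,000 bases are
   dropped; then any non-circular contig 95%-contained in another at 95%
   identity (single alignment) is removed, after transitive closure of the
   containment relation and collapsing mutual-containment classes to their
   longest member.
4. **Fix starts** (`fix_starts()`). Circular contigs are rotated to begin at
   an anchor gene (dnaA homologs by default) found by six-frame translated
   search at a minimum of 80% amino-acid identity, full gene length in one
   hit; without a match, the start of a predicted ORF nearest the contig
   middle is used.

Two overlap-only baselines are included for comparison:
`iterative_end_trim()` (repeated removal of duplicated prefixes, the
optimized BLAST-style method) and `split_merge_circularize()` (break in half
and re-merge, the optimized Minimus2-style protocol, applied per contig).

## The aligner

Decisions consume `Hit` tables from a seed-chain-extend aligner
(`align_all()`): exact 17-mer anchors (all occurrences), collapsed into
maximal exact segments, chained when adjacent diagonals differ by at most 25
and gaps on either sequence are at most `breaklen` (500 bases by default;
the knob that carries alignments across poorly-aligned patches), extended
outward over exact matches, and scored by banded global alignment with full
traceback. Percent identity is matches over alignment columns, unrounded for
thresholding and rounded half-up to two decimals only in coords-file export.
Equal-score choices break toward the lower reference coordinate, so all
outputs are deterministic. `read_coords()`/`write_coords()` interoperate with
show-coords-style tables (1-based inclusive, reverse strand as descending
query coordinates), so hits from an external aligner can be substituted at
scale. For higher-error nanopore-grade data,
`pipeline_params(nanopore = TRUE)` relaxes matching to 85% identity with
`breaklen` 1000.

The translated anchor search runs the same engine over amino-acid codes
(5-mer anchors) on all six frames; `find_anchor()` searches the contig
extended past its origin, so an anchor gene straddling the linearization
point is still seen at full length - without this, rotation would not be a
fixpoint.

## The local assembler

Corrected reads are high identity, so assembly uses exact suffix-prefix
overlaps, trying overlap lengths 127, 121, 111, 101, 95, 91, 85, 81, 75, 71
in turn and keeping the first ladder value that either assembles something
longer than the longest read or closes a circle. Contained reads are removed
first; mutual-best overlaps are followed into unitigs; any tie (two
extensions with equal overlap length) ends the unitig, the conservative
unitig convention. A path that closes onto its first read is emitted once
around as a circular unit; a single read spanning its replicon more than once
is collapsed to its minimal period (KMP border). Both read orientations are
considered and strand-duplicate unitigs removed. `min_overlap_id` (default
100) admits substitution-tolerant overlap verification for lower-quality
read sets; the default is exact, matching the corrected-read contract.

## The simulator

`simulate_truth_set()` builds random uniform-composition circles, derives one
contig per replicon according to its pathology, and samples reads of normally
distributed length (default mean 10,000, sd 1,000 bases - corrected
long-read scale) at 20x coverage, uniformly around the circle (crossing the
origin) on random strands. `per_base_error` defaults to 0: the pipeline's
contract is *corrected* reads, and the properties tested are structural.
Duplicated contig ends are mutated at 5% (substitutions and indels) to
emulate low-quality ends; this exercises the sub-100% identity thresholds.

One generator choice deserves explanation. For the `false_overlap` negative
control (a linear fragment with identical repeats at both ends), reads are
sampled from the fragment *embedded in random flanking sequence*, not from
the bare fragment. A read set that stops dead at the fragment ends is
information-theoretically indistinguishable from the read set of a smaller
circle - every overlap assembler, this one included, will then weld the two
repeat copies into a circular unit, and no downstream rule can tell the
difference. In reality such contigs break at repeats *inside* a larger
molecule, and reads run past the contig ends into sequence that differs
between repeat copies; with those flanks the weld cannot form, the unit stays
linear, and the decision rules (same-unit requirement, strict interval
ordering on the unit, no-longer-match veto) reject the join. The end-trim
baseline, which never looks at reads, falsely circularizes the same fixtures.

`score_against_truth()` compares output to truth up to rotation and strand by
searching the doubled truth for the output and its reverse complement;
"correctly circularized" means flagged circular with zero length difference
and an exact match. What passing these tests shows is that the *decision
logic* is correct on structurally faithful inputs; they do not exercise raw
long-read error profiles (chimeras, homopolymer bias), GC skew, or polishing,
which are out of scope (consensus accuracy is the polisher's job).

## Problem sizes and parameter regimes in the shipped checks

The test suite and `scripts/acceptance.R` run the full pipeline on 4, 20 and
50 kb replicons - plasmid/organelle scale, where circularization pathologies
actually occur, and small enough that the whole battery runs in minutes on
one CPU. Two parameter regimes are used, both deliberate:

* **Plasmid-scale fixtures** run with `b2r_length_cutoff` = 300,000, above
  the largest pathological contig (250 kb for tandem x5 of a 50 kb circle),
  i.e. in the short-contig regime where all reads feed the local assembly.
  This is a geometric requirement, not a tuning: with the default 100,000
  cutoff, a 50 kb end window falls exactly on the circle origin of a tandem
  contig, so junction-crossing reads are trimmed at the one position whose
  evidence is needed, and no circular unit can exist. The length cutoff is
  the documented, most influential user parameter for exactly this reason.
* **Fragmented-replicon fixtures** (three ~16 kb arcs of a 50 kb circle)
  run with cutoff 10,000, end window 4,000 and 4 kb reads: the same
  window-to-contig geometry as the defaults on chromosome-scale data, scaled
  down so the long-contig merge machinery (window filtering, read trimming,
  bridging units, the iterate-to-fixpoint loop) is exercised as designed.

## Numerical and tie-break choices

* End-join junctions are placed at hit *endpoints* - exact aligned
  correspondences - never interpolated positions, so indel-bearing
  low-quality ends cannot shift the junction. When the mediating unit is
  circular, the output is the unit rotated to the contig's start coordinate:
  exact, free of low-quality contig tails, and byte-stable on re-runs.
* A contig already flagged circular is never re-circularized and never
  treated as contained; re-running the pipeline on its own output is the
  identity on clean data.
* `iterative_end_trim()` removes the *shortest* qualifying prefix/suffix
  overlap per iteration; a tandem triple therefore needs (at least) two
  trims, reproducing the iterative behavior that motivated the method.
* Mutual-containment ties break to the lexicographically smallest id; anchor
  ties break on (contig position, gene file order); fallback-ORF ties prefer
  the forward strand, then the lower coordinate.
* The no-longer-match veto is scoped to hits between the chosen unit and any
  contig during merging, but to hits with *this* contig during
  circularization - otherwise a whole-circle unit's matches to the other
  fragments of the same replicon would veto a legitimate end-join.

## Known limitations

* The middle-ORF fallback rotation is not a fixpoint: rotating to the gene
  nearest the middle changes which gene is nearest the middle. Anchor-gene
  rotation is idempotent; provide a gene set when stability matters. The
  shipped `inst/extdata/synthetic_dnaA.fasta` is a synthetic stand-in so the
  machinery runs out of the box; real analyses should supply genuine dnaA
  (or other marker) sequences.
* The exact-overlap assembler assumes corrected reads; at raw nanopore error
  rates it will fragment. The module boundary accepts externally assembled
  units (FASTA with a ` circular=true` description token), so a heavier
  assembler can be slotted in.
* Junction sequence is taken from local reassembly of corrected reads and is
  not polished; downstream consensus polishing with raw reads remains
  necessary, as for any circularization method.
* Percent identity of a bridged hit is computed over the final merged
  alignment; external delta-filter implementations may resolve
  bridge-versus-identity edge cases differently near the threshold.
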