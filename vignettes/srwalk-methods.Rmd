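---
title: "Methods: selective recursive local assembly by in silico chromosome walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selective recursive local assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the strategy

Whole-genome assembly is expensive, and many questions concern a single
gene: what does the homolog of a known gene look like in an organism (or
individual) for which only unassembled short reads exist? `srwalk`
answers this by targeted local assembly. A probe — a protein or cDNA
sequence from a related species — seeds the recruitment of reads that
could plausibly belong to the homologous locus. Recruited reads are
assembled locally, and the resulting contigs become the queries of the
next round, pulling in reads that overlap the current contig ends. The
recursion is the in silico analogue of chromosome walking: each round
extends the assembled region by roughly a read/insert length on each
flank, first jumping quickly between coding exons (which the probe
matches directly) and then crawling outward through introns and flanks.

A round consists of four steps:

1. **Matching.** Every read sharing an exact substring of at least
   `min_match_dna` = 30 nt (DNA queries, either strand) or
   `min_match_prot` = 10 aa (protein probe, any of the six reading
   frames) with some query is recruited. Matches are found from a
   per-chunk k-mer index (k = 15 nt / 5 aa) and extended to maximal
   exact matches; this exact-substring model is a deliberately
   testable replacement for a heuristic local aligner, and its
   equivalence to a brute-force common-substring scan is asserted in
   the test suite.
2. **Mate completion.** For paired-end libraries, both members of a
   pair are kept when either mate matches. This is what lets the walk
   cross introns quickly: a mate anchored in an exon drags its partner
   up to an insert length into unsequenced-by-the-probe territory.
3. **Local assembly.** The entire found pool is reassembled from
   scratch each round with a de Bruijn unitig assembler, swept over
   k = 15, 25, 35, 45. The sweep keeps the assembly whose single best
   contig achieves the greatest spliced-alignment length against the
   original probe. The winning contigs (minimum length 200 bp) are
   DUST-masked and become the next round's queries.
4. **Stopping.** The walk stops on (1) a hit contig — length >= 200 bp,
   spliced-alignment similarity >= 0.5, probe coverage >= 0.8; (2) no
   new reads; (3) the round cap; or (4) every contig reaching the
   maximum contig length (10,000 bp). A `force_max_rounds` flag ignores
   criterion 1; `extra_rounds` > 0 instead arms a countdown of extra
   rounds at the first hit (further hits do not extend it).

Periodically (every 4 rounds, or immediately when more than 500 contigs
appear) the state is cleaned: contigs with no partial probe match are
culled — "partial" meaning the recruitment matcher run with half the
minimum match length, so cleaning is strictly more permissive than
recruitment and can never discard a contig the probe itself seeded —
and found reads matching none of the surviving contigs are dropped,
with mate closure re-applied. Contigs exceeding the maximum length are
retired from querying: a symmetrically trimmed copy (half the excess
off each end, the odd base off the tail) is kept as a candidate, and a
candidate whose sequence is reassembled intact the next round inside
another maximum-length contig is promoted to a permanent long contig.
Reads matching permanent long contigs leave the assembly pool (they
remain in the found set), and the permanent contigs are emitted
unchanged in the final output. Candidates that are not reassembled the
following round are replaced by that round's candidates.

## The assembler

The graph is built over canonical k-mers (the lexicographic minimum of
a k-mer and its reverse complement; k is odd so the two always differ),
held in 128-bit integers so the sweep's k = 35 and 45 need no special
casing. Cleanup iterates three operations to a fixpoint:

* **Coverage floor** (`min_count`, default 2 in the sweep, 1 — i.e.
  disabled — in the bare `simplify_graph()`): k-mers seen fewer than
  `min_count` times are dropped first. At a 2% per-base error rate
  roughly half of read k-mers carry an error, and nearly all of these
  are singletons, so the floor removes the bulk of error nodes at one
  stroke. The cost is that genuinely single-copy k-mers (contig
  termini, very low coverage regions) are lost too, which is why the
  walker expects several-fold local coverage and why assemblies at 10X
  are visibly more fragmented than at 20X — fragmentation the
  original study observed at 10X as well.
* **Tip clipping** (`tip_len` = 2k bp): dead-end paths shorter than
  `tip_len` whose mean coverage is below the competing branch at their
  junction are removed. A single sequencing error within a read can
  create a tip of at most 2k - 1 bp, so the default is exactly the
  bound that covers them.
* **Bubble popping** (`bubble_identity` = 0.9): at every junction the
  dominant (highest-coverage) path is walked forward, straight through
  any further in- or out-branches, always following the
  highest-coverage successor. Every other arm is walked the same way;
  an arm that reconverges onto the dominant path is deleted when its
  gapped identity to the dominant spelling is at least
  `bubble_identity` and its mean coverage does not exceed the
  dominant's; an arm that dead-ends is deleted as a tip under the same
  length rule. Walking *through* internal branches matters: when two
  reads happen to carry the same error at the same position (common at
  20X and a 2% error rate — such arms also survive the coverage
  floor), their arm often carries secondary branches from additional
  errors, and a bubble detector restricted to clean two-path bubbles
  never fires on it.

Unitigs (maximal non-branching paths) are reported in canonical
orientation, sorted by decreasing length then sequence, so identical
pools give byte-identical output regardless of hash iteration order or
worker count. Ties in the k-mer sweep go to the larger k, which
resolves repeats better.

The sweep metric deserves a note. Scoring each assembly by the *sum*
of per-contig alignment lengths lets a fragmented assembly — whose
overlapping pieces each align part of the probe — outscore an assembly
with one contig spanning the probe, which then deprives the walk of
its hit. Scoring by the single greatest spliced-alignment length
matches the walk's actual objective (one contig covering the query)
and proved markedly more robust across simulation seeds.

## The spliced aligner

Probe-to-contig comparison allows intron-scale gaps on the contig axis
only. Exact seeds (5 aa in translated space, codon-granular on the
contig; 12 nt in DNA space) are extended to maximal exact matches and
chained by dynamic programming; gaps wider than 40 bp on the contig
with little probe gap are treated as introns, free when flanked by
GT...AG and mildly penalized otherwise, up to 20 kb. Within an exon,
inter-anchor gaps are filled by global DP (BLOSUM62 for proteins) and
terminal ends are extended by ungapped x-drop. Both orientations are
tried. The similarity score is identities over aligned probe
positions — a bounded [0, 1] quantity that is monotone in alignment
quality, standing in for the unpublished internal score of spliced
alignment tools; probe coverage is the fraction of probe positions
inside alignment blocks; the alignment length (the sweep metric) is
the total contig bp inside blocks. Coordinates are 0-based half-open
internally and 1-based only in serialized reports.

DUST masking scores every `window` = 64 bp window by its triplet
composition, S = sum over triplet types of c(c-1)/2 divided by
(w - 3); windows scoring above `level`/10 = 2 are lowercased and
masked intervals within `linker` = 1 bp merge. Masked (lowercase)
query regions seed no matches, which is the mechanism that stops
low-complexity sequence from recruiting reads genome-wide; matches
seeded elsewhere may still extend across masked bases. Reported
contigs keep their case; only queries are masked.

## The simulator

`make_genome()` plants multi-exon genes in uniform random background:
the CDS is random non-stop codons opening with ATG and closing with a
stop, exons are codon-aligned (introns are inserted at codon
boundaries — a simplification; real splice sites may split codons, so
a probe residue spanning a real splice junction would be slightly
harder to seed than in these fixtures), and introns carry GT...AG.
`diverge_probe()` substitutes residues to a target protein identity
(default 0.85, emulating a cross-species probe) and emits a
synonymously-biased cDNA alongside. `simulate_reads()` draws
N = floor(L * coverage / (2 * read_len)) fragments with uniform
starts and normal insert lengths (340 +/- 50 bp, truncated at two read
lengths), reading 70 bp mates from either end; sequencing errors are
substitutions at 2% per base, and haplotype mutations (default rate 0,
of which 10% would be 1 bp indels) are separate, so the default
configuration produces substitution-only errors. Read names carry the
true fragment coordinates for downstream truth checks. All randomness
flows through an explicit seed with an internal deterministic
generator, so outputs are bit-for-bit reproducible across platforms.

What the simulator does **not** model: coverage bias, quality-score
structure, PCR duplicates, adapter read-through, repeats beyond what
uniform random sequence produces, or real intron/exon statistics.
Passing tests on these fixtures show the machinery is correct under
the stated error model, not that recruitment thresholds are tuned for
any particular real library.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full workflow on a
1 Mb genome with one planted 3-exon gene (~1.5 kb CDS, introns 350 and
420 bp) at 10X and 20X coverage — sizes chosen so a complete walk
takes tens of seconds while still exercising chunked preprocessing,
six-frame recruitment, the full sweep, cleaning and stopping logic.
Identity of a recovered contig to the truth locus is measured as
percent identity of the best local alignment (either orientation),
the same definition a BLASTN comparison of contig versus reference
reports; at 20X the gene body is typically recovered end-to-end at
~100% identity, while at 10X contigs are shorter (the coverage floor
costs about 2% of true k-mers there) but remain essentially exact.
Remaining numerical choices: the matcher deduplicates reads by
(library, chunk, ordinal) rather than name, so simulated libraries may
repeat names; chunk searches are unioned in a fixed order, making
results independent of worker count; the cleaning cadence counter is
not reset by a contig-count-triggered clean; reads retired with
permanent long contigs stay out of later assemblies but remain in the
found set; and when a round's assembly yields no contig of reportable
length the walker falls back to querying with the found reads
themselves (the same mechanism as the delayed-assembly option), which
is what lets sparse early rounds keep walking instead of stalling.

## Known limitations

* Recruitment is exact-substring based; probes below ~70% protein
  identity to the target seed poorly at the default 10 aa threshold.
* At 10X coverage and 2% error the coverage floor fragments
  assemblies; hits may not be reached even though the assembled
  sequence is accurate.
* A k-mer shared between two recruited regions (a genuine repeat at
  the smallest sweep k) can fragment that k's assembly; the sweep
  usually, but not always, rescues the round via a larger k.
* The aligner's similarity is not numerically comparable to any
  specific external spliced aligner's score; only its thresholds'
  semantics are preserved.
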