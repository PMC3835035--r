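---
title: "Methods: characterizing projectin-like giant muscle genes in silico"
author: "projectin package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing projectin-like giant muscle genes in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(projectin)
```

## The biological problem

Insect striated muscle contains a third, elastic filament system built from
giant modular proteins — projectin and kettin/sallimus in insects, titin in
vertebrates.  Projectin's architecture is strongly conserved: an N-terminal
region of two immunoglobulin-like (Ig) tracts, canonically eight (N8Ig) and
six (N6Ig) domains, separated by a unique region; a central core of tandem
[Fn-Fn-Ig] modules (canonically fourteen); and a C-terminal kinase domain.
The unique region divides into a compositionally biased, rapidly diverging
**PEVK** segment — enriched in proline, glutamate, valine and lysine, with
compositions spanning roughly 42–100% across insects — and a conserved block
of 112–138 residues (**NTCS-1**) that in derived insects begins with a YERP
motif.  Alternative splicing of PEVK exons generates isoforms whose lengths
correlate with passive muscle stiffness, which makes the PEVK splice
repertoire of each species a quantity of direct biomechanical interest.

Characterizing such a gene from genome-project contigs is a desk exercise
with several error-prone steps: curating overlapping contigs (some
misassembled), predicting the exon–intron structure by homology to a
reference projectin, scanning translations for PEVK-like open stretches,
mapping the domain architecture, enumerating splice isoforms, and predicting
the RT-PCR ladder each muscle type should show.  This package implements
that workflow as tested, reusable functions, together with a seeded
synthetic-data generator that provides ground truth for every stage.

## Coordinate and sequence conventions

All coordinates are **1-based closed intervals**, the native convention of
IRanges/GRanges, Biostrings and GFF3 itself, so no shifting occurs at the
file boundary.  Minus-strand gene models are normalized to the coding strand
at load time (`readGeneModel()`); downstream code only ever sees `"+"`.
Translation uses the standard genetic code; codons containing IUPAC
ambiguity codes translate as `X`, and ambiguity codes are permitted in
primers and raw contigs but not inside synthetic exons.

## Maximal compositional-bias segments

"Open stretches with elevated PEVK content" are formalized as **maximal
scoring segments**: each residue scores $+(1-t)$ if it belongs to the bias
alphabet (default `P,E,V,K`) and $-t$ otherwise, where $t$ is
`minFraction`; a window's score is non-negative exactly when its alphabet
fraction is at least $t$.  `scanSegments()` recursively extracts the top
scoring window (ties: leftmost, then longest) and recurses into the flanks,
yielding disjoint maximal segments that never cross a stop marker.  This is
the classic maximal-scoring-subsequence decomposition used for
low-complexity segment detection, and it reproduces the intuitive reading
of "maximal open stretch": a fully biased 12-mer is reported whole, and a
PEVK core flanked by non-biased tails is reported without the tails.

Two practical consequences are worth noting.  First, when the threshold is
*lowered*, the top window can lengthen and absorb neighbouring segments;
a sub-`minLength` flank that was previously inside its own segment can then
be orphaned, so segment boundaries are not monotone in $t$ (the tests
assert the defensible form of monotonicity: strict-threshold segments are
always met by loose-threshold segments).  Second, in **frame space**
(`threeFrameScan()`) a segment may extend up to one codon past a
frame-aligned exon edge, because a GT–AG intron's donor always reads
`GTx` = valine and an intron ending `...A+AG` reads `AAG` = lysine — both
bias-alphabet residues.  Boundary-exact recovery is therefore a
protein-space property (see the unique-region delineation below), and
frame-space tests allow one codon of slack per edge.

Defaults: `minLength = 10` aa (the conventional visual-scan cutoff) and
`minFraction = 0.6`, a config knob rather than a constant; 0.6 keeps the
scanner specific enough to separate the PEVK block from the low-bias
NTCS-1 while catching every realistic long-form composition.

## Greedy exact-overlap assembly

`assembleFragments()` mirrors manual contig curation at desk scale:
repeatedly merge the pair with the longest **exact** suffix–prefix overlap
(≥ `minOverlap`, default 20 nt), trying both orientations.  Among
equal-length candidates the lexicographically smallest merged sequence is
chosen, and a merge and its reverse complement are treated as one event
whose representative leaves the fewest fragments on the minus strand —
together these make the output independent of input order and keep
unperturbed assemblies in the input orientation.  The repetitive-sequence
hazard is handled conservatively: a fragment whose *same end* overlaps two
different partners equally well is never merged by guessing; it is reported
`ambiguous_overlap` and left out.  Equal overlaps on opposite ends are, of
course, just a fragment with two neighbours.

Curation hazards are surfaced as conflicts: merge-time orientation flips
become `strand_inversion` rows; a scaffold whose terminal sequence recurs
*inside* another scaffold indicates an `internal_deletion` in the fragment
that supplied the terminus; and `bridgeGaps()` records an `order_inversion`
when a cDNA matches both flanks of a junction in inconsistent order.  A gap
is bridged when one cDNA matches both flanking scaffolds with at least
`minOverlap` exact nucleotides in consistent orientation and order —
spliced cDNAs bridge intronic gaps through their flanking exons.

## Homology-guided exon prediction

`anchorDomains()` slides each reference peptide along the three
forward-frame translations of the genome and computes full-length ungapped
identity at every offset; offsets at or above `minIdentity` (default 0.7)
become candidate anchors, which are resolved greedily by identity (then
score, then position) into a non-overlapping set.  The deliberate design
choice here is **substitution-only homology**: the anchoring model has no
gap states.  Within this package's scope the homologs are diverged by
substitutions, a regime in which windowed identity is exact, finds *all*
copies of a repeated domain in one pass, and runs in $O(Ln)$ per reference;
a gapped local aligner adds failure modes (fragmenting anchors, clipping
ends) without adding recoverable signal.  Reported anchor scores use
match +2 / mismatch −1.  Indel-containing homology is a stated limitation,
not a silent one.

`refineBoundaries()` then searches a ±60 nt window around each adjacent
anchor edge for a canonical donor `GT` / acceptor `AG` pair such that the
spliced reading frame is continuous across the junction, and scores each
candidate pair by translating only the few codons flanking the junction
and comparing them with the reference residues.  Ties are never broken
silently: the junction is flagged `ambiguous`, matching the practice of
resolving such sites with bench evidence.  `verifyWithCdna()` confirms
models by exact containment of cDNAs in some isoform's spliced transcript
(all alternative-exon combinations are tried), reports mismatch positions
against the closest isoform otherwise, and upgrades ambiguous junctions
covered by a confirming cDNA.

## Architecture mapping

`findDomains()` scans the packaged consensus library — fixed ~90 aa
Ig-like, ~100 aa Fn-like and ~250 aa kinase-like peptides that are
synthetic stand-ins, not Pfam consensi — with the same windowed-identity
machinery and resolves overlaps by score.  `classifyArchitecture()`
segments the ordered calls into leading Ig tract, unique region, second Ig
tract, core and kinase, using the template's maximum linker length (46 aa)
to separate within-tract spacing from the unique-region gap.  Core repeats
are counted strictly: only consecutive `[Fn,Fn,Ig]` triplets extend the
run, and any interrupting call terminates it and is listed as a deviation.
Deviations also cover tract-size mismatches, missing kinase, out-of-range
linkers (template 5–46 aa) and NTCS-1 lengths outside 112–138 aa.

`delineateUniqueRegion()` places the PEVK/NTCS-1 boundary by composition:
the PEVK sub-region runs from the start of the unique region to the end of
the last maximal bias segment, and NTCS-1 is the remainder abutting the
second tract, so the two partition the unique region whenever both are
non-empty.  YERP motifs are counted and located but deliberately *not*
used to place the boundary: the two-motif geometry (one mid-PEVK, one
starting NTCS-1) is reported as positions, without asserting which region
owns a motif.

## Isoforms and in silico RT-PCR

`enumerateIsoforms()` expands all $2^k$ combinations of the $k$
alternative exons (guarded at $k \le 20$) and labels them `A`, `B`, ... by
descending spliced length, ties broken lexicographically — so the longest
variant is always `A` and the shortest always the last label.
`pevkStats()` translates the included PEVK-region exons and reports length
and composition; `lengthRatioPercent()` rounds half away from zero, which
is what makes 205/377 print as 54.  `inSilicoPcr()` requires one
full-length (IUPAC-aware) binding site per primer — multiple sites are an
error, not a multi-product simulation — and sizes include both primer
footprints.  `ampliconLadder()` collects per-sample product sizes and
flags any size absent from at least one other sample as sample-specific,
the in-silico analogue of a muscle-specific gel band.

The packaged `msextaFixture()` encodes only printed constraints: seven
PEVK exons with #3 and #6 alternatively spliced, exon 5 of 24 nt, exon 6
of 33 nt, PEVK regions of 377/366/216/205 aa for isoforms A–D, two YERP
motifs present in every variant, and Ms1-6R-style amplicons of 926/893 bp
for C/D.  Exon lengths not fixed by those constraints (the 483 nt
alternative exon 3, the 150 nt constitutive exons, the flanks) are
synthetic and chosen once; the published A/B product sizes are not
asserted because they are inconsistent with a pure two-optional-exon model.

## Pairwise global identity

`globalIdentity()` is a hand-written Needleman–Wunsch with linear gap
penalty (defaults match +1, mismatch 0, gap −1).  Identity is
matches / alignment columns, which is *not* invariant across co-optimal
alignments; the DP therefore optimizes the tuple (score, matches, aligned
pairs) lexicographically, making the reported identity deterministic and
well-defined.  Tests compare it against an independent memoized
suffix-recursion oracle on short pairs.  `conservationTrack()` emits a
per-column agreement track against an anchor sequence as a lightweight
stand-in for shaded multiple alignments; progressive MSA is out of scope.

## The synthetic-data generator

`generateGene()` builds the protein architecture from the consensus
library, mutates domain copies at `domainMutationRate` (default 0.05,
i.e. reference identity 0.95), plants PEVK exons with compositions drawn
from `pevkContentRange` (default 0.42–1.0, the documented cross-species
span), reverse-translates with uniform synonymous codon choice (no
codon-usage table), and joins exons with decoy-free GT–AG introns of
70–150 nt whose bodies are G-free — a body without G can contain neither a
`GT` nor an `AG`, so each boundary-search window sees exactly one
canonical pair (decoys can be switched on to stress-test refinement).
Every exon is codon-preserving, so alternative splicing never shifts
frame.  Two YERP motifs are planted (one mid-PEVK, one starting NTCS-1),
and the last PEVK exon's composition is floored at 0.7 so the PEVK/NTCS-1
boundary is recoverable by composition.  Non-alphabet filler residues are
spread evenly through each planted exon's interior with a three-residue
alphabet margin at the ends, which guarantees the maximal segment reaches
the exon boundary.  All randomness flows through R's integer sampler under
the configured seed; generation is byte-identical across runs.

What the generator deliberately does **not** emulate: sequencing errors and
coverage, codon usage bias, indel divergence between homologs, non-canonical
splice sites, and expression levels.  Tests passing on generator output
therefore demonstrate the correctness of the algorithms under a clean,
substitution-only model — not robustness to noisy real-genome input.

`generateFragments()` tiles the genome with 800–1500 nt fragments
overlapping by 30–80 nt and can plant three curation hazards: an
unsequenced gap (coverage dropped over an intron interior), a strand
inversion, and an internal deletion that reaches into the overlap zone
with the next fragment (which is what makes it detectable after assembly).
`generateCdnaPools()` splices per-muscle transcript pools in which the
shortest isoform is restricted to thorax and flight;
`generateDegeneratePrimers()` copies primers from constitutive exons
flanking the PEVK region and degenerates a configured number of positions
to IUPAC codes covering the true base — placing a primer inside an
alternative exon is rejected, since such a primer could not bind all
isoforms.

## Problem sizes used by the test-suite

The default template (8/6 Ig tracts, 14 core repeats, kinase) yields a
~30 kb gene and a ~7800 aa protein and is used where the canonical
architecture itself is under test.  Property suites that repeat generation
many times (exon-model recovery over 100 seeded genes, assembly event
suites) use a reduced template — 3/2 Ig tracts, 2 core repeats, 4 PEVK
exons — which preserves every structural feature (two tracts, unique
region, core, kinase, alternative PEVK exons) at roughly a quarter of the
sequence length; these sizes are the package's chosen test conditions.
Scanner-oracle suites run 500 random proteins of up to 200 aa against a
brute-force enumeration oracle, and alignment oracles cover all pairs up
to 12 aa.

## A worked run

```{r example, eval = FALSE}
fx <- msextaFixture()
isofs <- enumerateIsoforms(spliceGraph(fx$model))
isoformTable(isofs, fx$model)
inSilicoPcr(isofs$C, fx$primers)   # 926 bp
inSilicoPcr(isofs$D, fx$primers)   # 893 bp
lengthRatioPercent(205, 377)       # 54

tr <- generateGene(generatorConfig(seed = 1))
calls <- findDomains(truthProtein(tr), consensusDomains())
classifyArchitecture(calls, truthProtein(tr))
```

## Known limitations

* Homology anchoring is substitution-only; indel-diverged references will
  fragment or miss anchors.
* Assembly uses exact overlaps only; sequencing errors in overlap regions
  would break merges (error-tolerant assembly is out of scope).
* Only canonical GT–AG splice sites are modelled; non-canonical junctions
  surface as `ambiguous` calls rather than predictions.
* In-silico PCR requires unique primer sites and does not model primer
  thermodynamics or multi-product amplification.
* The consensus domain library is synthetic; real-genome annotation would
  substitute profile-based domain calls at the same interface.
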