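---
title: "Methods: CLASH hybrid discovery and methylation-guide classification"
author: "snoclash"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: CLASH hybrid discovery and methylation-guide classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind each pipeline stage, the
parameters that matter, the numerical choices, what the synthetic data
generator does and does not emulate, and the design decisions taken where
the methodology was genuinely open.

# Background and scope

Box C/D snoRNAs guide site-specific ribose 2′-*O*-methylation. The
canonical model: the snoRNA pairs with its target over an extended region
of complementarity (at least 12 bp) positioned immediately upstream of the
box D or box D′ motif, and the target nucleotide paired with the snoRNA
base exactly five nucleotides upstream of the box receives the methyl
group (the "+5 rule"). CLASH libraries capture these interactions as
chimeric reads: two ligated RNA fragments sequenced as one cDNA.

The package takes such a library from FASTQ to (i) a table of two-arm
hybrids with duplex folding energies, (ii) stability- and
reproducibility-filtered interaction sites, (iii) a per-hybrid guide /
non-guide classification with predicted methylation positions, (iv)
positional and gene-feature summaries, and (v) over-representation tests
of mRNA targets against an externally computed differential-expression
table. Differential expression itself, conservation analysis, and any
wet-lab concerns are out of scope.

# Reference construction (`buildReference`)

Records are **unspliced gene spans** (introns included), because hybrid
arms do map to introns; introns are derived as gaps between exon features.
Minus-strand genes are reverse-complemented at build time so every record
reads 5′→3′; the aligner searches both read strands instead.

Two operations mirror how a mapping reference for snoRNA CLASH must be
built:

* **Extension**: each snoRNA gene is extended by `snornaExtension`
  (default 20 nt) on both sides, clipped at contig ends. Recovered
  fragments frequently run a few nucleotides past annotated snoRNA ends;
  without flanks those arms would be truncated or lost.
* **Host masking**: wherever a snoRNA is nested inside another gene, the
  snoRNA footprint is replaced by N in the host record, so an arm arising
  from the snoRNA cannot be attributed to the host. We mask whenever a
  snoRNA is contained in another gene — the alternative ("only when
  ambiguity was observed") is not reproducible from inputs alone.

Coordinates are 0-based half-open in memory and 1-based inclusive in every
file, with the conversion confined to readers and writers.

## Box annotation (`locateBoxes`)

Curated box coordinates always take precedence. The motif search is a
fallback: box C = RUGAUGA with ≤ 1 mismatch in the first 30 nt, box D =
exact CUGA in the last 20 nt, internal D′ (CUGA, ≤ 1 mismatch) and C′
(RUGAUGA, ≤ 2 mismatches) between them, reported only as an ordered
D′ < C′ pair. Ties are broken by fewest mismatches, then by proximity to
the canonical end — 5′ terminus for box C, 3′ terminus for box D; the D′
candidate prefers the 5′ side and C′ the 3′ side of the internal region,
mirroring the terminal geometry of the C/D pair. Records lacking either
terminal box are flagged unannotatable rather than erroring: such snoRNAs
still appear in hybrid tables, merely unclassifiable as guides. Windows
and allowances are parameters; the defaults reflect how tightly the
terminal boxes sit against mature snoRNA ends. When records carry mapping
flanks, `annotateBoxes(extension =)` strips them for the search and
reports record-local coordinates.

# Preprocessing (`preprocessReads`)

The library structure is: 3-nt random tag, sample barcode, insert, 3′
adapter (miRCat-33, `TGGAATTCTCGGGTGCCAAG`). Demultiplexing matches
barcodes as exact prefixes at offset 3 (longest first); barcodes are short
and required to be prefix-free, so no mismatch tolerance is allowed —
a one-off barcode is more plausibly a different sample than an error.
Adapter trimming removes, at the leftmost position, either a full-length
adapter match with ≤ 1 mismatch or an exact adapter prefix (≥ 6 nt)
running to the read end; inserts shorter than 16 nt are dropped as
unalignable. Trimming precedes duplicate collapsing so adapter-length
variation cannot split true duplicates. PCR duplicates collapse on exact
(tag, insert) identity within a sample — the random tag is part of the
sequence being collapsed, and distinguishes independent molecules that
happen to share an insert.

# Chimera calling (`callHybrids`)

Arms are found by seed-and-extend local alignment: exact 11-mers
(the blastn-style word size) hashed over the reference, seed hits
clustered by (reference, diagonal), each cluster extended by affine-gap
Smith–Waterman (match +2, mismatch −3, gap open 5, extend 2; minimum
score 24; minimum identity 0.9).

Two numerical refinements matter in practice:

* **Identity-constrained sub-segment.** The raw local-alignment optimum
  often drags a low-identity tail across the ligation junction — chance
  matches at ~70% are net-positive under +2/−3 — and would then fail the
  identity filter outright. The aligner instead reports the
  maximal-scoring contiguous sub-segment of the optimal path whose
  identity meets the threshold.
* **Junction overlap resolution.** The two arms' read intervals may still
  overlap (each alignment extended past the junction). Overlaps up to
  `maxJunctionOverlap` (25 nt) — and at most 60% of the shorter alignment,
  so a genuinely double-mapped single fragment is never split into a fake
  chimera — are resolved by the split point maximising the number of
  bases matching their respective references on each side. Each arm's
  bases are mapped anchored at its *outer* end, so indels inside a dilute
  overrun cannot corrupt the profile. On flat tie plateaus (contested
  bases matching both references) the junction is placed at the edge
  adjacent to the arm that matches the entire overlap, else mid-plateau.

A hybrid requires two disjoint arms of ≥ 16 nt, an unaligned middle gap of
≤ 4 nt, and joint coverage of ≥ 90% of the read. Among score-tied
candidate pairs, pairs containing a snoRNA arm win (preference order
snoRNA > rRNA > mRNA > other), reflecting that the library is a snoRNA
pull-down. An arm with more than four equal-score placements makes the
read ambiguous and it is dropped; a read fully explained by a single
alignment is "single"; intramolecular chimeras (both arms in one record,
disjoint reference intervals) are retained — they carry snoRNA
intermolecular stem information. In the stored record the snoRNA arm
always comes first.

# Duplex folding (`duplexMFE`)

The folding energy of a hybrid is the minimum-free-energy
**intermolecular** duplex of its two arm sequences: dynamic programming
over antiparallel, non-crossing pairings with nearest-neighbour stacking,
bulge and internal-loop penalties (loop sides bounded at 15 nt), a duplex
initiation penalty (+4.09 kcal/mol) and a +0.45 penalty per AU/GU helix
end. No intramolecular structure, dangles or coaxial stacking are
modelled: the quantity of interest is a single interaction energy for the
arm–arm duplex, and the simpler model makes exhaustive enumeration
feasible as an independent oracle. The shipped parameter set
(`inst/extdata/nn_*.tsv`) is a Turner-2004-style table: Watson–Crick
stacks from the Xia et al. measurements, published GU stacks, and
Jacobson–Stockmayer logarithmic loop extrapolation, at 37 °C only.

Conventions: a structure with no admissible pair, or whose best energy is
positive, is the no-duplex sentinel (ΔG = +∞); a single isolated pair can
never beat initiation, so lone pairs are never reported. The test oracle
`enumerateDuplexes()` scores every pairing with an independent R
implementation of the same energy function and is guarded to
len₁+len₂ ≤ 16; equality of the dynamic program with this oracle — exact
ΔG, and a reported pairing that scores to exactly the optimal energy under
the independent scorer — is the module's acceptance gate. (Co-optimal
structures exist, so structures are compared through their energy, not
base-by-base.)

Absolute ΔG values are engine- and parameter-set-dependent; published
per-interaction energies from other folding engines are therefore never
asserted. What the threshold below needs is a consistent scale.

# Stability and reproducibility (`filterEnergy`, `clusterAndSupport`)

Stability: keep hybrids with ΔG ≤ −12 kcal/mol. The threshold is
inclusive; the two natural readings ("−12 or below" vs "less than −12")
differ only on exact boundary values, which are rare, and the rule is a
parameter (`dgThreshold`).

Reproducibility: two hybrids demonstrate independent recovery of the same
interaction when they involve the same ordered reference pair and both
their arm-1 and arm-2 intervals overlap (≥ 1 nt). Connected components of
this relation — single linkage — are the interaction clusters;
one interaction site per cluster (interval union on both partners), and a
hybrid is reproducible iff its cluster has ≥ 2 distinct post-deduplication
members. Support is counted on the set pooled across samples, with sample
provenance retained on the members; a per-experiment mode would merely
change the grouping key. Single linkage can chain non-overlapping hybrids
through intermediates; this is intentional and tested as such — sites are
maximal footprints, not fixed-width peaks.

# Guide classification (`classifyGuides`)

For each box present (D, then D′), with *d* the 0-based box start and the
offset 5: if the duplex pairs snoRNA position *d*−5, the target nucleotide
paired with it is the candidate methylation position, and the call is
`guide_D`/`guide_Dprime` when a contiguous helix of ≥ 12 pairs covers
snoRNA positions *d*−1 … *d*−5. When both boxes validate, a prediction
coinciding with an annotated site is preferred, then box D. Failing that,
a hybrid whose target arm covers an annotated methylation site is
`overlapping_nonguide` — stable binding at a site without guide geometry,
the competitive/regulatory class — and otherwise `nonoverlapping`.

One measurement detail: the helix is measured as the maximal contiguous
complementary run **at the pairing register anchored by the duplex pair of
position *d*−5**, evaluated over the full record sequences. The dynamic
program may trade a terminal pair of a perfect guide helix for a chance
flank extension plus an internal loop (the energy difference can favour
the trade), and recovered fragment ends sometimes clip the helix by a
base or two; neither changes the register of the +5 pair, and neither
should change a biological classification that is about complementarity
geometry, not about which of several near-degenerate foldings won. The
duplex remains the anchor evidence: a hybrid whose fold does not pair
position *d*−5 at all is never called a guide. GU wobbles count as pairing
by default (`allowGU = FALSE` restricts the helix to Watson–Crick pairs);
the interaction energies already treat GU as pairing, and the rule's
defaults are exposed in `guideRule()`.

`tabulateMethylationSites()` gives the per-site table (interactions
overlapping each annotated site; interactions predicted to guide it) and
its complement (interactions away from any site), and `guideFraction()`
reports guides as a fraction of site-overlapping hybrids — the statistic
that distinguishes a methylation-competent interaction profile from a
binding-dominated one.

# Annotation (`coverageProfile`, `assignMrnaFeatures`)

Coverage profiles add +1 per covered position per hybrid (deduplicated
molecules, not read copies), with optional flanks, clipping at window
edges; mass is conserved (sum of counts = sum of clipped arm lengths).
mRNA-arm hybrids are assigned to the feature containing the arm midpoint;
for even-length arms the midpoint index is the downstream of the two
central positions, so boundary-straddling arms go to the 3′ feature —
deterministic and length-unbiased. Arms whose midpoint lies in no
annotated feature (e.g. a masked region) are excluded from the four-way
UTR/CDS/intron/UTR tabulation as `unclassified`.

# Enrichment statistics (`targetEnrichment`)

The gene universe is the differential-expression table itself (the only
universe reproducible from the inputs); DE means adjusted p < 0.05 by
default. Both a two-sided Fisher exact test and a Yates-corrected
chi-square are always reported; the wrappers call the standard R
implementations, and the tests verify them against full hypergeometric
enumeration (every 2×2 table with N ≤ 12) and the corrected closed form.
Degenerate conventions: a zero margin gives p = 1; a zero expected cell
gives NA with a warning. No multiple-testing correction across snoRNAs is
applied — the analyses are single-set tests.

# The synthetic data generator

`simulateReference()` builds a mock genome: one rDNA-like gene (6 kb)
carrying 20 annotated methylation sites; 12 box C/D snoRNAs — each with
boxes C and D, eight with a D′/C′ cassette, two hosted inside mRNA introns
so extension and masking are exercised; 50 mRNAs with
5′UTR/CDS–intron–CDS/3′UTR structure on both strands. Guide snoRNAs carry
a 12–14 nt antisense element perfectly complementary to the target window,
placed so the site pairs the snoRNA base exactly 5 nt upstream of box D or
D′; every snoRNA also carries a 14 nt "blocking" element complementary to
a window overlapping a non-cognate site but far from any box, so the +5
geometry fails while site overlap holds.

`simulateReads()` emits, per unique molecule: 3-nt random tag + sample
barcode (the ten-linker default set) + two arms (18–40 nt, sampled to
leave ≥ 3 nt of flank around planted elements — recovered fragments extend
past the duplex) + the miRCat-33 adapter; arm order on the read is random.
Molecules get 1 + geometric PCR copies (mean 3) and i.i.d. substitution
errors per copy (0.002/base); constant Q40 qualities are written, since
the pipeline does not use qualities. Class mix defaults:
45% cognate guides, 15% blocking, 10% snoRNA–snoRNA, 10% snoRNA–mRNA,
15% single fragments, 5% unmappable noise.

Three constructions keep the ground truth exact rather than merely likely:

* (sample, tag, insert) triples are unique across molecules by rejection
  sampling, so error-free PCR collapse recovers the molecule count
  exactly — truth rows are unique molecules by definition.
* Spacer and terminal segments of synthetic snoRNAs are drawn from an
  {A,C} alphabet, and planted windows are rejected if their reverse
  complements contain CUGA or RUGAUGA, so motif-based box recovery on
  error-free sequences is exact.
* Guide-site neighbourhoods are rejected if they contain the reverse
  complement of the UGAUGA box core: such chance complementarity to the
  snoRNA's own C/C′ boxes can out-fold the planted guide helix and
  invalidate the planted label. The planted condition "cognate guide"
  must be true of the generated molecule, not just intended.

What the generator does **not** emulate: indels and quality-dependent
errors; ligation and fragmentation biases; abundance skew between
snoRNAs; intramolecular snoRNA stems; rRNA secondary structure; real
genome repeat content and paralogy. Passing the simulation-based checks
therefore demonstrates correctness of the algorithms under the stated
read model — it does not certify recovery rates on real libraries, where
mapping ambiguity and bias structure are harsher.

# Verification scales and determinism

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen to finish in minutes on one CPU while keeping binomial bands
tight: 500 random pairs for the duplex-vs-enumeration oracle (sequences
≤ 7 nt, the enumeration bound); a 20,000-molecule library (substitution
rate 0.002, duplication mean 3) for end-to-end recovery, with a
20,000-molecule error-free control for collapse exactness; 4,000
error-free molecules for classifier exactness; a 6,000-molecule mixture
with 7% cognate guides among site-overlapping chimeras for fraction
calibration; 1,000 random hybrids against the O(n²) clustering oracle;
all 1,820 2×2 tables with N ≤ 12 for the Fisher oracle; 150 label
permutations over a 20,000-gene universe for the null-uniformity check
(margins kept large so the discrete Fisher p has small atoms).

Every random draw descends from one user seed; reruns are byte-identical,
and `runAll()` writes a manifest with input checksums alongside the
output tables.

# Known limitations

* The energy model is deliberately minimal (no dangles, no coaxial
  stacking, no loop-asymmetry terms, single temperature); energies are
  comparable within the package but not directly against other engines.
* Spliced alignment is not supported; arms spanning exon–exon junctions
  of spliced transcripts would be missed (records are unspliced genes by
  design).
* Multi-mapping is handled by a preference order and an ambiguity cutoff,
  not by probabilistic assignment; on repeat-rich real genomes this is
  cruder than a dedicated mapper.
* Reproducibility support counts pooled molecules; replicate-aware
  designs need the per-sample provenance kept on the member hybrids.
* The acetylation-guide snoRNAs are not modelled: their hybrids simply
  classify as non-guide interactions, as no positional rule analogous to
  +5 exists for them.
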