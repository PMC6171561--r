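# snoclash

Analysis of CLASH libraries for box C/D snoRNAs: from raw barcoded
sequencing reads to filtered snoRNA–target interaction hybrids,
methylation-guide classification, positional annotation and
target-enrichment statistics.

## The problem

CLASH (crosslinking, ligation and sequencing of hybrids) captures RNA–RNA
interactions in vivo: UV-crosslinked, protein-bound RNA fragments are
ligated together so that two interacting RNAs appear as a single chimeric
cDNA. For box C/D snoRNAs — the guides of ribosomal RNA
2′-*O*-methylation — each chimeric read is evidence of a snoRNA bound to a
target. The analytical questions this package answers for such a library:

* Which reads are genuine two-arm chimeras, and where do the two arms map?
* Is each snoRNA–target duplex thermodynamically stable, and is the
  interaction reproducible across independent molecules?
* Does the duplex have methylation-*guide* geometry — and if so, which
  target nucleotide does it predict as methylated?
* Are the mRNA targets over-represented among differentially expressed
  genes?

## The models at the core

**Guide geometry (+5 rule).** A box C/D snoRNA carries terminal box C
(RUGAUGA) and box D (CUGA) motifs, with internal D′/C′ counterparts. It
guides 2′-*O*-methylation through an extended region of complementarity
(≥ 12 bp) with the target in which the methylated nucleotide pairs with the
snoRNA base exactly 5 nt upstream of box D (or D′). `classifyGuide()`
implements this rule on each hybrid's duplex: if a contiguous helix of
≥ 12 bp includes snoRNA positions *d*−1 … *d*−5 (*d* = box start), the
target base paired with *d*−5 is the predicted methylation site
(`guide_D` / `guide_Dprime`); otherwise the hybrid is
`overlapping_nonguide` when its target arm covers an annotated site, else
`nonoverlapping`.

**Duplex stability.** `duplexMFE()` computes the minimum-free-energy
intermolecular duplex of the two arms by dynamic programming over
antiparallel, non-crossing pairings under a nearest-neighbour model
(stacking energies, bulge/internal-loop penalties, duplex initiation,
terminal AU/GU penalty; 37 °C). Hybrids with ΔG ≤ −12 kcal/mol are retained
(`filterEnergy()`), and `clusterAndSupport()` groups hybrids whose two arms
both overlap into interaction sites, flagging those supported by at least
two independent molecules as reproducible.

**Chimera calling.** `callHybrids()` aligns each deduplicated read by
seeded Smith–Waterman (word size 11, match +2 / mismatch −3, gap 5/2) and
selects the best pair of disjoint arms, preferring snoRNA-containing
assignments on score ties.

A synthetic data generator (`simulateReference()`, `simulateReads()`)
builds a mock genome — rDNA with planted methylation sites, snoRNAs
carrying boxes and antisense elements that satisfy the +5 rule exactly,
intron-containing mRNAs — and emits barcoded, UMI-tagged, adapter-carrying
FASTQ reads with PCR duplication and substitution errors, plus a
ground-truth table, so every stage is verifiable.

## Worked example

```r
library(snoclash)

cfg    <- simConfig(seed = 7, n_reads = 3000)
simref <- simulateReference(cfg, dir = "sim")
sim    <- simulateReads(simref, cfg, fastqPath = "sim/reads.fastq")

run <- runAll(pipelineConfig(fastq = "sim/reads.fastq",
                             referenceBundle = simref$paths$bundle,
                             outputDir = "run1"))
#> [snoclash] preprocess: 8951 reads -> 3793 unique molecules
#> [snoclash] chimera: 3026 hybrids (545 single, 222 unmapped, 0 ambiguous)
#> [snoclash] filter: 2349 stable, 2295 reproducible, 97 interaction sites
```

The 8,951 FASTQ records collapse to 3,793 unique molecules (3-nt random
tag + identical insert within a sample = one molecule); 3,026 of them are
two-arm chimeras. After the ΔG ≤ −12 filter and the two-independent-
molecules rule, 2,295 reproducible hybrids cluster into 97 interaction
sites. The summary shows what they are:

```r
run$summary$target_category_percent
#> $snoRNA 0.523   $rRNA 98.9   $mRNA 0.61   $other 0
run$summary$guide_calls
#> guide_D 1022   guide_Dprime 678   nonoverlapping 757   overlapping_nonguide 569
run$summary$guide_fraction
#> [1] 0.749
```

Most reproducible targets are rRNA, and 74.9% of the site-overlapping
hybrids have guide geometry — matching the simulated class mix (45%
cognate guides vs 15% site-blocking interactions). The per-gene feature
breakdown of the snoRNA–mRNA hybrids
(`run$summary$mrna_feature_counts`: 66 5′UTR / 147 CDS / 60 intron /
71 3′UTR here) mirrors the planted feature distribution.

All tables (hybrids, interaction sites, guide calls, feature assignments)
are written under `outputDir` as TSV with 1-based inclusive coordinates,
alongside a manifest with input checksums. A thin command-line front end
over the same functions ships in `inst/scripts/snoclash.R`.

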