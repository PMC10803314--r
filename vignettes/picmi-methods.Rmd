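---
title: "Detecting and quantifying PICMI phage satellites: models and methods"
author: "picmiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying PICMI phage satellites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picmiscan)
```

## The biological problem

PICMIs (phage-inducible chromosomal minimalist islands) are a family of very
small (~6 kb) phage satellites of marine vibrios. They integrate into the
bacterial chromosome immediately downstream of the *fis* regulator gene,
delimited by a pair of short exact direct repeats (17 bp in the prototype),
and carry a minimal gene set: an integrase (*int*), the AlpA-like regulator
(*alpA*), a primase (*prim*), and a handful of genes of unknown function
(*iolg*, *up1*, *up2*). Upon infection by a helper phage they excise,
replicate, and hijack the helper's capsids: because the satellite is roughly
one eighth of the helper genome, it is packaged as a head-to-tail concatemer
of about eight copies filling one helper-sized capsid.

`picmiscan` implements the in-silico side of the biology: detecting
PICMI-like loci in annotated genomes, extracting their boundaries,
comparing elements across genomes, and quantifying how many helper particles
are hitchhiked by the satellite in particle-sequencing data. A seeded
synthetic-data generator provides ground-truthed genomes and read sets for
validation.

## The detection model

Detection is a gene co-localization model over domain-annotated genes, in the
tradition of MacSyFinder-style rule engines. A locus is called when one gene
matching each mandatory marker role occurs on one contig, with at most
`maxGeneGap` intervening genes between consecutive marker-bearing genes
(order-agnostic, either strand):

* **integrase** — Pfam PF00589, PF00239 or PF07508;
* **alpA** — PF05930 or PF12728;
* **primase** — PF13148 (DUF3987) or PF19263 (DUF5906);
* **fis** — PF02954.

Domain accessions are matched case-insensitively with version suffixes
stripped, because annotators disagree on versions. `fisPolicy` controls
whether fis is mandatory (the default) or merely an optional anchor label;
the mandatory default reflects that no complete element has been observed
without a *fis* anchor, while the switch allows screens for elements using
other integration sites.

`maxGeneGap` defaults to 5 intervening genes. No co-localization distance is
canonical for this family; 5 is the conventional default of co-localization
rule engines in this field, and the parameter is exposed so that users can
tighten or relax it. With typical gene density this corresponds to roughly
5-8 kb, comfortably larger than any observed PICMI inter-marker distance.

Candidates are then filtered:

* `cross_contig` — marker hits joined from different contigs during the
  edge-merge step for draft assemblies;
* `other_family` — a gene inside the span carries a hallmark product label
  of another satellite family (*terS*, *sid*, *ppi*, *psu* for PICI,
  cf-PICI, P4 and PLE respectively);
* `bad_fis_anchor` — the anchor gene's global protein identity to a fis
  reference falls below 30%, or below its identity to a user-supplied decoy
  anchor. The 30% floor operationalizes "integrated into a gene with lower
  identity to fis" as a concrete, configurable threshold at protein level;
  protein rather than nucleotide identity was chosen because the anchor
  test is a homology question and protein comparisons remain informative at
  far greater divergence.
* `oversize` — span beyond `maxElementLen` (50 kb default, the upper bound
  of helper-phage genome sizes this family associates with).

## Boundary extraction

The element proper runs from the first base of the *fis* gene to the distal
copy of the flanking direct repeat past the integrase. The repeat pair is
found by exact longest-common-substring search between an anchor window at
the *fis* 3' end and a search window downstream of *int*; the search is
exact-match only with a 15 bp floor, because the known repeats are exact
17-mers and no mismatch tolerance has been described. Ties prefer the pair
spanning the largest interval, then the leftmost pair. When no repeat
reaches the floor, extraction falls back to `[fis start, int end + 1000 bp]`
and records the absence; repeat-less extraction has no described precedent,
so the fallback margin is deliberately generous and flagged rather than
silent. Sequences are always reported fis-forward (reverse-complemented when
*fis* lies on the minus strand).

Within extracted elements, `findSmallOrfs()` runs a six-frame scan of
non-coding stretches for ATG-initiated, stop-terminated ORFs of 30-59
amino acids (the questionable small proteins in the prototype are 32-44 aa).
Each ATG is paired with its nearest in-frame stop; ORFs overlapping an
annotated gene by more than 30 bp are discarded.

## Comparative analysis

**Pairwise identity.** Element sequences are compared by end-to-end global
alignment with affine gaps (match +1, mismatch -1, gap open 4, extend 1 —
conventional, configurable); identity is matches over alignment columns with
gap columns in the denominator, because elements are compared over their
full extracted span, indels included.

**Subfamilies.** Elements cluster at >= 90% identity. How pairwise
identities become groups is genuinely open; the default is single linkage
(connected components of the threshold graph), which never splits a pair
above threshold, with complete linkage available for users who prefer
compact clusters. The cutoff is inclusive (>= 0.90) by default with a
`strict` switch, since both ">90%" and ">=90%" conventions circulate.
Subfamily ids are dense integers ordered by decreasing cluster size.

**Gene families.** Proteins cluster by reciprocal best hit: all-vs-all
local alignment (BLOSUM62, gap open 11/extend 1), hits valid at >= 20%
identity and >= 50% coverage of both partners, best hit per (query, target
proteome) by score with ties broken by identity then lexicographic id, and
families as connected components of the reciprocal graph. Ties are broken
deterministically so the output is invariant to input order. Small ORFs and
pseudogenes are excluded from family clustering, mirroring how
non-functional elements are treated in comparative screens.

**Integrase neighbor.** The gene between *int* and *alpA* is typed as
*iolg* when its coordinates overlap *int* (1, 4 or 13 nt in known elements;
the 4 nt overlap ATGA is the most frequent configuration), *icg* when
present but non-overlapping, or *absent*. The overlap motif is reported
5'->3' on the fis-forward strand.

## Packaging quantification

`hitchhikerFraction()` normalizes read counts per bp of element, divides
the satellite depth by the concatemer copy number to obtain particle
equivalents, and reports the satellite-filled share of particles. Two values
are returned deliberately: the full-precision percentage, and a
printed-convention value that rounds intermediates to two decimals and
truncates the final percentage to an integer. The prototype numbers
(634,740/47,851 = 13.26; 108,219/6,110 = 17.71; 17.71/8 = 2.21;
2.21/13.26 -> 16%) follow the two-decimal chain, so the printed-convention
output reproduces them digit for digit while displays default to full
precision.

`headfulCopyNumber()` returns the k >= 1 minimizing |k x satellite - helper|
with ties to the larger k (a headful mechanism overshoots rather than
undershoots); for the 47,851/6,110 bp pair this gives k = 8, the observed
concatemer.

`classifyReads()` assigns reads to helper, satellite, hybrid or unassigned
by best local alignment on both strands: a reference anchors a read when at
least 50 aligned bases match at >= 80% identity, and hybrids anchor to both.
Alignment was chosen over k-mer classification so the same operation serves
short and long reads. `mapConcatemerReads()` places long reads on an
artificial tandem reference of 13 unit copies (any count covering the
longest read is equivalent) and reports the start phase modulo the unit
length; reads below 70% alignment identity, or aligning over less than half
their length, are dropped with a logged count.

`extremityRandomnessTest()` distinguishes headful (pac-like) from
fixed-end (cos-like) packaging: read start phases are binned into 20
equal-width bins of the unit and tested against uniformity by chi-square
goodness of fit. Chi-square over binned phases was preferred to a
Kolmogorov-Smirnov test because phases are circular on the unit and a
binned test is insensitive to the arbitrary origin. Fewer than 20 reads is
an error (underpowered), not a verdict.

## The synthetic-data generator

`generateGenome()` emulates the study conditions: a random-background
contig carrying a zntR-fis anchor and a 6,110 bp cassette in gene order
fis - up2 - prim - up1 - alpA - iolg - int between exact 17 bp direct
repeats, an iolg overlapping int by 4 nt with motif ATGA (1, 13, 0 nt and
iolg-free variants configurable), a 47,851 bp helper, 8 concatemer copies,
and a chimera rate of 1e-4 of reads (loosely matching 16 hybrid reads in
~743,000). Planted gene sequences are random ORFs with fixed per-role
lengths, so label-driven detection and sequence-driven operations are both
exercised. Background composition is uniform ACGT; GC bias, real sequencing
error profiles and assembly artifacts are out of scope, so passing tests
demonstrate correctness of the algorithms under the stated model, not
robustness to real-data noise.

One numerical subtlety: the bases flanking each repeat copy are pinned to
differ between the two copies. Without this, with probability ~1/2 per
genome a flanking base would match by chance, the true longest common
substring would be 18 bp rather than the planted 17, and extracted
coordinates would be off by one - a property of the random background, not
of real attachment sites, which are by definition maximal.

Decoy loci exercise each filter: an other-family locus carrying a
terS-labeled gene, core genes scattered beyond the co-localization gap, an
element split across two contig edges, and a cassette anchored at a
fis-labeled gene whose protein is unrelated to the fis reference.

`mutateElement()` applies substitutions plus 10% indel events (1-3 bp) at a
target per-base divergence; `generateSubfamilySet()` plants subfamily
structure by deriving founders at the between-subfamily divergence from a
base cassette and members at half the within-subfamily divergence from each
founder, so that pairwise within-subfamily divergence matches the
configured value. `simulateReads()` draws per-read origins from the
particle mixture (satellite probability f Lc / (f Lc + (1-f) Lh)), which is
exact for uniform per-base sampling and lets the fraction-recovery suites
run at n = 100,000 reads without per-base sequence simulation; sequence
emission is available for the alignment-based operations at smaller n.

## Problem sizes and numerical choices

The validation suites run at sizes chosen to exercise every code path while
staying within a desk-scale compute budget: 50 genomes for planted-element
recovery (mixing all decoy types, both strands, one negative control in
ten), 5 planted subfamilies of 2 members at 3%/20% divergence for
clustering recovery, 10 proteome pairs for RBH-vs-oracle agreement, 100,000
reads per fraction for recovery within 3 binomial standard errors, and 100
seeded uniform-null replicates of 500 phases for the calibration of the
extremity test (observed type-I error is required to lie in [0.01, 0.10] at
alpha = 0.05). Brute-force oracles (quadratic window enumeration, all-pair
substring search, six-frame ORF walk, transitive-closure clustering,
exhaustive RBH) are implemented independently in the test suite and agree
exactly with the package implementations on these fixtures.

Known limitations: detection consumes existing domain annotations and is
blind to unannotated or mislabeled marker genes; the repeat search is exact
and will shorten boundaries at attachment sites containing SNPs between
repeat copies; subfamily clustering at full element length is O(n^2) global
alignments and is intended for tens-to-hundreds of elements, not thousands;
and the hybrid-read definition (dual anchoring) does not require
junction-spanning alignment, so co-packaged but non-chimeric molecules are
not distinguished from true chimeras.

## A worked example

```{r example, eval = FALSE}
library(picmiscan)

# simulate a genome with a planted element and decoys, then detect
cfg <- simulationConfig(seed = 3, decoys = c("other_family", "cross_contig"))
g <- generateGenome(cfg, 1)
res <- detectElements(g$genome, picmiModel(), fisReferenceProtein())
el <- res$elements[[1]]
el
classifyIntNeighbor(el)

# packaging arithmetic of the prototype system
est <- hitchhikerFraction(packagingCounts(634740, 108219, 47851, 6110, 8))
est
headfulCopyNumber(47851, 6110)
```
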