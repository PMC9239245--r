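---
title: "Methods: pangenome, variant and mobile-element comparison of closely related strains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome, variant and mobile-element comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model system

`strainpan` compares panels of closely related bacterial genomes. Its
design point is a panel like the *Synechococcus elongatus* strain group:
several long-cultivated laboratory strains that are nearly identical
(pairwise nucleotide divergence on the order of 0.1%) plus one divergent
environmental isolate (~1.5%), with the biologically interesting
differences concentrated in mobile elements — tRNA-integrated prophages,
plasmid gain/loss and fusion, a large chromosomal inversion bounded by
HIP1 octamers, CRISPR arrays — and in blocks of strain-unique genes whose
functional categories depart from the genomic background.

Everything is validated end to end on synthetic panels with a complete,
machine-readable truth log; the package never needs network access.

# The synthetic panel and its truth log

`generateAncestor()` packs intact open reading frames (bacterial genetic
code, table 11), tRNA genes (70–90 bp, plus strand) and one ncRNA into a
chromosome and two plasmids, plants HIP1 octamers (`GCGATCGC`) in
intergenic space at a Poisson per-kb rate, and labels every gene with a
COG-like category, a product string and evidence flags (transcribed /
essential). Default sizes are deliberately scaled down from a real
cyanobacterial genome — a 150-kb chromosome with 120 genes, a 40-kb and
an 8-kb plasmid — so that a full panel analysis runs in minutes on one
CPU; the event densities, not the absolute genome size, are what the
detectors respond to.

`deriveStrain()` applies events in a fixed, documented order:
substitutions → indels → inversion → prophage insertion → plasmid events
→ CRISPR array → unique gene blocks → annotation-only tweaks. Fixing the
order makes every recorded coordinate reproducible. Each sequence-level
operation is appended to a script that `replayTruth()` folds back over
the ancestor; a test asserts byte-identical reconstruction of every
derived genome.

Key generator choices:

* **Substitutions.** Counts are Binomial(site count, rate) per feature
  and per intergenic stretch. Inside CDSs, at most one substitution is
  placed per codon and the amino-acid-changing fraction is drawn
  explicitly (default `pNonsyn = 0.2`, mirroring the observed one-fifth
  of coding SNPs that alter proteins in real strain panels). Codons that
  cannot yield the drawn class (ATG, TGG have no synonymous neighbour)
  are swapped for another codon rather than silently reassigned, keeping
  the configured fraction unbiased. Start/stop codons and the terminal
  bases of the prophage anchor tRNA are masked so that planted structure
  stays intact.
* **Indels.** 1–12 bp, geometric length, excluded from tRNA/ncRNA genes,
  from 30 bp around CDS boundaries, from planned inversion spans, and
  from anywhere a left-shift could move them — the generator only plants
  indels that are already in their leftmost-equivalent placement, so the
  caller's normalized coordinates can be compared exactly.
* **Prophage.** The element is inserted immediately 3′ of the anchor
  tRNA and ends with an exact copy of the tRNA's terminal 60 bp (the
  att duplication). Strains given the same element seed receive an
  identical element, so the five laboratory strains share one prophage
  while the environmental strain carries a different one at a different
  tRNA — exactly two distinct elements per panel.
* **Inversion.** Bounds are chosen as a planted HIP1 octamer pair about
  20 kb apart; the octamer is its own reverse complement, so the
  boundaries survive inversion. Pairs spanning a tRNA are excluded so
  prophage anchors keep their orientation.
* **Plasmid fusion.** The environmental strain's large plasmid keeps the
  full backbone and gains an expanded gene region bracketed by a
  duplicated copy of an adjacent backbone gene pair — the signature the
  plasmid comparison is asked to recover.
* **Annotation discrepancies.** Start-codon truncations (+9 nt in a
  minority of strains), untranscribed "hypothetical protein" genes and a
  pseudogene (dropped by consensus), and an ncRNA annotated in a single
  strain with transcription and essentiality evidence (promoted).

What the generator does **not** emulate: sequencing error, assembly gaps,
rearrangement hotspots, horizontal transfer with homology to the host
genome, or realistic phylogenetic correlation between strains (each
strain derives independently from the ancestor). Passing the truth-recovery
tests therefore demonstrates correctness of the algorithms under clean
assemblies, not robustness to assembly artefacts.

# Orthology and the pangenome

Gene-versus-gene scoring is global affine-gap alignment of nucleotide
sequences (match +2, mismatch −3, gap open 5, gap extend 2 — near common
nucleotide-search defaults; the substitution scheme is configurable in
one place). Identity is defined once: identical columns divided by
alignment length including internal gap columns, excluding terminal
overhangs; N never counts as a match. A k-mer prefilter (k = 12)
restricts which pairs are aligned; at the panel's divergences the true
ortholog shares hundreds of 12-mers, so the prefilter cannot change best
hits. For equal-length pairs at ≥90% gapless identity the gapless
alignment is provably score-optimal (a mismatch at −3 is always cheaper
than the bracketing gap pair), so the dynamic program is skipped — an
exactness-preserving fast path, not an approximation.

Reciprocal best hits (ties broken toward the lexicographically smaller
locus tag) with ≥70% identity over ≥50% of the shorter gene become edges;
groups are the single-linkage closure built greedily by decreasing edge
score under the constraint of at most one member per strain. A
conflicting merge is skipped, which is exactly the "keep the best edge,
re-seed the rest" resolution for within-strain duplicates such as the
fusion plasmid's duplicated flank genes. Classification is by membership
count (core = all strains, unique = one).

# Variants and effects

Groups are aligned by a center-star progressive scheme: every member is
aligned to the longest member and gap runs are normalized to their
leftmost equivalent placement before merging on center coordinates. At
panel divergences the center-star solution coincides with the optimal
multiple alignment; equal-length, high-identity groups use the gapless
stack directly. Leading/trailing overhangs (annotation-length
differences) are treated as missing data so that a truncated start
annotation does not masquerade as a deletion.

One call is emitted per polymorphic column (SNPs; multi-allelic columns
stay one call with per-strain alleles) or per contiguous gap-column run
(indels). Indel calls are anchored on the base immediately left of the
run in gene orientation; per-strain 1-based replicon coordinates are
back-computed through each member's feature. Effects are classified
against the reference strain (default: the first bundle): codons are
rebuilt from the reference frame, the full mutated codon of the first
differing strain is translated (neighbouring substitutions in the same
codon are honoured even though calls are not merged), stop gain is
nonsense, CDS indels are frameshift iff length mod 3 ≠ 0, tRNA/ncRNA and
pseudogene features give `noncoding_gene`, positions outside features are
intergenic. The summary statistic `pct_aa_changing` is the percentage of
reference-frame coding SNPs with effect missense or nonsense; on the
synthetic panel it runs one to two points above the generator's planted
20% because classification is referenced to one strain (reverse
substitutions where the reference itself carries the variant, and rare
codon collisions between strains, reclassify a small minority of calls).

# ANI and AAI

ANI follows the fragment (ANIb-like) definition: the query is chopped
into non-overlapping 1020-bp fragments (the final partial fragment is
discarded), each fragment is placed at its best seed diagonal in the
subject (15-mer seeds, both strands) and aligned within a banded window
(band 0.2 × fragment length). Identity is evaluated on a local alignment,
so a fragment straddling a homology boundary contributes the identity of
its aligned part and the ≥30% identity / ≥70% coverage filters decide
whether it counts — the published cutoffs of the fragment-based method.
One-way ANI is the mean identity of kept fragments; the reported value is
the two-direction mean. Fragments with no seed k-mer fall back to full
dynamic programming only on small subjects (≤100 kb total); on larger
genomes a placement able to pass the 30%/70% filters would share a
15-mer with near certainty, so seedless fragments are counted as
unaligned. AAI is the mean identity of reciprocal-best-hit protein pairs
(BLOSUM62, gap 11/1) passing the same 30%/70% filters.

# Mobilome detectors

* **Prophages.** For each tRNA, occurrences of its 3′-terminal 15-mer on
  the same strand within 150 kb downstream are extended leftwards to the
  maximal exact duplication; the largest duplication (15–200 bp) whose
  copy closes an element of ≥5 kb is called, with attL at the tRNA's
  terminus and attR at the distal copy. Minus-strand anchors are handled
  by transforming to the reverse complement and mapping back. The 150-kb
  window covers elements far larger than the ~90-kb prophages seen in
  real panels; 5 kb suppresses spurious short duplications.
* **Inversions.** k-mers (k = 21) unique in both genomes anchor
  collinear blocks (vectorized chaining; drift tolerance 200 bp, block
  break at 5-kb anchor jumps); blocks in the minority orientation are
  inversions, with boundary uncertainty equal to the flanking anchor gap
  and `boundary_hip1` set when a HIP1 octamer lies in both uncertainty
  intervals.
* **Plasmid fusion.** Anchor-chained homology blocks give the shared
  backbone length; B genes whose best A hit is shared two-to-one flag
  duplicated flanks, and the inter-flank segment is reported as the
  candidate expanded (fusion) region.
* **CRISPR arrays.** Repeated 21-mers with plausible periodicity are
  extended to the maximal identical repeat across all copies and
  validated: repeat 21–50 bp, ≥3 copies, spacer lengths within
  [0.6, 2.5] × repeat length, spacers mutually distinct (which rejects
  plain tandem repeats). Spacers are exported as FASTA; searching them
  against external databases is out of scope.

# Enrichment statistics

`fisherTwoSided()` implements the standard two-sided Fisher exact test —
the sum of hypergeometric probabilities, over tables with the observed
margins, not exceeding the observed table's probability — in log space
with a 1e-7 relative comparison guard; a test asserts agreement with an
exhaustive enumeration oracle to 1e-12 on every 2×2 table with total
≤ 60, and with `stats::fisher.test` on random tables. `bhFdr()` applies
the Benjamini–Hochberg step-up (delegating the arithmetic to
`stats::p.adjust`, which implements exactly the printed formula) and is
checked against hand-executed cases. Fold enrichment is
`F = Ngc / Egc`, `Egc = Ng · fc`, `fc = Nc / N`. Genes with several
category labels contribute to each category's table independently with N
fixed at the gene total; categories with `Nc = 0` are skipped rather than
emitting NaN. The FDR family is the set of categories tested for one
gene set — pooling all gene sets into a single family is the other
defensible choice, but the per-set family matches how per-figure
analyses are usually read and is what the package documents.

The type-I calibration test draws 1,000 random 300-gene sets from a
3,000-gene genome with ten categories and checks that the fraction of
p ≤ 0.05 falls in the binomial 99% band around 5%; at these table sizes
the hypergeometric distribution is fine-grained enough that the discrete
conservatism of the exact test stays inside the band.

# Consensus annotation

Per group: start-coordinate disagreement is read off the group
alignment's leading overhangs and resolved to the majority offset (ties
toward the longest ORF — the conservative choice that keeps sequence);
hypothetical/pseudogene groups whose evidence-bearing members are all
untranscribed, with no essential member, are dropped; ncRNA groups with
transcription evidence anywhere are promoted. Groups without any
evidence are kept and annotated "no evidence". An invariant test asserts
that no dropped group contains an essential member, and the panel test
asserts the planted counts (three start adjustments, four drops, one
promotion) are recovered exactly. Transcription evidence is consumed as
a boolean and never re-derived from coverage — the thresholds behind
published evidence layers are not reproducible from the data shipped
here.

# Numerical and engineering choices

* Coordinates are 1-based inclusive everywhere, carried by
  `GRanges`/`IRanges`; BED export converts to 0-based half-open at the
  boundary.
* The genetic code is fixed to bacterial table 11; there is no knob.
* All randomness flows from explicit seeds; panel generation, every
  detector and the pipeline are deterministic given the configuration.
* Problem sizes in tests (a 150-kb six-strain panel; 25 replicate
  mini-genomes for the prophage error-rate property; 60-kb pairs for ANI
  calibration) are the package's own scaled-down study conditions,
  chosen so the full suite exercises every code path on one CPU in
  minutes while keeping event counts high enough for the statistical
  bands to be meaningful.

# Known limitations

* Orthology is single-copy by construction; true paralog families are
  split, not modelled.
* The center-star alignment is exact only at low divergence; above ~10%
  divergence a proper progressive aligner would be preferable.
* ANI values on structurally divergent genomes sit slightly below the
  pure substitution expectation because boundary fragments contribute
  partial homology — a property shared with the fragment-based method
  itself.
* The variant caller sees only genic regions (homology groups);
  intergenic variation is generated and logged but not called, matching
  the pangenome-alignment design.
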