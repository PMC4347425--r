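---
title: "Methods: lineage-restricted OR discovery and screen quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-restricted OR discovery and screen quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orscreen)
```

# Overview

Odorant receptors (ORs) form the largest mammalian G-protein-coupled
receptor family, and most human ORs have no known agonist. `orscreen`
implements, as a reusable pipeline, two linked analyses:

1. **Lineage-restricted gene discovery.** Curate human OR genes as
   functional or pseudogene from their open reading frames, align each
   functional gene against the chimpanzee, dog, mouse and rat genomes,
   call per-species presence from alignment identity and coverage, and
   select the genes restricted to humans (or to humans and chimpanzees).
   The selected set is characterized by a pairwise amino-acid identity
   matrix and a bootstrap-supported neighbor-joining tree.
2. **Heterologous screen quantification.** Quantify a 96-well CRE
   reporter assay in which HEK293T cells expressing one OR are challenged
   with one odorant per plate at 10, 100 and 1000 µM: background
   double subtraction, a fixed hit threshold, replicate aggregation,
   percent-of-maximum dose–response normalization, potency classes and
   combinatorial screen summaries.

Every stage has a seeded simulator emitting ground-truth records, so the
whole pipeline is testable offline with parameter-recovery tests.

# Curation model

OR coding regions are intronless, so curation reduces to ORF arithmetic.
An ORF runs from an ATG to the first in-frame stop over all six frames;
the stop codon is counted inside the coding length (configurable with
`include_stop`). A gene is a pseudogene when it has no ORF, its longest
ORF is shorter than `min_coding_nt` (default 900 nt, i.e. 300 codons with
the stop), or its annotation flags a frameshift. The boundary case of
exactly 900 nt is classified functional: the rule is *pseudogene iff
length < 900*. Because curated exceptions exist in practice — a receptor
with a 293-residue ORF (882 nt with stop) that carries every family motif
and is merely short at the N-terminus — an override list can force
individual genes to functional status while retaining the original
reasons for auditability.

Motif checking scans the ORF translation for three consensus patterns
characteristic of the OR family (a `MAYDRYVAIC`-like DRY box, a
`KAFSTCASH`-like TM6 motif, and a `PMLNPFIY`-like NPxxY region), each
allowing one mismatch. The exact motifs a curator uses are a judgement
call; ours are standard family consensus patterns supplied as data
(`or_default_motifs()`), not code, and they inform the report without
gating the functional/pseudogene status.

# Homology screen

## Aligner

`seed_and_extend_align()` is a BLAT-style nucleotide search: exact k-mer
seeds (default k = 11, two-bit encoded) locate candidate diagonals in
each target contig; seeds are clustered on the diagonal (split at jumps
larger than the 50-column band padding, and across target gaps longer
than one query length); overlapping candidate regions are merged; and
each region is aligned to the query by full local dynamic programming
with affine gaps (match +1, mismatch −2, gap open −3, gap extend −1) in a
C++ kernel with traceback. Within a seeded region the reported score is
therefore the exact Smith–Waterman optimum, which the tests verify
against an independent implementation (Biostrings local alignment) on
planted-homology instances. Both strands are searched; minus-strand hits
carry forward-strand query coordinates.

One sensitivity refinement: when the primary pass finds no hit at all,
the search re-seeds once at k = 8 (the smallest seed we allow). Around
85% nucleotide identity a 150–300-nt query has an appreciable chance of
containing no exact 11-mer match, and a screen for *absence* must not
mistake seed sparsity for divergence; k = 8 makes missed counterparts at
the 70% decision boundary vanishingly rare while leaving the common case
untouched.

## Presence and lineage rules

For each (query, species) the best hit is the highest score (ties: more
matches, then smaller target start). Identity is `100 · matches /
aligned_cols` of the best hit — all alignment columns count, so gaps
penalize identity (an alternative `match_mismatch` denominator is
available). Coverage is the aligned query fraction of the single best
hit, a conservative and deterministic choice. A query is *present* in a
species when identity ≥ 70 **and** coverage ≥ 70, both inclusive
("at least 70%"). Lineage categories follow the presence pattern over
exactly four species: absent everywhere → `human_only`; present in
chimpanzee and absent in dog, mouse, rat → `human_chimp_only`; anything
else → `shared`. The selected set is the union of the first two
categories minus curated (non-overridden) pseudogenes. The screen is
one-directional; reciprocal-best-hit filtering is deliberately not
applied.

# Identity matrix and tree

Pairwise amino-acid identities use global (Needleman–Wunsch, affine-gap,
BLOSUM62) alignment of each unordered pair, aligned once so the matrix is
exactly symmetric. Identity = identical columns / columns remaining after
dropping pair-gap columns and stripping terminal-gap columns; internal
gap columns count against identity. This approximates common
percent-identity reports; the convention is configurable and matters at
the margin when comparing against numbers produced by other alignment
tools, whose identity definitions differ subtly.

The tree is built by canonical neighbor joining on `d = (100 −
identity)/100`, exact on additive distances; negative NJ branch lengths
are clamped to zero with the raw values retained. We use distance-based
NJ rather than maximum-likelihood inference deliberately: the tree's role
here is to display relationships among a few dozen receptors, NJ is
exact whenever the distances are additive, and it keeps the package free
of external phylogenetics binaries. Bootstrap supports resample alignment
columns with replacement (default 100 replicates, seeded), rebuild the
identity → distance → NJ tree per replicate, and report the percentage of
replicates containing each bipartition of the full-data tree.

# Screen quantification

The response statistic for one (OR, odorant, concentration) cell is

$$R = [F(\mathrm{OR{+}od}) - F(\mathrm{empty{+}od})] -
      [F(\mathrm{OR}) - F(\mathrm{empty})]$$

in arbitrary fluorescence units, where each F term is the mean over
replicates of the matching wells on that plate. Pre-averaging before
subtraction is the only order compatible with sharing one set of
empty-vector wells per plate; the displayed standard error is taken over
per-replicate responses with replicates paired by index. The statistic is
invariant to plate-wide additive offsets, which the tests assert exactly.
A cell missing any of its four conditions is *not evaluable* — reported
as NA, never as zero — and negative responses are kept so that
inhibition-like artifacts stay visible.

A response is a hit when `R > 3e5` AU, a strict inequality applied to the
replicate-mean response (switchable threshold). The lowest concentration
with a hit sets the potency class: 10 µM → high, 100 µM → mid, 1000 µM →
low. Rho-tagged and untagged constructs are distinct conditions end to
end and are never pooled, because tag effects on surface expression can
change odorant responses in either direction. Plates whose GFP
transfection fraction is below 0.70 (inclusive pass at exactly 0.70) are
excluded with a logged reason before any response is computed.
Dose–response display uses percent-of-maximum normalization over a chosen
receptor set and is refused when the set has no positive response. No
EC50/Hill fitting is attempted: three concentrations per odorant cannot
constrain a sigmoid, and the potency-class encoding is the analysis
output.

# Synthetic data: what it emulates, and what not

The generators define the study conditions used by every test:

* `simulate_or_gene()` — a single-ORF, 310-codon (930 nt) gene with the
  family motifs planted at canonical relative positions; 294 codons
  reproduce the 882-nt curation edge case.
* `simulate_or_family()` — 20 genes, 5 with lesions (single-nucleotide
  frameshift or premature stop). Lesions sit between codons 80 and 150,
  which bounds every surviving ORF below 900 nt (upstream ≤ 453 nt,
  downstream ≤ 690 nt), so status recovery is exact by construction and
  the recovery test is a genuine implementation check rather than a
  coin flip. Frameshifts are redrawn until the shifted frame stops within
  50 codons; the generator verifies this on its own product by direct
  codon inspection.
* `mutate_to_identity()` — plants exactly `round(L·(1−t/100))` distinct
  substitutions, so realized identity is always within ±0.5 points of
  target; truth records report the realized value.
* `plant_gene()` — inserts a gene prefix (truncation models partial
  counterparts) at a random position on either strand.
* `simulate_plate_dataset()` — one odorant per plate, OR and empty-vector
  wells with and without odorant, two replicates, GFP control wells, and
  Gaussian well noise (default σ = 3e4 AU, one tenth of the hit
  threshold, which makes that threshold meaningful in simulation).
  Agonist effects saturate with concentration: 0.6/0.9/1.0 of the effect
  at 10/100/1000 µM for potent agonists, 0/0.5/1.0 for weak ones —
  qualitatively the large-dot/small-dot potency dichotomy. Truth potency
  classes are derived in closed form from these parameters, never by
  running the quantification.

The simulators do **not** emulate realistic genome composition (repeats,
GC structure, gene families of near-identical paralogs), alignment-level
indel divergence (orthologs differ by substitutions only), codon-usage
bias, or pharmacological dose–response shapes. Passing recovery tests
therefore demonstrates that the pipeline's decisions are correct for its
stated rules, not that the 70/70 rule or the 3e5 threshold would
reproduce any particular species count or hit list on real genomes and
plates — those depend on assembly versions, annotation snapshots and
assay chemistry outside the package's scope.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere; minus-strand features are
  reported re-mapped to forward coordinates.
* N-containing codons translate to X and never serve as start or stop.
* ORF ties break to the earlier start, then the forward strand; best-hit
  ties break on score, matches, leftmost target start — full determinism.
* All randomness flows through explicit `seed` arguments
  (`withr::with_seed`); identical seeds give byte-identical FASTA, plate
  tables and Newick output.
* Alignment scoring defaults (+1/−2/−3/−1, k = 11, min score 30) are in
  the BLAT-like regime; "default parameters" of genome-browser aligners
  pin nothing reimplementable, so the values are stated, echoed into
  output headers, and configurable.
* `build_nj_tree()` rejects asymmetric or non-zero-diagonal inputs rather
  than silently symmetrizing.
* Degenerate inputs: empty hit lists summarize to (0, 0); all-gap pair
  columns are dropped by the identity rule; normalization over a set with
  no positive response is refused; single-replicate cells carry an
  undefined (NA) s.e.m.

# Problem sizes used in tests

The shipped suite and acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path in a few minutes: 120 random
sequences for the ORF brute-force comparison; 50 planted alignment
instances (150–300-nt queries, ≤2-kb targets) for the Smith–Waterman
oracle; 100 replicates each of 80%- and 60%-identity ortholog plants in
3-kb genomes; a 10-query lineage cohort on multi-contig toy genomes (one
planted ortholog per contig, so random insertions cannot split one
another); 200 random 6–12-taxon additive matrices for NJ recovery; and
200 seeded 9 × 37 plate screens for the hit-calling error rates. Each
ortholog lives in its own contig in the cohorts because a random
insertion landing inside an earlier insert would split it — a property of
toy genome construction, not of the screen logic.

# Worked example

```{r example, eval = FALSE}
set.seed(1)
fam <- simulate_or_family(n = 6, n_pseudo = 2, seed = 42)
curate_or_set(fam$genes)

sim <- simulate_plate_dataset(
  or_names = c("OR_a", "OR_b"), odorants = c("vanillin_like", "ester_x"),
  agonists = data.frame(or_name = "OR_a", odorant = "ester_x",
                        potency = "potent", effect_AU = 9e5),
  seed = 7)
quant <- quantify_plate_dataset(sim$wells, qc = sim$qc)
hit_table(quant$responses)
```

# Known limitations

* Nucleotide-level search only (as for genome-browser alignment of gene
  sequences); a translated search would be more sensitive deep in the
  twilight zone but is out of scope.
* Coverage comes from the single best hit; a counterpart split across two
  distant hits (or contigs) under-reports coverage. A union-of-hits mode
  is a natural extension.
* The identity convention approximates, but does not exactly match, the
  conventions of specific MSA tools; published identity ranges can differ
  by up to about a percentage point for the same sequences.
* Bootstrap supports are for the distance-NJ tree, not a likelihood tree;
  supports on short alignments are conservative.
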