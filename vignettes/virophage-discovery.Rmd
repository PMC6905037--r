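---
title: "Virophage discovery, classification and host prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virophage discovery, classification and host prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Virophages (family *Lavidaviridae*) are small dsDNA viruses that co-infect
unicellular eukaryotes together with a giant virus (NCLDV) and parasitize
its replication factory. They are hard to isolate, so discovery is
computational: assembled metagenome contigs are screened with profile models
of the major capsid protein (MCP), the one gene specific enough to act as
bait. Candidate contigs are then filtered by size and by the presence of the
four core genes conserved across virophages — MCP, the minor capsid protein
(mCP), a genome-packaging ATPase and a cysteine protease (PRO) — and
completeness is judged from assembly topology: a circular genome shows
overlapping 5'/3' contig ends, a linear one may carry inverted terminal
repeats (ITRs). High-quality (HQ) genomes are classified into clades from a
concatenated four-core-gene phylogeny, their proteins are clustered into
virophage protein clusters (VpPCs), and putative co-infecting giant viruses
are predicted through the MIMIVIRE criterion: an exact 24–30 nt sequence
shared between the two genomes whose ~18 nt subset recurs inside one
giant-virus gene.

`lavidascope` implements this whole workflow as composable R functions with
a synthetic-data generator that plants every feature the pipeline is
supposed to find, so each stage is testable against exact ground truth
without any external database.

## Profile models and E-values

The published pipeline uses HMMER as a black box; the operative contract is
"E-value-thresholded homology search with iteratively refined models". We
implement that contract directly:

* A model family is built by clustering proteins with the bidirectional
  rule — local-alignment identity ≥ 30% over ≥ 70% of *both* sequences —
  and taking connected components (singletons dropped; component and member
  order deterministic by id).
* Each family is aligned (progressive aligner below) and converted to a
  position-specific scoring matrix. Columns with more than 50% gaps are
  excluded. Column scores are `log2(p/bg)` with one pseudocount per residue
  and a uniform background; with this choice every column's expected score
  under the background is strictly negative, so local segment scores cannot
  drift upward on unrelated sequences.
* Search scores are the best local *ungapped* segment of the sequence
  against the PSSM (Smith–Waterman-style maximal segment, computed in C).
  Significance comes from an explicit null: at least 1000 length- and
  composition-matched shuffled decoys are scanned, a Gumbel distribution is
  fitted to their maxima by moments, and `E = N · exp(−λ(S − μ))` with `N`
  the database size. The default screening threshold is `E < 1e-6`;
  core-gene labelling within a contig uses the laxer `E < 1e-3` because the
  candidate set is tiny.

Iterative refinement alternates search and rebuild: round 1 builds one
model per seed alignment; each later round recruits database hits whose
gene length is ≥ 700 nt (on synthetic data `3·aa + 3`), pools them with the
current members, re-clusters with the 30/70 rule and rebuilds. A remote
homolog reachable only through an intermediate sequence therefore enters
the model in round 2 even though it is not a member of any round-1 model.
Note that a full-length homolog at 40% identity to a 593-aa family *is*
found by the round-1 search itself — no calibrated local search misses
40% identity over that length — so the value the iteration adds is
membership: the recruit reshapes the model so that its whole neighbourhood
scores as family, which is what the membership-by-round records assert.

MCP completeness uses the published length statistics, mean 593 aa and SD
40.1: `complete` when length ≥ mean − SD, `ge_half` when ≥ half the mean,
`partial` otherwise. The rule is one-sided by design — an MCP longer than
average is still complete; the upper bound is deliberately left open.

## Quality, topology and de-replication

* **Circularity**: the longest exact terminal duplication of ≥ 20 nt
  (prefix equals suffix). At 20 nt the chance of a spurious call on a
  random contig is below 1e−6, which is why 20 was chosen where the
  published rule says only "overlapping 5′ and 3′ ends".
* **ITRs**: the longest block of ≥ 100 bp in the first/last 5 kb whose left
  copy equals the reverse complement of the right copy, exact by default
  (`max_mismatch` configurable). The 5 kb terminal window is our choice;
  the published rule states only the 100 bp minimum.
* **Tiers**: HQ requires ≥ 10 kb and all four core genes; HQ-complete
  additionally requires circular or ITR topology; everything else is
  partial. The three tiers partition the input by construction.
* **De-replication** is greedy, longest-first (ties by id), mirroring
  common practice (cd-hit) since representative selection is otherwise
  unspecified: an item joins the first representative with identity ≥ 95%
  (matches/aligned columns of a local alignment) over ≥ 95% (genes) or
  ≥ 80% (contigs) of the shorter sequence. For contig pairs in which both
  sides exceed 10 kb the quadratic alignment is replaced by an
  anchored-diagonal comparison (exact 16-mer chains, then base-by-base
  identity along the dominant diagonal). Near-duplicates at the 95%
  threshold are substitution-dominated, where the two measures agree; the
  test suite checks the greedy clustering against a brute-force all-pairs
  oracle on sequences small enough for the exact path.

## Protein clusters (VpPCs)

Two-step clustering, following the same decision rules as the published
analysis:

1. All-vs-all Smith–Waterman (BLOSUM62, affine 11/1, score computed in C)
   defines a weighted graph; edges need raw score ≥ 30 and E ≤ 0.01, with
   E calibrated on shuffled decoy pairs and scaled by database size. An
   inverted-index prefilter (pairs sharing a 5-residue word) skips the
   quadratic scan; it can only remove pairs that would not form edges at
   these thresholds on realistic inputs, and can be disabled.
2. InfoMap (two-level map equation, via igraph) partitions the graph;
   isolated proteins stay as singleton groups.
3. Groups are merged by profile–profile comparison: members de-replicated
   at 90% identity, aligned, turned into a PSSM; group pairs are scored
   consensus-versus-PSSM in both directions (maximum taken), coverage is
   aligned columns over the shorter profile (the usual profile-search
   convention). The match probability is a logistic map of the score
   calibrated on column-shuffled decoy profiles,
   `p = plogis(λ(S − μ) − log(n_comparisons))` — equivalently `1/(1 + E)`
   with a multiplicity-corrected E-value. Groups link iff
   `p ≥ 0.90 ∧ cov ≥ 0.50` or `p ≥ 0.99 ∧ cov ≥ 0.20 ∧ aligned ≥ 100 aa`,
   the two published acceptance disjuncts verbatim. Connected components
   become VpPCs; only clusters of ≥ 2 proteins are kept. Profiles under 10
   columns are left unmerged with a warning.

Categories use prevalence across HQ genomes: `core` at exactly 1.0,
`common` in [0.25, 0.60], `accessory` below 0.25. The (0.60, 1.0) band is
undefined in the published scheme; we report it as its own `common_high`
band rather than forcing it into either neighbour. Marker VpPCs are those
confined to exactly one clade (or habitat) and present in ≥ 2 genomes.

The thresholds were selected in the source analysis so that the four core
gene families each land in a single PC; the acceptance suite re-derives
that property on synthetic lineages diverged to ~30% between-lineage
identity.

## Phylogeny, clades and synteny

Full-length core genes of HQ genomes are aligned per gene with the
in-package progressive aligner (pairwise and profile–profile
Needleman–Wunsch, BLOSUM62 with affine 11/1, guide tree from 3-mer
distances; an external aligner can be slotted behind the same contract),
columns with > 90% gaps are trimmed, and the four blocks are concatenated
with recorded partition boundaries. The default tree is neighbour joining
on WAG maximum-likelihood pairwise distances (phangorn/ape), midpoint
rooted, with supports from a seeded column-resampling bootstrap (default
100 replicates). NJ+bootstrap keeps desk-scale runs deterministic; an ML
backend can replace it behind the same interface.

Clades are the maximal subtrees whose mean root-to-leaf path length is
below 1.2 substitutions/site with support ≥ 0.8 — the auto-collapse
semantics of common tree viewers; "average branch length" is interpreted
as mean root-to-leaf depth within the subtree (configurable to mean
pairwise distance). Leaves not covered become flagged singleton clades, so
clades always partition the genomes. The published "manual adjustment"
step is replaced by these deterministic rules for reproducibility. Clade
numbering is by tree traversal order — published clade numbers depend on
the published data and are not reproducible.

A genome's synteny signature lists its core genes (plus MTase) in genomic
order with strands, canonicalized so the MCP lies on the forward strand
(reverse the order and flip strands otherwise; circular genomes are
additionally rotated so MCP comes first). A genome and its reverse
complement therefore share one signature. Block templates tally the
five-gene ancestral arrangement (four core genes plus MTase colocalized),
the four-gene truncation, the three-gene truncation without ATPase, and
MCP–mCP adjacency; "colocalized" means consecutive core genes separated by
at most 1 kb, which on the synthetic cassette (80–400 bp spacers) is
unambiguous.

The model × habitat profile converts hit counts to per-habitat
percentages, quantile-normalizes the habitat columns (limma) and clusters
both axes by complete-linkage on Euclidean distances.

## MIMIVIRE host linkage

Shared seeds are all maximal exact common substrings of ≥ 24 nt between a
virophage and a giant-virus contig, found by 24-mer anchoring with run
extension on both giant-virus strands. Matches longer than 30 nt are
reported once as a single maximal match and still qualify — the 24–30 nt
range is read as a minimum-information window, not an exclusion of longer
identity. A link additionally requires a repeated subset: among all
substrings of the seed of length 18 ± 2, the one with the most exact
occurrences (distinct start positions; overlaps allowed) on the coding
strand of the giant-virus gene containing the seed, with at least
`min_copies = 2` — the seed's own occurrence plus at least one more, the
minimal reading of "repeated"; the published example shows three copies
and the generator plants three by default. The seed region is translated
in all three frames on each side; frame agreement holds iff some frame
pair yields an identical peptide of ≥ 6 aa. Links are ranked by copy
count, seed length, frame agreement and same-sample co-occurrence.

Giant-virus inputs are a user-supplied FASTA + GFF3; mining an NCLDV
database with a giant-virus capsid model is the same profile machinery but
ships untrained, since its reference alignments are external.

## The synthetic generator

The generator is first-class, tested code; its defaults are the study
conditions every acceptance property is measured under:

* 50 virophages across 3 lineages plus 100 decoys; complete genomes
  10 900–42 300 bp (the published complete-genome range), decoys
  5–20 kb of i.i.d. uniform DNA — the simplest null that makes chance
  24-mer matches vanish (~L²/4²⁴) and lets every seed count be exact.
* Each lineage has a fixed core-gene order and strand pattern (a five-gene
  MTase block, a four-gene block with PRO reversed, and the
  ATPase–mCP–MCP colocalized order). Members diverge from their lineage
  ancestor by exact-count substitutions at 60–90% identity — substitutions
  only; indel robustness is exercised through aligner tests, not the
  generator. Back-translation draws synonymous codons uniformly.
* Lineage ancestors sit at 55% identity to a per-gene root (≈ 30%
  between lineages), chosen so that profile merging must bridge lineages
  while pairwise clustering alone cannot. For phylogeny fixtures lineage
  ancestors are drawn independently (`lineage_identity = 0`): the 1.2
  substitutions/site collapse rule needs deep splits to leave more than
  one clade, and with within-lineage identity ~0.9 the between:within
  divergence ratio is far above the required 5.
* Topologies: 40% circular (50 bp terminal duplication — the
  assembler-overlap convention by which circularity is detectable), 30%
  ITR (100–500 bp), 30% linear. Single-base chance extensions of planted
  repeats and seeds are rejection-guarded so detected lengths equal
  planted lengths exactly.
* 80% of virophages are planted HQ; the rest are undersized (8–9.9 kb) or
  miss one non-MCP core gene.
* Around each planted gene the spacer carries an in-frame stop guard so
  the ORF caller's maximal-ORF convention reproduces planted coordinates
  exactly; ORF calls are allowed to be a superset (random ORFs in
  intergenic DNA are part of the test conditions, as decoy proteins).
* Giant viruses (20–40 kb, 4–8 genes) receive a 27-nt seed copied verbatim
  from a linked virophage's intergenic DNA into one gene at a codon
  boundary, plus two further codon-aligned copies of an 18-nt subset —
  three copies total, the published repeat pattern. Decoy giant viruses
  and decoy contigs carry no seed; decoys are rejection-sampled so no
  decoy ORF reaches 30% identity over 70% coverage against any core-gene
  ancestor.
* Habitats: each lineage has a home habitat assigned with probability 0.7.

What the generator does *not* emulate — and hence what green tests do not
show about real data: sequencing error and chimeric assembly, real codon
usage and GC bias, indels and domain rearrangements, provirophages
embedded in host contigs, and realistic protein length/composition
distributions. Results on real metagenomes depend on those factors;
the package's claims are about the correctness of the decision rules, not
about sensitivity on any particular habitat.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (the GFF3 and Bioconductor
  convention); converters to 0-based half-open intervals are provided and
  tested as exact inverses.
* Gumbel fits use the method of moments; lambda is floored away from zero
  for degenerate score sets.
* Ties break deterministically throughout: lexicographic ids in
  clustering and de-replication, gene coordinate (with a warning) in
  core-gene assignment; repeat units with equal copy counts prefer the
  length closest to the nominal 18 nt (longer first), then the leftmost
  position in the seed. Repeat occurrences are counted at distinct start
  positions with overlaps included (lookahead matching), which matters for
  low-complexity seeds.
* Degenerate inputs: all-gap alignments, uncalibrated models, trees with
  < 4 leaves and over-trimmed alignments raise errors; palindromic
  contigs report their terminus-spanning ITR once; empty protein or
  contig sets flow through as empty, well-formed results.
* Every stochastic step (decoy calibration, bootstrap, community
  detection, the generator itself) consumes the single configured seed;
  reruns are byte-identical, which the suite checks with file digests.

## Problem sizes

The shipped tests and the acceptance script run, per stage: the
50-virophage/100-decoy discovery corpus; 1000 random linear decoys for
topology false positives; ten 20-sequence sets for the de-replication
oracle; 80 proteins in 10 families plus 60 core-gene proteins across 3
lineages for clustering; 15 genomes across 3 deep lineages with a
100-replicate bootstrap for clade recovery; and 100 random contig pairs
for the MIMIVIRE null. These sizes resolve every planted structure with
comfortable statistical margins while keeping a full run in minutes on one
CPU. The published study's headline counts (tens of thousands of MCPs,
hundreds of HQ genomes, 27 clades) depend on IMG/M-scale data and are out
of scope by design.

## Known limitations

* The PSSM search is ungapped; indel-rich remote homologs score lower
  than under a full profile HMM. The model interface is pluggable so an
  external HMMER backend can stand behind the same contract.
* The permissive +1-per-residue pseudocount makes profile scores
  sensitive down to ~15–20% identity against the decoy null; specificity
  comes from calibration, not from a hard identity floor. Unrelated
  *random* sequences are rejected reliably, but genuinely homologous
  non-virophage capsids would be recruited — as they are in the published
  bait strategy.
* The anchored-diagonal identity used for very long contig pairs assumes
  substitution-dominated divergence; indel-heavy duplicates above 10 kb
  would need the exact alignment path (raise `max_align_len`).
* NJ+bootstrap supports are not the SH-like supports of fast ML tools;
  both semantics are exposed (`bootstrap = 0` disables supports).
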