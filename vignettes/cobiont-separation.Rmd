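---
title: "Separating cobiont genomes from long-read assemblies with ssusieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating cobiont genomes from long-read assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a eukaryote is sequenced for genome assembly, the DNA extract almost
never contains one species. Symbionts, parasites, gut microbes, food and
surface organisms — *cobionts* — are co-sequenced and co-assembled with the
target. Left in place they contaminate the host assembly; discarded
wholesale they throw away complete, often novel, genomes. `ssusieve`
separates them: it profiles a draft long-read assembly by its small-subunit
(SSU) rRNA content, classifies each SSU locus to a taxonomic family, pulls
every sequencing read belonging to the detected families out of the read
set with a k-mer classifier, cleans the per-family contig bins with
evidence filters, and reassembles each family's reads into an independent
genome draft.

Every stage is implemented in this package at desk scale — the SSU search,
the low-complexity masker, the k-mer classifier, the aligner and the
assembler are all in-repo — so the whole workflow, and its tests, run
without external databases or binaries. A synthetic community generator
provides truth-labelled inputs.

## The procedure

1. **SSU screen.** Contigs are searched (both strands) against a
   multi-domain SSU reference panel by seed-and-extend: exact 15-mer seeds
   nominate diagonals, which are scored gap-free at match +1 / mismatch −3.
   Candidate hits need ≥ 300 aligned bases at ≥ 75% identity; a hit is
   *retained* when its aligned length strictly exceeds 1,000 bases or its
   alignment score reaches 1,000. The score branch replaces a profile-HMM
   e-value cutoff — e-values are estimator-specific and unreproducible
   without the original profile software, while the threshold chosen here
   is calibrated so that any exact match of at least 1,000 bases passes;
   with the aligned-length alternative carrying the main detection load,
   the rule's behaviour is preserved.
2. **Redundancy collapse.** Retained loci are clustered greedily,
   longest-first (ties broken by id); a locus joins a representative only
   above 99% global identity, so representatives are pairwise ≤ 99%
   identical.
3. **Family consensus.** Each representative is compared with every panel
   member; hits are kept above 90% nucleotide identity, and the best 20
   vote. Each hit's taxon is resolved under two label systems (NCBI-style
   primary names and SILVA-style synonyms) mapped onto one harmonized node
   set; a hit votes only when both systems agree on the family (a taxon
   resolvable in just one system counts under that system). A family is
   called at ≥ 80% concordance — 16 of 20 passes. With fewer than 20
   surviving hits all of them vote: the alternative, discarding sparse
   evidence, would blind the method to exactly the rare taxa it exists to
   find.
4. **Read binning.** Reference genomes of the catalogued families and of
   the host's relatives are DUST-masked and decomposed into canonical
   50-mers; k-mers shared by several families store the families' lowest
   common ancestor. Reads vote with their k-mers and are assigned the
   deepest taxon on the maximum-scoring root-to-leaf path (ties resolve to
   the LCA), with a minimum winning fraction of 0.10 of the read's k-mers.
   Reads resolving above family rank — for example chimeras with equal
   evidence for two families — are binned to no family.
5. **Bin refinement.** A contig stays in a family bin only if the bin's
   reads cover it end to end *and* it carries a single-copy marker gene or
   sufficient similarity to a family reference genome. The full-coverage
   rule is what protects against horizontal transfer: a host contig that
   merely contains a cobiont-derived insertion is touched by cobiont reads
   only across the insertion and is discarded.
6. **Reassembly.** Each family's reads are reassembled by greedy exact
   suffix–prefix overlap merging (minimum overlap 500 bases, both
   orientations tracked, containments absorbed, deterministic
   tie-breaking). Contigs whose start reappears at their end (≥ 99%
   identity over ≥ 500 bases) are flagged circular and trimmed of the
   duplicated wrap. Reassembled contigs pass the same marker-or-similarity
   evidence filter.
7. **Evaluation.** Against a truth table, bins are scored by
   length-normalised precision (correctly assigned bases over bin bases),
   recall (over the family's truth bases) and
   F1 = 2·P·R/(P + R); an empty bin has precision 0 by convention so F1 is
   0 rather than undefined. Assembly statistics are span, N50 and a marker
   completeness triple (single / duplicated / missing counts over the
   panel).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| SSU retention length | > 1,000 | bases | near-full-length SSU regions only |
| retention score | ≥ 1,000 | score (+1/−3) | stand-in for a profile e-value cutoff |
| collapse identity | > 0.99 | fraction | merges alleles/copies, keeps distinct taxa |
| hit identity filter | > 0.90 | fraction | family-level resolution of SSU identity |
| consensus | ≥ 0.80 of top 20 | fraction | the integer reading is 16 of 20 |
| k | 50 | bases | long k-mers make family labels near-unique |
| classifier confidence | 0.10 | fraction of read k-mers | guards against single spurious k-mer hits; not a value inherited from any published tool |
| terminal slack | 25 | bases | reads cannot overhang contig ends, so "fully covered" tolerates that many terminal bases |
| marker hit | ≥ 0.90 identity over ≥ 0.80 of marker | fractions | nucleotide-level stand-in for protein marker search |
| reference similarity | ≥ 0.90 identity over ≥ 0.50 of contig | fractions | explicitly a package default — no published value exists for this step |
| minimum assembly overlap | 500 | bases | repeats shorter than this cannot fragment fixture assemblies |

All are exposed through `pipeline_config(params = list(...))`.

## The synthetic community

`default_community_spec()` describes the study conditions: a 500 kb
host-genome surrogate plus three bacterial cobionts (80, 60, 40 kb) and one
compositionally divergent microsporidian-like eukaryote (30 kb), at
staggered abundance weights 100:20:10:5:2 with a total of 137-fold
coverage — so the weights are per-species fold-coverages directly. Genomes
are drawn from second-order Markov chains whose per-context probabilities
are perturbed by a species-specific seed under an exact GC constraint,
making species compositionally separable while holding GC on target. Each
genome receives one embedded SSU gene (two identical copies in the host, so
redundancy collapse is exercised), twenty 900-base single-copy markers, and
— in the host — one 800-base insertion copied from the first cobiont's
genome, emulating horizontal transfer. Reference genomes diverge from the
true genomes by 1.5% substitutions, SSU panel members by 2% from each
family's ancestral SSU, and embedded SSU copies by 3%, so the 90% and 99%
identity thresholds are exercised from both sides. The lowest-abundance
species is omitted from the simulated draft assembly: its reads are
present, its SSU is not in any contig, and the correct behaviour — no
catalogue entry plus an explicit report line — is part of the test
surface.

Reads are error-free (the high-accuracy long-read regime; an error rate is
configurable and defaults to 0) and their start positions are stratified —
evenly spaced with bounded jitter — rather than uniform-random. Stratified
starts guarantee gap-free tiling above ~1.5× depth, which makes the
full-coverage filter decidable at desk-scale depths; uniform sampling
would need far deeper simulated coverage to avoid stochastic coverage
gaps, without changing what the filter tests.

What the fixtures deliberately do not model: sequencing errors and
chimeric reads, indel divergence (all divergence is substitution-only, so
the in-package aligner works on exact-seed diagonals without gaps), real
SSU conservation across domains of life, repeat structure beyond what the
Markov chains produce, and uneven real-world coverage. Passing tests
therefore demonstrate the correctness of the decision logic under the
stated model, not performance on real sequencing data — on real data the
alignment stages would need a gapped aligner and the assembler an
error-tolerant overlap.

## Numerical and design choices

- **Coordinates** are 0-based, half-open everywhere.
- **Masking** scores every window of 64 bases as
  10·Σc(c−1)/2 / (n−1) over its overlapping triplet counts (triplets
  containing N ignored) and masks windows scoring above 20, merging
  overlaps. This is the symmetric sliding-window form of the DUST score;
  the perfect-subinterval refinement of published implementations is
  omitted and the exhaustive window scan is the tested definition.
- **Alignment** is gap-free by design (see above); the mismatch penalty is
  derived from each stage's identity threshold (penalty =
  t/(1 − t)) so that segments score positive exactly above the threshold.
  Smith–Waterman, via an independent dynamic-programming implementation,
  serves as the oracle in tests, never in the pipeline.
- **Vote resolution** maximises the root-to-leaf path sum of clade votes,
  the standard k-mer-classifier semantics; a literal "maximal clade sum"
  would always select the root whenever any ancestor-labelled k-mer votes.
  Ties resolve to the LCA of the tied nodes, which keeps equal-evidence
  chimeras above family rank.
- **Greedy assembly ties** break by overlap length, then by the
  lexicographically smallest constituent read id of each side, making the
  output order-independent and byte-reproducible.
- **Circularity** is anchored on an exact match of the contig's first 31
  bases near its end; with error-free input the wrap overlap is exact, and
  the anchor makes false positives on random sequence vanishingly rare
  (0/1,000 in the acceptance checks).
- **Degenerate inputs**: empty bins have precision 0; an empty marker
  panel warns and reports no markers; an empty family reference set means
  "no similarity evidence", so novel families rely on markers; reads
  shorter than k are unclassifiable.
- **Fragmented markers** (a category some completeness tools report) are
  folded into "missing": fragment calling is a protein-profile concept
  with no nucleotide-panel equivalent here.

## Problem sizes

The default fixture produces ~6,900 reads (~53 Mb) over 16 contigs; the
full pipeline runs in about a minute on one core. The circular-reassembly
check uses a 200 kb genome at 20× (500 reads of ~8 kb). Unit tests run on
a reduced four-species community (80/40/30/25 kb genomes at 40× total).
These sizes were chosen so that every stage's behaviour — including the
low-abundance failure mode — is observable while the whole suite stays
interactive.

## Known limitations

- Family-level resolution only: two cobionts of the same family share one
  bin, as in the underlying method.
- The greedy assembler fragments on exact repeats longer than the minimum
  overlap; fixtures keep repeats below it, and a hook for an external
  assembler command is the intended route for real data.
- The dual-taxonomy concordance rule (both systems must map a hit to the
  same harmonized family node) is one defensible operationalisation of
  "using both taxonomies"; others (union, intersection at higher ranks)
  would differ on pathological synonym tables.
- Reference-similarity thresholds (50% breadth at 90% identity) are
  package defaults, prominently configurable, not values taken from any
  published pipeline.
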