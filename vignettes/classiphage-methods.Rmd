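---
title: "Taxon-specific profile HMM libraries: model, parameters and design"
author: "ClassiPhage package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxon-specific profile HMM libraries: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ClassiPhage` classifies phage genomes by the *combination* of profile
HMM hits they collect, not by any single marker. The underlying
assumption is that each phage family maintains a repertoire of
conserved protein families — capsid, replication, morphogenesis
proteins — and that a genome of family *F* will be recognized by many
of *F*'s models and few of any other family's. This sidesteps the two
classic failure modes of phage taxonomy: there is no universal marker
gene to build a tree from, and pairwise alignment loses signal between
distant relatives, where a profile HMM built from a diverse alignment
still finds homologs.

The pipeline has five stages, each behind its own exported functions:

1. protein-family definition (redundancy removal, BLASTP similarity
   graph, Markov clustering);
2. model construction (MAFFT alignment, `hmmbuild`, consensus via
   `hmmemit -c`);
3. hit filtering;
4. model refinement to a fixpoint (consensus-coverage pruning,
   membership updates, merging);
5. application: genome classification, intergenic CDS recovery,
   prophage locus calling.

Stages that are standard sequence-analysis steps delegate to the
field's tools (BLAST+, MAFFT, HMMER3); the method-specific logic —
MCL, the greedy redundancy clustering, the refinement rules, the
decision rules — is implemented in the package itself.

## Scores and the hit filter

A hit of model $m$ (length $L$ match states) on protein $t$ carries a
bit score $S$, an E-value, model coverage
$(\mathrm{hmm_{to}}-\mathrm{hmm_{from}}+1)/L$, and the normalized
score $S/3L$. The $3L$ denominator expresses the consensus size in
base pairs; it is a constant rescaling per model whose purpose is
cross-model comparability (long models would otherwise dominate every
aggregate), and `normUnit = "aa"` switches to the amino-acid length.
Per (model, target) pair only the best-scoring domain is kept; its
domain bit score and independent E-value are reported, because the
coverage cut-off is a per-domain notion. Multi-domain accounting is
out of scope.

Hits are *rejected* when any of three conditions holds: coverage
below 50%, a non-positive bit score, or an E-value above
$1.5\times10^{-8}$. The package reads these as rejection rules (a hit
must survive all three), applied identically during refinement,
classification, CDS recovery and host scanning.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `identity_threshold` | 0.9 | greedy redundancy clustering: global identity (matches / shorter length) at which a sequence joins a representative |
| `evalue_cutoff` | 1e-5 | BLASTP edge threshold for the similarity graph |
| `inflation` | 2.0 | MCL inflation; the canonical default granularity |
| `min_cluster_size` | 5 | smallest cluster that seeds a model — fewer sequences cannot support a diverse alignment |
| `coverage_threshold` | 0.5 | consensus-coverage pruning (fraction of the consensus a member's BLASTP alignment must span) |
| `min_coverage`, `max_evalue` | 0.5, 1.5e-8 | the hit filter above |
| `min_distinct_models` | 2 | a classification/locus call needs at least two distinct models — a single hit is never enough |
| `min_consecutive` | 4 | a prophage locus needs strictly more than three hit genes |
| `max_gene_gap` | 2 | non-hit genes tolerated inside a locus run (unannotated or non-family phage genes) |
| `min_intergenic_nt`, `min_orf_aa` | 90, 30 | CDS recovery floors; 30 aa is a common lower bound for a detectable domain |

Edge weights in the similarity graph are $-\log_{10} E$ capped at 200,
so identical pairs (reported $E = 0$) get a finite weight. The MCL
self-loop weight (1.0) is applied on the scale of the largest edge
weight, which makes clustering exactly invariant to uniform rescaling
of all edge weights.

## Design choices where the design was open

* **Clustering per family label.** Models must carry a family to act
  as taxonomic indicators, so proteins are clustered within their
  family label; cross-family homology then shows up (and is measured)
  at scan time, in the cross-match matrix, rather than being merged
  away at clustering time.
* **Coverage is measured on the model**, not the target: model
  coverage is the standard profile-search convention and is the
  quantity the consensus-pruning step controls.
* **Merging requires exact set equality** of (hit targets ∪ members).
  A Jaccard relaxation would merge near-duplicates but risks chaining;
  exactness keeps the fixpoint well-defined.
* **Consensus-coverage pruning runs once, at initialization**, before
  the scan loop; the scan loop's own membership rule then governs.
* **Fixpoint detection** hashes the multiset of member-id sets; a
  bounded history of three states catches oscillation, and models are
  processed in model-id order so the result does not depend on list
  order. Models falling below two members are retired — a one-row
  alignment cannot define a meaningful profile.
* **Scanning uses `hmmsearch`** (models as queries) rather than
  `hmmscan` over pressed binaries: the statistics are the same and the
  model library stays a single text file. Model text is kept inside
  the `ProfileHMM` object with a fixed DATE stamp, so rebuilding from
  the same alignment is byte-identical.
* **Coordinates are 1-based closed** throughout (the
  GRanges/IRanges convention this package is built on); GFF3 output
  needs no conversion.
* **"Consecutive" hits are counted in gene ordinals**, not base
  pairs: gene-space runs are robust to intergenic length variation.
  On circular replicons runs are joined across the origin, and the
  wrap-around intergenic gap is likewise treated as a single region.
* **Six reading frames.** Intergenic recovery translates both strands
  in all three frames; a single-frame reading would miss
  reverse-strand genes.

## The synthetic data generator

The generator emulates the structure the method relies on: each phage
family owns a set of ancestral proteins drawn i.i.d. from a uniform
20-letter model (inter-family identity therefore sits at the ~5%
background); a genome carries each ancestral family with probability
0.9 and its copies diverge by independent per-site substitutions
(default 0.3); genes are reverse-translated with random synonymous
codons, placed on random strands with 50–200 nt random spacers, and
written as GenBank files with `/translation` qualifiers. Host genomes
are random unrelated proteins with an optionally implanted contiguous
block of family genes, with truth coordinates recorded in a manifest.

What it deliberately does **not** emulate: insertions/deletions
(substitution-only evolution keeps hit coverage near 1 and isolates
the threshold logic from aligner quality), natural amino-acid
composition (uniform composition maximizes family separation, so any
cross-family hit is a genuine bug signal), genome mosaicism, shared
gene pools between families, and annotation noise. Passing tests on
these fixtures therefore demonstrate the machinery — clustering,
model building, decision rules, coordinate bookkeeping — not
performance on real phage data, where families share genes and
E-value/score distributions are far less separated. On real data the
cross-match fractions and the unassigned rate are expected to be
substantially less clean.

The test suite and the acceptance script use 4 families × 12 genomes
with 10 ancestral protein families each (about 440 proteins and 40
models), 20 delete-one-gene genomes for recovery, and 50 implanted
plus 50 phage-free hosts of ~41–51 genes for the prophage screen —
sizes at which every stage's behaviour is unambiguous and the whole
suite runs in minutes on one CPU.

## Numerical and degenerate-input behaviour

* MCL iterates on a dense column-stochastic matrix; entries below
  1e-12 are truncated, convergence is max-entry change < 1e-6, and
  clusters are the connected components of the converged flow's
  support (threshold 1e-5). Ties everywhere break toward the
  lexicographically smallest id. Non-symmetric input is symmetrized
  by the maximum, with a warning.
* The greedy redundancy pass sorts by length (ties by id) and uses a
  conservative shared-4-mer prescreen before aligning; at threshold
  0.9 the prescreen cannot discard a pair that could reach 90%
  identity by substitutions.
* Empty inputs: a genome with zero CDS parses with a warning and
  yields an empty protein set; an empty proteome classifies as
  `unassigned`; a null host yields zero loci; `filterClusters` warns
  when nothing survives.
* E-values depend on the scanned database size (HMMER's convention);
  bit scores do not, and the suite asserts that database splits leave
  bit scores unchanged.

## Known limitations

* Locus boundaries are gene-span boundaries; attachment sites and
  tRNA targets are not modelled, so precise prophage edges are out of
  scope.
* A genome whose family has no models (too few clustered proteins)
  can only come out `unassigned` — the min-cluster-size floor
  trades sensitivity for model quality.
* Redundancy bookkeeping assumes protein ids are stable across the
  run; re-extracting with different genome ids invalidates a saved
  redundancy map.
* The GenBank parser covers the subset of the format the pipeline
  needs (LOCUS/DEFINITION/SOURCE, source and CDS features with
  join/complement locations, ORIGIN); exotic location operators or
  records without ORIGIN are rejected rather than guessed at.
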