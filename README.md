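# ClassiPhage

Taxon-specific profile-HMM libraries for bacteriophage classification
and prophage detection.

## The problem

Most phage genomes recovered from sequencing projects and metagenomes
cannot be placed in the ICTV taxonomy: phages share no universal marker
gene, and pairwise-alignment methods lose power between distantly
related genomes. `ClassiPhage` targets this gap with a
protein-family approach. From a training set of classified phage
genomes it learns, per phage family, a library of profile hidden Markov
models (HMMs) — one per conserved protein family — and then uses the
*combination* of model hits as the taxonomic signal. The same libraries
also recover unannotated coding sequences from intergenic DNA and flag
integrated prophages inside bacterial host genomes.

It is aimed at phage genomics and microbiome researchers who have
GenBank-annotated genomes and want a classifier that is transparent
(every call is backed by a table of model hits) and retrainable on
their own taxa.

## The method

1. **Protein families.** All CDS proteins of the training genomes are
   pooled; redundant sequences are removed by greedy incremental
   clustering at 90% identity (matches / shorter length, global
   alignment). Per family label, an all-vs-all BLASTP similarity graph
   (edge weight `-log10 E`, capped at 200, edges at `E <= 1e-5`) is
   clustered with the Markov clustering algorithm (MCL, inflation 2).
   Clusters with at least 5 members seed models.
2. **Profile HMMs.** Each cluster is aligned with MAFFT and compiled
   into a profile HMM (`hmmbuild`); the consensus sequence is emitted
   (`hmmemit -c`). A hit of model *m* on protein *t* carries an
   E-value, a bit score *S*, model coverage
   `(hmm_to − hmm_from + 1) / L` for model length *L*, and the
   normalized score `S / 3L` (bit score per consensus base pair),
   which makes scores comparable across models.
3. **Hit filter.** Hits are rejected when coverage `< 50%`, the bit
   score is not positive, or `E > 1.5 × 10⁻⁸`.
4. **Refinement.** Members that cover less than half of their model's
   consensus (BLASTP) are pruned; then scan–update–merge iterates to a
   fixpoint: proteins that are hit and unassigned are added, members no
   longer hit are removed, redundancy-removed proteins are never added,
   and models whose hit-and-input sets coincide are merged.
5. **Classification.** A genome's filtered hits are aggregated per
   family; the family hitting the most *distinct* models wins (summed
   normalized score breaks ties) if it hits at least 2 models and
   strictly beats the runner-up — one model hit is never enough.
6. **Prophage loci.** Host proteomes are scanned gene by gene; a locus
   is a run of more than three hit genes (at most 2 non-hit genes
   between them, measured in gene ordinals), classified with the same
   family rule and comparable against an external prophage-region
   coordinate table (e.g. a PHASTER export).

A deterministic synthetic-fixture module generates phage families,
genomes and host genomes with implanted prophages, so the whole
pipeline is testable without downloads.

## Worked example

```r
library(ClassiPhage)

## synthetic training data: 2 phage families, 6 genomes each
specs <- generateFamilies(nFamilies = 2, nProteinFamilies = 5,
                          divergence = 0.3, seed = 7)
dir <- tempdir()
fx <- list()
for (sp in specs) for (j in 1:6) {
  gid <- sprintf("%s_g%d", sp$label, j)
  fx[[gid]] <- evolveGenome(sp, gid, seed = 700 + length(fx), dir = dir)
}

## build and refine the model library
proteins <- combineProteins(lapply(fx, function(x)
  extractCdsProteins(readGenBank(x$path,
    familyLabel = genomeMetadata(x$genome)$family_label))))
cl <- clusterProteins(proteins)
models <- buildFamilyModels(cl$clusters, proteins)
state <- refineToFixpoint(new("RefinementState", models = models,
  redundancy = cl$redundancy, masterProteins = proteins,
  round = 0L, changed = TRUE))

## classify a new genome
query <- evolveGenome(specs$FamB, "query", seed = 999, dir = dir)
res <- classifyGenome(extractCdsProteins(query$genome), state@models)
res$call
#> [1] "FamB"
res$evidence
#>   family_label models_hit n_hits sum_norm_score
#> 1         FamA          0      0       0.000000
#> 2         FamB          5      5       2.100399
```

The call is `FamB` because five distinct FamB models hit the proteome
(summed normalized score 2.06) and no FamA model does. A host-genome
scan looks the same from the other end:

```r
host <- implantProphage(specs$FamA, "host1", seed = 21, dir = dir,
                        nBackgroundGenes = 30, implantSize = 5,
                        positions = 12)
loci <- callLoci(scanHost(host$genome, state@models))
loci[, c("replicon_id", "start", "end", "n_consecutive", "family_call")]
#>   replicon_id start  end n_consecutive family_call
#> 1  host1_chr1  7188 9399             4        FamA
```

A thin command-line wrapper is installed with the package
(`inst/scripts/classiphage`) with `extract`, `fixtures` and `run`
subcommands; `runPipeline()` is the same entry point from R.

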