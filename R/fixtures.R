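## Deterministic synthetic phage families, phage genomes and host
## genomes with implanted prophages.

## Synonymous codon table (sense codons; identical translations under
## the bacterial/phage code used at read time).
.codonTable <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[setdiff(unique(gc), "*")]
})

.randomProtein <- function(len) {
  paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

.mutateProtein <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < divergence
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(.AA20, a), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

.reverseTranslate <- function(aa) {
  chars <- strsplit(aa, "")[[1]]
  codons <- vapply(chars, function(a) {
    opts <- .codonTable[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""), "TAA")
}

.randomSpacer <- function(minLen = 50L, maxLen = 200L) {
  paste(sample(c("A", "C", "G", "T"),
               sample.int(maxLen - minLen + 1L, 1L) + minLen - 1L,
               replace = TRUE), collapse = "")
}

## Assemble genes (+ spacers) into one replicon with CDS annotation.
.assembleReplicon <- function(id, genes, topology = "linear") {
  pieces <- character(0)
  rows <- list()
  pos <- 0L
  for (g in genes) {
    sp <- .randomSpacer()
    pieces <- c(pieces, sp)
    pos <- pos + nchar(sp)
    nt <- .reverseTranslate(g$protein)
    if (g$strand == "-") {
      nt <- as.character(reverseComplement(DNAString(nt)))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start = pos + 1L, end = pos + nchar(nt), strand = g$strand,
      locus_tag = g$locus_tag, product = g$product,
      translation = g$protein, stringsAsFactors = FALSE
    )
    pieces <- c(pieces, nt)
    pos <- pos + nchar(nt)
  }
  pieces <- c(pieces, .randomSpacer())
  seqChars <- paste(pieces, collapse = "")
  tab <- do.call(rbind, rows)
  gr <- GRanges(seqnames = id,
                ranges = IRanges(tab$start, tab$end),
                strand = tab$strand)
  mcols(gr)$locus_tag <- tab$locus_tag
  mcols(gr)$product <- tab$product
  mcols(gr)$translation <- tab$translation
  new("Replicon", id = id, sequence = DNAString(seqChars),
      topology = topology, features = gr)
}

#' Generate synthetic phage family specifications
#'
#' Each family is defined by a set of ancestral proteins drawn i.i.d.
#' from a uniform 20-letter model, so ancestors of different families
#' share only background identity (about 1/20). Deterministic for a
#' given seed.
#'
#' @param nFamilies Number of phage families (>= 2 for classification
#'   tests; default 4).
#' @param nProteinFamilies Ancestral protein families per phage family
#'   (default 10).
#' @param lengthRange Ancestral protein length range in aa
#'   (default 80--160).
#' @param presenceProb Probability a genome carries each protein
#'   family (default 0.9).
#' @param divergence Expected per-site substitution fraction applied
#'   when a genome's copy is evolved (default 0.3).
#' @param seed Master seed.
#' @return A named list of family specs; each has `label`, `ancestors`
#'   (named [Biostrings::AAStringSet]), `presenceProb`, `divergence`.
#' @export
generateFamilies <- function(nFamilies = 4L, nProteinFamilies = 10L,
                             lengthRange = c(80L, 160L),
                             presenceProb = 0.9, divergence = 0.3,
                             seed = 42L) {
  stopifnot(nFamilies >= 1L, presenceProb > 0, presenceProb <= 1,
            divergence >= 0, divergence < 0.8, lengthRange[1] >= 60L)
  set.seed(seed)
  labels <- sprintf("Fam%s", LETTERS[seq_len(nFamilies)])
  specs <- lapply(seq_len(nFamilies), function(i) {
    lens <- sample(lengthRange[1]:lengthRange[2], nProteinFamilies,
                   replace = TRUE)
    anc <- Biostrings::AAStringSet(vapply(lens, .randomProtein,
                                          character(1)))
    names(anc) <- sprintf("pf%02d", seq_len(nProteinFamilies))
    list(label = labels[i], ancestors = anc,
         presenceProb = presenceProb, divergence = divergence)
  })
  names(specs) <- labels
  specs
}

#' Evolve one synthetic phage genome from a family spec
#'
#' Each carried protein family is mutated at the divergence rate
#' (substitutions only, uniform over sites and replacement residues),
#' reverse-translated with random synonymous codons, and placed on a
#' random strand with 50--200 nt random intergenic spacers. The genome
#' is written as a GenBank file with `/translation` qualifiers.
#'
#' @param spec One family spec from [generateFamilies()].
#' @param genomeId Genome identifier.
#' @param seed Seed for this genome.
#' @param dir Output directory (default `tempdir()`).
#' @param divergence,presenceProb Override the spec values.
#' @return A list: `path` (GenBank file), `genome`
#'   ([GenBankGenome-class]), `manifest` (data.frame: locus_tag,
#'   protein_family, start, end, strand, protein).
#' @export
evolveGenome <- function(spec, genomeId, seed, dir = tempdir(),
                         divergence = spec$divergence,
                         presenceProb = spec$presenceProb) {
  set.seed(seed)
  pf <- names(spec$ancestors)
  carried <- pf[stats::runif(length(pf)) < presenceProb]
  if (length(carried) < 2L) carried <- pf[1:2]  # classification floor
  genes <- lapply(carried, function(p) {
    list(protein = .mutateProtein(as.character(spec$ancestors[[p]]),
                                  divergence),
         locus_tag = p,
         product = paste0(spec$label, " family protein ", p),
         strand = sample(c("+", "-"), 1L))
  })
  rep <- .assembleReplicon(genomeId, genes)
  genome <- new("GenBankGenome", genomeId = genomeId,
                replicons = list(rep),
                metadata = list(
                  definition = paste("synthetic phage", genomeId),
                  organism = paste("synthetic", spec$label, "phage"),
                  isolation_source = "synthetic fixture",
                  genome_size_bp = length(rep@sequence),
                  family_label = spec$label
                ))
  path <- file.path(dir, paste0(genomeId, ".gbk"))
  writeGenBank(genome, path)
  ft <- rep@features
  manifest <- data.frame(
    locus_tag = mcols(ft)$locus_tag,
    protein_family = mcols(ft)$locus_tag,
    start = GenomicRanges::start(ft), end = GenomicRanges::end(ft),
    strand = as.character(GenomicRanges::strand(ft)),
    protein = mcols(ft)$translation,
    stringsAsFactors = FALSE
  )
  list(path = path, genome = genome, manifest = manifest)
}

#' Build a synthetic host genome, optionally with implanted prophages
#'
#' Background genes are random proteins with no homology to any
#' family; a contiguous block of `implantSize` evolved family genes is
#' inserted at each requested gene position. The manifest records the
#' truth coordinates of every implant.
#'
#' @param spec Family spec supplying the implanted genes (may be
#'   `NULL` when `positions` is empty).
#' @param hostId Host genome identifier.
#' @param seed Seed for this host.
#' @param dir Output directory.
#' @param nBackgroundGenes Background genes per replicon (default 40).
#' @param implantSize Genes per implant (default 10).
#' @param positions Integer vector of gene positions (1-based, one per
#'   implant; empty for a null host). Must lie within
#'   `1..nBackgroundGenes + 1`.
#' @param implantReplicon Replicon index per implant (default 1).
#' @param nReplicons Number of replicons (default covers the implants).
#' @param divergence Override the spec divergence.
#' @return A list: `path`, `genome`, `manifest` (data.frame of truth
#'   loci: replicon_id, start, end, first_ordinal, last_ordinal,
#'   family_label, n_genes; zero rows for a null host).
#' @export
implantProphage <- function(spec, hostId, seed, dir = tempdir(),
                            nBackgroundGenes = 40L, implantSize = 10L,
                            positions = integer(0),
                            implantReplicon = rep(1L, length(positions)),
                            nReplicons = max(c(1L, implantReplicon)),
                            divergence = if (is.null(spec)) 0 else
                              spec$divergence) {
  if (length(positions) &&
      (any(positions < 1L) || any(positions > nBackgroundGenes + 1L))) {
    stop("implant position outside the host gene range", call. = FALSE)
  }
  set.seed(seed)
  reps <- list()
  truth <- list()
  for (r in seq_len(nReplicons)) {
    rid <- sprintf("%s_chr%d", hostId, r)
    genes <- lapply(seq_len(nBackgroundGenes), function(i) {
      list(protein = .randomProtein(sample(100:250, 1L)),
           locus_tag = sprintf("bg%03d", i),
           product = "host protein",
           strand = sample(c("+", "-"), 1L))
    })
    myImplants <- which(implantReplicon == r)
    ## insert later positions first so earlier indices stay valid
    for (k in myImplants[order(-positions[myImplants])]) {
      anc <- spec$ancestors[seq_len(min(implantSize,
                                        length(spec$ancestors)))]
      block <- lapply(names(anc), function(p) {
        list(protein = .mutateProtein(as.character(anc[[p]]), divergence),
             locus_tag = sprintf("imp%d_%s", k, p),
             product = paste0(spec$label, " prophage protein ", p),
             strand = sample(c("+", "-"), 1L))
      })
      genes <- append(genes, block, after = positions[k] - 1L)
    }
    rep <- .assembleReplicon(rid, genes)
    reps[[r]] <- rep
    ft <- rep@features
    isImp <- grepl("^imp", mcols(ft)$locus_tag)
    if (any(isImp)) {
      for (k in unique(sub("^imp(\\d+)_.*$", "\\1",
                           mcols(ft)$locus_tag[isImp]))) {
        sel <- grepl(sprintf("^imp%s_", k), mcols(ft)$locus_tag)
        truth[[length(truth) + 1L]] <- data.frame(
          replicon_id = rid,
          start = min(GenomicRanges::start(ft)[sel]),
          end = max(GenomicRanges::end(ft)[sel]),
          first_ordinal = min(which(sel)),
          last_ordinal = max(which(sel)),
          family_label = spec$label,
          n_genes = sum(sel), stringsAsFactors = FALSE
        )
      }
    }
  }
  genome <- new("GenBankGenome", genomeId = hostId, replicons = reps,
                metadata = list(
                  definition = paste("synthetic host", hostId),
                  organism = "synthetic host bacterium",
                  isolation_source = "synthetic fixture",
                  genome_size_bp = sum(vapply(reps, function(x)
                    length(x@sequence), integer(1))),
                  family_label = NA_character_
                ))
  path <- file.path(dir, paste0(hostId, ".gbk"))
  writeGenBank(genome, path)
  manifest <- if (length(truth)) do.call(rbind, truth) else data.frame(
    replicon_id = character(0), start = integer(0), end = integer(0),
    first_ordinal = integer(0), last_ordinal = integer(0),
    family_label = character(0), n_genes = integer(0),
    stringsAsFactors = FALSE
  )
  list(path = path, genome = genome, manifest = manifest)
}

#' Delete random CDS annotations from a fixture genome
#'
#' Removes `k` CDS features from the annotation (the nucleotide
#' sequence is untouched, so the deleted spans become intergenic) and
#' rewrites the GenBank file.
#'
#' @param fixture A list with `genome`/`path` (as from
#'   [evolveGenome()]) or a [GenBankGenome-class].
#' @param k Number of CDS to delete (default 1).
#' @param seed Seed for the choice.
#' @param dir Output directory for the rewritten file.
#' @return A list: `path`, `genome`, `removed` (data.frame: replicon_id,
#'   locus_tag, start, end, strand, protein).
#' @export
deleteRandomCds <- function(fixture, k = 1L, seed = 1L, dir = tempdir()) {
  genome <- if (is(fixture, "GenBankGenome")) fixture else fixture$genome
  set.seed(seed)
  all <- do.call(rbind, lapply(genome@replicons, function(rep) {
    data.frame(replicon_id = rep@id,
               idx = seq_along(rep@features),
               stringsAsFactors = FALSE)
  }))
  if (k > nrow(all)) stop("k exceeds the number of CDS", call. = FALSE)
  removedRows <- if (k > 0L) {
    all[sample.int(nrow(all), k), , drop = FALSE]
  } else all[0, , drop = FALSE]
  removed <- list()
  reps <- lapply(genome@replicons, function(rep) {
    drop <- removedRows$idx[removedRows$replicon_id == rep@id]
    if (length(drop)) {
      ft <- rep@features[drop]
      removed[[length(removed) + 1L]] <<- data.frame(
        replicon_id = rep@id, locus_tag = mcols(ft)$locus_tag,
        start = GenomicRanges::start(ft), end = GenomicRanges::end(ft),
        strand = as.character(GenomicRanges::strand(ft)),
        protein = mcols(ft)$translation, stringsAsFactors = FALSE
      )
      rep@features <- rep@features[-drop]
    }
    rep
  })
  genome@replicons <- reps
  newId <- paste0(genome@genomeId, "_del", k)
  genome@genomeId <- newId
  path <- file.path(dir, paste0(newId, ".gbk"))
  writeGenBank(genome, path)
  list(path = path, genome = genome,
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(replicon_id = character(0), locus_tag = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), protein = character(0),
                    stringsAsFactors = FALSE))
}
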