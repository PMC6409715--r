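## Memoized fixture sets shared across test files. Everything is
## generated in code from fixed seeds; the heavyweight model libraries
## are built once per test run.

.cpCache <- new.env(parent = emptyenv())

.cpMemo <- function(key, builder) {
  if (is.null(.cpCache[[key]])) .cpCache[[key]] <- builder()
  .cpCache[[key]]
}

## Small set: 2 families x 6 genomes, 5 protein families. Fast units.
cpSmall <- function() {
  .cpMemo("small", function() {
    specs <- generateFamilies(2L, 5L, divergence = 0.3, seed = 7L)
    dir <- file.path(tempdir(), "cp_small")
    dir.create(dir, showWarnings = FALSE)
    gs <- list()
    k <- 0L
    for (sp in specs) for (j in 1:6) {
      k <- k + 1L
      gid <- sprintf("%s_g%d", sp$label, j)
      gs[[gid]] <- evolveGenome(sp, gid, seed = 700L + k, dir = dir)
    }
    proteins <- combineProteins(lapply(gs, function(x)
      extractCdsProteins(x$genome)))
    cl <- clusterProteins(proteins)
    models <- buildFamilyModels(cl$clusters, proteins)
    list(specs = specs, dir = dir, genomes = gs, proteins = proteins,
         clustering = cl, models = models)
  })
}

## Study-scale set: 4 families x 12 genomes, 10 protein families,
## divergence 0.3, master seed 42. Refined model library included.
cpStudy <- function() {
  .cpMemo("study", function() {
    specs <- generateFamilies(4L, 10L, divergence = 0.3, seed = 42L)
    dir <- file.path(tempdir(), "cp_study")
    dir.create(dir, showWarnings = FALSE)
    gs <- list()
    k <- 0L
    for (sp in specs) for (j in 1:12) {
      k <- k + 1L
      gid <- sprintf("%s_g%02d", sp$label, j)
      gs[[gid]] <- evolveGenome(sp, gid, seed = 42000L + k, dir = dir)
    }
    proteins <- combineProteins(lapply(gs, function(x)
      extractCdsProteins(x$genome)))
    cl <- clusterProteins(proteins)
    models <- buildFamilyModels(cl$clusters, proteins)
    state <- refineToFixpoint(new("RefinementState", models = models,
                                  redundancy = cl$redundancy,
                                  masterProteins = proteins,
                                  round = 0L, changed = TRUE))
    hits <- filterHits(scanProteins(proteins, state@models))
    list(specs = specs, dir = dir, genomes = gs, proteins = proteins,
         clustering = cl, state = state, models = state@models,
         hits = hits)
  })
}

## A constructed hit table row, with the derived fields consistent.
cpHitRow <- function(model_id = "m1", family_label = "FamA",
                     target_id = "t1", evalue = 1e-20, bit_score = 100,
                     hmm_from = 1, hmm_to = 100, model_length = 100,
                     norm_score = bit_score / (3 * model_length)) {
  data.frame(
    model_id = model_id, family_label = family_label,
    target_id = target_id, evalue = evalue, bit_score = bit_score,
    hmm_from = hmm_from, hmm_to = hmm_to, ali_from = 1,
    ali_to = hmm_to - hmm_from + 1, model_length = model_length,
    coverage = (hmm_to - hmm_from + 1) / model_length,
    norm_score = norm_score, stringsAsFactors = FALSE
  )
}

## A constructed gene-hit row for locus-calling tests.
cpGeneHit <- function(ordinal, replicon_id = "chr1", model_id = "m1",
                      family_label = "FamA", start = ordinal * 1000,
                      end = ordinal * 1000 + 900, norm_score = 0.5) {
  data.frame(
    replicon_id = replicon_id, ordinal = as.integer(ordinal),
    start = start, end = end, strand = "+",
    locus_tag = paste0("g", ordinal), model_id = model_id,
    family_label = family_label, evalue = 1e-20, bit_score = 100,
    coverage = 1, norm_score = norm_score, stringsAsFactors = FALSE
  )
}

cpRandomProteins <- function(n, len = 100L, seed = 1L, prefix = "r") {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  x <- Biostrings::AAStringSet(vapply(seq_len(n), function(i)
    paste(sample(aa, len, replace = TRUE), collapse = ""), character(1)))
  names(x) <- paste0(prefix, seq_len(n))
  x
}
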