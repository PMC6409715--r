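## End-to-end pipeline: extract -> cluster -> build -> refine ->
## evaluate -> (classify | scan hosts | recover CDS), with cached
## stage outputs and a config snapshot.

#' Default pipeline configuration
#'
#' All tunables in one place. Unknown keys passed to [runPipeline()]
#' are rejected.
#'
#' @return A named list of defaults.
#' @export
pipelineConfig <- function() {
  list(
    identity_threshold = 0.9,   # redundancy removal
    evalue_cutoff = 1e-5,       # similarity-graph edges
    inflation = 2,              # MCL
    min_cluster_size = 5L,      # model-building floor
    coverage_threshold = 0.5,   # consensus-coverage pruning
    min_coverage = 0.5,         # hit filter
    max_evalue = 1.5e-8,        # hit filter
    min_distinct_models = 2L,   # classification floor
    min_consecutive = 4L,       # locus calling (> 3 hits)
    max_gene_gap = 2L,          # tolerated non-hit genes in a locus
    max_rounds = 20L,           # refinement
    min_intergenic_nt = 90L,    # CDS recovery
    min_orf_aa = 30L            # CDS recovery
  )
}

.mergeConfig <- function(config) {
  base <- pipelineConfig()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base[names(config)] <- config
  base
}

#' Run the full pipeline
#'
#' Stages: extract proteins from labeled training GenBank files,
#' cluster into protein families, build and refine family model sets,
#' evaluate taxon specificity, then optionally classify unlabeled
#' phage genomes and scan host genomes for prophage loci. Every
#' stage's outputs and a config snapshot are persisted under `outDir`;
#' a rerun with an unchanged config and inputs reuses the saved model
#' library.
#'
#' @param trainFiles Character vector of phage GenBank files.
#' @param trainLabels Phage family label per training file.
#' @param outDir Artifact directory.
#' @param classifyFiles Optional GenBank files to classify.
#' @param hostFiles Optional host GenBank files to scan.
#' @param regionsFile Optional external prophage-region TSV
#'   (replicon_id, start, end) for overlap comparison.
#' @param config Named list overriding [pipelineConfig()] entries.
#' @return A list with `models`, `specificity`, `calls` (or NULL),
#'   `loci` (or NULL), `overlap` (or NULL), `outDir`.
#' @export
runPipeline <- function(trainFiles, trainLabels, outDir,
                        classifyFiles = NULL, hostFiles = NULL,
                        regionsFile = NULL, config = list()) {
  cfg <- .mergeConfig(config)
  stopifnot(length(trainFiles) == length(trainLabels))
  missing <- trainFiles[!file.exists(trainFiles)]
  if (length(missing)) {
    stop("stage extract: missing input file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  snapshot <- list(config = cfg, train = basename(trainFiles),
                   labels = trainLabels)
  snapFile <- file.path(outDir, "config.json")
  modelDir <- file.path(outDir, "models")
  cached <- FALSE
  if (file.exists(snapFile) &&
      file.exists(file.path(modelDir, "models.tsv"))) {
    old <- jsonlite::fromJSON(snapFile, simplifyVector = TRUE)
    if (identical(jsonlite::toJSON(snapshot, auto_unbox = TRUE),
                  jsonlite::toJSON(old, auto_unbox = TRUE))) {
      cached <- TRUE
    }
  }
  jsonlite::write_json(snapshot, snapFile, auto_unbox = TRUE,
                       pretty = TRUE)

  ## --- extract --------------------------------------------------------
  .msg("stage extract: ", length(trainFiles), " training genome(s)")
  genomes <- lapply(seq_along(trainFiles), function(i) {
    tryCatch(
      readGenBank(trainFiles[i], familyLabel = trainLabels[i]),
      error = function(e) stop("stage extract failed on '",
                               trainFiles[i], "': ",
                               conditionMessage(e), call. = FALSE)
    )
  })
  proteins <- combineProteins(lapply(genomes, extractCdsProteins))
  writeMultiFasta(proteins, file.path(outDir, "proteins.faa"))

  if (cached) {
    .msg("unchanged config: reusing cached model library")
    models <- loadModels(modelDir)
    redundancy <- jsonlite::fromJSON(file.path(outDir, "redundancy.json"),
                                     simplifyVector = FALSE)
    redundancy <- lapply(redundancy, unlist)
  } else {
    ## --- cluster ------------------------------------------------------
    .msg("stage cluster: ", length(proteins), " proteins")
    cl <- clusterProteins(
      proteins,
      identityThreshold = cfg$identity_threshold,
      evalueCutoff = cfg$evalue_cutoff,
      inflation = cfg$inflation,
      minClusterSize = cfg$min_cluster_size
    )
    clustersTab <- do.call(rbind, lapply(cl$allClusters, function(x) {
      data.frame(cluster_id = x@clusterId, family = x@familyLabel,
                 size = length(x@memberIds),
                 members = paste(x@memberIds, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(clustersTab, file.path(outDir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cl$redundancy,
                         file.path(outDir, "redundancy.json"),
                         auto_unbox = FALSE)
    redundancy <- cl$redundancy

    ## --- build + prune + refine ---------------------------------------
    .msg("stage build: ", length(cl$clusters), " cluster(s)")
    models <- buildFamilyModels(cl$clusters, proteins)
    pruned <- list()
    for (m in models) {
      cluster <- new("ProteinCluster", clusterId = m@modelId,
                     familyLabel = m@familyLabel,
                     memberIds = m@memberIds)
      pc <- pruneByConsensusCoverage(cluster, m@consensus, proteins,
                                     cfg$coverage_threshold)
      if (is.null(pc)) next
      pruned[[pc@clusterId]] <- if (identical(sort(pc@memberIds),
                                              sort(m@memberIds))) {
        m
      } else {
        buildHMM(alignCluster(pc, proteins), pc@clusterId, pc@familyLabel)
      }
    }
    .msg("stage refine")
    state <- new("RefinementState", models = pruned,
                 redundancy = redundancy, masterProteins = proteins,
                 round = 0L, changed = TRUE)
    state <- refineToFixpoint(state, maxRounds = cfg$max_rounds,
                              minCoverage = cfg$min_coverage,
                              maxEvalue = cfg$max_evalue)
    models <- state@models
    saveModels(models, modelDir)
  }

  ## --- evaluate -------------------------------------------------------
  .msg("stage evaluate: ", length(models), " model(s)")
  fams <- vapply(models, familyLabel, character(1))
  byFam <- lapply(split(names(proteins), mcols(proteins)$family_label),
                  function(ids) proteins[ids])
  allHits <- filterHits(scanProteins(proteins, models),
                        minCoverage = cfg$min_coverage,
                        maxEvalue = cfg$max_evalue)
  specificity <- lapply(models, evaluateSpecificity,
                        proteomesByFamily = byFam, hits = allHits,
                        minHits = cfg$min_cluster_size)
  specTab <- data.frame(
    model_id = vapply(specificity, `[[`, character(1), "model_id"),
    family = vapply(specificity, `[[`, character(1), "family_label"),
    indicator = vapply(specificity, `[[`, logical(1), "indicator"),
    stringsAsFactors = FALSE
  )
  utils::write.table(specTab, file.path(outDir, "specificity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeHitsTsv(allHits, file.path(outDir, "train_hits.tsv"))

  ## --- classify -------------------------------------------------------
  calls <- NULL
  if (length(classifyFiles)) {
    .msg("stage classify: ", length(classifyFiles), " genome(s)")
    proteomes <- lapply(classifyFiles, function(f) {
      extractCdsProteins(readGenBank(f))
    })
    names(proteomes) <- vapply(classifyFiles, function(f)
      tools::file_path_sans_ext(basename(f)), character(1))
    calls <- classifyGenomes(proteomes, models,
                             minDistinctModels = cfg$min_distinct_models,
                             minCoverage = cfg$min_coverage,
                             maxEvalue = cfg$max_evalue)
    utils::write.table(calls, file.path(outDir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## --- scan hosts -----------------------------------------------------
  loci <- NULL
  overlap <- NULL
  if (length(hostFiles)) {
    .msg("stage scan-host: ", length(hostFiles), " host genome(s)")
    hosts <- lapply(hostFiles, readGenBank)
    scan <- scanHost(hosts, models, minCoverage = cfg$min_coverage,
                     maxEvalue = cfg$max_evalue)
    loci <- callLoci(scan, minConsecutive = cfg$min_consecutive,
                     maxGeneGap = cfg$max_gene_gap,
                     minDistinctModels = cfg$min_distinct_models)
    writeLociGff(loci, file.path(outDir, "loci.gff3"))
    utils::write.table(loci, file.path(outDir, "loci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(regionsFile)) {
      regions <- utils::read.table(regionsFile, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
      overlap <- compareToRegions(loci, regions)
      utils::write.table(overlap$regions,
                         file.path(outDir, "overlap.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  list(models = models, specificity = specificity, calls = calls,
       loci = loci, overlap = overlap, outDir = outDir)
}
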