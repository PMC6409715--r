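## Consensus-coverage pruning, membership refinement, model merging,
## fixpoint iteration and intergenic CDS recovery.

#' Prune cluster members by consensus coverage
#'
#' Each member is aligned against the model's consensus sequence with
#' BLASTP; members whose best local alignment covers less than
#' `coverageThreshold` of the consensus are removed. If fewer than two
#' members remain the cluster is retired (returns `NULL` with a
#' message).
#'
#' @param cluster A [ProteinCluster-class].
#' @param consensus Consensus amino-acid string (from the cluster's
#'   model).
#' @param proteins Master [Biostrings::AAStringSet].
#' @param coverageThreshold Minimum consensus coverage (default 0.5);
#'   0 disables pruning.
#' @return The pruned [ProteinCluster-class], or `NULL` if retired.
#' @export
pruneByConsensusCoverage <- function(cluster, consensus, proteins,
                                     coverageThreshold = 0.5) {
  if (coverageThreshold <= 0) return(cluster)
  wd <- .tmpDir("consblast")
  on.exit(unlink(wd, recursive = TRUE))
  consFa <- file.path(wd, "cons.faa")
  cons <- Biostrings::AAStringSet(consensus)
  names(cons) <- "consensus"
  writeMultiFasta(cons, consFa)
  db <- file.path(wd, "db")
  .runTool("makeblastdb", c("-in", consFa, "-dbtype", "prot", "-out", db))
  memFa <- file.path(wd, "members.faa")
  writeMultiFasta(proteins[cluster@memberIds], memFa)
  out <- file.path(wd, "cov.tsv")
  .runTool("blastp", c("-query", memFa, "-db", db,
                       "-outfmt", shQuote("6 qseqid sstart send"),
                       "-evalue", "10", "-num_threads", "1",
                       "-out", out))
  covOf <- stats::setNames(numeric(length(cluster@memberIds)),
                           cluster@memberIds)
  if (file.size(out)) {
    tab <- utils::read.table(out, sep = "\t", stringsAsFactors = FALSE)
    names(tab) <- c("q", "sstart", "send")
    covHsp <- (abs(tab$send - tab$sstart) + 1) / nchar(consensus)
    best <- tapply(covHsp, tab$q, max)
    covOf[names(best)] <- best
  }
  keep <- cluster@memberIds[covOf[cluster@memberIds] >= coverageThreshold]
  dropped <- setdiff(cluster@memberIds, keep)
  if (length(dropped)) {
    .msg(cluster@clusterId, ": ", length(dropped),
         " member(s) below consensus coverage ", coverageThreshold)
  }
  if (length(keep) < 2L) {
    .msg(cluster@clusterId, " retired (<2 members after pruning)")
    return(NULL)
  }
  new("ProteinCluster", clusterId = cluster@clusterId,
      familyLabel = cluster@familyLabel, memberIds = keep)
}

#' Refine one model's membership from its scan hits
#'
#' Membership update rules: proteins that are hit and not yet assigned
#' to any model are added; proteins that built the model but are no
#' longer hit are removed; proteins that were removed as redundant are
#' never added.
#'
#' @param model A [ProfileHMM-class].
#' @param hitTargets Character vector: the model's filtered hit targets
#'   against the master set.
#' @param redundancy Redundancy map (named list) from
#'   [removeRedundant()].
#' @param assignedIds Ids currently belonging to any model.
#' @return A list with `memberIds` (the new membership, sorted) and
#'   `changed` (logical).
#' @export
refineMembership <- function(model, hitTargets, redundancy, assignedIds) {
  removedIds <- unlist(redundancy, use.names = FALSE)
  kept <- intersect(model@memberIds, hitTargets)
  added <- setdiff(hitTargets, union(assignedIds, removedIds))
  newMembers <- sort(union(kept, added))
  list(memberIds = newMembers,
       changed = !identical(newMembers, sort(model@memberIds)))
}

#' Merge models with identical hit-and-input sets
#'
#' Models whose union of filtered hit targets and member sets are
#' exactly equal are merged (pairwise-transitively): members are
#' unioned, realigned and one model is rebuilt under the
#' lexicographically smallest of the merged ids. All other models are
#' untouched.
#'
#' @param models List of [ProfileHMM-class] objects.
#' @param hitsets Named list (by model id) of filtered hit-target
#'   character vectors.
#' @param proteins Master [Biostrings::AAStringSet] (for rebuilding).
#' @return The merged model list (named by model id).
#' @export
mergeEquivalentModels <- function(models, hitsets, proteins) {
  if (!length(models)) return(models)
  keys <- vapply(models, function(m) {
    hs <- hitsets[[m@modelId]]
    paste(sort(union(hs, m@memberIds)), collapse = "\r")
  }, character(1))
  out <- list()
  for (key in unique(keys)) {
    grp <- models[keys == key]
    if (length(grp) == 1L) {
      out[[grp[[1]]@modelId]] <- grp[[1]]
      next
    }
    ids <- sort(unname(vapply(grp, modelId, character(1))))
    members <- sort(unique(unlist(lapply(grp, memberIds))))
    .msg("merging models ", paste(ids, collapse = " + "))
    msa <- alignCluster(members, proteins)
    out[[ids[1]]] <- buildHMM(msa, ids[1], grp[[1]]@familyLabel)
  }
  out[order(names(out))]
}

.membershipHash <- function(models) {
  paste(sort(vapply(models, function(m) {
    paste(m@modelId, paste(sort(m@memberIds), collapse = ","))
  }, character(1))), collapse = ";")
}

#' Iterate scan / membership update / merge to a fixpoint
#'
#' Each round scans the master protein set with the current library,
#' filters the hits, applies [refineMembership()] to every model (in
#' model-id order, against the assignments at the round start), rebuilds
#' models whose membership changed, and merges equivalent models. The
#' loop stops when a round changes nothing, when the state oscillates
#' (a bounded history of 3 states is kept), or at `maxRounds`.
#'
#' @param state A [RefinementState-class] (round 0).
#' @param maxRounds Maximum rounds (default 20).
#' @param minCoverage,maxEvalue Hit filter cut-offs
#'   (see [filterHits()]).
#' @return The final [RefinementState-class]; `@changed` is `FALSE` iff
#'   a fixpoint was reached.
#' @export
refineToFixpoint <- function(state, maxRounds = 20L, minCoverage = 0.5,
                             maxEvalue = 1.5e-8) {
  if (maxRounds < 1L) {
    warning("maxRounds < 1: state returned unchanged")
    return(state)
  }
  history <- .membershipHash(state@models)
  for (round in seq_len(maxRounds)) {
    models <- state@models
    if (!length(models)) break
    hits <- filterHits(scanProteins(state@masterProteins, models),
                       minCoverage = minCoverage, maxEvalue = maxEvalue)
    hitsets <- split(hits$target_id, hits$model_id)
    assigned <- unique(unlist(lapply(models, memberIds)))
    anyChange <- FALSE
    newModels <- list()
    for (mid in sort(vapply(models, modelId, character(1)))) {
      m <- models[[mid]]
      upd <- refineMembership(m, hitsets[[mid]] %||% character(0),
                              state@redundancy, assigned)
      if (length(upd$memberIds) < 2L) {
        .msg("model ", mid, " retired (<2 members at round ", round, ")")
        anyChange <- TRUE
        next
      }
      if (upd$changed) {
        anyChange <- TRUE
        msa <- alignCluster(upd$memberIds, state@masterProteins)
        newModels[[mid]] <- buildHMM(msa, mid, m@familyLabel)
      } else {
        newModels[[mid]] <- m
      }
    }
    ## merge on the hit sets of the scan that drove this round
    merged <- mergeEquivalentModels(newModels, hitsets,
                                    state@masterProteins)
    if (length(merged) != length(newModels)) anyChange <- TRUE
    state@models <- merged
    state@round <- state@round + 1L
    state@changed <- anyChange
    if (!anyChange) return(state)
    h <- .membershipHash(state@models)
    if (h %in% history) {
      warning("refinement oscillates; returning last state")
      return(state)
    }
    history <- utils::tail(c(history, h), 3L)
  }
  if (state@changed) warning("refinement did not stabilize within ",
                             maxRounds, " rounds")
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recover unannotated CDS from intergenic regions
#'
#' Intergenic regions of each genome are six-frame translated; the
#' candidates are scanned with the refined library and hits surviving
#' the cut-offs (coverage >= 0.5, positive bit score, E <= 1.5e-8 by
#' default) become recovered CDS with genomic coordinates.
#'
#' @param genomes A list of [GenBankGenome-class] objects.
#' @param models List of refined [ProfileHMM-class] objects.
#' @param minLenNt Minimum intergenic region length (default 90).
#' @param minOrfAa Minimum candidate ORF length (default 30).
#' @param minCoverage,maxEvalue Filter cut-offs (see [filterHits()]).
#' @return A list with `recovered` (data.frame: candidate_id, model_id,
#'   family_label, genome_id, replicon_id, start, end, strand, evalue,
#'   bit_score, coverage, norm_score) and `candidates` (the
#'   AAStringSet of recovered candidate sequences).
#' @export
recoverMissingCds <- function(genomes, models, minLenNt = 90L,
                              minOrfAa = 30L, minCoverage = 0.5,
                              maxEvalue = 1.5e-8) {
  if (is(genomes, "GenBankGenome")) genomes <- list(genomes)
  cands <- list()
  candMeta <- list()
  for (g in genomes) {
    for (rep in g@replicons) {
      regs <- extractIntergenicRegions(rep, minLenNt = minLenNt)
      for (i in seq_len(nrow(regs))) {
        orfs <- sixFrameTranslate(
          regs[i, ], minOrfAa = minOrfAa,
          idPrefix = paste(g@genomeId, rep@id, regs$start[i], sep = "|")
        )
        if (!length(orfs)) next
        cands[[length(cands) + 1L]] <- orfs
        candMeta[[length(candMeta) + 1L]] <- data.frame(
          candidate_id = names(orfs), genome_id = g@genomeId,
          replicon_id = mcols(orfs)$replicon_id,
          start = mcols(orfs)$start, end = mcols(orfs)$end,
          strand = mcols(orfs)$strand, stringsAsFactors = FALSE
        )
      }
    }
  }
  emptyRec <- data.frame(
    candidate_id = character(0), model_id = character(0),
    family_label = character(0), genome_id = character(0),
    replicon_id = character(0), start = integer(0), end = integer(0),
    strand = character(0), evalue = numeric(0), bit_score = numeric(0),
    coverage = numeric(0), norm_score = numeric(0),
    stringsAsFactors = FALSE
  )
  if (!length(cands)) {
    return(list(recovered = emptyRec, candidates = Biostrings::AAStringSet()))
  }
  allCands <- do.call(c, lapply(cands, function(x) {
    y <- Biostrings::AAStringSet(as.character(x))
    names(y) <- names(x)
    y
  }))
  meta <- do.call(rbind, candMeta)
  hits <- filterHits(scanProteins(allCands, models),
                     minCoverage = minCoverage, maxEvalue = maxEvalue)
  if (!nrow(hits)) {
    return(list(recovered = emptyRec, candidates = Biostrings::AAStringSet()))
  }
  idx <- match(hits$target_id, meta$candidate_id)
  rec <- data.frame(
    candidate_id = hits$target_id,
    model_id = hits$model_id,
    family_label = hits$family_label,
    genome_id = meta$genome_id[idx],
    replicon_id = meta$replicon_id[idx],
    start = meta$start[idx], end = meta$end[idx],
    strand = meta$strand[idx],
    evalue = hits$evalue, bit_score = hits$bit_score,
    coverage = hits$coverage, norm_score = hits$norm_score,
    stringsAsFactors = FALSE
  )
  rownames(rec) <- NULL
  list(recovered = rec, candidates = allCands[unique(hits$target_id)])
}

#' Fold recovered CDS into a model and rebuild
#'
#' Appends the recovered sequences to the model's member alignment,
#' realigns, rebuilds, and reports a before/after comparison of the
#' model's filtered hits on the master set (hit-target sets and score
#' shifts), so the effect of the refinement on model performance can be
#' inspected.
#'
#' @param model A [ProfileHMM-class].
#' @param recoveredSeqs [Biostrings::AAStringSet] of recovered
#'   candidates assigned to this model (may be empty).
#' @param proteins Master [Biostrings::AAStringSet].
#' @param minCoverage,maxEvalue Filter cut-offs for the report.
#' @return A list with `model` (the rebuilt [ProfileHMM-class]; the
#'   member registry is unchanged — recovered sequences enter the
#'   alignment only) and `report` (data.frame: target_id, bit_before,
#'   bit_after, in_before, in_after).
#' @export
integrateAndRebuild <- function(model, recoveredSeqs, proteins,
                                minCoverage = 0.5, maxEvalue = 1.5e-8) {
  if (!length(recoveredSeqs)) {
    return(list(model = model,
                report = data.frame(target_id = character(0),
                                    bit_before = numeric(0),
                                    bit_after = numeric(0),
                                    in_before = logical(0),
                                    in_after = logical(0))))
  }
  pool <- c(proteins[model@memberIds],
            recoveredSeqs[setdiff(names(recoveredSeqs),
                                  model@memberIds)])
  msa <- alignCluster(names(pool), pool)
  rebuilt <- buildHMM(msa, model@modelId, model@familyLabel)
  rebuilt@memberIds <- model@memberIds
  before <- filterHits(scanProteins(proteins, list(model)),
                       minCoverage = minCoverage, maxEvalue = maxEvalue)
  after <- filterHits(scanProteins(proteins, list(rebuilt)),
                      minCoverage = minCoverage, maxEvalue = maxEvalue)
  targets <- union(before$target_id, after$target_id)
  report <- data.frame(
    target_id = targets,
    bit_before = before$bit_score[match(targets, before$target_id)],
    bit_after = after$bit_score[match(targets, after$target_id)],
    in_before = targets %in% before$target_id,
    in_after = targets %in% after$target_id,
    stringsAsFactors = FALSE
  )
  list(model = rebuilt, report = report)
}
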