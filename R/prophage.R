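## Host-genome scanning, consecutive-hit locus calling, locus
## classification, external region comparison.

#' Scan host replicons for phage-like genes
#'
#' Extracts the host CDS proteins with coordinates and gene ordinals,
#' scans them with the model library, filters the hits and maps them
#' back onto the genes.
#'
#' @param host A [GenBankGenome-class] (possibly multi-replicon) or a
#'   list of them.
#' @param models List of [ProfileHMM-class] objects.
#' @param minCoverage,maxEvalue Filter cut-offs (see [filterHits()]).
#' @param hits Optional precomputed filtered hits for the combined
#'   host proteome(s).
#' @return A list with `geneHits` (data.frame: replicon_id, ordinal,
#'   start, end, strand, locus_tag, model_id, family_label, evalue,
#'   bit_score, coverage, norm_score) and `repliconInfo` (data.frame:
#'   replicon_id, n_genes, topology).
#' @export
scanHost <- function(host, models, minCoverage = 0.5, maxEvalue = 1.5e-8,
                     hits = NULL) {
  hosts <- if (is(host, "GenBankGenome")) list(host) else host
  prot <- combineProteins(lapply(hosts, extractCdsProteins))
  info <- do.call(rbind, lapply(hosts, function(g) {
    data.frame(
      replicon_id = vapply(g@replicons, repliconId, character(1)),
      n_genes = vapply(g@replicons, function(r) length(r@features),
                       integer(1)),
      topology = vapply(g@replicons, topology, character(1)),
      stringsAsFactors = FALSE
    )
  }))
  empty <- data.frame(
    replicon_id = character(0), ordinal = integer(0), start = integer(0),
    end = integer(0), strand = character(0), locus_tag = character(0),
    model_id = character(0), family_label = character(0),
    evalue = numeric(0), bit_score = numeric(0), coverage = numeric(0),
    norm_score = numeric(0), stringsAsFactors = FALSE
  )
  if (!length(prot)) return(list(geneHits = empty, repliconInfo = info))
  if (is.null(hits)) {
    hits <- filterHits(scanProteins(prot, models),
                       minCoverage = minCoverage, maxEvalue = maxEvalue)
  }
  if (!nrow(hits)) return(list(geneHits = empty, repliconInfo = info))
  pm <- mcols(prot)
  ## gene ordinal: rank of start within its replicon
  ord <- stats::ave(pm$start, pm$replicon_id,
                    FUN = function(x) rank(x, ties.method = "first"))
  idx <- match(hits$target_id, names(prot))
  gh <- data.frame(
    replicon_id = pm$replicon_id[idx],
    ordinal = as.integer(ord[idx]),
    start = pm$start[idx], end = pm$end[idx],
    strand = pm$strand[idx],
    locus_tag = hits$target_id,
    model_id = hits$model_id, family_label = hits$family_label,
    evalue = hits$evalue, bit_score = hits$bit_score,
    coverage = hits$coverage, norm_score = hits$norm_score,
    stringsAsFactors = FALSE
  )
  gh <- gh[order(gh$replicon_id, gh$ordinal, gh$model_id), , drop = FALSE]
  rownames(gh) <- NULL
  list(geneHits = gh, repliconInfo = info)
}

#' Assign a family to a prophage locus
#'
#' Same decision rule as genome classification, restricted to the
#' locus's supporting hits: the winning family needs at least
#' `minDistinctModels` distinct models and a strict lead over the
#' runner-up, otherwise the locus is `"unresolved"`.
#'
#' @param supportingHits Gene-hit data.frame rows supporting the locus.
#' @param minDistinctModels Minimum distinct models (default 2).
#' @return A family label or `"unresolved"`.
#' @export
assignLocusFamily <- function(supportingHits, minDistinctModels = 2L) {
  if (!nrow(supportingHits)) return("unresolved")
  ev <- .familyEvidence(supportingHits,
                        sort(unique(supportingHits$family_label)))
  .callFromEvidence(ev, minDistinctModels, "unresolved", "unresolved")
}

#' Call prophage loci from consecutive gene hits
#'
#' A locus is a maximal run of hit genes on one replicon in which
#' consecutive hit genes are separated by at most `maxGeneGap` non-hit
#' genes, containing at least `minConsecutive` hit genes (strictly more
#' than three at the default). The locus spans the first to the last
#' supporting gene; on circular replicons runs are joined across the
#' origin. Consecutiveness is measured in gene ordinals, not base
#' pairs.
#'
#' @param scan Output of [scanHost()] (or a gene-hit data.frame, in
#'   which case `repliconInfo` must be supplied).
#' @param minConsecutive Minimum supporting hit genes (default 4).
#' @param maxGeneGap Maximum tolerated non-hit genes inside a run
#'   (default 2).
#' @param minDistinctModels Passed to [assignLocusFamily()].
#' @param repliconInfo Replicon gene counts/topology when `scan` is a
#'   bare data.frame.
#' @return A data.frame of loci: replicon_id, start, end,
#'   n_consecutive, family_call, mean_norm_score, first_ordinal,
#'   last_ordinal; with the supporting hits in
#'   `attr(, "supporting_hits")` (a list).
#' @export
callLoci <- function(scan, minConsecutive = 4L, maxGeneGap = 2L,
                     minDistinctModels = 2L, repliconInfo = NULL) {
  if (is.data.frame(scan)) {
    geneHits <- scan
    info <- repliconInfo
  } else {
    geneHits <- scan$geneHits
    info <- scan$repliconInfo
  }
  out <- data.frame(
    replicon_id = character(0), start = integer(0), end = integer(0),
    n_consecutive = integer(0), family_call = character(0),
    mean_norm_score = numeric(0), first_ordinal = integer(0),
    last_ordinal = integer(0), stringsAsFactors = FALSE
  )
  support <- list()
  if (!nrow(geneHits)) {
    attr(out, "supporting_hits") <- support
    return(out)
  }
  for (rid in unique(geneHits$replicon_id)) {
    gh <- geneHits[geneHits$replicon_id == rid, , drop = FALSE]
    ords <- sort(unique(gh$ordinal))
    ## group hit ordinals into runs tolerating <= maxGeneGap non-hit genes
    runId <- cumsum(c(1L, diff(ords) > maxGeneGap + 1L))
    runs <- split(ords, runId)
    nGenes <- if (!is.null(info)) {
      info$n_genes[match(rid, info$replicon_id)]
    } else NA_integer_
    topo <- if (!is.null(info)) {
      info$topology[match(rid, info$replicon_id)]
    } else "linear"
    ## join the terminal runs across the origin of a circular replicon
    if (!is.na(nGenes) && identical(topo, "circular") &&
        length(runs) >= 2L) {
      firstRun <- runs[[1]]
      lastRun <- runs[[length(runs)]]
      wrapGap <- (nGenes - max(lastRun)) + (min(firstRun) - 1L)
      if (wrapGap <= maxGeneGap) {
        runs[[1]] <- c(lastRun, firstRun)
        runs[[length(runs)]] <- NULL
      }
    }
    for (run in runs) {
      if (length(run) < minConsecutive) next
      sh <- gh[gh$ordinal %in% run, , drop = FALSE]
      out <- rbind(out, data.frame(
        replicon_id = rid,
        start = min(sh$start), end = max(sh$end),
        n_consecutive = length(run),
        family_call = assignLocusFamily(sh, minDistinctModels),
        mean_norm_score = mean(sh$norm_score),
        first_ordinal = min(run), last_ordinal = max(run),
        stringsAsFactors = FALSE
      ))
      support[[length(support) + 1L]] <- sh
    }
  }
  rownames(out) <- NULL
  attr(out, "supporting_hits") <- support
  out
}

#' Compare called loci with an external prophage region table
#'
#' Generic coordinate-table overlap: a locus and an external region on
#' the same replicon match when their overlap covers at least
#' `minOverlapFraction` of the shorter interval. Loci are labeled
#' confirmed/novel, external regions confirmed/missed, and the triad of
#' counts is summarized.
#'
#' @param loci Locus data.frame from [callLoci()].
#' @param regions External region data.frame with `replicon_id`,
#'   `start`, `end` (e.g. read from a TSV).
#' @param minOverlapFraction Minimum overlap as a fraction of the
#'   shorter interval (default 0.5).
#' @return A list with `loci` (input plus `status`), `regions` (input
#'   plus `status`) and `summary` (confirmed, novel, missed counts).
#' @export
compareToRegions <- function(loci, regions, minOverlapFraction = 0.5) {
  known <- unique(loci$replicon_id)
  bad <- !(regions$replicon_id %in% known)
  if (any(bad) && nrow(loci)) {
    warning(sum(bad), " external region(s) on unknown replicon ids skipped")
  }
  overlapFrac <- function(s1, e1, s2, e2) {
    ov <- min(e1, e2) - max(s1, s2) + 1
    if (ov <= 0) return(0)
    ov / min(e1 - s1 + 1, e2 - s2 + 1)
  }
  lociStatus <- rep("novel", nrow(loci))
  regStatus <- rep("missed", nrow(regions))
  regStatus[bad] <- "skipped"
  for (i in seq_len(nrow(loci))) {
    for (j in seq_len(nrow(regions))) {
      if (bad[j] || regions$replicon_id[j] != loci$replicon_id[i]) next
      if (overlapFrac(loci$start[i], loci$end[i],
                      regions$start[j], regions$end[j]) >=
          minOverlapFraction) {
        lociStatus[i] <- "confirmed"
        regStatus[j] <- "confirmed"
      }
    }
  }
  loci$status <- lociStatus
  regions$status <- regStatus
  list(
    loci = loci, regions = regions,
    summary = c(
      confirmed = sum(regStatus == "confirmed"),
      novel = sum(lociStatus == "novel"),
      missed = sum(regStatus == "missed")
    )
  )
}
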