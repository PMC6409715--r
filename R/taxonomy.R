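## Taxon specificity evaluation, cross-match accounting, classification.

## Aggregate filtered hits for one proteome: per family, the number of
## distinct models hit, total hits, summed norm score.
.familyEvidence <- function(hits, familyLevels) {
  ev <- data.frame(
    family_label = familyLevels,
    models_hit = 0L, n_hits = 0L, sum_norm_score = 0,
    stringsAsFactors = FALSE
  )
  if (nrow(hits)) {
    for (i in seq_along(familyLevels)) {
      sub <- hits[hits$family_label == familyLevels[i], , drop = FALSE]
      ev$models_hit[i] <- length(unique(sub$model_id))
      ev$n_hits[i] <- nrow(sub)
      ev$sum_norm_score[i] <- sum(sub$norm_score)
    }
  }
  ev
}

#' Evaluate a model's taxon specificity
#'
#' A model is a taxonomic indicator when its own-family filtered hit
#' count reaches `minHits` (the cluster-size floor) and its own-family
#' mean normalized score strictly exceeds every other family's mean.
#' The full per-family table is returned for heatmap-style matrices.
#'
#' @param model A [ProfileHMM-class].
#' @param proteomesByFamily Named list of [Biostrings::AAStringSet]
#'   proteomes, one per phage family.
#' @param hits Optional precomputed *filtered* hits of this model
#'   against the concatenation of those proteomes (must carry
#'   `target_id` resolvable in the proteomes); computed if `NULL`.
#' @param minHits Own-family hit floor (default 5).
#' @param minCoverage,maxEvalue Filter cut-offs when `hits` is
#'   computed here.
#' @return A list with `model_id`, `family_label`, `table` (per-family
#'   hit count and mean norm score) and `indicator` (logical).
#' @export
evaluateSpecificity <- function(model, proteomesByFamily, hits = NULL,
                                minHits = 5L, minCoverage = 0.5,
                                maxEvalue = 1.5e-8) {
  fams <- names(proteomesByFamily)
  famOf <- rep(fams, vapply(proteomesByFamily, length, integer(1)))
  names(famOf) <- unlist(lapply(proteomesByFamily, names),
                         use.names = FALSE)
  if (is.null(hits)) {
    all <- do.call(c, lapply(fams, function(f) {
      x <- proteomesByFamily[[f]]
      Biostrings::AAStringSet(stats::setNames(as.character(x), names(x)))
    }))
    hits <- filterHits(scanProteins(all, list(model)),
                       minCoverage = minCoverage, maxEvalue = maxEvalue)
  } else {
    hits <- hits[hits$model_id == model@modelId, , drop = FALSE]
  }
  tab <- data.frame(
    family_label = fams, n_hits = 0L, mean_norm_score = 0,
    stringsAsFactors = FALSE
  )
  if (nrow(hits)) {
    hf <- famOf[hits$target_id]
    for (i in seq_along(fams)) {
      sub <- hits[!is.na(hf) & hf == fams[i], , drop = FALSE]
      tab$n_hits[i] <- nrow(sub)
      tab$mean_norm_score[i] <- if (nrow(sub)) mean(sub$norm_score) else 0
    }
  }
  own <- tab[tab$family_label == model@familyLabel, , drop = FALSE]
  others <- tab[tab$family_label != model@familyLabel, , drop = FALSE]
  indicator <- nrow(own) == 1L && own$n_hits >= minHits &&
    (nrow(others) == 0L || own$mean_norm_score > max(others$mean_norm_score))
  list(model_id = model@modelId, family_label = model@familyLabel,
       table = tab, indicator = indicator)
}

#' Cross-match accounting over labeled proteomes
#'
#' For every protein the set of families whose models hit it (filtered
#' hits) is recorded. Hit proteins fall into three categories: matched
#' exclusively by their own family's models; cross-matched within a
#' family group; cross-matched between groups. Fractions are over all
#' hit proteins and sum to 1.
#'
#' @param models List of [ProfileHMM-class] objects.
#' @param proteins Master [Biostrings::AAStringSet] with a
#'   `family_label` metadata column (the protein's source family).
#' @param groups Optional named character vector mapping family label
#'   to group (e.g. tailed vs filamentous); with no grouping every
#'   cross match counts as within-group.
#' @param hits Optional precomputed filtered hits; computed if `NULL`.
#' @param minCoverage,maxEvalue Filter cut-offs when computing hits.
#' @return A list with `fractions` (named numeric: exclusive,
#'   cross_within, cross_between), `counts` (same, integer),
#'   `n_hit_proteins`, and `per_protein` (data.frame: target_id,
#'   own_family, hit_families, category).
#' @export
crossMatchMatrix <- function(models, proteins, groups = NULL, hits = NULL,
                             minCoverage = 0.5, maxEvalue = 1.5e-8) {
  if (is.null(hits)) {
    hits <- filterHits(scanProteins(proteins, models),
                       minCoverage = minCoverage, maxEvalue = maxEvalue)
  }
  famOf <- stats::setNames(mcols(proteins)$family_label, names(proteins))
  cats <- c("exclusive", "cross_within", "cross_between")
  if (!nrow(hits)) {
    return(list(fractions = stats::setNames(rep(NaN, 3), cats),
                counts = stats::setNames(rep(0L, 3), cats),
                n_hit_proteins = 0L,
                per_protein = data.frame(target_id = character(0),
                                         own_family = character(0),
                                         hit_families = character(0),
                                         category = character(0))))
  }
  hitFams <- split(hits$family_label, hits$target_id)
  targets <- names(hitFams)
  own <- famOf[targets]
  category <- vapply(seq_along(targets), function(i) {
    fams <- unique(hitFams[[i]])
    foreign <- setdiff(fams, own[i])
    if (!length(foreign)) return("exclusive")
    if (is.null(groups)) return("cross_within")
    og <- groups[[own[i]]]
    if (any(groups[foreign] != og)) "cross_between" else "cross_within"
  }, character(1))
  counts <- stats::setNames(
    vapply(cats, function(cc) sum(category == cc), integer(1)), cats)
  list(
    fractions = counts / length(targets),
    counts = counts,
    n_hit_proteins = length(targets),
    per_protein = data.frame(
      target_id = targets, own_family = unname(own),
      hit_families = vapply(hitFams, function(x)
        paste(sort(unique(x)), collapse = ","), character(1)),
      category = category, stringsAsFactors = FALSE
    )
  )
}

## Winner selection shared by genome classification and locus calls.
.callFromEvidence <- function(ev, minDistinctModels, noneLabel,
                              tieLabel) {
  ev <- ev[ev$models_hit > 0L, , drop = FALSE]
  if (!nrow(ev)) return(noneLabel)
  o <- order(-ev$models_hit, -ev$sum_norm_score, ev$family_label)
  ev <- ev[o, , drop = FALSE]
  top <- ev[1, ]
  if (top$models_hit < minDistinctModels) return(noneLabel)
  if (nrow(ev) >= 2L) {
    second <- ev[2, ]
    if (second$models_hit == top$models_hit &&
        second$sum_norm_score == top$sum_norm_score) {
      return(tieLabel)
    }
  }
  top$family_label
}

#' Classify a phage genome from aggregated model hits
#'
#' Filtered hits are aggregated per family; the primary criterion is
#' the number of distinct models hit (robust against one promiscuous
#' protein), with the summed normalized score as tie-break. The winning
#' family must reach `minDistinctModels` (a single model hit is never
#' enough) and strictly beat the runner-up, otherwise the call is
#' `"unassigned"` / `"ambiguous"`.
#'
#' @param genomeProteins [Biostrings::AAStringSet]: the genome's
#'   proteome.
#' @param models List of [ProfileHMM-class] objects (>= 1).
#' @param minDistinctModels Minimum distinct models hit (default 2).
#' @param hits Optional precomputed filtered hits for this proteome.
#' @param minCoverage,maxEvalue Filter cut-offs when computing hits.
#' @return A list with `call` (family label, `"unassigned"` or
#'   `"ambiguous"`), `evidence` (per-family data.frame) and `hits`
#'   (the supporting hit table).
#' @export
classifyGenome <- function(genomeProteins, models, minDistinctModels = 2L,
                           hits = NULL, minCoverage = 0.5,
                           maxEvalue = 1.5e-8) {
  fams <- sort(unique(vapply(models, familyLabel, character(1))))
  if (is.null(hits)) {
    hits <- if (length(genomeProteins)) {
      filterHits(scanProteins(genomeProteins, models),
                 minCoverage = minCoverage, maxEvalue = maxEvalue)
    } else {
      filterHits(data.frame(coverage = numeric(0), evalue = numeric(0),
                            bit_score = numeric(0)))
    }
  }
  ev <- .familyEvidence(hits, fams)
  call <- if (!nrow(hits)) "unassigned" else {
    .callFromEvidence(ev, minDistinctModels, "unassigned", "ambiguous")
  }
  list(call = call, evidence = ev, hits = hits)
}

#' Classify many genomes against a model library
#'
#' Convenience wrapper: scans each proteome once and applies
#' [classifyGenome()]. Deterministic and invariant to protein input
#' order.
#'
#' @param proteomes Named list of [Biostrings::AAStringSet] (one per
#'   genome).
#' @param models List of [ProfileHMM-class] objects.
#' @param ... Passed to [classifyGenome()].
#' @return A data.frame: genome_id, call, plus per-family
#'   `models_hit.<family>` columns.
#' @export
classifyGenomes <- function(proteomes, models, ...) {
  rows <- lapply(names(proteomes), function(gid) {
    res <- classifyGenome(proteomes[[gid]], models, ...)
    counts <- stats::setNames(res$evidence$models_hit,
                              paste0("models_hit.",
                                     res$evidence$family_label))
    c(list(genome_id = gid, call = res$call), as.list(counts))
  })
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}
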