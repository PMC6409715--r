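## Cluster assembly and size filtering.

#' Filter clusters by minimum size
#'
#' Profile HMMs are only built from clusters with at least
#' `minClusterSize` proteins (default 5); smaller clusters are dropped
#' and logged — these exclusions are why some protein families never
#' yield a model.
#'
#' @param clusters A list of [ProteinCluster-class] objects.
#' @param minClusterSize Minimum member count (default 5).
#' @return The retained list of clusters.
#' @export
filterClusters <- function(clusters, minClusterSize = 5L) {
  sizes <- vapply(clusters, function(cl) length(cl@memberIds), integer(1))
  drop <- sizes < minClusterSize
  if (any(drop)) {
    .msg("dropping ", sum(drop), " cluster(s) below size ", minClusterSize,
         " (sizes: ", paste(sizes[drop], collapse = ","), ")")
  }
  if (all(drop)) warning("no cluster reaches the minimum size",
                         call. = FALSE)
  clusters[!drop]
}

#' Cluster proteins into families
#'
#' The full protein-family definition chain: greedy redundancy removal,
#' per-family all-vs-all BLASTP similarity graph, Markov clustering,
#' and the minimum-size filter. Clustering is run separately per phage
#' family label, so every cluster (and hence every model) carries one
#' family.
#'
#' @param proteins [Biostrings::AAStringSet] with a `family_label`
#'   metadata column.
#' @param identityThreshold Redundancy-removal identity (default 0.9).
#' @param evalueCutoff Similarity-graph E-value cutoff (default 1e-5).
#' @param inflation MCL inflation (default 2).
#' @param minClusterSize Minimum cluster size for model building
#'   (default 5).
#' @return A list with `clusters` (retained [ProteinCluster-class]
#'   list), `allClusters` (before the size filter), `representatives`
#'   (post-redundancy AAStringSet) and `redundancy` (the redundancy
#'   map).
#' @export
clusterProteins <- function(proteins, identityThreshold = 0.9,
                            evalueCutoff = 1e-5, inflation = 2,
                            minClusterSize = 5L) {
  red <- removeRedundant(proteins, identityThreshold)
  reps <- red$representatives
  fams <- mcols(reps)$family_label
  if (is.null(fams)) fams <- rep(NA_character_, length(reps))
  fams[is.na(fams)] <- "unlabeled"
  allClusters <- list()
  for (fam in sort(unique(fams))) {
    sub <- reps[fams == fam]
    g <- buildSimilarityGraph(sub, evalueCutoff = evalueCutoff)
    parts <- mclCluster(g, inflation = inflation)
    for (k in seq_along(parts)) {
      allClusters[[length(allClusters) + 1L]] <- new(
        "ProteinCluster",
        clusterId = sprintf("%s_c%03d", fam, k),
        familyLabel = fam,
        memberIds = parts[[k]]
      )
    }
  }
  list(
    clusters = filterClusters(allClusters, minClusterSize),
    allClusters = allClusters,
    representatives = reps,
    redundancy = red$redundancy
  )
}
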