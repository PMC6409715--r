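## Greedy incremental redundancy clustering (CD-hit-like).

#' @importFrom Biostrings pairwiseAlignment nmatch
NULL

.kmerSet <- function(x, k = 4L) {
  n <- nchar(x)
  if (n < k) return(x)
  unique(substring(x, 1:(n - k + 1L), k:n))
}

.globalIdentity <- function(a, b) {
  aln <- pairwiseAlignment(a, b, type = "global",
                           substitutionMatrix = "BLOSUM62",
                           gapOpening = 10, gapExtension = 0.5)
  nmatch(aln) / min(nchar(a), nchar(b))
}

#' Remove redundant proteins by greedy incremental clustering
#'
#' Re-implements the classic greedy algorithm: sequences are sorted by
#' length (descending, ties by id), and each sequence joins the first
#' representative to which its global alignment identity (matches
#' divided by the shorter length) reaches the threshold, otherwise it
#' becomes a new representative. A shared-k-mer prescreen skips
#' hopeless alignments; it is conservative for the identity range the
#' threshold permits.
#'
#' @param proteins An [Biostrings::AAStringSet] with unique names.
#' @param identityThreshold Identity threshold in (0.5, 1]; default 0.9.
#' @return A list with `representatives` (AAStringSet, original
#'   metadata retained) and `redundancy` (named list: representative id
#'   -> character vector of removed member ids).
#' @export
removeRedundant <- function(proteins, identityThreshold = 0.9) {
  stopifnot(identityThreshold > 0.5, identityThreshold <= 1)
  if (!length(proteins)) {
    return(list(representatives = proteins, redundancy = list()))
  }
  ids <- names(proteins)
  if (anyDuplicated(ids)) stop("protein ids must be unique", call. = FALSE)
  o <- order(-Biostrings::width(proteins), ids)
  seqs <- as.character(proteins)[o]
  ids <- ids[o]
  ## conservative lower bound on shared-4-mer containment at the threshold
  minShared <- max(0, 1 - 4 * (1 - identityThreshold)) * 0.5
  repIdx <- integer(0)
  repKmers <- list()
  assignment <- integer(length(ids))
  for (i in seq_along(ids)) {
    km <- .kmerSet(seqs[i])
    found <- 0L
    for (r in seq_along(repIdx)) {
      shared <- sum(km %in% repKmers[[r]]) / length(km)
      if (shared < minShared) next
      if (.globalIdentity(seqs[i], seqs[repIdx[r]]) >= identityThreshold) {
        found <- r
        break
      }
    }
    if (found) {
      assignment[i] <- found
    } else {
      repIdx <- c(repIdx, i)
      repKmers[[length(repKmers) + 1L]] <- km
      assignment[i] <- length(repIdx)
    }
  }
  repIds <- ids[repIdx]
  redundancy <- list()
  for (r in seq_along(repIdx)) {
    members <- ids[assignment == r & seq_along(ids) != repIdx[r]]
    if (length(members)) redundancy[[repIds[r]]] <- members
  }
  keep <- names(proteins) %in% repIds
  list(representatives = proteins[keep], redundancy = redundancy)
}
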