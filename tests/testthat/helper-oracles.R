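## Independent oracles, coded separately from the package internals.

## Brute-force dense MCL oracle. Uses the attractor interpretation
## (rows with positive diagonal mass define clusters; overlapping
## attractor systems are unioned), with explicit-loop matrix products —
## a different route than the package's component extraction.
mclOracle <- function(A, inflation = 2, loopWeight = 1,
                      maxIter = 100L, tol = 1e-6) {
  n <- nrow(A)
  ids <- rownames(A)
  if (is.null(ids)) ids <- paste0("n", seq_len(n))
  mx <- max(A)
  if (mx > 0) A <- A / mx  # loops sit on the edge-weight scale
  for (i in seq_len(n)) A[i, i] <- A[i, i] + loopWeight
  normalize <- function(M) {
    for (j in seq_len(n)) {
      s <- sum(M[, j])
      if (s > 0) M[, j] <- M[, j] / s
    }
    M
  }
  M <- normalize(A)
  for (iter in seq_len(maxIter)) {
    old <- M
    ## explicit-loop expansion
    E <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      E[i, j] <- sum(M[i, ] * M[, j])
    }
    E <- E^inflation
    E[E < 1e-12] <- 0
    M <- normalize(E)
    if (max(abs(M - old)) < tol) break
  }
  ## attractor-based clusters
  attractors <- which(diag(M) > 1e-5)
  memberOf <- lapply(attractors, function(a) which(M[a, ] > 1e-5))
  ## union attractor systems that share members
  groups <- list()
  for (m in memberOf) {
    hit <- which(vapply(groups, function(g) length(intersect(g, m)) > 0,
                        logical(1)))
    if (!length(hit)) {
      groups[[length(groups) + 1L]] <- m
    } else {
      merged <- sort(unique(c(unlist(groups[hit]), m)))
      groups <- groups[-hit]
      groups[[length(groups) + 1L]] <- merged
    }
  }
  ## any node left out (numerically orphaned) becomes a singleton
  left <- setdiff(seq_len(n), unlist(groups))
  for (v in left) groups[[length(groups) + 1L]] <- v
  parts <- lapply(groups, function(g) sort(ids[g]))
  parts[order(vapply(parts, `[`, character(1), 1L))]
}

## Canonical form of a partition for set comparison.
partitionKey <- function(parts) {
  sort(unname(vapply(parts, function(p) paste(sort(p), collapse = ","),
                     character(1))))
}

## Random symmetric weighted graph on n nodes (connected not enforced).
randomGraphMatrix <- function(n, pEdge = 0.4) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < pEdge) {
      w <- stats::runif(1, 0.5, 2)
      A[i, j] <- w
      A[j, i] <- w
    }
  }
  rownames(A) <- colnames(A) <- sprintf("v%02d", seq_len(n))
  A
}

## Independently coded hit-filter predicate (the three rejection rules).
hitKeptOracle <- function(coverage, bit_score, evalue,
                          minCoverage = 0.5, maxEvalue = 1.5e-8) {
  if (coverage < minCoverage) return(FALSE)
  if (!(bit_score > 0)) return(FALSE)
  if (evalue > maxEvalue) return(FALSE)
  TRUE
}
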