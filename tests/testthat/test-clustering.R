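test_that("greedy redundancy removal: identical pairs collapse, diverged sequences stay", {
  set.seed(23)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- paste(sample(aa, 120, replace = TRUE), collapse = "")
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(ch), k)
    ch[idx] <- vapply(ch[idx], function(a) sample(setdiff(aa, a), 1),
                      character(1))
    paste(ch, collapse = "")
  }
  ## two identical + one 95% identical -> one representative
  near <- mutate(base, 6L)   # 114/120 = 95%
  far1 <- mutate(base, 60L)  # ~50% identical, below 0.9 by construction
  far2 <- paste(sample(aa, 120, replace = TRUE), collapse = "")
  p <- Biostrings::AAStringSet(c(a = base, b = base, c = near,
                                 d = far1, e = far2))
  res <- removeRedundant(p, 0.9)
  expect_length(res$representatives, 3L)
  reps <- names(res$representatives)
  expect_true(all(c("d", "e") %in% reps))
  expect_setequal(unlist(res$redundancy, use.names = FALSE),
                  setdiff(c("a", "b", "c"), reps))
  ## removed ids appear under exactly one representative
  expect_false(anyDuplicated(unlist(res$redundancy)) > 0)
  expect_false(any(names(res$redundancy) %in%
                   unlist(res$redundancy, use.names = FALSE)))
  ## empty input
  e <- removeRedundant(Biostrings::AAStringSet(), 0.9)
  expect_length(e$representatives, 0L)
  expect_length(e$redundancy, 0L)
})

test_that("redundancy removal is idempotent on its representatives", {
  sm <- cpSmall()
  sub <- sm$proteins[1:30]
  r1 <- removeRedundant(sub, 0.9)
  r2 <- removeRedundant(r1$representatives, 0.9)
  expect_identical(names(r2$representatives), names(r1$representatives))
  expect_length(r2$redundancy, 0L)
})

test_that("similarity graph: self-identity at the cap, unrelated sequences unconnected", {
  set.seed(29)
  p1 <- cpRandomProteins(1L, len = 500L, seed = 29L, prefix = "x")
  ## exact long copy pair: reported E-value 0 -> edge at the weight cap
  pair <- c(p1, p1)
  names(pair) <- c("x1", "x1copy")
  g <- buildSimilarityGraph(pair)
  expect_equal(igraph::gsize(g), 1L)
  expect_equal(igraph::E(g)$weight, 200)
  ## two unrelated random sequences -> no edge at 1e-5
  pu <- cpRandomProteins(2L, len = 100L, seed = 31L, prefix = "u")
  gu <- buildSimilarityGraph(pu)
  expect_equal(igraph::gsize(gu), 0L)
  expect_equal(igraph::gorder(gu), 2L)
  ## single protein -> 1 node, 0 edges
  g1 <- buildSimilarityGraph(p1)
  expect_equal(igraph::gorder(g1), 1L)
  expect_equal(igraph::gsize(g1), 0L)
})

test_that("MCL separates disjoint cliques and the barbell graph", {
  clique <- function(ids) {
    A <- matrix(1, length(ids), length(ids))
    diag(A) <- 0
    rownames(A) <- colnames(A) <- ids
    A
  }
  ## two disjoint 4-cliques
  A <- matrix(0, 8, 8)
  rownames(A) <- colnames(A) <- paste0("n", 1:8)
  A[1:4, 1:4] <- clique(paste0("n", 1:4))
  A[5:8, 5:8] <- clique(paste0("n", 5:8))
  cl <- mclCluster(A)
  expect_length(cl, 2L)
  expect_setequal(vapply(cl, length, integer(1)), c(4L, 4L))
  ## singleton graph
  s <- matrix(0, 1, 1, dimnames = list("solo", "solo"))
  expect_identical(mclCluster(s), list("solo"))
  ## barbell: two 5-cliques joined by one unit edge, inflation 2
  B <- matrix(0, 10, 10)
  rownames(B) <- colnames(B) <- sprintf("b%02d", 1:10)
  B[1:5, 1:5] <- clique(sprintf("b%02d", 1:5))
  B[6:10, 6:10] <- clique(sprintf("b%02d", 6:10))
  B[5, 6] <- B[6, 5] <- 1
  clB <- mclCluster(B, inflation = 2)
  expect_length(clB, 2L)
  expect_identical(partitionKey(clB),
                   partitionKey(mclOracle(B, inflation = 2)))
})

test_that("MCL output is a partition, invariant to relabeling and weight scaling", {
  set.seed(37)
  ## planted two-block graphs: dense blocks, one weak bridge
  planted <- function(n1, n2) {
    n <- n1 + n2
    A <- matrix(0, n, n)
    A[1:n1, 1:n1] <- stats::runif(n1 * n1, 0.8, 1.2)
    A[(n1 + 1):n, (n1 + 1):n] <- stats::runif(n2 * n2, 0.8, 1.2)
    A <- pmax(A, t(A))
    diag(A) <- 0
    A[1, n1 + 1] <- A[n1 + 1, 1] <- 0.05
    rownames(A) <- colnames(A) <- sprintf("v%02d", seq_len(n))
    A
  }
  for (trial in 1:5) {
    A <- planted(sample(3:5, 1L), sample(3:5, 1L))
    cl <- mclCluster(A)
    ## partition: disjoint cover of all nodes
    all <- unlist(cl)
    expect_setequal(all, rownames(A))
    expect_false(anyDuplicated(all) > 0)
    ## uniform weight scaling changes nothing
    expect_identical(partitionKey(mclCluster(A * 3)), partitionKey(cl))
    ## node order must not matter (labels travel with the rows)
    perm <- sample(nrow(A))
    expect_identical(partitionKey(mclCluster(A[perm, perm])),
                     partitionKey(cl))
  }
  ## pure noise graphs still yield a partition
  for (trial in 1:5) {
    A <- randomGraphMatrix(7L)
    cl <- mclCluster(A)
    all <- unlist(cl)
    expect_setequal(all, rownames(A))
    expect_false(anyDuplicated(all) > 0)
  }
})

test_that("MCL matches the dense brute-force oracle on small random graphs", {
  set.seed(41)
  for (trial in 1:20) {
    n <- sample(3:8, 1L)
    A <- randomGraphMatrix(n)
    expect_identical(partitionKey(mclCluster(A)),
                     partitionKey(mclOracle(A)),
                     info = paste("trial", trial))
  }
})

test_that("non-symmetric MCL input is symmetrized with a warning", {
  A <- matrix(c(0, 1, 0, 0), 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  expect_warning(cl <- mclCluster(A), "symmetriz")
  expect_length(cl, 1L)
})

test_that("cluster size filtering keeps only model-worthy clusters", {
  mk <- function(id, n) new("ProteinCluster", clusterId = id,
                            familyLabel = "FamA",
                            memberIds = paste0(id, "_", seq_len(n)))
  cls <- list(mk("c1", 7L), mk("c2", 5L), mk("c3", 4L), mk("c4", 1L))
  kept <- suppressMessages(filterClusters(cls, 5L))
  expect_identical(vapply(kept, clusterId, character(1)), c("c1", "c2"))
  ## min 1 is the identity
  expect_length(filterClusters(cls, 1L), 4L)
  ## everything too small -> empty with a warning
  expect_warning(none <- suppressMessages(filterClusters(cls, 10L)),
                 "minimum size")
  expect_length(none, 0L)
})

test_that("per-family clustering recovers the ancestral protein families", {
  sm <- cpSmall()
  cl <- sm$clustering
  ## one cluster per ancestral protein family (2 families x 5)
  expect_length(cl$clusters, 10L)
  for (x in cl$clusters) {
    ## members of one cluster are copies of one ancestral protein
    tags <- unique(sub("^.*\\|", "", x@memberIds))
    expect_length(tags, 1L)
    fams <- unique(sub("_g\\d+\\|.*$", "", x@memberIds))
    expect_identical(fams, x@familyLabel)
  }
  ## clusters partition the representatives
  all <- unlist(lapply(cl$allClusters, memberIds))
  expect_setequal(all, names(cl$representatives))
  expect_false(anyDuplicated(all) > 0)
})
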