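test_that("consensus-coverage pruning removes short-overlap members", {
  sm <- cpSmall()
  cl <- sm$clustering$clusters[[1]]
  m <- sm$models[[clusterId(cl)]]
  ## every genuine member covers its own consensus fully
  kept <- suppressMessages(pruneByConsensusCoverage(cl, consensusSeq(m),
                                                    sm$proteins, 0.5))
  expect_identical(sort(memberIds(kept)), sort(memberIds(cl)))
  ## a member sharing only a short segment with the consensus is pruned:
  ## build a chimera carrying just the first 20 residues
  frag <- paste0(substr(consensusSeq(m), 1, 20),
                 as.character(cpRandomProteins(1L, len = 80L,
                                               seed = 59L)[[1]]))
  pool <- c(sm$proteins, Biostrings::AAStringSet(c(fragment = frag)))
  cl2 <- new("ProteinCluster", clusterId = clusterId(cl),
             familyLabel = familyLabel(cl),
             memberIds = c(memberIds(cl), "fragment"))
  pruned <- suppressMessages(pruneByConsensusCoverage(cl2, consensusSeq(m),
                                                      pool, 0.5))
  expect_false("fragment" %in% memberIds(pruned))
  expect_setequal(memberIds(pruned), memberIds(cl))
  ## threshold 0 is the identity
  expect_identical(memberIds(pruneByConsensusCoverage(cl2, consensusSeq(m),
                                                      pool, 0)),
                   memberIds(cl2))
  ## retiring below two members
  tiny <- new("ProteinCluster", clusterId = "tiny", familyLabel = "FamA",
              memberIds = c(memberIds(cl)[1], "fragment"))
  expect_null(suppressMessages(pruneByConsensusCoverage(
    tiny, as.character(cpRandomProteins(1L, len = 100L, seed = 61L)[[1]]),
    pool, 0.5)))
})

test_that("membership update follows the hit/assigned/redundancy rules", {
  m <- new("ProfileHMM", modelId = "m1", familyLabel = "FamA",
           memberIds = c("p1", "p2", "p3"), consensus = "MKVL",
           modelLength = 4L, hmmLines = "HMM")
  ## hits exactly equal members: fixpoint
  upd <- refineMembership(m, c("p1", "p2", "p3"), list(), c("p1", "p2", "p3"))
  expect_false(upd$changed)
  expect_setequal(upd$memberIds, c("p1", "p2", "p3"))
  ## a member that is no longer hit is removed
  upd2 <- refineMembership(m, c("p1", "p2"), list(), c("p1", "p2", "p3"))
  expect_true(upd2$changed)
  expect_setequal(upd2$memberIds, c("p1", "p2"))
  ## an unassigned hit target is added
  upd3 <- refineMembership(m, c("p1", "p2", "p3", "p9"), list(),
                           c("p1", "p2", "p3"))
  expect_setequal(upd3$memberIds, c("p1", "p2", "p3", "p9"))
  ## a redundancy-removed target is never added
  upd4 <- refineMembership(m, c("p1", "p2", "p3", "p9"),
                           list(p1 = "p9"), c("p1", "p2", "p3"))
  expect_setequal(upd4$memberIds, c("p1", "p2", "p3"))
  ## a target assigned to another model is not poached
  upd5 <- refineMembership(m, c("p1", "p2", "p3", "q1"), list(),
                           c("p1", "p2", "p3", "q1"))
  expect_setequal(upd5$memberIds, c("p1", "p2", "p3"))
})

test_that("models with identical hit-and-input sets merge; near-identical do not", {
  sm <- cpSmall()
  cl <- sm$clustering$clusters[[1]]
  msa <- alignCluster(cl, sm$proteins)
  ## two models from the same (duplicated) cluster
  mA <- buildHMM(msa, "dupA", familyLabel(cl))
  mB <- buildHMM(msa, "dupB", familyLabel(cl))
  hs <- list(dupA = memberIds(cl), dupB = memberIds(cl))
  merged <- suppressMessages(mergeEquivalentModels(
    list(dupA = mA, dupB = mB), hs, sm$proteins))
  expect_length(merged, 1L)
  expect_identical(modelId(merged[[1]]), "dupA")  # smallest id wins
  expect_setequal(memberIds(merged[[1]]), memberIds(cl))
  ## hit sets differing by one protein: no merge
  hs2 <- list(dupA = memberIds(cl), dupB = c(memberIds(cl), "extra"))
  merged2 <- mergeEquivalentModels(list(dupA = mA, dupB = mB), hs2,
                                   sm$proteins)
  expect_length(merged2, 2L)
  ## empty input is a no-op
  expect_length(mergeEquivalentModels(list(), list(), sm$proteins), 0L)
})

test_that("refinement reaches a self-consistent fixpoint", {
  sm <- cpSmall()
  state <- new("RefinementState", models = sm$models,
               redundancy = sm$clustering$redundancy,
               masterProteins = sm$proteins, round = 0L, changed = TRUE)
  final <- refineToFixpoint(state, maxRounds = 10L)
  expect_false(final@changed)
  expect_lte(final@round, 5L)
  ## at the fixpoint, membership == filtered hit targets minus
  ## redundancy-removed ids
  hits <- filterHits(scanProteins(final@masterProteins, final@models))
  removed <- unlist(final@redundancy, use.names = FALSE)
  for (m in final@models) {
    targets <- setdiff(hits$target_id[hits$model_id == modelId(m)],
                       removed)
    expect_setequal(memberIds(m), targets)
  }
  ## no protein belongs to two models
  all <- unlist(lapply(final@models, memberIds))
  expect_false(anyDuplicated(all) > 0)
  ## running again changes nothing further (stable after 1 round)
  again <- refineToFixpoint(final, maxRounds = 10L)
  expect_false(again@changed)
  expect_equal(again@round, final@round + 1L)
  expect_identical(lapply(again@models, memberIds),
                   lapply(final@models, memberIds))
  ## maxRounds = 0 returns the input with a warning
  expect_warning(zero <- refineToFixpoint(state, maxRounds = 0L),
                 "unchanged")
  expect_identical(lapply(zero@models, memberIds),
                   lapply(state@models, memberIds))
})

test_that("an unassigned protein that is hit becomes a member at the fixpoint", {
  sm <- cpSmall()
  models <- sm$models
  ## drop one member from one model's registry: it is unassigned now,
  ## still hit by the model, so refinement must reinstate it
  victim <- models[[1]]
  dropped <- memberIds(victim)[1]
  victim@memberIds <- memberIds(victim)[-1]
  models[[1]] <- victim
  state <- new("RefinementState", models = models,
               redundancy = sm$clustering$redundancy,
               masterProteins = sm$proteins, round = 0L, changed = TRUE)
  final <- refineToFixpoint(state, maxRounds = 10L)
  expect_false(final@changed)
  expect_true(dropped %in% memberIds(final@models[[modelId(victim)]]))
})

test_that("deleted CDS are recovered from intergenic regions at their coordinates", {
  sm <- cpSmall()
  fx <- sm$genomes[[3]]
  del <- deleteRandomCds(fx, k = 1L, seed = 67L, dir = tempdir())
  rec <- recoverMissingCds(list(del$genome), sm$models)
  expect_gte(nrow(rec$recovered), 1L)
  ## recovered span overlaps the deleted CDS on the same strand
  hit <- rec$recovered[1, ]
  expect_identical(hit$replicon_id, del$removed$replicon_id)
  expect_lt(max(hit$start, del$removed$start),
            min(hit$end, del$removed$end))
  expect_identical(hit$strand, del$removed$strand)
  ## every reported hit satisfies the cut-offs bit-exactly
  expect_true(all(rec$recovered$coverage >= 0.5))
  expect_true(all(rec$recovered$bit_score > 0))
  expect_true(all(rec$recovered$evalue <= 1.5e-8))
  ## a fully annotated genome yields nothing
  rec0 <- recoverMissingCds(list(fx$genome), sm$models)
  expect_equal(nrow(rec0$recovered), 0L)
})

test_that("integrating recovered CDS rebuilds a model with the same hit set", {
  sm <- cpSmall()
  fx <- sm$genomes[[5]]
  del <- deleteRandomCds(fx, k = 1L, seed = 71L, dir = tempdir())
  rec <- recoverMissingCds(list(del$genome), sm$models)
  expect_gte(nrow(rec$recovered), 1L)
  mid <- rec$recovered$model_id[1]
  m <- sm$models[[mid]]
  seqs <- rec$candidates[rec$recovered$candidate_id[
    rec$recovered$model_id == mid]]
  out <- integrateAndRebuild(m, seqs, sm$proteins)
  expect_identical(memberIds(out$model), memberIds(m))
  ## the rebuilt model still hits every previous member, and nothing new
  expect_true(all(out$report$in_before == out$report$in_after))
  expect_setequal(out$report$target_id[out$report$in_after],
                  out$report$target_id[out$report$in_before])
  ## zero recovered sequences: model returned untouched
  noop <- integrateAndRebuild(m, Biostrings::AAStringSet(), sm$proteins)
  expect_identical(noop$model@hmmLines, m@hmmLines)
  expect_equal(nrow(noop$report), 0L)
})
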