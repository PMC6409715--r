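## Profile HMM construction and scanning (MAFFT + HMMER3 behind a
## uniform contract).

#' Align a protein cluster
#'
#' Multiple alignment of all cluster members with MAFFT (deterministic
#' for a fixed input order). A singleton cluster yields a degenerate
#' one-row alignment.
#'
#' @param cluster A [ProteinCluster-class] (or a character vector of
#'   ids).
#' @param proteins The master [Biostrings::AAStringSet] the member ids
#'   index into.
#' @return An aligned [Biostrings::AAStringSet] (equal widths, gap
#'   symbol `-`), rows named by member id.
#' @export
alignCluster <- function(cluster, proteins) {
  ids <- if (is(cluster, "ProteinCluster")) cluster@memberIds else cluster
  missing <- setdiff(ids, names(proteins))
  if (length(missing)) {
    stop("cluster members absent from the protein set: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  seqs <- proteins[ids]
  if (length(seqs) < 2L) return(seqs)
  wd <- .tmpDir("mafft")
  on.exit(unlink(wd, recursive = TRUE))
  inFa <- file.path(wd, "in.faa")
  outFa <- file.path(wd, "out.faa")
  writeMultiFasta(seqs, inFa)
  .runTool("mafft", c("--quiet", "--amino", "--thread", "1", inFa),
           stdout = outFa)
  aln <- readMultiFasta(outFa)
  up <- AAStringSet(toupper(as.character(aln)))
  names(up) <- names(aln)
  up[ids]  # restore input order
}

#' Build a profile HMM from an alignment
#'
#' Runs `hmmbuild` with default construction and weighting, then
#' `hmmemit -c` for the majority-rule consensus sequence. The model's
#' HMMER3 flat text is kept inside the returned object.
#'
#' @param msa An aligned [Biostrings::AAStringSet] (as from
#'   [alignCluster()]).
#' @param modelId Model name.
#' @param familyLabel Phage family carried by the model.
#' @return A [ProfileHMM-class].
#' @export
buildHMM <- function(msa, modelId, familyLabel = NA_character_) {
  if (!length(msa)) stop("empty alignment", call. = FALSE)
  gapOnly <- all(grepl("^-*$", as.character(msa)))
  if (gapOnly) stop("alignment has no residues", call. = FALSE)
  wd <- .tmpDir("hmmbuild")
  on.exit(unlink(wd, recursive = TRUE))
  afa <- file.path(wd, "msa.afa")
  writeMultiFasta(msa, afa)
  hmm <- file.path(wd, "model.hmm")
  .runTool("hmmbuild", c("--amino", "-n", shQuote(modelId), hmm, afa))
  lines <- readLines(hmm)
  ## fix the free-text DATE stamp so rebuilds are byte-identical
  lines[startsWith(lines, "DATE")] <- "DATE  -"
  leng <- as.integer(sub("^LENG\\s+", "",
                         grep("^LENG", lines, value = TRUE)[1]))
  consFa <- file.path(wd, "cons.faa")
  .runTool("hmmemit", c("-c", "-o", consFa, hmm))
  cons <- as.character(readMultiFasta(consFa)[[1]])
  new("ProfileHMM", modelId = modelId, familyLabel = familyLabel,
      memberIds = names(msa), consensus = toupper(cons),
      modelLength = leng, hmmLines = lines)
}

#' Align and build models for a list of clusters
#'
#' @param clusters A list of [ProteinCluster-class] objects.
#' @param proteins The master [Biostrings::AAStringSet].
#' @return A list of [ProfileHMM-class] objects (named by model id;
#'   model ids equal cluster ids).
#' @export
buildFamilyModels <- function(clusters, proteins) {
  models <- lapply(clusters, function(cl) {
    buildHMM(alignCluster(cl, proteins), cl@clusterId, cl@familyLabel)
  })
  names(models) <- vapply(models, modelId, character(1))
  models
}

#' Write a model list as one HMMER3 library file
#'
#' @param models A list of [ProfileHMM-class] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHmmLibrary <- function(models, path) {
  writeLines(unlist(lapply(models, slot, "hmmLines")), path)
  invisible(path)
}

#' Persist / restore a model library with its member registry
#'
#' `saveModels()` writes one `.hmm` per model plus a `models.tsv`
#' registry (model id, family, consensus, members); `loadModels()`
#' restores the [ProfileHMM-class] list.
#'
#' @param models A list of [ProfileHMM-class] objects.
#' @param dir Directory to write into / read from.
#' @return `saveModels()`: `dir` invisibly; `loadModels()`: the model
#'   list.
#' @export
saveModels <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in models) {
    writeLines(m@hmmLines,
               file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_",
                                          m@modelId), ".hmm")))
  }
  reg <- data.frame(
    model_id = vapply(models, modelId, character(1)),
    family_label = vapply(models, familyLabel, character(1)),
    model_length = vapply(models, modelLength, integer(1)),
    consensus = vapply(models, consensusSeq, character(1)),
    members = vapply(models, function(m) paste(m@memberIds, collapse = ","),
                     character(1)),
    file = vapply(models, function(m) paste0(gsub("[^A-Za-z0-9._-]", "_",
                                                  m@modelId), ".hmm"),
                  character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(reg, file.path(dir, "models.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname saveModels
#' @export
loadModels <- function(dir) {
  reg <- utils::read.table(file.path(dir, "models.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(reg)), function(i) {
    new("ProfileHMM",
        modelId = reg$model_id[i], familyLabel = reg$family_label[i],
        memberIds = strsplit(reg$members[i], ",", fixed = TRUE)[[1]],
        consensus = reg$consensus[i],
        modelLength = as.integer(reg$model_length[i]),
        hmmLines = readLines(file.path(dir, reg$file[i])))
  })
  names(models) <- reg$model_id
  models
}

## Parse hmmsearch --domtblout (22 fixed columns + free-text description).
.parseDomTbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  cols <- c("target_id", "tacc", "tlen", "model_id", "qacc", "qlen",
            "seq_evalue", "seq_score", "seq_bias", "dom_n", "dom_of",
            "c_evalue", "i_evalue", "dom_score", "dom_bias",
            "hmm_from", "hmm_to", "ali_from", "ali_to",
            "env_from", "env_to", "acc")
  if (!length(lines)) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  mat <- t(vapply(toks, function(x) x[seq_along(cols)],
                  character(length(cols))))
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- cols
  num <- c("tlen", "qlen", "seq_evalue", "seq_score", "seq_bias",
           "dom_n", "dom_of", "c_evalue", "i_evalue", "dom_score",
           "dom_bias", "hmm_from", "hmm_to", "ali_from", "ali_to",
           "env_from", "env_to", "acc")
  out[num] <- lapply(out[num], as.numeric)
  out
}

#' Scan proteins with a model library
#'
#' Runs `hmmsearch --domtblout` of the whole library against the
#' protein set and returns typed hits. Per (model, target) pair only
#' the best-scoring domain is kept; its independent E-value and domain
#' bit score are reported. Model coverage is
#' `(hmm_to - hmm_from + 1) / model_length`; the normalized score is
#' the bit score divided by the consensus size — by default in base
#' pairs, i.e. `3 * model_length` (`normUnit = "aa"` divides by the
#' amino-acid length instead).
#'
#' @param proteins [Biostrings::AAStringSet] to scan (>= 1 sequence).
#' @param models A list of [ProfileHMM-class] objects (>= 1).
#' @param reportEvalue Reporting threshold passed to hmmsearch
#'   (default 10).
#' @param normUnit `"bp"` (default) or `"aa"`.
#' @return A data.frame with columns `model_id`, `family_label`,
#'   `target_id`, `evalue`, `bit_score`, `hmm_from`, `hmm_to`,
#'   `ali_from`, `ali_to`, `model_length`, `coverage`, `norm_score`.
#' @export
scanProteins <- function(proteins, models, reportEvalue = 10,
                         normUnit = c("bp", "aa")) {
  normUnit <- match.arg(normUnit)
  if (!length(models)) stop("empty model library", call. = FALSE)
  if (!length(proteins)) stop("no proteins to scan", call. = FALSE)
  wd <- .tmpDir("hmmsearch")
  on.exit(unlink(wd, recursive = TRUE))
  lib <- file.path(wd, "lib.hmm")
  writeHmmLibrary(models, lib)
  fa <- file.path(wd, "prot.faa")
  writeMultiFasta(proteins, fa)
  dom <- file.path(wd, "dom.txt")
  .runTool("hmmsearch", c("--noali", "--cpu", "1",
                          "-E", format(reportEvalue),
                          "--domE", format(reportEvalue),
                          "--domtblout", dom, lib, fa),
           stdout = FALSE)
  tab <- .parseDomTbl(dom)
  fam <- vapply(models, familyLabel, character(1))
  names(fam) <- vapply(models, modelId, character(1))
  if (!nrow(tab)) {
    return(data.frame(
      model_id = character(0), family_label = character(0),
      target_id = character(0), evalue = numeric(0),
      bit_score = numeric(0), hmm_from = numeric(0), hmm_to = numeric(0),
      ali_from = numeric(0), ali_to = numeric(0),
      model_length = numeric(0), coverage = numeric(0),
      norm_score = numeric(0), stringsAsFactors = FALSE
    ))
  }
  ## best-scoring domain per (model, target)
  key <- paste(tab$model_id, tab$target_id, sep = "\r")
  o <- order(key, -tab$dom_score, tab$i_evalue)
  tab <- tab[o, , drop = FALSE]
  tab <- tab[!duplicated(key[o]), , drop = FALSE]
  denom <- if (normUnit == "bp") 3 * tab$qlen else tab$qlen
  out <- data.frame(
    model_id = tab$model_id,
    family_label = unname(fam[tab$model_id]),
    target_id = tab$target_id,
    evalue = tab$i_evalue,
    bit_score = tab$dom_score,
    hmm_from = tab$hmm_from, hmm_to = tab$hmm_to,
    ali_from = tab$ali_from, ali_to = tab$ali_to,
    model_length = tab$qlen,
    coverage = (tab$hmm_to - tab$hmm_from + 1) / tab$qlen,
    norm_score = tab$dom_score / denom,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$model_id, out$evalue, out$target_id), , drop = FALSE]
}

#' Filter HMM hits at the refinement cut-offs
#'
#' Keeps hits that survive all three rejection rules: model coverage at
#' least `minCoverage`, a positive bit score, and an E-value no larger
#' than `maxEvalue`. Order is preserved; the operation is idempotent.
#'
#' @param hits A hit data.frame from [scanProteins()].
#' @param minCoverage Minimum model coverage (default 0.5).
#' @param maxEvalue Maximum E-value (default 1.5e-8).
#' @param requirePositiveBits Reject non-positive bit scores
#'   (default TRUE).
#' @return The filtered data.frame.
#' @export
filterHits <- function(hits, minCoverage = 0.5, maxEvalue = 1.5e-8,
                       requirePositiveBits = TRUE) {
  if (!nrow(hits)) return(hits)
  keep <- hits$coverage >= minCoverage & hits$evalue <= maxEvalue
  if (requirePositiveBits) keep <- keep & hits$bit_score > 0
  hits[keep, , drop = FALSE]
}
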