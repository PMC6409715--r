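#' @import methods
#' @importClassesFrom Biostrings DNAString AAStringSet
NULL

#' Replicon: one annotated nucleotide sequence
#'
#' A replicon is a single GenBank record: the nucleotide sequence, its
#' topology and the ordered CDS annotation. CDS features are held as a
#' [GenomicRanges::GRanges] (1-based closed coordinates) with metadata
#' columns `locus_tag`, `product`, `translation`.
#'
#' @slot id Replicon identifier (GenBank LOCUS name).
#' @slot sequence A [Biostrings::DNAString] with the full sequence.
#' @slot topology `"linear"` or `"circular"`.
#' @slot features A `GRanges` of CDS features, sorted by start.
#'
#' @exportClass Replicon
setClass("Replicon",
  representation(
    id = "character",
    sequence = "DNAString",
    topology = "character",
    features = "GRanges"
  )
)

setValidity("Replicon", function(object) {
  msgs <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msgs <- c(msgs, "id must be a non-empty string")
  if (!object@topology %in% c("linear", "circular"))
    msgs <- c(msgs, "topology must be 'linear' or 'circular'")
  ft <- object@features
  if (length(ft)) {
    if (any(GenomicRanges::start(ft) < 1L) ||
        any(GenomicRanges::end(ft) > length(object@sequence)))
      msgs <- c(msgs, "feature coordinates outside the sequence")
    if (is.unsorted(GenomicRanges::start(ft)))
      msgs <- c(msgs, "features must be sorted by start")
    if (!all(as.character(GenomicRanges::strand(ft)) %in% c("+", "-")))
      msgs <- c(msgs, "feature strand must be '+' or '-'")
  }
  if (length(msgs)) msgs else TRUE
})

#' GenBankGenome: one parsed GenBank file
#'
#' Possibly multi-replicon (e.g. a host genome with two chromosomes plus
#' plasmids). `metadata` holds what could be extracted from the header:
#' definition, organism, taxonomy, isolation source, total size.
#'
#' @slot genomeId Genome identifier (defaults to the file base name).
#' @slot replicons A list of [Replicon-class] objects.
#' @slot metadata A named list (definition, organism, source,
#'   isolation_source, genome_size_bp, family_label).
#'
#' @exportClass GenBankGenome
setClass("GenBankGenome",
  representation(
    genomeId = "character",
    replicons = "list",
    metadata = "list"
  )
)

setValidity("GenBankGenome", function(object) {
  if (!all(vapply(object@replicons, is, logical(1), "Replicon")))
    return("replicons must all be Replicon objects")
  sz <- object@metadata$genome_size_bp
  if (!is.null(sz) && sz <= 0) return("genome_size_bp must be > 0")
  TRUE
})

#' ProteinCluster: an MCL protein family, the seed of one HMM
#'
#' @slot clusterId Cluster identifier.
#' @slot familyLabel Phage family shared by the member genomes.
#' @slot memberIds Character vector of protein ids.
#'
#' @exportClass ProteinCluster
setClass("ProteinCluster",
  representation(
    clusterId = "character",
    familyLabel = "character",
    memberIds = "character"
  )
)

setValidity("ProteinCluster", function(object) {
  if (length(object@memberIds) < 1L) return("cluster needs >= 1 member")
  if (anyDuplicated(object@memberIds)) return("member ids must be distinct")
  TRUE
})

#' ProfileHMM: a built profile hidden Markov model
#'
#' Wraps one HMMER3 model: its ASCII text (kept in the object so that the
#' model is self-contained and byte-reproducible), the emitted consensus
#' sequence, the match-state count, and the registry of member proteins
#' the model was built from.
#'
#' @slot modelId Model name (equals the HMMER NAME field).
#' @slot familyLabel Phage family of the source cluster.
#' @slot memberIds Ids of the proteins in the underlying alignment.
#' @slot consensus Consensus amino-acid sequence (hmmemit -c).
#' @slot modelLength Number of match states; equals `nchar(consensus)`.
#' @slot hmmLines The HMMER3 flat text of the model.
#'
#' @exportClass ProfileHMM
setClass("ProfileHMM",
  representation(
    modelId = "character",
    familyLabel = "character",
    memberIds = "character",
    consensus = "character",
    modelLength = "integer",
    hmmLines = "character"
  )
)

setValidity("ProfileHMM", function(object) {
  if (object@modelLength != nchar(object@consensus))
    return("modelLength must equal nchar(consensus)")
  if (!length(object@hmmLines)) return("empty model text")
  TRUE
})

#' RefinementState: the mutable state of the scan-update-merge loop
#'
#' @slot models List of [ProfileHMM-class] objects.
#' @slot redundancy Named list: representative id -> removed member ids.
#' @slot masterProteins The master protein set
#'   ([Biostrings::AAStringSet] with metadata columns).
#' @slot round Rounds executed so far.
#' @slot changed Whether the last round changed anything.
#'
#' @exportClass RefinementState
setClass("RefinementState",
  representation(
    models = "list",
    redundancy = "list",
    masterProteins = "AAStringSet",
    round = "integer",
    changed = "logical"
  )
)

setValidity("RefinementState", function(object) {
  ok <- vapply(object@models, is, logical(1), "ProfileHMM")
  if (!all(ok)) return("models must all be ProfileHMM objects")
  mem <- unlist(lapply(object@models, slot, "memberIds"), use.names = FALSE)
  if (!all(mem %in% names(object@masterProteins)))
    return("model members must be drawn from the master protein set")
  TRUE
})
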