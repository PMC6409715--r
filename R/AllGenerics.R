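#' Accessors for ClassiPhage classes
#'
#' Small read-only accessors for the S4 containers; slots are never meant
#' to be touched directly.
#'
#' @param object A ClassiPhage S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("repliconId", function(object) standardGeneric("repliconId"))
#' @rdname accessors
#' @export
setGeneric("topology", function(object) standardGeneric("topology"))
#' @rdname accessors
#' @export
setGeneric("features", function(object) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("genomeId", function(object) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("replicons", function(object) standardGeneric("replicons"))
#' @rdname accessors
#' @export
setGeneric("genomeMetadata", function(object) standardGeneric("genomeMetadata"))
#' @rdname accessors
#' @export
setGeneric("clusterId", function(object) standardGeneric("clusterId"))
#' @rdname accessors
#' @export
setGeneric("familyLabel", function(object) standardGeneric("familyLabel"))
#' @rdname accessors
#' @export
setGeneric("memberIds", function(object) standardGeneric("memberIds"))
#' @rdname accessors
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setGeneric("consensusSeq", function(object) standardGeneric("consensusSeq"))
#' @rdname accessors
#' @export
setGeneric("modelLength", function(object) standardGeneric("modelLength"))

#' @rdname accessors
#' @export
setMethod("repliconId", "Replicon", function(object) object@id)
#' @rdname accessors
#' @export
setMethod("topology", "Replicon", function(object) object@topology)
#' @rdname accessors
#' @export
setMethod("features", "Replicon", function(object) object@features)
#' @rdname accessors
#' @export
setMethod("genomeId", "GenBankGenome", function(object) object@genomeId)
#' @rdname accessors
#' @export
setMethod("replicons", "GenBankGenome", function(object) object@replicons)
#' @rdname accessors
#' @export
setMethod("genomeMetadata", "GenBankGenome", function(object) object@metadata)
#' @rdname accessors
#' @export
setMethod("clusterId", "ProteinCluster", function(object) object@clusterId)
#' @rdname accessors
#' @export
setMethod("familyLabel", "ProteinCluster", function(object) object@familyLabel)
#' @rdname accessors
#' @export
setMethod("familyLabel", "ProfileHMM", function(object) object@familyLabel)
#' @rdname accessors
#' @export
setMethod("memberIds", "ProteinCluster", function(object) object@memberIds)
#' @rdname accessors
#' @export
setMethod("memberIds", "ProfileHMM", function(object) object@memberIds)
#' @rdname accessors
#' @export
setMethod("modelId", "ProfileHMM", function(object) object@modelId)
#' @rdname accessors
#' @export
setMethod("consensusSeq", "ProfileHMM", function(object) object@consensus)
#' @rdname accessors
#' @export
setMethod("modelLength", "ProfileHMM", function(object) object@modelLength)

setMethod("show", "Replicon", function(object) {
  cat("Replicon", object@id, "|", length(object@sequence), "bp,",
      object@topology, "|", length(object@features), "CDS\n")
})

setMethod("show", "GenBankGenome", function(object) {
  cat("GenBankGenome", object@genomeId, "|", length(object@replicons),
      "replicon(s),", sum(vapply(object@replicons,
        function(r) length(r@features), integer(1))), "CDS\n")
})

setMethod("show", "ProteinCluster", function(object) {
  cat("ProteinCluster", object@clusterId, "[", object@familyLabel, "]",
      length(object@memberIds), "members\n")
})

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM", object@modelId, "[", object@familyLabel, "] length",
      object@modelLength, ",", length(object@memberIds), "members\n")
})

setMethod("show", "RefinementState", function(object) {
  cat("RefinementState:", length(object@models), "models, round",
      object@round, if (object@changed) "(changed)" else "(stable)", "\n")
})
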