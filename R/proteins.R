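## CDS protein extraction, intergenic regions, six-frame translation.

#' @importFrom Biostrings AAStringSet width
#' @importFrom IRanges IRanges reduce gaps
NULL

#' Extract CDS proteins from a genome
#'
#' One protein record per annotated CDS. Ids are globally unique
#' (`genome|replicon|locus_tag`); duplicate locus tags are disambiguated
#' with an ordinal suffix. Trailing stop symbols are stripped and the
#' sequence restricted to the 20-letter alphabet plus X.
#'
#' @param genome A [GenBankGenome-class] (or a list of
#'   [Replicon-class] objects).
#' @param genomeId Genome id used in protein ids; defaults to the
#'   genome's own id.
#' @param familyLabel Optional phage family label attached to every
#'   record (overrides the genome metadata label).
#' @return An [Biostrings::AAStringSet]; `names()` are the protein ids
#'   and `mcols()` carries `source_genome`, `family_label`,
#'   `replicon_id`, `start`, `end`, `strand`, `product`.
#' @export
extractCdsProteins <- function(genome, genomeId = NULL, familyLabel = NULL) {
  if (is(genome, "GenBankGenome")) {
    reps <- genome@replicons
    if (is.null(genomeId)) genomeId <- genome@genomeId
    if (is.null(familyLabel)) familyLabel <- genome@metadata$family_label
  } else {
    reps <- genome
    if (is.null(genomeId)) stop("genomeId required for a replicon list")
  }
  if (is.null(familyLabel)) familyLabel <- NA_character_

  rows <- list()
  for (rep in reps) {
    ft <- rep@features
    if (!length(ft)) next
    tags <- mcols(ft)$locus_tag
    dup <- tags %in% tags[duplicated(tags)]
    if (any(dup)) {
      for (tg in unique(tags[dup])) {
        idx <- which(tags == tg)
        tags[idx] <- paste0(tg, "_", seq_along(idx))
      }
      .msg("duplicate locus_tags on ", rep@id, " disambiguated")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = paste(genomeId, rep@id, tags, sep = "|"),
      sequence = .cleanProtein(mcols(ft)$translation),
      source_genome = genomeId,
      family_label = familyLabel,
      replicon_id = rep@id,
      start = GenomicRanges::start(ft),
      end = GenomicRanges::end(ft),
      strand = as.character(GenomicRanges::strand(ft)),
      product = mcols(ft)$product,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    aa <- AAStringSet()
    mcols(aa) <- S4Vectors::DataFrame(
      source_genome = character(0), family_label = character(0),
      replicon_id = character(0), start = integer(0), end = integer(0),
      strand = character(0), product = character(0)
    )
    return(aa)
  }
  tab <- do.call(rbind, rows)
  keep <- nzchar(tab$sequence)
  tab <- tab[keep, , drop = FALSE]
  aa <- AAStringSet(tab$sequence)
  names(aa) <- tab$id
  mcols(aa) <- S4Vectors::DataFrame(tab[, setdiff(colnames(tab),
                                                  c("id", "sequence"))])
  aa
}

#' Combine protein sets
#'
#' Concatenates AAStringSets produced by [extractCdsProteins()] while
#' keeping their metadata columns, checking id uniqueness.
#'
#' @param ... AAStringSet objects (or a single list of them).
#' @return A single AAStringSet.
#' @export
combineProteins <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "AAStringSet")) {
    sets <- sets[[1]]
  }
  sets <- sets[vapply(sets, length, integer(1)) > 0L]
  if (!length(sets)) return(AAStringSet())
  out <- do.call(c, unname(sets))
  mcols(out) <- S4Vectors::DataFrame(
    do.call(rbind, lapply(sets, function(x) as.data.frame(mcols(x))))
  )
  if (anyDuplicated(names(out))) {
    stop("duplicate protein ids across combined sets", call. = FALSE)
  }
  out
}

#' Extract intergenic regions of a replicon
#'
#' Maximal gaps between consecutive CDS spans, including the 5'/3'
#' flanks; on a circular replicon the two terminal flanks are merged
#' into one wrap-around region. Regions shorter than `minLenNt` are
#' dropped. Coordinates are 1-based closed; a wrap-around region has
#' `wrap = TRUE` and `start > end` (it runs through the origin).
#'
#' @param replicon A [Replicon-class].
#' @param minLenNt Minimum region length in nucleotides (default 90,
#'   i.e. at least 30 codons).
#' @return A data.frame with `replicon_id`, `start`, `end`, `wrap`,
#'   `length`, `sequence`.
#' @export
extractIntergenicRegions <- function(replicon, minLenNt = 90L) {
  stopifnot(minLenNt >= 1L)
  L <- length(replicon@sequence)
  ft <- replicon@features
  seqChars <- as.character(replicon@sequence)
  emptyOut <- data.frame(
    replicon_id = character(0), start = integer(0), end = integer(0),
    wrap = logical(0), length = integer(0), sequence = character(0),
    stringsAsFactors = FALSE
  )
  if (!length(ft)) {
    if (L < minLenNt) return(emptyOut)
    return(data.frame(
      replicon_id = replicon@id, start = 1L, end = L, wrap = FALSE,
      length = L, sequence = seqChars, stringsAsFactors = FALSE
    ))
  }
  cds <- reduce(IRanges(GenomicRanges::start(ft), GenomicRanges::end(ft)))
  gapsIR <- gaps(cds, start = 1L, end = L)
  gs <- IRanges::start(gapsIR)
  ge <- IRanges::end(gapsIR)
  wrap <- rep(FALSE, length(gs))
  if (replicon@topology == "circular" && length(gs) >= 1L) {
    firstFlank <- length(gs) && gs[1] == 1L && IRanges::start(cds)[1] > 1L
    lastFlank <- length(gs) && ge[length(ge)] == L &&
      IRanges::end(cds)[length(cds)] < L
    if (firstFlank && lastFlank && length(gs) >= 2L) {
      ## merge terminal flanks into one origin-spanning region
      ws <- gs[length(gs)]
      we <- ge[1]
      gs <- gs[-c(1L, length(gs))]
      ge <- ge[-c(1L, length(ge))]
      wrap <- rep(FALSE, length(gs))
      gs <- c(gs, ws); ge <- c(ge, we); wrap <- c(wrap, TRUE)
    }
  }
  if (!length(gs)) return(emptyOut)
  len <- ifelse(wrap, (L - gs + 1L) + ge, ge - gs + 1L)
  seqs <- vapply(seq_along(gs), function(i) {
    if (wrap[i]) {
      paste0(substr(seqChars, gs[i], L), substr(seqChars, 1L, ge[i]))
    } else {
      substr(seqChars, gs[i], ge[i])
    }
  }, character(1))
  keep <- len >= minLenNt
  data.frame(
    replicon_id = replicon@id, start = as.integer(gs[keep]),
    end = as.integer(ge[keep]), wrap = wrap[keep],
    length = as.integer(len[keep]), sequence = seqs[keep],
    stringsAsFactors = FALSE
  )[order(gs[keep]), , drop = FALSE]
}

#' Six-frame translation of a nucleotide region
#'
#' Translates all six reading frames (table 11) and emits every maximal
#' stop-free stretch of at least `minOrfAa` residues as a candidate
#' protein, with coordinates mapped back to the genomic strand and span.
#'
#' @param region One row of [extractIntergenicRegions()] output, or a
#'   list/data.frame with `sequence`, `replicon_id`, `start` (genomic
#'   position of the region's first base; default 1).
#' @param minOrfAa Minimum candidate length in amino acids (default 30).
#' @param idPrefix Prefix for candidate ids.
#' @return An [Biostrings::AAStringSet] with `mcols()` columns
#'   `replicon_id`, `start`, `end`, `strand`, `frame`.
#' @export
sixFrameTranslate <- function(region, minOrfAa = 30L, idPrefix = NULL) {
  stopifnot(minOrfAa >= 1L)
  seqChars <- toupper(region$sequence[1])
  repId <- if (!is.null(region$replicon_id)) region$replicon_id[1] else "region"
  gStart <- if (!is.null(region$start)) as.integer(region$start[1]) else 1L
  if (is.null(idPrefix)) idPrefix <- paste0(repId, ":", gStart)
  n <- nchar(seqChars)
  empty <- {
    aa <- AAStringSet()
    mcols(aa) <- S4Vectors::DataFrame(
      replicon_id = character(0), start = integer(0), end = integer(0),
      strand = character(0), frame = integer(0)
    )
    aa
  }
  if (n < 3L * minOrfAa) return(empty)

  dna <- DNAString(seqChars)
  rc <- as.character(reverseComplement(dna))
  code <- getGeneticCode("11")

  out <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") seqChars else rc
    for (f in 0:2) {
      usable <- ((n - f) %/% 3L) * 3L
      if (usable < 3L) next
      aa <- as.character(suppressWarnings(translate(
        DNAString(substr(src, f + 1L, f + usable)),
        genetic.code = code, if.fuzzy.codon = "X"
      )))
      segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
      pos <- 1L  # 1-based aa position within the frame
      for (sg in segs) {
        ln <- nchar(sg)
        if (ln >= minOrfAa) {
          ## aa positions pos..pos+ln-1 within this frame
          ntFrom <- f + 3L * (pos - 1L) + 1L  # within src
          ntTo <- f + 3L * (pos + ln - 1L)
          if (strand == "+") {
            gs <- gStart + ntFrom - 1L
            gePos <- gStart + ntTo - 1L
          } else {
            gs <- gStart + (n - ntTo)
            gePos <- gStart + (n - ntFrom)
          }
          out[[length(out) + 1L]] <- list(
            seq = sg, replicon_id = repId, start = gs, end = gePos,
            strand = strand, frame = f
          )
        }
        pos <- pos + ln + 1L
      }
    }
  }
  if (!length(out)) return(empty)
  aa <- AAStringSet(vapply(out, `[[`, character(1), "seq"))
  names(aa) <- sprintf("%s|orf%02d", idPrefix, seq_along(out))
  mcols(aa) <- S4Vectors::DataFrame(
    replicon_id = vapply(out, `[[`, character(1), "replicon_id"),
    start = vapply(out, function(x) as.integer(x$start), integer(1)),
    end = vapply(out, function(x) as.integer(x$end), integer(1)),
    strand = vapply(out, `[[`, character(1), "strand"),
    frame = vapply(out, function(x) as.integer(x$frame), integer(1))
  )
  aa
}
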