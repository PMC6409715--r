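## GenBank flat-file reading and writing.
##
## A deliberately small parser covering the subset of the format the
## pipeline consumes: LOCUS/DEFINITION/SOURCE headers, the FEATURES table
## (source + CDS keys, with join/complement locations and multi-line
## qualifiers) and the ORIGIN sequence block. Multi-record files (hosts
## with several replicons) are supported.

#' @importFrom Biostrings DNAString DNAStringSet AAString reverseComplement
#'   translate getGeneticCode subseq
#' @importFrom GenomicRanges GRanges start end strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

## --- location strings ------------------------------------------------------

## Parse a (possibly join/complement) location into strand + span matrix.
.parseLocation <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  strand <- if (grepl("complement", loc, fixed = TRUE)) "-" else "+"
  loc <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  spans <- t(vapply(parts, function(p) {
    nums <- as.integer(strsplit(p, "\\.\\.|\\^")[[1]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    nums[1:2]
  }, integer(2)))
  dimnames(spans) <- NULL
  list(strand = strand, spans = spans)
}

## Translate a CDS span set with the bacterial/phage code (table 11).
.translateSpans <- function(seq, spans, strand) {
  pieces <- lapply(seq_len(nrow(spans)), function(i) {
    subseq(seq, spans[i, 1], spans[i, 2])
  })
  nt <- do.call(Biostrings::xscat, pieces)
  if (strand == "-") nt <- reverseComplement(nt)
  nt <- subseq(nt, 1, 3L * (length(nt) %/% 3L))
  if (length(nt) == 0L) return("")
  aa <- as.character(suppressWarnings(
    translate(nt, genetic.code = getGeneticCode("11"), if.fuzzy.codon = "X")
  ))
  sub("\\*$", "", aa)
}

## --- record parsing ---------------------------------------------------------

.parseQualifiers <- function(lines) {
  txt <- sub("^ {21}", "", lines)
  starts <- grep("^/[A-Za-z_]+=?", txt)
  quals <- list()
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1] - 1L else length(txt)
    joined <- paste(txt[from:to], collapse = "")
    m <- regmatches(joined, regexec("^/([A-Za-z_]+)=?(.*)$", joined))[[1]]
    val <- gsub("^\"|\"$", "", m[3])
    quals[[m[2]]] <- val
  }
  quals
}

.parseRecord <- function(lines, firstLine) {
  locusIdx <- grep("^LOCUS", lines)
  if (!length(locusIdx)) {
    stop("GenBank format error near line ", firstLine,
         ": record without LOCUS line", call. = FALSE)
  }
  toks <- strsplit(lines[locusIdx[1]], "[[:space:]]+")[[1]]
  id <- toks[2]
  topo <- if (any(tolower(toks) == "circular")) "circular" else "linear"

  defIdx <- grep("^DEFINITION", lines)
  definition <- if (length(defIdx)) {
    sub("^DEFINITION\\s+", "", lines[defIdx[1]])
  } else NA_character_
  orgIdx <- grep("^\\s{0,4}ORGANISM", lines)
  organism <- if (length(orgIdx)) {
    sub("^\\s*ORGANISM\\s+", "", lines[orgIdx[1]])
  } else NA_character_

  originIdx <- grep("^ORIGIN", lines)
  if (!length(originIdx)) {
    stop("GenBank format error near line ", firstLine + locusIdx[1] - 1L,
         ": record without ORIGIN block", call. = FALSE)
  }
  seqLines <- lines[(originIdx[1] + 1L):length(lines)]
  seqChars <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  dna <- DNAString(seqChars)

  featIdx <- grep("^FEATURES", lines)
  featList <- list()
  isolation <- NA_character_
  if (length(featIdx)) {
    block <- lines[(featIdx[1] + 1L):(originIdx[1] - 1L)]
    keyAt <- grep("^ {5}\\S", block)
    for (k in seq_along(keyAt)) {
      from <- keyAt[k]
      to <- if (k < length(keyAt)) keyAt[k + 1] - 1L else length(block)
      sub <- block[from:to]
      key <- sub("^ {5}(\\S+).*$", "\\1", sub[1])
      ## location may wrap before the first qualifier line
      qualAt <- grep("^ {21}/", sub)
      locEnd <- if (length(qualAt)) qualAt[1] - 1L else length(sub)
      loc <- paste(c(sub("^ {5}\\S+\\s*", "", sub[1]),
                     trimws(sub(" {21}", "", sub[seq_len(locEnd)[-1]]))),
                   collapse = "")
      quals <- if (length(qualAt)) {
        .parseQualifiers(sub[qualAt[1]:length(sub)])
      } else list()
      if (key == "source") {
        if (!is.null(quals$isolation_source)) isolation <- quals$isolation_source
        if (is.na(organism) && !is.null(quals$organism)) organism <- quals$organism
      } else if (key == "CDS") {
        featList[[length(featList) + 1L]] <- list(loc = loc, quals = quals)
      }
    }
  }

  if (!length(featList)) {
    warning("replicon ", id, " has no CDS features", call. = FALSE)
    gr <- GRanges(seqnames = character(0), ranges = IRanges())
    mcols(gr) <- S4Vectors::DataFrame(
      locus_tag = character(0), product = character(0),
      translation = character(0)
    )
  } else {
    rows <- lapply(seq_along(featList), function(i) {
      f <- featList[[i]]
      pl <- .parseLocation(f$loc)
      tr <- f$quals$translation
      if (is.null(tr) || !nzchar(tr)) {
        tr <- .translateSpans(dna, pl$spans, pl$strand)
      }
      lt <- f$quals$locus_tag
      if (is.null(lt)) lt <- f$quals$gene
      if (is.null(lt)) lt <- sprintf("cds%03d", i)
      pr <- f$quals$product
      if (is.null(pr)) pr <- "hypothetical protein"
      list(start = min(pl$spans), end = max(pl$spans),
           strand = pl$strand, locus_tag = lt, product = pr,
           translation = .cleanProtein(tr))
    })
    o <- order(vapply(rows, `[[`, numeric(1), "start"))
    rows <- rows[o]
    gr <- GRanges(
      seqnames = id,
      ranges = IRanges(
        start = vapply(rows, `[[`, numeric(1), "start"),
        end = vapply(rows, `[[`, numeric(1), "end")
      ),
      strand = vapply(rows, `[[`, character(1), "strand")
    )
    mcols(gr)$locus_tag <- vapply(rows, `[[`, character(1), "locus_tag")
    mcols(gr)$product <- vapply(rows, `[[`, character(1), "product")
    mcols(gr)$translation <- vapply(rows, `[[`, character(1), "translation")
  }

  list(
    replicon = new("Replicon", id = id, sequence = dna,
                   topology = topo, features = gr),
    definition = definition, organism = organism,
    isolation_source = isolation
  )
}

#' Read a GenBank flat file
#'
#' Parses one (possibly multi-record) GenBank flat file into a
#' [GenBankGenome-class]: one [Replicon-class] per record, CDS features
#' sorted by start. A CDS carrying a `/translation` qualifier uses it
#' verbatim (sanitized to the 20-letter alphabet plus X, stop symbols
#' stripped); a CDS without one is translated from its span with the
#' bacterial/phage genetic code (table 11).
#'
#' @param path Path to a GenBank flat file.
#' @param genomeId Genome identifier; defaults to the file base name.
#' @param familyLabel Optional phage family label to attach.
#' @return A [GenBankGenome-class] object.
#' @examples
#' gbk <- evolveGenome(generateFamilies(2, 3, seed = 1)[[1]], "g1", seed = 1,
#'                     dir = tempdir())
#' readGenBank(gbk$path)
#' @export
readGenBank <- function(path, genomeId = NULL, familyLabel = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines))) {
    stop("GenBank format error in '", path,
         "' near line 1: no LOCUS line found", call. = FALSE)
  }
  if (is.null(genomeId)) {
    genomeId <- tools::file_path_sans_ext(basename(path))
  }
  ends <- grep("^//\\s*$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  recs <- list()
  for (i in seq_along(ends)) {
    chunk <- lines[starts[i]:ends[i]]
    if (!any(nzchar(trimws(chunk)))) next
    recs[[length(recs) + 1L]] <- .parseRecord(chunk, starts[i])
  }
  reps <- lapply(recs, `[[`, "replicon")
  sizes <- sum(vapply(reps, function(r) length(r@sequence), integer(1)))
  meta <- list(
    definition = recs[[1]]$definition,
    organism = recs[[1]]$organism,
    isolation_source = recs[[1]]$isolation_source,
    genome_size_bp = sizes,
    family_label = familyLabel
  )
  new("GenBankGenome", genomeId = genomeId, replicons = reps, metadata = meta)
}

## --- writing ---------------------------------------------------------------

.wrapQualifier <- function(name, value, quote = TRUE, width = 58L) {
  val <- if (quote) paste0("\"", value, "\"") else value
  first <- paste0("/", name, "=", val)
  out <- character(0)
  while (nchar(first) > width) {
    out <- c(out, substr(first, 1, width))
    first <- substr(first, width + 1L, nchar(first))
  }
  out <- c(out, first)
  paste0(strrep(" ", 21), out)
}

.formatOrigin <- function(seqChars) {
  n <- nchar(seqChars)
  starts <- seq(1L, n, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(seqChars, s, min(s + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    sprintf("%9d %s", s, paste(tolower(tens), collapse = " "))
  }, character(1))
}

#' Write a GenBankGenome back to a GenBank flat file
#'
#' Emits the minimal well-formed subset of the format the package's own
#' parser reads (LOCUS/DEFINITION, source + CDS features with
#' `/locus_tag`, `/product` and `/translation`, ORIGIN). Used by the
#' synthetic fixture generator.
#'
#' @param genome A [GenBankGenome-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rep in genome@replicons) {
    L <- length(rep@sequence)
    writeLines(sprintf("LOCUS       %-17s %9d bp    DNA     %-8s PHG 01-JAN-2000",
                       rep@id, L, rep@topology), con)
    def <- genome@metadata$definition
    if (is.null(def) || is.na(def)) def <- paste(genome@genomeId, rep@id)
    writeLines(paste("DEFINITION ", def), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", L), con)
    org <- genome@metadata$organism
    if (!is.null(org) && !is.na(org)) {
      writeLines(.wrapQualifier("organism", org), con)
    }
    iso <- genome@metadata$isolation_source
    if (!is.null(iso) && !is.na(iso)) {
      writeLines(.wrapQualifier("isolation_source", iso), con)
    }
    ft <- rep@features
    for (i in seq_along(ft)) {
      loc <- sprintf("%d..%d", GenomicRanges::start(ft)[i],
                     GenomicRanges::end(ft)[i])
      if (as.character(GenomicRanges::strand(ft))[i] == "-") {
        loc <- sprintf("complement(%s)", loc)
      }
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(.wrapQualifier("locus_tag", mcols(ft)$locus_tag[i]), con)
      writeLines(.wrapQualifier("product", mcols(ft)$product[i]), con)
      writeLines(.wrapQualifier("translation", mcols(ft)$translation[i]), con)
    }
    writeLines("ORIGIN", con)
    writeLines(.formatOrigin(as.character(rep@sequence)), con)
    writeLines("//", con)
  }
  invisible(path)
}
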