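## Tabular / FASTA / GFF3 output plumbing.

#' Write protein or nucleotide records as multi-FASTA
#'
#' @param records An `XStringSet` (ids in `names()`).
#' @param path Output path.
#' @param description Optional character vector of description lines
#'   appended after each id.
#' @return `path`, invisibly.
#' @export
writeMultiFasta <- function(records, path, description = NULL) {
  if (!is.null(description)) {
    names(records) <- paste(names(records), description)
  }
  tryCatch(
    Biostrings::writeXStringSet(records, filepath = path),
    error = function(e) stop("cannot write '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Read a multi-FASTA of proteins
#'
#' @param path Path to a FASTA file.
#' @return An [Biostrings::AAStringSet] (full header retained in names
#'   up to the first whitespace; descriptions dropped).
#' @export
readMultiFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  aa
}

#' Write an HMM hit table as TSV
#'
#' Columns mirror `hmmsearch --domtblout` semantics plus the derived
#' `coverage` and `norm_score`.
#'
#' @param hits A hit data.frame as returned by [scanProteins()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHitsTsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write prophage loci as GFF3
#'
#' One `prophage_locus` feature per locus; the family call, the number
#' of consecutive supporting hits and the mean normalized score go into
#' the attributes column. Coordinates are written 1-based inclusive.
#'
#' @param loci A locus data.frame as returned by [callLoci()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLociGff <- function(loci, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "'",
                                           call. = FALSE))
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(loci))) {
    attrs <- sprintf(
      "ID=locus%03d;family_call=%s;n_consecutive=%d;mean_norm_score=%.4f",
      i, loci$family_call[i], loci$n_consecutive[i], loci$mean_norm_score[i]
    )
    writeLines(paste(
      loci$replicon_id[i], "ClassiPhage", "prophage_locus",
      loci$start[i], loci$end[i], ".",
      if (!is.null(loci$strand)) loci$strand[i] else ".",
      ".", attrs, sep = "\t"
    ), con)
  }
  invisible(path)
}
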