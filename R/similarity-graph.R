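## All-vs-all protein similarity graph (BLASTP) feeding MCL.

#' @importFrom igraph graph_from_data_frame make_empty_graph vertices
#'   as_adjacency_matrix V components
NULL

## Run blastp all-vs-all on an AAStringSet; returns the raw pair table.
.blastAllVsAll <- function(proteins, evalueCutoff) {
  wd <- .tmpDir("blast")
  on.exit(unlink(wd, recursive = TRUE))
  fa <- file.path(wd, "prot.faa")
  writeMultiFasta(proteins, fa)
  db <- file.path(wd, "db")
  .runTool("makeblastdb", c("-in", fa, "-dbtype", "prot", "-out", db))
  out <- file.path(wd, "hits.tsv")
  .runTool("blastp", c("-query", fa, "-db", db,
                       "-outfmt", shQuote("6 qseqid sseqid evalue bitscore"),
                       "-evalue", format(evalueCutoff, scientific = TRUE),
                       "-max_target_seqs", "100000",
                       "-num_threads", "1", "-out", out))
  if (!file.size(out)) {
    return(data.frame(q = character(0), s = character(0),
                      evalue = numeric(0), bits = numeric(0)))
  }
  tab <- utils::read.table(out, sep = "\t", stringsAsFactors = FALSE)
  names(tab) <- c("q", "s", "evalue", "bits")
  tab
}

#' Build an all-vs-all protein similarity graph
#'
#' Every protein is aligned against every other with BLASTP; pairs with
#' E-value at or below the cutoff become undirected edges. The default
#' edge weight is `-log10(E)` capped at `cap` (identical pairs report
#' E = 0); bit score is available as an alternative. The two directions
#' of a pair are symmetrized by the maximum.
#'
#' @param proteins An [Biostrings::AAStringSet] (>= 1 sequence, unique
#'   names).
#' @param evalueCutoff Keep pairs with E-value <= this (default 1e-5).
#' @param weight `"log_evalue"` (default) or `"bitscore"`.
#' @param cap Weight cap for the `-log10(E)` scale (default 200).
#' @return An undirected weighted [igraph::igraph] whose vertices are
#'   all protein ids (isolated proteins included); no self-loops.
#' @export
buildSimilarityGraph <- function(proteins, evalueCutoff = 1e-5,
                                 weight = c("log_evalue", "bitscore"),
                                 cap = 200) {
  weight <- match.arg(weight)
  if (!length(proteins)) stop("need at least one protein", call. = FALSE)
  ids <- names(proteins)
  tab <- .blastAllVsAll(proteins, evalueCutoff)
  tab <- tab[tab$q != tab$s, , drop = FALSE]
  if (nrow(tab)) {
    w <- if (weight == "log_evalue") {
      pmin(-log10(pmax(tab$evalue, 1e-300)), cap)
    } else {
      tab$bits
    }
    if (weight == "log_evalue") w[tab$evalue == 0] <- cap
    ## unordered pair key; keep the max weight over directions/HSPs
    a <- pmin(tab$q, tab$s)
    b <- pmax(tab$q, tab$s)
    key <- paste(a, b, sep = "\r")
    best <- tapply(w, key, max)
    pairs <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
    edges <- data.frame(from = pairs[, 1], to = pairs[, 2],
                        weight = as.numeric(best),
                        stringsAsFactors = FALSE)
    g <- graph_from_data_frame(edges, directed = FALSE,
                               vertices = data.frame(name = ids))
  } else {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(ids)
  }
  g
}
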