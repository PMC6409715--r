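test_that("multi-record host files parse into sorted, coordinate-valid replicons", {
  specs <- generateFamilies(2L, 5L, seed = 11L)
  host <- implantProphage(specs[[1]], "hostIO", seed = 12L,
                          dir = tempdir(), nBackgroundGenes = 8L,
                          implantSize = 4L, positions = c(3L, 2L),
                          implantReplicon = c(1L, 2L))
  g <- readGenBank(host$path)
  expect_s4_class(g, "GenBankGenome")
  expect_length(replicons(g), 2L)
  for (rep in replicons(g)) {
    ft <- features(rep)
    expect_false(is.unsorted(GenomicRanges::start(ft)))
    expect_true(all(GenomicRanges::end(ft) <= length(rep@sequence)))
    expect_true(all(as.character(GenomicRanges::strand(ft)) %in% c("+", "-")))
  }
  expect_equal(genomeMetadata(g)$genome_size_bp,
               sum(vapply(replicons(g), function(r) length(r@sequence),
                          integer(1))))
})

test_that("CDS without /translation are translated from the span (table 11)", {
  specs <- generateFamilies(1L, 10L, seed = 13L)
  fx <- evolveGenome(specs[[1]], "gTr", seed = 14L, dir = tempdir(),
                     presenceProb = 1)
  lines <- readLines(fx$path)
  ## drop the /translation qualifier block of the first CDS
  tStart <- grep("/translation=", lines)[1]
  tEnd <- tStart
  while (tEnd + 1L <= length(lines) &&
         grepl("^ {21}[^/]", lines[tEnd + 1L])) tEnd <- tEnd + 1L
  path2 <- file.path(tempdir(), "gTr_stripped.gbk")
  writeLines(lines[-(tStart:tEnd)], path2)

  g <- readGenBank(path2)
  p <- extractCdsProteins(g, genomeId = "gTr")
  expect_length(p, 10L)
  ## independent oracle: seqinr translation of the span
  rep <- replicons(g)[[1]]
  ft <- features(rep)[1]  # stripped CDS is the first by construction order
  nt <- substr(as.character(rep@sequence), GenomicRanges::start(ft),
               GenomicRanges::end(ft))
  if (as.character(GenomicRanges::strand(ft)) == "-") {
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  }
  oracle <- paste(seqinr::translate(strsplit(tolower(nt), "")[[1]],
                                    numcode = 11), collapse = "")
  oracle <- sub("\\*$", "", oracle)
  got <- S4Vectors::mcols(features(rep))$translation[1]
  expect_identical(got, oracle)
  ## and it matches the protein the fixture actually encoded
  expect_identical(got, fx$manifest$protein[
    fx$manifest$locus_tag == S4Vectors::mcols(features(rep))$locus_tag[1]])
})

test_that("unparsable GenBank input is a format error", {
  empty <- tempfile(fileext = ".gbk")
  file.create(empty)
  expect_error(readGenBank(empty), "format error")
  junk <- tempfile(fileext = ".gbk")
  writeLines(c("this is", "not genbank"), junk)
  expect_error(readGenBank(junk), "format error")
  expect_error(readGenBank(tempfile()), "no such file")
})

test_that("GenBank write/read round trip preserves sequences, features and ids", {
  specs <- generateFamilies(1L, 6L, seed = 15L)
  fx <- evolveGenome(specs[[1]], "gRT", seed = 16L, dir = tempdir())
  g2 <- readGenBank(fx$path)
  rep1 <- fx$genome@replicons[[1]]
  rep2 <- replicons(g2)[[1]]
  expect_identical(as.character(rep2@sequence), as.character(rep1@sequence))
  expect_identical(S4Vectors::mcols(features(rep2))$locus_tag,
                   S4Vectors::mcols(features(rep1))$locus_tag)
  expect_equal(GenomicRanges::start(features(rep2)),
               GenomicRanges::start(features(rep1)))
  expect_identical(as.character(GenomicRanges::strand(features(rep2))),
                   as.character(GenomicRanges::strand(features(rep1))))
  expect_identical(S4Vectors::mcols(features(rep2))$translation,
                   S4Vectors::mcols(features(rep1))$translation)
})

test_that("protein extraction: cardinality, id uniqueness, duplicate tags, empty genomes", {
  specs <- generateFamilies(1L, 5L, seed = 17L)
  fx <- evolveGenome(specs[[1]], "gEx", seed = 18L, dir = tempdir(),
                     presenceProb = 1)
  p <- extractCdsProteins(fx$genome)
  expect_length(p, 5L)
  expect_false(anyDuplicated(names(p)) > 0)
  expect_true(all(S4Vectors::mcols(p)$family_label == specs[[1]]$label))
  ## duplicate locus tags get ordinal suffixes
  rep <- fx$genome@replicons[[1]]
  S4Vectors::mcols(rep@features)$locus_tag <- rep("orf1", 5)
  gDup <- new("GenBankGenome", genomeId = "gDup", replicons = list(rep),
              metadata = fx$genome@metadata)
  pd <- suppressMessages(extractCdsProteins(gDup))
  expect_setequal(sub("^.*\\|", "", names(pd)), paste0("orf1_", 1:5))
  ## zero-CDS replicon
  rep0 <- rep
  rep0@features <- rep@features[0]
  g0 <- new("GenBankGenome", genomeId = "g0", replicons = list(rep0),
            metadata = fx$genome@metadata)
  expect_length(extractCdsProteins(g0), 0L)
})

test_that("intergenic regions are the maximal CDS-free gaps", {
  mkRep <- function(len, starts, ends, topo = "linear") {
    gr <- GenomicRanges::GRanges("r", IRanges::IRanges(starts, ends),
                                 strand = "+")
    S4Vectors::mcols(gr)$locus_tag <- paste0("g", seq_along(starts))
    S4Vectors::mcols(gr)$product <- "p"
    S4Vectors::mcols(gr)$translation <- "M"
    new("Replicon", id = "r",
        sequence = Biostrings::DNAString(paste(rep("ACGT", len / 4),
                                               collapse = "")),
        topology = topo, features = gr)
  }
  ## two abutting CDS covering everything -> nothing
  expect_equal(nrow(extractIntergenicRegions(mkRep(900, c(1, 451),
                                                   c(450, 900)))), 0L)
  ## CDS [1,300],[601,900] -> one region 301..600
  r <- extractIntergenicRegions(mkRep(900, c(1, 601), c(300, 900)),
                                minLenNt = 90L)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end, r$length), c(301L, 600L, 300L))
  ## regions are disjoint from CDS spans
  rep2 <- mkRep(2000, c(201, 1001), c(400, 1400))
  regs <- extractIntergenicRegions(rep2, minLenNt = 1L)
  for (i in seq_len(nrow(regs))) {
    expect_true(all(regs$end[i] < c(201, 1001) |
                    regs$start[i] > c(400, 1400)))
  }
  ## circular wrap-around: single CDS [101,400] on 1000 nt -> one
  ## origin-spanning region of length 700, checked against a
  ## linearized-doubling oracle
  repC <- mkRep(1000, 101, 400, topo = "circular")
  rc <- extractIntergenicRegions(repC, minLenNt = 90L)
  expect_equal(nrow(rc), 1L)
  expect_true(rc$wrap)
  expect_equal(rc$length, 700L)
  doubled <- strrep(as.character(repC@sequence), 2)
  expect_identical(rc$sequence, substr(doubled, 401, 1100))
})

test_that("six-frame translation finds stop-free ORFs with correct genomic mapping", {
  ## poly-A: Lys codons in all frames, no stops
  regA <- list(sequence = strrep("A", 99), replicon_id = "r", start = 1L)
  orfs <- sixFrameTranslate(regA, minOrfAa = 30L)
  expect_length(orfs, 6L)
  fwd0 <- orfs[S4Vectors::mcols(orfs)$strand == "+" &
               S4Vectors::mcols(orfs)$frame == 0L]
  expect_identical(as.character(fwd0[[1]]), strrep("K", 33))
  expect_equal(S4Vectors::mcols(fwd0)$start, 1L)
  expect_equal(S4Vectors::mcols(fwd0)$end, 99L)
  ## stops in all six frames (TTAA repeat is its own reverse complement)
  regStop <- list(sequence = strrep("TTAA", 30), replicon_id = "r",
                  start = 1L)
  expect_length(sixFrameTranslate(regStop, minOrfAa = 30L), 0L)
  ## region shorter than 3 * minOrfAa
  expect_length(sixFrameTranslate(list(sequence = strrep("A", 100),
                                       replicon_id = "r", start = 1L),
                                  minOrfAa = 40L), 0L)
  ## reverse-complement symmetry: same candidates, strands flipped
  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
             collapse = "")
  a <- sixFrameTranslate(list(sequence = s, replicon_id = "r",
                              start = 101L), minOrfAa = 25L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  b <- sixFrameTranslate(list(sequence = rc, replicon_id = "r",
                              start = 101L), minOrfAa = 25L)
  keyA <- sort(paste(as.character(a), S4Vectors::mcols(a)$start,
                     S4Vectors::mcols(a)$end, S4Vectors::mcols(a)$strand))
  ## reversing the region mirrors coordinates within it and flips strands
  mirror <- 2L * 101L + 400L - 1L
  keyB <- sort(paste(as.character(b),
                     mirror - S4Vectors::mcols(b)$end,
                     mirror - S4Vectors::mcols(b)$start,
                     chartr("+-", "-+", S4Vectors::mcols(b)$strand)))
  expect_identical(keyA, keyB)
})

test_that("FASTA and GFF writers: round trips, empty inputs, strand column", {
  p <- cpRandomProteins(5L, seed = 19L)
  fa <- tempfile(fileext = ".faa")
  writeMultiFasta(p, fa)
  back <- readMultiFasta(fa)
  expect_identical(names(back), names(p))
  expect_identical(as.character(back), as.character(p))
  ## empty set -> empty valid file
  fa0 <- tempfile(fileext = ".faa")
  writeMultiFasta(Biostrings::AAStringSet(), fa0)
  expect_length(readMultiFasta(fa0), 0L)
  ## GFF: strand column and 1-based coordinates
  loci <- data.frame(replicon_id = "chr1", start = 100L, end = 900L,
                     n_consecutive = 5L, family_call = "FamA",
                     mean_norm_score = 0.42, strand = "-",
                     stringsAsFactors = FALSE)
  gff <- tempfile(fileext = ".gff3")
  writeLociGff(loci, gff)
  lines <- readLines(gff)
  expect_identical(lines[1], "##gff-version 3")
  cells <- strsplit(lines[2], "\t")[[1]]
  expect_identical(cells[c(1, 4, 5, 7)], c("chr1", "100", "900", "-"))
  expect_match(cells[9], "family_call=FamA")
})
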