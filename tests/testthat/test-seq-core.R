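test_that("translation follows the standard code, drops partial codons, marks stops", {
  expect_equal(as.character(translateFrame("ATGAAA", 0)), "MK")
  # frame 1 of ATGAAA reads TGA only: a stop, with AA dropped as partial
  expect_equal(as.character(translateFrame("ATGAAA", 1)), "*")
  expect_equal(as.character(translateFrame("ATGAAA", 2)), "E")
  expect_equal(as.character(translateFrame("AT", 0)), "")
  # a codon containing an ambiguity code translates as X
  expect_equal(as.character(translateFrame("ATGANA", 0)), "MX")
  expect_error(translateFrame("ATGAAA", 3), "frame")
  expect_error(translateFrame("ATGQAA", 0), "invalid DNA")
})

test_that("a 33 bp codon-preserving exon encodes 11 residues", {
  fx <- cachedFixture()
  tab <- exonTable(fx$model)
  e6 <- tab[tab$label == "pevk_6", ]
  expect_equal(e6$width, 33L)
  seq6 <- substr(as.character(genomeSeq(fx$model)), e6$start, e6$end)
  expect_equal(nchar(as.character(translateFrame(seq6, 0))), 11L)
})

test_that("reverse complement handles IUPAC codes and is an involution", {
  expect_equal(revComp("ACGT"), "ACGT")
  expect_equal(revComp("AAAA"), "TTTT")
  expect_equal(revComp("ACGTN"), "NACGT")
  expect_error(revComp("ACGQ"), "invalid DNA")
  set.seed(11)
  for (i in 1:40) {
    x <- paste(sample(c("A", "C", "G", "T", "N", "R", "Y", "W", "S"),
                      sample(5:80, 1), replace = TRUE), collapse = "")
    expect_equal(revComp(revComp(x)), x)
  }
})

test_that("splicing concatenates exons in genomic order and checks contracts", {
  # toy 3-exon gene, lengths 9 / 33 / 12
  genome <- paste0("ATGGCTGCT", strrep("C", 10), strrep("GCT", 11),
                   strrep("C", 10), "GCTGCTGCTGCT")
  m <- newGeneModel("toy", genome, data.frame(
    label = c("e1", "e2", "e3"),
    start = c(1, 20, 63), end = c(9, 52, 74),
    splicing_class = c("constitutive", "alternative", "constitutive")))
  full <- spliceTranscript(m)
  expect_equal(length(full), 9L + 33L + 12L)
  dropped <- spliceTranscript(m, included = c("e1", "e3"))
  expect_equal(length(dropped), 21L)
  expect_equal(as.character(transcriptSeq(dropped)),
               paste0("ATGGCTGCT", "GCTGCTGCTGCT"))
  # single-exon identity
  single <- newGeneModel("s", "ATGAAACCC",
                         data.frame(label = "e1", start = 1, end = 9))
  expect_equal(as.character(transcriptSeq(spliceTranscript(single))),
               "ATGAAACCC")
  expect_error(spliceTranscript(m, included = c("e1", "e2")), "constitutive")
  expect_error(spliceTranscript(m, included = c("e1", "e2", "nope")),
               "unknown")
})

test_that("adding an exon never shortens the transcript", {
  fx <- cachedFixture()
  g <- spliceGraph(fx$model)
  base <- spliceTranscript(fx$model, included = constitutiveExons(g))
  for (opt in optionalExons(g)) {
    grown <- spliceTranscript(fx$model,
                              included = c(constitutiveExons(g), opt))
    expect_gte(length(grown), length(base))
  }
})

test_that("gene model validity enforces ordering, introns and frame flags", {
  g <- strrep("ACGT", 30)
  expect_error(newGeneModel("bad", g, data.frame(
    label = c("a", "b"), start = c(1, 5), end = c(10, 20))), "intron|overlap")
  expect_error(newGeneModel("bad", g, data.frame(
    label = c("a", "b"), start = c(1, 12), end = c(10, 20))), "intron")
  m <- newGeneModel("ok", g, data.frame(
    label = c("a", "b"), start = c(1, 30), end = c(10, 33),
    splicing_class = c("constitutive", "alternative")))
  tab <- exonTable(m)
  expect_true(tab$frame_shifting[tab$label == "b"])  # 4 nt alternative exon
  expect_equal(tab$phase, c(0L, 1L))
})

test_that("FASTA round-trips preserve residues regardless of wrapping", {
  seqs <- Biostrings::DNAStringSet(c(one = strrep("ACGTTGCA", 30),
                                     two = "ACGT"))
  fa <- tempfile(fileext = ".fasta")
  writeFasta(seqs, fa)
  back <- readFastaDNA(fa)
  expect_equal(as.character(back), as.character(seqs))
  # manually wrapped differently
  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">one", substr(as.character(seqs[[1]]), 1, 100),
               substr(as.character(seqs[[1]]), 101, 240)), fa2)
  expect_equal(as.character(readFastaDNA(fa2)[[1]]),
               as.character(seqs[[1]]))
})

test_that("GFF3 round-trip is lossless and uses 1-based closed coordinates", {
  fx <- cachedFixture()
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fasta")
  writeGeneModel(fx$model, gff, fastaPath = fa)
  back <- readGeneModel(gff, fa)
  expect_identical(exonTable(back), exonTable(fx$model))
  expect_equal(as.character(genomeSeq(back)),
               as.character(genomeSeq(fx$model)))
  # a feature written as 10..42 spans 33 bases
  g <- strrep("ACGT", 30)
  gff2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "toy\ttest\tgene\t10\t42\t.\t+\t.\tID=toy",
               "toy\ttest\texon\t10\t42\t.\t+\t.\tID=e1;Parent=toy"), gff2)
  m <- readGeneModel(gff2, g)
  tab <- exonTable(m)
  expect_equal(tab$start, 10L)
  expect_equal(tab$end, 42L)
  expect_equal(tab$width, 33L)
})

test_that("minus-strand models are normalized to the coding strand on load", {
  fx <- cachedFixture()
  plus <- fx$model
  L <- length(genomeSeq(plus))
  tab <- exonTable(plus)
  flipped <- data.frame(label = rev(tab$label),
                        start = L - rev(tab$end) + 1L,
                        end = L - rev(tab$start) + 1L,
                        splicing_class = rev(tab$splicing_class))
  gff <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t-\t.\tID=%s",
                     geneId(plus), min(flipped$start), max(flipped$end),
                     geneId(plus)),
             sprintf("%s\ttest\texon\t%d\t%d\t.\t-\t.\tID=%s;Parent=%s;splicing_class=%s",
                     geneId(plus), flipped$start, flipped$end, flipped$label,
                     geneId(plus), flipped$splicing_class))
  writeLines(lines, gff)
  minusGenome <- revComp(as.character(genomeSeq(plus)))
  back <- readGeneModel(gff, minusGenome)
  expect_equal(as.character(genomeSeq(back)), as.character(genomeSeq(plus)))
  bt <- exonTable(back)
  expect_equal(bt$start, tab$start)
  expect_equal(bt$end, tab$end)
  expect_equal(bt$label, tab$label)
})
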