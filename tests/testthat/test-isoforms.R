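.toyModel <- function(k, exonLen = 6L) {
  # k alternative mini-exons plus two constitutive flanks
  nEx <- k + 2L
  starts <- seq(1L, by = exonLen + 10L, length.out = nEx)
  genome <- strrep("ACGTCA", (max(starts) + exonLen + 10L) %/% 6L + 2L)
  newGeneModel("toy", substr(genome, 1, max(starts) + exonLen + 9L),
               data.frame(label = c("left", sprintf("alt%02d", seq_len(k)),
                                    "right"),
                          start = starts, end = starts + exonLen - 1L,
                          splicing_class = c("constitutive",
                                             rep("alternative", k),
                                             "constitutive")))
}

test_that("isoform enumeration covers all 2^k combinations", {
  fx <- cachedFixture()
  expect_length(fx$isoforms, 4L)          # two optional exons -> 4 variants
  expect_length(enumerateIsoforms(spliceGraph(.toyModel(0L))), 1L)
  expect_length(enumerateIsoforms(spliceGraph(.toyModel(3L))), 8L)
  expect_error(enumerateIsoforms(spliceGraph(.toyModel(21L))), "20")
})

test_that("labels run A, B, ... by descending length; extremes are all/none", {
  fx <- cachedFixture()
  lens <- vapply(fx$isoforms, length, integer(1))
  expect_equal(names(fx$isoforms), c("A", "B", "C", "D"))
  expect_true(all(diff(lens) <= 0))
  opt <- optionalExons(spliceGraph(fx$model))
  expect_true(all(opt %in% includedExons(fx$isoforms$A)))
  expect_false(any(opt %in% includedExons(fx$isoforms$D)))
  # deterministic across recomputation
  again <- enumerateIsoforms(spliceGraph(fx$model))
  expect_identical(lapply(again, includedExons),
                   lapply(fx$isoforms, includedExons))
})

test_that("PEVK statistics reproduce the printed isoform lengths", {
  fx <- cachedFixture()
  tab <- isoformTable(fx$isoforms, fx$model)
  expect_equal(tab$pevk_length_aa[tab$isoform == "A"], 377L)
  expect_equal(tab$pevk_length_aa[tab$isoform == "D"], 205L)
  # dropping the 33 bp exon removes exactly 11 residues
  expect_equal(tab$pevk_length_aa[tab$isoform == "C"] -
                 tab$pevk_length_aa[tab$isoform == "D"], 11L)
  # the shortest variant also has the lower PEVK content
  expect_lt(tab$pevk_content[tab$isoform == "D"],
            tab$pevk_content[tab$isoform == "A"])
})

test_that("pevkStats measures the translated PEVK region", {
  codons <- c(P = "CCA", E = "GAA", V = "GTT", K = "AAA")
  coding <- strrep(paste(codons, collapse = ""), 10)
  genome <- paste0("ATGGCTGCT", strrep("T", 10), coding)
  m <- newGeneModel("t", genome, data.frame(
    label = c("flank", "pevk_1"),
    start = c(1, 20), end = c(9, 19 + nchar(coding))))
  iso <- spliceTranscript(m, label = "A")
  st <- pevkStats(iso, m)
  expect_equal(st$length_aa, 40L)
  expect_equal(st$content, 1.0)
  # an internal stop in the PEVK region is a contract error
  bad <- sub("CCA", "TAA", genome, fixed = TRUE)
  m2 <- newGeneModel("t", bad, data.frame(
    label = c("flank", "pevk_1"),
    start = c(1, 20), end = c(9, 19 + nchar(coding))))
  expect_error(pevkStats(spliceTranscript(m2, label = "A"), m2), "stop")
})

test_that("length ratios round half away from zero", {
  expect_equal(lengthRatioPercent(205, 377), 54L)
  expect_equal(lengthRatioPercent(7, 7), 100L)
  expect_equal(lengthRatioPercent(75, 530), 14L)
  expect_equal(lengthRatioPercent(1, 8), 13L)   # 12.5 rounds away from zero
  expect_error(lengthRatioPercent(0, 10), "positive")
  expect_error(lengthRatioPercent(11, 10), "exceed")
})

test_that("in silico PCR requires one full-length site per primer", {
  fx <- cachedFixture()
  ampC <- inSilicoPcr(fx$isoforms$C, fx$primers)
  ampD <- inSilicoPcr(fx$isoforms$D, fx$primers)
  expect_equal(ampC$size_bp, 926L)
  expect_equal(ampD$size_bp, 893L)
  expect_equal(ampC$size_bp - ampD$size_bp, 33L)
  # primers copied verbatim from the transcript ends span the whole molecule
  tr <- as.character(transcriptSeq(fx$isoforms$D))
  ends <- primerPair("ends", substr(tr, 1, 20),
                     revComp(substr(tr, nchar(tr) - 19, nchar(tr))))
  expect_equal(inSilicoPcr(fx$isoforms$D, ends)$size_bp, nchar(tr))
  # product size ignores sequence outside the primer span
  padded <- Biostrings::DNAString(paste0(strrep("G", 37), tr, strrep("C", 53)))
  expect_equal(inSilicoPcr(padded, ends)$size_bp, nchar(tr))
})

test_that("PCR errors name the failing primer and list multiple sites", {
  fx <- cachedFixture()
  nf <- primerPair("noFwd", strrep("ACGTT", 4), substr(
    revComp(as.character(transcriptSeq(fx$isoforms$A))), 1, 20))
  expect_error(inSilicoPcr(fx$isoforms$A, nf), "no amplification.*noFwd")
  dupSeq <- paste0("AAACCCGGGTTTAAACCCGG", strrep("T", 50),
                   "AAACCCGGGTTTAAACCCGG", strrep("T", 50),
                   "CATCATCATCATCATCATCA")
  dup <- primerPair("dup", "AAACCCGGGTTTAAACCCGG",
                    revComp("CATCATCATCATCATCATCA"))
  expect_error(inSilicoPcr(Biostrings::DNAString(dupSeq), dup),
               "ambiguous.*binds at")
})

test_that("degenerate IUPAC positions match their expansion sets", {
  core <- paste0("TTTTTTTTTTTTTTTTTTTT", strrep("C", 30), "GGGGGGGGGGGGGGGGGGGG")
  alleleA <- paste0("TTTTTTTTTATTTTTTTTTT", strrep("C", 30), "GGGGGGGGGGGGGGGGGGGG")
  alleleG <- paste0("TTTTTTTTTGTTTTTTTTTT", strrep("C", 30), "GGGGGGGGGGGGGGGGGGGG")
  pp <- primerPair("deg", "TTTTTTTTTRTTTTTTTTTT", revComp(substr(core, 51, 70)))
  expect_equal(inSilicoPcr(Biostrings::DNAString(alleleA), pp)$size_bp, 70L)
  expect_equal(inSilicoPcr(Biostrings::DNAString(alleleG), pp)$size_bp, 70L)
  expect_error(primerPair("short", "ACGTACGTAC", strrep("ACGT", 5)), "15-35")
})

test_that("amplicon ladders flag sample-specific sizes", {
  fx <- cachedFixture()
  lad <- ampliconLadder(fx$pools, fx$isoforms, fx$primers)
  dRows <- lad[lad$isoform == "D", ]
  expect_setequal(dRows$sample, c("thorax", "flight"))
  expect_true(all(dRows$sample_specific))      # absent from leg and head
  aRows <- lad[lad$isoform == "A", ]
  expect_false(any(aRows$sample_specific))     # present everywhere
  # identical pools: no flags at all
  same <- ampliconLadder(list(a = c("A", "B"), b = c("A", "B")),
                         fx$isoforms, fx$primers)
  expect_false(any(same$sample_specific))
  # empty pool: empty ladder
  none <- ampliconLadder(list(a = character(0)), fx$isoforms, fx$primers)
  expect_equal(nrow(none), 0L)
  expect_error(ampliconLadder(list(a = "Z"), fx$isoforms, fx$primers),
               "unknown isoform")
})
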