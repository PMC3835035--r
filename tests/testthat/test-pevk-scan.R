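test_that("pevkFraction counts bias-alphabet residues", {
  expect_equal(pevkFraction("PEVK"), 1.0)
  expect_equal(pevkFraction("GGGG"), 0.0)
  expect_equal(pevkFraction("PPEGVKAA"), 5 / 8)
  expect_error(pevkFraction(""), "empty")
  expect_error(pevkFraction("PEV*K"), "stop")
  expect_error(biasAlphabet(character(0)), "non-empty")
})

test_that("scanSegments finds maximal elevated segments", {
  # fully biased 12-mer: one segment covering everything
  s <- scanSegments(strrep("PEVK", 3), minLength = 10, minFraction = 0.6)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$start_aa, s$end_aa, s$fraction), c(1, 12, 1))
  # nothing qualifying
  expect_equal(nrow(scanSegments(strrep("G", 50))), 0L)
  # the PEVK core is reported without the flanking tails
  s2 <- scanSegments(paste0("AAAA", strrep("PEVK", 5), "AAAA"),
                     minLength = 10, minFraction = 0.9)
  expect_equal(nrow(s2), 1L)
  expect_equal(c(s2$start_aa, s2$end_aa), c(5, 24))
  expect_error(scanSegments("PEVK", minFraction = 0), "minFraction")
})

test_that("segments never cross a stop marker", {
  p <- paste0(strrep("PEVK", 4), "*", strrep("PEVK", 4))
  s <- scanSegments(p, minLength = 10, minFraction = 0.9)
  expect_equal(nrow(s), 2L)
  expect_true(all(s$end_aa < 17 | s$start_aa > 17))
})

test_that("scanSegments matches the brute-force oracle on random sequences", {
  set.seed(101)
  for (i in 1:120) {
    n <- sample(25:200, 1)
    p <- randomProtein(n, pevkPatch = TRUE, stops = i %% 4 == 0)
    t <- sample(c(0.5, 0.6, 0.7), 1)
    ml <- sample(c(5L, 10L), 1)
    got <- scanSegments(p, ml, t)
    want <- oracleScanSegments(p, ml, t)
    expect_equal(got$start_aa, want$start_aa,
                 info = sprintf("case %d seq %s t=%.1f ml=%d", i, p, t, ml))
    expect_equal(got$end_aa, want$end_aa,
                 info = sprintf("case %d", i))
  }
})

test_that("segments found at a strict threshold persist at a looser one", {
  # Maximal segments can shift their exact boundaries when the threshold
  # drops (a longer top window may absorb a shorter one and orphan a
  # sub-minimum flank), but every strict-threshold segment must still be
  # met by a loose-threshold segment, and coverage never vanishes.
  set.seed(77)
  for (i in 1:40) {
    p <- randomProtein(sample(40:150, 1), pevkPatch = TRUE)
    hi <- scanSegments(p, 10, 0.7)
    lo <- scanSegments(p, 10, 0.55)
    if (nrow(hi) == 0L) next
    expect_gt(nrow(lo), 0L)
    for (r in seq_len(nrow(hi))) {
      expect_true(any(lo$start_aa <= hi$end_aa[r] &
                        lo$end_aa >= hi$start_aa[r]),
                  info = sprintf("case %d segment %d", i, r))
    }
    expect_gte(sum(lo$length), max(hi$length))
  }
})

test_that("identical input yields identical segment lists", {
  p <- randomProtein(150)
  expect_identical(scanSegments(p), scanSegments(p))
})

test_that("threeFrameScan annotates the reading frame and maps coordinates", {
  coding <- paste(vapply(strsplit(strrep("PEVK", 10), "")[[1]], function(a) {
    c(P = "CCA", E = "GAA", V = "GTT", K = "AAA")[[a]]
  }, character(1)), collapse = "")
  dna <- paste0("G", coding, "TT")
  segs <- threeFrameScan(dna, minLength = 10, minFraction = 0.9)
  expect_true(all(segs$frame == 1L))
  expect_equal(segs$nt_start[1], 2L)
  # stop-codon-only input yields nothing
  expect_equal(nrow(threeFrameScan(strrep("TAA", 30))), 0L)
})

test_that("planted PEVK exons are recovered from the genomic three-frame scan", {
  fx <- cachedFixture()
  segs <- threeFrameScan(genomeSeq(fx$model))
  tab <- exonTable(fx$model)
  pevk <- tab[grepl("^pevk", tab$label) & tab$width >= 30, ]
  for (r in seq_len(nrow(pevk))) {
    hit <- segs[segs$nt_start <= pevk$start[r] + 3 &
                  segs$nt_end >= pevk$end[r] - 3, ]
    expect_equal(nrow(hit), 1L, info = pevk$label[r])
    # splice-boundary codons (donor GTx = Val, ...A+AG = Lys) may extend a
    # frame-space segment by at most one codon per edge
    expect_lte(pevk$start[r] - hit$nt_start, 3L)
    expect_lte(hit$nt_end - pevk$end[r], 3L)
  }
})

test_that("motif counting is exact, non-overlapping and leftmost-first", {
  expect_equal(countMotif("AYERPA"), 1L)
  expect_equal(countMotif("YERPYERP"), 2L)
  expect_equal(countMotif("YERYERP"), 1L)
  expect_equal(countMotif("GGGG"), 0L)
  expect_equal(motifPositions("AYERPAYERP"), c(2L, 7L))
  expect_error(countMotif("YERP", motif = ""), "non-empty")
})
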